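---
title: "Quantifying conformational diversity of TCR CDR loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational diversity of TCR CDR loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrshape)
```

## The scientific question

T-cell receptors recognise peptide-MHC through six hypervariable loops, the
complementarity-determining regions (CDR1-3) of the alpha and beta variable
domains. CDR1 and CDR2 are germline-encoded and, like their antibody
counterparts, adopt a small repertoire of recurrent "canonical"
conformations. CDR3 spans the V(D)J junction and is the main carrier of
antigen specificity; whether it, too, falls into discrete conformational
classes — and how strongly its conformation is determined by sequence or by
the V/J gene choice — is the question this package's analyses quantify.

The package provides the measurement machinery (region extraction,
anchor-aligned RMSD, clustering, sequence metrics, benchmarking statistics)
plus a synthetic repertoire generator that plants known structure into the
data, so every stage can be validated end to end against exact ground truth
without any external structure deposit.

## Region definitions and coordinate conventions

Loops and anchors are defined on IMGT positions, which this package consumes
(from the residue-number field of the input PDB) and never computes:

| Region | Anchors            | Loop      |
|--------|--------------------|-----------|
| CDR1   | 22-27, 39-44       | 28-38     |
| CDR2   | 51-56, 66-71       | 57-65     |
| CDR3   | 100-105, 118-123   | 106-117   |

All ranges are inclusive; IMGT numbers are 1-based. CDR3 length variation is
absorbed by insertion codes around the loop apex: within position 111 codes
ascend (111, 111A, 111B, ...) and within position 112 they descend (...,
112B, 112A, 112). This is the only ordering consistent with the IMGT
gap-filling convention, and `imgt_sort_key()` encodes it; an ordering
property test exercises it directly. Shorter loops vacate apex positions
symmetrically (`loop_positions()`).

Chains are identified by an explicit `chain_map`, never inferred from
sequence. Absent backbone atoms are represented as absent, never fabricated;
a region whose anchors are incomplete is flagged `anchors_degraded`, and
superposition proceeds on whatever atoms both partners share, erroring only
below 3 common atoms (where a rigid fit is underdetermined). This is the
weakest assumption that keeps the superposition well-posed.

## Structural distance

The core measurement is *align on anchors, measure on loops*:

1. match anchor backbone atoms (N, CA, C, O) between the two structures by
   (IMGT number, insertion code, atom name), dropping unmatched atoms
   pairwise;
2. least-squares rigid superposition (Kabsch, proper rotation) on those
   anchor atoms only — loop atoms never influence the fit;
3. RMSD over the matched loop backbone atoms.

For loops of unequal residue counts, where atomwise RMSD is undefined, the
backbone trace (4L atoms in canonical order) of each loop is interpolated by
a **natural cubic spline** per Cartesian coordinate, parameterised by knot
index normalised to [0, 1], and both traces are resampled at
`M = 4 * max(L_a, L_b)` uniform parameter values; the distance is the RMS
point-to-point deviation over those samples. Because the uniform sample
points coincide with the knots when the lengths are equal, the spline
distance degenerates *exactly* to the plain RMSD at equal lengths — this
RMSD-equivalence is a designed-in calibration, asserted to 1e-9 over
randomized fixtures. The exact spline parameterisation at unequal lengths is
otherwise a free design choice; a dense-resampling oracle (1000 samples)
bounds its behaviour in tests rather than pinning it.

Numerical choices: all distances in Angstrom; internal floating-point
comparisons use absolute tolerance 1e-9; the Kabsch reflection case is
resolved by flipping the smallest singular direction so the rotation is
always proper.

## Greedy threshold clustering

Clustering is a deliberately simple single pass: scanning items in index
order, an unclustered item seeds a new cluster and every later unclustered
item within strict distance tau of the *seed* joins it. (A common
statement of this procedure appends the distance value to the cluster in
its interior step; the only reading under which the output partitions the
index set is appending the item, and that is what is implemented.) The
procedure depends on item order, which is
therefore treated as part of the input: callers pin an id order for
reproducibility.

Two useful invariants hold on every output and are asserted post hoc:
the clusters partition `1..N`, and every non-seed member lies strictly
within tau of its seed. One intuitive property does **not** hold: the
cluster count is not monotone in tau. Absorbing an item into an earlier
cluster at a larger tau can prevent that item from seeding and absorbing
others, and random Euclidean configurations do produce such violations.
The tests therefore assert only the true boundary behaviour (all singletons
below the minimum distance, one cluster above the maximum).

At tau = 0 the strict comparison yields all singletons; this degenerate
case is permitted so that a 100% sequence-identity threshold (tau = 1 - s =
0) is well-defined in the identity scan.

## Sequence identity

Identity is a gap-penalty-free global alignment score normalised by the
longer sequence: with unit match, zero mismatch and zero gap cost, the
optimal number of matched pairs is exactly the longest-common-subsequence
length, so the implementation is the LCS dynamic programme (ties among
co-optimal alignments are irrelevant because only the score is used). Tests
check exhaustive equality with an independently written, batch-vectorised
DP over every pair of sequences up to length 6 on a three-letter alphabet,
and spot-check against a general alignment engine under the same scoring.

Sequence distance is `d = 1 - identity`; the identity threshold scan
clusters at `tau = 1 - s` for each identity level `s`.

## Benchmarking statistics

`region_report()` evaluates a predictor against references per record and
region. CDR loops use the anchor-aligned distance above. The framework (FW)
is defined as the complement of the three CDR loop ranges (the loops are
defined precisely, the framework only as everything else, so the
complement is the documented convention) — and FW/whole-chain RMSD are
measured after superposition on *all* backbone atoms of the chain
(`fit_framework_only = TRUE` switches to the framework-only alternative).

Sub-threshold counting is strict (`RMSD < 2.0` Angstrom counts, exactly 2.0
does not), matching "sub-2 Angstrom" usage. Quadrant classification and the
best-of ensemble fraction (`mean(pmin(a, b) < t)`) compare two predictors on
paired records.

The model-comparison statistic is `t = |mu_1 - mu_2| / sqrt((s_1^2 + s_2^2) / N)` with
`p = 2 * S_t(t, N - 1)` where `S_t` is the t survival function. Note this
pools by a single N with `N - 1` degrees of freedom and is *not* Welch's
test; the sigma is taken as the sample standard deviation (the formula
itself does not fix the denominator convention). A standard Welch option exists
behind `welch = TRUE` but is never the default, so that reported numbers
follow one declared convention.

t-SNE (perplexity 10, exact quadratic-time implementation on the
precomputed distance matrix) is for visualisation only: cluster colours are
always the greedy-clustering labels passed through, never re-derived from
the embedding.

## What the synthetic generator emulates — and what it does not

`generate_repertoire()` produces IMGT-numbered paired-chain structures with
idealised backbone geometry:

* a single framework scaffold per chain shared bit-for-bit by all records,
  so anchor superposition between any two records is the identity and
  planted loop distances are exact;
* canonical regions: K planted cluster centroids (smooth arcs between the
  anchor endpoints) displaced by exact multiples of `cluster_separation`
  (default 3 Angstrom) along one direction, plus isotropic Gaussian atom
  noise of RMS `noise_radius` (default 0.3 Angstrom);
* diffuse regions (`K = 0`): a fresh displacement per record drawn
  uniformly from a ball of radius `diffuse_spread` (default 6 Angstrom),
  emulating a quasi-continuous conformational landscape in which most loops
  are structural singletons at a 1 Angstrom threshold;
* VJ organisation (CDR3): each VJ gene pair is coherent with probability
  `vj_coherence` (defaults 0.44 for the first chain and 0.22 for the
  second, the coherence levels reported for natural TRAV-TRAJ and
  TRBV-TRBJ pairings); a coherent pair's members share one conformational
  mode, an incoherent pair's members split across two modes at least 6
  Angstrom apart — three times the 2 Angstrom coherence threshold, so the
  planted mode count is recovered exactly and the recovered
  single-cluster fraction is binomially distributed around the target;
* sequences: per-cluster random consensus strings mutated per residue at
  `seq_mutation_rate` (default 0.1); default CDR3 lengths 10-15 peaked at
  12-13, in the range typical of human TCR repertoires.

Deliberate non-goals: no physical stereochemistry (bond lengths/angles are
plausible constants; no forcefield validation), no side chains, no
sequence-to-structure coupling (a cluster's consensus sequence is random,
so sequence identity and structural distance are independent *within* the
repertoire — the calibrated `generate_identity_rmsd_pairs()` generator,
a linear map of a correlated bivariate normal clipped only far in the
tails, provides the planted-correlation counterpart). Consequently,
passing tests demonstrate that the *measurement pipeline* is correct and
well-calibrated, not that real repertoires behave like the synthetic ones;
analyses of real data replace the generator with structures read from disk
and inherit every downstream stage unchanged.

An antibody-mode preset (light/heavy chains, canonical CDR3 on the light
chain, diffuse on the heavy) mirrors the cross-receptor contrast used in
the repertoire analyses.

## Problem sizes

The shipped analyses and checks run at desk scale, chosen so the full suite
completes in minutes while keeping every statistical tolerance meaningful:
repertoires of 300-500 records (45,000-125,000 loop pairs per distance
matrix at the upper end), 50 VJ pairs of 10 structures for coherence
recovery, 10,000 draws for correlation recovery, a 45-record benchmark
fixture mirroring the canonical test-set size, and 100 generator seeds for
cluster-count recovery. All randomness flows from explicit integer seeds;
identical configurations byte-reproduce every artifact.

## Known limitations

* The spline distance at unequal lengths is one defensible
  parameterisation among several; only its equal-length limit is pinned.
* Greedy clustering is order-dependent by construction; cluster counts on
  real data are reproducible only once an id order is pinned, and
  comparisons across differently ordered runs carry that caveat.
* The default t statistic is not a standard two-sample test; it is kept
  for comparability with the convention above, with Welch's test
  available explicitly.
* The small-residue set {G, A, S, C, P, T} used for the flexibility
  fraction is a documented choice; every profile reports the set used.
* Multi-copy structures in one file are exposed via the chain map; the
  package does not adjudicate between copies.
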