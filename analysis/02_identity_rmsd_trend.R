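#!/usr/bin/env Rscript

# How predictive is CDR3 sequence identity of CDR3 structural similarity?
# Computes pairwise sequence identity and anchor-aligned loop RMSD over the
# diffuse repertoire's CDR3 loops, fits the linear trend, and stratifies the
# Pearson correlation at identity 0.65 -- the regime split above which
# sequence identity carries structural signal and below which it mostly
# does not.

suppressPackageStartupMessages(library(tcrshape))

dir.create("results", showWarnings = FALSE)
rep <- generate_repertoire(generator_config(
  n_records = 150, seed = 102, vj_coherence = NULL))

rows <- NULL
for (chain in c("alpha", "beta")) {
  loops <- collect_loops(rep$records, chain, "CDR3")
  D <- pairwise_distance_matrix(loops)
  seqs <- vapply(loops, `[[`, "", "sequence")
  S <- sequence_distance_matrix(seqs)
  ut <- upper.tri(D)
  pairs <- data.frame(identity = 1 - S[ut], rmsd = D[ut])
  tr <- identity_rmsd_trend(pairs, split = 0.65)
  cat(sprintf(
    "CDR3%s: n = %d pairs; PCC overall %.3f | id > 0.65: %.3f (n=%d) | id < 0.65: %.3f (n=%d)\n",
    substr(chain, 1, 1), tr$n, tr$pcc_overall, tr$pcc_high, tr$n_high,
    tr$pcc_low, tr$n_low))
  rows <- rbind(rows, data.frame(
    chain = chain, n_pairs = tr$n, pcc_overall = tr$pcc_overall,
    pcc_high = tr$pcc_high, n_high = tr$n_high,
    pcc_low = tr$pcc_low, n_low = tr$n_low,
    slope = tr$slope, intercept = tr$intercept))
}
write.csv(rows, "results/identity_rmsd_trend.csv", row.names = FALSE)
cat("Wrote results/identity_rmsd_trend.csv\n")
cat("Note: synthetic loop sequences are drawn independently of the planted\n")
cat("conformations, so the within-repertoire correlation is near zero by\n")
cat("construction; the calibrated-correlation generator (see\n")
cat("generate_identity_rmsd_pairs) provides the planted-PCC counterpart.\n")
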