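#' Canonical IMGT positions for a loop of a given length
#'
#' Positions are taken symmetrically from both ends of the region's loop
#' range, leaving the gap in the middle (the IMGT convention: shorter loops
#' vacate the top positions). Loops longer than the range -- possible only
#' for CDR3 -- receive insertion codes at positions 111 (ascending letters)
#' and 112 (descending letters), growing from both sides towards the loop
#' apex.
#'
#' @param region_name "CDR1", "CDR2" or "CDR3"
#' @param length loop length in residues
#' @return data.frame with columns `imgt`, `icode`, in canonical order
#' @export
#' @examples
#' loop_positions("CDR3", 13)$icode   # one 111A insertion
loop_positions <- function(region_name, length) {
  def <- region_definitions()[[match.arg(region_name, c("CDR1", "CDR2", "CDR3"))]]
  lo <- min(def$loop)
  hi <- max(def$loop)
  width <- hi - lo + 1L
  if (length < 1) stop_with("usage_error", "loop length must be >= 1")
  if (length <= width) {
    n_left <- ceiling(length / 2)
    n_right <- length - n_left
    imgt <- c(seq(lo, length.out = n_left),
              if (n_right > 0) seq(hi - n_right + 1L, hi))
    return(data.frame(imgt = as.integer(imgt), icode = "",
                      stringsAsFactors = FALSE))
  }
  if (region_name != "CDR3") {
    stop_with("usage_error",
              sprintf("%s loops cannot exceed %d residues", region_name, width))
  }
  extra <- length - width
  n111 <- ceiling(extra / 2)
  n112 <- extra - n111
  if (n111 > 26 || n112 > 26) stop_with("usage_error", "loop too long for IMGT insertion codes")
  imgt <- c(lo:111, rep(111L, n111), rep(112L, n112), 112:hi)
  icode <- c(rep("", 111 - lo + 1L), LETTERS[seq_len(n111)],
             if (n112 > 0) rev(LETTERS[seq_len(n112)]) else character(),
             rep("", hi - 112 + 1L))
  data.frame(imgt = as.integer(imgt), icode = icode, stringsAsFactors = FALSE)
}

# idealised backbone geometry: CA trace on a helix-like curve, fixed local
# offsets for N, C, O. Plausible scale, no stereochemical validation -- the
# analyses under test are purely geometric.
.BB_OFFSETS <- list(N = c(-1.20, 0.50, -0.40), CA = c(0, 0, 0),
                    C = c(1.20, 0.50, 0.40), O = c(1.30, 1.60, 0.60))
.REGION_BULGE <- list(CDR1 = c(3, 0, 0), CDR2 = c(0, 3, 0),
                      CDR3 = c(2.83, 2.83, 0))

scaffold_ca <- function(i, origin = c(0, 0, 0)) {
  cbind(2.3 * cos(1.75 * i) + origin[1],
        2.3 * sin(1.75 * i) + origin[2],
        1.50 * i + origin[3])
}

#' Shared framework scaffold for one chain
#'
#' Deterministic: every generated record shares this scaffold exactly, so
#' anchor superposition between records is the identity and planted loop
#' distances are controlled exactly.
#' @noRd
scaffold_atoms <- function(origin = c(0, 0, 0)) {
  pos <- 1:128
  ca <- scaffold_ca(pos, origin)
  aa <- AA20[(pos %% 20L) + 1L]
  atoms <- lapply(names(.BB_OFFSETS), function(at) {
    off <- .BB_OFFSETS[[at]]
    data.frame(imgt = pos, icode = "", aa = aa, atom = at,
               x = ca[, 1] + off[1], y = ca[, 2] + off[2], z = ca[, 3] + off[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, atoms)
}

runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

rball <- function(radius) runit() * radius * stats::runif(1)^(1 / 3)

random_sequence <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(old) sample(setdiff(AA20, old), 1), "")
  }
  paste(ch, collapse = "")
}

#' Loop atoms on an interpolated arc between the flanking anchor CAs
#' @noRd
build_loop_atoms <- function(region_name, positions, origin, delta, noise_sd,
                             seq_chars) {
  def <- region_definitions()[[region_name]]
  p_start <- scaffold_ca(min(def$loop) - 1L, origin)[1, ]
  p_end <- scaffold_ca(max(def$loop) + 1L, origin)[1, ]
  L <- nrow(positions)
  f <- seq_len(L) / (L + 1)
  ca <- outer(1 - f, p_start) + outer(f, p_end) +
    outer(sin(pi * f), .REGION_BULGE[[region_name]]) +
    matrix(delta, L, 3, byrow = TRUE)
  atoms <- lapply(names(.BB_OFFSETS), function(at) {
    off <- .BB_OFFSETS[[at]]
    data.frame(imgt = positions$imgt, icode = positions$icode, aa = seq_chars,
               atom = at,
               x = ca[, 1] + off[1], y = ca[, 2] + off[2], z = ca[, 3] + off[3],
               stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, atoms)
  if (noise_sd > 0) {
    at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
      matrix(stats::rnorm(nrow(at) * 3, sd = noise_sd), nrow(at), 3)
  }
  at
}

#' Configuration for the synthetic repertoire generator
#'
#' The generator plants exact statistical structure so every analysis stage
#' can be validated against known ground truth: discrete conformational
#' clusters with Gaussian coordinate noise for canonical loops (CDR1/CDR2
#' behaviour), diffuse non-clustering conformations for CDR3, a tunable
#' VJ-gene-to-structure coherence, and cluster-consensus-derived sequences.
#'
#' @param n_records number of paired records
#' @param loop_lengths per-region length distributions: named numeric vectors
#'   of probabilities, names = lengths
#' @param clusters_per_region named list `CDR1`, `CDR2`, `CDR3`; each entry a
#'   single K (both chains) or a length-2 vector (first chain, second chain).
#'   `K = 0` means no planted clusters: the region is diffuse, or -- when
#'   `vj_coherence` is set, CDR3 only -- conformational modes are organised
#'   per VJ gene pair.
#' @param noise_radius Angstrom; RMS displacement of each atom about its
#'   cluster centroid (isotropic Gaussian)
#' @param cluster_separation Angstrom; exact centroid-to-centroid RMSD
#'   between adjacent planted clusters (must exceed `2 * noise_radius` when
#'   K >= 2)
#' @param diffuse_spread Angstrom; radius of the uniform ball from which
#'   diffuse loop displacements are drawn
#' @param vj_vocab list per chain slot with elements `v`, `j`: gene label
#'   vocabularies
#' @param n_vj_pairs VJ pairs drawn (without replacement) per chain
#' @param vj_coherence length-2 vector (first chain, second chain): target
#'   proportion of VJ pairs whose members share a single CDR3 conformational
#'   mode; pairs failing the coin flip are split across two modes separated
#'   well beyond the 2 Angstrom coherence threshold. `NULL` disables the VJ
#'   organisation (fully diffuse CDR3).
#' @param seq_mutation_rate per-residue substitution probability from the
#'   cluster consensus sequence
#' @param receptor "tcr" (alpha/beta) or "antibody" (light/heavy)
#' @param seed integer RNG seed; generation is fully reproducible
#' @return a validated config list of class `generator_config`
#' @export
generator_config <- function(
    n_records = 200,
    loop_lengths = list(
      CDR1 = c(`11` = 1),
      CDR2 = c(`9` = 1),
      CDR3 = c(`10` = 0.08, `11` = 0.16, `12` = 0.26, `13` = 0.24,
               `14` = 0.16, `15` = 0.10)),
    clusters_per_region = list(CDR1 = 6, CDR2 = 4, CDR3 = 0),
    noise_radius = 0.3,
    cluster_separation = 3,
    diffuse_spread = 6,
    vj_vocab = NULL,
    n_vj_pairs = 20,
    vj_coherence = c(0.44, 0.22),
    seq_mutation_rate = 0.1,
    receptor = c("tcr", "antibody"),
    seed = 1) {
  receptor <- match.arg(receptor)
  kinds <- if (receptor == "tcr") c("alpha", "beta") else c("light", "heavy")
  if (is.null(vj_vocab)) {
    vj_vocab <- if (receptor == "tcr") {
      list(list(v = paste0("TRAV", 1:12), j = paste0("TRAJ", 1:20)),
           list(v = paste0("TRBV", 1:12), j = paste0("TRBJ", 1:13)))
    } else {
      list(list(v = paste0("IGLV", 1:10), j = paste0("IGLJ", 1:5)),
           list(v = paste0("IGHV", 1:10), j = paste0("IGHJ", 1:6)))
    }
  }
  for (reg in names(loop_lengths)) {
    p <- loop_lengths[[reg]]
    if (abs(sum(p) - 1) > 1e-9) {
      stop_with("config_error", paste("length probabilities must sum to 1 for", reg))
    }
  }
  if (noise_radius < 0) stop_with("config_error", "noise_radius must be >= 0")
  ks <- unlist(clusters_per_region)
  if (any(ks >= 2) && cluster_separation <= 2 * noise_radius) {
    stop_with("config_error",
              "cluster_separation must exceed 2 * noise_radius when K >= 2")
  }
  if (!is.null(vj_coherence) &&
      (any(vj_coherence < 0) || any(vj_coherence > 1))) {
    stop_with("config_error", "vj_coherence must lie in [0, 1]")
  }
  structure(list(n_records = n_records, loop_lengths = loop_lengths,
                 clusters_per_region = clusters_per_region,
                 noise_radius = noise_radius,
                 cluster_separation = cluster_separation,
                 diffuse_spread = diffuse_spread, vj_vocab = vj_vocab,
                 n_vj_pairs = n_vj_pairs, vj_coherence = vj_coherence,
                 seq_mutation_rate = seq_mutation_rate, receptor = receptor,
                 chain_kinds = kinds, seed = seed),
            class = "generator_config")
}

k_for_chain <- function(cfg, ci, region) {
  k <- cfg$clusters_per_region[[region]]
  if (length(k) == 1) k else k[ci]
}

draw_length <- function(cfg, region, n = 1) {
  p <- cfg$loop_lengths[[region]]
  as.integer(sample(names(p), n, replace = TRUE, prob = p))
}

#' Generate a synthetic IMGT-numbered repertoire with planted ground truth
#'
#' Every record shares one idealised framework scaffold per chain (so anchor
#' superposition between records is exact); loop conformations are planted
#' as cluster centroids (smooth arcs between the anchor endpoints, displaced
#' per cluster by exact multiples of `cluster_separation`) plus isotropic
#' Gaussian atom noise of RMS `noise_radius`. Diffuse regions draw a fresh
#' displacement per record from a ball of radius `diffuse_spread`. When
#' `vj_coherence` is set, CDR3 conformational modes are organised per VJ
#' pair: a coherent pair's members share one mode, an incoherent pair's
#' members are split across two modes at least 6 Angstrom apart. Sequences
#' are cluster-consensus strings mutated at `seq_mutation_rate`.
#'
#' @param config a [generator_config()]
#' @return list with `records` (list of `tcr_record`), `truth` (planted
#'   labels per chain/region, VJ pair tables with intended mode counts,
#'   consensus sequences), `config`
#' @export
generate_repertoire <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_records
    noise_sd <- config$noise_radius / sqrt(3)
    origins <- list(c(0, 0, 0), c(60, 0, 0))
    chains <- vector("list", 2)
    truth <- list(labels = list(), vj = list(), record_vj = list(),
                  consensus = list())
    for (ci in 1:2) {
      kind <- config$chain_kinds[ci]
      origin <- origins[[ci]]
      fw <- scaffold_atoms(origin)
      defs <- region_definitions()
      loop_all <- unlist(lapply(defs, function(d) seq(min(d$loop), max(d$loop))))
      fw <- fw[!(fw$imgt %in% loop_all), , drop = FALSE]

      vocab <- config$vj_vocab[[ci]]
      grid <- expand.grid(v = vocab$v, j = vocab$j, stringsAsFactors = FALSE)
      np <- min(config$n_vj_pairs, nrow(grid))
      vj_pairs <- grid[sample.int(nrow(grid), np), , drop = FALSE]
      rownames(vj_pairs) <- NULL
      pair_of <- rep(seq_len(np), length.out = n)

      plans <- list()
      lab_out <- list()
      cons_out <- list()
      for (reg in c("CDR1", "CDR2", "CDR3")) {
        K <- k_for_chain(config, ci, reg)
        coh <- if (!is.null(config$vj_coherence)) config$vj_coherence[ci] else NULL
        if (K > 0) {
          u <- runit()
          lens <- draw_length(config, reg, K)
          deltas <- lapply(seq_len(K), function(k) {
            (k - 1) * config$cluster_separation * u
          })
          cons <- vapply(lens, random_sequence, "")
          # every planted cluster is realised, remainder uniform
          labels <- c(seq_len(min(K, n)),
                      if (n > K) sample.int(K, n - K, replace = TRUE))
        } else if (reg == "CDR3" && !is.null(coh)) {
          coherent <- stats::runif(np) < coh
          mode_sep <- max(6, config$cluster_separation)
          pair_len <- draw_length(config, reg, np)
          deltas <- list()
          cons <- character(0)
          pair_modes <- vector("list", np)
          for (g in seq_len(np)) {
            d1 <- rball(config$diffuse_spread)
            m1 <- length(deltas) + 1L
            deltas[[m1]] <- d1
            cons[m1] <- random_sequence(pair_len[g])
            if (coherent[g]) {
              pair_modes[[g]] <- m1
            } else {
              m2 <- m1 + 1L
              deltas[[m2]] <- d1 + mode_sep * runit()
              cons[m2] <- random_sequence(pair_len[g])
              pair_modes[[g]] <- c(m1, m2)
            }
          }
          labels <- integer(n)
          for (g in seq_len(np)) {
            members <- which(pair_of == g)
            modes <- pair_modes[[g]]
            labels[members] <- modes[((seq_along(members) - 1L) %% length(modes)) + 1L]
          }
          lens <- vapply(deltas, function(d) 0L, 0L)  # placeholder
          mode_pair <- rep(seq_len(np), vapply(pair_modes, length, 0L))
          lens <- pair_len[mode_pair]
          truth$vj[[kind]] <- data.frame(
            v_gene = vj_pairs$v, j_gene = vj_pairs$j, coherent = coherent,
            n_modes = vapply(pair_modes, length, 0L),
            loop_length = pair_len, stringsAsFactors = FALSE)
        } else {
          lens <- draw_length(config, reg, n)
          deltas <- lapply(seq_len(n), function(i) rball(config$diffuse_spread))
          cons <- vapply(lens, random_sequence, "")
          labels <- seq_len(n)
        }
        plans[[reg]] <- list(lens = lens, deltas = deltas, cons = cons,
                             labels = labels)
        lab_out[[reg]] <- labels
        cons_out[[reg]] <- cons
      }
      truth$labels[[kind]] <- lab_out
      truth$consensus[[kind]] <- cons_out
      truth$record_vj[[kind]] <- data.frame(
        v_gene = vj_pairs$v[pair_of], j_gene = vj_pairs$j[pair_of],
        stringsAsFactors = FALSE)

      chains[[ci]] <- lapply(seq_len(n), function(i) {
        parts <- list(fw)
        for (reg in c("CDR1", "CDR2", "CDR3")) {
          pl <- plans[[reg]]
          lab <- pl$labels[i]
          L <- pl$lens[lab]
          seqs <- strsplit(mutate_sequence(pl$cons[lab],
                                           config$seq_mutation_rate), "")[[1]]
          parts[[length(parts) + 1L]] <- build_loop_atoms(
            reg, loop_positions(reg, L), origin, pl$deltas[[lab]], noise_sd,
            seqs)
        }
        chain_structure(kind, do.call(rbind, parts),
                        v_gene = vj_pairs$v[pair_of[i]],
                        j_gene = vj_pairs$j[pair_of[i]])
      })
    }
    records <- lapply(seq_len(n), function(i) {
      tcr_record(sprintf("SYN%04d", i), chains[[1]][[i]], chains[[2]][[i]],
                 source = "synthetic")
    })
    list(records = records, truth = truth, config = config)
  })
}

#' Write a synthetic repertoire to disk
#'
#' Emits one PDB per record, a V/J gene table CSV and the planted ground
#' truth as JSON.
#'
#' @param repertoire result of [generate_repertoire()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_repertoire <- function(repertoire, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in repertoire$records) {
    write_structure(rec, file.path(dir, paste0(rec$record_id, ".pdb")))
  }
  k1 <- repertoire$config$chain_kinds[1]
  k2 <- repertoire$config$chain_kinds[2]
  genes <- data.frame(
    record_id = vapply(repertoire$records, `[[`, "", "record_id"),
    alpha_v = repertoire$truth$record_vj[[k1]]$v_gene,
    alpha_j = repertoire$truth$record_vj[[k1]]$j_gene,
    beta_v = repertoire$truth$record_vj[[k2]]$v_gene,
    beta_j = repertoire$truth$record_vj[[k2]]$j_gene,
    stringsAsFactors = FALSE)
  utils::write.csv(genes, file.path(dir, "gene_table.csv"), row.names = FALSE)
  jsonlite::write_json(repertoire$truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Joint draws of (sequence identity, loop RMSD) with a planted correlation
#'
#' Draws from a correlated bivariate normal mapped linearly into the
#' identity/RMSD domain (identity centred at 0.5, RMSD centred at 3
#' Angstrom), clipped to the valid ranges far in the tails so the empirical
#' Pearson correlation converges to `target_pcc` as n grows.
#'
#' @param n_pairs number of pairs
#' @param target_pcc target Pearson correlation, in (-1, 0]
#' @param seed RNG seed
#' @return data.frame with columns `identity` (in \[0, 1\]) and `rmsd`
#'   (>= 0)
#' @export
generate_identity_rmsd_pairs <- function(n_pairs, target_pcc, seed = 1) {
  if (target_pcc > 0 || target_pcc <= -1) {
    stop_with("usage_error", "target_pcc must lie in (-1, 0]")
  }
  with_seed(seed, {
    z1 <- stats::rnorm(n_pairs)
    z2 <- target_pcc * z1 + sqrt(1 - target_pcc^2) * stats::rnorm(n_pairs)
    data.frame(identity = pmin(1, pmax(0, 0.5 + 0.12 * z1)),
               rmsd = pmax(0, 3 + 0.8 * z2))
  })
}

#' Rigidly displace one loop of a record by an exact RMSD
#'
#' Translates every atom of the named loop by a vector of length
#' `displacement`, leaving anchors and all other atoms untouched, so the
#' anchor-aligned loop RMSD to the original equals `displacement` exactly.
#' A fixture factory for benchmarking tests.
#'
#' @param record a `tcr_record`
#' @param chain_kind chain to perturb
#' @param region_name loop to perturb
#' @param displacement Angstrom
#' @param seed optional seed for a random displacement direction
#' @param direction optional explicit direction (3-vector, normalised
#'   internally); default +z when no seed is given
#' @return a modified copy of `record`
#' @export
perturb_record <- function(record, chain_kind, region_name, displacement,
                           seed = NULL, direction = NULL) {
  def <- region_definitions()[[match.arg(region_name, c("CDR1", "CDR2", "CDR3"))]]
  slot <- if (record$alpha$chain_kind == chain_kind) "alpha"
          else if (record$beta$chain_kind == chain_kind) "beta"
          else stop_with("extraction_error",
                         sprintf("no %s chain in %s", chain_kind, record$record_id))
  dir <- if (!is.null(direction)) direction / sqrt(sum(direction^2))
         else if (is.null(seed)) c(0, 0, 1)
         else with_seed(seed, runit())
  chain <- record[[slot]]
  at <- chain$atoms
  sel <- at$imgt >= min(def$loop) & at$imgt <= max(def$loop)
  if (!any(sel)) {
    stop_with("extraction_error",
              sprintf("region %s missing from %s", region_name, record$record_id))
  }
  at[sel, c("x", "y", "z")] <- at[sel, c("x", "y", "z")] +
    matrix(displacement * dir, sum(sel), 3, byrow = TRUE)
  record[[slot]] <- chain_structure(chain$chain_kind, at, chain$v_gene,
                                    chain$j_gene, chain$species)
  record
}
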