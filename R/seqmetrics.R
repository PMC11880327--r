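#' Longest-common-subsequence length of two strings
#'
#' Row-wise dynamic programme; the inner recurrence is vectorised with a
#' running maximum, which is valid because LCS rows are non-decreasing.
#' @noRd
lcs_length <- function(a_chars, b_chars) {
  lb <- length(b_chars)
  prev <- integer(lb + 1L)
  for (ch in a_chars) {
    tmp <- c(0L, prev[seq_len(lb)] + (b_chars == ch))
    prev <- cummax(pmax(prev, tmp))
  }
  prev[lb + 1L]
}

#' Pairwise sequence identity of two loop sequences
#'
#' Global alignment with unit match score and no mismatch, gap or insertion
#' penalties, normalised by the longer sequence:
#' `identity = matches / max(len_a, len_b)`. Under that scoring the maximal
#' number of matched pairs is exactly the longest-common-subsequence length,
#' which is how it is computed here; ties among co-optimal alignments are
#' irrelevant because only the score is used.
#'
#' @param a,b non-empty one-letter amino-acid strings
#' @return identity in \[0, 1\]
#' @export
#' @examples
#' sequence_identity("CASSLG", "CASSG")   # 5/6
sequence_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1 ||
      !nzchar(a) || !nzchar(b)) {
    stop_with("usage_error", "a and b must be single non-empty strings")
  }
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  lcs_length(ac, bc) / max(length(ac), length(bc))
}

#' Pairwise sequence distance matrix
#'
#' `d[i, j] = 1 - identity(i, j)`: symmetric with zero diagonal.
#'
#' @param sequences character vector of loop sequences
#' @param ids item identifiers (default: names, else indices)
#' @return symmetric numeric matrix
#' @export
sequence_distance_matrix <- function(sequences, ids = NULL) {
  n <- length(sequences)
  if (n < 2) stop_with("usage_error", "need >= 2 sequences")
  ids <- ids %||% (names(sequences) %||% as.character(seq_len(n)))
  chars <- strsplit(sequences, "", fixed = TRUE)
  lens <- lengths(chars)
  if (any(lens == 0)) stop_with("usage_error", "empty sequence")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      idn <- lcs_length(chars[[i]], chars[[j]]) / max(lens[i], lens[j])
      D[i, j] <- D[j, i] <- 1 - idn
    }
  }
  D
}

#' Greedy sequence clustering across identity thresholds
#'
#' For each identity threshold `s`, greedy-clusters the sequence distance
#' matrix at `tau = 1 - s` and reports the cluster count. Used to compare how
#' quickly sequence space fragments for different loop types as the identity
#' requirement tightens.
#'
#' @param sequences character vector of loop sequences
#' @param thresholds identity levels in (0, 1]
#' @return data.frame with columns `threshold`, `n_clusters`
#' @export
identity_threshold_scan <- function(sequences, thresholds) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop_with("usage_error", "identity thresholds must lie in (0, 1]")
  }
  D <- sequence_distance_matrix(sequences)
  n_clusters <- vapply(thresholds, function(s) {
    length(greedy_cluster(D, 1 - s)$clusters)
  }, 0L)
  data.frame(threshold = thresholds, n_clusters = n_clusters)
}

#' Amino-acid composition, per-position logo matrix and entropy
#'
#' Overall amino-acid frequencies are computed over all residues of all
#' sequences. Per-position outputs (position-frequency matrix for logos and
#' Shannon entropy in bits) require a single length class. The small-residue
#' fraction is the total frequency mass on `small_set` -- residues whose
#' small side chains are conducive to loop flexibility. The default set
#' {G, A, S, C, P, T} is a choice, not a community standard, and is always
#' reported alongside the fraction.
#'
#' @param sequences character vector of loop sequences
#' @param small_set amino acids counted as small (default G, A, S, C, P, T)
#' @param per_position compute per-position outputs? Default: only if all
#'   sequences share one length. Requesting them for mixed lengths is an
#'   error.
#' @return object of class `composition_profile`: list with
#'   `overall_frequencies` (named, sums to 1), `small_residue_fraction`,
#'   `small_set`, `n_sequences`, and (if applicable)
#'   `per_position_frequencies` (20 x L matrix) and `per_position_entropy`
#'   (bits)
#' @export
composition_profile <- function(sequences,
                                small_set = c("G", "A", "S", "C", "P", "T"),
                                per_position = NULL) {
  if (length(sequences) == 0) stop_with("usage_error", "no sequences")
  chars <- strsplit(sequences, "", fixed = TRUE)
  lens <- lengths(chars)
  if (any(lens == 0)) stop_with("usage_error", "empty sequence")
  one_length <- length(unique(lens)) == 1L
  per_position <- per_position %||% one_length
  if (per_position && !one_length) {
    stop_with("usage_error",
              "per-position profile requires sequences of one length")
  }
  all_aa <- unlist(chars)
  overall <- table(factor(all_aa, levels = AA20))
  overall <- as.numeric(overall) / length(all_aa)
  names(overall) <- AA20
  out <- list(overall_frequencies = overall,
              small_residue_fraction = sum(overall[names(overall) %in% small_set]),
              small_set = small_set,
              n_sequences = length(sequences))
  if (per_position) {
    L <- lens[1]
    mat <- do.call(rbind, chars)
    pfm <- vapply(seq_len(L), function(p) {
      as.numeric(table(factor(mat[, p], levels = AA20))) / nrow(mat)
    }, numeric(length(AA20)))
    rownames(pfm) <- AA20
    colnames(pfm) <- seq_len(L)
    ent <- apply(pfm, 2, function(p) {
      p <- p[p > 0]
      -sum(p * log2(p))
    })
    out$per_position_frequencies <- pfm
    out$per_position_entropy <- ent
  }
  structure(out, class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "<composition_profile: %d sequences; small-residue fraction %.3f (set %s)>\n",
    x$n_sequences, x$small_residue_fraction,
    paste(x$small_set, collapse = "")))
  invisible(x)
}
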