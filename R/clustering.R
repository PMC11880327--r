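#' Greedy threshold clustering of a distance matrix
#'
#' Single-pass greedy clustering: items are scanned in index order; an
#' unclustered item seeds a new cluster and every later unclustered item `j`
#' with `D[i, j] < tau` (strict) joins it. The first member of each cluster
#' is its representative (seed). The result is deterministic for a fixed item
#' order, and the order of `ids` is therefore part of the procedure: callers
#' who need a reproducible canonical order should sort their ids first.
#'
#' @param D symmetric non-negative distance matrix (zero diagonal); Angstrom
#'   for structural distances, dimensionless for sequence distances
#' @param tau clustering threshold (>= 0; at `tau = 0` the strict comparison
#'   yields all singletons apart from exact duplicates, which never join
#'   either)
#' @return object of class `cluster_assignment`: list with `clusters` (list
#'   of integer index vectors, seed first), `ids`, `threshold`
#' @export
greedy_cluster <- function(D, tau) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop_with("integrity_error", "D must be a square matrix")
  }
  if (any(D < -1e-12)) stop_with("integrity_error", "negative distances in D")
  if (max(abs(D - t(D))) > 1e-9) {
    stop_with("integrity_error", "D is not symmetric")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    stop_with("usage_error", "tau must be a single non-negative number")
  }
  n <- nrow(D)
  clustered <- logical(n)
  clusters <- list()
  for (i in seq_len(n)) {
    if (clustered[i]) next
    clustered[i] <- TRUE
    js <- unname(which(!clustered & D[i, ] < tau))
    js <- js[js > i]
    clustered[js] <- TRUE
    clusters[[length(clusters) + 1L]] <- c(i, js)
  }
  structure(list(clusters = clusters,
                 ids = rownames(D) %||% as.character(seq_len(n)),
                 threshold = tau),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d items, %d clusters at tau = %g>\n",
              length(x$ids), length(x$clusters), x$threshold))
  invisible(x)
}

#' Cluster representatives (seed items)
#'
#' @param assignment a `cluster_assignment`
#' @return integer vector of seed indices, one per cluster
#' @export
cluster_representatives <- function(assignment) {
  vapply(assignment$clusters, `[`, 0L, 1L)
}

#' Per-item cluster labels
#'
#' @param assignment a `cluster_assignment`
#' @return integer vector: `labels[i]` is the cluster index of item i
#' @export
cluster_labels <- function(assignment) {
  n <- length(assignment$ids)
  lab <- integer(n)
  for (k in seq_along(assignment$clusters)) lab[assignment$clusters[[k]]] <- k
  lab
}

#' Census of a cluster assignment
#'
#' @param assignment a `cluster_assignment`
#' @return list with `n_clusters`, `sizes` (in cluster order), `n_items`,
#'   `singleton_fraction`
#' @export
cluster_census <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  sizes <- lengths(assignment$clusters)
  structure(list(n_clusters = length(sizes), sizes = as.integer(sizes),
                 n_items = sum(sizes),
                 singleton_fraction = if (length(sizes)) mean(sizes == 1L) else NA_real_),
            class = "cluster_census")
}

#' @export
print.cluster_census <- function(x, ...) {
  cat(sprintf("<cluster_census: %d clusters / %d items, %.1f%% singletons>\n",
              x$n_clusters, x$n_items, 100 * x$singleton_fraction))
  invisible(x)
}

#' Export a cluster assignment as a tidy data.frame
#'
#' @param assignment a `cluster_assignment`
#' @return data.frame with columns `id`, `cluster_index`, `is_representative`
#' @export
cluster_table <- function(assignment) {
  lab <- cluster_labels(assignment)
  reps <- cluster_representatives(assignment)
  data.frame(id = assignment$ids, cluster_index = lab,
             is_representative = seq_along(lab) %in% reps,
             stringsAsFactors = FALSE)
}

#' VJ-gene structural coherence of CDR3 loops
#'
#' Groups loops by their (V gene, J gene) pair, discards pairs with fewer
#' than `min_group` structures, greedy-clusters each remaining group's
#' pairwise structural distances at `tau`, and reports how many distinct
#' conformations each gene pair adopts. `fraction_single_cluster` is the
#' proportion of counted pairs that map onto exactly one structural cluster
#' -- the degree to which the VJ recombination choice determines the CDR3
#' conformation.
#'
#' @param loops list of `loop_structure` carrying `v_gene` and `j_gene`
#' @param tau RMSD threshold in Angstrom (default 2)
#' @param min_group minimum structures per VJ pair to be counted (default 5)
#' @return object of class `vj_coherence_report`: list with `per_pair`
#'   data.frame (`v_gene`, `j_gene`, `n_structures`, `n_clusters`),
#'   `min_group_size`, `threshold`, `fraction_single_cluster`
#' @export
vj_coherence <- function(loops, tau = 2, min_group = 5) {
  v <- vapply(loops, `[[`, "", "v_gene")
  j <- vapply(loops, `[[`, "", "j_gene")
  if (anyNA(v) || anyNA(j)) {
    stop_with("usage_error", "every loop must carry V and J gene labels")
  }
  grp <- split(seq_along(loops), paste(v, j, sep = "\t"))
  grp <- grp[lengths(grp) >= min_group]
  if (length(grp) == 0) {
    warning("no VJ pair reaches min_group; empty coherence report")
    per <- data.frame(v_gene = character(), j_gene = character(),
                      n_structures = integer(), n_clusters = integer(),
                      stringsAsFactors = FALSE)
    return(structure(list(per_pair = per, min_group_size = min_group,
                          threshold = tau,
                          fraction_single_cluster = NA_real_),
                     class = "vj_coherence_report"))
  }
  nclust <- vapply(grp, function(idx) {
    D <- pairwise_distance_matrix(loops[idx])
    length(greedy_cluster(D, tau)$clusters)
  }, 0L)
  keys <- do.call(rbind, strsplit(names(grp), "\t", fixed = TRUE))
  per <- data.frame(v_gene = keys[, 1], j_gene = keys[, 2],
                    n_structures = as.integer(lengths(grp)),
                    n_clusters = as.integer(nclust),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  structure(list(per_pair = per, min_group_size = min_group, threshold = tau,
                 fraction_single_cluster = mean(per$n_clusters == 1L)),
            class = "vj_coherence_report")
}

#' @export
print.vj_coherence_report <- function(x, ...) {
  cat(sprintf(
    "<vj_coherence: %d VJ pairs (>= %d structures) at %g A; %.1f%% single-cluster>\n",
    nrow(x$per_pair), x$min_group_size, x$threshold,
    100 * x$fraction_single_cluster))
  invisible(x)
}

#' Reproducible uniform sampling without replacement
#'
#' @param records a list (or vector)
#' @param n sample size (must not exceed the population)
#' @param seed RNG seed; the global RNG state is left untouched
#' @return sampled subset, in sampled order
#' @export
sample_records <- function(records, n, seed) {
  if (n > length(records)) {
    stop_with("size_error", sprintf("cannot sample %d of %d records", n,
                                    length(records)))
  }
  idx <- with_seed(seed, sample.int(length(records), n))
  records[idx]
}
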