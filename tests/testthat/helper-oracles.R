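# Independent oracles and fixture builders used across test files.
# These deliberately re-derive results by a different route than the package
# (literal pseudocode transcriptions, brute-force optimisation, vectorised
# dynamic programming) so that agreement is evidence, not tautology.

# --- fixture builders -------------------------------------------------------

# CA-only loop with explicit coordinates; anchors default to a fixed
# non-degenerate 4-point frame shared by partners unless overridden.
default_anchor_ca <- function() {
  rbind(c(0, 10, 0), c(5, 10, 0), c(0, 10, 5), c(5, 10, 5))
}

toy_loop <- function(ca, anchors_ca = default_anchor_ca(), region = "CDR3",
                     parent = "toy", chain = "alpha",
                     v_gene = NA_character_, j_gene = NA_character_) {
  pos <- loop_positions(region, nrow(ca))
  def <- region_definitions()[[region]]
  loopdf <- data.frame(imgt = pos$imgt, icode = pos$icode, aa = "A",
                       atom = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                       stringsAsFactors = FALSE)
  anum <- def$anchors[seq_len(nrow(anchors_ca))]
  anchdf <- data.frame(imgt = anum, icode = "", aa = "A", atom = "CA",
                       x = anchors_ca[, 1], y = anchors_ca[, 2],
                       z = anchors_ca[, 3], stringsAsFactors = FALSE)
  loop_structure(parent, chain, region, loopdf, anchdf,
                 v_gene = v_gene, j_gene = j_gene)
}

# Full-backbone loop (4 atoms per residue) for spline tests; coordinates are
# a smooth random trace so the spline has a sensible geometry.
full_loop <- function(L, seed, region = "CDR3", parent = "toy",
                      anchors_ca = default_anchor_ca(), jitter = 0.3) {
  set.seed(seed)
  pos <- loop_positions(region, L)
  base <- cbind(seq(0, 3 * L, length.out = L),
                2 * sin(seq(0, pi, length.out = L)),
                cumsum(rnorm(L, sd = jitter)))
  offs <- list(N = c(-1.2, 0.5, -0.4), CA = c(0, 0, 0),
               C = c(1.2, 0.5, 0.4), O = c(1.3, 1.6, 0.6))
  loopdf <- do.call(rbind, lapply(names(offs), function(at) {
    data.frame(imgt = pos$imgt, icode = pos$icode, aa = "A", atom = at,
               x = base[, 1] + offs[[at]][1], y = base[, 2] + offs[[at]][2],
               z = base[, 3] + offs[[at]][3], stringsAsFactors = FALSE)
  }))
  def <- region_definitions()[[region]]
  anum <- def$anchors[seq_len(nrow(anchors_ca))]
  anchdf <- data.frame(imgt = anum, icode = "", aa = "A", atom = "CA",
                       x = anchors_ca[, 1], y = anchors_ca[, 2],
                       z = anchors_ca[, 3], stringsAsFactors = FALSE)
  loop_structure(parent, "alpha", region, loopdf, anchdf)
}

# Apply one rigid transform (rotation about z by theta + translation) to all
# atoms of a loop structure, rebuilding it.
rigid_move_loop <- function(loop, theta = 0, shift = c(0, 0, 0)) {
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  mv <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[1]
    df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  loop_structure(loop$parent_id, loop$chain_kind, loop$region_name,
                 mv(loop$loop_atoms), mv(loop$anchor_atoms),
                 v_gene = loop$v_gene, j_gene = loop$j_gene)
}

# --- greedy clustering: literal pseudocode transcription --------------------

greedy_cluster_oracle <- function(D, tau) {
  N <- nrow(D)
  clusters <- list()
  clustered_indices <- integer(0)
  count <- 0
  for (i in seq_len(N)) {
    if (!(i %in% clustered_indices)) {
      count <- count + 1
      clusters[[count]] <- i
      clustered_indices <- c(clustered_indices, i)
      if (i < N) {
        for (j in (i + 1):N) {
          if (!(j %in% clustered_indices) && D[i, j] < tau) {
            clusters[[count]] <- c(clusters[[count]], j)
            clustered_indices <- c(clustered_indices, j)
          }
        }
      }
    }
  }
  clusters
}

random_distance_matrix <- function(n, spread = 3) {
  X <- matrix(rnorm(n * 3, sd = spread), n)
  as.matrix(dist(X))
}

# --- LCS oracle: DP vectorised across all pairs at once ---------------------
# Computes LCS lengths for many (a, b) index pairs simultaneously; an
# independent formulation of the recurrence (cell-by-cell max over three
# predecessors, explicit serial inner dependency resolved by iteration).
lcs_oracle_batch <- function(seqs_a, seqs_b) {
  stopifnot(length(seqs_a) == length(seqs_b))
  pad_to <- max(nchar(c(seqs_a, seqs_b)))
  # pad with symbols that can never match each other or real letters
  pad <- function(s, ch) {
    vapply(s, function(x) {
      paste0(x, strrep(ch, pad_to - nchar(x)))
    }, "", USE.NAMES = FALSE)
  }
  A <- do.call(rbind, strsplit(pad(seqs_a, "%"), "", fixed = TRUE))
  B <- do.call(rbind, strsplit(pad(seqs_b, "#"), "", fixed = TRUE))
  np <- nrow(A)
  L <- pad_to
  prev <- replicate(L + 1, integer(np), simplify = FALSE)
  for (i in seq_len(L)) {
    cur <- vector("list", L + 1)
    cur[[1]] <- integer(np)
    for (j in seq_len(L)) {
      m <- as.integer(A[, i] == B[, j])
      cur[[j + 1]] <- pmax(prev[[j + 1]], cur[[j]], prev[[j]] + m)
    }
    prev <- cur
  }
  prev[[L + 1]]
}

# --- misc -------------------------------------------------------------------

silhouette_mean <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# exact t-distribution survival by numerical integration (independent of pt)
t_surv_integrate <- function(t, df) {
  stats::integrate(function(x) stats::dt(x, df), t, Inf,
                   rel.tol = 1e-12)$value
}
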