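#' Perplexity-calibrated input affinities from a distance matrix
#'
#' Binary-searches a per-point Gaussian precision so that the conditional
#' distribution over neighbours has the requested perplexity, then
#' symmetrises.
#' @noRd
tsne_affinities <- function(D, perplexity, tol = 1e-5) {
  n <- nrow(D)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  D2 <- D^2
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    beta <- 1
    lo <- -Inf
    hi <- Inf
    for (iter in 1:60) {
      p <- exp(-d2 * beta)
      sp <- sum(p)
      if (sp == 0) {
        H <- 0
        p[] <- 0
      } else {
        H <- log(sp) + beta * sum(d2 * p) / sp
        p <- p / sp
      }
      diff <- H - target
      if (abs(diff) < tol) break
      if (diff > 0) {            # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of a precomputed distance matrix
#'
#' Exact (quadratic-time) t-SNE for visualising loop distance matrices in two
#' dimensions. The embedding is for visualisation only: any cluster labels
#' supplied in `labels` are passed through untouched, never re-derived from
#' the embedded coordinates.
#'
#' @param D symmetric distance matrix
#' @param perplexity neighbourhood size parameter (default 10); requires
#'   `nrow(D) > 3 * perplexity`
#' @param seed RNG seed for the random initialisation
#' @param labels optional per-item labels (e.g. from [cluster_labels()])
#'   carried into the output as the `cluster` column
#' @param n_iter gradient-descent iterations (default 500)
#' @return data.frame with columns `id`, `x`, `y` and, if given, `cluster`
#' @export
embed_tsne <- function(D, perplexity = 10, seed = 1, labels = NULL,
                       n_iter = 500) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n <= 3 * perplexity) {
    stop_with("usage_error", "need more than 3 * perplexity items")
  }
  if (!is.null(labels) && length(labels) != n) {
    stop_with("usage_error", "labels must match the matrix size")
  }
  P <- tsne_affinities(D, perplexity)
  exaggeration <- 12
  eta <- 200
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pe <- P * exaggeration
  for (it in seq_len(n_iter)) {
    Puse <- if (it <= 100) Pe else P
    momentum <- if (it <= 250) 0.5 else 0.8
    sy <- rowSums(Y^2)
    num <- 1 / (1 + outer(sy, sy, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    gains <- pmax(0.01, ifelse(sign(grad) != sign(V), gains + 0.2, gains * 0.8))
    V <- momentum * V - eta * gains * grad
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  out <- data.frame(id = rownames(D) %||% as.character(seq_len(n)),
                    x = Y[, 1], y = Y[, 2], stringsAsFactors = FALSE)
  if (!is.null(labels)) out$cluster <- labels
  out
}
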