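#' Least-squares rigid superposition (Kabsch)
#'
#' Proper rotation + translation minimising the summed squared deviation of
#' `P` (mobile, n x 3) onto `Q` (reference, n x 3). The reflection case is
#' corrected by flipping the smallest singular direction, so the returned
#' rotation always has determinant +1.
#'
#' @return list with `rotation` (3 x 3), `translation` (length 3); the fitted
#'   mobile coordinates are `P %*% t(rotation) + translation` (row-vectors).
#' @noRd
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  pbar <- colMeans(P)
  qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar)
  Qc <- sweep(Q, 2, qbar)
  H <- crossprod(Pc, Qc)                      # sum_i p_i q_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(qbar - R %*% pbar))
}

#' Superpose one loop onto another by anchor backbone atoms
#'
#' Anchor atoms are matched between the two structures by
#' (IMGT number, insertion code, atom name); atoms absent in either partner
#' are dropped pairwise. At least 3 common atoms are required, otherwise the
#' rigid fit is underdetermined. The loop atoms never influence the fit.
#'
#' @param mobile,reference `loop_structure` objects of the same region
#' @return object of class `superposition` with fields `rotation` (proper,
#'   det +1), `translation` (Angstrom), `anchor_rmsd`, `n_atoms_used`
#' @export
superpose_by_anchors <- function(mobile, reference) {
  stopifnot(inherits(mobile, "loop_structure"), inherits(reference, "loop_structure"))
  if (mobile$region_name != reference$region_name) {
    stop_with("usage_error", "cannot superpose loops of different regions")
  }
  common <- intersect(mobile$anchor_key, reference$anchor_key)
  if (length(common) < 3) {
    stop_with("underdetermined_error",
              sprintf("only %d common anchor atoms (need >= 3)", length(common)))
  }
  P <- mobile$anchor_xyz[match(common, mobile$anchor_key), , drop = FALSE]
  Q <- reference$anchor_xyz[match(common, reference$anchor_key), , drop = FALSE]
  k <- kabsch(P, Q)
  fitted <- P %*% t(k$rotation) + matrix(k$translation, nrow(P), 3, byrow = TRUE)
  structure(list(rotation = k$rotation, translation = k$translation,
                 anchor_rmsd = sqrt(mean(rowSums((fitted - Q)^2))),
                 n_atoms_used = length(common)),
            class = "superposition")
}

#' Apply a superposition to a coordinate matrix
#'
#' @param sup a `superposition`
#' @param xyz n x 3 matrix of row-vector coordinates
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(sup, xyz) {
  stopifnot(inherits(sup, "superposition"))
  xyz %*% t(sup$rotation) + matrix(sup$translation, nrow(xyz), 3, byrow = TRUE)
}

loop_distance <- function(value, kind, n_points) {
  structure(list(value = value, kind = kind, n_points = n_points),
            class = "loop_distance")
}

#' @export
print.loop_distance <- function(x, ...) {
  cat(sprintf("<loop_distance %.4f A (%s, %d points)>\n", x$value, x$kind,
              x$n_points))
  invisible(x)
}

#' Anchor-aligned backbone RMSD between two equal-length loops
#'
#' Superposes `a` onto `b` by anchor backbone atoms, then measures the
#' root-mean-square deviation over loop backbone atoms (N, CA, C, O) matched
#' by (IMGT number, insertion code, atom name). There is no re-fitting on the
#' loop atoms: align on anchors, measure on loops.
#'
#' @param a,b `loop_structure` objects of the same region with equal residue
#'   counts (for unequal lengths use [upsampled_distance()])
#' @return a `loop_distance` with `kind = "rmsd_equal_length"`
#' @export
loop_rmsd <- function(a, b) {
  if (a$region_name != b$region_name) {
    stop_with("usage_error", "loops are of different regions")
  }
  if (a$n_residues != b$n_residues) {
    stop_with("length_error",
              "loops differ in residue count; use upsampled_distance()")
  }
  sup <- superpose_by_anchors(a, b)
  common <- intersect(a$loop_key, b$loop_key)
  if (length(common) == 0) stop_with("empty_error", "no matched loop atoms")
  A <- apply_superposition(sup, a$loop_xyz[match(common, a$loop_key), , drop = FALSE])
  B <- b$loop_xyz[match(common, b$loop_key), , drop = FALSE]
  loop_distance(sqrt(mean(rowSums((A - B)^2))), "rmsd_equal_length",
                length(common))
}

#' Spline up-sampled backbone distance for loops of unequal length
#'
#' Each loop's ordered backbone trace (N, CA, C, O per residue, canonical
#' residue order) is interpolated by a natural cubic spline per Cartesian
#' coordinate over a parameter normalised to \[0, 1\] at the atom knots. Both
#' traces are resampled at `M = 4 * max(L_a, L_b)` uniformly spaced parameter
#' values and the root-mean-square point-to-point distance over the M samples
#' is returned. When the loops have equal residue counts the sample points
#' coincide with the knots, so the value degenerates exactly to the plain
#' anchor-aligned RMSD -- the distance is RMSD-equivalent at equal lengths by
#' construction.
#'
#' @param a,b `loop_structure` objects of the same region, each with >= 2
#'   residues and a complete backbone
#' @return a `loop_distance` (`kind = "spline_upsampled"` when lengths
#'   differ)
#' @export
upsampled_distance <- function(a, b) {
  if (a$region_name != b$region_name) {
    stop_with("usage_error", "loops are of different regions")
  }
  if (a$n_residues < 2 || b$n_residues < 2) {
    stop_with("too_short_error", "spline up-sampling needs >= 2 residues")
  }
  if (!a$complete_backbone || !b$complete_backbone) {
    stop_with("incomplete_backbone_error",
              "spline up-sampling needs a complete N, CA, C, O backbone")
  }
  sup <- superpose_by_anchors(a, b)
  Ta <- apply_superposition(sup, a$loop_xyz)
  Tb <- b$loop_xyz
  M <- 4L * max(a$n_residues, b$n_residues)
  resample <- function(Tr) {
    x <- seq(0, 1, length.out = nrow(Tr))
    xout <- seq(0, 1, length.out = M)
    vapply(1:3, function(k) {
      stats::spline(x, Tr[, k], xout = xout, method = "natural")$y
    }, numeric(M))
  }
  Sa <- resample(Ta)
  Sb <- resample(Tb)
  kind <- if (a$n_residues == b$n_residues) "rmsd_equal_length" else "spline_upsampled"
  loop_distance(sqrt(mean(rowSums((Sa - Sb)^2))), kind, M)
}

#' Pairwise structural distance matrix over a set of loops
#'
#' Entry (i, j) is the anchor-aligned backbone RMSD when loops i and j have
#' the same residue count, and the spline up-sampled distance otherwise.
#'
#' @param loops list of `loop_structure`, all of one region and chain kind
#' @param ids item identifiers (default: parent record ids, made unique)
#' @return symmetric numeric matrix with zero diagonal and `ids` as dimnames
#' @export
pairwise_distance_matrix <- function(loops, ids = NULL) {
  n <- length(loops)
  stopifnot(n >= 1)
  regs <- unique(vapply(loops, `[[`, "", "region_name"))
  kinds <- unique(vapply(loops, `[[`, "", "chain_kind"))
  if (length(regs) != 1 || length(kinds) != 1) {
    stop_with("usage_error", "all loops must share region_name and chain_kind")
  }
  ids <- ids %||% make.unique(vapply(loops, `[[`, "", "parent_id"))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n == 1) return(D)
  nres <- vapply(loops, `[[`, 0L, "n_residues")
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch({
        if (nres[i] == nres[j]) loop_rmsd(loops[[i]], loops[[j]])$value
        else upsampled_distance(loops[[i]], loops[[j]])$value
      }, tcrshape_error = function(e) {
        stop_with("pair_error", sprintf("distance (%s, %s) failed: %s",
                                        ids[i], ids[j], conditionMessage(e)))
      })
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Write / read a distance matrix as headered CSV
#'
#' Ids form the header row and first column. Values are written with 17
#' significant digits so the CSV re-reads bit-exactly.
#'
#' @param D symmetric matrix with dimnames
#' @param path CSV file
#' @return `path` invisibly (write); the matrix (read)
#' @export
write_distance_csv <- function(D, path) {
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  txt <- matrix(formatC(D, digits = 17, format = "g"), nrow(D),
                dimnames = dimnames(D))
  utils::write.csv(as.data.frame(txt, check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        colClasses = "character")
  D <- apply(as.matrix(df), c(1, 2), as.numeric)
  dimnames(D) <- list(rownames(df), colnames(df))
  D
}
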