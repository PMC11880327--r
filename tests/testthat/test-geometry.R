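test_that("anchor superposition recovers exact rigid motions", {
  ca <- rbind(c(0, 0, 0), c(1.5, 1, 0), c(3, 0, 1))
  a <- toy_loop(ca)
  # identical partner: identity transform
  sup <- superpose_by_anchors(a, a)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-12)
  expect_equal(sup$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sup$anchor_rmsd, 0, tolerance = 1e-12)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-12)

  # partner rotated 90 degrees about z and translated (5, 0, 0)
  b <- rigid_move_loop(a, theta = pi / 2, shift = c(5, 0, 0))
  sup2 <- superpose_by_anchors(a, b)
  expect_lt(sup2$anchor_rmsd, 1e-6)
  expect_equal(det(sup2$rotation), 1, tolerance = 1e-9)
  moved <- apply_superposition(sup2, a$loop_xyz)
  expect_lt(max(abs(moved - b$loop_xyz)), 1e-6)
  expect_lt(loop_rmsd(a, b)$value, 1e-6)
})

test_that("superposition matches brute-force minimisation and bio3d", {
  # 6-atom anchor frame with one atom displaced by 1 A
  anch <- rbind(c(0, 10, 0), c(5, 10, 0), c(0, 10, 5), c(5, 10, 5),
                c(2.5, 12, 2.5), c(2.5, 8, 2.5))
  anch_b <- anch
  anch_b[6, ] <- anch_b[6, ] + c(0, 0, 1)
  a <- toy_loop(rbind(c(0, 0, 0), c(1, 0, 0)), anchors_ca = anch)
  b <- toy_loop(rbind(c(0, 0, 0), c(1, 0, 0)), anchors_ca = anch_b)
  sup <- superpose_by_anchors(a, b)

  # oracle 1: numeric optimisation over rotation angles + translation
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    P <- anch %*% t(Rz %*% Ry %*% Rx)
    P <- sweep(P, 2, -par[4:6])
    sqrt(mean(rowSums((P - anch_b)^2)))
  }
  fit <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(sup$anchor_rmsd, fit$value, tolerance = 1e-4)

  # oracle 2: bio3d's least-squares fit on the same atom sets
  fx <- as.numeric(t(anch_b))
  mx <- as.numeric(t(anch))
  moved <- bio3d::fit.xyz(fixed = fx, mobile = mx,
                          fixed.inds = 1:18, mobile.inds = 1:18)
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(moved, ncol = 3, byrow = TRUE) - anch_b)^2)))
  expect_equal(sup$anchor_rmsd, rmsd_bio3d, tolerance = 1e-8)

  # optimality: no random rotation perturbation lowers the anchor error
  set.seed(42)
  base_err <- sup$anchor_rmsd
  P0 <- apply_superposition(sup, a$anchor_xyz)
  ctr <- colMeans(P0)
  for (k in 1:100) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 1e-4, 0.2)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    Rp <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    Pp <- sweep(sweep(P0, 2, ctr) %*% t(Rp), 2, -ctr)
    expect_gte(sqrt(mean(rowSums((Pp - b$anchor_xyz)^2))) + 1e-12, base_err)
  }
})

test_that("loop RMSD equals hand-computed values on printed coordinates", {
  a <- toy_loop(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(loop_rmsd(a, a)$value, 0)

  # partner with per-residue displacements (0,0,1), (0,0,0), (0,1,0)
  b <- toy_loop(rbind(c(0, 0, 1), c(1, 0, 0), c(2, 1, 0)))
  expect_equal(loop_rmsd(a, b)$value, sqrt((1 + 0 + 1) / 3), tolerance = 1e-6)

  # uniform translation by 2 A forces RMSD exactly 2
  d <- toy_loop(sweep(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 2,
                      c(0, 0, -2)))
  expect_equal(loop_rmsd(a, d)$value, 2, tolerance = 1e-9)

  # unequal lengths are a classed error pointing at the spline distance
  e <- toy_loop(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(loop_rmsd(a, e), class = "length_error")
  expect_error(loop_rmsd(a, toy_loop(rbind(c(0, 0, 0)), region = "CDR1")),
               class = "usage_error")
})

test_that("fewer than 3 common anchor atoms is underdetermined", {
  a <- toy_loop(rbind(c(0, 0, 0), c(1, 0, 0)),
                anchors_ca = rbind(c(0, 10, 0), c(5, 10, 0)))
  expect_error(superpose_by_anchors(a, a), class = "underdetermined_error")
})

test_that("spline distance degenerates to RMSD at equal lengths", {
  for (k in 1:25) {
    L <- sample(4:14, 1)
    a <- full_loop(L, seed = 1000 + k)
    b <- full_loop(L, seed = 2000 + k)
    expect_lt(abs(upsampled_distance(a, b)$value - loop_rmsd(a, b)$value),
              1e-9)
  }
})

test_that("spline distance matches a dense-resampling oracle across lengths", {
  dense_oracle <- function(a, b, M = 1000) {
    sup <- superpose_by_anchors(a, b)
    Ta <- apply_superposition(sup, a$loop_xyz)
    Tb <- b$loop_xyz
    res <- function(Tr) {
      x <- seq(0, 1, length.out = nrow(Tr))
      xout <- seq(0, 1, length.out = M)
      sapply(1:3, function(kk) {
        splinefun(x, Tr[, kk], method = "natural")(xout)
      })
    }
    sqrt(mean(rowSums((res(Ta) - res(Tb))^2)))
  }
  a <- full_loop(4, seed = 31)
  b <- full_loop(5, seed = 32)
  d <- upsampled_distance(a, b)
  expect_equal(d$kind, "spline_upsampled")
  expect_equal(d$n_points, 20L)
  expect_lt(abs(d$value - dense_oracle(a, b)), 0.05)
  # self-distance is zero even after deleting a residue elsewhere
  expect_equal(upsampled_distance(b, b)$value, 0, tolerance = 1e-12)
})

test_that("distances are symmetric and invariant under rigid motion", {
  for (k in 1:10) {
    a <- full_loop(sample(5:12, 1), seed = 100 + k)
    b <- full_loop(sample(5:12, 1), seed = 300 + k)
    dab <- if (a$n_residues == b$n_residues) loop_rmsd(a, b)$value else
      upsampled_distance(a, b)$value
    dba <- if (a$n_residues == b$n_residues) loop_rmsd(b, a)$value else
      upsampled_distance(b, a)$value
    expect_lt(abs(dab - dba), 1e-9)
    # move structure b rigidly (anchors + loop together)
    bm <- rigid_move_loop(b, theta = 0.73, shift = c(3, -8, 2))
    dm <- if (a$n_residues == b$n_residues) loop_rmsd(a, bm)$value else
      upsampled_distance(a, bm)$value
    expect_lt(abs(dm - dab), 1e-6)
  }
})

test_that("pairwise matrices dispatch by length and reflect planted geometry", {
  ca <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  a1 <- toy_loop(ca, parent = "p1")
  a2 <- toy_loop(sweep(ca, 2, c(0, 0, -2)), parent = "p2")
  a3 <- toy_loop(ca, parent = "p3")
  D <- pairwise_distance_matrix(list(a1, a2, a3))
  expect_equal(diag(D), setNames(rep(0, 3), c("p1", "p2", "p3")))
  expect_equal(unname(D["p1", "p2"]), 2, tolerance = 1e-9)
  expect_equal(unname(D["p1", "p3"]), 0, tolerance = 1e-12)
  expect_equal(D, t(D))

  # two planted conformational clusters: every within-pair distance smaller
  # than every between-pair distance
  rep <- generate_repertoire(generator_config(
    n_records = 10, seed = 21,
    loop_lengths = list(CDR1 = c(`11` = 1), CDR2 = c(`9` = 1),
                        CDR3 = c(`12` = 1)),
    clusters_per_region = list(CDR1 = 2, CDR2 = 1, CDR3 = 1),
    noise_radius = 0.2, cluster_separation = 4, vj_coherence = NULL))
  loops <- collect_loops(rep$records, "alpha", "CDR1")
  D2 <- pairwise_distance_matrix(loops)
  lab <- rep$truth$labels$alpha$CDR1
  same <- outer(lab, lab, "==") & upper.tri(D2)
  diff <- outer(lab, lab, "!=") & upper.tri(D2)
  expect_lt(max(D2[same]), min(D2[diff]))
})

test_that("distance CSVs re-read bit-exactly", {
  set.seed(8)
  D <- random_distance_matrix(6)
  dimnames(D) <- list(paste0("id", 1:6), paste0("id", 1:6))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(D, tf)
  expect_identical(read_distance_csv(tf), D)
})
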