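make_bench_set <- function(n = 5, seed = 101) {
  generate_repertoire(generator_config(
    n_records = n, seed = seed,
    loop_lengths = list(CDR1 = c(`11` = 1), CDR2 = c(`9` = 1),
                        CDR3 = c(`12` = 1)),
    clusters_per_region = list(CDR1 = 1, CDR2 = 1, CDR3 = 1),
    noise_radius = 0.2, vj_coherence = NULL))$records
}

test_that("region report is zero for identical structures", {
  refs <- make_bench_set(3)
  rpt <- region_report(refs, refs, model_name = "self")
  vals <- as.matrix(rpt$per_record[, rpt$regions])
  expect_true(all(is.finite(vals)))
  expect_lt(max(vals), 1e-9)
})

test_that("an injected CDR3b displacement shows up in exactly one cell", {
  refs <- make_bench_set(3)
  preds <- refs
  preds[[2]] <- perturb_record(preds[[2]], "beta", "CDR3", 2.0)
  rpt <- region_report(preds, refs)
  expect_equal(rpt$per_record$CDR3b[2], 2.0, tolerance = 1e-9)
  loop_cols <- c("CDR1a", "CDR2a", "CDR3a", "CDR1b", "CDR2b")
  expect_lt(max(as.matrix(rpt$per_record[, loop_cols])), 1e-9)
  # whole-beta and FWb are affected by the fit but bounded by the injection
  expect_lt(rpt$per_record$beta[2], 2.0)
  expect_gt(rpt$per_record$beta[2], 0)
})

test_that("per-cell report values match direct geometry recomputation", {
  refs <- make_bench_set(5)
  preds <- refs
  disp <- c(0.5, 1.0, 1.5, 2.5, 3.5)
  for (i in seq_along(preds)) {
    preds[[i]] <- perturb_record(preds[[i]], "alpha", "CDR3", disp[i],
                                 seed = 400 + i)
  }
  rpt <- region_report(preds, refs)
  for (i in seq_along(preds)) {
    direct <- loop_rmsd(extract_region(preds[[i]], "alpha", "CDR3"),
                        extract_region(refs[[i]], "alpha", "CDR3"))$value
    expect_equal(rpt$per_record$CDR3a[i], direct, tolerance = 1e-12)
    expect_equal(direct, disp[i], tolerance = 1e-9)
  }
  expect_error(region_report(preds[1:4], refs), class = "pairing_error")
})

test_that("sub-threshold counting is strict", {
  refs <- make_bench_set(3)
  preds <- refs
  for (i in 1:3) {
    preds[[i]] <- perturb_record(preds[[i]], "beta", "CDR3",
                                 c(1.9, 2.0, 2.1)[i])
  }
  rpt <- region_report(preds, refs)
  res <- subthreshold_count(rpt, "CDR3b", 2.0)
  expect_equal(res$count, 1L)
  expect_equal(res$fraction, 1 / 3)
  # fraction is non-increasing as the threshold tightens
  expect_lte(subthreshold_count(rpt, "CDR3b", 1.5)$fraction, res$fraction)
})

test_that("quadrant classification matches manual enumeration", {
  refs <- make_bench_set(6)
  da <- c(1, 1, 3, 3, 1, 3)   # model a displacements
  db <- c(1, 3, 1, 3, 1, 3)   # model b displacements
  pa <- pb <- refs
  for (i in 1:6) {
    pa[[i]] <- perturb_record(pa[[i]], "beta", "CDR3", da[i])
    pb[[i]] <- perturb_record(pb[[i]], "beta", "CDR3", db[i])
  }
  ra <- region_report(pa, refs, "a")
  rb <- region_report(pb, refs, "b")
  q <- quadrant_classify(ra, rb, "CDR3b", 2.0)
  expect_equal(q$both_below, 2L)
  expect_equal(q$both_at_or_above, 2L)
  expect_equal(q$only_a_below, 1L)
  expect_equal(q$only_b_below, 1L)
  expect_equal(q$both_below + q$both_at_or_above + q$only_a_below +
                 q$only_b_below, q$n)
  # relabelling the models swaps the one-sided counts exactly
  q2 <- quadrant_classify(rb, ra, "CDR3b", 2.0)
  expect_equal(q2$only_a_below, q$only_b_below)
  expect_equal(q2$only_b_below, q$only_a_below)

  # ensemble best-of: complementary failures rescue everything
  expect_equal(ensemble_best(ra, rb, "CDR3b", 2.0), 4 / 6)
  expect_gte(ensemble_best(ra, rb, "CDR3b", 2.0),
             max(subthreshold_count(ra, "CDR3b")$fraction,
                 subthreshold_count(rb, "CDR3b")$fraction))
  comp <- quadrant_classify(ra, rb, "CDR3b", 2.0)
  expect_equal(ensemble_best(ra, rb, "CDR3b", 2.0),
               (comp$n - comp$both_at_or_above) / comp$n)
})

test_that("the model-comparison t statistic follows the printed formula", {
  x <- c(1, 2, 3, 4, 5)
  r0 <- rmsd_t_test(x, x)
  expect_equal(r0$t_value, 0)
  expect_equal(r0$p_value, 1.0)

  # mean difference 1, sd 1 in both arms, n = 45: t = 1 / sqrt(2/45)
  set.seed(20)
  a <- rnorm(45)
  a <- (a - mean(a)) / sd(a)
  b <- a + 1
  r <- rmsd_t_test(a, b)
  expect_equal(r$t_value, 1 / sqrt(2 / 45), tolerance = 1e-12)
  expect_equal(r$df, 44)
  expect_equal(r$p_value, 2 * t_surv_integrate(r$t_value, 44),
               tolerance = 1e-8)
  # symmetric in the two models
  r_sw <- rmsd_t_test(b, a)
  expect_equal(r_sw$t_value, r$t_value)
  expect_equal(r_sw$p_value, r$p_value)

  # randomized agreement with the formula and the survival oracle
  set.seed(21)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    va <- rexp(n)
    vb <- rexp(n) * runif(1, 0.5, 2)
    rr <- rmsd_t_test(va, vb)
    t_direct <- abs(mean(va) - mean(vb)) / sqrt((var(va) + var(vb)) / n)
    expect_equal(rr$t_value, t_direct, tolerance = 1e-10)
    expect_equal(rr$p_value, 2 * t_surv_integrate(t_direct, n - 1),
                 tolerance = 1e-8)
  }
  expect_error(rmsd_t_test(1, 1), class = "usage_error")
  # Welch option exists but is a different statistic in general
  rw <- rmsd_t_test(a, b, welch = TRUE)
  expect_equal(rw$method, "welch")
})

test_that("identity-RMSD trend stratifies at the split point", {
  pairs <- data.frame(identity = seq(0, 1, length.out = 50),
                      rmsd = seq(5, 0, length.out = 50))
  tr <- identity_rmsd_trend(pairs)
  expect_equal(tr$pcc_overall, -1.0)
  expect_equal(tr$pcc_high, -1.0)
  expect_lt(tr$slope, 0)
  expect_equal(tr$n_high + tr$n_low +
                 sum(pairs$identity == 0.65), nrow(pairs))

  # degenerate stratum: flagged, not an error
  pairs2 <- data.frame(identity = c(rep(0.9, 5), 0.1, 0.2, 0.3),
                       rmsd = c(rep(2, 5), 3, 2, 1))
  tr2 <- identity_rmsd_trend(pairs2)
  expect_true(is.na(tr2$pcc_high))
  expect_true(tr2$degenerate[["high"]])
  expect_false(tr2$degenerate[["low"]])
})
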