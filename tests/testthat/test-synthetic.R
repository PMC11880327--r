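test_that("generation is bit-reproducible and leaves the caller's RNG alone", {
  cfg <- generator_config(n_records = 3, seed = 42)
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  r1 <- generate_repertoire(cfg)
  after <- rnorm(1)
  expect_identical(before, after)

  r2 <- generate_repertoire(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_repertoire(r1, d1)
  write_repertoire(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("generated structures pass IO round-trip and extraction cleanly", {
  rep <- generate_repertoire(generator_config(n_records = 4, seed = 9))
  d <- withr::local_tempdir()
  expect_no_warning(write_repertoire(rep, d))
  f <- list.files(d, pattern = "\\.pdb$", full.names = TRUE)[1]
  rec <- expect_no_warning(read_structure(f))
  for (rg in c("CDR1", "CDR2", "CDR3")) {
    l <- expect_no_warning(extract_region(rec, "beta", rg))
    expect_false(l$anchors_degraded)
    expect_true(l$complete_backbone)
    expect_equal(nchar(l$sequence), l$n_residues)
  }
  genes <- read_gene_table(file.path(d, "gene_table.csv"))
  expect_equal(nrow(genes), 4L)
  expect_true(all(grepl("^TRAV", genes$alpha_v)))
})

test_that("zero noise with one planted cluster collapses all distances", {
  rep <- generate_repertoire(generator_config(
    n_records = 5, seed = 2, noise_radius = 0,
    loop_lengths = list(CDR1 = c(`11` = 1), CDR2 = c(`9` = 1),
                        CDR3 = c(`12` = 1)),
    clusters_per_region = list(CDR1 = 1, CDR2 = 1, CDR3 = 1),
    seq_mutation_rate = 0, vj_coherence = NULL))
  D <- pairwise_distance_matrix(collect_loops(rep$records, "alpha", "CDR1"))
  expect_lt(max(D), 1e-9)
  # sequences are the untouched consensus
  seqs <- vapply(collect_loops(rep$records, "alpha", "CDR3"), `[[`, "",
                 "sequence")
  expect_length(unique(seqs), 1L)
})

test_that("planted clusters are recovered exactly under matched thresholds", {
  rep <- generate_repertoire(generator_config(
    n_records = 20, seed = 6,
    loop_lengths = list(CDR1 = c(`11` = 1), CDR2 = c(`9` = 1),
                        CDR3 = c(`12` = 1)),
    clusters_per_region = list(CDR1 = 3, CDR2 = 1, CDR3 = 1),
    noise_radius = 0.2, cluster_separation = 4, vj_coherence = NULL))
  D <- pairwise_distance_matrix(collect_loops(rep$records, "alpha", "CDR1"))
  ca <- greedy_cluster(D, 1)
  expect_equal(cluster_census(ca)$n_clusters, 3L)
  truth <- rep$truth$labels$alpha$CDR1
  got <- cluster_labels(ca)
  agree <- outer(truth, truth, "==") == outer(got, got, "==")
  expect_true(all(agree))
})

test_that("VJ-organised CDR3 modes respect the planted coherence structure", {
  rep <- generate_repertoire(generator_config(
    n_records = 60, n_vj_pairs = 10, seed = 12,
    vj_coherence = c(0.5, 0.5)))
  loops <- collect_loops(rep$records, "alpha", "CDR3")
  rpt <- vj_coherence(loops, tau = 2, min_group = 5)
  truth <- rep$truth$vj$alpha
  key <- paste(rpt$per_pair$v_gene, rpt$per_pair$j_gene)
  tkey <- paste(truth$v_gene, truth$j_gene)
  expect_setequal(key, tkey)
  expect_equal(rpt$per_pair$n_clusters,
               truth$n_modes[match(key, tkey)])
})

test_that("identity-RMSD pair generation hits the planted correlation", {
  p0 <- generate_identity_rmsd_pairs(5000, 0, seed = 3)
  expect_lt(abs(cor(p0$identity, p0$rmsd)), 3 / sqrt(5000))
  expect_true(all(p0$identity >= 0 & p0$identity <= 1))
  expect_true(all(p0$rmsd >= 0))
  # degenerate n = 2 draw has |PCC| = 1
  p2 <- generate_identity_rmsd_pairs(2, -0.3, seed = 1)
  expect_equal(abs(cor(p2$identity, p2$rmsd)), 1, tolerance = 1e-9)
  expect_error(generate_identity_rmsd_pairs(10, 0.5), class = "usage_error")
})

test_that("loop perturbation translates one loop by an exact RMSD", {
  rec <- generate_repertoire(generator_config(n_records = 1, seed = 33))$records[[1]]
  same <- perturb_record(rec, "beta", "CDR3", 0)
  expect_equal(same$beta$atoms, rec$beta$atoms, tolerance = 1e-12)

  p <- perturb_record(rec, "beta", "CDR3", 2.0, seed = 5)
  expect_equal(loop_rmsd(extract_region(p, "beta", "CDR3"),
                         extract_region(rec, "beta", "CDR3"))$value,
               2.0, tolerance = 1e-9)
  # alpha chain untouched
  expect_identical(p$alpha$atoms, rec$alpha$atoms)

  # two orthogonal 1 A displacements compose to sqrt(2)
  p1 <- perturb_record(rec, "alpha", "CDR2", 1.0, direction = c(0, 0, 1))
  p12 <- perturb_record(p1, "alpha", "CDR2", 1.0, direction = c(0, 1, 0))
  expect_equal(loop_rmsd(extract_region(p12, "alpha", "CDR2"),
                         extract_region(rec, "alpha", "CDR2"))$value,
               sqrt(2), tolerance = 1e-9)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(noise_radius = 2, cluster_separation = 3,
                                clusters_per_region = list(CDR1 = 3, CDR2 = 1,
                                                           CDR3 = 0)),
               class = "config_error")
  expect_error(generator_config(vj_coherence = c(1.4, 0.2)),
               class = "config_error")
  expect_error(generator_config(loop_lengths = list(CDR1 = c(`11` = 0.5),
                                                    CDR2 = c(`9` = 1),
                                                    CDR3 = c(`12` = 1))),
               class = "config_error")
})

test_that("antibody preset plants canonical CDR3 light-chain behaviour", {
  cfg <- generator_config(n_records = 16, receptor = "antibody", seed = 14,
                          clusters_per_region = list(CDR1 = 2, CDR2 = 2,
                                                     CDR3 = c(3, 0)),
                          loop_lengths = list(CDR1 = c(`11` = 1),
                                              CDR2 = c(`9` = 1),
                                              CDR3 = c(`12` = 1)),
                          noise_radius = 0.2, cluster_separation = 4,
                          vj_coherence = NULL)
  rep <- generate_repertoire(cfg)
  expect_equal(rep$records[[1]]$alpha$chain_kind, "light")
  expect_equal(rep$records[[1]]$beta$chain_kind, "heavy")
  # light CDR3 clusters into 3 canonical forms; heavy CDR3 is diffuse
  Dl <- pairwise_distance_matrix(collect_loops(rep$records, "light", "CDR3"))
  Dh <- pairwise_distance_matrix(collect_loops(rep$records, "heavy", "CDR3"))
  nl <- cluster_census(greedy_cluster(Dl, 1))$n_clusters
  nh <- cluster_census(greedy_cluster(Dh, 1))$n_clusters
  expect_equal(nl, 3L)
  expect_gt(nh, nl)
})
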