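test_that("cohort generation is seed-deterministic and shape-correct", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$mrna$counts, b$mrna$counts)
  expect_identical(a$mirna$counts, b$mirna$counts)
  expect_identical(as.data.frame(a$samples), as.data.frame(b$samples))
  expect_identical(dim(a$mrna), c(60L, 55L))
  expect_identical(dim(a$mirna), c(20L, 55L))
  # a different seed changes the counts
  c2 <- generate_cohort(small_config(seed = 8L))
  expect_false(identical(a$mrna$counts, c2$mrna$counts))
})

test_that("reference config carries the documented constants and structure", {
  cfg <- default_recovery_config()
  expect_identical(cfg$n_genes, 300L)
  expect_identical(cfg$n_mirnas, 60L)
  expect_identical(cfg$n_normal, 50L)
  expect_identical(cfg$n_early, 60L)
  expect_identical(cfg$n_advanced, 40L)
  expect_identical(cfg$n_paired_patients, 40L)
  expect_identical(cfg$n_planted_pairs, 30L)
  expect_identical(cfg$rho_normal, -0.75)
  expect_identical(cfg$rho_tumor, -0.05)
  expect_identical(cfg$lfc_planted, 1.5)
  coh <- ref_cohort()
  expect_identical(nrow(coh$mrna$counts), 300L)
  expect_identical(nrow(coh$truth$planted_pairs), 30L)
  # every planted pair appears in the emitted interaction database
  expect_true(all(pair_key(coh$truth$planted_pairs) %in% pair_key(coh$db)))
  # paired patients own exactly one normal and one tumor sample each
  ps <- paired_subset(coh$samples)
  expect_identical(ps$patient_ids, coh$truth$paired_patients)
})

test_that("config invariants reject inconsistent sizes and couplings", {
  expect_error(sim_config(n_planted_pairs = 500), "exceeds min")
  expect_error(sim_config(n_paired_patients = 60, n_normal = 50), "n_normal")
  expect_error(sim_config(rho_normal = -0.1, rho_tumor = -0.5), "exceed")
  expect_error(sim_config(rho_normal = 0.5), "rho_normal")
  expect_error(sim_config(nb_dispersion = 0), "positive")
})

test_that("planted coupling shows up as strong negative sample correlation", {
  # near-deterministic latent coupling: even after NB marginalization the
  # normal-tissue correlation of every planted pair stays clearly negative
  cfg <- sim_config(n_genes = 40, n_mirnas = 12, n_normal = 200, n_early = 10,
                    n_advanced = 10, n_paired_patients = 10,
                    n_planted_pairs = 8, targets_per_mirna = 2,
                    rho_normal = -0.99, rho_tumor = 0,
                    n_extra_de_genes = 0, seed = 11L)
  coh <- generate_cohort(cfg)
  norm_g <- normalize_log2(coh$mrna)
  norm_m <- normalize_log2(coh$mirna)
  hc <- coh$samples$sample_id[coh$samples$group == "HC"]
  r_planted <- vapply(seq_len(nrow(coh$truth$planted_pairs)), function(i) {
    pr <- coh$truth$planted_pairs[i, ]
    pearson_cor(norm_m$values[pr$mirna_id, hc], norm_g$values[pr$gene_id, hc])$r
  }, numeric(1))
  expect_true(all(r_planted < -0.5))

  # with rho_tumor = 0 the tumor-sample correlations sit near zero
  tu <- coh$samples$sample_id[coh$samples$tissue == "tumor"]
  cfg2 <- sim_config(n_genes = 40, n_mirnas = 12, n_normal = 10, n_early = 100,
                     n_advanced = 100, n_paired_patients = 10,
                     n_planted_pairs = 8, targets_per_mirna = 2,
                     rho_normal = -0.99, rho_tumor = 0,
                     n_extra_de_genes = 0, seed = 11L)
  coh2 <- generate_cohort(cfg2)
  ng2 <- normalize_log2(coh2$mrna); nm2 <- normalize_log2(coh2$mirna)
  tu2 <- coh2$samples$sample_id[coh2$samples$tissue == "tumor"]
  r_tumor <- vapply(seq_len(nrow(coh2$truth$planted_pairs)), function(i) {
    pr <- coh2$truth$planted_pairs[i, ]
    pearson_cor(nm2$values[pr$mirna_id, tu2], ng2$values[pr$gene_id, tu2])$r
  }, numeric(1))
  expect_true(all(abs(r_tumor) < 0.2))
})

test_that("stronger latent coupling never weakens mean planted correlation", {
  rhos <- c(-0.3, -0.6, -0.9)
  mean_abs_r <- vapply(rhos, function(rho) {
    cfg <- sim_config(n_genes = 40, n_mirnas = 12, n_normal = 80, n_early = 10,
                      n_advanced = 10, n_paired_patients = 10,
                      n_planted_pairs = 8, targets_per_mirna = 2,
                      rho_normal = rho, rho_tumor = 0,
                      n_extra_de_genes = 0, seed = 13L)
    coh <- generate_cohort(cfg)
    ng <- normalize_log2(coh$mrna); nm <- normalize_log2(coh$mirna)
    hc <- coh$samples$sample_id[coh$samples$group == "HC"]
    mean(abs(vapply(seq_len(8), function(i) {
      pr <- coh$truth$planted_pairs[i, ]
      pearson_cor(nm$values[pr$mirna_id, hc], ng$values[pr$gene_id, hc])$r
    }, numeric(1))))
  }, numeric(1))
  expect_true(all(diff(mean_abs_r) >= 0))
})

test_that("decoy pairs are uncorrelated and library size is normalized away", {
  coh <- ref_cohort()
  ng <- normalize_log2(coh$mrna); nm <- normalize_log2(coh$mirna)
  hc <- coh$samples$sample_id[coh$samples$group == "HC"]
  r_decoy <- vapply(seq_len(nrow(coh$truth$decoy_pairs)), function(i) {
    pr <- coh$truth$decoy_pairs[i, ]
    pearson_cor(nm$values[pr$mirna_id, hc], ng$values[pr$gene_id, hc])$r
  }, numeric(1))
  expect_lt(mean(abs(r_decoy)), 2 / sqrt(length(hc)))

  # doubling the library-size spread leaves normalized planted correlations
  # within sampling error: normalization removes the shared size factor
  cfg2 <- default_recovery_config()
  cfg2$libsize_sigma <- cfg2$libsize_sigma * 2
  coh2 <- generate_cohort(cfg2)
  ng2 <- normalize_log2(coh2$mrna); nm2 <- normalize_log2(coh2$mirna)
  r1 <- vapply(seq_len(30), function(i) {
    pr <- coh$truth$planted_pairs[i, ]
    pearson_cor(nm$values[pr$mirna_id, hc], ng$values[pr$gene_id, hc])$r
  }, numeric(1))
  r2 <- vapply(seq_len(30), function(i) {
    pr <- coh2$truth$planted_pairs[i, ]
    pearson_cor(nm2$values[pr$mirna_id, hc], ng2$values[pr$gene_id, hc])$r
  }, numeric(1))
  expect_lt(abs(mean(r1) - mean(r2)), 2 / sqrt(length(hc)))
})

test_that("cohorts write to the formats the readers accept", {
  d <- withr::local_tempdir()
  coh <- small_cohort()
  write_cohort(coh, d)
  mrna <- read_count_matrix(file.path(d, "counts_mrna.tsv"), "mRNA")
  expect_identical(mrna$counts, coh$mrna$counts)
  st <- read_sample_table(file.path(d, "samples.tsv"))
  expect_identical(st$group, coh$samples$group)
  db <- read_interactions(file.path(d, "interactions.tsv"))
  expect_setequal(pair_key(db), pair_key(coh$db))
})
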