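test_that("pearson matches brute-force sums on random instances", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  res <- pearson_cor(x, y)
  oracle <- brute_pearson(x, y)
  expect_equal(res$r, oracle$r, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- pearson_cor(x, y)
    oracle <- brute_pearson(x, y)
    expect_equal(res$r, oracle$r, tolerance = 1e-12)
    expect_equal(res$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("pearson handles degenerate and exact cases without error", {
  x <- 1:10
  res <- pearson_cor(x, -x)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_equal(res$p, 0)
  const <- pearson_cor(x, rep(2, 10))
  expect_true(is.na(const$r) && is.na(const$p))
  short <- pearson_cor(c(1, 2), c(2, 1))
  expect_true(is.na(short$r))
  expect_identical(short$n, 2L)
  expect_error(pearson_cor(1:3, 1:4), "equal length")
})

test_that("pearson is symmetric and invariant to positive affine maps", {
  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(12); y <- rnorm(12)
    a <- pearson_cor(x, y); b <- pearson_cor(y, x)
    expect_equal(a$r, b$r, tolerance = 1e-12)
    aff <- pearson_cor(3.2 * x + 5, 0.7 * y - 2)
    expect_equal(aff$r, a$r, tolerance = 1e-12)
    expect_equal(aff$p, a$p, tolerance = 1e-12)
  }
})

test_that("candidate pairs are the validated interactions with both members DE", {
  db <- interaction_db(data.frame(
    mirna_id = c("m1", "m1", "m2", "m3"),
    gene_id = c("g1", "g2", "g1", "g3")))
  dems <- data.frame(feature_id = c("m1", "m2"),
                     final_direction = c("up", "down"))
  degs <- data.frame(feature_id = "g1", final_direction = "down")
  cands <- candidate_pairs(dems, degs, db)
  expect_setequal(pair_key(cands), c("m1/g1", "m2/g1"))
  expect_identical(cands$gene_direction, c("down", "down"))
  empty <- interaction_db(data.frame(mirna_id = character(),
                                     gene_id = character()))
  expect_identical(nrow(candidate_pairs(dems, degs, empty)), 0L)
})

test_that("critical screen gates on strict r and p cuts in healthy controls", {
  cfg <- threshold_config()
  expect_true(mirrewire:::is_critical(-0.5, 0.01, cfg))
  expect_false(mirrewire:::is_critical(-0.19, 1e-4, cfg))
  expect_false(mirrewire:::is_critical(-0.5, 0.06, cfg))
  # exact boundary values are rejected (strict inequalities)
  expect_false(mirrewire:::is_critical(-0.2, 1e-6, cfg))
  expect_false(mirrewire:::is_critical(-0.9, 0.05, cfg))
  expect_false(mirrewire:::is_critical(NA_real_, NA_real_, cfg))
})

test_that("the screen computes on log2-normalized values, not raw counts", {
  # scale one HC sample's library 10x: raw-count correlations shift, but the
  # normalized screen result is unchanged
  coh <- small_cohort()
  res1 <- run_single_cancer(coh$mrna, coh$mirna, coh$samples, coh$db)
  mr <- coh$mrna$counts; mi <- coh$mirna$counts
  hc1 <- coh$samples$sample_id[coh$samples$group == "HC"][1]
  mr[, hc1] <- mr[, hc1] * 10L
  mi[, hc1] <- mi[, hc1] * 10L
  res2 <- run_single_cancer(count_matrix(mr, "mRNA"), count_matrix(mi, "miRNA"),
                            coh$samples, coh$db)
  expect_identical(pair_key(res1$critical_pairs), pair_key(res2$critical_pairs))
  expect_equal(res1$critical_pairs$r_hc, res2$critical_pairs$r_hc,
               tolerance = 1e-2)
  # while raw-count correlation does move for at least one critical pair
  pr <- res1$critical_pairs[1, ]
  hc <- coh$samples$sample_id[coh$samples$group == "HC"]
  raw1 <- cor(coh$mirna$counts[pr$mirna_id, hc], coh$mrna$counts[pr$gene_id, hc])
  raw2 <- cor(mi[pr$mirna_id, hc], mr[pr$gene_id, hc])
  expect_gt(abs(raw1 - raw2), 1e-4)
})

test_that("paired subset selects one normal and one tumor sample per patient", {
  st <- sample_table(c("s1", "s2", "s3", "s4", "s5", "s0"),
                     c("p1", "p1", "p2", "p3", "p1", "p1"),
                     c("normal", "tumor", "tumor", "normal", "tumor", "normal"),
                     c(NA, "I", "III", NA, NA, NA))
  ps <- paired_subset(st)
  # p1 has two normals (s1, s0) and two tumors (s2, s5): smallest ids win;
  # p2 lacks a normal, p3 lacks a tumor
  expect_identical(ps$patient_ids, "p1")
  expect_identical(ps$normal_ids, "s0")
  expect_identical(ps$tumor_ids, "s2")
})

test_that("paired correlations define delta_r = r_tumor - r_normal", {
  coh <- ref_cohort()
  res <- ref_result()
  pp <- res$paired_pairs
  expect_identical(nrow(pp), nrow(res$critical_pairs))
  expect_equal(pp$delta_r, pp$r_tumor - pp$r_normal, tolerance = 1e-12)
  expect_identical(pp$weaker_in_tumor, pp$delta_r > 0)
  expect_true(all(pp$n_pairs == 40L))
  # planted rewiring direction: anticorrelation much weaker in tumor
  planted <- pp[pair_key(pp) %in% pair_key(coh$truth$planted_pairs), ]
  expect_gt(mean(planted$delta_r), 0)
  expect_lt(mean(planted$r_normal), mean(planted$r_tumor))
})

test_that("pairs split by gene direction into a partition", {
  pairs <- data.frame(mirna_id = c("m1", "m2", "m3"),
                      gene_id = c("g1", "g2", "g3"),
                      gene_direction = c("up", "down", "up"))
  sp <- direction_split(pairs)
  expect_identical(nrow(sp$up) + nrow(sp$down), nrow(pairs))
  expect_setequal(sp$up$gene_id, c("g1", "g3"))
  all_up <- direction_split(pairs[pairs$gene_direction == "up", ])
  expect_identical(nrow(all_up$down), 0L)
  empty <- direction_split(pairs[0, ])
  expect_identical(nrow(empty$up), 0L)
  expect_identical(nrow(empty$down), 0L)
})
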