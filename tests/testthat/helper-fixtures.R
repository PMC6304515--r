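# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# reference cohort and its full pipeline run (the recovery suite's inputs)
ref_cohort <- function() memo("ref_cohort", generate_cohort(default_recovery_config()))

ref_result <- function() memo("ref_result", {
  coh <- ref_cohort()
  run_single_cancer(coh$mrna, coh$mirna, coh$samples, coh$db)
})

# a small, fast cohort for structural tests
small_config <- function(...) {
  args <- list(n_genes = 60, n_mirnas = 20, n_normal = 20, n_early = 20,
               n_advanced = 15, n_paired_patients = 15, n_planted_pairs = 6,
               targets_per_mirna = 2, n_extra_de_genes = 8,
               n_extra_de_mirnas = 0, seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

small_cohort <- function() memo("small_cohort", generate_cohort(small_config()))

pair_key <- function(df) paste(df$mirna_id, df$gene_id, sep = "/")

# tiny deterministic count matrix
toy_counts <- function(kind = "mRNA") {
  m <- matrix(c(10L, 20L, 30L, 60L), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  count_matrix(m, kind)
}

# brute-force Pearson r and p from explicit sums (independent oracle)
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0
  for (i in seq_len(n)) { sx <- sx + x[i]; sy <- sy + y[i] }
  mx <- sx / n; my <- sy / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

# exhaustive Benjamini-Hochberg step-up (independent oracle)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj[o[i]] <- running_min
  }
  pmin(adj, 1)
}

# exact hypergeometric upper tail from binomial coefficients (oracle)
brute_hyper_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
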