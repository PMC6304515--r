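#!/usr/bin/env Rscript
# Stage 2: run the per-cancer screen on every cohort written by stage 1,
# reading the inputs back from disk (exercising the same readers a real
# count-matrix analysis would use), and report how well the screen recovers
# the planted ground truth.

library(mirrewire)

cfg <- threshold_config()
cohort_dirs <- list.dirs("results/cohorts", recursive = FALSE)
if (length(cohort_dirs) == 0)
  stop("no cohorts found; run analysis/01_simulate_cohorts.R first")

for (dir in cohort_dirs) {
  label <- basename(dir)
  mrna <- read_count_matrix(file.path(dir, "counts_mrna.tsv"), "mRNA")
  mirna <- read_count_matrix(file.path(dir, "counts_mirna.tsv"), "miRNA")
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  db <- read_interactions(file.path(dir, "interactions.tsv"))
  res <- run_single_cancer(mrna, mirna, samples, db, cfg, per_stage = TRUE)
  out <- file.path("results", label)
  write_results(res, out)

  truth <- utils::read.delim(file.path(dir, "ground_truth_pairs.tsv"))
  key <- function(df) paste(df$mirna_id, df$gene_id)
  recovery <- mean(key(truth) %in% key(res$critical_pairs))
  pp <- res$paired_pairs
  planted <- pp[key(pp) %in% key(truth), ]
  cat(sprintf(paste0("%s: %d DEGs, %d DEMs, %d critical pairs | planted",
                     " recovery %.0f%%, weaker-in-tumor %.0f%%, mean r",
                     " normal %.2f vs tumor %.2f -> %s\n"),
              label, nrow(res$status_mrna), nrow(res$status_mirna),
              nrow(res$critical_pairs), 100 * recovery,
              100 * mean(planted$weaker_in_tumor),
              mean(planted$r_normal), mean(planted$r_tumor), out))
}
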