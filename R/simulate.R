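#' Simulation configuration for a synthetic tumor/normal cohort
#'
#' Describes a cohort with negative-binomial read counts, sample-specific
#' library sizes, a set of planted miRNA-target pairs whose latent
#' (Gaussian-copula) coupling is strong and negative in normal tissue and
#' attenuated in tumor, planted log2 fold changes between normal and tumor,
#' and patients contributing paired tumor/normal samples.
#'
#' Planted-pair members always carry the planted fold change (miRNA up, gene
#' down in tumor) so they pass the differential-expression arm of the screen;
#' an equal number of decoy pairs gets fold changes of the opposite
#' orientation (miRNA down, gene up) but no latent coupling, so the
#' anticorrelation screen is the step that must reject them, and the
#' balanced shift directions keep the count composition symmetric for
#' median-of-ratios normalization. Additional standalone DE features are
#' planted disjointly from all pair members to let tests exercise the DE
#' screen in isolation.
#'
#' @param n_genes,n_mirnas numbers of mRNA and miRNA features.
#' @param n_normal,n_early,n_advanced group sample sizes (normal tissue,
#'   stage I-II tumors, stage III-IV tumors).
#' @param n_paired_patients patients owning one normal and one tumor sample
#'   each; must be <= n_normal and <= n_early + n_advanced.
#' @param n_planted_pairs coupled miRNA-gene pairs; an equal number of decoy
#'   pairs is added.
#' @param targets_per_mirna planted target genes per miRNA (default 3):
#'   pairs share miRNAs the way real miRNAs regulate many targets, which
#'   also keeps the fraction of shifted miRNA features low enough for
#'   median-of-ratios size factors to stay identifiable.
#' @param rho_normal latent copula correlation of planted pairs in normal
#'   samples, in (-1, 0).
#' @param rho_tumor latent correlation in tumor samples, in (-1, 0]; must be
#'   weaker in magnitude than rho_normal.
#' @param lfc_planted magnitude of planted log2 fold changes.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param mean_log_range range (natural-log scale) of feature baseline means.
#' @param libsize_sigma log-normal spread of per-sample library-size factors.
#' @param n_extra_de_genes,n_extra_de_mirnas standalone planted DE features
#'   disjoint from pair members (alternating up/down).
#' @param seed integer seed driving all draws through per-stream substreams.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 300L, n_mirnas = 60L, n_normal = 50L,
                       n_early = 60L, n_advanced = 40L,
                       n_paired_patients = 40L, n_planted_pairs = 30L,
                       rho_normal = -0.75, rho_tumor = -0.05,
                       targets_per_mirna = 3L,
                       lfc_planted = 1.5, nb_dispersion = 0.15,
                       mean_log_range = c(3, 8), libsize_sigma = 0.25,
                       n_extra_de_genes = 20L, n_extra_de_mirnas = 0L,
                       seed = 101L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              n_normal = as.integer(n_normal), n_early = as.integer(n_early),
              n_advanced = as.integer(n_advanced),
              n_paired_patients = as.integer(n_paired_patients),
              n_planted_pairs = as.integer(n_planted_pairs),
              targets_per_mirna = as.integer(targets_per_mirna),
              rho_normal = rho_normal, rho_tumor = rho_tumor,
              lfc_planted = lfc_planted, nb_dispersion = nb_dispersion,
              mean_log_range = mean_log_range,
              libsize_sigma = libsize_sigma,
              n_extra_de_genes = as.integer(n_extra_de_genes),
              n_extra_de_mirnas = as.integer(n_extra_de_mirnas),
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1 || n_mirnas < 1) stopf("need at least one feature of each kind")
    if (n_normal < 1 || n_early < 1 || n_advanced < 1)
      stopf("all three sample groups must be non-empty")
    if (n_planted_pairs > min(n_genes, n_mirnas))
      stopf("n_planted_pairs exceeds min(n_genes, n_mirnas)")
    if (targets_per_mirna < 1) stopf("targets_per_mirna must be >= 1")
    if (2L * n_planted_pairs + n_extra_de_genes > n_genes)
      stopf("n_genes too small for planted + decoy + extra DE genes")
    n_pm <- ceiling(n_planted_pairs / targets_per_mirna)
    if (2L * n_pm + n_extra_de_mirnas > n_mirnas)
      stopf("n_mirnas too small for planted + decoy + extra DE miRNAs")
    if (n_paired_patients > n_normal)
      stopf("n_paired_patients exceeds n_normal")
    if (n_paired_patients > n_early + n_advanced)
      stopf("n_paired_patients exceeds the tumor sample count")
    if (rho_normal <= -1 || rho_normal >= 0)
      stopf("rho_normal must be in (-1, 0)")
    if (rho_tumor <= -1 || rho_tumor > 0)
      stopf("rho_tumor must be in (-1, 0]")
    if (abs(rho_normal) <= abs(rho_tumor))
      stopf("|rho_normal| must exceed |rho_tumor| (coupling weakens in tumor)")
    if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
    if (length(mean_log_range) != 2 || mean_log_range[1] > mean_log_range[2])
      stopf("mean_log_range must be an increasing pair")
    if (libsize_sigma <= 0) stopf("libsize_sigma must be positive")
  })
  structure(cfg, class = "sim_config")
}

#' Reference cohort configuration used by the recovery suite
#'
#' 300 genes, 60 miRNAs, 50 normal / 60 early / 40 advanced samples, 40
#' paired patients, 30 planted pairs with latent correlation -0.75 in normal
#' and -0.05 in tumor, planted |log2FC| of 1.5, fixed seed.
#'
#' @return a \code{sim_config}.
#' @export
default_recovery_config <- function() sim_config()

#' Generate a synthetic tumor/normal cohort with ground truth
#'
#' Counts are drawn through a Gaussian copula: each feature owns a latent
#' standard-normal vector across samples; a planted pair's gene latent is
#' coupled to its miRNA latent with correlation \code{rho_normal} in normal
#' samples and \code{rho_tumor} in tumor samples; latents map through the
#' normal CDF to negative-binomial quantiles with feature-specific baseline
#' means (log-uniform on \code{mean_log_range}), common dispersion, a
#' log-normal per-sample library-size factor, and a \code{2^(+/-lfc_planted)}
#' tumor mean shift for planted DE features. The emitted interaction
#' database holds the planted pairs plus an equal number of uncoupled decoy
#' pairs. All randomness derives from \code{cfg$seed} via independent
#' substreams, so regenerating with the same config is bit-identical and
#' enlarging the cohort does not reshuffle existing draws.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a list of class \code{"sim_cohort"} with elements \code{mrna} and
#'   \code{mirna} (\code{count_matrix}), \code{samples}
#'   (\code{sample_table}), \code{db} (\code{interaction_db}) and
#'   \code{truth} (planted pairs, decoy pairs, planted DE features, paired
#'   patient ids).
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("miR-sim-%03d", seq_len(cfg$n_mirnas))

  ## --- samples -------------------------------------------------------------
  n_tumor <- cfg$n_early + cfg$n_advanced
  sid <- c(sprintf("N%03d", seq_len(cfg$n_normal)),
           sprintf("E%03d", seq_len(cfg$n_early)),
           sprintf("A%03d", seq_len(cfg$n_advanced)))
  tissue <- c(rep("normal", cfg$n_normal), rep("tumor", n_tumor))
  stage <- c(rep(NA_character_, cfg$n_normal),
             rep(c("I", "II"), length.out = cfg$n_early),
             rep(c("III", "IV"), length.out = cfg$n_advanced))
  # paired patients own normal sample i and tumor sample i
  patient <- character(length(sid))
  np <- cfg$n_paired_patients
  normal_idx <- seq_len(cfg$n_normal)
  tumor_idx <- cfg$n_normal + seq_len(n_tumor)
  patient[normal_idx] <- c(sprintf("P%03d", seq_len(np)),
                           sprintf("PN%03d", seq_len(cfg$n_normal - np) + np))[normal_idx]
  patient[tumor_idx] <- c(sprintf("P%03d", seq_len(np)),
                          sprintf("PT%03d", seq_len(n_tumor - np) + np))
  samples <- sample_table(sid, patient, tissue, stage)
  is_tumor <- tissue == "tumor"

  ## --- feature-level parameters -------------------------------------------
  r <- cfg$mean_log_range
  set.seed(substream_seed(cfg$seed, 1L))
  mu_gene <- exp(stats::runif(cfg$n_genes, r[1], r[2]))
  set.seed(substream_seed(cfg$seed, 2L))
  mu_mirna <- exp(stats::runif(cfg$n_mirnas, r[1], r[2]))
  set.seed(substream_seed(cfg$seed, 3L))
  libsize <- exp(stats::rnorm(length(sid), 0, cfg$libsize_sigma))

  P <- cfg$n_planted_pairs
  n_pm <- as.integer(ceiling(P / cfg$targets_per_mirna))
  # pair k couples miRNA planted_mirna[k] to gene planted_gene[k]; miRNAs
  # are shared across targets_per_mirna pairs
  planted_mirna <- rep(seq_len(n_pm), each = cfg$targets_per_mirna)[seq_len(P)]
  planted_gene <- seq_len(P)
  decoy_mirna <- n_pm + planted_mirna
  decoy_gene <- P + seq_len(P)
  extra_gene <- 2L * P + seq_len(cfg$n_extra_de_genes)
  extra_mirna <- 2L * n_pm + seq_len(cfg$n_extra_de_mirnas)

  # planted tumor fold changes (log2): coupled pairs are miRNA-up/gene-down,
  # decoy pairs miRNA-down/gene-up, extras alternate -- balancing the up and
  # down shifts keeps the count composition symmetric so median-of-ratios
  # size factors stay unbiased
  lfc_gene <- numeric(cfg$n_genes)
  lfc_gene[planted_gene] <- -cfg$lfc_planted
  lfc_gene[decoy_gene] <- cfg$lfc_planted
  lfc_gene[extra_gene] <- cfg$lfc_planted *
    rep(c(1, -1), length.out = length(extra_gene))
  lfc_mirna <- numeric(cfg$n_mirnas)
  lfc_mirna[unique(planted_mirna)] <- cfg$lfc_planted
  lfc_mirna[unique(decoy_mirna)] <- -cfg$lfc_planted
  lfc_mirna[extra_mirna] <- cfg$lfc_planted *
    rep(c(1, -1), length.out = length(extra_mirna))

  ## --- latent copula draws -------------------------------------------------
  ns <- length(sid)
  size <- 1 / cfg$nb_dispersion
  z_mirna <- matrix(0, cfg$n_mirnas, ns)
  for (j in seq_len(cfg$n_mirnas)) {
    set.seed(substream_seed(cfg$seed, 4L, j))
    z_mirna[j, ] <- stats::rnorm(ns)
  }
  rho_vec <- ifelse(is_tumor, cfg$rho_tumor, cfg$rho_normal)
  z_gene <- matrix(0, cfg$n_genes, ns)
  pair_of_gene <- integer(cfg$n_genes)  # 0 = uncoupled
  pair_of_gene[planted_gene] <- planted_mirna
  for (i in seq_len(cfg$n_genes)) {
    set.seed(substream_seed(cfg$seed, 5L, i))
    eps <- stats::rnorm(ns)
    k <- pair_of_gene[i]
    z_gene[i, ] <- if (k == 0) eps
                   else rho_vec * z_mirna[k, ] + sqrt(1 - rho_vec^2) * eps
  }

  ## --- map to negative-binomial counts -------------------------------------
  nb_counts <- function(z, mu_base, lfc) {
    m <- matrix(0L, nrow(z), ns)
    for (i in seq_len(nrow(z))) {
      mu <- mu_base[i] * libsize * ifelse(is_tumor, 2^lfc[i], 1)
      m[i, ] <- stats::qnbinom(stats::pnorm(z[i, ]), size = size, mu = mu)
    }
    storage.mode(m) <- "integer"
    m
  }
  cm <- nb_counts(z_gene, mu_gene, lfc_gene)
  dimnames(cm) <- list(gene_ids, sid)
  cmi <- nb_counts(z_mirna, mu_mirna, lfc_mirna)
  dimnames(cmi) <- list(mirna_ids, sid)

  ## --- interaction database and ground truth -------------------------------
  planted <- data.frame(mirna_id = mirna_ids[planted_mirna],
                        gene_id = gene_ids[planted_gene],
                        rho_normal = cfg$rho_normal,
                        rho_tumor = cfg$rho_tumor,
                        stringsAsFactors = FALSE)
  decoys <- data.frame(mirna_id = mirna_ids[decoy_mirna],
                       gene_id = gene_ids[decoy_gene],
                       stringsAsFactors = FALSE)
  db <- interaction_db(data.frame(
    mirna_id = c(planted$mirna_id, decoys$mirna_id),
    gene_id = c(planted$gene_id, decoys$gene_id),
    sources = "simulated", stringsAsFactors = FALSE))
  de_feat <- data.frame(
    feature_id = c(gene_ids[lfc_gene != 0], mirna_ids[lfc_mirna != 0]),
    kind = c(rep("mRNA", sum(lfc_gene != 0)),
             rep("miRNA", sum(lfc_mirna != 0))),
    direction = ifelse(c(lfc_gene[lfc_gene != 0],
                         lfc_mirna[lfc_mirna != 0]) > 0, "up", "down"),
    stringsAsFactors = FALSE)
  truth <- list(planted_pairs = planted, decoy_pairs = decoys,
                planted_de_features = de_feat,
                paired_patients = sprintf("P%03d", seq_len(np)))

  structure(list(mrna = count_matrix(cm, "mRNA"),
                 mirna = count_matrix(cmi, "miRNA"),
                 samples = samples, db = db, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits \code{counts_mrna.tsv}, \code{counts_mirna.tsv}, \code{samples.tsv},
#' \code{interactions.tsv} (readable by the corresponding \code{read_*}
#' functions) plus \code{ground_truth_pairs.tsv},
#' \code{ground_truth_decoys.tsv} and \code{ground_truth_de.tsv}.
#'
#' @param cohort a \code{sim_cohort}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(cohort$mrna, file.path(dir, "counts_mrna.tsv"))
  write_count_matrix(cohort$mirna, file.path(dir, "counts_mirna.tsv"))
  write_tsv(as.data.frame(cohort$samples)[, c("sample_id", "patient_id",
                                              "tissue", "stage")],
            file.path(dir, "samples.tsv"))
  db <- as.data.frame(cohort$db)
  names(db)[names(db) == "sources"] <- "source"
  write_tsv(db, file.path(dir, "interactions.tsv"))
  write_tsv(cohort$truth$planted_pairs, file.path(dir, "ground_truth_pairs.tsv"))
  write_tsv(cohort$truth$decoy_pairs, file.path(dir, "ground_truth_decoys.tsv"))
  write_tsv(cohort$truth$planted_de_features, file.path(dir, "ground_truth_de.tsv"))
  invisible(dir)
}
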