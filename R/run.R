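#' Run the per-cancer miRNA-target rewiring pipeline
#'
#' The full single-cancer analysis: intersect the samples present in both
#' count matrices and the annotation; normalize each matrix by
#' median-of-ratios size factors; call differentially expressed miRNAs and
#' genes between healthy controls and each tumor stage group (TNS samples
#' are excluded from differential expression and unpaired correlations);
#' intersect with the validated interactions; screen candidates for
#' healthy-control anticorrelation; and quantify the correlation change on
#' the paired tumor/normal design (paired tumor samples of every stage,
#' including TNS, are eligible). The run is deterministic: identical inputs
#' give identical outputs.
#'
#' @param mrna,mirna \code{\link{count_matrix}} objects of the matching kind.
#' @param samples a \code{\link{sample_table}}.
#' @param db an \code{\link{interaction_db}}.
#' @param cfg a \code{\link{threshold_config}}.
#' @param per_stage also compute per-stage (I-IV) correlations of critical
#'   pairs.
#' @return list of class \code{"cancer_result"} with elements
#'   \code{de_mrna}, \code{de_mirna} (per-comparison record tables),
#'   \code{status_mrna}, \code{status_mirna} (consistent DE status),
#'   \code{critical_pairs}, \code{paired_pairs}, \code{samples}
#'   (the intersected annotation), \code{config}.
#' @export
run_single_cancer <- function(mrna, mirna, samples, db,
                              cfg = threshold_config(), per_stage = FALSE) {
  if (!inherits(mrna, "count_matrix") || mrna$kind != "mRNA")
    stopf("mrna must be a count_matrix of kind mRNA")
  if (!inherits(mirna, "count_matrix") || mirna$kind != "miRNA")
    stopf("mirna must be a count_matrix of kind miRNA")
  common <- Reduce(intersect, list(sample_ids(mrna), sample_ids(mirna),
                                   samples$sample_id))
  if (length(common) == 0)
    stopf("no sample is shared by the mRNA matrix, miRNA matrix and sample table")
  samples <- samples[match(common, samples$sample_id), , drop = FALSE]
  class(samples) <- c("sample_table", "data.frame")
  if (!any(samples$group == "HC"))
    stopf("no healthy-control (normal tissue) samples: the screen requires them")
  mrna <- subset_samples(mrna, common)
  mirna <- subset_samples(mirna, common)

  norm_mrna <- normalize_log2(mrna, cfg)
  norm_mirna <- normalize_log2(mirna, cfg)

  # TNS tumors carry no stage and enter neither DE comparison nor the
  # unpaired group correlations; they stay in sample accounting and in the
  # paired tumor arm.
  samples_de <- samples[samples$group != "TNS", , drop = FALSE]
  de_g <- de_status(norm_mrna, samples_de, cfg)
  de_m <- de_status(norm_mirna, samples_de, cfg)

  cands <- candidate_pairs(de_m$status, de_g$status, db)
  critical <- screen_critical(cands, norm_mrna, norm_mirna, samples_de, cfg,
                              per_stage = per_stage)

  paired <- paired_subset(samples)
  paired_pairs <- paired_correlation(critical, norm_mrna, norm_mirna, paired)

  structure(list(de_mrna = de_g$records, de_mirna = de_m$records,
                 status_mrna = de_g$status, status_mirna = de_m$status,
                 critical_pairs = critical, paired_pairs = paired_pairs,
                 samples = samples, paired = paired, config = cfg),
            class = "cancer_result")
}

#' @export
print.cancer_result <- function(x, ...) {
  cat(sprintf(paste0("cancer_result: %d samples (%d HC), %d DEGs, %d DEMs, ",
                     "%d critical pairs, %d paired patients\n"),
              nrow(x$samples), sum(x$samples$group == "HC"),
              nrow(x$status_mrna), nrow(x$status_mirna),
              nrow(x$critical_pairs), length(x$paired$patient_ids)))
  invisible(x)
}

#' Write a per-cancer result bundle as TSV tables
#'
#' Emits, with fixed column orders: \code{de_mrna.tsv}, \code{de_mirna.tsv},
#' \code{status_mrna.tsv}, \code{status_mirna.tsv},
#' \code{critical_pairs.tsv}, \code{paired_pairs.tsv},
#' \code{samples_used.tsv}.
#'
#' @param res a \code{cancer_result}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ord <- function(df, keys) df[do.call(order, df[keys]), , drop = FALSE]
  write_tsv(ord(res$de_mrna, c("comparison", "feature_id")),
            file.path(dir, "de_mrna.tsv"))
  write_tsv(ord(res$de_mirna, c("comparison", "feature_id")),
            file.path(dir, "de_mirna.tsv"))
  write_tsv(res$status_mrna, file.path(dir, "status_mrna.tsv"))
  write_tsv(res$status_mirna, file.path(dir, "status_mirna.tsv"))
  write_tsv(res$critical_pairs, file.path(dir, "critical_pairs.tsv"))
  write_tsv(ord(res$paired_pairs, c("mirna_id", "gene_id")),
            file.path(dir, "paired_pairs.tsv"))
  write_tsv(as.data.frame(res$samples), file.path(dir, "samples_used.tsv"))
  invisible(dir)
}

#' Aggregate per-cancer results into pan-cancer tables and the network
#'
#' @param results named list (cancer label -> \code{cancer_result}).
#' @param cfg a \code{\link{threshold_config}}.
#' @return list with \code{features} (DE frequency table over genes and
#'   miRNAs combined), \code{pairs} (pair frequency table with per-cancer
#'   delta-r) and \code{network} (\code{bipartite_network}).
#' @export
run_pan <- function(results, cfg = threshold_config()) {
  if (is.null(names(results)) || anyDuplicated(names(results)))
    stopf("results must be a uniquely named list of cancer_result objects")
  status_all <- lapply(results, function(r) rbind(r$status_mrna, r$status_mirna))
  dems <- lapply(results, `[[`, "status_mirna")
  degs <- lapply(results, `[[`, "status_mrna")
  pairs_pc <- lapply(results, `[[`, "paired_pairs")
  features <- aggregate_status(status_all)
  pair_entries <- aggregate_pairs(pairs_pc)
  network <- build_network(pair_entries, dems, degs, cfg)
  list(features = features, pairs = pair_entries, network = network)
}

#' Write pan-cancer outputs
#'
#' Emits \code{pan_features.tsv} and \code{pan_pairs.tsv} (absent entries
#' rendered as \code{"/"}), \code{network.sif}, \code{network.graphml} and
#' \code{network_edges.tsv}.
#'
#' @param pan a \code{\link{run_pan}} result.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_pan <- function(pan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slash <- function(df) {
    for (cn in names(df)) {
      col <- df[[cn]]
      if (cn %in% c("item_id", "mirna_id", "gene_id", "frequency")) next
      col <- if (is.numeric(col)) sprintf("%.4f", col) else as.character(col)
      col[is.na(df[[cn]])] <- "/"
      df[[cn]] <- col
    }
    df
  }
  write_tsv(slash(pan$features), file.path(dir, "pan_features.tsv"))
  write_tsv(slash(pan$pairs), file.path(dir, "pan_pairs.tsv"))
  export_network(pan$network, "sif", file.path(dir, "network.sif"))
  export_network(pan$network, "graphml", file.path(dir, "network.graphml"))
  export_network(pan$network, "tsv", file.path(dir, "network_edges.tsv"))
  invisible(dir)
}
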