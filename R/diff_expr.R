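#' Differential expression between healthy controls and a tumor stage group
#'
#' For every feature, the log2 fold change is the fold change of group means
#' on the normalized (pre-log) scale,
#' \code{log2((mean_tumor + pc) / (mean_hc + pc))}, and the p-value comes
#' from a two-sided Welch unequal-variance t-test on the log2-transformed
#' normalized values. Features constant in both groups get p = 1 when the
#' group means agree and p = 0 otherwise.
#'
#' @param norm a \code{\link{normalize_log2}} result.
#' @param samples a \code{\link{sample_table}}; only its HC and compared
#'   tumor group are used.
#' @param comparison \code{"HC_vs_Early"} or \code{"HC_vs_Advanced"}.
#' @param cfg a \code{\link{threshold_config}} (pseudocount).
#' @return data.frame with columns feature_id, comparison, log2FC, pvalue,
#'   mean_hc, mean_tumor (p-values unadjusted).
#' @export
de_test <- function(norm, samples, comparison = c("HC_vs_Early", "HC_vs_Advanced"),
                    cfg = threshold_config()) {
  comparison <- match.arg(comparison)
  tumor_group <- if (comparison == "HC_vs_Early") "Early" else "Advanced"
  hc_ids <- intersect(samples$sample_id[samples$group == "HC"],
                      colnames(norm$values))
  tu_ids <- intersect(samples$sample_id[samples$group == tumor_group],
                      colnames(norm$values))
  if (length(hc_ids) < 2 || length(tu_ids) < 2)
    stopf("%s: both groups need >= 2 samples (HC: %d, %s: %d)",
          comparison, length(hc_ids), tumor_group, length(tu_ids))
  pc <- cfg$pseudocount
  mean_hc <- rowMeans(norm$norm_counts[, hc_ids, drop = FALSE])
  mean_tu <- rowMeans(norm$norm_counts[, tu_ids, drop = FALSE])
  lfc <- log2((mean_tu + pc) / (mean_hc + pc))
  x <- norm$values[, hc_ids, drop = FALSE]
  y <- norm$values[, tu_ids, drop = FALSE]
  pvals <- vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]; yi <- y[i, ]
    if (stats::var(xi) == 0 && stats::var(yi) == 0)
      return(if (mean(xi) == mean(yi)) 1 else 0)
    tryCatch(stats::t.test(yi, xi, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(feature_id = rownames(norm$values), comparison = comparison,
             log2FC = unname(lfc), pvalue = pvals,
             mean_hc = unname(mean_hc), mean_tumor = unname(mean_tu),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, capped at 1.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted values in the input order.
#' @export
adjust_bh <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify a feature's regulation direction
#'
#' Up when \code{log2FC > lfc_cut} and \code{padj < padj_cut}; down when
#' \code{log2FC < -lfc_cut} and \code{padj < padj_cut}; otherwise none. Both
#' inequalities are strict, so a fold change sitting exactly on the cut is
#' not called.
#'
#' @param log2FC,padj numeric vectors.
#' @param cfg a \code{\link{threshold_config}}.
#' @return character vector, \code{"up"}/\code{"down"}/\code{"none"}.
#' @export
classify_direction <- function(log2FC, padj, cfg = threshold_config()) {
  sig <- !is.na(padj) & padj < cfg$padj_cut & !is.na(log2FC)
  ifelse(sig & log2FC > cfg$lfc_cut, "up",
         ifelse(sig & log2FC < -cfg$lfc_cut, "down", "none"))
}

#' Low-abundance filter on direction calls
#'
#' Demotes a down-call to none when the healthy-control mean of normalized
#' counts is below \code{abundance_min}, and an up-call to none when the
#' compared tumor group's mean is below \code{abundance_min}. Inequalities
#' are strict ("less than 5" removes, 5 itself survives).
#'
#' @param records a \code{\link{de_test}} data.frame carrying a
#'   \code{direction} column (see \code{\link{classify_direction}}).
#' @param cfg a \code{\link{threshold_config}}.
#' @return the records with \code{direction} demoted where the filter fires
#'   and a logical \code{passed_abundance} column.
#' @export
abundance_filter <- function(records, cfg = threshold_config()) {
  fails <- (records$direction == "down" & records$mean_hc < cfg$abundance_min) |
           (records$direction == "up" & records$mean_tumor < cfg$abundance_min)
  records$passed_abundance <- !fails
  records$direction[fails] <- "none"
  records
}

#' Features regulated consistently in early and advanced tumors
#'
#' Keeps only features whose post-filter direction is identical and non-none
#' in both the HC-vs-Early and HC-vs-Advanced comparisons; that shared
#' direction becomes \code{final_direction}. With
#' \code{cfg$abundance_scope == "either"}, an up-regulated feature is also
#' dropped when either tumor group's mean is below \code{abundance_min}.
#'
#' @param early,advanced classified (and abundance-filtered) record
#'   data.frames for the two comparisons, sharing the feature universe.
#' @param cfg a \code{\link{threshold_config}}.
#' @return data.frame with columns feature_id, final_direction, dir_early,
#'   dir_advanced, passed_abundance -- one row per consistently regulated
#'   feature, sorted by feature_id.
#' @export
consistent_features <- function(early, advanced, cfg = threshold_config()) {
  if (!setequal(early$feature_id, advanced$feature_id))
    stopf("the two comparisons must share the feature universe")
  adv <- advanced[match(early$feature_id, advanced$feature_id), ]
  dir_e <- early$direction
  dir_a <- adv$direction
  if (cfg$abundance_scope == "either") {
    low_either <- pmin(early$mean_tumor, adv$mean_tumor) < cfg$abundance_min
    dir_e[dir_e == "up" & low_either] <- "none"
    dir_a[dir_a == "up" & low_either] <- "none"
  }
  keep <- dir_e != "none" & dir_e == dir_a
  out <- data.frame(feature_id = early$feature_id[keep],
                    final_direction = dir_e[keep],
                    dir_early = dir_e[keep], dir_advanced = dir_a[keep],
                    passed_abundance = early$passed_abundance[keep] &
                      adv$passed_abundance[keep],
                    stringsAsFactors = FALSE)
  out[order(out$feature_id), , drop = FALSE]
}

# Full DE arm for one matrix: test both comparisons, adjust within each,
# classify, abundance-filter, and intersect on direction consistency.
# Returns list(records = both comparisons' tables, status = DEStatus table).
de_status <- function(norm, samples, cfg = threshold_config()) {
  run_one <- function(comparison) {
    rec <- de_test(norm, samples, comparison, cfg)
    rec$padj <- adjust_bh(rec$pvalue)
    rec$direction <- classify_direction(rec$log2FC, rec$padj, cfg)
    abundance_filter(rec, cfg)
  }
  early <- run_one("HC_vs_Early")
  advanced <- run_one("HC_vs_Advanced")
  cols <- c("feature_id", "comparison", "log2FC", "pvalue", "padj",
            "mean_hc", "mean_tumor", "direction", "passed_abundance")
  list(records = rbind(early[, cols], advanced[, cols]),
       status = consistent_features(early, advanced, cfg))
}
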