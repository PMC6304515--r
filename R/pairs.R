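#' Pearson correlation with a t-based two-sided p-value
#'
#' Returns the product-moment coefficient and the p-value of
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} against a t distribution with
#' \code{n - 2} degrees of freedom. The result is undefined (r and p are NA)
#' when fewer than 3 complete pairs remain or either vector is constant;
#' undefined results are reported, never raised as errors.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with elements \code{r}, \code{p}, \code{n}.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  if (1 - r^2 <= .Machine$double.eps) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

# strict screen rule shared by screen_critical and the boundary tests
is_critical <- function(r, p, cfg = threshold_config()) {
  !is.na(r) & !is.na(p) & r < cfg$r_cut & p < cfg$p_cut
}

#' Candidate miRNA-target pairs
#'
#' The validated interactions whose miRNA is a differentially expressed
#' miRNA and whose gene is a differentially expressed gene.
#'
#' @param dems,degs DEStatus data.frames (see
#'   \code{\link{consistent_features}}) for miRNAs and genes, or character
#'   vectors of feature ids.
#' @param db an \code{\link{interaction_db}}.
#' @return data.frame with columns mirna_id, gene_id, mirna_direction,
#'   gene_direction (directions NA when plain id vectors were supplied).
#' @export
candidate_pairs <- function(dems, degs, db) {
  ids <- function(x) if (is.data.frame(x)) x$feature_id else as.character(x)
  dirs <- function(x, want) {
    if (!is.data.frame(x)) return(rep(NA_character_, length(want)))
    x$final_direction[match(want, x$feature_id)]
  }
  keep <- db$mirna_id %in% ids(dems) & db$gene_id %in% ids(degs)
  out <- data.frame(mirna_id = db$mirna_id[keep], gene_id = db$gene_id[keep],
                    stringsAsFactors = FALSE)
  out$mirna_direction <- dirs(dems, out$mirna_id)
  out$gene_direction <- dirs(degs, out$gene_id)
  out
}

# correlation of one pair over a set of sample ids, on log2 values
pair_cor <- function(mirna_id, gene_id, norm_mrna, norm_mirna, ids) {
  pearson_cor(norm_mirna$values[mirna_id, ids], norm_mrna$values[gene_id, ids])
}

#' Screen candidates for critical pairs by healthy-control anticorrelation
#'
#' For each candidate pair the Pearson correlation of log2-normalized miRNA
#' and gene expression is computed over the healthy-control samples; a pair
#' is critical when \code{r < r_cut} and \code{p < p_cut} (both strict;
#' undefined correlations fail the screen). For kept pairs the early- and
#' advanced-group correlations are also computed, plus optional per-stage
#' (I-IV) correlations. A Benjamini-Hochberg column over the HC p-values of
#' all candidates is emitted for transparency but never gates the screen.
#'
#' @param cands \code{\link{candidate_pairs}} output.
#' @param norm_mrna,norm_mirna \code{\link{normalize_log2}} results.
#' @param samples a \code{\link{sample_table}}.
#' @param cfg a \code{\link{threshold_config}}.
#' @param per_stage also compute per-stage correlations (default FALSE).
#' @return data.frame of critical pairs with r/p/n per group, sorted by
#'   (mirna_id, gene_id).
#' @export
screen_critical <- function(cands, norm_mrna, norm_mirna, samples,
                            cfg = threshold_config(), per_stage = FALSE) {
  joint <- intersect(colnames(norm_mrna$values), colnames(norm_mirna$values))
  grp_ids <- function(g) intersect(samples$sample_id[samples$group == g], joint)
  hc <- grp_ids("HC")
  empty_cols <- function(prefix) {
    out <- data.frame(r = numeric(0), p = numeric(0), n = integer(0))
    names(out) <- paste0(c("r_", "p_", "n_"), prefix)
    out
  }
  if (nrow(cands) == 0) {
    out <- cbind(cands[, c("mirna_id", "gene_id", "mirna_direction",
                           "gene_direction")],
                 empty_cols("hc"), p_hc_bh = numeric(0),
                 empty_cols("early"), empty_cols("advanced"))
    return(out)
  }
  cors <- function(ids) {
    res <- lapply(seq_len(nrow(cands)), function(i)
      pair_cor(cands$mirna_id[i], cands$gene_id[i], norm_mrna, norm_mirna, ids))
    data.frame(r = vapply(res, `[[`, numeric(1), "r"),
               p = vapply(res, `[[`, numeric(1), "p"),
               n = vapply(res, `[[`, integer(1), "n"))
  }
  hc_res <- cors(hc)
  # BH over all candidate HC p-values, reported only
  p_bh <- rep(NA_real_, nrow(cands))
  defined <- !is.na(hc_res$p)
  if (any(defined)) p_bh[defined] <- adjust_bh(hc_res$p[defined])
  keep <- is_critical(hc_res$r, hc_res$p, cfg)
  out <- cands[keep, , drop = FALSE]
  hc_keep <- hc_res[keep, , drop = FALSE]
  kept_cors <- function(g) {
    ids <- grp_ids(g)
    res <- lapply(seq_len(nrow(out)), function(i)
      pair_cor(out$mirna_id[i], out$gene_id[i], norm_mrna, norm_mirna, ids))
    data.frame(r = vapply(res, `[[`, numeric(1), "r"),
               p = vapply(res, `[[`, numeric(1), "p"),
               n = vapply(res, `[[`, integer(1), "n"))
  }
  early <- kept_cors("Early")
  advanced <- kept_cors("Advanced")
  names(hc_keep) <- paste0(c("r_", "p_", "n_"), "hc")
  names(early) <- paste0(c("r_", "p_", "n_"), "early")
  names(advanced) <- paste0(c("r_", "p_", "n_"), "advanced")
  res <- cbind(out, hc_keep, p_hc_bh = p_bh[keep], early, advanced)
  if (per_stage) {
    for (st in c("I", "II", "III", "IV")) {
      ids <- intersect(samples$sample_id[samples$tissue == "tumor" &
                                           !is.na(samples$stage) &
                                           samples$stage == st], joint)
      sc <- lapply(seq_len(nrow(res)), function(i)
        pair_cor(res$mirna_id[i], res$gene_id[i], norm_mrna, norm_mirna, ids))
      res[[paste0("r_stage_", st)]] <- vapply(sc, `[[`, numeric(1), "r")
      res[[paste0("p_stage_", st)]] <- vapply(sc, `[[`, numeric(1), "p")
    }
  }
  res <- res[order(res$mirna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Patients contributing both a normal and a tumor sample
#'
#' Selects the patients owning at least one normal and one tumor sample and,
#' per patient, the lexicographically smallest sample id of each tissue, so
#' the selection is deterministic when a patient has multiple aliquots.
#' Tumor samples of every stage group (including TNS) are eligible.
#'
#' @param samples a \code{\link{sample_table}}.
#' @return list with patient-aligned equal-length vectors
#'   \code{normal_ids}, \code{tumor_ids} and \code{patient_ids}, ordered by
#'   patient id.
#' @export
paired_subset <- function(samples) {
  pick <- function(tis) {
    sub <- samples[samples$tissue == tis, , drop = FALSE]
    vapply(split(sub$sample_id, sub$patient_id), function(s) sort(s)[1],
           character(1))
  }
  nrm <- pick("normal")
  tum <- pick("tumor")
  pts <- sort(intersect(names(nrm), names(tum)))
  list(normal_ids = unname(nrm[pts]), tumor_ids = unname(tum[pts]),
       patient_ids = pts)
}

#' Correlation change of critical pairs in the paired design
#'
#' For every pair, the Pearson correlation over the paired patients' normal
#' samples and over the same patients' tumor samples, their difference
#' \code{delta_r = r_tumor - r_normal}, and the flag
#' \code{weaker_in_tumor = delta_r > 0}. delta_r is defined only when both
#' component correlations are defined. Restricting both correlations to the
#' same patients removes sample-size and inter-patient confounding.
#'
#' @param pairs data.frame with mirna_id and gene_id columns (e.g.
#'   \code{\link{screen_critical}} output).
#' @param norm_mrna,norm_mirna \code{\link{normalize_log2}} results.
#' @param paired a \code{\link{paired_subset}} result; patients whose
#'   samples are missing from either matrix are dropped.
#' @return data.frame with columns mirna_id, gene_id, r_normal, p_normal,
#'   r_tumor, p_tumor, n_pairs, delta_r, weaker_in_tumor.
#' @export
paired_correlation <- function(pairs, norm_mrna, norm_mirna, paired) {
  joint <- intersect(colnames(norm_mrna$values), colnames(norm_mirna$values))
  ok <- paired$normal_ids %in% joint & paired$tumor_ids %in% joint
  nrm <- paired$normal_ids[ok]
  tum <- paired$tumor_ids[ok]
  one <- function(i) {
    a <- pair_cor(pairs$mirna_id[i], pairs$gene_id[i], norm_mrna, norm_mirna, nrm)
    b <- pair_cor(pairs$mirna_id[i], pairs$gene_id[i], norm_mrna, norm_mirna, tum)
    delta <- if (is.na(a$r) || is.na(b$r)) NA_real_ else b$r - a$r
    data.frame(mirna_id = pairs$mirna_id[i], gene_id = pairs$gene_id[i],
               r_normal = a$r, p_normal = a$p, r_tumor = b$r, p_tumor = b$p,
               n_pairs = length(nrm), delta_r = delta,
               weaker_in_tumor = if (is.na(delta)) NA else delta > 0,
               stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      r_normal = numeric(), p_normal = numeric(),
                      r_tumor = numeric(), p_tumor = numeric(),
                      n_pairs = integer(), delta_r = numeric(),
                      weaker_in_tumor = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), one))
  rownames(out) <- NULL
  out
}

#' Split critical pairs by the target gene's regulation direction
#'
#' @param pairs data.frame with a \code{gene_direction} column.
#' @return list with elements \code{up} and \code{down}; their union is the
#'   input.
#' @export
direction_split <- function(pairs) {
  list(up = pairs[!is.na(pairs$gene_direction) & pairs$gene_direction == "up", ,
                  drop = FALSE],
       down = pairs[!is.na(pairs$gene_direction) & pairs$gene_direction == "down", ,
                    drop = FALSE])
}
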