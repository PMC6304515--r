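#' Median-of-ratios size factors
#'
#' The classic size-factor estimator for RNA-seq counts: for each sample j,
#' \deqn{s_j = \mathrm{median}_i \; k_{ij} / (\prod_v k_{iv})^{1/n}}
#' where the median runs over the features whose counts are positive in every
#' sample (rows containing a zero are excluded from the median, not from the
#' matrix). Dividing a sample's counts by its size factor makes samples with
#' different sequencing depths comparable.
#'
#' @param counts a \code{\link{count_matrix}} or a numeric matrix
#'   (features x samples).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (!is.matrix(m) || !is.numeric(m)) stopf("counts must be a numeric matrix")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stopf(paste("no feature has positive counts in every sample;",
                "prefilter low-abundance features or add pseudocounts",
                "before computing size factors"))
  logm <- log(m[pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(stats::median(col - loggeo)))
  names(sf) <- colnames(m)
  sf
}

#' Normalize counts and log2-transform
#'
#' Divides each sample's counts by its median-of-ratios size factor and
#' stores both the normalized (pre-log) counts and
#' \code{log2(count / size_factor + pseudocount)}. With the default
#' pseudocount of 1, zero counts map to a log2 value of 0.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param cfg a \code{\link{threshold_config}} (supplies the pseudocount).
#' @return an object of class \code{"normalized_matrix"}: a list with
#'   \code{values} (log2 scale), \code{norm_counts} (pre-log),
#'   \code{size_factors}, \code{pseudocount} and \code{kind}.
#' @export
normalize_log2 <- function(counts, cfg = threshold_config()) {
  if (!inherits(counts, "count_matrix")) stopf("counts must be a count_matrix")
  sf <- size_factors(counts)
  norm_counts <- sweep(counts$counts, 2, sf, "/")
  values <- log2(norm_counts + cfg$pseudocount)
  if (any(!is.finite(values))) stopf("non-finite normalized values")
  structure(list(values = values, norm_counts = norm_counts,
                 size_factors = sf, pseudocount = cfg$pseudocount,
                 kind = counts$kind),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d features x %d samples, pseudocount %g\n",
              x$kind, nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Group mean of normalized (pre-log) expression
#'
#' @param norm a \code{normalized_matrix}.
#' @param samples a \code{\link{sample_table}}.
#' @param group one of \code{"HC"}, \code{"Early"}, \code{"Advanced"},
#'   \code{"TNS"}.
#' @param features feature ids (default: all).
#' @return named numeric vector of per-feature means over the group's
#'   samples present in the matrix; \code{NA} for an empty group.
#' @export
group_mean <- function(norm, samples, group, features = NULL) {
  features <- features %||% rownames(norm$norm_counts)
  ids <- intersect(samples$sample_id[samples$group == group],
                   colnames(norm$norm_counts))
  if (length(ids) == 0) {
    out <- rep(NA_real_, length(features))
    names(out) <- features
    return(out)
  }
  rowMeans(norm$norm_counts[features, ids, drop = FALSE])
}

#' Write a normalized matrix with its size-factor sidecar
#'
#' @param norm a \code{normalized_matrix}.
#' @param path destination TSV for the log2 values; the size factors go to
#'   \code{<path dir>/size_factors.tsv}.
#' @return the path, invisibly.
#' @export
write_normalized <- function(norm, path) {
  df <- data.frame(feature_id = rownames(norm$values), norm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(data.frame(sample_id = names(norm$size_factors),
                       size_factor = unname(norm$size_factors),
                       stringsAsFactors = FALSE),
            file.path(dirname(path), "size_factors.tsv"))
  invisible(path)
}
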