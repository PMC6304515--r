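#' Analysis threshold configuration
#'
#' Bundles every tunable cut-off of the pipeline. Defaults follow the study
#' design this package implements: differential expression requires
#' \code{|log2FC| > 1} and adjusted p below 0.05, low-abundance features
#' (group mean of normalized counts below 5) are removed, the healthy-control
#' anticorrelation screen requires Pearson \code{r < -0.2} with
#' \code{p < 0.05}, and the pan-cancer network keeps pairs seen in at least
#' three cancer types. All threshold inequalities are strict.
#'
#' @param lfc_cut positive cut applied to \code{|log2FC|} (default 1).
#' @param padj_cut adjusted-p cut for differential expression (default 0.05).
#' @param abundance_min minimum group mean of normalized (pre-log) counts
#'   (default 5).
#' @param r_cut negative Pearson correlation cut for the healthy-control
#'   screen (default -0.2).
#' @param p_cut correlation p-value cut (default 0.05).
#' @param min_pair_frequency minimum number of cancer types a pair must
#'   appear in to enter the pan-cancer network (default 3).
#' @param enrich_p_cut raw-p significance cut for gene-set enrichment
#'   (default 0.05).
#' @param pseudocount added inside the log2 transform and to fold-change
#'   means (default 1).
#' @param abundance_scope \code{"comparison"} (default) applies the
#'   up-regulated abundance filter to the mean of the compared tumor group
#'   only; \code{"either"} drops an up-call when either tumor group's mean is
#'   below \code{abundance_min}.
#' @param weaker_mode how "weaker correlation in tumor" is adjudicated:
#'   \code{"paired"} (default) uses the paired-design delta-r; an
#'   \code{"unpaired"} fallback compares the mean of the early/advanced r to
#'   the healthy-control r.
#' @return a list of class \code{"threshold_config"}.
#' @export
threshold_config <- function(lfc_cut = 1, padj_cut = 0.05, abundance_min = 5,
                             r_cut = -0.2, p_cut = 0.05,
                             min_pair_frequency = 3L, enrich_p_cut = 0.05,
                             pseudocount = 1,
                             abundance_scope = c("comparison", "either"),
                             weaker_mode = c("paired", "unpaired")) {
  abundance_scope <- match.arg(abundance_scope)
  weaker_mode <- match.arg(weaker_mode)
  if (!is.numeric(lfc_cut) || lfc_cut <= 0) stopf("lfc_cut must be > 0")
  if (padj_cut <= 0 || padj_cut >= 1) stopf("padj_cut must be in (0, 1)")
  if (abundance_min < 0) stopf("abundance_min must be >= 0")
  if (r_cut >= 0) stopf("r_cut must be negative")
  if (p_cut <= 0 || p_cut >= 1) stopf("p_cut must be in (0, 1)")
  min_pair_frequency <- as.integer(min_pair_frequency)
  if (min_pair_frequency < 1L) stopf("min_pair_frequency must be >= 1")
  if (enrich_p_cut <= 0 || enrich_p_cut >= 1) stopf("enrich_p_cut must be in (0, 1)")
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  structure(list(lfc_cut = lfc_cut, padj_cut = padj_cut,
                 abundance_min = abundance_min, r_cut = r_cut, p_cut = p_cut,
                 min_pair_frequency = min_pair_frequency,
                 enrich_p_cut = enrich_p_cut, pseudocount = pseudocount,
                 abundance_scope = abundance_scope,
                 weaker_mode = weaker_mode),
            class = "threshold_config")
}

#' Read a threshold configuration from YAML or JSON
#'
#' Fields absent from the file keep their \code{\link{threshold_config}}
#' defaults; unknown fields are an error so typos do not silently revert a
#' cut-off to its default.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return a \code{threshold_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stopf("config file %s does not contain a mapping", path)
  known <- names(formals(threshold_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(threshold_config, vals)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("threshold_config:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
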