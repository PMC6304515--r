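#' Read gene sets from a GMT file
#'
#' One term per line: term id, term name, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return list with \code{sets} (named list of member vectors) and
#'   \code{term_names} (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short))
    stopf("%s: line(s) %s have fewer than 3 fields", path,
          paste(which(short), collapse = ", "))
  ids <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(ids))
    stopf("%s: duplicate term id(s): %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  term_names <- stats::setNames(vapply(fields, `[`, character(1), 2), ids)
  list(sets = sets, term_names = term_names)
}

#' Assemble a gene-set collection against a background universe
#'
#' Members are restricted to the universe; terms emptied by the restriction
#' are dropped. The default universe for enrichment of pipeline results is
#' the genes present in the expression matrix intersected with the
#' annotation.
#'
#' @param sets named list of member gene-id vectors (e.g.
#'   \code{read_gmt()$sets}).
#' @param universe character vector of background gene ids.
#' @param term_names optional named character vector of term descriptions.
#' @return list of class \code{"gene_set_collection"} with \code{sets},
#'   \code{term_names}, \code{universe}.
#' @export
gene_set_collection <- function(sets, universe, term_names = NULL) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stopf("empty universe")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must be uniquely named")
  restricted <- lapply(sets, function(s) intersect(unique(s), universe))
  keep <- vapply(restricted, length, integer(1)) > 0
  restricted <- restricted[keep]
  tn <- term_names %||% stats::setNames(names(sets), names(sets))
  structure(list(sets = restricted, term_names = tn[names(restricted)],
                 universe = universe),
            class = "gene_set_collection")
}

#' Upper-tail hypergeometric test
#'
#' Probability of observing at least \code{k} annotated genes in a query of
#' size \code{n} drawn from a universe of \code{N} genes of which \code{K}
#' carry the annotation: \eqn{P[X \ge k]} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}.
#'
#' @param k overlap count(s).
#' @param K term size(s) in the universe.
#' @param n query size(s) in the universe.
#' @param N universe size(s).
#' @return p-value(s) in [0, 1]; vectorized over its arguments.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0))
    stopf("counts must be non-negative")
  if (any(K > N) || any(n > N)) stopf("K and n must not exceed N")
  if (any(k > pmin(K, n))) stopf("k must not exceed min(K, n)")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests every term with at least one query member by the upper-tail
#' hypergeometric test; reports the Bonferroni-adjusted p alongside the raw
#' p. Significance at \code{cfg$enrich_p_cut} is flagged on the raw p (the
#' selection cut-off), while \code{p_adj} is reported for headline terms.
#' Query ids outside the universe are dropped with a message.
#'
#' @param query character vector of gene ids.
#' @param gsc a \code{\link{gene_set_collection}}.
#' @param cfg a \code{\link{threshold_config}}.
#' @return data.frame with columns term_id, term_name, k, K, n, N, p, p_adj,
#'   significant; sorted by p ascending then term_id.
#' @export
enrich <- function(query, gsc, cfg = threshold_config()) {
  if (!inherits(gsc, "gene_set_collection"))
    stopf("gsc must be a gene_set_collection")
  query <- unique(as.character(query))
  dropped <- setdiff(query, gsc$universe)
  if (length(dropped) > 0)
    message(sprintf("enrich: dropped %d query id(s) outside the universe",
                    length(dropped)))
  q <- intersect(query, gsc$universe)
  N <- length(gsc$universe)
  n <- length(q)
  k <- vapply(gsc$sets, function(s) length(intersect(s, q)), integer(1))
  K <- vapply(gsc$sets, length, integer(1))
  keep <- k >= 1
  if (!any(keep))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  k <- k[keep]; K <- K[keep]
  p <- hypergeom_test(k, K, n, N)
  out <- data.frame(term_id = names(gsc$sets)[keep],
                    term_name = unname(gsc$term_names[names(gsc$sets)[keep]]),
                    k = k, K = K, n = n, N = N, p = unname(p),
                    p_adj = pmin(1, unname(p) * sum(keep)),
                    stringsAsFactors = FALSE)
  out$significant <- out$p < cfg$enrich_p_cut
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
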