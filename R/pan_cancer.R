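#' Aggregate per-cancer DE status into a frequency table
#'
#' One row per feature differentially expressed in at least one cancer type,
#' one column per cancer holding the feature's direction there (NA when the
#' feature was not called in that cancer), and a frequency column counting
#' the non-absent entries. Rows are sorted by frequency descending, then
#' feature id.
#'
#' @param per_cancer named list (cancer label -> DEStatus data.frame with
#'   columns feature_id, final_direction).
#' @return data.frame with columns item_id, one column per cancer, frequency.
#' @export
aggregate_status <- function(per_cancer) {
  if (anyDuplicated(names(per_cancer)) || is.null(names(per_cancer)))
    stopf("per_cancer must be a uniquely named list")
  items <- sort(unique(unlist(lapply(per_cancer, `[[`, "feature_id"))))
  out <- data.frame(item_id = items, stringsAsFactors = FALSE)
  for (cn in names(per_cancer)) {
    st <- per_cancer[[cn]]
    out[[cn]] <- st$final_direction[match(items, st$feature_id)]
  }
  status <- out[, names(per_cancer), drop = FALSE]
  out$frequency <- as.integer(rowSums(!is.na(status)))
  out <- out[order(-out$frequency, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-cancer pair results into a frequency table
#'
#' Keys pairs as \code{"mirna/gene"}; each cancer column holds that cancer's
#' delta-r (tumor r minus normal r) for the pair, NA when the pair was not
#' critical there; frequency counts the non-absent entries.
#'
#' @param per_cancer named list (cancer label -> data.frame with columns
#'   mirna_id, gene_id, delta_r), e.g. \code{\link{paired_correlation}}
#'   outputs.
#' @return data.frame with columns item_id, mirna_id, gene_id, one numeric
#'   column per cancer, frequency; sorted by frequency descending then key.
#' @export
aggregate_pairs <- function(per_cancer) {
  if (anyDuplicated(names(per_cancer)) || is.null(names(per_cancer)))
    stopf("per_cancer must be a uniquely named list")
  keyed <- lapply(per_cancer, function(df) {
    df$item_id <- paste(df$mirna_id, df$gene_id, sep = "/")
    df
  })
  items <- sort(unique(unlist(lapply(keyed, `[[`, "item_id"))))
  if (length(items) == 0) {
    out <- data.frame(item_id = character(), mirna_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
    for (cn in names(per_cancer)) out[[cn]] <- numeric(0)
    out$frequency <- integer(0)
    return(out)
  }
  parts <- strsplit(items, "/", fixed = TRUE)
  out <- data.frame(item_id = items,
                    mirna_id = vapply(parts, `[`, character(1), 1),
                    gene_id = vapply(parts, function(p)
                      paste(p[-1], collapse = "/"), character(1)),
                    stringsAsFactors = FALSE)
  for (cn in names(per_cancer)) {
    df <- keyed[[cn]]
    out[[cn]] <- df$delta_r[match(items, df$item_id)]
  }
  vals <- out[, names(per_cancer), drop = FALSE]
  out$frequency <- as.integer(rowSums(!is.na(vals)))
  out <- out[order(-out$frequency, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the pan-cancer bipartite miRNA-gene network
#'
#' Edges are the aggregated pairs seen in at least
#' \code{cfg$min_pair_frequency} cancer types, annotated with their frequency
#' and the list of cancers; nodes are the endpoints of retained edges
#' (isolated nodes are never emitted) and carry a regulation attribute taken
#' from the per-cancer DE directions -- \code{"mixed"} when a node is up in
#' some cancers and down in others.
#'
#' @param pair_entries \code{\link{aggregate_pairs}} output.
#' @param dems,degs named lists (cancer -> DEStatus data.frame) for miRNAs
#'   and genes, used to label node regulation.
#' @param cfg a \code{\link{threshold_config}}.
#' @return list of class \code{"bipartite_network"} with \code{nodes}
#'   (id, node_type, regulation) and \code{edges} (mirna_id, gene_id,
#'   frequency, cancers).
#' @export
build_network <- function(pair_entries, dems, degs, cfg = threshold_config()) {
  cancer_cols <- setdiff(names(pair_entries),
                         c("item_id", "mirna_id", "gene_id", "frequency"))
  keep <- pair_entries$frequency >= cfg$min_pair_frequency
  sel <- pair_entries[keep, , drop = FALSE]
  cancers <- vapply(seq_len(nrow(sel)), function(i) {
    present <- cancer_cols[!is.na(unlist(sel[i, cancer_cols]))]
    paste(present, collapse = ";")
  }, character(1))
  edges <- data.frame(mirna_id = sel$mirna_id, gene_id = sel$gene_id,
                      frequency = sel$frequency,
                      cancers = if (nrow(sel)) cancers else character(0),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  node_regulation <- function(id, status_lists) {
    dirs <- unique(unlist(lapply(status_lists, function(st)
      st$final_direction[st$feature_id == id])))
    dirs <- dirs[!is.na(dirs)]
    if (length(dirs) == 0) NA_character_
    else if (length(dirs) == 1) dirs else "mixed"
  }
  mids <- sort(unique(edges$mirna_id))
  gids <- sort(unique(edges$gene_id))
  clash <- intersect(mids, gids)
  if (length(clash) > 0)
    stopf("id(s) appear as both miRNA and gene: %s",
          paste(clash, collapse = ", "))
  nodes <- data.frame(
    id = c(mids, gids),
    node_type = c(rep("miRNA", length(mids)), rep("gene", length(gids))),
    regulation = c(vapply(mids, node_regulation, character(1), dems),
                   vapply(gids, node_regulation, character(1), degs)),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d edges, %d miRNAs, %d genes\n",
              nrow(x$edges), sum(x$nodes$node_type == "miRNA"),
              sum(x$nodes$node_type == "gene")))
  invisible(x)
}

# igraph view; also asserts bipartiteness structurally
as_igraph_network <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$mirna_id, to = net$edges$gene_id,
                   frequency = net$edges$frequency,
                   cancers = net$edges$cancers, stringsAsFactors = FALSE),
    directed = FALSE, vertices = net$nodes)
  igraph::V(g)$type <- igraph::V(g)$node_type == "gene"
  ends <- igraph::as_edgelist(g)
  tmap <- stats::setNames(net$nodes$node_type, net$nodes$id)
  if (nrow(ends) > 0 && any(tmap[ends[, 1]] == tmap[ends[, 2]]))
    stopf("network is not bipartite")
  g
}

#' Export the pan-cancer network
#'
#' \code{"sif"} writes Cytoscape simple-interaction lines
#' (\code{mirna<TAB>targets<TAB>gene}); \code{"graphml"} writes GraphML with
#' node_type/regulation node attributes and frequency/cancers edge
#' attributes; \code{"tsv"} writes a lossless edge list (including endpoint
#' regulation) that \code{\link{read_network_edgelist}} re-imports to an
#' identical network.
#'
#' @param net a \code{bipartite_network}.
#' @param format \code{"sif"}, \code{"graphml"} or \code{"tsv"}.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
export_network <- function(net, format = c("sif", "graphml", "tsv"), path) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\ttargets\t%s", net$edges$mirna_id, net$edges$gene_id)
    writeLines(lines, path)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph_network(net), path, format = "graphml")
  } else {
    reg <- stats::setNames(net$nodes$regulation, net$nodes$id)
    df <- data.frame(mirna_id = net$edges$mirna_id,
                     gene_id = net$edges$gene_id,
                     frequency = net$edges$frequency,
                     cancers = net$edges$cancers,
                     mirna_regulation = unname(reg[net$edges$mirna_id]),
                     gene_regulation = unname(reg[net$edges$gene_id]),
                     stringsAsFactors = FALSE)
    write_tsv(df, path)
  }
  invisible(path)
}

#' Re-import a network edge list written by \code{export_network(..., "tsv")}
#'
#' @param path edge-list TSV path.
#' @return a \code{bipartite_network} equal to the exported one.
#' @export
read_network_edgelist <- function(path) {
  df <- read_tsv(path)
  need <- c("mirna_id", "gene_id", "frequency", "cancers",
            "mirna_regulation", "gene_regulation")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  edges <- data.frame(mirna_id = as.character(df$mirna_id),
                      gene_id = as.character(df$gene_id),
                      frequency = as.integer(df$frequency),
                      cancers = as.character(df$cancers),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  mreg <- unique(data.frame(id = df$mirna_id, regulation = df$mirna_regulation,
                            stringsAsFactors = FALSE))
  greg <- unique(data.frame(id = df$gene_id, regulation = df$gene_regulation,
                            stringsAsFactors = FALSE))
  mreg <- mreg[order(mreg$id), , drop = FALSE]
  greg <- greg[order(greg$id), , drop = FALSE]
  nodes <- data.frame(id = c(mreg$id, greg$id),
                      node_type = c(rep("miRNA", nrow(mreg)),
                                    rep("gene", nrow(greg))),
                      regulation = c(mreg$regulation, greg$regulation),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "bipartite_network")
}

#' Parse a published wide frequency table back into per-cancer lists
#'
#' Inverse of the aggregation step for externally published tables: a wide
#' TSV with an \code{item_id} column, one column per cancer holding a status
#' token (\code{"/"} meaning absent) and a printed \code{frequency} column.
#' Feeding the result to \code{\link{aggregate_status}} or
#' \code{\link{aggregate_pairs}} recounts the frequencies independently of
#' the printed column.
#'
#' @param path TSV path.
#' @param kind \code{"status"} (direction tokens, feature rows) or
#'   \code{"pairs"} (numeric delta-r tokens, \code{"mirna/gene"} keys).
#' @return list with \code{per_cancer} (named list of per-cancer
#'   data.frames) and \code{printed} (data.frame item_id, frequency).
#' @export
read_frequency_table <- function(path, kind = c("status", "pairs")) {
  kind <- match.arg(kind)
  df <- read_tsv(path, colClasses = "character")
  need <- c("item_id", "frequency")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  cancers <- setdiff(names(df), c("item_id", "frequency", "term_name"))
  per_cancer <- lapply(cancers, function(cn) {
    tok <- df[[cn]]
    present <- tok != "/"
    if (kind == "status") {
      data.frame(feature_id = df$item_id[present],
                 final_direction = tok[present], stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(df$item_id[present], "/", fixed = TRUE)
      data.frame(mirna_id = vapply(parts, `[`, character(1), 1),
                 gene_id = vapply(parts, function(p)
                   paste(p[-1], collapse = "/"), character(1)),
                 delta_r = as.numeric(tok[present]), stringsAsFactors = FALSE)
    }
  })
  names(per_cancer) <- cancers
  list(per_cancer = per_cancer,
       printed = data.frame(item_id = df$item_id,
                            frequency = as.integer(df$frequency),
                            stringsAsFactors = FALSE))
}
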