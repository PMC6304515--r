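#' Construct a validated count matrix
#'
#' @param counts numeric matrix of non-negative integral read counts,
#'   features in rows, samples in columns, with unique non-empty dimnames.
#' @param kind feature kind, \code{"mRNA"} or \code{"miRNA"}.
#' @return an object of class \code{"count_matrix"}: a list with elements
#'   \code{counts} (integer-valued matrix) and \code{kind}.
#' @export
count_matrix <- function(counts, kind = c("mRNA", "miRNA")) {
  kind <- match.arg(kind)
  if (!is.matrix(counts)) stopf("counts must be a matrix")
  fid <- rownames(counts); sid <- colnames(counts)
  if (is.null(fid) || is.null(sid))
    stopf("counts must carry feature rownames and sample colnames")
  if (nrow(counts) == 0) stopf("count matrix has zero features")
  if (any(fid == "") || any(sid == ""))
    stopf("empty feature or sample id")
  if (anyDuplicated(fid))
    stopf("duplicate feature id(s): %s",
          paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stopf("duplicate sample id(s): %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!is.numeric(counts)) stopf("non-numeric counts")
  if (anyNA(counts)) stopf("missing values in counts")
  if (any(counts < 0)) stopf("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8)) stopf("non-integral counts")
  structure(list(counts = counts, kind = kind), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix (%s): %d features x %d samples\n",
              x$kind, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Feature and sample identifiers
#' @param x a \code{count_matrix} or \code{normalized_matrix}.
#' @return character vector of ids.
#' @export
feature_ids <- function(x) rownames(if (inherits(x, "count_matrix")) x$counts else x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(if (inherits(x, "count_matrix")) x$counts else x$values)

#' Subset a count matrix to a set of samples
#' @param x a \code{count_matrix}.
#' @param ids sample ids to keep (order preserved).
#' @return a \code{count_matrix}.
#' @export
subset_samples <- function(x, ids) {
  missing <- setdiff(ids, sample_ids(x))
  if (length(missing) > 0)
    stopf("sample id(s) not in matrix: %s", paste(missing, collapse = ", "))
  count_matrix(x$counts[, ids, drop = FALSE], x$kind)
}

#' Read a count matrix from TSV
#'
#' The file must have a header row of sample ids and one row per feature,
#' feature ids in the first column. Cells must be non-negative integers.
#'
#' @param path file path.
#' @param kind \code{"mRNA"} or \code{"miRNA"}.
#' @return a \code{count_matrix}.
#' @export
read_count_matrix <- function(path, kind = c("mRNA", "miRNA")) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1L)
  if (length(first) == 0)
    stopf("%s: zero features (empty file)", path)
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  sid <- header[-1]
  if (length(sid) == 0) stopf("%s: no sample columns", path)
  if (anyDuplicated(sid))
    stopf("%s: duplicate sample id(s): %s", path,
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stopf("%s: zero features", path)
  fid <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum))
    stopf("%s: non-numeric cell(s) in column(s): %s", path,
          paste(sid[nonnum], collapse = ", "))
  m <- as.matrix(vals)
  dimnames(m) <- list(fid, sid)
  count_matrix(m, kind)
}

#' Write a count matrix as TSV
#' @param x a \code{count_matrix}.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(feature_id = feature_ids(x), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

# ---------------------------------------------------------------------------

#' Derive the analysis group of each sample
#'
#' Normal tissue is the healthy-control group (HC) regardless of stage; tumor
#' samples with pathologic stage I or II are Early, stage III or IV are
#' Advanced, and tumors lacking stage annotation are TNS (tumor, no stage).
#'
#' @param tissue character vector, \code{"normal"} or \code{"tumor"}.
#' @param stage character vector of major stages \code{"I".."IV"} or NA.
#' @return character vector of groups HC/Early/Advanced/TNS.
#' @export
derive_group <- function(tissue, stage) {
  ifelse(tissue == "normal", "HC",
         ifelse(is.na(stage), "TNS",
                ifelse(stage %in% c("I", "II"), "Early", "Advanced")))
}

# Normalize clinical stage tokens: case-insensitive, optional "Stage "
# prefix, substage letters (IIIa -> III). Unknown tokens are an error.
parse_stage <- function(x) {
  raw <- as.character(x)
  tok <- tolower(trimws(raw))
  tok <- sub("^stage[ _]?", "", tok)
  is_na <- is.na(raw) | tok %in% c("na", "", "not available", "[not available]", "nx")
  tok <- sub("^(i{1,3}|iv|[1-4])[abc]$", "\\1", tok)  # substage -> major stage
  out <- rep(NA_character_, length(tok))
  map <- c(i = "I", ii = "II", iii = "III", iv = "IV",
           "1" = "I", "2" = "II", "3" = "III", "4" = "IV")
  known <- tok %in% names(map)
  out[known] <- map[tok[known]]
  bad <- !is_na & !known
  if (any(bad))
    stopf("unknown stage token(s): %s",
          paste(unique(raw[bad]), collapse = ", "))
  out
}

#' Read a sample annotation table
#'
#' Expects TSV columns \code{sample_id}, \code{patient_id}, \code{tissue},
#' \code{stage}. Stage tokens are accepted case-insensitively with an
#' optional \code{"Stage "} prefix, and substage suffixes (e.g. "IIIa")
#' truncate to the major stage. A \code{group} column (HC/Early/Advanced/TNS)
#' is derived per \code{\link{derive_group}}.
#'
#' @param path file path.
#' @return a data.frame with columns sample_id, patient_id, tissue, stage,
#'   group; class \code{c("sample_table","data.frame")}.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("sample_id", "patient_id", "tissue", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  sample_table(df$sample_id, df$patient_id, df$tissue, df$stage)
}

#' Build a validated sample table
#'
#' @param sample_id,patient_id character vectors; sample ids must be unique.
#' @param tissue \code{"normal"} or \code{"tumor"} (case-insensitive).
#' @param stage clinical stage tokens (see \code{\link{read_sample_table}}).
#' @return a \code{sample_table} data.frame.
#' @export
sample_table <- function(sample_id, patient_id, tissue, stage) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stopf("duplicate sample id(s): %s",
          paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  tissue <- tolower(trimws(as.character(tissue)))
  bad <- !tissue %in% c("normal", "tumor")
  if (any(bad))
    stopf("unknown tissue token in row(s) %s: %s",
          paste(which(bad), collapse = ", "),
          paste(unique(tissue[bad]), collapse = ", "))
  stage <- parse_stage(stage)
  df <- data.frame(sample_id = sample_id,
                   patient_id = as.character(patient_id),
                   tissue = tissue, stage = stage,
                   group = derive_group(tissue, stage),
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_table", "data.frame")
  df
}

# ---------------------------------------------------------------------------

#' Build a validated miRNA-target interaction database
#'
#' @param pairs data.frame with columns \code{mirna_id}, \code{gene_id} and
#'   optionally \code{sources} (semicolon-joined labels). Duplicate pairs
#'   collapse to one entry whose sources are the union of labels.
#' @return a data.frame of class \code{c("interaction_db","data.frame")} with
#'   one row per unique pair, sorted by (mirna_id, gene_id).
#' @export
interaction_db <- function(pairs) {
  need <- c("mirna_id", "gene_id")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0)
    stopf("interaction table missing column(s): %s",
          paste(miss, collapse = ", "))
  src <- if ("sources" %in% names(pairs)) as.character(pairs$sources)
         else rep("", nrow(pairs))
  key <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
  agg_src <- vapply(split(src, key), function(s) {
    labs <- sort(unique(unlist(strsplit(s, ";", fixed = TRUE))))
    paste(labs[labs != ""], collapse = ";")
  }, character(1))
  keys <- sort(unique(key))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(mirna_id = vapply(parts, `[`, character(1), 1),
                   gene_id = vapply(parts, `[`, character(1), 2),
                   sources = unname(agg_src[keys]),
                   stringsAsFactors = FALSE)
  class(df) <- c("interaction_db", "data.frame")
  df
}

#' Read and merge validated miRNA-target interaction tables
#'
#' Each file is a TSV with columns \code{mirna_id}, \code{gene_id} and an
#' optional \code{source}; files missing the source column are labelled with
#' their base file name. The union over files is taken and duplicated pairs
#' merge with the union of their source labels, mirroring the merge of
#' validated-interaction databases such as miRTarBase and miRecords.
#'
#' @param paths character vector of file paths.
#' @return an \code{interaction_db}.
#' @export
read_interactions <- function(paths) {
  parts <- lapply(paths, function(p) {
    df <- read_tsv(p, colClasses = "character")
    miss <- setdiff(c("mirna_id", "gene_id"), names(df))
    if (length(miss) > 0)
      stopf("%s: missing column(s): %s", p, paste(miss, collapse = ", "))
    if (nrow(df) == 0)
      return(data.frame(mirna_id = character(), gene_id = character(),
                        sources = character(), stringsAsFactors = FALSE))
    src <- if ("source" %in% names(df)) as.character(df$source)
           else rep(sub("\\.[^.]*$", "", basename(p)), nrow(df))
    data.frame(mirna_id = df$mirna_id, gene_id = df$gene_id, sources = src,
               stringsAsFactors = FALSE)
  })
  interaction_db(do.call(rbind, parts))
}
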