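# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a 32-bit sub-seed for an independent random stream. Streams are keyed
# by (stream id, element index) so that enlarging a cohort (more features,
# more samples) never reshuffles draws already made for existing elements.
substream_seed <- function(seed, stream, index = 0L) {
  base <- (as.double(seed) %% 1048576) + 1
  as.integer((base * 2654435 + as.double(stream) * 131071 +
                as.double(index) * 7919) %% 2147483629)
}

# Deterministic TSV writer: fixed column order is the caller's job, this
# fixes quoting/NA/eol so byte-identical inputs give byte-identical files.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
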