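# Small shared I/O helpers. All tables are plain TSV; pipeline outputs get a
# '#'-prefixed provenance header so reruns are byte-comparable.

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wb")  # binary mode: LF endings on all platforms
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con, sep = "\n")
  utils::write.table(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#", ...)
}

write_matrix_tsv <- function(m, path, id_col = "id", header = NULL) {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path, header = header)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

# Deterministic 32-bit djb2 hash of a string; used for config provenance
# lines without pulling in a hashing dependency.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
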