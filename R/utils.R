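# Round to `digits` decimals, half away from zero (the convention used
# for all reported percentages; base round() is half-to-even).
roundHalfAway <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Strict TSV reader: UTF-8, header row, tab-delimited, no quoting.
readTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8",
                    na.strings = NULL)
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Require named columns in a table read from `path`; error names the
# first missing column.
requireColumns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop("missing required column '", missing[[1L]], "' in ", path)
  invisible(TRUE)
}
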