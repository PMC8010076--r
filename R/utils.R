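# Internal helpers: classed error constructors and small utilities.

stop_dq <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "dualquant_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

config_error <- function(field, fmt, ...) {
  stop_dq("dualquant_config_error", paste0("config field '", field, "': ", fmt), ...)
}

design_error <- function(fmt, ...) stop_dq("dualquant_design_error", fmt, ...)

input_error <- function(fmt, ...) stop_dq("dualquant_input_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x, open_right = FALSE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
}

# 32-bit FNV-1a over the deparsed object; used to stamp a config fingerprint
# into output headers. Not cryptographic; collisions are inconsequential here.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a table as TSV with commented provenance header
#'
#' Writes `# key: value` comment lines followed by a tab-separated table.
#' Companion reader: [read_dq_tsv()].
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param meta named list of scalar provenance values written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_dq_tsv <- function(x, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_dq_tsv()]
#'
#' @param path file path.
#' @return data frame; header comment lines are returned in attribute `"meta"`.
#' @export
read_dq_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  attr(df, "meta") <- sub("^#\\s*", "", meta)
  df
}
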