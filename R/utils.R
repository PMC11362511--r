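# Internal helpers shared across modules.

#' TMT10plex reporter tags, in mass order
#'
#' @format Character vector of the ten reporter-channel tags.
#' @export
TMT10_TAGS <- c("126", "127N", "127C", "128N", "128C",
                "129N", "129C", "130N", "130C", "131")

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# standard deviation of log(noise) for a multiplicative log-normal factor
# with unit mean and coefficient of variation cv
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# FNV-1a hash of a character scalar, returned as 8 hex digits; used to
# fingerprint run configurations in the manifest without extra dependencies
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a double
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to avoid losing
    # precision past 2^53
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

# format numbers for TSV output: full precision, plain notation
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
}
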