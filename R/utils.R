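#' @keywords internal
"_PACKAGE"

#' @importFrom stats pbeta pchisq rbeta rbinom rnorm rpois runif var optim
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# reverse complement of plain character DNA (N allowed)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x) !grepl("[^ACGTN]", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_msi <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "msiscope_error")))
}

# serialize/parse a repeat-length histogram as "length:count,..." with
# ascending lengths -- lossless, diff-friendly
format_hist <- function(h) {
  if (length(h) == 0) return("")
  len <- as.integer(names(h))
  o <- order(len)
  paste(sprintf("%d:%d", len[o], as.integer(h)[o]), collapse = ",")
}

parse_hist <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop_msi("malformed histogram field '%s'", s, class = "msi_parse_error")
  h <- as.integer(vapply(kv, `[`, "", 2L))
  names(h) <- vapply(kv, `[`, "", 1L)
  if (anyNA(h) || anyNA(suppressWarnings(as.integer(names(h)))))
    stop_msi("malformed histogram field '%s'", s, class = "msi_parse_error")
  h
}
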