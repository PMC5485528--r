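#' @importFrom stats optimize optim runif rlnorm setNames rbinom
#' @importFrom utils read.table write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Phred+33 helpers ------------------------------------------------------

#' Convert a Phred+33 quality string to integer qualities
#' @param qual character vector of quality strings
#' @return list of integer vectors
#' @keywords internal
qual_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Convert integer Phred qualities to a Phred+33 string
#' @param q integer vector
#' @keywords internal
int_to_qual <- function(q) {
  rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L))
}

phred_to_err <- function(q) 10^(-q / 10)
err_to_phred <- function(e) round(-10 * log10(e))

# Sequence helpers ------------------------------------------------------

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Count mismatches between paired equal-length strings, vectorised.
# Strings are compared bytewise; lengths must match elementwise.
count_mismatches <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(integer(0))
  lens <- nchar(x)
  stopifnot(all(lens == nchar(y)))
  xr <- charToRaw(paste(x, collapse = ""))
  yr <- charToRaw(paste(y, collapse = ""))
  neq <- as.integer(xr != yr)
  as.integer(rowsum(neq, rep.int(seq_along(x), lens)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
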