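# Shared low-level helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; tabular reports here use the
#' conventional round-half-up so printed percentages match hand-computed
#' values (e.g. 15/26 -> 57.69).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement (without reversal) of a DNA string
#' @param x character vector of DNA strings
#' @return character vector of complements
#' @export
complement_dna <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s) of given lengths under the current RNG state.
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# Split a DNA string into a character vector of single bases.
dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# All k-mers of a string as a character vector (positions 1..n-k+1).
kmers <- function(seq, k, stride = 1L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = stride)
  substring(seq, starts, starts + k - 1L)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(dna_chars(a) != dna_chars(b))
}

# Format a proportion as a percentage string with 2 decimals, half-up.
format_percent <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.2f", round_half_up(100 * p, 2)))
}

# Wilson score interval for x successes out of n trials.
wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Write a TSV with a provenance header ("# key: value" lines).
write_tsv_report <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) {
    for (k in names(header)) {
      writeLines(sprintf("# %s: %s", k, header[[k]]), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by write_tsv_report (skips "#" header lines).
read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
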