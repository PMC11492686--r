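# FASTA / FASTQ input and output.
#
# Sequences are carried as plain data.frames with columns id, sequence and
# circular (a "seq_records" object). Parsing is delegated to Biostrings;
# validation and normalisation (case folding, U->T, alphabet checks) are
# enforced on top so every downstream consumer can assume uppercase
# A/C/G/T/N.

#' Construct a set of sequence records
#'
#' @param id character vector of unique, nonempty identifiers
#' @param sequence character vector of DNA sequences (uppercase ACGTN)
#' @param circular logical vector, whether each sequence is circular
#' @return a data.frame of class `seq_records`
#' @export
seq_records <- function(id, sequence, circular = FALSE) {
  stopifnot(length(id) == length(sequence))
  if (any(!nzchar(id))) stop("sequence ids must be nonempty")
  if (anyDuplicated(id)) stop("duplicate sequence ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- normalize_dna(sequence)
  if (any(nchar(sequence) < 1L)) stop("sequences must have length >= 1")
  df <- data.frame(id = as.character(id), sequence = sequence,
                   circular = rep_len(as.logical(circular), length(id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("seq_records", "data.frame")
  df
}

# Uppercase, map U->T, reject anything outside {A,C,G,T,N}.
normalize_dna <- function(x) {
  x <- chartr("U", "T", toupper(x))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGTN]", "", x[bad]), "")))
    stop("invalid sequence characters: ", paste(ch, collapse = " "))
  }
  x
}

#' Read a FASTA file
#'
#' Headers are truncated at the first whitespace to form ids. Sequences are
#' uppercased, U is mapped to T, and characters outside A/C/G/T/N raise a
#' format error, as do empty files and duplicate ids.
#'
#' @param path path to a FASTA file
#' @return a `seq_records` data.frame
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seq_records(ids, as.character(set))
}

#' Read long reads from FASTA or FASTQ
#'
#' Format is chosen by the first non-empty character (`>` vs `@`). FASTQ
#' quality strings are discarded: the recombination procedure uses only
#' alignment geometry.
#'
#' @param path path to a FASTA or FASTQ file
#' @return a `seq_records` data.frame
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "@")) {
    set <- Biostrings::readBStringSet(path, format = "fastq")
    if (length(set) == 0L) stop("empty FASTQ file: ", path)
    seq_records(sub("\\s.*$", "", names(set)), as.character(set))
  } else {
    read_fasta(path)
  }
}

#' Write sequence records to a FASTA file
#'
#' @param records a `seq_records` data.frame (or anything with id/sequence)
#' @param path output path
#' @param width line wrap width
#' @return the path, invisibly
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
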