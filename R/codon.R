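# Codon counting and relative synonymous codon usage (RSCU).
#
# RSCU(c) = n_c * k / sum(n_c' over the synonymous family), where k is
# the family size: the observed count divided by the expectation under
# uniform usage within the family. Single-codon families (ATG, TGG under
# the standard code) therefore have RSCU identically 1 whenever observed.

#' Count codons in a CDS set
#'
#' Reads frame-0 triplets from each sequence. Trailing incomplete codons
#' are trimmed with a warning; codons containing N are skipped and
#' tallied; stop codons are counted separately and excluded from sense
#' counts.
#'
#' @param records a `seq_records` of CDS sequences
#' @param genetic_code named character vector mapping codons to amino
#'   acids ("*" = stop); defaults to the standard code, which plant
#'   mitochondria use
#' @return list of class `codon_counts`: `counts` (named integer over
#'   sense codons), `stop_counts`, `n_skipped`, `n_sequences`,
#'   `n_codons_total`, `genetic_code`
#' @export
count_codons <- function(records, genetic_code = Biostrings::GENETIC_CODE) {
  code <- stats::setNames(as.character(genetic_code),
                          chartr("U", "T", names(genetic_code)))
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  counts <- stats::setNames(integer(length(sense)), sense)
  stop_counts <- stats::setNames(integer(length(stops)), stops)
  n_skipped <- 0L
  n_used <- 0L
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    n <- nchar(s)
    if (n < 6L) {
      warning("sequence ", records$id[i], " shorter than 6 nt; skipped")
      next
    }
    if (n %% 3L != 0L) {
      warning("sequence ", records$id[i],
              " length not a multiple of 3; trailing bases trimmed")
      n <- n - n %% 3L
    }
    starts <- seq.int(1L, n, by = 3L)
    cods <- substring(s, starts, starts + 2L)
    n_used <- n_used + 1L
    withN <- grepl("N", cods, fixed = TRUE)
    n_skipped <- n_skipped + sum(withN)
    t2 <- table(cods[!withN])
    is_stop <- names(t2) %in% stops
    counts[names(t2)[!is_stop]] <-
      counts[names(t2)[!is_stop]] + as.integer(t2[!is_stop])
    stop_counts[names(t2)[is_stop]] <-
      stop_counts[names(t2)[is_stop]] + as.integer(t2[is_stop])
  }
  structure(list(counts = counts, stop_counts = stop_counts,
                 n_skipped = n_skipped, n_sequences = n_used,
                 n_codons_total = sum(counts) + sum(stop_counts),
                 genetic_code = code),
            class = "codon_counts")
}

#' Relative synonymous codon usage
#'
#' @param counts a `codon_counts` object from [count_codons()]
#' @return data.frame: codon, amino_acid, count, family_size, rscu
#'   (NA for families with zero observations), aa_fraction (per-row copy
#'   of the amino acid's share of all sense codons)
#' @export
rscu <- function(counts) {
  code <- counts$genetic_code
  sense <- names(counts$counts)
  aa <- code[sense]
  fam_total <- tapply(counts$counts, aa, sum)
  fam_size <- table(aa)
  total_sense <- sum(counts$counts)
  vals <- ifelse(fam_total[aa] > 0,
                 counts$counts * as.integer(fam_size[aa]) / fam_total[aa],
                 NA_real_)
  data.frame(codon = sense, amino_acid = unname(aa),
             count = unname(counts$counts),
             family_size = as.integer(fam_size[aa]),
             rscu = unname(vals),
             aa_fraction = unname(
               if (total_sense > 0) fam_total[aa] / total_sense
               else rep(NA_real_, length(aa))),
             stringsAsFactors = FALSE)
}

#' Write an RSCU table as TSV
#' @param tab data.frame from [rscu()]
#' @param path output path
#' @param header optional provenance header
#' @return the path, invisibly
#' @export
write_rscu_table <- function(tab, path, header = NULL) {
  write_tsv_report(tab, path, header)
}
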