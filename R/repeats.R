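# SSR and dispersed-repeat detection.
#
# SSRs follow the MISA convention: perfect tandem runs of a 1-6 bp motif
# meeting per-class minimum copy numbers (default 10, 5, 4, 3, 3, 3 for
# mono- through hexanucleotide motifs). Dispersed repeats follow the
# REPuter classes: maximal pairs of similar intervals under one of four
# orientation transforms (forward, reverse, complement, palindromic),
# with a Hamming-distance bound (no indels), a minimum length, and an
# output cap.

#' Find simple sequence repeats
#'
#' Reports maximal perfect tandem runs of 1-6 bp motifs whose copy number
#' meets the class threshold. A run is reported once, under its shortest
#' primitive motif (no rotated or periodic duplicates); the trailing
#' partial copy, if any, is not counted, so the reported interval length
#' is motif length x repeat count.
#'
#' @param seq DNA string
#' @param thresholds integer vector of minimum copy numbers for motif
#'   lengths 1..6
#' @param sequence_id id stored in the output rows
#' @return data.frame: sequence_id, motif, motif_length, repeat_count,
#'   start, end (1-based inclusive)
#' @export
find_ssrs <- function(seq, thresholds = c(10L, 5L, 4L, 3L, 3L, 3L),
                      sequence_id = "seq") {
  stopifnot(length(thresholds) == 6L)
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  ch <- dna_chars(seq)
  out <- list()
  for (m in 1:6) {
    if (n < m * thresholds[m]) next
    eq <- ch[seq_len(n - m)] == ch[seq_len(n - m) + m]
    # maximal TRUE runs of eq: run starting at i of length r means
    # seq[i .. i+r+m-1] has period m
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]
      total <- r$lengths[k] + m
      copies <- total %/% m
      if (copies < thresholds[m]) next
      motif <- substr(seq, i, i + m - 1L)
      if (motif_period(motif) < m) next   # covered by a shorter motif class
      if (grepl("N", motif, fixed = TRUE)) next
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = sequence_id, motif = motif, motif_length = m,
        repeat_count = copies, start = i, end = i + m * copies - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sequence_id = character(0), motif = character(0),
                      motif_length = integer(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$motif_length), , drop = FALSE]
}

# Smallest period of a string (m if primitive).
motif_period <- function(motif) {
  m <- nchar(motif)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L &&
        motif == paste(rep(substr(motif, 1L, d), m / d), collapse = "")) {
      return(d)
    }
  }
  m
}

# Maximal <=k-mismatch windows along one diagonal, given a logical match
# vector. Returns data.frame(start, end, mismatches) in vector coordinates;
# only windows of length >= min_len.
diagonal_windows <- function(match_vec, max_mismatch, min_len) {
  n <- length(match_vec)
  mm <- which(!match_vec)
  bounds <- c(0L, mm, n + 1L)
  k <- max_mismatch
  nb <- length(bounds)
  if (nb - 2L <= k) {
    # few enough mismatches: whole vector is the single maximal window
    return(data.frame(start = 1L, end = n, mismatches = nb - 2L)[
      n >= min_len, , drop = FALSE])
  }
  t <- seq_len(nb - k - 1L)
  start <- bounds[t] + 1L
  end <- bounds[t + k + 1L] - 1L
  len <- end - start + 1L
  keep <- len >= min_len
  data.frame(start = start[keep], end = end[keep],
             mismatches = vapply(t[keep], function(i)
               sum(mm > bounds[i] & mm < bounds[i + k + 1L]), integer(1)))
}

# Transform a sequence for a dispersed-repeat class; returns the
# transformed string of seq2 plus a coordinate mapper back to seq2.
class_transform <- function(seq2, class) {
  n <- nchar(seq2)
  switch(class,
    forward = list(seq = seq2,
                   map = function(s, e) c(s, e)),
    reverse = list(seq = paste(rev(dna_chars(seq2)), collapse = ""),
                   map = function(s, e) c(n - e + 1L, n - s + 1L)),
    complement = list(seq = complement_dna(seq2),
                      map = function(s, e) c(s, e)),
    palindromic = list(seq = revcomp(seq2),
                       map = function(s, e) c(n - e + 1L, n - s + 1L)))
}

#' Find dispersed repeats
#'
#' Detects maximal pairs of intervals whose sequences match under one of
#' the four orientation transforms with at most `max_mismatch`
#' substitutions (Hamming distance; indels are not modelled) and length
#' at least `min_len`. Candidate diagonals come from shared exact seeds
#' (pigeonhole: a qualifying repeat must contain an exact run of length
#' `>= ceiling((min_len - max_mismatch) / (max_mismatch + 1))`); each
#' candidate diagonal is then scanned exactly. Self-overlapping pairs are
#' excluded (they belong to tandem analysis) and each unordered pair is
#' reported once. Output is truncated to `cap` rows by descending length.
#'
#' @param seq DNA string (self-comparison), or use `seq2` to compare two
#'   sequences
#' @param min_len minimum repeat length (default 30)
#' @param max_mismatch maximum Hamming distance (default 3)
#' @param cap maximum number of reported repeats (default 5000)
#' @param classes subset of c("forward","palindromic","reverse",
#'   "complement")
#' @param seq2 optional second sequence (e.g. a second molecule)
#' @return data.frame: class, start1, end1, start2, end2, length,
#'   mismatches
#' @export
find_dispersed <- function(seq, min_len = 30L, max_mismatch = 3L,
                           cap = 5000L,
                           classes = c("forward", "palindromic",
                                       "reverse", "complement"),
                           seq2 = NULL) {
  seq <- normalize_dna(seq)
  self <- is.null(seq2)
  seq2 <- if (self) seq else normalize_dna(seq2)
  seed <- max(4L, min(32L,
                      as.integer(ceiling((min_len - max_mismatch) /
                                           (max_mismatch + 1)))))
  ch1 <- dna_chars(seq)
  out <- list()
  for (cls in classes) {
    tr <- class_transform(seq2, cls)
    ch2 <- dna_chars(tr$seq)
    n1 <- length(ch1); n2 <- length(ch2)
    k1 <- kmers(seq, seed)
    k2 <- kmers(tr$seq, seed)
    # forward self-comparison: every k-mer trivially matches itself, so
    # only k-mers occurring more than once can seed a genuine repeat
    common <- if (self && cls == "forward") {
      unique(k1[duplicated(k1)])
    } else intersect(k1, k2)
    if (!length(common)) next
    i1 <- which(k1 %in% common)
    i2 <- which(k2 %in% common)
    pos1 <- split(i1, k1[i1])[common]
    pos2 <- split(i2, k2[i2])[common]
    diags <- unique(unlist(lapply(common, function(km) {
      as.vector(outer(pos2[[km]], pos1[[km]], "-"))
    })))
    for (d in diags) {
      if (self && cls == "forward" && d == 0L) next   # trivial identity
      i0 <- max(1L, 1L - d)            # seq1 start of diagonal
      j0 <- i0 + d                      # transformed seq2 start
      len <- min(n1 - i0, n2 - j0) + 1L
      if (len < min_len) next
      idx <- seq_len(len)
      mv <- ch1[i0 + idx - 1L] == ch2[j0 + idx - 1L]
      wins <- diagonal_windows(mv, max_mismatch, min_len)
      for (w in seq_len(nrow(wins))) {
        s1 <- i0 + wins$start[w] - 1L
        e1 <- i0 + wins$end[w] - 1L
        m2 <- tr$map(j0 + wins$start[w] - 1L, j0 + wins$end[w] - 1L)
        out[[length(out) + 1L]] <- data.frame(
          class = cls, start1 = s1, end1 = e1,
          start2 = m2[1], end2 = m2[2],
          length = e1 - s1 + 1L, mismatches = wins$mismatches[w],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(class = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), length = integer(0),
                      mismatches = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  if (self) {
    # drop the trivial full-length self match and canonicalize pairs
    res <- res[!(res$class == "forward" &
                   res$start1 == res$start2 & res$end1 == res$end2), ,
               drop = FALSE]
    flip <- res$start2 < res$start1 |
      (res$start2 == res$start1 & res$end2 < res$end1)
    tmp <- res[flip, c("start2", "end2", "start1", "end1")]
    res[flip, c("start1", "end1", "start2", "end2")] <- tmp
    res <- unique(res)
    # exclude self-overlapping pairs (tandem territory)
    res <- res[res$start2 > res$end1 | res$start1 > res$end2, , drop = FALSE]
  }
  res <- res[order(-res$length, res$start1, res$start2), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, cap)
}

#' Bin dispersed repeats by length and class
#'
#' Uses the conventional bins 30-39, 40-49, 50-99, 100-399 and >= 400 bp.
#'
#' @param repeats data.frame from [find_dispersed()]
#' @return list with `counts` (class x bin matrix) and `fractions`
#' @export
bin_dispersed <- function(repeats) {
  bins <- c("30-39", "40-49", "50-99", "100-399", ">=400")
  classes <- c("forward", "palindromic", "reverse", "complement")
  cut_bin <- function(len) {
    findInterval(len, c(30, 40, 50, 100, 400))
  }
  counts <- matrix(0L, nrow = length(classes), ncol = length(bins),
                   dimnames = list(classes, bins))
  if (nrow(repeats)) {
    b <- cut_bin(repeats$length)
    keep <- b >= 1L
    t2 <- table(factor(repeats$class[keep], levels = classes),
                factor(bins[b[keep]], levels = bins))
    counts[] <- as.integer(t2)
  }
  total <- sum(counts)
  list(counts = counts,
       fractions = if (total > 0) counts / total else counts)
}
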