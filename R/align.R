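# Long-read to window alignment: k-mer anchoring with chained extension.
#
# The engine indexes each window's k-mers, collects shared k-mers with the
# read as anchors, keeps the densest diagonal band, and chains anchors by
# increasing read position. Gaps between consecutive anchors are scored by
# direct character comparison when they are length-matched (pure
# substitutions) and by Levenshtein edit counts otherwise; unanchored read
# tails are projected ungapped onto the window. This recovers exact
# coordinates for substitution-only reads and close approximations under
# indels, which is all the downstream flanking-coverage rule needs. Any
# external local aligner producing window/read intervals, strand and
# identity could be substituted behind the same record shape.

#' Alignment parameters
#'
#' @param k anchor k-mer size (window must be at least k long)
#' @param stride sample every `stride`-th read k-mer (speed/sensitivity
#'   trade-off; 1 = every position)
#' @param band diagonal band half-width for anchor clustering (bp)
#' @param min_identity minimum alignment identity to report (long-read
#'   error regime default 0.70)
#' @param min_anchors minimum number of chained anchors
#' @return list of parameters
#' @export
align_params <- function(k = 15L, stride = 3L, band = 100L,
                         min_identity = 0.70, min_anchors = 3L) {
  list(k = as.integer(k), stride = as.integer(stride), band = as.integer(band),
       min_identity = min_identity, min_anchors = as.integer(min_anchors))
}

# Align one read (one strand, pre-extracted k-mers) against one indexed
# window. widx: list(kmers = character vector of window k-mers, seq, n)
align_one <- function(read_seq, qk, qpos, widx, params) {
  k <- params$k
  if (!length(qk)) return(NULL)
  wpos <- match(qk, widx$kmers)
  hit <- !is.na(wpos)
  if (sum(hit) < params$min_anchors) return(NULL)
  q <- qpos[hit]; w <- wpos[hit]
  diag <- w - q
  # densest diagonal bucket (plus neighbors) defines the band
  bucket <- round(diag / params$band)
  tb <- tabulate(bucket - min(bucket) + 1L)
  centre <- which.max(tb) + min(bucket) - 1L
  keep <- abs(bucket - centre) <= 1L
  q <- q[keep]; w <- w[keep]
  if (length(q) < params$min_anchors) return(NULL)
  o <- order(q)
  q <- q[o]; w <- w[o]
  # enforce strictly increasing window positions (greedy chain); the
  # running maximum of kept positions equals the running maximum overall
  keep <- w > c(-1L, cummax(w)[-length(w)])
  q <- q[keep]; w <- w[keep]
  nA <- length(q)
  if (nA < params$min_anchors) return(NULL)

  # anchor k-mers: matched bases = union coverage of the anchor intervals
  matches <- sum(pmin(k, diff(q))) + k
  mismatches <- 0L; gaps <- 0L
  # inter-anchor gaps (only where anchors do not overlap)
  for (i in which(diff(q) > k | diff(w) > k)) {
    gq <- q[i + 1L] - (q[i] + k)
    gw <- w[i + 1L] - (w[i] + k)
    if (gq == gw) {
      a <- substr(read_seq, q[i] + k, q[i + 1L] - 1L)
      b <- substr(widx$seq, w[i] + k, w[i + 1L] - 1L)
      d <- hamming(a, b)
      mismatches <- mismatches + d
      matches <- matches + gq - d
    } else {
      a <- substr(read_seq, max(q[i] + k, 1L), q[i + 1L] - 1L)
      b <- substr(widx$seq, max(w[i] + k, 1L), w[i + 1L] - 1L)
      cnt <- attr(utils::adist(a, b, counts = TRUE), "counts")[1, 1, ]
      mismatches <- mismatches + cnt[["sub"]]
      gaps <- gaps + cnt[["ins"]] + cnt[["del"]]
      matches <- matches + min(nchar(a), nchar(b)) - cnt[["sub"]]
    }
  }
  # project unanchored tails ungapped onto the window, clipped at edges
  rlen <- nchar(read_seq)
  left_ext <- min(q[1] - 1L, w[1] - 1L)
  right_ext <- min(rlen - (q[nA] + k - 1L), widx$n - (w[nA] + k - 1L))
  if (left_ext > 0L) {
    a <- substr(read_seq, q[1] - left_ext, q[1] - 1L)
    b <- substr(widx$seq, w[1] - left_ext, w[1] - 1L)
    d <- hamming(a, b)
    mismatches <- mismatches + d; matches <- matches + left_ext - d
  }
  if (right_ext > 0L) {
    a <- substr(read_seq, q[nA] + k, q[nA] + k - 1L + right_ext)
    b <- substr(widx$seq, w[nA] + k, w[nA] + k - 1L + right_ext)
    d <- hamming(a, b)
    mismatches <- mismatches + d; matches <- matches + right_ext - d
  }
  aln_len <- matches + mismatches + gaps
  if (aln_len == 0L) return(NULL)
  identity <- matches / aln_len
  if (identity < params$min_identity) return(NULL)
  list(window_start = w[1] - left_ext, window_end = w[nA] + k - 1L + right_ext,
       read_start = q[1] - left_ext, read_end = q[nA] + k - 1L + right_ext,
       identity = identity,
       score = matches - 2L * mismatches - 3L * gaps)
}

# Precompute a window index.
index_window <- function(seq, k) {
  list(kmers = kmers(seq, k), seq = seq, n = nchar(seq))
}

#' Align reads against repeat windows
#'
#' Both strands of every read are searched against every window; for each
#' read x window the best-scoring local alignment meeting the identity
#' floor is reported.
#'
#' @param reads a `seq_records` of long reads
#' @param windows a `repeat_windows` data.frame (see [build_windows()])
#' @param params an [align_params()] list
#' @return data.frame of read alignments: read_id, window_id,
#'   window_start, window_end, read_start, read_end, strand, identity,
#'   score
#' @export
align_reads <- function(reads, windows, params = align_params()) {
  if (nrow(reads) == 0L || nrow(windows) == 0L) {
    stop("alignment requires nonempty reads and windows")
  }
  if (any(nchar(windows$sequence) < params$k)) {
    stop("window shorter than anchor k-mer size")
  }
  idx <- lapply(windows$sequence, index_window, k = params$k)
  rc <- revcomp(reads$sequence)
  out <- vector("list", nrow(reads) * nrow(windows))
  n_out <- 0L
  for (i in seq_len(nrow(reads))) {
    strands <- list("+" = reads$sequence[i], "-" = rc[i])
    qks <- lapply(strands, kmers, k = params$k, stride = params$stride)
    qpos <- lapply(qks, function(x)
      seq.int(1L, by = params$stride, length.out = length(x)))
    for (j in seq_len(nrow(windows))) {
      best <- NULL; best_strand <- "+"
      for (strand in c("+", "-")) {
        a <- align_one(strands[[strand]], qks[[strand]], qpos[[strand]],
                       idx[[j]], params)
        if (!is.null(a) && (is.null(best) || a$score > best$score)) {
          best <- a; best_strand <- strand
        }
      }
      if (!is.null(best)) {
        n_out <- n_out + 1L
        out[[n_out]] <- data.frame(
          read_id = reads$id[i], window_id = windows$window_id[j],
          window_start = best$window_start, window_end = best$window_end,
          read_start = best$read_start, read_end = best$read_end,
          strand = best_strand, identity = best$identity,
          score = best$score, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_out == 0L) {
    return(data.frame(read_id = character(0), window_id = character(0),
                      window_start = integer(0), window_end = integer(0),
                      read_start = integer(0), read_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      score = numeric(0)))
  }
  do.call(rbind, out[seq_len(n_out)])
}
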