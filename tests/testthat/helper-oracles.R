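# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately use different algorithms from the package
# implementations they check.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# --- SSR oracle: per-position forward scan -------------------------------
# For every (start, motif length) pair, count the maximal periodic extent
# by direct character comparison and keep leftmost, primitive,
# threshold-meeting runs.
ssr_bruteforce <- function(seq, thresholds = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  ch <- chars(seq)
  n <- length(ch)
  out <- list()
  for (m in 1:6) {
    for (i in seq_len(max(0L, n - m * thresholds[m] + 1L))) {
      # leftmost: the base before must break the period
      if (i > 1L && i + m - 1L <= n && ch[i - 1L] == ch[i + m - 1L]) next
      ext <- m
      while (i + ext <= n && ch[i + ext] == ch[i + ext - m]) ext <- ext + 1L
      copies <- ext %/% m
      if (copies < thresholds[m]) next
      motif <- paste(ch[i:(i + m - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      # primitive motif: no smaller period
      primitive <- TRUE
      for (d in seq_len(m - 1L)) {
        if (m %% d == 0L &&
            motif == strrep(substr(motif, 1L, d), m / d)) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, motif_length = m, repeat_count = copies,
        start = i, end = i + m * copies - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), motif_length = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$motif_length), , drop = FALSE]
}

# --- dispersed-repeat oracle: two-pointer sliding window per diagonal ----
oracle_transform <- function(s, class) {
  ch <- chars(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  switch(class,
    forward = ch,
    reverse = rev(ch),
    complement = unname(comp[ch]),
    palindromic = unname(comp[rev(ch)]))
}

dispersed_bruteforce <- function(seq, min_len = 30L, max_mismatch = 3L,
                                 classes = c("forward", "palindromic",
                                             "reverse", "complement")) {
  ch1 <- chars(seq)
  n <- length(ch1)
  out <- list()
  for (cls in classes) {
    ch2 <- oracle_transform(seq, cls)
    for (d in (-(n - 1L)):(n - 1L)) {
      i0 <- max(1L, 1L - d)
      len <- min(n - i0, n - (i0 + d)) + 1L
      if (len < min_len) next
      mv <- ch1[i0:(i0 + len - 1L)] == ch2[(i0 + d):(i0 + d + len - 1L)]
      # candidate windows start right after a mismatch (or at the
      # diagonal start) and end right before the (k+1)-th following
      # mismatch (or at the diagonal end)
      mm_pos <- which(!mv)
      M <- length(mm_pos)
      k <- max_mismatch
      t <- 0:M
      lo <- c(1L, mm_pos + 1L)
      hi <- ifelse(t + k + 1L <= M,
                   c(mm_pos, len + 1L)[pmin(t + k + 1L, M + 1L)] - 1L,
                   len)
      n_mm <- pmin(M, t + k) - t
      # a window is maximal iff it cannot be widened: left edge at the
      # diagonal start or already carrying the full mismatch budget (the
      # right edge is blocked by construction of hi)
      keep <- (hi - lo + 1L >= min_len) & (lo == 1L | n_mm == k) & hi >= lo
      for (w in which(keep)) {
        stopifnot(sum(!mv[lo[w]:hi[w]]) == n_mm[w])   # verify directly
        s1 <- i0 + lo[w] - 1L
        e1 <- i0 + hi[w] - 1L
        j_s <- i0 + d + lo[w] - 1L
        j_e <- i0 + d + hi[w] - 1L
        m2 <- if (cls %in% c("reverse", "palindromic")) {
          c(n - j_e + 1L, n - j_s + 1L)
        } else c(j_s, j_e)
        out[[length(out) + 1L]] <- data.frame(
          class = cls, start1 = s1, end1 = e1,
          start2 = m2[1], end2 = m2[2], length = hi[w] - lo[w] + 1L,
          mismatches = n_mm[w], stringsAsFactors = FALSE)
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
  res <- res[!(res$class == "forward" &
                 res$start1 == res$start2 & res$end1 == res$end2), ,
             drop = FALSE]
  flip <- res$start2 < res$start1 |
    (res$start2 == res$start1 & res$end2 < res$end1)
  tmp <- res[flip, c("start2", "end2", "start1", "end1")]
  res[flip, c("start1", "end1", "start2", "end2")] <- tmp
  res <- unique(res)
  res <- res[res$start2 > res$end1 | res$start1 > res$end2, , drop = FALSE]
  res <- res[order(-res$length, res$start1, res$start2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# canonical key for comparing repeat sets
dispersed_key <- function(df) {
  sort(sprintf("%s:%d-%d/%d-%d", df$class, df$start1, df$end1,
               df$start2, df$end2))
}

# --- spanning-support oracle ---------------------------------------------
# Decide support by explicitly counting covered flank positions.
support_oracle <- function(a, b, rs, re, min_flank) {
  covers_repeat <- a <= rs && b >= re
  left_flank <- sum((a:b) >= (rs - min_flank) & (a:b) <= (rs - 1L))
  right_flank <- sum((a:b) >= (re + 1L) & (a:b) <= (re + min_flank))
  covers_repeat && left_flank >= min_flank && right_flank >= min_flank
}

# --- shared toy fixture ---------------------------------------------------
toy_with_reads <- function(seed, p, read_count,
                           error_rates = c(sub = 0, ins = 0, del = 0)) {
  sc <- sim_config(seed = seed, mixture = p, read_count = read_count,
                   error_rates = error_rates)
  toy <- make_toy_genome(sc)
  confs <- repeat_conformations(toy$graph, "R1")
  iso <- lapply(confs, mitorecomb:::molecule_seqs, graph = toy$graph)
  sim <- simulate_reads(iso, c(reference = 1 - p, crossover = p), sc)
  list(toy = toy, confs = confs, iso = iso, reads = sim$reads,
       truth = sim$truth, config = sc)
}
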