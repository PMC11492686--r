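# Mitochondrial plastid DNA (MTPT) detection.
#
# Chloroplast-derived segments in the mitogenome are found by seeded
# ungapped local alignment on both strands, scored match +1 / mismatch -2,
# with significance assessed by the ungapped Karlin-Altschul formula
# E = K * m * n * exp(-lambda * S) (lambda ~ 1.28, K ~ 0.46 for these
# scores). Retained hits are merged on mitogenome coordinates to report
# total transferred length and genome fraction, optionally listing fully
# contained chloroplast genes.

#' MTPT search parameters
#' @param word_size exact seed length (BLASTN-like default 11)
#' @param evalue E-value threshold (default 1e-5)
#' @param xdrop maximum extension radius around a seed cluster (bp)
#' @param lambda,K Karlin-Altschul parameters for +1/-2 ungapped scoring
#' @return parameter list
#' @export
mtpt_params <- function(word_size = 11L, evalue = 1e-5, xdrop = 4000L,
                        lambda = 1.28, K = 0.46) {
  list(word_size = as.integer(word_size), evalue = evalue,
       xdrop = as.integer(xdrop), lambda = lambda, K = K)
}

# Best-scoring segment (match +1 / mismatch -2) of a logical match vector,
# restricted to segments containing at least one position of `anchor`.
best_segment <- function(mv) {
  sc <- ifelse(mv, 1, -2)
  cs <- c(0, cumsum(sc))
  # max over j>i of cs[j]-cs[i]: track running minimum
  runmin <- cummin(cs[-length(cs)])
  gain <- cs[-1] - runmin
  j <- which.max(gain)
  i <- which.min(cs[seq_len(j)])   # position of running min used
  list(start = i, end = j, score = gain[j],
       matches = sum(mv[i:j]), mismatches = sum(!mv[i:j]))
}

#' Seeded ungapped local search between a mitogenome and a chloroplast
#' genome
#'
#' @param mt mitogenome DNA string (or single-row `seq_records`)
#' @param cp chloroplast DNA string
#' @param params an [mtpt_params()] list
#' @return data.frame of hits: mt_start, mt_end, cp_start, cp_end,
#'   strand, identity, length, score, evalue
#' @export
local_search <- function(mt, cp, params = mtpt_params()) {
  if (is.data.frame(mt)) mt <- mt$sequence[1]
  if (is.data.frame(cp)) cp <- cp$sequence[1]
  mt <- normalize_dna(mt); cp <- normalize_dna(cp)
  w <- params$word_size
  if (nchar(mt) < w || nchar(cp) < w) {
    stop("genome shorter than the seed length")
  }
  m <- nchar(mt); n <- nchar(cp)
  ch_mt <- dna_chars(mt)
  mtk <- kmers(mt, w)
  hits <- list()
  for (strand in c("+", "-")) {
    cps <- if (strand == "+") cp else revcomp(cp)
    ch_cp <- dna_chars(cps)
    cpk <- kmers(cps, w)
    common <- intersect(mtk, cpk)
    if (!length(common)) next
    im <- which(mtk %in% common)
    ic <- which(cpk %in% common)
    pos_mt <- split(im, mtk[im])[common]
    pos_cp <- split(ic, cpk[ic])[common]
    seeds <- do.call(rbind, lapply(common, function(km) {
      cbind(rep(pos_mt[[km]], each = length(pos_cp[[km]])),
            rep(pos_cp[[km]], times = length(pos_mt[[km]])))
    }))
    diag <- seeds[, 2] - seeds[, 1]
    for (d in unique(diag)) {
      sp <- seeds[diag == d, 1]           # mt positions of seeds
      # cluster seeds on this diagonal; extend around each cluster
      sp <- sort(unique(sp))
      cl <- cumsum(c(1L, diff(sp) > params$xdrop))
      for (g in unique(cl)) {
        cs <- sp[cl == g]
        lo <- max(1L, min(cs) - params$xdrop, 1L - d)
        hi <- min(m, max(cs) + w - 1L + params$xdrop, n - d)
        if (hi - lo + 1L < w) next
        idx <- lo:hi
        mv <- ch_mt[idx] == ch_cp[idx + d]
        seg <- best_segment(mv)
        S <- seg$score
        E <- params$K * as.numeric(m) * n * exp(-params$lambda * S)
        if (E > params$evalue) next
        mt_s <- lo + seg$start - 1L
        mt_e <- lo + seg$end - 1L
        cp_s <- mt_s + d; cp_e <- mt_e + d
        if (strand == "-") {
          tmp <- cp_s
          cp_s <- n - cp_e + 1L
          cp_e <- n - tmp + 1L
        }
        hits[[length(hits) + 1L]] <- data.frame(
          mt_start = mt_s, mt_end = mt_e, cp_start = cp_s, cp_end = cp_e,
          strand = strand,
          identity = seg$matches / (seg$matches + seg$mismatches),
          length = mt_e - mt_s + 1L, score = S, evalue = E,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(mt_start = integer(0), mt_end = integer(0),
                      cp_start = integer(0), cp_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      length = integer(0), score = numeric(0),
                      evalue = numeric(0)))
  }
  res <- unique(do.call(rbind, hits))
  # collapse duplicate/contained hits on the same mt interval
  o <- order(res$mt_start, -res$length)
  res <- res[o, , drop = FALSE]
  keep <- !logical(nrow(res))
  if (nrow(res) > 1L) {
    for (i in 2:nrow(res)) {
      j <- which(keep[seq_len(i - 1L)])
      contained <- any(res$mt_start[j] <= res$mt_start[i] &
                         res$mt_end[j] >= res$mt_end[i] &
                         res$cp_start[j] <= res$cp_start[i] &
                         res$cp_end[j] >= res$cp_end[i])
      if (contained) keep[i] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Locate large chloroplast repeats (inverted-repeat-like duplications)
#'
#' Self-comparison of the chloroplast genome (via [find_dispersed()] at a
#' 1 kb minimum) returns the intervals of large duplications such as the
#' canonical inverted repeat, so MTPT hits duplicated by them can be
#' deduplicated rather than double-counted.
#'
#' @param cp chloroplast DNA string
#' @param min_len minimum duplication length (default 1000)
#' @return data.frame with columns start, end (one row per repeat copy)
#' @export
mask_cp_repeats <- function(cp, min_len = 1000L) {
  rep_df <- find_dispersed(cp, min_len = min_len, max_mismatch = 3L)
  if (!nrow(rep_df)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(
    start = c(rep_df$start1, rep_df$start2),
    end = c(rep_df$end1, rep_df$end2)))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

#' Summarize MTPT hits
#'
#' Deduplicates hits whose chloroplast intervals fall in distinct copies
#' of a chloroplast repeat but cover the same mitogenome interval
#' (keeping the best E-value), merges the retained mitogenome intervals,
#' and reports total transferred length and its fraction of the
#' mitogenome. If a chloroplast gene annotation is supplied, genes whose
#' full span lies inside some hit's chloroplast interval are listed by
#' category.
#'
#' @param hits data.frame from [local_search()] (or with at least
#'   mt_start/mt_end, cp_start/cp_end, evalue)
#' @param cp_repeats data.frame from [mask_cp_repeats()] (may be empty)
#' @param mt_length mitogenome length in bp
#' @param annotations optional data.frame with columns gene, type (e.g.
#'   "PCG", "rRNA", "tRNA"), start, end on the chloroplast genome
#' @return list of class `mtpt_summary`: `intervals` (merged mt
#'   intervals), `total_length`, `fraction` (raw), `percent` (2-decimal
#'   half-up), `n_fragments`, `contained_genes`
#' @export
summarize_mtpt <- function(hits, cp_repeats = NULL, mt_length,
                           annotations = NULL) {
  if (is.null(cp_repeats)) cp_repeats <- data.frame(start = integer(0),
                                                    end = integer(0))
  if (nrow(hits) > 1L && nrow(cp_repeats)) {
    rr <- IRanges::IRanges(cp_repeats$start, cp_repeats$end)
    in_rep <- IRanges::overlapsAny(
      IRanges::IRanges(hits$cp_start, hits$cp_end), rr)
    # among repeat-borne hits, drop worse-E duplicates of the same mt span
    o <- order(hits$evalue)
    drop <- logical(nrow(hits))
    seen <- IRanges::IRanges()
    for (i in o) {
      if (!in_rep[i]) next
      iv <- IRanges::IRanges(hits$mt_start[i], hits$mt_end[i])
      ov <- IRanges::findOverlaps(iv, seen)
      dup <- FALSE
      if (length(ov)) {
        w <- IRanges::width(IRanges::pintersect(
          rep(iv, length(ov)), seen[S4Vectors::subjectHits(ov)]))
        dup <- any(w / IRanges::width(iv) > 0.9)
      }
      if (dup) drop[i] <- TRUE else seen <- c(seen, iv)
    }
    hits <- hits[!drop, , drop = FALSE]
  }
  merged <- if (nrow(hits)) {
    IRanges::reduce(IRanges::IRanges(hits$mt_start, hits$mt_end))
  } else IRanges::IRanges()
  total <- sum(IRanges::width(merged))
  fraction <- total / mt_length
  contained <- NULL
  if (!is.null(annotations) && nrow(hits)) {
    cp_iv <- IRanges::IRanges(hits$cp_start, hits$cp_end)
    g_iv <- IRanges::IRanges(annotations$start, annotations$end)
    full <- IRanges::overlapsAny(g_iv, cp_iv, type = "within")
    contained <- annotations[full, c("gene", "type"), drop = FALSE]
  }
  structure(list(
    intervals = data.frame(start = IRanges::start(merged),
                           end = IRanges::end(merged)),
    total_length = total, fraction = fraction,
    percent = round_half_up(100 * fraction, 2),
    n_fragments = length(merged),
    contained_genes = contained), class = "mtpt_summary")
}

#' @export
print.mtpt_summary <- function(x, ...) {
  cat("MTPTs:", x$n_fragments, "merged fragments,", x$total_length,
      "bp (", sprintf("%.2f%%", x$percent), "of the mitogenome )\n")
  if (!is.null(x$contained_genes) && nrow(x$contained_genes)) {
    cat("contained full genes:",
        paste(x$contained_genes$gene, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read gene annotations from GFF3 or BED
#'
#' Minimal reader for the optional gene-containment step: returns gene
#' name, a coarse type (PCG/rRNA/tRNA) and 1-based inclusive coordinates.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file
#' @return data.frame: gene, type, start, end
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (length(f) && length(f[[1]]) >= 8L && grepl("gff", path,
                                                 ignore.case = TRUE)) {
    keep <- vapply(f, function(x) x[3] %in% c("gene", "tRNA", "rRNA", "CDS"),
                   logical(1))
    f <- f[keep]
    do.call(rbind, lapply(f, function(x) {
      attrs <- x[9]
      gene <- sub(".*(?:Name|ID|gene)=([^;]+).*", "\\1", attrs)
      type <- switch(x[3], tRNA = "tRNA", rRNA = "rRNA", "PCG")
      if (x[3] == "gene" && grepl("^trn", gene)) type <- "tRNA"
      if (x[3] == "gene" && grepl("^rrn", gene)) type <- "rRNA"
      data.frame(gene = gene, type = type,
                 start = as.integer(x[4]), end = as.integer(x[5]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    # BED: 0-based half-open
    do.call(rbind, lapply(f, function(x) {
      gene <- if (length(x) >= 4L) x[4] else "."
      type <- if (grepl("^trn", gene)) "tRNA"
              else if (grepl("^rrn", gene)) "rRNA" else "PCG"
      data.frame(gene = gene, type = type,
                 start = as.integer(x[2]) + 1L, end = as.integer(x[3]),
                 stringsAsFactors = FALSE)
    }))
  }
}
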