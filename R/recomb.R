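# Repeat-mediated recombination quantification from long-read spanning
# support.
#
# For each two-copy repeat the graph admits two conformations; each
# conformation exposes two repeat-plus-flank windows (four path labels per
# repeat). Long reads are aligned to the windows and a read counts as
# support for a path only if a single contiguous alignment covers the
# repeat copy plus at least `min_flank` bp of unique flanking sequence on
# each side. Path counts roll up to per-conformation totals and isoform
# proportions.

#' Build repeat-plus-flank windows for both conformations
#'
#' Extracts, for every traversal of the repeat in every molecule of each
#' conformation, the repeat copy with up to `flank` bp of sequence on
#' either side. Flanks are truncated at linear molecule ends (recorded in
#' the `truncated_*` columns); circular molecules wrap. In multi-copy
#' mode, two traversals of the repeat separated by a single interior
#' element are fused into one window spanning copy1-interior-copy2, for
#' repeats whose copies are close enough that individual reads traverse
#' both.
#'
#' @param conformations list of two `molecule_set`s named `reference` and
#'   `crossover` (see [repeat_conformations()])
#' @param graph a `mito_graph` with element sequences
#' @param repeat_id the repeat the windows are for
#' @param flank target flank length in bp (default 5000: windows take
#'   exactly this much where available)
#' @param mode "single" (one window per repeat copy traversal) or
#'   "multi" (fuse adjacent traversals, multi-copy spanning mode)
#' @return a `repeat_windows` data.frame: window_id, conformation,
#'   sequence, repeat_start, repeat_end, left_flank, right_flank,
#'   truncated_left, truncated_right
#' @export
build_windows <- function(conformations, graph, repeat_id, flank = 5000L,
                          mode = c("single", "multi")) {
  mode <- match.arg(mode)
  out <- list()
  for (conf_name in names(conformations)) {
    mols <- conformations[[conf_name]]
    for (m in seq_len(nrow(mols))) {
      path <- parse_path(mols$path[m])
      circular <- identical(mols$topology[m], "circular")
      ms <- molecule_sequence(mols$path[m], graph)
      L <- nchar(ms$sequence)
      occ <- which(ms$layout$element == repeat_id)
      if (!length(occ)) next
      n_el <- length(path)
      neighbor <- function(i, step) {
        j <- i + step
        if (circular) path[(j - 1L) %% n_el + 1L]
        else if (j >= 1L && j <= n_el) path[j] else NA_character_
      }
      spans <- if (mode == "multi" && length(occ) >= 2L) {
        lapply(seq_len(length(occ) - 1L), function(t) {
          i <- occ[t]; j <- occ[t + 1L]
          list(start = ms$layout$start[i], end = ms$layout$end[j],
               label = paste(c(neighbor(i, -1L), path[i:j], neighbor(j, 1L)),
                             collapse = "-"))
        })
      } else {
        lapply(occ, function(i) {
          list(start = ms$layout$start[i], end = ms$layout$end[i],
               label = paste(c(neighbor(i, -1L), path[i], neighbor(i, 1L)),
                             collapse = "-"))
        })
      }
      for (sp in spans) {
        if (circular) {
          if (2L * flank + (sp$end - sp$start + 1L) > L) {
            stop("circular molecule ", mols$molecule[m],
                 " smaller than the requested window; reduce flank")
          }
          lf <- flank; rf <- flank
          dbl <- paste0(ms$sequence, ms$sequence)
          a <- sp$start - lf
          shift <- if (a < 1L) L else 0L
          wseq <- substr(dbl, a + shift, sp$end + rf + shift)
        } else {
          lf <- min(flank, sp$start - 1L)
          rf <- min(flank, L - sp$end)
          wseq <- substr(ms$sequence, sp$start - lf, sp$end + rf)
        }
        rep_len_bp <- sp$end - sp$start + 1L
        out[[length(out) + 1L]] <- data.frame(
          window_id = sp$label, conformation = conf_name,
          sequence = wseq,
          repeat_start = lf + 1L, repeat_end = lf + rep_len_bp,
          left_flank = lf, right_flank = rf,
          truncated_left = lf < flank, truncated_right = rf < flank,
          stringsAsFactors = FALSE)
      }
    }
  }
  win <- do.call(rbind, out)
  if (is.null(win)) stop("repeat ", repeat_id, " not found in any molecule")
  # path labels can collide across conformations in degenerate
  # geometries; disambiguate deterministically
  win$window_id <- make.unique(win$window_id, sep = "#")
  stopifnot(all(nchar(win$sequence) ==
                  win$left_flank + (win$repeat_end - win$repeat_start + 1L) +
                  win$right_flank))
  class(win) <- c("repeat_windows", "data.frame")
  win
}

#' Classify one alignment against the flanking-coverage rule
#'
#' A read supports a path if its (single, contiguous) alignment covers
#' the whole repeat interval plus at least `min_flank` bp on both sides:
#' `window_start <= repeat_start - min_flank` and
#' `window_end >= repeat_end + min_flank`.
#'
#' @param window_start,window_end 1-based inclusive window interval
#'   covered by the alignment (vectorised)
#' @param repeat_start,repeat_end 1-based inclusive repeat interval of
#'   the window
#' @param min_flank required flank coverage in bp (default 50)
#' @return logical vector: TRUE = supports, FALSE = no call
#' @export
classify_support <- function(window_start, window_end, repeat_start,
                             repeat_end, min_flank = 50L) {
  window_start <= repeat_start - min_flank &
    window_end >= repeat_end + min_flank
}

#' Resolve reads aligning to several windows of the same repeat
#'
#' Keeps, per read, the supporting alignment with the highest score.
#' Reads whose top two supporting scores are within `margin` of one
#' another (strict ties at the default 0) are discarded as ambiguous and
#' reported.
#'
#' @param alignments data.frame from [align_reads()] restricted to one
#'   repeat's windows, with a logical `supports` column
#' @param margin minimum score margin between best and second-best
#' @return list with `calls` (one row per read: the winning alignment)
#'   and `ambiguous` (number of reads discarded)
#' @export
resolve_multimapping <- function(alignments, margin = 0) {
  sup <- alignments[alignments$supports, , drop = FALSE]
  if (nrow(sup) == 0L) return(list(calls = sup, ambiguous = 0L))
  keep <- logical(nrow(sup))
  ambiguous <- 0L
  for (ids in split(seq_len(nrow(sup)), sup$read_id)) {
    sc <- sup$score[ids]
    best <- which.max(sc)
    if (length(ids) > 1L && sort(sc, decreasing = TRUE)[2] >= sc[best] - margin) {
      ambiguous <- ambiguous + 1L
    } else {
      keep[ids[best]] <- TRUE
    }
  }
  list(calls = sup[keep, , drop = FALSE], ambiguous = ambiguous)
}

#' Tally path support into conformation totals and proportions
#'
#' Standard mode sums each conformation's two path counts into its total;
#' proportions divide by the grand total. (Averaging the two paths
#' instead of summing rescales numerator and denominator equally, so
#' proportions are identical under either reading.) Multi-copy mode takes
#' each conformation's single direct count as its total.
#'
#' @param counts named list with one element per conformation, each a
#'   named numeric vector of per-path read counts (one entry per path
#'   label; a single entry per conformation in multi-copy mode)
#' @param repeat_id repeat identifier for the output rows
#' @param mode "standard" or "multi"
#' @return a `support_table` data.frame: repeat_id, conformation,
#'   path_label, path_count, conformation_total, proportion
#' @export
tally_support <- function(counts, repeat_id = "repeat",
                          mode = c("standard", "multi")) {
  mode <- match.arg(mode)
  totals <- vapply(counts, sum, numeric(1))
  grand <- sum(totals)
  rows <- lapply(names(counts), function(conf) {
    pc <- counts[[conf]]
    data.frame(repeat_id = repeat_id, conformation = conf,
               path_label = names(pc), path_count = as.numeric(pc),
               conformation_total = totals[[conf]],
               proportion = if (grand > 0) totals[[conf]] / grand else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("support_table", "data.frame")
  tab
}

#' Point estimates with Wilson confidence intervals
#'
#' @param table a `support_table`
#' @param conf confidence level (default 0.95)
#' @return data.frame: repeat_id, conformation, total, proportion, lower,
#'   upper
#' @export
estimate_ratio <- function(table, conf = 0.95) {
  key <- paste(table$repeat_id, table$conformation)
  idx <- !duplicated(key)
  sub <- table[idx, , drop = FALSE]
  out <- do.call(rbind, lapply(unique(sub$repeat_id), function(r) {
    rows <- sub[sub$repeat_id == r, ]
    grand <- sum(rows$conformation_total)
    ci <- t(vapply(rows$conformation_total, wilson_interval,
                   numeric(2), n = grand, conf = conf))
    data.frame(repeat_id = r, conformation = rows$conformation,
               total = rows$conformation_total,
               proportion = if (grand > 0) rows$conformation_total / grand
                            else NA_real_,
               lower = ci[, 1], upper = ci[, 2], stringsAsFactors = FALSE)
  }))
  out
}

#' Write a support table as TSV
#'
#' Percentages carry exactly two decimals, rounded half-up; zero-read
#' repeats print NA.
#'
#' @param table a `support_table`
#' @param path output path
#' @param header optional named list for the provenance header
#' @return the path, invisibly
#' @export
write_support_table <- function(table, path, header = NULL) {
  df <- data.frame(repeat_id = table$repeat_id,
                   path_label = table$path_label,
                   path_count = table$path_count,
                   conformation_total = table$conformation_total,
                   conformation_percent = format_percent(table$proportion),
                   stringsAsFactors = FALSE)
  write_tsv_report(df, path, header)
}

# Fast pre-screen: does a read share any k-mers with the repeat sequence?
screen_reads <- function(reads, repeat_seq, k = 15L, stride = 20L) {
  rk <- unique(c(kmers(repeat_seq, k), kmers(revcomp(repeat_seq), k)))
  hits <- vapply(reads$sequence, function(s) {
    any(!is.na(match(kmers(s, k, stride), rk)))
  }, logical(1), USE.NAMES = FALSE)
  reads[hits, , drop = FALSE]
}

#' Quantify recombination for every repeat in a graph
#'
#' End-to-end spanning-support procedure: for each repeat, build the four
#' repeat-plus-flank windows across both conformations, align the reads,
#' apply the flanking-coverage rule, resolve multi-mapping, and tally
#' conformation support. A read is counted at most once per repeat but
#' may support different repeats independently.
#'
#' @param graph a `mito_graph` with sequences
#' @param reads a `seq_records` of long reads
#' @param flank window flank size (bp)
#' @param min_flank flanking-coverage rule threshold (bp)
#' @param params [align_params()]
#' @param mode per-repeat window mode, recycled ("single"/"multi")
#' @return list with `table` (a `support_table` over all repeats),
#'   `ambiguous` (named per-repeat discard counts) and `windows`
#' @export
quantify_recombination <- function(graph, reads, flank = 5000L,
                                   min_flank = 50L,
                                   params = align_params(),
                                   mode = "single") {
  rids <- graph$repeats$id
  mode <- rep_len(mode, length(rids))
  tabs <- list(); amb <- stats::setNames(integer(length(rids)), rids)
  wins <- list()
  for (i in seq_along(rids)) {
    r <- rids[i]
    confs <- repeat_conformations(graph, r)
    win <- build_windows(confs, graph, r, flank = flank, mode = mode[i])
    wins[[r]] <- win
    cand <- screen_reads(reads, element_sequence(graph, r), k = params$k)
    counts <- lapply(split(win$window_id, win$conformation), function(lab)
      stats::setNames(numeric(length(lab)), lab))
    if (nrow(cand)) {
      aln <- align_reads(cand, win, params)
      if (nrow(aln)) {
        wi <- match(aln$window_id, win$window_id)
        aln$supports <- classify_support(aln$window_start, aln$window_end,
                                         win$repeat_start[wi],
                                         win$repeat_end[wi], min_flank)
        res <- resolve_multimapping(aln)
        amb[r] <- res$ambiguous
        if (nrow(res$calls)) {
          tc <- table(res$calls$window_id)
          for (conf in names(counts)) {
            lab <- names(counts[[conf]])
            got <- tc[lab]; got[is.na(got)] <- 0
            counts[[conf]] <- stats::setNames(as.numeric(got), lab)
          }
        }
      }
    }
    tabs[[r]] <- tally_support(counts, repeat_id = r,
                               mode = if (mode[i] == "multi") "multi"
                                      else "standard")
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  class(tab) <- c("support_table", "data.frame")
  list(table = tab, ambiguous = amb, windows = wins)
}
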