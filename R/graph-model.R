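# Structural model of a multi-contig organelle genome.
#
# A mito_graph holds single-copy contigs, two-copy long-repeat elements and
# the adjacencies between them. Each repeat copy is a placement
# (left-neighbor contig, right-neighbor contig) in the master traversal
# orientation; recombination across the repeat swaps which left neighbor
# continues into which right neighbor. All elements are traversed in the +
# orientation of the master conformation; this matches how resolved
# organelle molecules are conventionally reported (path strings such as
# contig1-LR11-contig5-...).

#' Construct a mitogenome structural graph
#'
#' @param contigs data.frame with columns id, length and optionally depth,
#'   sequence
#' @param repeats data.frame with columns id, length and optionally depth,
#'   sequence
#' @param placements named list: for each repeat id, a list of exactly two
#'   character vectors `c(left, right)` naming the neighbor contigs of each
#'   copy (in master traversal order). `NA` marks a molecule end. A copy
#'   may carry a third element, its relative orientation (`"+"` default;
#'   `"-"` marks the second copy as inverted with respect to the first,
#'   i.e. the copies form an inverted rather than a direct repeat pair).
#' @param links data.frame with columns from, to: direct contig-to-contig
#'   adjacencies (from's right end joins to's left end)
#' @return an object of class `mito_graph`
#' @export
mito_graph <- function(contigs, repeats, placements, links = NULL) {
  stopifnot(all(c("id", "length") %in% names(contigs)))
  if (is.null(contigs$depth)) contigs$depth <- NA_real_
  if (is.null(contigs$sequence)) contigs$sequence <- NA_character_
  if (is.null(repeats)) {
    repeats <- data.frame(id = character(0), length = integer(0),
                          depth = numeric(0), sequence = character(0),
                          stringsAsFactors = FALSE)
  }
  if (is.null(repeats$depth)) repeats$depth <- NA_real_
  if (is.null(repeats$sequence)) repeats$sequence <- NA_character_
  if (is.null(links)) {
    links <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }
  if (any(contigs$length < 1) || any(repeats$length < 1)) {
    stop("element lengths must be >= 1")
  }
  if (nrow(repeats) && !setequal(names(placements), repeats$id)) {
    stop("placements must be given for exactly the repeat ids")
  }
  for (r in repeats$id) {
    pl <- placements[[r]]
    if (length(pl) != 2L) stop("repeat ", r, " must have exactly 2 copies")
    ors <- vapply(pl, function(p) if (length(p) >= 3L) p[3] else "+",
                  character(1))
    if (!all(ors %in% c("+", "-"))) {
      stop("repeat ", r, " copy orientations must be '+' or '-'")
    }
    nb <- unlist(lapply(pl, function(p) p[1:2]))
    unknown <- setdiff(nb[!is.na(nb)], contigs$id)
    if (length(unknown)) {
      stop("repeat ", r, " placement names unknown contig(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  unknown <- setdiff(c(links$from, links$to), contigs$id)
  if (length(unknown)) stop("link names unknown contig(s): ",
                            paste(unknown, collapse = ", "))
  structure(list(contigs = contigs, repeats = repeats,
                 placements = placements, links = links),
            class = "mito_graph")
}

#' @export
print.mito_graph <- function(x, ...) {
  cat("mito_graph:", nrow(x$contigs), "contigs,", nrow(x$repeats),
      "two-copy repeats,", nrow(x$links), "direct links\n")
  invisible(x)
}

element_length <- function(graph, id) {
  i <- match(id, graph$contigs$id)
  len <- graph$contigs$length[i]
  j <- match(id, graph$repeats$id)
  len[is.na(i)] <- graph$repeats$length[j[is.na(i)]]
  if (anyNA(len)) {
    stop("unknown element(s): ", paste(id[is.na(len)], collapse = ", "))
  }
  len
}

element_sequence <- function(graph, id) {
  i <- match(id, graph$contigs$id)
  s <- graph$contigs$sequence[i]
  j <- match(id, graph$repeats$id)
  s[is.na(i)] <- graph$repeats$sequence[j[is.na(i)]]
  s
}

#' Build a mito_graph from path strings
#'
#' Convenience constructor from resolved-molecule path notation: repeat
#' placements and direct links are derived from element adjacency along the
#' paths (circular paths close around the end).
#'
#' @param contigs,repeats as for [mito_graph()]
#' @param paths data.frame with columns molecule, path (dash-separated
#'   element ids) and topology ("linear" or "circular")
#' @param inverted character vector of repeat ids whose two copies sit in
#'   inverted relative orientation (path strings do not record strand;
#'   inversion shows up in which flank pairs the crossover conformation
#'   joins)
#' @return a `mito_graph`
#' @export
mito_graph_from_paths <- function(contigs, repeats, paths,
                                  inverted = character(0)) {
  placements <- stats::setNames(vector("list", nrow(repeats)), repeats$id)
  links <- NULL
  for (i in seq_len(nrow(paths))) {
    els <- parse_path(paths$path[i])
    circ <- identical(paths$topology[i], "circular")
    n <- length(els)
    prv <- if (circ) c(els[n], els[-n]) else c(NA, els[-n])
    nxt <- if (circ) c(els[-1], els[1]) else c(els[-1], NA)
    for (k in seq_len(n)) {
      e <- els[k]
      if (e %in% repeats$id) {
        placements[[e]] <- c(placements[[e]], list(c(prv[k], nxt[k])))
      } else if (!is.na(nxt[k]) && nxt[k] %in% contigs$id) {
        links <- rbind(links, data.frame(from = e, to = nxt[k],
                                         stringsAsFactors = FALSE))
      }
    }
  }
  for (r in intersect(inverted, repeats$id)) {
    placements[[r]][[2]] <- c(placements[[r]][[2]][1:2], "-")
  }
  mito_graph(contigs, repeats, placements, links)
}

#' Parse a path string into element ids
#' @param path dash-separated path string, e.g. "contig1-LR11-contig5"
#' @return character vector of element ids
#' @export
parse_path <- function(path) {
  if (is.character(path) && length(path) == 1L && grepl("-", path)) {
    strsplit(path, "-", fixed = TRUE)[[1]]
  } else {
    as.character(path)
  }
}

#' Enumerate the two flank pairings of a two-copy repeat
#'
#' A repeat with copies (L1, R1) and (L2, R2) admits exactly two
#' conformations. The reference pairing keeps each copy's own neighbors
#' (L1-LR-R1 / L2-LR-R2). The crossover pairing depends on the relative
#' orientation of the copies: for a direct repeat it exchanges the right
#' neighbors (L1-LR-R2 / L2-LR-R1); for an inverted repeat,
#' recombination joins like flanks (L1-LR-L2 / R1-LR-R2), with the
#' intervening segment reversed.
#'
#' @param graph a `mito_graph`
#' @param repeat_id repeat element id
#' @return list with elements `reference` and `crossover`, each a list of
#'   two pairs `c(left, right)` with a `labels` attribute of path labels
#'   and an `inverted` attribute on the crossover pairing
#' @export
enumerate_pairings <- function(graph, repeat_id) {
  pl <- graph$placements[[repeat_id]]
  if (is.null(pl)) stop("unknown repeat: ", repeat_id)
  L <- c(pl[[1]][1], pl[[2]][1])
  R <- c(pl[[1]][2], pl[[2]][2])
  ors <- vapply(pl, function(p) if (length(p) >= 3L) p[3] else "+",
                character(1))
  inv <- ors[1] != ors[2]
  if (anyNA(L)) stop("repeat ", repeat_id, " copy has no left neighbor ",
                     "(molecule end); cannot enumerate pairings")
  if (anyNA(R)) stop("repeat ", repeat_id, " copy has no right neighbor ",
                     "(molecule end); cannot enumerate pairings")
  lab <- function(l, r) paste(l, repeat_id, r, sep = "-")
  ref <- list(c(L[1], R[1]), c(L[2], R[2]))
  crs <- if (inv) list(c(L[1], L[2]), c(R[1], R[2]))
         else list(c(L[1], R[2]), c(L[2], R[1]))
  attr(ref, "labels") <- vapply(ref, function(p) lab(p[1], p[2]),
                                character(1))
  attr(crs, "labels") <- vapply(crs, function(p) lab(p[1], p[2]),
                                character(1))
  attr(crs, "inverted") <- inv
  list(reference = ref, crossover = crs)
}

#' Length of a molecule along its path
#'
#' Sums element lengths along the path; a repeat traversed twice
#' contributes twice. Linear and circular molecules are treated
#' identically (elements are non-overlapping, so no overlap subtraction).
#'
#' @param path path string or character vector of element ids
#' @param graph a `mito_graph`
#' @return length in bp
#' @export
molecule_length <- function(path, graph) {
  sum(element_length(graph, parse_path(path)))
}

#' Stitch the sequence of a molecule along its path
#'
#' @param path path string or element id vector
#' @param graph a `mito_graph` whose elements carry sequences
#' @return list with `sequence` (the concatenated DNA string) and `layout`
#'   (data.frame element, start, end: 1-based inclusive offsets)
#' @export
molecule_sequence <- function(path, graph) {
  els <- parse_path(path)
  seqs <- element_sequence(graph, els)
  if (anyNA(seqs)) stop("element(s) without sequence: ",
                        paste(els[is.na(seqs)], collapse = ", "))
  lens <- nchar(seqs)
  end <- cumsum(lens)
  layout <- data.frame(element = els, start = end - lens + 1L, end = end,
                       stringsAsFactors = FALSE)
  list(sequence = paste(seqs, collapse = ""), layout = layout)
}

# Successor map over contigs under a per-repeat pairing choice.
# choices: named character vector repeat id -> "reference"|"crossover".
build_successors <- function(graph, choices) {
  nxt <- list()
  add <- function(from, to, via) {
    if (!is.null(nxt[[from]])) {
      stop("resolution error: contig ", from,
           " has more than one outgoing adjacency")
    }
    nxt[[from]] <<- list(to = to, via = via)
  }
  for (i in seq_len(nrow(graph$links))) {
    add(graph$links$from[i], graph$links$to[i], NA_character_)
  }
  for (r in graph$repeats$id) {
    pr <- enumerate_pairings(graph, r)
    sel <- pr[[choices[[r]]]]
    if (isTRUE(attr(sel, "inverted"))) {
      stop("resolution error: crossover across the inverted repeat ", r,
           " reverses contig traversals; signed-path resolution is not ",
           "supported")
    }
    for (pair in sel) add(pair[1], pair[2], r)
  }
  nxt
}

#' Resolve the graph into representative molecules
#'
#' Selects one pairing per repeat (by default the one with the larger
#' spanning-read proportion) and walks all adjacencies into disjoint
#' molecules. Every contig lands in exactly one molecule exactly once;
#' each repeat appears once per copy across the set.
#'
#' @param graph a `mito_graph`
#' @param ratios named numeric vector: per-repeat proportion of the
#'   crossover conformation in `[0,1]`; crossover is chosen when the
#'   proportion exceeds 0.5, ties go to the reference pairing (logged).
#'   Alternatively a named character vector of explicit choices
#'   ("reference"/"crossover").
#' @return a `molecule_set`: data.frame with columns molecule, path,
#'   topology, length and mean_depth
#' @export
resolve_major <- function(graph, ratios = NULL) {
  rid <- graph$repeats$id
  if (is.null(ratios)) {
    choices <- stats::setNames(rep("reference", length(rid)), rid)
  } else if (is.character(ratios)) {
    stopifnot(all(ratios %in% c("reference", "crossover")))
    choices <- ratios[rid]
  } else {
    if (!all(rid %in% names(ratios))) {
      stop("ratios must name every repeat: ",
           paste(setdiff(rid, names(ratios)), collapse = ", "))
    }
    ties <- rid[ratios[rid] == 0.5]
    if (length(ties)) {
      message("tie at 0.5 for ", paste(ties, collapse = ", "),
              "; keeping reference pairing")
    }
    choices <- stats::setNames(
      ifelse(ratios[rid] > 0.5, "crossover", "reference"), rid)
  }
  names(choices) <- rid
  nxt <- build_successors(graph, choices)
  prev <- list()
  for (from in names(nxt)) prev[[nxt[[from]]$to]] <- from

  visited <- character(0)
  molecules <- list()
  for (start in sort(graph$contigs$id)) {
    if (start %in% visited) next
    # walk backwards first so linear molecules start at their real end
    head <- start
    repeat {
      p <- prev[[head]]
      if (is.null(p) || p == start) break
      head <- p
    }
    circular <- !is.null(prev[[head]])
    path <- head
    visited <- c(visited, head)
    cur <- head
    repeat {
      step <- nxt[[cur]]
      if (is.null(step)) break
      if (!is.na(step$via)) path <- c(path, step$via)
      if (step$to == head) break
      if (step$to %in% visited) {
        stop("resolution error: contig ", step$to,
             " reached from two molecules")
      }
      path <- c(path, step$to)
      visited <- c(visited, step$to)
      cur <- step$to
    }
    if (circular) {
      # canonical rotation: smallest contig id first
      cids <- path[path %in% graph$contigs$id]
      k <- which(path == min(cids))[1]
      if (k > 1L) path <- c(path[k:length(path)], path[1:(k - 1L)])
    }
    molecules[[length(molecules) + 1L]] <-
      list(path = path, topology = if (circular) "circular" else "linear")
  }

  df <- do.call(rbind, lapply(seq_along(molecules), function(i) {
    m <- molecules[[i]]
    cids <- m$path[m$path %in% graph$contigs$id]
    d <- graph$contigs$depth[match(cids, graph$contigs$id)]
    w <- graph$contigs$length[match(cids, graph$contigs$id)]
    md <- if (all(is.na(d))) NA_real_ else
      sum(d * w, na.rm = TRUE) / sum(w[!is.na(d)])
    data.frame(molecule = paste0("M", i),
               path = paste(m$path, collapse = "-"),
               topology = m$topology,
               length = molecule_length(m$path, graph),
               mean_depth = md, stringsAsFactors = FALSE)
  }))
  # repeat copy-count bookkeeping invariant
  cnt <- table(unlist(lapply(df$path, parse_path)))
  for (r in graph$repeats$id) {
    if (is.na(cnt[r]) || cnt[r] != 2L) {
      stop("resolution error: repeat ", r, " traversed ",
           ifelse(is.na(cnt[r]), 0L, cnt[r]), " times, expected 2")
    }
  }
  class(df) <- c("molecule_set", "data.frame")
  df
}

#' Check repeat depths against the two-copy expectation
#'
#' A repeat present in two copies should show roughly the summed coverage
#' of its two single-copy contexts. For each repeat the expected depth is
#' the sum over its two copies of the mean depth of that copy's flanking
#' contigs; repeats whose observed/expected ratio deviates by more than
#' `tol` are flagged.
#'
#' @param graph a `mito_graph` with depths
#' @param tol relative tolerance (default 0.10)
#' @return data.frame: repeat_id, observed, expected, ratio, flagged
#' @export
depth_consistency <- function(graph, tol = 0.10) {
  rows <- lapply(graph$repeats$id, function(r) {
    obs <- graph$repeats$depth[match(r, graph$repeats$id)]
    pl <- graph$placements[[r]]
    flank_depth <- vapply(pl, function(p) {
      d <- graph$contigs$depth[match(p[!is.na(p)], graph$contigs$id)]
      mean(d, na.rm = TRUE)
    }, numeric(1))
    if (is.na(obs) || anyNA(flank_depth)) {
      warning("missing depths for repeat ", r, "; skipped")
      return(NULL)
    }
    expd <- sum(flank_depth)
    data.frame(repeat_id = r, observed = obs, expected = expd,
               ratio = obs / expd,
               flagged = abs(obs / expd - 1) > tol,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(repeat_id = character(0), observed = numeric(0),
                      expected = numeric(0), ratio = numeric(0),
                      flagged = logical(0))
  }
  out
}

#' Convert a GFA graph to a mito_graph
#'
#' Segments named in `repeat_ids` become two-copy repeat elements; their
#' placements are read off the GFA links (segments linking into the repeat
#' are left neighbors, segments the repeat links to are right neighbors).
#' The GFA does not record which left neighbor belongs with which right
#' neighbor, so copies are paired in sorted order as an arbitrary
#' reference conformation.
#'
#' @param gfa a `gfa_graph`
#' @param repeat_ids character vector of segment names that are repeats
#' @return a `mito_graph`
#' @export
as_mito_graph <- function(gfa, repeat_ids = character(0)) {
  seg <- gfa$segments
  is_rep <- seg$name %in% repeat_ids
  contigs <- data.frame(id = seg$name[!is_rep], length = seg$length[!is_rep],
                        depth = seg$depth[!is_rep],
                        sequence = seg$sequence[!is_rep],
                        stringsAsFactors = FALSE)
  repeats <- data.frame(id = seg$name[is_rep], length = seg$length[is_rep],
                        depth = seg$depth[is_rep],
                        sequence = seg$sequence[is_rep],
                        stringsAsFactors = FALSE)
  lk <- gfa$links
  placements <- stats::setNames(vector("list", nrow(repeats)), repeats$id)
  for (r in repeats$id) {
    lefts <- sort(lk$from[lk$to == r])
    rights <- sort(lk$to[lk$from == r])
    if (length(lefts) != 2L || length(rights) != 2L) {
      stop("repeat ", r, " must have exactly 2 incoming and 2 outgoing links")
    }
    placements[[r]] <- list(c(lefts[1], rights[1]), c(lefts[2], rights[2]))
  }
  direct <- lk[!(lk$from %in% repeats$id) & !(lk$to %in% repeats$id),
               c("from", "to")]
  mito_graph(contigs, repeats, placements, direct)
}
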