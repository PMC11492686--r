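# GFA1 assembly-graph input/output (S and L lines only).
#
# Only segment and link semantics are relied on: the overlap field is
# accepted but treated as 0M, because organelle assembly contigs here are
# non-overlapping and repeat copies are separate segments.

#' Construct a GFA graph object
#'
#' @param segments data.frame with columns name, length, sequence (may be
#'   NA) and depth (may be NA)
#' @param links data.frame with columns from, from_orient, to, to_orient,
#'   overlap
#' @return an object of class `gfa_graph`
#' @export
gfa_graph <- function(segments, links) {
  stopifnot(all(c("name", "length") %in% names(segments)))
  if (is.null(segments$sequence)) segments$sequence <- NA_character_
  if (is.null(segments$depth)) segments$depth <- NA_real_
  if (anyDuplicated(segments$name)) stop("duplicate segment names")
  if (is.null(links)) {
    links <- data.frame(from = character(0), from_orient = character(0),
                        to = character(0), to_orient = character(0),
                        overlap = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(links)) {
    missing <- setdiff(c(links$from, links$to), segments$name)
    if (length(missing)) {
      stop("link references unknown segment(s): ",
           paste(missing, collapse = ", "))
    }
    if (!all(c(links$from_orient, links$to_orient) %in% c("+", "-"))) {
      stop("link orientations must be '+' or '-'")
    }
  }
  structure(list(segments = segments, links = links), class = "gfa_graph")
}

#' @export
print.gfa_graph <- function(x, ...) {
  cat("GFA graph:", nrow(x$segments), "segments,", nrow(x$links), "links\n")
  invisible(x)
}

#' Read a GFA1 file
#'
#' Captures S and L lines; other record types are skipped with a warning.
#' Segment length comes from the sequence when present, else from an LN
#' tag. A dp/DP tag is parsed as mean depth.
#'
#' @param path path to a GFA1 file
#' @return a `gfa_graph`
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  type <- substr(lines, 1L, 1L)
  other <- setdiff(unique(type), c("S", "L", "H", "#"))
  if (length(other)) {
    warning("ignoring GFA line type(s): ", paste(other, collapse = " "))
  }

  seg_rows <- strsplit(lines[type == "S"], "\t", fixed = TRUE)
  segments <- do.call(rbind, lapply(seg_rows, function(f) {
    seqf <- f[3]
    has_seq <- !is.na(seqf) && seqf != "*"
    tags <- if (length(f) > 3) f[-(1:3)] else character(0)
    ln <- grep("^LN:i:", tags, value = TRUE)
    dp <- grep("^(dp|DP):f:", tags, value = TRUE)
    len <- if (has_seq) nchar(seqf) else if (length(ln)) {
      as.integer(sub("^LN:i:", "", ln[1]))
    } else NA_integer_
    data.frame(name = f[2], length = len,
               sequence = if (has_seq) normalize_dna(seqf) else NA_character_,
               depth = if (length(dp)) as.numeric(sub("^..:f:", "", dp[1]))
                       else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(segments)) stop("GFA file has no S lines: ", path)

  link_rows <- strsplit(lines[type == "L"], "\t", fixed = TRUE)
  links <- if (length(link_rows)) {
    do.call(rbind, lapply(link_rows, function(f) {
      data.frame(from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
                 overlap = if (length(f) >= 6) f[6] else "0M",
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  gfa_graph(segments, links)
}

#' Write a `gfa_graph` to a GFA1 file
#'
#' @param graph a `gfa_graph`
#' @param path output path
#' @return the path, invisibly
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  seg <- graph$segments
  for (i in seq_len(nrow(seg))) {
    f <- c("S", seg$name[i],
           if (is.na(seg$sequence[i])) "*" else seg$sequence[i],
           paste0("LN:i:", seg$length[i]))
    if (!is.na(seg$depth[i])) f <- c(f, sprintf("dp:f:%g", seg$depth[i]))
    writeLines(paste(f, collapse = "\t"), con)
  }
  lk <- graph$links
  for (i in seq_len(nrow(lk))) {
    writeLines(paste(c("L", lk$from[i], lk$from_orient[i], lk$to[i],
                       lk$to_orient[i], lk$overlap[i]), collapse = "\t"), con)
  }
  invisible(path)
}
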