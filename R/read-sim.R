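# Seeded synthetic-data generators.
#
# These emulate the stated world of the analysis at desk scale: a
# multi-contig toy genome carrying a two-copy long repeat, a mixture of
# recombinant conformations at a known proportion, long reads with a
# log-normal length distribution and configurable per-base error, a
# chloroplast genome with planted homologous segments, and CDS sets with
# controlled codon bias. Everything is bit-reproducible under the seed.

#' Default simulation configuration
#'
#' Read lengths follow a truncated log-normal with natural-scale mean
#' 12 kb, sd 6 kb and minimum 1 kb, a desk-scale stand-in for a ~20 kb
#' SMRT long-read library: reads must routinely span a repeat copy plus
#' 50 bp of flank on both sides for spanning support to be measurable.
#' Default error rates (substitution 0.05, insertion 0.03, deletion 0.03)
#' mimic a CLR-like profile; tests that need exactness use zero error.
#'
#' @param seed integer seed
#' @param contig_lengths contig lengths in bp
#' @param repeat_lengths lengths of the two-copy repeats to embed
#' @param mixture per-repeat crossover-conformation proportion in `[0,1]`
#' @param read_count number of reads to draw
#' @param read_length c(mean, sd, min) of the log-normal read length (bp)
#' @param error_rates c(sub, ins, del) per-base probabilities
#' @param weighting "per_molecule" (pick a molecule uniformly within the
#'   chosen isoform) or "length" (length-weighted molecule choice)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = rep(9000L, 4L),
                       repeat_lengths = 2000L,
                       mixture = 0.5,
                       read_count = 1000L,
                       read_length = c(mean = 12000, sd = 6000, min = 1000),
                       error_rates = c(sub = 0.05, ins = 0.03, del = 0.03),
                       weighting = c("per_molecule", "length")) {
  weighting <- match.arg(weighting)
  stopifnot(all(mixture >= 0 & mixture <= 1),
            all(error_rates >= 0), sum(error_rates) < 1,
            read_length[["min"]] >= 1)
  structure(list(seed = as.integer(seed),
                 contig_lengths = as.integer(contig_lengths),
                 repeat_lengths = as.integer(repeat_lengths),
                 mixture = mixture, read_count = as.integer(read_count),
                 read_length = read_length, error_rates = error_rates,
                 weighting = weighting),
            class = "sim_config")
}

#' Generate a toy multi-contig genome with two-copy repeats
#'
#' Builds random contig sequences and embeds each repeat's sequence
#' identically at two placements of a single circular master
#' conformation: repeat k is inserted after contig k and after contig
#' k + floor(n/2), giving the classic assembly-graph topology in which a
#' repeat's two copies pair four unique flanking contigs.
#'
#' @param config a [sim_config()]
#' @return list with `graph` (a `mito_graph` carrying sequences), `gfa`
#'   (the same graph as a `gfa_graph`), `master` (the master circular
#'   path string) and `truth` (per-repeat configured crossover
#'   proportions)
#' @export
make_toy_genome <- function(config) {
  set.seed(config$seed)
  nc <- length(config$contig_lengths)
  nr <- length(config$repeat_lengths)
  if (any(config$repeat_lengths < 1L)) stop("repeat length must be >= 1")
  if (2L * nr > nc) stop("need at least two contigs per repeat")
  if (any(config$repeat_lengths >= min(config$contig_lengths))) {
    stop("repeat longer than flanking contig; enlarge contigs")
  }
  cid <- paste0("c", seq_len(nc))
  rid <- paste0("R", seq_len(nr))
  contigs <- data.frame(id = cid, length = config$contig_lengths,
                        depth = NA_real_,
                        sequence = random_dna(config$contig_lengths),
                        stringsAsFactors = FALSE)
  repeats <- data.frame(id = rid, length = config$repeat_lengths,
                        depth = NA_real_,
                        sequence = random_dna(config$repeat_lengths),
                        stringsAsFactors = FALSE)
  # master circular order: insert repeat k after contig k and contig k+n/2
  after <- stats::setNames(rep(NA_character_, nc), cid)
  half <- nc %/% 2L
  for (k in seq_len(nr)) {
    after[[cid[k]]] <- rid[k]
    after[[cid[k + half]]] <- rid[k]
  }
  master <- unlist(lapply(cid, function(c) c(c, after[[c]])))
  master <- master[!is.na(master)]
  paths <- data.frame(molecule = "master",
                      path = paste(master, collapse = "-"),
                      topology = "circular", stringsAsFactors = FALSE)
  graph <- mito_graph_from_paths(contigs, repeats, paths)
  mix <- rep_len(config$mixture, nr)
  list(graph = graph, gfa = mito_graph_to_gfa(graph),
       master = paths$path,
       truth = stats::setNames(mix, rid))
}

#' Export a mito_graph as a gfa_graph
#' @param graph a `mito_graph`
#' @return a `gfa_graph` (each adjacency written once, + orientations)
#' @export
mito_graph_to_gfa <- function(graph) {
  seg <- rbind(graph$contigs[c("id", "length", "sequence", "depth")],
               graph$repeats[c("id", "length", "sequence", "depth")])
  names(seg)[1] <- "name"
  links <- graph$links
  for (r in graph$repeats$id) {
    for (pl in graph$placements[[r]]) {
      links <- rbind(links,
                     data.frame(from = c(pl[1], r), to = c(r, pl[2]),
                                stringsAsFactors = FALSE))
    }
  }
  links <- unique(links)
  links <- data.frame(from = links$from, from_orient = "+", to = links$to,
                      to_orient = "+", overlap = "0M",
                      stringsAsFactors = FALSE)
  gfa_graph(seg, links)
}

#' Both conformations of the graph with respect to one repeat
#'
#' @param graph a `mito_graph`
#' @param repeat_id which repeat to toggle
#' @param base named character vector of pairing choices for the other
#'   repeats (default all "reference")
#' @return list of two `molecule_set`s: `reference` and `crossover`
#' @export
repeat_conformations <- function(graph, repeat_id, base = NULL) {
  rid <- graph$repeats$id
  choices <- stats::setNames(rep("reference", length(rid)), rid)
  if (!is.null(base)) choices[names(base)] <- base
  ref <- choices; ref[repeat_id] <- "reference"
  crs <- choices; crs[repeat_id] <- "crossover"
  list(reference = resolve_major(graph, ref),
       crossover = resolve_major(graph, crs))
}

#' Materialize molecule sequences of a molecule set
#' @param mols a `molecule_set` from [resolve_major()]
#' @param graph the `mito_graph` carrying element sequences
#' @return data.frame: molecule, sequence, topology
#' @export
molecule_seqs <- function(mols, graph) {
  data.frame(molecule = mols$molecule,
             sequence = vapply(mols$path, function(p)
               molecule_sequence(p, graph)$sequence, character(1)),
             topology = mols$topology, stringsAsFactors = FALSE)
}

# Apply per-base substitution/insertion/deletion errors to a DNA string.
apply_read_errors <- function(seq, rates) {
  if (sum(rates) == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  ch <- dna_chars(seq)
  n <- length(ch)
  ch <- ch[stats::runif(n) >= rates[["del"]]]
  n <- length(ch)
  sub_at <- which(stats::runif(n) < rates[["sub"]])
  if (length(sub_at)) {
    ch[sub_at] <- vapply(ch[sub_at], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  }
  n_ins <- stats::rbinom(1L, n, rates[["ins"]])
  if (n_ins > 0L) {
    pos <- sort(sample.int(n, n_ins, replace = TRUE))
    out <- character(n + n_ins)
    idx <- seq_len(n) + findInterval(seq_len(n) - 1L, pos)
    out[idx] <- ch
    out[-idx] <- sample(bases, n_ins, replace = TRUE)
    ch <- out
  }
  paste(ch, collapse = "")
}

#' Simulate long reads from a mixture of conformational isoforms
#'
#' Each read first draws an isoform with probability equal to its weight,
#' then a molecule within the isoform (uniformly per molecule or
#' length-weighted), a start position uniform along the molecule
#' (circular molecules wrap), and a truncated log-normal length capped at
#' the molecule length. Per-base errors are applied and the read is
#' reverse-complemented with probability 0.5. Provenance is recorded.
#'
#' @param isoforms named list: each element a data.frame with columns
#'   molecule, sequence, topology (see [molecule_seqs()])
#' @param weights numeric isoform weights summing to 1
#' @param config a [sim_config()] (read_count, read_length, error_rates,
#'   weighting, seed)
#' @return list with `reads` (a `seq_records`) and `truth` (data.frame
#'   read_id, isoform, molecule, start, end, strand; end may exceed the
#'   molecule length when a circular read wraps)
#' @export
simulate_reads <- function(isoforms, weights, config) {
  if (length(isoforms) == 0L) stop("no isoforms to simulate from")
  stopifnot(length(weights) == length(isoforms))
  if (abs(sum(weights) - 1) > 1e-8) stop("isoform weights must sum to 1")
  if (is.null(names(isoforms))) {
    names(isoforms) <- paste0("iso", seq_along(isoforms))
  }
  set.seed(config$seed)
  rl <- config$read_length
  sigma2 <- log(1 + (rl[["sd"]] / rl[["mean"]])^2)
  meanlog <- log(rl[["mean"]]) - sigma2 / 2
  n <- config$read_count
  iso_idx <- sample.int(length(isoforms), n, replace = TRUE, prob = weights)
  lens <- pmax(round(stats::rlnorm(n, meanlog, sqrt(sigma2))), rl[["min"]])
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    iso <- isoforms[[iso_idx[i]]]
    j <- if (config$weighting == "length") {
      sample.int(nrow(iso), 1L, prob = nchar(iso$sequence))
    } else sample.int(nrow(iso), 1L)
    mol <- iso$sequence[j]
    L <- nchar(mol)
    len <- min(lens[i], L)
    circular <- identical(iso$topology[j], "circular")
    start <- if (circular) sample.int(L, 1L)
             else sample.int(L - len + 1L, 1L)
    raw <- if (circular && start + len - 1L > L) {
      paste0(substr(mol, start, L), substr(mol, 1L, start + len - 1L - L))
    } else substr(mol, start, start + len - 1L)
    seqs[i] <- apply_read_errors(raw, config$error_rates)
    truth[[i]] <- data.frame(read_id = sprintf("read%06d", i),
                             isoform = names(isoforms)[iso_idx[i]],
                             molecule = iso$molecule[j],
                             start = start, end = start + len - 1L,
                             strand = strands[i], stringsAsFactors = FALSE)
  }
  minus <- strands == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  list(reads = seq_records(sprintf("read%06d", seq_len(n)), seqs),
       truth = do.call(rbind, truth))
}

#' Plant chloroplast-derived segments into a mitogenome
#'
#' Copies randomly chosen chloroplast intervals into the mitogenome
#' (overwriting in place, so genome lengths are unchanged), applying
#' per-base point mutations at rate `1 - identity`. Ground-truth
#' intervals on both genomes are returned for recovery tests.
#'
#' @param mt mitogenome DNA string
#' @param cp chloroplast DNA string
#' @param segments data.frame with columns length and identity
#' @param seed integer seed
#' @return list with `mt` (modified string) and `truth` (data.frame
#'   mt_start, mt_end, cp_start, cp_end, length, identity)
#' @export
plant_mtpt <- function(mt, cp, segments, seed = 1L) {
  set.seed(seed)
  stopifnot(all(segments$length >= 1),
            all(segments$identity > 0 & segments$identity <= 1))
  pick_disjoint <- function(glen, lens, gap = 100L) {
    taken <- IRanges::IRanges()
    starts <- integer(length(lens))
    for (i in seq_along(lens)) {
      ok <- FALSE
      for (try in 1:1000) {
        s <- sample.int(glen - lens[i] + 1L, 1L)
        cand <- IRanges::IRanges(start = max(1L, s - gap),
                                 end = min(glen, s + lens[i] - 1L + gap))
        if (!length(IRanges::findOverlaps(cand, taken))) {
          taken <- c(taken, cand); starts[i] <- s; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place segments without overlap")
    }
    starts
  }
  cp_start <- pick_disjoint(nchar(cp), segments$length)
  mt_start <- pick_disjoint(nchar(mt), segments$length)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(segments))) {
    frag <- substr(cp, cp_start[i], cp_start[i] + segments$length[i] - 1L)
    ch <- dna_chars(frag)
    mut <- which(stats::runif(length(ch)) < 1 - segments$identity[i])
    if (length(mut)) {
      ch[mut] <- vapply(ch[mut], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
    substr(mt, mt_start[i], mt_start[i] + segments$length[i] - 1L) <-
      paste(ch, collapse = "")
  }
  list(mt = mt,
       truth = data.frame(mt_start = mt_start,
                          mt_end = mt_start + segments$length - 1L,
                          cp_start = cp_start,
                          cp_end = cp_start + segments$length - 1L,
                          length = segments$length,
                          identity = segments$identity))
}

#' Generate a CDS set with controlled codon bias
#'
#' Genes start with ATG, end with a stop codon drawn uniformly from the
#' three stops, and draw internal codons from the supplied weights over
#' sense codons.
#'
#' @param codon_weights named nonnegative weights over sense codons
#'   (missing codons get weight 0); NULL for uniform usage
#' @param n_genes number of genes
#' @param gene_length_range c(min, max) gene length in codons (internal
#'   codons, excluding start and stop)
#' @param seed integer seed
#' @return list with `records` (a `seq_records`) and `truth_counts`
#'   (named integer vector of drawn internal codon counts)
#' @export
make_cds_set <- function(codon_weights = NULL, n_genes = 10L,
                         gene_length_range = c(100L, 300L), seed = 1L) {
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE)[
                     Biostrings::GENETIC_CODE == "*"])
  w <- stats::setNames(rep(1, length(sense)), sense)
  if (!is.null(codon_weights)) {
    w[] <- 0
    keep <- intersect(names(codon_weights), sense)
    w[keep] <- codon_weights[keep]
  }
  if (all(w == 0)) stop("all codon weights are zero")
  stops <- c("TAA", "TAG", "TGA")
  tally <- stats::setNames(integer(length(sense)), sense)
  seqs <- character(n_genes)
  for (g in seq_len(n_genes)) {
    ncod <- sample(gene_length_range[1]:gene_length_range[2], 1L)
    inner <- sample(sense, ncod, replace = TRUE, prob = w)
    t2 <- table(inner)
    tally[names(t2)] <- tally[names(t2)] + as.integer(t2)
    seqs[g] <- paste(c("ATG", inner, sample(stops, 1L)), collapse = "")
  }
  list(records = seq_records(sprintf("gene%03d", seq_len(n_genes)), seqs),
       truth_counts = tally)
}
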