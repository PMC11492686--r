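# Pipeline orchestration, packaged study fixtures, and the CLI entry
# point.
#
# The contig geometry (lengths, depths, coordinates) and the printed
# spanning-read counts of the two Fagaceae mitogenomes studied here
# (Castanopsis carlesii, GenBank PP853255, and Castanea henryi,
# PP856681-PP856683) ship as plain-text fixtures, so molecule-length and
# isoform-proportion arithmetic can be exercised without any download.

fixture_path <- function(name) {
  system.file("extdata", name, package = "mitorecomb", mustWork = TRUE)
}

#' Packaged assembly-table fixture
#'
#' Machine-readable transcription of the assembled contig/repeat table
#' and resolved path strings for one of the two study species, as a
#' structural graph.
#'
#' @param species "C_carlesii" or "Ca_henryi"
#' @return list with `graph` (a `mito_graph`), `contigs`, `repeats`
#'   (data.frames incl. genome coordinates) and `paths` (the resolved
#'   molecule paths with topology)
#' @export
table1_fixture <- function(species = c("C_carlesii", "Ca_henryi")) {
  species <- match.arg(species)
  tab <- read_tsv_report(fixture_path("assembly_contigs.tsv"))
  tab <- tab[tab$species == species, , drop = FALSE]
  paths <- read_tsv_report(fixture_path("resolved_paths.tsv"))
  paths <- paths[paths$species == species,
                 c("molecule", "path", "topology"), drop = FALSE]
  contigs <- tab[tab$type == "contig", , drop = FALSE]
  repeats <- tab[tab$type == "repeat", , drop = FALSE]
  graph <- mito_graph_from_paths(
    contigs[c("id", "length", "depth")],
    repeats[c("id", "length", "depth")], paths,
    inverted = repeats$id[!is.na(repeats$copy2_orient) &
                            repeats$copy2_orient == "-"])
  list(graph = graph, contigs = contigs, repeats = repeats, paths = paths)
}

#' Packaged spanning-read count fixture
#'
#' The printed per-path valid spanning-read counts for every
#' recombination-active repeat of the study species.
#'
#' @param species "C_carlesii" or "Ca_henryi"
#' @return named list per repeat: `counts` (list of named count vectors,
#'   one element per conformation) and `mode` ("standard"/"multi")
#' @export
table3_counts <- function(species = c("C_carlesii", "Ca_henryi")) {
  species <- match.arg(species)
  tab <- read_tsv_report(fixture_path("spanning_counts.tsv"))
  tab <- tab[tab$species == species, , drop = FALSE]
  out <- list()
  for (r in unique(tab$repeat_id)) {
    sub <- tab[tab$repeat_id == r, , drop = FALSE]
    counts <- lapply(split(sub, sub$conformation), function(s)
      stats::setNames(s$count, s$path_label))
    out[[r]] <- list(counts = counts, mode = sub$mode[1])
  }
  out
}

#' Support table for all repeats of a study species from printed counts
#'
#' @param species "C_carlesii" or "Ca_henryi"
#' @return a `support_table` data.frame
#' @export
fixture_support_table <- function(species = c("C_carlesii", "Ca_henryi")) {
  species <- match.arg(species)
  cts <- table3_counts(species)
  tab <- do.call(rbind, lapply(names(cts), function(r)
    tally_support(cts[[r]]$counts, repeat_id = r, mode = cts[[r]]$mode)))
  rownames(tab) <- NULL
  class(tab) <- c("support_table", "data.frame")
  tab
}

default_config <- function() {
  list(seed = 1L, outdir = "mitorecomb_out", log_level = "info",
       stages = c("simulate", "quantify", "resolve", "report"),
       sim = list(contig_lengths = rep(9000L, 4L), repeat_lengths = 2000L,
                  mixture = 0.3, read_count = 800L,
                  error_rates = c(sub = 0, ins = 0, del = 0)),
       quantify = list(flank = 5000L, min_flank = 50L),
       rscu = list(cds_fasta = NULL),
       repeats = list(fasta = NULL, ssr_thresholds = c(10, 5, 4, 3, 3, 3),
                      min_repeat = 30L, hamming = 3L, cap = 5000L),
       mtpt = list(mt_fasta = NULL, cp_fasta = NULL, evalue = 1e-5,
                   gff = NULL))
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), paste0(...)))
}

provenance <- function(config, extra = NULL) {
  c(list(tool = "mitorecomb",
         version = as.character(utils::packageVersion("mitorecomb")),
         seed = config$seed), extra)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order inside the output
#' directory; every report carries a provenance header (tool version,
#' seed, parameters). With identical config and seed all outputs are
#' byte-identical.
#'
#' @param config nested list (see `mitorecomb:::default_config()` for
#'   the shape) or a path to a YAML file with the same structure
#' @return named list of per-stage results, invisibly
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::yaml.load_file(config)
  }
  config <- merge_config(default_config(), config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  toy <- NULL
  reads <- NULL

  for (stage in config$stages) {
    t0 <- Sys.time()
    log_msg("info", "stage ", stage, " started")
    if (stage == "simulate") {
      sc <- do.call(sim_config,
                    c(list(seed = config$seed), config$sim))
      toy <- make_toy_genome(sc)
      confs <- repeat_conformations(toy$graph, toy$graph$repeats$id[1])
      isoforms <- lapply(confs, molecule_seqs, graph = toy$graph)
      p <- toy$truth[[1]]
      simres <- simulate_reads(isoforms, c(reference = 1 - p,
                                           crossover = p), sc)
      reads <- simres$reads
      write_gfa(toy$gfa, file.path(config$outdir, "toy_graph.gfa"))
      write_fasta(reads, file.path(config$outdir, "reads.fasta"))
      write_tsv_report(simres$truth,
                       file.path(config$outdir, "read_truth.tsv"),
                       provenance(config))
      results$simulate <- list(graph = toy$graph, truth = toy$truth,
                               n_reads = nrow(reads))
    } else if (stage == "quantify") {
      if (is.null(toy)) stop("dependency error: stage 'quantify' needs ",
                             "stage 'simulate' (or supply reads/graph)")
      q <- quantify_recombination(toy$graph, reads,
                                  flank = config$quantify$flank,
                                  min_flank = config$quantify$min_flank)
      write_support_table(q$table,
                          file.path(config$outdir, "support.tsv"),
                          provenance(config))
      results$quantify <- q
    } else if (stage == "resolve") {
      if (is.null(results$quantify)) {
        stop("dependency error: stage 'resolve' needs stage 'quantify'")
      }
      est <- estimate_ratio(results$quantify$table)
      cross <- est[est$conformation == "crossover", ]
      ratios <- stats::setNames(cross$proportion, cross$repeat_id)
      mols <- resolve_major(toy$graph, ratios)
      write_tsv_report(as.data.frame(mols),
                       file.path(config$outdir, "molecules.tsv"),
                       provenance(config))
      results$resolve <- mols
    } else if (stage == "rscu") {
      cds <- read_fasta(config$rscu$cds_fasta)
      tab <- rscu(count_codons(cds))
      write_rscu_table(tab, file.path(config$outdir, "rscu.tsv"),
                       provenance(config))
      results$rscu <- tab
    } else if (stage == "detect_repeats") {
      fa <- read_fasta(config$repeats$fasta)
      ssrs <- do.call(rbind, lapply(seq_len(nrow(fa)), function(i)
        find_ssrs(fa$sequence[i],
                  thresholds = config$repeats$ssr_thresholds,
                  sequence_id = fa$id[i])))
      disp <- find_dispersed(paste(fa$sequence, collapse = ""),
                             min_len = config$repeats$min_repeat,
                             max_mismatch = config$repeats$hamming,
                             cap = config$repeats$cap)
      bins <- bin_dispersed(disp)
      write_tsv_report(ssrs, file.path(config$outdir, "ssr.tsv"),
                       provenance(config))
      write_tsv_report(disp, file.path(config$outdir, "dispersed.tsv"),
                       provenance(config))
      write_tsv_report(as.data.frame.table(bins$counts,
                                           responseName = "count"),
                       file.path(config$outdir, "dispersed_bins.tsv"),
                       provenance(config))
      results$detect_repeats <- list(ssrs = ssrs, dispersed = disp,
                                     bins = bins)
    } else if (stage == "mtpt") {
      mt <- read_fasta(config$mtpt$mt_fasta)
      cp <- read_fasta(config$mtpt$cp_fasta)
      hits <- local_search(mt$sequence[1], cp$sequence[1],
                           mtpt_params(evalue = config$mtpt$evalue))
      ann <- if (!is.null(config$mtpt$gff)) {
        read_annotations(config$mtpt$gff)
      } else NULL
      summ <- summarize_mtpt(hits, mask_cp_repeats(cp$sequence[1]),
                             nchar(mt$sequence[1]), ann)
      write_tsv_report(hits, file.path(config$outdir, "mtpt_hits.tsv"),
                       provenance(config))
      write_tsv_report(
        data.frame(total_length = summ$total_length,
                   percent = sprintf("%.2f", summ$percent),
                   n_fragments = summ$n_fragments),
        file.path(config$outdir, "mtpt_summary.tsv"), provenance(config))
      results$mtpt <- summ
    } else if (stage == "report") {
      if (!is.null(results$quantify)) {
        est <- estimate_ratio(results$quantify$table)
        write_tsv_report(est, file.path(config$outdir, "proportions.tsv"),
                         provenance(config))
        results$report <- est
      }
    } else {
      stop("unknown stage: ", stage)
    }
    log_msg("info", "stage ", stage, " finished in ",
            sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))))
  }
  invisible(results)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `quantify-recomb`, `resolve`,
#' `detect-repeats`, `rscu`, `mtpt` and `report` onto [run_pipeline()].
#' Flags are `--key value` pairs mirroring the config fields; `--config
#' file.yaml` loads a YAML config first (flag > config file > default).
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`
#' @return exit status (0 on success), invisibly
#' @export
mito_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: mitorecomb <simulate|quantify-recomb|resolve|",
            "detect-repeats|rscu|mtpt|report> [--key value ...]")
    return(invisible(1L))
  }
  sub <- args[1]
  flags <- args[-1]
  kv <- list()
  i <- 1L
  while (i <= length(flags)) {
    key <- sub("^--", "", flags[i])
    kv[[key]] <- if (i + 1L <= length(flags)) flags[i + 1L] else TRUE
    i <- i + 2L
  }
  config <- if (!is.null(kv$config)) kv$config else list()
  if (is.character(config)) {
    config <- yaml::yaml.load_file(config)
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  stage_map <- c("simulate" = "simulate",
                 "quantify-recomb" = "quantify",
                 "resolve" = "resolve",
                 "detect-repeats" = "detect_repeats",
                 "rscu" = "rscu", "mtpt" = "mtpt", "report" = "report")
  if (!sub %in% names(stage_map)) {
    message("unknown subcommand: ", sub)
    return(invisible(1L))
  }
  stages <- switch(sub,
    "quantify-recomb" = c("simulate", "quantify"),
    "resolve" = c("simulate", "quantify", "resolve"),
    "report" = c("simulate", "quantify", "report"),
    stage_map[[sub]])
  config$stages <- stages
  if (!is.null(kv$seed)) config$seed <- as.integer(kv$seed)
  if (!is.null(kv$out)) config$outdir <- kv$out
  if (!is.null(kv$flank)) config$quantify$flank <- num(kv$flank)
  if (!is.null(kv[["min-flank"]])) {
    config$quantify$min_flank <- num(kv[["min-flank"]])
  }
  if (!is.null(kv$fasta)) config$repeats$fasta <- kv$fasta
  if (!is.null(kv$cds)) config$rscu$cds_fasta <- kv$cds
  if (!is.null(kv$mt)) config$mtpt$mt_fasta <- kv$mt
  if (!is.null(kv$cp)) config$mtpt$cp_fasta <- kv$cp
  if (!is.null(kv$evalue)) config$mtpt$evalue <- num(kv$evalue)
  if (!is.null(kv$gff)) config$mtpt$gff <- kv$gff
  status <- tryCatch({ run_pipeline(config); 0L },
                     error = function(e) {
                       message("error: ", conditionMessage(e)); 1L
                     })
  invisible(status)
}
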