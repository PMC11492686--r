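# Structural-graph model: pairings, lengths, resolution, depth checks.

carlesii <- table1_fixture("C_carlesii")
henryi <- table1_fixture("Ca_henryi")

# order-insensitive path-label comparison (a label and its reversal name
# the same adjacency)
label_key <- function(labels) {
  sort(vapply(labels, function(l) {
    e <- strsplit(l, "-", fixed = TRUE)[[1]]
    paste(sort(c(e[1], e[3])), collapse = "|")
  }, character(1), USE.NAMES = FALSE))
}

test_that("enumerate_pairings returns the 2x2 pairing combinatorics", {
  g <- mito_graph(
    data.frame(id = c("L1", "L2", "R1", "R2"), length = 100L),
    data.frame(id = "LR", length = 10L),
    list(LR = list(c("L1", "R1"), c("L2", "R2"))))
  pr <- enumerate_pairings(g, "LR")
  expect_equal(attr(pr$reference, "labels"), c("L1-LR-R1", "L2-LR-R2"))
  expect_equal(attr(pr$crossover, "labels"), c("L1-LR-R2", "L2-LR-R1"))
  # both pairings traverse the repeat using each neighbor exactly once
  for (pairing in pr) {
    nb <- unlist(pairing)
    expect_setequal(nb, c("L1", "L2", "R1", "R2"))
  }

  g2 <- mito_graph(
    data.frame(id = c("L1", "R1", "L2"), length = 100L),
    data.frame(id = "LR", length = 10L),
    list(LR = list(c("L1", "R1"), c("L2", NA))))
  expect_error(enumerate_pairings(g2, "LR"), "right neighbor")
})

test_that("enumerate_pairings reproduces the printed LR9 path labels", {
  pr <- enumerate_pairings(carlesii$graph, "LR9")
  expect_equal(label_key(attr(pr$reference, "labels")),
               label_key(c("contig7-LR9-contig4", "contig2-LR9-contig8")))
  expect_equal(label_key(attr(pr$crossover, "labels")),
               label_key(c("contig2-LR9-contig4", "contig7-LR9-contig8")))
})

test_that("molecule_length reproduces the published molecule sizes", {
  expect_equal(molecule_length(carlesii$paths$path[1], carlesii$graph),
               592702)
  hen <- stats::setNames(henryi$paths$path, henryi$paths$molecule)
  expect_equal(molecule_length(hen[["chr1"]], henryi$graph), 252027)
  expect_equal(molecule_length(hen[["chr2"]], henryi$graph), 86851)
  expect_equal(molecule_length(hen[["chr3"]], henryi$graph), 41051)

  g1 <- mito_graph(data.frame(id = "c", length = 7L), NULL, list())
  expect_equal(molecule_length("c", g1), 7)
  expect_error(molecule_length("nope", g1), "unknown element")
})

test_that("resolve_major walks the published Ca. henryi chromosomes", {
  mols <- resolve_major(henryi$graph)
  expect_equal(nrow(mols), 3L)
  expect_true(all(mols$topology == "circular"))
  expect_setequal(mols$length, c(252027, 86851, 41051))
  expect_equal(sum(mols$length), 379929)
})

test_that("toy crossover flips between one and two circular molecules", {
  toy <- make_toy_genome(sim_config(seed = 5))
  ref <- resolve_major(toy$graph, c(R1 = "reference"))
  crs <- resolve_major(toy$graph, c(R1 = "crossover"))
  expect_equal(nrow(ref), 1L)
  expect_equal(nrow(crs), 2L)
  expect_true(all(c(ref$topology, crs$topology) == "circular"))
  # total length is invariant under the pairing choice
  expect_equal(sum(ref$length), sum(crs$length))
  # each contig exactly once, repeat twice, in both resolutions
  for (mols in list(ref, crs)) {
    els <- unlist(lapply(mols$path, parse_path))
    expect_equal(sort(els[grepl("^c", els)]), sort(toy$graph$contigs$id))
    expect_equal(sum(els == "R1"), 2L)
  }
})

test_that("molecule_length matches stitched sequence length", {
  toy <- make_toy_genome(sim_config(seed = 6))
  for (choice in c("reference", "crossover")) {
    mols <- resolve_major(toy$graph, c(R1 = choice))
    for (i in seq_len(nrow(mols))) {
      ms <- molecule_sequence(mols$path[i], toy$graph)
      expect_equal(nchar(ms$sequence), mols$length[i])
    }
  }
})

test_that("total length is invariant under pairing choices (henryi)", {
  # LR7's copies are inverted (crossover would reverse contig
  # traversals, which signed-path resolution does not model), so vary
  # the two direct repeats
  combos <- expand.grid(LR8 = c("reference", "crossover"),
                        LR9 = c("reference", "crossover"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    choice <- c(LR7 = "reference", unlist(combos[i, ]))
    mols <- resolve_major(henryi$graph, choice)
    expect_equal(sum(mols$length), 379929)
  }
  expect_error(resolve_major(henryi$graph, c(LR7 = "crossover",
                                             LR8 = "reference",
                                             LR9 = "reference")),
               "inverted repeat")
})

test_that("graph with no repeats resolves to its connected components", {
  g <- mito_graph(data.frame(id = c("a", "b", "c"), length = c(5L, 6L, 7L)),
                  NULL, list(),
                  links = data.frame(from = "a", to = "b",
                                     stringsAsFactors = FALSE))
  mols <- resolve_major(g)
  expect_equal(nrow(mols), 2L)
  expect_setequal(mols$path, c("a-b", "c"))
  expect_true(all(mols$topology == "linear"))
})

test_that("depth_consistency flags violations of the 2-copy expectation", {
  # two molecules at 150x sharing one repeat -> repeat ~300x: consistent
  g <- mito_graph(
    data.frame(id = c("a", "b", "c", "d"), length = 1000L,
               depth = c(150, 150, 150, 150)),
    data.frame(id = "LR", length = 100L, depth = 300),
    list(LR = list(c("a", "b"), c("c", "d"))))
  rep1 <- depth_consistency(g)
  expect_false(rep1$flagged)
  expect_equal(rep1$expected, 300)

  # all depths equal: violates the expectation, flagged
  g2 <- mito_graph(
    data.frame(id = c("a", "b", "c", "d"), length = 1000L, depth = 150),
    data.frame(id = "LR", length = 100L, depth = 150),
    list(LR = list(c("a", "b"), c("c", "d"))))
  expect_true(depth_consistency(g2)$flagged)

  g3 <- mito_graph(
    data.frame(id = c("a", "b", "c", "d"), length = 1000L, depth = 150),
    data.frame(id = "LR", length = 100L),
    list(LR = list(c("a", "b"), c("c", "d"))))
  expect_warning(out <- depth_consistency(g3), "missing depths")
  expect_equal(nrow(out), 0L)
})

test_that("depth_consistency holds on simulated coverage", {
  # single-molecule toy, repeat traversed twice at uniform read coverage:
  # the repeat accumulates ~2x the contig depth
  fx <- toy_with_reads(seed = 21, p = 0, read_count = 400)
  mols <- resolve_major(fx$toy$graph, c(R1 = "reference"))
  ms <- molecule_sequence(mols$path[1], fx$toy$graph)
  cov <- numeric(nchar(ms$sequence))
  tr <- fx$truth
  L <- nchar(ms$sequence)
  for (i in seq_len(nrow(tr))) {
    idx <- (tr$start[i]:tr$end[i] - 1L) %% L + 1L
    cov[idx] <- cov[idx] + 1
  }
  g <- fx$toy$graph
  lay <- ms$layout
  el_depth <- vapply(seq_len(nrow(lay)), function(i)
    mean(cov[lay$start[i]:lay$end[i]]), numeric(1))
  # a 2-copy repeat's observed assembly depth is the summed coverage of
  # its traversals
  rep_rows <- lay$element == "R1"
  g$repeats$depth <- sum(el_depth[rep_rows])
  first <- !duplicated(lay$element) & !rep_rows
  g$contigs$depth <- el_depth[first][match(g$contigs$id,
                                           lay$element[first])]
  out <- depth_consistency(g, tol = 0.10)
  expect_false(out$flagged)
  expect_gt(out$ratio, 0.9)
  expect_lt(out$ratio, 1.1)
})
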