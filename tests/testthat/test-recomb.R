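# Windows, alignment, the flanking-coverage rule, tallying, estimation.

test_that("windows have the stated arithmetic and truncation behavior", {
  fx <- toy_with_reads(seed = 31, p = 0.5, read_count = 1)
  win <- build_windows(fx$confs, fx$toy$graph, "R1", flank = 5000L)
  expect_equal(nrow(win), 4L)
  expect_true(all(nchar(win$sequence) == 12000L))
  expect_true(all(win$repeat_start == 5001L & win$repeat_end == 7000L))
  expect_false(any(win$truncated_left | win$truncated_right))
  expect_setequal(win$conformation[duplicated(win$conformation)],
                  c("reference", "crossover"))

  # windows equal substrings extracted independently by coordinates
  mols <- resolve_major(fx$toy$graph, c(R1 = "reference"))
  ms <- molecule_sequence(mols$path[1], fx$toy$graph)
  dbl <- paste0(ms$sequence, ms$sequence)
  L <- nchar(ms$sequence)
  for (i in which(win$conformation == "reference")) {
    occ <- which(ms$layout$element == "R1")
    starts <- ms$layout$start[occ]
    hit <- vapply(starts, function(s) {
      a <- (s - 5000L - 1L) %% L + 1L
      substr(dbl, a, a + 11999L) == win$sequence[i]
    }, logical(1))
    expect_true(any(hit))
  }
})

test_that("flank truncation at linear molecule ends is recorded", {
  set.seed(32)
  contigs <- data.frame(id = c("a", "b"), length = c(3100L, 8000L),
                        sequence = c(rand_dna(3100), rand_dna(8000)),
                        stringsAsFactors = FALSE)
  repeats <- data.frame(id = "LR", length = 2000L,
                        sequence = rand_dna(2000),
                        stringsAsFactors = FALSE)
  g <- mito_graph(contigs, repeats, list(LR = list(c("a", "b"), c("b", "a"))))
  mols <- data.frame(molecule = "M1", path = "a-LR-b", topology = "linear",
                     stringsAsFactors = FALSE)
  win <- build_windows(list(reference = mols), g, "LR", flank = 5000L)
  expect_equal(win$left_flank, 3100L)
  expect_true(win$truncated_left)
  expect_equal(win$right_flank, 5000L)
  expect_false(win$truncated_right)
  expect_equal(win$repeat_start, 3101L)
})

test_that("window error when a circular molecule is too small", {
  fx <- toy_with_reads(seed = 33, p = 0.5, read_count = 1)
  expect_error(build_windows(fx$confs, fx$toy$graph, "R1", flank = 20001L),
               "smaller than the requested window")
})

test_that("exact reads align with exact coordinates and identity 1", {
  fx <- toy_with_reads(seed = 34, p = 0, read_count = 1)
  win <- build_windows(fx$confs, fx$toy$graph, "R1")
  frag <- substr(win$sequence[1], 2001, 10000)   # 8 kb inside window 1
  reads <- seq_records(c("exact", "rc", "alien"),
                       c(frag, revcomp(frag), rand_dna(3000)))
  aln <- align_reads(reads, win[1, , drop = FALSE])
  a <- aln[aln$read_id == "exact", ]
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$window_start, a$window_end), c(2001, 10000))
  expect_equal(a$identity, 1.0)
  expect_equal(a$strand, "+")
  r <- aln[aln$read_id == "rc", ]
  expect_equal(c(r$window_start, r$window_end), c(2001, 10000))
  expect_equal(r$strand, "-")
  expect_false("alien" %in% aln$read_id)
  expect_error(align_reads(reads[0, ], win), "nonempty")
})

test_that("alignment coordinates track truth under 5% substitutions", {
  set.seed(35)
  fx <- toy_with_reads(seed = 35, p = 0, read_count = 1)
  win <- build_windows(fx$confs, fx$toy$graph, "R1")[1, , drop = FALSE]
  n <- 200L
  starts <- sample(1:3000, n, replace = TRUE)
  lens <- sample(4000:8000, n, replace = TRUE)
  raw <- substring(win$sequence, starts, pmin(starts + lens - 1L, 12000L))
  noisy <- vapply(raw, function(s) {
    ch <- chars(s)
    at <- which(stats::runif(length(ch)) < 0.05)
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  reads <- seq_records(sprintf("r%03d", 1:n), noisy)
  aln <- align_reads(reads, win)
  i <- match(aln$read_id, reads$id)
  d_start <- abs(aln$window_start - starts[i])
  d_end <- abs(aln$window_end - pmin(starts[i] + lens[i] - 1L, 12000L))
  ok <- d_start <= 10 & d_end <= 10
  expect_gte(mean(ok[!is.na(ok)]) * nrow(aln) / n, 0.95)
})

test_that("classify_support implements the 50 bp flank rule exactly", {
  # boundary: exactly 50 bp each side supports; 49 bp does not
  expect_true(classify_support(4951L, 9050L, 5001L, 7000L, 50L))
  expect_false(classify_support(4952L, 9050L, 5001L, 7000L, 50L))
  expect_false(classify_support(4951L, 7049L, 5001L, 7000L, 50L))

  # exhaustive check against the position-counting oracle on a toy window
  rs <- 31L; re <- 50L; wlen <- 80L; mf <- 5L
  for (a in 1:wlen) {
    for (b in a:wlen) {
      expect_identical(classify_support(a, b, rs, re, mf),
                       support_oracle(a, b, rs, re, mf))
    }
  }
})

test_that("classify_support is monotone in the cover interval", {
  set.seed(36)
  for (i in 1:200) {
    rs <- sample(50:100, 1); re <- rs + sample(10:50, 1)
    a <- sample(1:rs, 1); b <- sample(re:(re + 80), 1)
    if (classify_support(a, b, rs, re, 20L)) {
      expect_true(classify_support(a - 1L, b + 1L, rs, re, 20L))
    }
  }
})

test_that("multimapping resolution keeps winners, discards ties", {
  aln <- data.frame(read_id = c("r1", "r2", "r2", "r3", "r3"),
                    window_id = c("w1", "w1", "w2", "w1", "w2"),
                    score = c(100, 90, 80, 70, 70),
                    supports = TRUE, stringsAsFactors = FALSE)
  res <- resolve_multimapping(aln)
  expect_equal(res$ambiguous, 1L)
  expect_setequal(res$calls$read_id, c("r1", "r2"))
  expect_equal(res$calls$window_id[res$calls$read_id == "r2"], "w1")
})

test_that("zero-error simulation yields no ambiguous reads", {
  fx <- toy_with_reads(seed = 37, p = 0.3, read_count = 300)
  q <- quantify_recombination(fx$toy$graph, fx$reads)
  expect_equal(unname(q$ambiguous["R1"]), 0L)
})

test_that("tally reproduces the printed proportions", {
  cts <- table3_counts("C_carlesii")
  tab <- tally_support(cts$LR9$counts, "LR9")
  expect_equal(unique(round_half_up(100 * tab$proportion)),
               c(57.69, 42.31))
  hen <- table3_counts("Ca_henryi")
  tab7 <- tally_support(hen$LR7$counts, "LR7")
  expect_equal(unique(tab7$conformation_total), c(488, 380))
  expect_equal(unique(round_half_up(100 * tab7$proportion)),
               c(56.22, 43.78))
  tab9 <- tally_support(hen$LR9$counts, "LR9", mode = "multi")
  expect_equal(unique(round_half_up(100 * tab9$proportion)),
               c(86.58, 13.42))
})

test_that("proportions respect label swap and sum/average equivalence", {
  counts <- list(A = c(p1 = 11, p2 = 4), B = c(p3 = 4, p4 = 7))
  tab <- tally_support(counts, "r")
  swapped <- tally_support(rev(counts), "r")
  pA <- tab$proportion[tab$conformation == "A"][1]
  pA2 <- swapped$proportion[swapped$conformation == "A"][1]
  expect_equal(pA, pA2)
  expect_equal(pA + tab$proportion[tab$conformation == "B"][1], 1)
  # averaging the two path counts instead of summing leaves proportions
  # unchanged (both numerator and denominator halve)
  avg <- tally_support(lapply(counts, function(x) x / 2), "r")
  expect_equal(unique(avg$proportion), unique(tab$proportion))
})

test_that("estimate_ratio attaches sensible Wilson intervals", {
  tab <- tally_support(list(A = c(p = 15), B = c(q = 11)), "r")
  est <- estimate_ratio(tab)
  expect_equal(est$proportion[est$conformation == "A"], 15 / 26)
  expect_true(all(est$lower < est$proportion & est$proportion < est$upper))

  tab0 <- tally_support(list(A = c(p = 0), B = c(q = 10)), "r")
  est0 <- estimate_ratio(tab0)
  zero <- est0[est0$conformation == "A", ]
  expect_equal(zero$proportion, 0)
  expect_gt(zero$upper, 0)   # nondegenerate interval at 0 successes
})

test_that("known mixtures are recovered within the Wilson interval", {
  fx <- toy_with_reads(seed = 38, p = 0.3, read_count = 600)
  q <- quantify_recombination(fx$toy$graph, fx$reads)
  est <- estimate_ratio(q$table, conf = 0.99)
  cr <- est[est$conformation == "crossover", ]
  expect_gt(sum(est$total), 250)
  expect_true(cr$lower <= 0.3 && 0.3 <= cr$upper)
})
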