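# SSR and dispersed-repeat detection against brute-force oracles.

test_that("find_ssrs handles threshold boundaries", {
  set.seed(41)
  s <- paste0(rand_dna(100), "CCCCCCCCCC", rand_dna(100))   # 10x C
  hit <- find_ssrs(s)
  mono <- hit[hit$motif_length == 1 & hit$motif == "C", ]
  expect_gte(nrow(mono), 1L)
  expect_gte(max(mono$repeat_count), 10L)

  # deterministic 9x run below threshold, flanked by breakers
  s9 <- paste0("T", strrep("A", 9), "T")
  expect_equal(nrow(find_ssrs(s9)), 0L)
  s10 <- paste0("T", strrep("A", 10), "T")
  hit10 <- find_ssrs(s10)
  expect_equal(hit10$repeat_count, 10L)
  expect_equal(c(hit10$start, hit10$end), c(2L, 11L))
})

test_that("SSR records respect their own invariants", {
  set.seed(42)
  for (i in 1:10) {
    s <- rand_dna(3000)
    hits <- find_ssrs(s)
    if (!nrow(hits)) next
    th <- c(10L, 5L, 4L, 3L, 3L, 3L)
    expect_true(all(hits$repeat_count >= th[hits$motif_length]))
    expect_true(all(hits$end - hits$start + 1L ==
                      hits$motif_length * hits$repeat_count))
    # the reported interval really is the motif repeated
    for (j in seq_len(nrow(hits))) {
      expect_identical(substr(s, hits$start[j], hits$end[j]),
                       strrep(hits$motif[j], hits$repeat_count[j]))
    }
  }
})

test_that("find_ssrs matches the brute-force scanner with planted SSRs", {
  set.seed(43)
  motifs <- c("A", "AT", "ACG", "AATC", "AACGT", "AACGTT")
  for (case in 1:50) {
    parts <- character(0)
    for (p in 1:3) {
      m <- sample(motifs, 1)
      reps <- sample(3:12, 1)
      parts <- c(parts, rand_dna(sample(50:200, 1)), strrep(m, reps))
    }
    s <- paste0(paste(parts, collapse = ""), rand_dna(100))
    got <- find_ssrs(s)
    want <- ssr_bruteforce(s)
    expect_equal(got[c("motif", "motif_length", "repeat_count",
                       "start", "end")],
                 want, ignore_attr = TRUE)
  }
})

test_that("SSRs mirror under reverse complement", {
  set.seed(44)
  s <- paste0(rand_dna(150), strrep("AG", 6), rand_dna(80),
              strrep("T", 11), rand_dna(150))
  n <- nchar(s)
  fwd <- find_ssrs(s)
  rev <- find_ssrs(revcomp(s))
  expect_equal(nrow(rev), nrow(fwd))
  # each mirrored record matches a forward record up to the < motif-length
  # shift that truncating a partial trailing copy can introduce
  for (i in seq_len(nrow(rev))) {
    st <- n - rev$end[i] + 1L
    en <- n - rev$start[i] + 1L
    m <- rev$motif_length[i]
    cand <- fwd[fwd$motif_length == m & abs(fwd$start - st) < m &
                  abs(fwd$end - en) < m, ]
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$repeat_count, rev$repeat_count[i])
    rots <- vapply(0:(m - 1), function(k)
      paste0(substr(cand$motif, k + 1, m), substr(cand$motif, 1, k)),
      character(1))
    expect_true(revcomp(rev$motif[i]) %in% rots)
  }
})

test_that("dispersed repeats: planted palindrome found with mismatches", {
  set.seed(45)
  core <- rand_dna(1000)
  g <- paste0(rand_dna(2000), core, rand_dna(10000), revcomp(core),
              rand_dna(2000))
  hits <- find_dispersed(g)
  pal <- hits[hits$class == "palindromic" & hits$length >= 1000, ]
  expect_gte(nrow(pal), 1L)
  expect_true(any(pal$start1 <= 2001 + 3 & pal$end1 >= 3000 - 3))

  # mutate two bases inside the second copy: still found, 2+ mismatches
  g2 <- g
  substr(g2, 13501, 13501) <- chartr("ACGT", "CGTA",
                                     substr(g2, 13501, 13501))
  substr(g2, 13701, 13701) <- chartr("ACGT", "CGTA",
                                     substr(g2, 13701, 13701))
  hits2 <- find_dispersed(g2)
  pal2 <- hits2[hits2$class == "palindromic" & hits2$length >= 900, ]
  expect_gte(nrow(pal2), 1L)
})

test_that("every dispersed repeat re-verifies its class transform", {
  set.seed(46)
  core <- rand_dna(120)
  g <- paste0(rand_dna(400), core, rand_dna(300),
              paste(rev(chars(core)), collapse = ""), rand_dna(200),
              core, rand_dna(300))
  hits <- find_dispersed(g)
  expect_gt(nrow(hits), 0L)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    a <- chars(substr(g, h$start1, h$end1))
    b <- chars(substr(g, h$start2, h$end2))
    b <- switch(h$class,
                forward = b,
                reverse = rev(b),
                complement = unname(c(A = "T", C = "G", G = "C",
                                      T = "A")[b]),
                palindromic = unname(c(A = "T", C = "G", G = "C",
                                       T = "A")[rev(b)]))
    expect_equal(sum(a != b), h$mismatches)
    expect_lte(h$mismatches, 3L)
    expect_gte(h$length, 30L)
  }
})

test_that("find_dispersed matches the brute-force scanner", {
  set.seed(47)
  for (case in 1:50) {
    core <- rand_dna(sample(30:60, 1))
    mid <- rand_dna(sample(60:150, 1))
    tail_ <- rand_dna(sample(40:100, 1))
    planted <- switch(case %% 4 + 1,
                      core, revcomp(core),
                      paste(rev(chars(core)), collapse = ""),
                      paste(unname(c(A = "T", C = "G", G = "C",
                                     T = "A")[chars(core)]), collapse = ""))
    s <- paste0(rand_dna(sample(40:120, 1)), core, mid, planted, tail_)
    got <- dispersed_key(find_dispersed(s))
    want <- dispersed_key(dispersed_bruteforce(s))
    expect_identical(got, want)
  }
})

test_that("bin_dispersed places boundary lengths correctly", {
  reps <- data.frame(class = "forward",
                     start1 = 1, end1 = 1, start2 = 2, end2 = 2,
                     length = c(30L, 45L, 399L, 400L),
                     mismatches = 0L)
  b <- bin_dispersed(reps)
  expect_equal(unname(b$counts["forward", ]), c(1L, 1L, 0L, 1L, 1L))
  empty <- bin_dispersed(reps[0, ])
  expect_true(all(empty$counts == 0L))
})

test_that("bin counts match a planted composition", {
  set.seed(48)
  lens <- c(32L, 41L, 60L, 150L, 500L)
  parts <- character(0)
  for (L in lens) {
    core <- rand_dna(L)
    parts <- c(parts, rand_dna(200), core, rand_dna(200), core)
  }
  s <- paste(c(parts, rand_dna(100)), collapse = "")
  hits <- find_dispersed(s, classes = "forward")
  b <- bin_dispersed(hits)
  expect_true(all(b$counts["forward", ] >= 1L))
})
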