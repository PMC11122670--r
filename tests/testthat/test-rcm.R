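test_that("a perfect reverse complement yields one full-length hit", {
  set.seed(1)
  s <- randSeq(300)
  hits <- findRCM(s, rcOf(s))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$up_start, 1L)
  expect_identical(hits$up_end, 300L)
  expect_identical(hits$down_start, 1L)
  expect_identical(hits$down_end, 300L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$score, 600)
})

test_that("degenerate inputs give empty results, not errors", {
  expect_identical(nrow(findRCM("ACGTACGTACGT", "ACGT",
                                rcmParams(word_size = 11L))), 0L)
  expect_identical(nrow(findRCM(strrep("N", 100), randSeq(100))), 0L)
  expect_error(findRCM("", "ACGT"), "empty")
  expect_error(findRCM("ACGTX", "ACGT"), "outside")
})

test_that("hit set matches the exhaustive diagonal oracle on short sequences", {
  params <- rcmParams(word_size = 4L, match = 2, mismatch = -3,
                      gap_open = -1e6, gap_extend = -1e6, xdrop = 1e9,
                      min_length = 4L, min_score = 30, redundancy = 1.0,
                      max_hits = 1000L)
  for (sd in c(5, 17, 23, 41)) {
    set.seed(sd)
    up <- randSeq(200)
    ## embed partial complementarity so hits exist
    down <- randSeq(200)
    ins <- rcOf(substr(up, 60, 110))
    substr(down, 90, 90 + nchar(ins) - 1) <- ins
    hits <- findRCM(up, down, params)
    orc <- oracleDiagonalBest(up, down, word = 4L)
    qualifying <- orc[orc$best_score >= 30 & orc$has_word, , drop = FALSE]
    nB <- nchar(down)
    hit_diag <- (nB - hits$down_end + 1L) - hits$up_start
    ## every qualifying diagonal is reported at its optimal score
    for (r in seq_len(nrow(qualifying))) {
      w <- which(hit_diag == qualifying$diag[r])
      expect_true(length(w) > 0)
      expect_equal(max(hits$score[w]), qualifying$best_score[r])
    }
    ## no hit outscores its diagonal's optimum
    for (r in seq_len(nrow(hits))) {
      o <- orc[orc$diag == hit_diag[r], ]
      expect_lte(hits$score[r], o$best_score)
    }
    ## the global best equals the optimal ungapped local alignment from
    ## an independent aligner
    if (nrow(hits)) {
      pa <- Biostrings::pairwiseAlignment(
        up, rcOf(down), type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 2, mismatch = -3, baseOnly = TRUE),
        gapOpening = 1e6, gapExtension = 1e6, scoreOnly = TRUE)
      expect_equal(max(hits$score), pa)
    }
  }
})

test_that("findRCM is symmetric in its two introns", {
  for (sd in c(3, 9)) {
    set.seed(sd)
    up <- randSeq(400)
    down <- randSeq(400)
    substr(down, 100, 179) <- rcOf(substr(up, 50, 129))
    p <- rcmParams(sensitive = TRUE)
    h1 <- findRCM(up, down, p)
    h2 <- findRCM(down, up, p)
    expect_identical(nrow(h1), nrow(h2))
    key1 <- h1[order(h1$up_start),
               c("up_start", "up_end", "down_start", "down_end",
                 "length", "identity", "score")]
    key2 <- h2[order(h2$down_start),
               c("down_start", "down_end", "up_start", "up_end",
                 "length", "identity", "score")]
    names(key2) <- names(key1)
    rownames(key1) <- rownames(key2) <- NULL
    expect_equal(key1, key2)
  }
})

test_that("reported scores are reproducible from the intervals", {
  b <- makeMimicLocus()
  fl <- flankingIntrons(bundleGenome(b), bundleCirc(b), b@extras$introns)
  p <- rcmParams(sensitive = TRUE)
  hits <- findRCM(fl$up, fl$down, p)
  expect_gt(nrow(hits), 0)
  for (r in seq_len(nrow(hits)))
    expect_equal(rcmHitScore(hits[r, ], fl$up, fl$down, p),
                 hits$score[r])
  ## no hit extends outside its intron
  expect_true(all(hits$up_start >= 1 & hits$up_end <= nchar(fl$up)))
  expect_true(all(hits$down_start >= 1 & hits$down_end <= nchar(fl$down)))
})

test_that("a planted interrupted repeat is chained into one gapped hit", {
  set.seed(77)
  up <- randSeq(600)
  seg <- substr(up, 101, 220)                 # 120 nt
  ## downstream copy carries a 3-nt insertion in the middle
  broken <- paste0(substr(seg, 1, 60), "ACT", substr(seg, 61, 120))
  down <- randSeq(600)
  substr(down, 201, 200 + nchar(broken)) <- rcOf(broken)
  hits <- findRCM(up, down, rcmParams())
  expect_gt(nrow(hits), 0)
  top <- hits[1, ]
  expect_gte(top$n_gaps, 3L)
  expect_gte(top$up_end - top$up_start + 1L, 115L)
  expect_equal(rcmHitScore(top, up, down, rcmParams()), top$score)
})

test_that("repeat annotation uses closed-interval overlap of >= 1 nt", {
  hits <- data.frame(up_start = 100L, up_end = 249L, down_start = 500L,
                     down_end = 600L, length = 150L, identity = 0.9,
                     score = 100, n_gaps = 0L, repeats = "")
  reps <- data.frame(name = c("SINE_a", "SINE_b"),
                     start = c(240L, 250L), end = c(400L, 400L))
  out <- annotateRepeats(hits, up_repeats = reps)
  expect_identical(out$repeats, "SINE_a")
  ## quadratic all-pairs oracle on random intervals
  set.seed(8)
  for (rep in 1:20) {
    h <- data.frame(up_start = sample(1:500, 5), down_start = 1L)
    h$up_end <- h$up_start + sample(20:80, 5)
    h$down_end <- 1L
    h$length <- 10L; h$identity <- 1; h$score <- 1; h$n_gaps <- 0L
    h$repeats <- ""
    rp <- data.frame(name = paste0("r", 1:6), start = sample(1:500, 6))
    rp$end <- rp$start + sample(10:100, 6)
    got <- annotateRepeats(h, up_repeats = rp)$repeats
    want <- vapply(seq_len(nrow(h)), function(i)
      paste(rp$name[rp$start <= h$up_end[i] & rp$end >= h$up_start[i]],
            collapse = ","), "")
    expect_identical(got, want)
  }
})

test_that("candidate ranking follows length, then identity, then score", {
  h <- data.frame(up_start = c(1L, 2L, 3L, 4L), up_end = 0L,
                  down_start = 0L, down_end = 0L,
                  length = c(300L, 120L, 800L, 120L),
                  identity = c(0.9, 0.88, 0.8, 0.99),
                  score = c(1, 2, 3, 4), n_gaps = 0L, repeats = "")
  r <- rankCandidates(h, 4L)
  expect_identical(r$length, c(800L, 300L, 120L, 120L))
  expect_identical(r$identity[3:4], c(0.99, 0.88))
  expect_identical(nrow(rankCandidates(h, 0L)), 0L)
  expect_identical(nrow(rankCandidates(h, 2L)), 2L)
})
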