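circleOf <- function(s) new("CircleSeq", sequence = s, source = "test")

test_that("buildCircle concatenates the chain strand-aware", {
  genome <- "TTAAATTCCCTT"
  circ <- circDef("c", "+", IRanges::IRanges(c(3, 8), c(5, 10)))
  expect_identical(circleSeq(buildCircle(genome, circ)), "AAACCC")
  circm <- circDef("c", "-", IRanges::IRanges(3, 6))   # genomic AAAT
  expect_identical(circleSeq(buildCircle(genome, circm)), "ATTT")
})

test_that("junctionWindow takes flank bases on each side of the seam", {
  cc <- circleOf("AAACCC")
  expect_identical(junctionWindow(cc, 2L), "CCAA")
  ## flank = length gives a full rotation starting mid-circle
  expect_identical(junctionWindow(cc, 6L), "AAACCCAAACCC")
  expect_error(junctionWindow(cc, 7L), "flank")
})

test_that("the junction window is absent from every linear mRNA", {
  b <- makeMimicLocus()
  cc <- buildCircle(bundleGenome(b), bundleCirc(b))
  for (flank in c(5L, 10L, 19L)) {
    w <- junctionWindow(cc, flank)
    expect_false(any(vapply(b@extras$mrnas, grepl, NA, pattern = w,
                            fixed = TRUE)))
  }
})

test_that("shRNA design enumerates junction-spanning frames and filters", {
  set.seed(5)
  s <- randSeq(200)
  cc <- circleOf(s)
  cand <- designJunctionShrna(cc, character(0), length = 19L,
                              min_arm = 5L, gc_range = c(0, 1))
  expect_identical(nrow(cand), 10L)         # left arms 5..14
  expect_true(all(cand$left_arm + cand$right_arm == 19L))
  expect_true(all(cand$left_arm >= 5L & cand$right_arm >= 5L))
  ## every candidate spans the junction of the doubled sequence frame
  for (r in seq_len(nrow(cand)))
    expect_identical(cand$sequence[r],
                     substr(paste0(s, s), cand$circ_offset[r],
                            cand$circ_offset[r] + 18L))
  ## a linear mRNA containing a target site suppresses that candidate
  lin <- substr(paste0(s, s), cand$circ_offset[1], cand$circ_offset[1] + 18L)
  cand2 <- designJunctionShrna(cc, lin, length = 19L, min_arm = 5L,
                               gc_range = c(0, 1))
  expect_identical(nrow(cand2), 9L)
  ## exclusion reasons are machine readable
  empty <- designJunctionShrna(cc, character(0), length = 19L,
                               min_arm = 5L, gc_range = c(0.99, 1))
  expect_identical(nrow(empty), 0L)
  expect_identical(sum(attr(empty, "reasons")), 10L)
})

test_that("designed shRNAs never occur in the fixture's linear mRNAs", {
  b <- makeMimicLocus()
  cc <- buildCircle(bundleGenome(b), bundleCirc(b))
  cand <- designJunctionShrna(cc, b@extras$mrnas)
  expect_gt(nrow(cand), 0)
  for (site in cand$sequence)
    expect_false(any(vapply(b@extras$mrnas, grepl, NA, pattern = site,
                            fixed = TRUE)))
})

test_that("divergent primers amplify across the junction, not the mRNA", {
  set.seed(11)
  s <- randSeq(300)
  cc <- circleOf(s)
  fwd <- substr(s, 231, 250)          # ends 50 nt before the junction
  rev <- rcOf(substr(s, 51, 70))      # site ends 70 nt after it
  rep <- checkDivergentPrimers(fwd, rev, cc, character(0))
  expect_identical(rep$status, "OK")
  expect_identical(rep$circ_amplicon_len, 140L)  # 100 gap + both primers
  expect_true(rep$spans_junction)
  expect_true(is.na(rep$linear_amplicon))
  ## a convergent pair within one exonic stretch also amplifies linear RNA
  fwd2 <- substr(s, 21, 40); rev2 <- rcOf(substr(s, 101, 120))
  rep2 <- checkDivergentPrimers(fwd2, rev2, cc, s)
  expect_identical(rep2$linear_amplicon, 100L)
  ## exact-match policy: one mismatch -> NOT_FOUND
  bad <- fwd; substr(bad, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                             substr(bad, 10, 10))[1]
  expect_identical(checkDivergentPrimers(bad, rev, cc,
                                         character(0))$status,
                   "NOT_FOUND")
})

test_that("circular ORFs: junction-spanning and rolling cases", {
  orfs <- findCircularOrfs(circleOf("GAAATAGAT"))
  expect_identical(nrow(orfs), 1L)
  expect_identical(orfs$start, 8L)
  expect_identical(orfs$peptide, "MK")
  expect_true(orfs$spans_junction)
  expect_identical(orfs$classification, "terminated")

  roll <- findCircularOrfs(circleOf("ATGAAA"), max_laps = 3L)
  expect_identical(roll$classification, "rolling")
  expect_identical(roll$laps, 3L)
  expect_identical(roll$aa_length, 6L)
})

test_that("circular ORFs equal the concatenation oracle on random circles", {
  set.seed(19)
  for (rep in 1:200) {
    s <- randSeq(sample(30:120, 1))
    got <- findCircularOrfs(circleOf(s))
    want <- oracleOrfs(s)
    if (!nrow(got)) { expect_identical(nrow(want), 0L); next }
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("ORF and seed results are rotation invariant", {
  set.seed(23)
  s <- randSeq(150)
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  ## plant one site so the seed scan is non-empty
  site <- paste0(rcOf(substr(chartr("U", "T", mir), 2, 8)), "A")
  substr(s, 40, 47) <- site
  cc <- circleOf(s)
  L <- nchar(s)
  for (r in c(1L, 50L, 149L)) {
    rot <- rotateCircle(cc, r)
    o1 <- findCircularOrfs(cc); o2 <- findCircularOrfs(rot)
    expect_identical(sort(((o2$start + r - 1L) %% L) + 1L) |> as.integer(),
                     sort(o1$start))
    expect_setequal(o2$peptide, o1$peptide)
    s1 <- scanSeedSites(cc, c(m = mir)); s2 <- scanSeedSites(rot, c(m = mir))
    expect_identical(as.integer(sort(((s2$circle_position + r - 1L) %% L) + 1L)),
                     sort(s1$circle_position))
    expect_setequal(s2$site_class, s1$site_class)
  }
})

test_that("N-terminus comparison reports the shared prefix", {
  expect_identical(compareNTerminus("MKLL", "MKAA")$shared_prefix_len, 2L)
  r <- compareNTerminus("MKLL", "MKLL")
  expect_identical(r$shared_prefix_len, 4L)
  expect_identical(r$circ_specific_suffix, "")
  expect_error(compareNTerminus("", "MK"), "empty")
})

test_that("seed classes follow the canonical definitions", {
  mir <- "UGGAAUGUAAAGAAGUAUGUAU"   # seed (2-8): GGAAUGU
  core6 <- rcOf("GGAATG")           # matches positions 2-7
  pad <- function(x) paste0(strrep("C", 20), x, strrep("C", 60))
  ## 8mer: revcomp(2-8) + A
  s8 <- pad(paste0(rcOf("GGAATGT"), "A"))
  got <- scanSeedSites(circleOf(s8), c(m = mir), min_class = "6mer")
  expect_identical(got$site_class, "8mer")
  ## 7mer-m8: revcomp(2-8), no A
  s7 <- pad(paste0(rcOf("GGAATGT"), "G"))
  got <- scanSeedSites(circleOf(s7), c(m = mir), min_class = "6mer")
  expect_identical(got$site_class, "7mer-m8")
  ## 7mer-A1: 6mer + A, wrong m8 base
  s7a <- pad(paste0("T", core6, "A"))
  got <- scanSeedSites(circleOf(s7a), c(m = mir), min_class = "6mer")
  expect_identical(got$site_class, "7mer-A1")
  ## 6mer only, and the min_class filter removes it by default
  s6 <- pad(paste0("T", core6, "G"))
  expect_identical(scanSeedSites(circleOf(s6), c(m = mir),
                                 min_class = "6mer")$site_class, "6mer")
  expect_identical(nrow(scanSeedSites(circleOf(s6), c(m = mir))), 0L)
})

test_that("junction-spanning seed sites are found exactly once", {
  set.seed(29)
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  site8 <- paste0(rcOf(substr(chartr("U", "T", mir), 2, 8)), "A")
  for (cut in 1:7) {
    s <- randSeq(120)
    L <- nchar(s)
    ## plant the 8-nt site across the junction: last `cut` nt at the end
    left <- substr(site8, 1, cut)
    right <- substr(site8, cut + 1, 8)
    substr(s, L - cut + 1, L) <- left
    substr(s, 1, 8 - cut) <- right
    got <- scanSeedSites(circleOf(s), c(m = mir), min_class = "6mer")
    planted <- got[got$circle_position == L - cut + 1L, ]
    expect_identical(nrow(planted), 1L)
    expect_identical(planted$site_class, "8mer")
    expect_true(planted$spans_junction)
  }
})

test_that("seed scan equals the doubled-sequence oracle", {
  set.seed(37)
  for (rep in 1:40) {
    s <- randSeq(sample(60:200, 1))
    mir <- paste0(chartr("T", "U", randSeq(22)))
    got <- scanSeedSites(circleOf(s), c(m = mir), min_class = "6mer")
    want <- oracleSeeds(s, mir, min_class = "6mer")
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_identical(got$circle_position, want$circle_position)
      expect_identical(got$site_class, want$site_class)
      expect_identical(got$spans_junction, want$spans_junction)
    }
  }
})
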