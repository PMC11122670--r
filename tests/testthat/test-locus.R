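ir <- function(s, e) IRanges::IRanges(s, e)

test_that("classifyOverlap distinguishes exonic, intronic and none", {
  circ <- circDef("chr", "+", ir(500, 600))
  tx_exonic <- transcriptModel("tx", ir(c(100, 500, 800),
                                        c(200, 600, 900)))
  tx_intronic <- transcriptModel("tx", ir(c(100, 800), c(200, 900)))
  tx_none <- transcriptModel("tx", ir(c(100, 300), c(200, 400)))
  expect_identical(classifyOverlap(tx_exonic, circ), "exonic")
  expect_identical(classifyOverlap(tx_intronic, circ), "intronic")
  expect_identical(classifyOverlap(tx_none, circ), "none")
  expect_error(classifyOverlap(tx_none, circ, strand = "-"),
               "strand mismatch")
})

test_that("classifyOverlap is monotone under exon addition", {
  set.seed(42)
  rank_of <- c(none = 0, intronic = 1, exonic = 2)
  for (rep in 1:40) {
    bnd <- sort(sample(seq(10, 2000, by = 10), 8))
    exons <- ir(bnd[c(1, 3, 5)], bnd[c(2, 4, 6)])
    circ <- circDef("c", "+", ir(bnd[7], bnd[8]))
    base <- classifyOverlap(transcriptModel("t", exons), circ)
    new_exon <- ir(bnd[8] + 10, bnd[8] + 50)
    grown <- classifyOverlap(
      transcriptModel("t", c(exons, new_exon)), circ)
    expect_gte(rank_of[[grown]], rank_of[[base]])
  }
})

test_that("spliceSiteUsage verdicts follow acceptor sharing", {
  ## protected transcript avoids the circ acceptor -> SA_MUTABLE
  circ <- circDef("c", "+", ir(500, 600))
  t_prot <- transcriptModel("prot", ir(c(100, 300), c(200, 700)),
                            cds = ir(100, 700), coding = TRUE,
                            is_canonical = TRUE)
  t_minor <- transcriptModel("minor", ir(c(100, 500, 800),
                                         c(200, 600, 900)))
  locus <- locusModel("g", "c", "+", list(t_prot, t_minor))
  rep <- spliceSiteUsage(locus, circ)
  expect_identical(rep$verdict, "SA_MUTABLE")
  expect_identical(rep$table$uses_SA, c(FALSE, TRUE))

  ## canonical transcript shares both sites -> SA_SHARED
  t_shared <- transcriptModel("prot", ir(c(100, 500, 800),
                                         c(200, 600, 900)),
                              cds = ir(100, 900), coding = TRUE,
                              is_canonical = TRUE)
  locus2 <- locusModel("g", "c", "+", list(t_shared, t_minor))
  expect_identical(spliceSiteUsage(locus2, circ)$verdict, "SA_SHARED")

  ## SA shared but SD free -> SD_MUTABLE
  t_sa_only <- transcriptModel("prot", ir(c(100, 500), c(200, 900)),
                               cds = ir(100, 900), coding = TRUE,
                               is_canonical = TRUE)
  locus3 <- locusModel("g", "c", "+", list(t_sa_only, t_minor))
  expect_identical(spliceSiteUsage(locus3, circ)$verdict, "SD_MUTABLE")
})

test_that("spliceSiteUsage agrees with brute-force acceptor enumeration", {
  set.seed(7)
  for (rep in 1:100) {
    n_ex <- sample(3:6, 1)
    bnd <- sort(sample(seq(10, 3000, by = 10), 2 * n_ex))
    exons <- ir(bnd[seq(1, 2 * n_ex, 2)], bnd[seq(2, 2 * n_ex, 2)])
    strand <- sample(c("+", "-"), 1)
    txs <- lapply(1:3, function(k) {
      idx <- sort(sample(seq_len(n_ex), sample(2:n_ex, 1)))
      transcriptModel(paste0("t", k), exons[idx],
                      is_canonical = (k == 1))
    })
    locus <- locusModel("g", "c", strand, txs)
    ci <- sample(2:(n_ex - 1), 1)
    circ <- circDef("c", strand, exons[ci])
    rep_out <- spliceSiteUsage(locus, circ,
                               protected = character(0))$table
    expect_identical(rep_out$uses_SA, unname(oracleUsesSA(locus, circ)))
  }
})

test_that("applyMutations edits in the original frame and validates refs", {
  s <- "AACCGGTTAACC"
  out <- applyMutations(s, data.frame(position = c(3L, 9L),
                                      ref = c("CC", "A"),
                                      alt = c("TT", "G")))
  expect_identical(out, "AATTGGTTGACC")
  expect_identical(hamming(s, out), 3L)
  expect_identical(applyMutations(s, NULL), s)
  expect_error(applyMutations(s, data.frame(position = 1L, ref = "G",
                                            alt = "T")),
               "ref mismatch at position 1")
  expect_error(applyMutations(s, data.frame(position = c(1L, 2L),
                                            ref = c("AA", "AC"),
                                            alt = c("TT", "GG"))),
               "overlapping")
})

test_that("cryptic acceptor scan finds the next downstream AG", {
  mk <- function(exon_seq) {
    genome <- paste0(strrep("C", 50), exon_seq, strrep("C", 50))
    circ <- circDef("c", "+", ir(51L, 50L + nchar(exon_seq)))
    crypticAcceptorScan(genome, circ, window = 50L)
  }
  r <- mk("AGGCTAAATTTCCC")
  expect_true(r$found)
  expect_identical(r$lost_prefix_len, 2L)
  r <- mk("CCAGTTTTTAAACC")
  expect_identical(r$lost_prefix_len, 4L)
  r <- mk(paste0(strrep("CT", 25), "AAAA"))  # no AG in the window
  expect_false(r$found)
  ## linear-scan oracle on random exons
  set.seed(31)
  for (rep in 1:30) {
    exon <- randSeq(60)
    r <- mk(exon)
    pos <- regexpr("AG", substr(exon, 1, 50), fixed = TRUE)
    if (pos == -1 || pos + 1 >= nchar(exon)) {
      expect_false(r$found)
    } else {
      expect_identical(r$lost_prefix_len, as.integer(pos) + 1L)
    }
  }
})

test_that("cryptic acceptor scan is strand-aware", {
  exon <- "CCAGTTTTTAAACC"
  genome <- paste0(strrep("C", 50), exon, strrep("C", 50))
  L <- nchar(genome)
  mgenome <- rcOf(genome)
  circ <- circDef("c", "-", ir(L - (50L + nchar(exon)) + 1L, L - 51L + 1L))
  r <- crypticAcceptorScan(mgenome, circ, window = 50L)
  expect_true(r$found)
  expect_identical(r$lost_prefix_len, 4L)
})

test_that("restriction fragments partition the amplicon", {
  expect_identical(rflpDigest("AACTGAGTTT", "CTNAG", 1L), c(3L, 7L))
  expect_identical(rflpDigest("AAAATTTT", "CTNAG", 1L), 8L)
  set.seed(13)
  for (rep in 1:50) {
    amp <- randSeq(sample(50:400, 1))
    motif <- sample(c("CTNAG", "GAATTC", "CCWGG", "RGATCY"), 1)
    off <- sample(seq_len(nchar(motif) - 1L), 1)
    fr <- rflpDigest(amp, motif, off)
    expect_identical(sum(fr), nchar(amp))
    expect_true(all(fr > 0))
  }
})

test_that("an acceptor-disrupting edit creates a discriminating Dde I RFLP", {
  ## synthetic 646-bp amplicon: canonical acceptor AG at 447..448 with a
  ## C just 5' and AG just 3', so the AG->TC edit creates CTCAG (= CTNAG)
  ## cut 446 nt in; the wild-type amplicon is scrubbed of Dde I sites.
  set.seed(97)
  amp <- strsplit(randSeq(646), "")[[1]]
  amp[446:450] <- c("C", "A", "G", "A", "G")
  wt <- paste(amp, collapse = "")
  repeat {
    m <- regexpr("CT[ACGT]AG", wt)
    if (m == -1) break
    substr(wt, m + 1, m + 1) <- "G"
  }
  expect_identical(substr(wt, 446, 450), "CAGAG")
  cd <- applyMutations(wt, data.frame(position = 447L, ref = "AG",
                                      alt = "TC"))
  res <- rflpCompare(wt, cd)
  expect_identical(res$fragments_a, 646L)
  expect_identical(res$fragments_b, c(446L, 200L))
  expect_identical(res$het_fragments, c(646L, 446L, 200L))
  expect_true(res$discriminates)
})

test_that("the full locus module mirrors onto the minus strand", {
  b <- makeMimicLocus()
  m <- mirrorBundle(b)
  u_plus <- spliceSiteUsage(bundleLocus(b), bundleCirc(b))
  u_minus <- spliceSiteUsage(bundleLocus(m), bundleCirc(m))
  expect_identical(u_minus$verdict, u_plus$verdict)
  expect_identical(u_minus$table, u_plus$table)
  expect_identical(circleSeq(buildCircle(bundleGenome(m), bundleCirc(m))),
                   circleSeq(buildCircle(bundleGenome(b), bundleCirc(b))))
})
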