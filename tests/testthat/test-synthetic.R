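test_that("bundle generation is deterministic and byte-stable on disk", {
  spec <- syntheticLocusSpec(seed = 1L, n_exons = 4L,
                             exon_lengths = c(60L, 80L, 70L, 50L),
                             intron_lengths = c(120L, 150L, 100L),
                             circ_exon_range = c(2L, 3L))
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  writeLocusBundle(makeLocus(spec), d1)
  writeLocusBundle(makeLocus(spec), d2)
  for (f in c("locus.fa", "locus.gff3", "circ.bed", "ct.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("planted RCM segments match revcomp at the requested identity", {
  mk <- function(len, id) {
    spec <- syntheticLocusSpec(
      seed = 7L, n_exons = 3L, exon_lengths = c(50L, 80L, 50L),
      intron_lengths = c(400L, 400L), circ_exon_range = c(2L, 2L),
      planted_rcms = data.frame(length = len, identity = id,
                                up_offset = 10L, down_offset = 10L))
    makeLocus(spec)
  }
  b <- mk(100L, 1.0)
  tr <- bundleRcmTruth(b)
  g <- bundleGenome(b)
  up <- substr(g, tr$up_start, tr$up_end)
  dn <- substr(g, tr$down_start, tr$down_end)
  expect_identical(up, rcOf(dn))

  b <- mk(200L, 0.9)
  tr <- bundleRcmTruth(b)
  g <- bundleGenome(b)
  up <- substr(g, tr$up_start, tr$up_end)
  dn <- substr(g, tr$down_start, tr$down_end)
  expect_identical(hamming(up, rcOf(dn)), 20L)
  expect_identical(tr$n_mismatches, 20L)
})

test_that("introns carry canonical GT..AG boundaries and the planted cryptic AG", {
  b <- smallBundle(11L)
  g <- bundleGenome(b)
  introns <- b@extras$introns
  for (i in seq_along(introns)) {
    expect_identical(substr(g, IRanges::start(introns)[i],
                            IRanges::start(introns)[i] + 1L), "GT")
    expect_identical(substr(g, IRanges::end(introns)[i] - 1L,
                            IRanges::end(introns)[i]), "AG")
  }
  acc <- circAcceptor(bundleCirc(b))
  exon_prefix <- substr(g, acc, acc + 9L)
  ## first exonic AG ends exactly at the planted offset (4)
  expect_identical(as.integer(regexpr("AG", exon_prefix)), 3L)
})

test_that("generated sequence GC content tracks the requested fraction", {
  for (gc in c(0.35, 0.5, 0.6)) {
    spec <- syntheticLocusSpec(seed = 3L, n_exons = 3L,
                               exon_lengths = c(100L, 100L, 100L),
                               intron_lengths = c(6000L, 6000L),
                               gc_content = gc,
                               circ_exon_range = c(2L, 2L))
    b <- makeLocus(spec)
    expect_lt(abs(gcContent(bundleGenome(b)) - gc), 0.05)
  }
})

test_that("GFF3 round-trip reproduces the locus model exactly", {
  b <- makeMimicLocus()
  dir <- file.path(tempdir(), "roundtrip")
  p <- writeLocusBundle(b, dir)
  locus2 <- parseAnnotation(p$gff3, p$fasta)
  attr(locus2, "sequence") <- NULL
  expect_equal(locus2, bundleLocus(b))
  circ2 <- readCircBed(p$circ_bed)
  expect_equal(circ2, bundleCirc(b))
})

test_that("spec validation rejects inconsistent recipes", {
  base <- list(seed = 1L, n_exons = 3L, exon_lengths = c(50L, 80L, 50L),
               intron_lengths = c(400L, 400L), circ_exon_range = c(2L, 2L))
  expect_error(do.call(syntheticLocusSpec, c(base, list(
    planted_rcms = data.frame(length = c(100L, 100L),
                              identity = c(1, 1),
                              up_offset = c(10L, 50L),
                              down_offset = c(10L, 250L))))),
    "overlap")
  expect_error(do.call(syntheticLocusSpec, c(base, list(
    cryptic_ag_offset = 999L))), "cryptic")
  expect_error(do.call(syntheticLocusSpec, c(base, list(
    planted_rcms = data.frame(length = 500L, identity = 1,
                              up_offset = 10L, down_offset = 10L)))),
    "fit inside")
})

test_that("synthetic Ct tables obey the Ct = baseline - log2(expr) model", {
  expr <- c(circ = 2, linear = 0, HK1 = 0, HK2 = 0)
  ct <- makeCtTable(expr, noise_sd = 0, n_replicates = 2L, baseline = 30)
  expect_true(all(ct$ct[ct$target == "circ"] == 28))
  expect_true(all(ct$ct[ct$target == "HK1"] == 30))
  ## equal target and housekeeper expression -> normalized value 1
  v <- relativeExpression(ct, "linear")
  expect_true(all(v$rel_expr == 1))
  ## 4x housekeeper expression -> dCt = -2
  v <- relativeExpression(makeCtTable(c(t = 2, HK1 = 0, HK2 = 0),
                                      noise_sd = 0), "t")
  expect_true(all(v$delta_ct == -2))
  ## determinism under noise
  t1 <- makeCtTable(expr, noise_sd = 0.2, seed = 5L)
  t2 <- makeCtTable(expr, noise_sd = 0.2, seed = 5L)
  expect_identical(t1, t2)
  expect_error(makeCtTable(expr, noise_sd = -1), "noise_sd")
  expect_error(makeCtTable(c(a = 1), noise_sd = 0), "housekeepers")
})
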