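## Deterministic synthetic locus generator. Emits a multi-transcript gene
## with a backsplice-competent exon block, flanking introns carrying
## planted reverse-complementary repeats, canonical GT..AG intron
## boundaries, a cryptic AG planted downstream of the canonical acceptor,
## and (optionally) SINE-like repeat intervals over the plants. Everything
## downstream of the generator is testable against the planted truth.

#' SyntheticLocusSpec: recipe for a synthetic locus
#'
#' @slot seed integer RNG seed; the whole bundle derives from one stream.
#' @slot n_exons number of exons (>= 3).
#' @slot exon_lengths integer vector, one per exon (nt).
#' @slot intron_lengths integer vector, `n_exons - 1` entries (nt).
#' @slot gc_content target GC fraction of generated sequence.
#' @slot circ_exon_range pair of exon indices forming the circularized
#'   block; must leave at least one flanking intron on each side.
#' @slot planted_rcms data.frame with columns `length`, `identity`,
#'   `up_offset`, `down_offset`; offsets are the number of intron bases
#'   preceding the planted segment in the upstream / downstream flanking
#'   intron.
#' @slot plant_sine_bed emit SINE-like repeat intervals over the plants?
#' @slot cryptic_ag_offset the planted cryptic AG ends this many nt into
#'   the first circularized exon (>= 2).
#' @slot transcript_recipes list of recipes: each a list with `id`,
#'   `exons` (list of integer vectors; a vector of consecutive indices is
#'   fused into a single exon), `coding`, `canonical`. Exactly one recipe
#'   must be canonical.
#' @slot flank lengths of the 5' and 3' intergenic flanks.
#' @export
setClass("SyntheticLocusSpec",
  representation(seed = "integer", n_exons = "integer",
                 exon_lengths = "integer", intron_lengths = "integer",
                 gc_content = "numeric", circ_exon_range = "integer",
                 planted_rcms = "data.frame", plant_sine_bed = "logical",
                 cryptic_ag_offset = "integer",
                 transcript_recipes = "list", flank = "integer"))

setValidity("SyntheticLocusSpec", function(object) {
  n <- object@n_exons
  if (n < 3L) return("n_exons must be >= 3")
  if (length(object@exon_lengths) != n) return("exon_lengths length != n_exons")
  if (length(object@intron_lengths) != n - 1L)
    return("intron_lengths must have n_exons - 1 entries")
  if (any(object@exon_lengths < 10L)) return("exons must be >= 10 nt")
  if (any(object@intron_lengths < 20L)) return("introns must be >= 20 nt")
  if (object@gc_content < 0 || object@gc_content > 1)
    return("gc_content must lie in [0,1]")
  cr <- object@circ_exon_range
  if (length(cr) != 2L || cr[1L] > cr[2L])
    return("circ_exon_range must be an ordered pair")
  if (cr[1L] < 2L || cr[2L] > n - 1L)
    return("circularized block must have a flanking intron on each side")
  co <- object@cryptic_ag_offset
  if (co < 2L || co > object@exon_lengths[cr[1L]])
    return("cryptic_ag_offset must land inside the first circ exon")
  pr <- object@planted_rcms
  if (nrow(pr)) {
    need <- c("length", "identity", "up_offset", "down_offset")
    if (!all(need %in% names(pr))) return("planted_rcms missing columns")
    up_len <- object@intron_lengths[cr[1L] - 1L]
    dn_len <- object@intron_lengths[cr[2L]]
    if (any(pr$up_offset < 2L) || any(pr$down_offset < 2L))
      return("planted RCM offsets must leave the GT intron start intact")
    if (any(pr$up_offset + pr$length > up_len - 2L))
      return("planted RCM does not fit inside the upstream intron")
    if (any(pr$down_offset + pr$length > dn_len - 2L))
      return("planted RCM does not fit inside the downstream intron")
    if (any(pr$identity <= 0 | pr$identity > 1))
      return("planted identity must lie in (0,1]")
    ov <- function(s, e) {
      if (length(s) < 2L) return(FALSE)
      o <- order(s); s <- s[o]; e <- e[o]
      any(s[-1L] <= e[-length(e)])
    }
    if (ov(pr$up_offset, pr$up_offset + pr$length - 1L) ||
        ov(pr$down_offset, pr$down_offset + pr$length - 1L))
      return("planted RCMs overlap within an intron")
  }
  rec <- object@transcript_recipes
  if (!length(rec)) return("at least one transcript recipe required")
  if (sum(vapply(rec, function(r) isTRUE(r$canonical), NA)) != 1L)
    return("exactly one transcript recipe must be canonical")
  for (r in rec) {
    idx <- unlist(r$exons)
    if (any(idx < 1L | idx > n)) return("recipe exon index out of range")
  }
  TRUE
})

#' Construct a SyntheticLocusSpec
#'
#' @param seed integer seed.
#' @param n_exons number of exons.
#' @param exon_lengths,intron_lengths segment lengths (nt).
#' @param gc_content target GC fraction (default 0.45).
#' @param circ_exon_range pair of exon indices circularized.
#' @param planted_rcms data.frame (`length`, `identity`, `up_offset`,
#'   `down_offset`); default none.
#' @param plant_sine_bed also emit SINE-like repeat intervals?
#' @param cryptic_ag_offset planted cryptic AG ends this many nt into the
#'   first circ exon (default 4).
#' @param transcript_recipes see [SyntheticLocusSpec-class]; default: a
#'   canonical coding transcript over all exons plus one non-coding minor
#'   transcript using the circ block as internal exons.
#' @param flank intergenic flank lengths (default 300/300).
#' @return a [SyntheticLocusSpec-class] object.
#' @export
syntheticLocusSpec <- function(seed, n_exons, exon_lengths, intron_lengths,
                               gc_content = 0.45, circ_exon_range,
                               planted_rcms = NULL, plant_sine_bed = FALSE,
                               cryptic_ag_offset = 4L,
                               transcript_recipes = NULL,
                               flank = c(300L, 300L)) {
  if (is.null(planted_rcms))
    planted_rcms <- data.frame(length = integer(0), identity = numeric(0),
                               up_offset = integer(0),
                               down_offset = integer(0))
  if (is.null(transcript_recipes)) {
    lo <- circ_exon_range[1L]; hi <- circ_exon_range[2L]
    minor <- seq.int(max(1L, lo - 1L), min(n_exons, hi + 1L))
    transcript_recipes <- list(
      list(id = "T1", exons = as.list(seq_len(n_exons)), coding = TRUE,
           canonical = TRUE),
      list(id = "T2", exons = as.list(minor), coding = FALSE,
           canonical = FALSE))
  }
  new("SyntheticLocusSpec", seed = as.integer(seed),
      n_exons = as.integer(n_exons),
      exon_lengths = as.integer(exon_lengths),
      intron_lengths = as.integer(intron_lengths),
      gc_content = as.numeric(gc_content),
      circ_exon_range = as.integer(circ_exon_range),
      planted_rcms = planted_rcms,
      plant_sine_bed = isTRUE(plant_sine_bed),
      cryptic_ag_offset = as.integer(cryptic_ag_offset),
      transcript_recipes = transcript_recipes,
      flank = as.integer(flank))
}

#' SyntheticLocusBundle: a generated locus plus its ground truth
#'
#' @slot genome the locus sequence (single record, character).
#' @slot locus the [LocusModel-class].
#' @slot circ the [CircDef-class] of the backsplice event.
#' @slot rcm_truth data.frame of planted RCM coordinates (intron-local and
#'   genomic) with the exact mismatch counts achieved.
#' @slot repeats data.frame of SINE-like repeat intervals (genomic).
#' @slot ct_table data.frame of synthetic qPCR Ct rows.
#' @slot spec the generating [SyntheticLocusSpec-class].
#' @slot extras list of derived conveniences (mature mRNA sequences,
#'   intron coordinates, planted ORF/protein strings for mimic loci).
#' @export
setClass("SyntheticLocusBundle",
  representation(genome = "character", locus = "LocusModel",
                 circ = "CircDef", rcm_truth = "data.frame",
                 repeats = "data.frame", ct_table = "data.frame",
                 spec = "SyntheticLocusSpec", extras = "list"))

setMethod("show", "SyntheticLocusBundle", function(object) {
  cat(sprintf("SyntheticLocusBundle: %d nt genome, %d transcripts, %d planted RCM(s)\n",
              nchar(object@genome), length(object@locus@transcripts),
              nrow(object@rcm_truth)))
})

#' @describeIn makeLocus genome sequence of a bundle (character).
#' @param x a SyntheticLocusBundle.
#' @export
bundleGenome <- function(x) x@genome

#' @describeIn makeLocus LocusModel of a bundle.
#' @export
bundleLocus <- function(x) x@locus

#' @describeIn makeLocus CircDef of a bundle.
#' @export
bundleCirc <- function(x) x@circ

#' @describeIn makeLocus planted RCM ground truth of a bundle.
#' @export
bundleRcmTruth <- function(x) x@rcm_truth

## Coordinates of exon i / intron i within the genome, given a spec.
segmentLayout <- function(spec) {
  n <- spec@n_exons
  starts_ex <- integer(n); ends_ex <- integer(n)
  starts_in <- integer(n - 1L); ends_in <- integer(n - 1L)
  pos <- spec@flank[1L] + 1L
  for (i in seq_len(n)) {
    starts_ex[i] <- pos; ends_ex[i] <- pos + spec@exon_lengths[i] - 1L
    pos <- ends_ex[i] + 1L
    if (i < n) {
      starts_in[i] <- pos; ends_in[i] <- pos + spec@intron_lengths[i] - 1L
      pos <- ends_in[i] + 1L
    }
  }
  list(exons = IRanges::IRanges(starts_ex, ends_ex),
       introns = IRanges::IRanges(starts_in, ends_in),
       total = pos - 1L + spec@flank[2L])
}

## Evenly spaced 1-based mismatch positions: exact count, reproducible.
evenPositions <- function(k, len) {
  if (k == 0L) return(integer(0))
  pos <- unique(as.integer(floor(((seq_len(k)) - 0.5) * len / k)) + 1L)
  if (length(pos) < k) pos <- seq_len(k)  # degenerate: very low identity
  pos[pos >= 1L & pos <= len][seq_len(min(k, len))]
}

## Substitute to a different base, deterministically (A->C->G->T->A).
substituteBase <- function(b) {
  DNA_BASES[(match(b, DNA_BASES) %% 4L) + 1L]
}

#' Generate a synthetic locus bundle
#'
#' Deterministic for a fixed `spec@seed`. Introns begin `GT` and end `AG`;
#' the acceptor of the first circularized exon is therefore immediately
#' preceded by an intronic `AG`. A cryptic `AG` is planted
#' `cryptic_ag_offset` nt into the first circ exon (with any earlier exonic
#' `AG` scrubbed so the planted one is the first downstream candidate).
#' For each planted RCM the upstream-intron segment equals the reverse
#' complement of the downstream-intron segment up to exactly
#' `round((1 - identity) * length)` evenly spaced substitutions.
#'
#' @param spec a [SyntheticLocusSpec-class].
#' @return a [SyntheticLocusBundle-class].
#' @export
makeLocus <- function(spec) {
  validObject(spec)
  lay <- segmentLayout(spec)
  lo <- spec@circ_exon_range[1L]; hi <- spec@circ_exon_range[2L]

  genome <- withSeed(spec@seed, {
    g <- strToChars(randomDna(lay$total, spec@gc_content))

    ## canonical intron boundaries
    for (i in seq_len(spec@n_exons - 1L)) {
      s <- IRanges::start(lay$introns)[i]; e <- IRanges::end(lay$introns)[i]
      g[s] <- "G"; g[s + 1L] <- "T"; g[e - 1L] <- "A"; g[e] <- "G"
    }

    ## planted RCMs in the two flanking introns
    pr <- spec@planted_rcms
    if (nrow(pr)) {
      up_in <- lay$introns[lo - 1L]; dn_in <- lay$introns[hi]
      for (r in seq_len(nrow(pr))) {
        len <- pr$length[r]
        seg <- strToChars(randomDna(len, spec@gc_content))
        up_s <- IRanges::start(up_in) + pr$up_offset[r]
        g[up_s:(up_s + len - 1L)] <- seg
        rcseg <- strToChars(revComp(charsToStr(seg)))
        k <- as.integer(round((1 - pr$identity[r]) * len))
        for (p in evenPositions(k, len)) rcseg[p] <- substituteBase(rcseg[p])
        dn_s <- IRanges::start(dn_in) + pr$down_offset[r]
        g[dn_s:(dn_s + len - 1L)] <- rcseg
      }
    }

    ## cryptic AG inside the first circ exon; scrub earlier exonic AGs
    ex1 <- lay$exons[lo]
    co <- spec@cryptic_ag_offset
    e_s <- IRanges::start(ex1)
    g[e_s + co - 2L] <- "A"; g[e_s + co - 1L] <- "G"
    if (co > 3L) {
      for (j in seq_len(co - 3L)) {           # exon positions 1..co-2
        if (g[e_s + j - 1L] == "A" && g[e_s + j] == "G")
          g[e_s + j] <- "C"
      }
    }
    g
  })

  ## transcripts from recipes
  txs <- lapply(spec@transcript_recipes, function(r) {
    iv <- lapply(r$exons, function(idx) {
      idx <- sort(as.integer(idx))
      if (length(idx) > 1L && any(diff(idx) != 1L))
        stop("fused exon groups must be consecutive indices")
      IRanges::IRanges(IRanges::start(lay$exons)[idx[1L]],
                       IRanges::end(lay$exons)[idx[length(idx)]])
    })
    ex <- do.call(c, iv)
    transcriptModel(r$id, ex,
                    cds = if (isTRUE(r$coding)) ex else IRanges::IRanges(),
                    coding = isTRUE(r$coding),
                    is_canonical = isTRUE(r$canonical))
  })
  locus <- locusModel("synthGene", "synthLocus", "+", txs)
  circ <- circDef("synthLocus", "+", lay$exons[lo:hi])

  ## planted RCM truth (genomic + intron-local coordinates)
  pr <- spec@planted_rcms
  if (nrow(pr)) {
    up_in <- lay$introns[lo - 1L]; dn_in <- lay$introns[hi]
    k <- as.integer(round((1 - pr$identity) * pr$length))
    rcm_truth <- data.frame(
      up_local_start = pr$up_offset + 1L,
      up_local_end = pr$up_offset + pr$length,
      down_local_start = pr$down_offset + 1L,
      down_local_end = pr$down_offset + pr$length,
      up_start = IRanges::start(up_in) + pr$up_offset,
      up_end = IRanges::start(up_in) + pr$up_offset + pr$length - 1L,
      down_start = IRanges::start(dn_in) + pr$down_offset,
      down_end = IRanges::start(dn_in) + pr$down_offset + pr$length - 1L,
      length = pr$length, planted_identity = pr$identity,
      n_mismatches = k, achieved_identity = 1 - k / pr$length)
  } else {
    rcm_truth <- data.frame()
  }

  ## SINE-like repeat intervals over the plants
  repeats <- data.frame(name = character(0), start = integer(0),
                        end = integer(0))
  if (spec@plant_sine_bed && nrow(rcm_truth)) {
    up_in <- lay$introns[lo - 1L]; dn_in <- lay$introns[hi]
    pad <- 15L
    repeats <- rbind(
      data.frame(name = sprintf("SINE_B1_up_%d", seq_len(nrow(rcm_truth))),
                 start = pmax(IRanges::start(up_in) + 2L,
                              rcm_truth$up_start - pad),
                 end = pmin(IRanges::end(up_in) - 2L,
                            rcm_truth$up_end + pad)),
      data.frame(name = sprintf("SINE_B1_dn_%d", seq_len(nrow(rcm_truth))),
                 start = pmax(IRanges::start(dn_in) + 2L,
                              rcm_truth$down_start - pad),
                 end = pmin(IRanges::end(dn_in) - 2L,
                            rcm_truth$down_end + pad)))
  }

  genome_str <- charsToStr(genome)
  mrnas <- vapply(txs, function(t)
    spliceSequence(genome_str, t@exons, "+"), "")
  names(mrnas) <- vapply(txs, function(t) t@transcript_id, "")

  ct <- makeCtTable(c(circ = 2, linear = 1, HK1 = 5, HK2 = 5),
                    noise_sd = 0.2, seed = spec@seed + 7919L)

  new("SyntheticLocusBundle", genome = genome_str, locus = locus,
      circ = circ, rcm_truth = rcm_truth, repeats = repeats, ct_table = ct,
      spec = spec,
      extras = list(exons = lay$exons, introns = lay$introns,
                    up_intron = lay$introns[lo - 1L],
                    down_intron = lay$introns[hi],
                    mrnas = mrnas))
}

## Mature (spliced) transcript sequence, strand-aware.
spliceSequence <- function(genome, exons, strand) {
  parts <- vapply(seq_along(exons), function(i)
    substr(genome, IRanges::start(exons)[i], IRanges::end(exons)[i]), "")
  s <- paste(parts, collapse = "")
  if (strand == "-") revComp(s) else s
}

#' Synthetic qPCR Ct table
#'
#' Emulates SYBR qPCR readout: `Ct = baseline - log2(expression) + noise`,
#' so a target at the housekeeper expression level has the housekeeper Ct
#' and each doubling of expression lowers Ct by one cycle.
#'
#' @param true_log2_expr named numeric: log2 expression per target; must
#'   include housekeepers `HK1` and `HK2`.
#' @param noise_sd Gaussian Ct noise (cycles, >= 0).
#' @param n_replicates samples per condition (default 3).
#' @param baseline Ct of a target with log2 expression 0 (default 30).
#' @param condition condition label for the rows (default "cond1").
#' @param seed RNG seed.
#' @return data.frame with columns `sample`, `condition`, `target`, `ct`.
#' @export
makeCtTable <- function(true_log2_expr, noise_sd = 0, n_replicates = 3L,
                        baseline = 30, condition = "cond1", seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(c("HK1", "HK2") %in% names(true_log2_expr)))
    stop("true_log2_expr must include housekeepers 'HK1' and 'HK2'")
  targets <- names(true_log2_expr)
  withSeed(seed, {
    rows <- expand.grid(sample = sprintf("%s_S%d", condition,
                                         seq_len(n_replicates)),
                        target = targets, stringsAsFactors = FALSE)
    rows$condition <- condition
    rows$ct <- baseline - true_log2_expr[rows$target] +
      rnorm(nrow(rows), 0, noise_sd)
    rownames(rows) <- NULL
    rows[, c("sample", "condition", "target", "ct")]
  })
}

## ---- mimic locus: a Tulp4-like fixture with every feature planted ------

## Deterministic codon choice per residue; serine deliberately avoids the
## AG-containing codons so planted exonic AGs stay under generator control.
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

encodePeptide <- function(aa) {
  paste(CODON_OF[strToChars(aa)], collapse = "")
}

## The 95-aa circle-specific peptide: residues 1-84 shared with the linear
## protein N terminus, residues 85-95 circle-specific. Residues 77-95 are
## arranged so that tryptic digestion (<=1 missed cleavage) yields
## NLRGHNSESCK, GHNSESCK and SPSRTFQS among the discriminative peptides.
mimicPeptides <- function() {
  prefix84 <- paste0("M", "ASTLEDVIEG", "K", "VTN",
                     strrep("LSTEDVAGIP", 6), "K", "NLRGHNSE")
  stopifnot(nchar(prefix84) == 84L)
  circ_pep <- paste0(prefix84, "SCKSPSRTFQS")          # 95 aa
  linear_prot <- paste0(prefix84, strrep("GADVTESLPI", 6))  # 144 aa
  list(circ = circ_pep, linear = linear_prot, shared = 84L)
}

#' Build the bundled multi-transcript mimic locus
#'
#' A fully planted fixture exhibiting every feature the pipeline analyzes:
#' six transcripts around a two-exon circularized block (overlap classes
#' exonic x4 / intronic x2; the two coding transcripts avoid the circ
#' acceptor while two non-coding minor transcripts use it, so the acceptor
#' is mutable without touching the protected transcripts), seven planted
#' RCMs of graded length in the flanking introns, a planted cryptic AG
#' four nt into the first circ exon, and a junction-spanning 95-aa ORF
#' whose first 84 residues match the linear protein's N terminus and whose
#' discriminative tryptic peptides include NLRGHNSESCK, GHNSESCK and
#' SPSRTFQS.
#'
#' @param seed integer seed (default 101).
#' @return a [SyntheticLocusBundle-class] with `extras$circ_peptide`,
#'   `extras$linear_protein` and `extras$orf_start_circle` filled in.
#' @export
makeMimicLocus <- function(seed = 101L) {
  plants <- data.frame(
    length = c(220L, 190L, 160L, 130L, 100L, 80L, 60L),
    identity = c(0.95, 0.95, 0.92, 0.95, 0.90, 0.95, 0.95),
    up_offset = c(50L, 350L, 650L, 950L, 1250L, 1550L, 1850L),
    down_offset = c(60L, 360L, 660L, 960L, 1260L, 1560L, 1840L))
  recipes <- list(
    list(id = "T1", exons = list(1L, 2L, c(3L, 4L), 5L, 6L, 7L, 8L),
         coding = TRUE, canonical = TRUE),
    list(id = "T2", exons = list(1L, 2L, 3L, 5L, 6L, 7L, 8L),
         coding = TRUE, canonical = FALSE),
    list(id = "T3", exons = list(3L, 4L, 5L), coding = FALSE,
         canonical = FALSE),
    list(id = "T4", exons = list(2L, 4L, 6L), coding = FALSE,
         canonical = FALSE),
    list(id = "T5", exons = list(3L, 6L), coding = FALSE,
         canonical = FALSE),
    list(id = "T6", exons = list(2L, 7L), coding = FALSE,
         canonical = FALSE))
  spec <- syntheticLocusSpec(
    seed = seed, n_exons = 8L,
    exon_lengths = c(150L, 120L, 180L, 400L, 120L, 140L, 110L, 160L),
    intron_lengths = c(350L, 300L, 2000L, 450L, 2000L, 320L, 280L),
    gc_content = 0.45, circ_exon_range = c(4L, 5L),
    planted_rcms = plants, plant_sine_bed = TRUE,
    cryptic_ag_offset = 4L, transcript_recipes = recipes)
  bundle <- makeLocus(spec)

  ## plant the junction-spanning ORF into the circle (exons 4 and 5)
  pep <- mimicPeptides()
  coding <- paste0(encodePeptide(pep$circ), "TAA")     # 288 nt with stop
  ## residue 13 re-encoded as GTA so that, together with residues 14-15
  ## (ACT, AAT), the two off-frames carry stop codons right after the
  ## junction; a TAA/TGA/TAA block just 5' of the start codon closes all
  ## three frames before the junction. The planted 95-aa ORF is then the
  ## unique long junction-spanning ORF of the circle.
  substr(coding, 37L, 39L) <- "GTA"
  stopifnot(identical(substr(coding, 34L, 45L), "AAAGTAACTAAT"))
  ex <- bundle@extras$exons
  e4s <- IRanges::start(ex)[4L]; e5s <- IRanges::start(ex)[5L]
  L4 <- IRanges::width(ex)[4L]; L5 <- IRanges::width(ex)[5L]
  Lc <- L4 + L5
  orf_start <- Lc - 32L                                 # circle coordinate
  g <- strToChars(bundle@genome)
  putCircle <- function(cp, base) {
    cp <- circIndex(cp, Lc)
    gp <- if (cp <= L4) e4s + cp - 1L else e5s + (cp - L4) - 1L
    g[gp] <<- base
  }
  stop_block <- strToChars("TAACTGACTAA")               # stops, 3 frames
  for (i in seq_along(stop_block))
    putCircle(orf_start - 12L + i - 1L, stop_block[i])
  for (i in seq_len(nchar(coding)))
    putCircle(orf_start + i - 1L, substr(coding, i, i))
  bundle@genome <- charsToStr(g)

  ## regenerate sequence-derived extras after the overwrite
  bundle@extras$mrnas <- vapply(bundle@locus@transcripts, function(t)
    spliceSequence(bundle@genome, t@exons, "+"), "")
  bundle@extras$circ_peptide <- pep$circ
  bundle@extras$linear_protein <- pep$linear
  bundle@extras$shared_prefix <- pep$shared
  bundle@extras$orf_start_circle <- orf_start
  bundle
}

#' Mirror a bundle onto the minus strand
#'
#' Reverse-complements the genome and flips every annotation coordinate,
#' producing the equivalent locus annotated on the minus strand. Used in
#' strand-handling tests: module results on the mirror must be the
#' mirrored results.
#'
#' @param bundle a [SyntheticLocusBundle-class] on the plus strand.
#' @return the mirrored bundle (strand "-").
#' @export
mirrorBundle <- function(bundle) {
  L <- nchar(bundle@genome)
  flip <- function(ir)
    sortRanges(IRanges::IRanges(L - IRanges::end(ir) + 1L,
                                L - IRanges::start(ir) + 1L))
  txs <- lapply(bundle@locus@transcripts, function(t)
    transcriptModel(t@transcript_id, flip(t@exons), flip(t@cds),
                    t@coding, t@is_canonical))
  locus <- locusModel(bundle@locus@gene_id, bundle@locus@seqname, "-", txs)
  circ <- circDef(bundle@circ@seqname, "-", flip(bundle@circ@exon_chain))
  out <- bundle
  out@genome <- revComp(bundle@genome)
  out@locus <- locus
  out@circ <- circ
  out@extras$mrnas <- vapply(txs, function(t)
    spliceSequence(out@genome, t@exons, "-"), "")
  out@extras$exons <- flip(bundle@extras$exons)
  out@extras$introns <- flip(bundle@extras$introns)
  out@extras$up_intron <- flip(bundle@extras$up_intron)
  out@extras$down_intron <- flip(bundle@extras$down_intron)
  if (nrow(out@rcm_truth)) {
    rt <- out@rcm_truth
    out@rcm_truth <- data.frame(
      up_start = L - rt$down_end + 1L, up_end = L - rt$down_start + 1L,
      down_start = L - rt$up_end + 1L, down_end = L - rt$up_start + 1L,
      length = rt$length, planted_identity = rt$planted_identity,
      n_mismatches = rt$n_mismatches,
      achieved_identity = rt$achieved_identity)
  }
  if (nrow(out@repeats))
    out@repeats <- data.frame(name = out@repeats$name,
                              start = L - out@repeats$end + 1L,
                              end = L - out@repeats$start + 1L)
  out
}
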