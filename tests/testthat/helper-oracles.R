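## Independent oracles and small fixture builders used across the suite.
## Each oracle re-derives the expected result by brute force or via an
## unrelated library code path; none shares machinery with the package
## implementation it checks.

rcOf <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

randSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Per-diagonal optimal ungapped segment between up and revcomp(down):
## exhaustive over all diagonals via prefix sums (no seeding, no X-drop).
## Returns the best score per diagonal plus whether the optimal segment
## contains a clean match run of at least `word` nt.
oracleDiagonalBest <- function(up, down, match = 2, mismatch = -3,
                               word = 4L) {
  rc <- rcOf(down)
  a <- strsplit(up, "")[[1]]
  b <- strsplit(rc, "")[[1]]
  nA <- length(a); nB <- length(b)
  out <- list()
  for (dv in (1 - nA):(nB - 1)) {
    lo <- max(1L, 1L - dv); hi <- min(nA, nB - dv)
    if (hi < lo) next
    eq <- a[lo:hi] == b[(lo + dv):(hi + dv)]
    sc <- ifelse(eq, match, mismatch)
    cum <- cumsum(sc)
    prev_min <- cummin(c(0, cum))[seq_along(cum)]
    ends_score <- cum - prev_min
    e <- which.max(ends_score)
    best <- ends_score[e]
    s <- which.min(c(0, cum)[seq_len(e)])  # prefix index before start
    seg_eq <- eq[s:e]
    runs <- rle(seg_eq)
    has_word <- any(runs$values & runs$lengths >= word)
    out[[length(out) + 1L]] <- data.frame(
      diag = dv, best_score = best, start = lo + s - 1L, end = lo + e - 1L,
      has_word = has_word)
  }
  do.call(rbind, out)
}

## Circular ORF oracle: translate a linear concatenation of the circle
## with Biostrings, one ORF per ATG start.
oracleOrfs <- function(seqchar, max_laps = 3L) {
  L <- nchar(seqchar)
  lin <- strrep(seqchar, max_laps + 1L)
  wrap <- paste0(seqchar, substr(seqchar, 1, 2))
  starts <- c()
  for (p in 1:L) if (substr(wrap, p, p + 2) == "ATG") starts <- c(starts, p)
  max_codons <- (max_laps * L) %/% 3L
  rows <- lapply(starts, function(p) {
    sub <- substr(lin, p, p + 3L * max_codons - 1L)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(sub), no.init.codon = TRUE))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0) {
      aa_len <- as.integer(stop_at) - 1L
      data.frame(start = p, aa_length = aa_len,
                 spans_junction = (p + 3L * (aa_len + 1L) - 1L) > L,
                 laps = (p + 3L * (aa_len + 1L) - 2L) %/% L,
                 classification = "terminated",
                 peptide = substr(aa, 1, aa_len))
    } else {
      data.frame(start = p, aa_length = max_codons,
                 spans_junction = TRUE, laps = max_laps,
                 classification = "rolling", peptide = aa)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out[order(out$start), , drop = FALSE]
}

## Seed-site oracle: naive scan of the doubled sequence, deduplicated
## modulo the circle length.
oracleSeeds <- function(seqchar, mirna, min_class = "7mer-A1") {
  L <- nchar(seqchar)
  dbl <- paste0(seqchar, seqchar)
  m <- chartr("Uu", "TT", toupper(mirna))
  s6 <- rcOf(substr(m, 2, 7))
  m8c <- rcOf(substr(m, 8, 8))
  lv <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
  rows <- list()
  for (q in 1:L) {
    if (substr(dbl, q + 1, q + 6) != s6) next    # q+1: leave room for m8
    has8 <- substr(dbl, q, q) == m8c
    hasA <- substr(dbl, q + 7, q + 7) == "A"
    cls <- if (has8 && hasA) "8mer" else if (has8) "7mer-m8"
           else if (hasA) "7mer-A1" else "6mer"
    start <- if (has8) q else q + 1L
    width <- if (has8 && hasA) 8L else if (has8 || hasA) 7L else 6L
    start_mod <- ((start - 1L) %% L) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      site_class = cls, circle_position = start_mod,
      spans_junction = start_mod + width - 1L > L)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(site_class = character(0),
                                      circle_position = integer(0)))
  out <- unique(out)
  out <- out[match(out$site_class, lv) >= match(min_class, lv), ,
             drop = FALSE]
  out[order(out$circle_position), , drop = FALSE]
}

## Brute-force splice-acceptor usage: enumerate every (transcript,
## internal exon) pair directly from the interval lists.
oracleUsesSA <- function(locus, circ) {
  strand <- locusStrand(locus)
  vapply(transcripts(locus), function(t) {
    ex <- t@exons
    ord <- if (strand == "+") order(IRanges::start(ex))
           else order(-IRanges::start(ex))
    ex <- ex[ord]
    if (length(ex) < 2) return(FALSE)
    any(vapply(2:length(ex), function(i) {
      acc <- if (strand == "+") IRanges::start(ex)[i]
             else IRanges::end(ex)[i]
      acc == circAcceptor(circ)
    }, NA))
  }, NA)
}

## Small random locus bundle for fuzz tests (no planted RCMs).
smallBundle <- function(seed, n_exons = 4L) {
  exl <- as.integer(sample(40:120, n_exons, replace = TRUE))
  inl <- as.integer(sample(60:150, n_exons - 1L, replace = TRUE))
  lo <- sample(2:(n_exons - 1L), 1L)
  makeLocus(syntheticLocusSpec(
    seed = seed, n_exons = n_exons, exon_lengths = exl,
    intron_lengths = inl, circ_exon_range = c(lo, lo),
    cryptic_ag_offset = 4L))
}
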