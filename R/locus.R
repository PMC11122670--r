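## Splice-site-usage analysis for circRNA-specific knockout design,
## cryptic-acceptor prediction after acceptor mutagenesis, and RFLP
## genotyping-fragment prediction.

#' Classify how a transcript shares sequence with a circRNA
#'
#' "exonic" when any circularized exon intersects a transcript exon;
#' otherwise "intronic" when the circ chain lies within the transcript's
#' genomic span (shared only as intron); otherwise "none".
#'
#' @param transcript a [TranscriptModel-class].
#' @param circ a [CircDef-class].
#' @param strand strand of the transcript's locus; must equal the circ
#'   strand (antisense relationships are out of scope).
#' @return one of "exonic", "intronic", "none".
#' @export
classifyOverlap <- function(transcript, circ, strand = "+") {
  if (strand != circ@strand)
    stop("strand mismatch between transcript and circRNA", call. = FALSE)
  ch <- circ@exon_chain
  if (sum(IRanges::countOverlaps(ch, transcript@exons)) > 0L)
    return("exonic")
  span <- IRanges::IRanges(min(IRanges::start(transcript@exons)),
                           max(IRanges::end(transcript@exons)))
  if (all(IRanges::start(ch) >= IRanges::start(span) &
          IRanges::end(ch) <= IRanges::end(span)))
    return("intronic")
  "none"
}

#' Splice-site usage report for knockout feasibility
#'
#' For each transcript, reports whether the circRNA's backsplice acceptor
#' (SA) or donor (SD) coincides with one of the transcript's own internal
#' splice boundaries (first exons are transcription starts and have no
#' acceptor; last exons have no donor), plus the sequence-sharing class.
#' The verdict is computed against a protected transcript set (default:
#' all coding transcripts):
#' \describe{
#'   \item{SA_MUTABLE}{no protected transcript uses the SA; mutating the
#'     acceptor knocks out the circRNA specifically.}
#'   \item{SD_MUTABLE}{the SA is shared but the SD is free.}
#'   \item{SA_SHARED}{both backsplice sites are shared with protected
#'     transcripts; site mutagenesis cannot be circRNA-specific.}
#'   \item{NEITHER}{degenerate: the locus has no protected transcripts.}
#' }
#'
#' @param locus a [LocusModel-class].
#' @param circ a [CircDef-class].
#' @param protected character vector of protected transcript ids; default
#'   all coding transcripts.
#' @return list with `table` (one row per transcript: `transcript_id`,
#'   `uses_SA`, `uses_SD`, `overlap_class`, `protected`) and `verdict`.
#' @export
spliceSiteUsage <- function(locus, circ, protected = NULL) {
  if (!length(locus@transcripts)) stop("empty locus", call. = FALSE)
  sp <- geneSpan(locus)
  ch <- circ@exon_chain
  if (min(IRanges::start(ch)) < IRanges::start(sp) ||
      max(IRanges::end(ch)) > IRanges::end(sp))
    stop("circRNA lies outside the gene span", call. = FALSE)
  if (is.null(protected))
    protected <- transcriptIds(locus)[vapply(locus@transcripts,
                                             function(t) t@coding, NA)]
  strand <- locus@strand
  rows <- do.call(rbind, lapply(locus@transcripts, function(t) {
    data.frame(
      transcript_id = t@transcript_id,
      uses_SA = circ@acceptor_pos %in% acceptorPositions(t, strand),
      uses_SD = circ@donor_pos %in% donorPositions(t, strand),
      overlap_class = classifyOverlap(t, circ, strand),
      protected = t@transcript_id %in% protected)
  }))
  rownames(rows) <- NULL
  prot <- rows[rows$protected, , drop = FALSE]
  verdict <- if (!nrow(prot)) "NEITHER"
  else if (!any(prot$uses_SA)) "SA_MUTABLE"
  else if (!any(prot$uses_SD)) "SD_MUTABLE"
  else "SA_SHARED"
  list(table = rows, verdict = verdict)
}

#' Apply point edits to a sequence
#'
#' Edits are given in the coordinates of the original sequence and applied
#' right-to-left, so earlier edits never shift later positions. Each
#' edit's `ref` must match the sequence; overlapping edits are rejected.
#'
#' @param sequence DNA string.
#' @param edits data.frame with columns `position` (1-based start), `ref`,
#'   `alt` (equal-length replacement strings).
#' @return the edited sequence (input untouched).
#' @export
applyMutations <- function(sequence, edits) {
  s <- as.character(sequence)
  if (is.null(edits) || nrow(edits) == 0L) return(s)
  edits <- edits[order(edits$position), , drop = FALSE]
  ends <- edits$position + nchar(edits$ref) - 1L
  if (nrow(edits) > 1L && any(edits$position[-1L] <= ends[-nrow(edits)]))
    stop("overlapping edits", call. = FALSE)
  for (i in rev(seq_len(nrow(edits)))) {
    p <- edits$position[i]; ref <- edits$ref[i]; alt <- edits$alt[i]
    if (nchar(ref) != nchar(alt))
      stop("only same-length substitutions are supported", call. = FALSE)
    have <- substr(s, p, p + nchar(ref) - 1L)
    if (have != ref)
      stop(sprintf("ref mismatch at position %d: expected %s, found %s",
                   p, ref, have), call. = FALSE)
    substr(s, p, p + nchar(ref) - 1L) <- alt
  }
  s
}

#' Scan for a cryptic splice acceptor after acceptor mutagenesis
#'
#' After the canonical intronic AG has been destroyed, backsplicing can
#' fall back on the next downstream 5'-AG-3'. The scan walks into the
#' first circularized exon (transcript orientation) and returns the first
#' AG within `window` nt; the shifted circle starts immediately 3' of that
#' AG, losing `lost_prefix_len` nt of the original first exon.
#'
#' @param mutated_sequence the reference sequence after the AG->TC edit.
#' @param circ the original [CircDef-class] (its acceptor must have been
#'   mutated).
#' @param window scan window in nt (default 100).
#' @return list with `found`, `lost_prefix_len`, `cryptic_acceptor_pos`
#'   (genomic position of the shifted first transcribed base) and
#'   `shifted_circ` (a [CircDef-class]); `found = FALSE` (NO_CRYPTIC) when
#'   no AG lies within the window.
#' @export
crypticAcceptorScan <- function(mutated_sequence, circ, window = 100L) {
  ch <- circ@exon_chain
  strand <- circ@strand
  first_exon <- if (strand == "+") ch[1L] else ch[length(ch)]
  w <- min(window, IRanges::width(first_exon))
  ## exon prefix in transcript orientation
  if (strand == "+") {
    seg <- substr(mutated_sequence, IRanges::start(first_exon),
                  IRanges::start(first_exon) + w - 1L)
  } else {
    seg <- revComp(substr(mutated_sequence,
                          IRanges::end(first_exon) - w + 1L,
                          IRanges::end(first_exon)))
  }
  hit <- regexpr("AG", seg, fixed = TRUE)
  if (hit == -1L)
    return(list(found = FALSE, lost_prefix_len = NA_integer_,
                cryptic_acceptor_pos = NA_integer_, shifted_circ = NULL))
  lost <- as.integer(hit) + 1L              # offset of the G = lost prefix
  if (lost >= IRanges::width(first_exon))
    return(list(found = FALSE, lost_prefix_len = NA_integer_,
                cryptic_acceptor_pos = NA_integer_, shifted_circ = NULL))
  if (strand == "+") {
    new_start <- IRanges::start(first_exon) + lost
    new_chain <- ch
    IRanges::start(new_chain)[1L] <- new_start
    cryptic_pos <- new_start
  } else {
    new_end <- IRanges::end(first_exon) - lost
    new_chain <- ch
    IRanges::end(new_chain)[length(new_chain)] <- new_end
    cryptic_pos <- new_end
  }
  list(found = TRUE, lost_prefix_len = lost,
       cryptic_acceptor_pos = cryptic_pos,
       shifted_circ = circDef(circ@seqname, strand, new_chain))
}

## Expand an IUPAC motif into a regular expression.
IUPAC_RE <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
              S = "[GC]", W = "[AT]", K = "[GT]", M = "[AC]",
              B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
              N = "[ACGT]")

iupacToRegex <- function(motif) {
  ch <- strToChars(toupper(motif))
  if (any(!ch %in% names(IUPAC_RE)))
    stop("motif contains non-IUPAC characters", call. = FALSE)
  paste(IUPAC_RE[ch], collapse = "")
}

#' Restriction fragments of one amplicon allele
#'
#' Cuts at every occurrence of the IUPAC `motif` on the forward strand,
#' `cut_offset` nt into the motif (Dde I: motif `CTNAG`, cut `C^TNAG`,
#' i.e. `cut_offset = 1`).
#'
#' @param amplicon DNA string.
#' @param motif IUPAC recognition motif (>= 2 nt).
#' @param cut_offset cut position within the motif (nt after the motif
#'   start, 1..len-1).
#' @return integer vector of fragment lengths (5' to 3'); sums to the
#'   amplicon length.
#' @export
rflpDigest <- function(amplicon, motif = "CTNAG", cut_offset = 1L) {
  s <- toupper(as.character(amplicon))
  if (!nchar(s)) stop("empty amplicon", call. = FALSE)
  if (nchar(motif) < 2L) stop("motif must be >= 2 nt", call. = FALSE)
  re <- iupacToRegex(motif)
  m <- gregexpr(sprintf("(?=%s)", re), s, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer(0) else as.integer(m) + cut_offset - 1L
  cuts <- cuts[cuts >= 1L & cuts < nchar(s)]
  diff(c(0L, sort(unique(cuts)), nchar(s)))
}

#' RFLP genotype discrimination between two alleles
#'
#' Digests both alleles and reports the heterozygote as the multiset union
#' of the two fragment sets (no intensity modelling). `discriminates` is
#' true when the allele fragment multisets differ.
#'
#' @param allele_a,allele_b amplicon sequences of the two alleles.
#' @inheritParams rflpDigest
#' @return list with `fragments_a`, `fragments_b`, `het_fragments`
#'   (descending lengths) and `discriminates`.
#' @export
rflpCompare <- function(allele_a, allele_b, motif = "CTNAG",
                        cut_offset = 1L) {
  fa <- rflpDigest(allele_a, motif, cut_offset)
  fb <- rflpDigest(allele_b, motif, cut_offset)
  list(fragments_a = fa, fragments_b = fb,
       het_fragments = sort(c(fa, fb), decreasing = TRUE),
       discriminates = !identical(sort(fa), sort(fb)))
}
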