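## Core S4 containers: transcript/locus models, backsplice definitions and
## circular sequences. Coordinates are 1-based inclusive (the native
## IRanges frame) on the plus strand of the reference sequence; BED I/O
## converts at the boundary.

#' TranscriptModel: one transcript of a locus
#'
#' Exons are genomic [IRanges::IRanges] in ascending genomic order
#' (irrespective of strand). `cds` may be empty for non-coding transcripts.
#'
#' @slot transcript_id single identifier.
#' @slot exons exon intervals, ascending, non-overlapping.
#' @slot cds coding intervals (possibly empty).
#' @slot coding logical flag.
#' @slot is_canonical logical flag.
#' @export
setClass("TranscriptModel",
  representation(transcript_id = "character", exons = "IRanges",
                 cds = "IRanges", coding = "logical",
                 is_canonical = "logical"))

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (length(ex) < 1L) return("transcript must have at least one exon")
  if (is.unsorted(IRanges::start(ex), strictly = TRUE) && length(ex) > 1L)
    return("exons must be in ascending genomic order")
  if (length(ex) > 1L &&
      any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
    return(sprintf("transcript %s has overlapping or unordered exons",
                   object@transcript_id))
  TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcript_id identifier.
#' @param exons IRanges of exons (any order; sorted internally).
#' @param cds IRanges of CDS intervals (default empty).
#' @param coding is the transcript protein coding?
#' @param is_canonical canonical flag.
#' @return a [TranscriptModel-class] object.
#' @export
transcriptModel <- function(transcript_id, exons, cds = IRanges::IRanges(),
                            coding = FALSE, is_canonical = FALSE) {
  exons <- sortRanges(exons)
  new("TranscriptModel", transcript_id = transcript_id, exons = exons,
      cds = sortRanges(cds), coding = coding, is_canonical = is_canonical)
}

#' LocusModel: a gene locus with its transcript structures
#'
#' @slot gene_id gene identifier.
#' @slot seqname name of the reference sequence the coordinates refer to.
#' @slot strand "+" or "-".
#' @slot transcripts named list of [TranscriptModel-class] objects.
#' @slot canonical_id id of the canonical transcript.
#' @export
setClass("LocusModel",
  representation(gene_id = "character", seqname = "character",
                 strand = "character", transcripts = "list",
                 canonical_id = "character"))

setValidity("LocusModel", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (!length(object@transcripts)) return("locus has no transcripts")
  ids <- vapply(object@transcripts, function(t) t@transcript_id, "")
  if (anyDuplicated(ids)) return("duplicated transcript ids")
  if (!object@canonical_id %in% ids)
    return("canonical_id does not name a transcript")
  flags <- vapply(object@transcripts, function(t) t@is_canonical, NA)
  if (sum(flags) != 1L) return("exactly one transcript must be canonical")
  if (ids[flags] != object@canonical_id)
    return("canonical flag and canonical_id disagree")
  TRUE
})

#' Construct a LocusModel
#'
#' When no transcript carries a canonical flag, the canonical transcript is
#' chosen as the one with the longest total CDS, ties broken by longest
#' transcript, then lexicographically smallest id.
#'
#' @param gene_id gene identifier.
#' @param seqname reference sequence name.
#' @param strand "+" or "-".
#' @param transcripts list of [TranscriptModel-class] objects.
#' @return a [LocusModel-class] object.
#' @export
locusModel <- function(gene_id, seqname, strand, transcripts) {
  names(transcripts) <- vapply(transcripts, function(t) t@transcript_id, "")
  flags <- vapply(transcripts, function(t) t@is_canonical, NA)
  if (!any(flags)) {
    cdslen <- vapply(transcripts, function(t) sum(IRanges::width(t@cds)), 0)
    txlen <- vapply(transcripts, function(t) sum(IRanges::width(t@exons)), 0)
    ids <- names(transcripts)
    ord <- order(-cdslen, -txlen, ids)
    pick <- ord[1L]
    transcripts[[pick]]@is_canonical <- TRUE
  }
  canon <- names(transcripts)[vapply(transcripts,
                                     function(t) t@is_canonical, NA)]
  new("LocusModel", gene_id = gene_id, seqname = seqname, strand = strand,
      transcripts = transcripts, canonical_id = canon)
}

#' @describeIn locusModel gene identifier accessor.
#' @param x a LocusModel.
#' @export
geneId <- function(x) x@gene_id

#' @describeIn locusModel canonical transcript id accessor.
#' @export
canonicalId <- function(x) x@canonical_id

#' @describeIn locusModel list of TranscriptModel accessor.
#' @export
transcripts <- function(x) x@transcripts

#' @describeIn locusModel transcript ids.
#' @export
transcriptIds <- function(x) names(x@transcripts)

#' @describeIn locusModel strand accessor.
#' @export
locusStrand <- function(x) x@strand

#' @describeIn locusModel genomic span (IRanges of length 1) of the gene.
#' @export
geneSpan <- function(x) {
  st <- min(vapply(x@transcripts,
                   function(t) min(IRanges::start(t@exons)), 0L))
  en <- max(vapply(x@transcripts,
                   function(t) max(IRanges::end(t@exons)), 0L))
  IRanges::IRanges(st, en)
}

#' Exons of one transcript
#' @param x a LocusModel.
#' @param id transcript id.
#' @return IRanges of exons.
#' @export
exonsOf <- function(x, id) {
  if (!id %in% names(x@transcripts)) stop("unknown transcript id: ", id)
  x@transcripts[[id]]@exons
}

setMethod("show", "LocusModel", function(object) {
  cat("LocusModel", object@gene_id, "on", object@seqname,
      paste0("(", object@strand, ")"), "with",
      length(object@transcripts), "transcripts\n")
  cat("  canonical:", object@canonical_id, "\n")
  for (t in object@transcripts)
    cat(sprintf("  %s: %d exon(s)%s%s\n", t@transcript_id,
                length(t@exons), if (t@coding) ", coding" else "",
                if (t@is_canonical) " [canonical]" else ""))
})

## Splice-boundary helpers. The "acceptor position" of an exon is its first
## transcribed base (strand-aware); the intronic AG occupies the two bases
## immediately 5' of it. First exons (transcription starts) have no
## acceptor; last exons have no donor.
txOrder <- function(exons, strand) {
  if (strand == "+") order(IRanges::start(exons))
  else order(-IRanges::start(exons))
}

acceptorPositions <- function(tx, strand) {
  ex <- tx@exons[txOrder(tx@exons, strand)]
  if (length(ex) < 2L) return(integer(0))
  internal <- ex[-1L]
  if (strand == "+") IRanges::start(internal) else IRanges::end(internal)
}

donorPositions <- function(tx, strand) {
  ex <- tx@exons[txOrder(tx@exons, strand)]
  if (length(ex) < 2L) return(integer(0))
  internal <- ex[-length(ex)]
  if (strand == "+") IRanges::end(internal) else IRanges::start(internal)
}

#' CircDef: a backsplice event
#'
#' The exon chain is the ordered set of genomic exons joined into the
#' circle; the backsplice acceptor (SA) is the first transcribed base of
#' the chain's first exon and the donor (SD) the last transcribed base of
#' its last exon (strand-aware).
#'
#' @slot seqname reference sequence name.
#' @slot strand "+" or "-".
#' @slot exon_chain IRanges of circularized exons, ascending genomic order.
#' @slot acceptor_pos genomic position of the backsplice acceptor.
#' @slot donor_pos genomic position of the backsplice donor.
#' @export
setClass("CircDef",
  representation(seqname = "character", strand = "character",
                 exon_chain = "IRanges", acceptor_pos = "integer",
                 donor_pos = "integer"))

setValidity("CircDef", function(object) {
  ch <- object@exon_chain
  if (length(ch) < 1L) return("exon chain must contain >= 1 exon")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (object@strand == "+") {
    if (object@acceptor_pos != IRanges::start(ch)[1L])
      return("acceptor must be the 5' boundary of the first chain exon")
    if (object@donor_pos != IRanges::end(ch)[length(ch)])
      return("donor must be the 3' boundary of the last chain exon")
  } else {
    if (object@acceptor_pos != IRanges::end(ch)[length(ch)])
      return("acceptor must be the 5' boundary of the first chain exon")
    if (object@donor_pos != IRanges::start(ch)[1L])
      return("donor must be the 3' boundary of the last chain exon")
  }
  TRUE
})

#' Construct a CircDef
#' @param seqname reference sequence name.
#' @param strand "+" or "-".
#' @param exon_chain IRanges of circularized exons.
#' @return a [CircDef-class] object.
#' @export
circDef <- function(seqname, strand, exon_chain) {
  exon_chain <- sortRanges(exon_chain)
  n <- length(exon_chain)
  if (strand == "+") {
    acc <- IRanges::start(exon_chain)[1L]
    don <- IRanges::end(exon_chain)[n]
  } else {
    acc <- IRanges::end(exon_chain)[n]
    don <- IRanges::start(exon_chain)[1L]
  }
  new("CircDef", seqname = seqname, strand = strand,
      exon_chain = exon_chain, acceptor_pos = as.integer(acc),
      donor_pos = as.integer(don))
}

#' @describeIn circDef backsplice acceptor position.
#' @param x a CircDef.
#' @export
circAcceptor <- function(x) x@acceptor_pos

#' @describeIn circDef backsplice donor position.
#' @export
circDonor <- function(x) x@donor_pos

#' @describeIn circDef the exon chain (IRanges).
#' @export
circChain <- function(x) x@exon_chain

setMethod("show", "CircDef", function(object) {
  cat(sprintf("CircDef on %s(%s): %d exon(s), SA %d, SD %d, %d nt\n",
              object@seqname, object@strand, length(object@exon_chain),
              object@acceptor_pos, object@donor_pos,
              sum(IRanges::width(object@exon_chain))))
})

#' CircleSeq: the circular RNA sequence
#'
#' The linearization starts at the acceptor-side first base; the backsplice
#' junction is the boundary between the last and the first base. All
#' downstream coordinates are rotation-invariant up to a shift.
#'
#' @slot sequence the linearized circle (DNA alphabet).
#' @slot source free-text provenance note.
#' @export
setClass("CircleSeq",
  representation(sequence = "character", source = "character"))

setValidity("CircleSeq", function(object) {
  if (nchar(object@sequence) < 1L) return("empty circle")
  if (grepl("[^ACGTN]", object@sequence)) return("non-DNA characters")
  TRUE
})

#' @describeIn buildCircle circle length (nt).
#' @param x a CircleSeq.
#' @export
circleLength <- function(x) nchar(x@sequence)

#' @describeIn buildCircle linearized sequence (character).
#' @export
circleSeq <- function(x) x@sequence

setMethod("show", "CircleSeq", function(object) {
  n <- nchar(object@sequence)
  cat(sprintf("CircleSeq of %d nt (junction between positions %d and 1)\n",
              n, n))
  cat(" ", substr(object@sequence, 1, min(60, n)),
      if (n > 60) "...\n" else "\n")
})
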