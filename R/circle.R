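## Junction-centric analyses on the circular topology: the circle is
## linearized starting at the acceptor-side first base, so the backsplice
## junction is the boundary between the last and the first base and every
## coordinate is rotation-invariant up to a shift.

#' Build the circular sequence of a backsplice event
#'
#' Concatenates the chain exons 5' to 3' (reverse-complementing for minus
#' strand genes). The junction sits between the donor-side last base and
#' the acceptor-side first base of the linearization.
#'
#' @param genome locus sequence (character).
#' @param circ a [CircDef-class].
#' @return a [CircleSeq-class].
#' @export
buildCircle <- function(genome, circ) {
  if (!length(circ@exon_chain)) stop("zero-length exon chain")
  s <- spliceSequence(as.character(genome), circ@exon_chain, circ@strand)
  new("CircleSeq", sequence = toupper(s),
      source = sprintf("backsplice %d..%d (%s)", circ@acceptor_pos,
                       circ@donor_pos, circ@strand))
}

#' Rotate a circle's linearization
#' @param circle a [CircleSeq-class].
#' @param shift rotate the origin forward by this many nt.
#' @return a [CircleSeq-class] with shifted linearization.
#' @export
rotateCircle <- function(circle, shift) {
  s <- circle@sequence; L <- nchar(s)
  shift <- ((shift %% L) + L) %% L
  if (shift == 0) return(circle)
  new("CircleSeq",
      sequence = paste0(substr(s, shift + 1L, L), substr(s, 1L, shift)),
      source = paste0(circle@source, sprintf(" rot%d", shift)))
}

#' Linear window centered on the backsplice junction
#'
#' Returns the last `flank` bases plus the first `flank` bases of the
#' linearization: the circle-specific sequence absent from every linear
#' isoform.
#'
#' @param circle a [CircleSeq-class].
#' @param flank nt on each side (<= circle length).
#' @return character of length `2 * flank`.
#' @export
junctionWindow <- function(circle, flank) {
  L <- circleLength(circle)
  if (flank > L) stop("flank exceeds circle length")
  paste0(substr(circle@sequence, L - flank + 1L, L),
         substr(circle@sequence, 1L, flank))
}

#' Design junction-spanning shRNA target sites
#'
#' Enumerates every `length`-nt window spanning the junction with both
#' arms >= `min_arm`, discards candidates whose target site occurs as an
#' exact substring of any provided linear mRNA (the selectivity
#' guarantee), filters by GC content and ranks the survivors: GC closest
#' to 0.45 first, then the most symmetric arms, then an A/T at the
#' guide's 5' end (= target 3' end), then circle offset.
#'
#' @param circle a [CircleSeq-class].
#' @param linear_mrnas character vector of mature linear transcript
#'   sequences.
#' @param length oligo length (default 19).
#' @param min_arm minimum nt on each side of the junction (default 5).
#' @param gc_range admissible GC fraction (default `c(0.3, 0.6)`).
#' @return data.frame of ranked candidates (`sequence` = target site
#'   sense sequence, `guide` = its reverse complement, `circ_offset` =
#'   1-based start on the linearization, `left_arm`, `right_arm`, `gc`,
#'   `kind`); when empty, the machine-readable exclusion counts are in
#'   `attr(, "reasons")`.
#' @export
designJunctionShrna <- function(circle, linear_mrnas, length = 19L,
                                min_arm = 5L, gc_range = c(0.3, 0.6)) {
  L <- circleLength(circle)
  if (L < length) stop("circle shorter than the oligo length")
  arms <- seq.int(min_arm, length - min_arm)   # left-arm sizes
  reasons <- c(in_linear = 0L, gc = 0L)
  rows <- lapply(arms, function(a) {
    site <- paste0(substr(circle@sequence, L - a + 1L, L),
                   substr(circle@sequence, 1L, length - a))
    data.frame(sequence = site, circ_offset = L - a + 1L,
               left_arm = a, right_arm = length - a,
               gc = gcContent(site), kind = "shRNA")
  })
  cand <- do.call(rbind, rows)
  hit_linear <- vapply(cand$sequence, occursIn, NA,
                       haystacks = linear_mrnas)
  reasons["in_linear"] <- sum(hit_linear)
  cand <- cand[!hit_linear, , drop = FALSE]
  bad_gc <- cand$gc < gc_range[1] | cand$gc > gc_range[2]
  reasons["gc"] <- sum(bad_gc)
  cand <- cand[!bad_gc, , drop = FALSE]
  if (!nrow(cand)) {
    out <- cand
    attr(out, "reasons") <- reasons
    return(out)
  }
  cand$guide <- vapply(cand$sequence, revComp, "")
  at5 <- substr(cand$sequence, nchar(cand$sequence),
                nchar(cand$sequence)) %in% c("A", "T")
  cand <- cand[order(abs(cand$gc - 0.45),
                     abs(cand$left_arm - cand$right_arm),
                     !at5, cand$circ_offset), , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "reasons") <- reasons
  cand
}

## All exact occurrence start positions (possibly overlapping) of
## `pattern` in `subject`.
allMatches <- function(pattern, subject) {
  m <- gregexpr(sprintf("(?=%s)", pattern), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Check a divergent primer pair on circular vs linear templates
#'
#' Primer binding is exact-match: the forward primer must occur on the
#' circle sense strand, the reverse primer as its reverse complement.
#' The amplicon is computed on circular topology (when the forward site
#' lies downstream of the reverse site in the linear frame the product
#' crosses the junction). The pair is circle-specific when no provided
#' linear mRNA supports a conventional (forward-then-reverse) product.
#'
#' @param fwd,rev primer sequences, 5' to 3' (>= 15 nt).
#' @param circle a [CircleSeq-class].
#' @param linear_mrnas character vector of mature linear transcripts.
#' @return list: `status` ("OK" or "NOT_FOUND"), `circ_amplicon_len`,
#'   `spans_junction`, `linear_amplicon` (NA when no linear product).
#' @export
checkDivergentPrimers <- function(fwd, rev, circle, linear_mrnas) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be >= 15 nt")
  s <- circle@sequence; L <- nchar(s)
  dbl <- paste0(s, s)
  f_pos <- allMatches(fwd, dbl); f_pos <- f_pos[f_pos <= L]
  r_rc <- revComp(rev)
  r_pos <- allMatches(r_rc, dbl); r_pos <- r_pos[r_pos <= L]
  if (!length(f_pos) || !length(r_pos))
    return(list(status = "NOT_FOUND", circ_amplicon_len = NA_integer_,
                spans_junction = NA, linear_amplicon = NA_integer_))
  f1 <- f_pos[1L]
  r_end <- r_pos + nchar(r_rc) - 1L
  span <- ((r_end - f1) %% L) + 1L          # circular product length
  amp <- min(span)
  r_pick <- r_pos[which.min(span)]
  spans <- (r_pick < f1) || (r_pick + nchar(r_rc) - 1L > L)
  lin <- NA_integer_
  for (mrna in linear_mrnas) {
    fp <- allMatches(fwd, mrna)
    rp <- allMatches(r_rc, mrna)
    if (length(fp) && length(rp)) {
      ok <- outer(rp + nchar(r_rc) - 1L, fp, "-") + 1L
      ok <- ok[ok >= nchar(fwd) + nchar(rev)]
      if (length(ok)) { lin <- min(ok); break }
    }
  }
  list(status = "OK", circ_amplicon_len = as.integer(amp),
       spans_junction = spans, linear_amplicon = lin)
}

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

translateCodons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  charsToStr(unname(aa))
}

#' Find ORFs on circular topology
#'
#' For every ATG on the circle (all three circular frames), translation
#' proceeds forward across the junction until a stop codon (a
#' "terminated" ORF; the peptide excludes the stop) or until `max_laps`
#' full passes of the circle have been read without a stop (a "rolling"
#' ORF, reported with `laps = max_laps`). `spans_junction` is true iff
#' any codon crosses the junction boundary.
#'
#' @param circle a [CircleSeq-class] (length >= 3).
#' @param start_codon start codon (default ATG).
#' @param max_laps cap on circle passes for stop-less frames (default 3).
#' @return data.frame: `start` (1-based circle coordinate of the A of
#'   ATG), `aa_length`, `spans_junction`, `laps`, `classification`,
#'   `peptide`.
#' @export
findCircularOrfs <- function(circle, start_codon = "ATG", max_laps = 3L) {
  s <- circle@sequence; L <- nchar(s)
  if (L < 3L) stop("circle shorter than one codon")
  ext <- strrep(s, max_laps + 1L)
  starts <- allMatches(start_codon, paste0(s, substr(s, 1L, 2L)))
  starts <- starts[starts <= L]
  if (!length(starts)) {
    return(data.frame(start = integer(0), aa_length = integer(0),
                      spans_junction = logical(0), laps = integer(0),
                      classification = character(0),
                      peptide = character(0)))
  }
  max_codons <- (max_laps * L) %/% 3L
  rows <- lapply(starts, function(p) {
    cstart <- seq.int(p, by = 3L, length.out = max_codons)
    codons <- substring(ext, cstart, cstart + 2L)
    stop_at <- match(TRUE, codons %in% GENETIC_CODE_STOPS)
    if (!is.na(stop_at)) {
      aa_len <- stop_at - 1L
      pep <- if (aa_len) translateCodons(codons[seq_len(aa_len)]) else ""
      end_index <- p + 3L * stop_at - 1L     # last base of the stop codon
      data.frame(start = p, aa_length = aa_len,
                 spans_junction = end_index > L,
                 laps = (end_index - 1L) %/% L,
                 classification = "terminated", peptide = pep)
    } else {
      pep <- translateCodons(codons)
      data.frame(start = p, aa_length = max_codons,
                 spans_junction = TRUE, laps = max_laps,
                 classification = "rolling", peptide = pep)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared N-terminus between a circle-encoded peptide and a protein
#'
#' @param circ_peptide amino-acid string of the circle-specific ORF.
#' @param linear_protein amino-acid string of the linear isoform.
#' @return list: `shared_prefix_len` (longest common prefix) and
#'   `circ_specific_suffix` (the discriminating region of the circle
#'   peptide).
#' @export
compareNTerminus <- function(circ_peptide, linear_protein) {
  if (!nchar(circ_peptide) || !nchar(linear_protein))
    stop("empty peptide")
  a <- strToChars(circ_peptide); b <- strToChars(linear_protein)
  n <- min(length(a), length(b))
  diff <- which(a[seq_len(n)] != b[seq_len(n)])
  lcp <- if (length(diff)) diff[1L] - 1L else n
  list(shared_prefix_len = lcp,
       circ_specific_suffix = substr(circ_peptide, lcp + 1L,
                                     nchar(circ_peptide)))
}

SEED_CLASS_LEVELS <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Scan a circle for canonical miRNA seed-match sites
#'
#' Canonical site classes on the target: 6mer (match to the reverse
#' complement of miRNA positions 2-7), 7mer-A1 (6mer plus an A opposite
#' miRNA position 1), 7mer-m8 (match to positions 2-8), 8mer (7mer-m8
#' plus the A1). The highest class is reported per position. The circle
#' is scanned with 7 wrap-around bases so junction-spanning sites are
#' found exactly once. No context scoring or thermodynamics.
#'
#' @param circle a [CircleSeq-class].
#' @param mirnas named character vector of miRNA sequences, 5' to 3'
#'   (>= 8 nt; U or T).
#' @param min_class lowest class reported (default "7mer-A1").
#' @return data.frame: `mirna_id`, `site_class`, `circle_position`
#'   (1-based start of the matched region on the linearization),
#'   `spans_junction`.
#' @export
scanSeedSites <- function(circle, mirnas, min_class = "7mer-A1") {
  stopifnot(min_class %in% SEED_CLASS_LEVELS)
  s <- circle@sequence; L <- nchar(s)
  ext <- paste0(s, substr(s, 1L, min(7L, L)))
  min_rank <- match(min_class, SEED_CLASS_LEVELS)
  if (is.null(names(mirnas)))
    names(mirnas) <- sprintf("mir%d", seq_along(mirnas))
  at <- function(p) substr(s, circIndex(p, L), circIndex(p, L))
  out <- lapply(names(mirnas), function(id) {
    m <- chartr("Uu", "TT", toupper(mirnas[[id]]))
    if (nchar(m) < 8L) stop("miRNA ", id, " shorter than 8 nt")
    s6 <- revComp(substr(m, 2L, 7L))         # matches target t7..t2
    m8c <- revComp(substr(m, 8L, 8L))        # target base pairing m8
    q <- allMatches(s6, ext)
    q <- q[q <= L]
    if (!length(q)) return(NULL)
    has_m8 <- vapply(q, function(p) at(p - 1L) == m8c, NA)
    has_a1 <- vapply(q, function(p) at(p + 6L) == "A", NA)
    cls <- ifelse(has_m8 & has_a1, "8mer",
           ifelse(has_m8, "7mer-m8",
           ifelse(has_a1, "7mer-A1", "6mer")))
    start <- ifelse(has_m8, circIndex(q - 1L, L), q)
    width <- ifelse(has_m8 & has_a1, 8L,
             ifelse(has_m8 | has_a1, 7L, 6L))
    data.frame(mirna_id = id, site_class = cls,
               circle_position = as.integer(start),
               spans_junction = start + width - 1L > L)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(mirna_id = character(0), site_class = character(0),
                      circle_position = integer(0),
                      spans_junction = logical(0)))
  out <- out[match(out$site_class, SEED_CLASS_LEVELS) >= min_rank, ,
             drop = FALSE]
  out <- out[order(out$mirna_id, out$circle_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
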