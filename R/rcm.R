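## Reverse-complementary-match (RCM) detection between the two introns
## flanking a circularized exon block. A from-scratch seed-and-extend
## local aligner over up_intron vs revcomp(down_intron): exact word seeds,
## per-diagonal ungapped extension with X-drop, cross-diagonal chaining of
## compatible segments re-scored by an affine-gap global alignment, then
## redundancy resolution and deterministic ranking. Not a general BLAST:
## no database indexing, no E-values, no translated searches.

#' RcmParams: scoring and filtering parameters for RCM detection
#'
#' Defaults mimic blastn: word 11, match +2, mismatch -3, gap open -5,
#' gap extend -2 (a gap of length g scores `gap_open + g * gap_extend`),
#' X-drop 20, minimum alignment length 20, minimum score 30. The
#' `sensitive` preset of [rcmParams()] lowers the word size to 5
#' (blastn-short-like) for short or degenerate repeats whose longest
#' clean match run is below the default word size.
#'
#' @slot word_size exact-match seed length (>= 4).
#' @slot match,mismatch per-base scores.
#' @slot gap_open,gap_extend affine gap scores (non-positive).
#' @slot xdrop extension stops when the running score falls this far
#'   below its maximum.
#' @slot min_length minimum alignment span (columns) reported.
#' @slot min_score minimum alignment score reported.
#' @slot max_hits cap on the number of reported hits.
#' @slot redundancy two hits conflict when they share more than this
#'   fraction of either interval; the higher-scoring one is kept.
#' @export
setClass("RcmParams",
  representation(word_size = "integer", match = "numeric",
                 mismatch = "numeric", gap_open = "numeric",
                 gap_extend = "numeric", xdrop = "numeric",
                 min_length = "integer", min_score = "numeric",
                 max_hits = "integer", redundancy = "numeric"))

setValidity("RcmParams", function(object) {
  if (object@word_size < 4L) return("word_size must be >= 4")
  if (object@mismatch > 0 || object@gap_open > 0 || object@gap_extend > 0)
    return("penalties must be non-positive scores")
  if (object@match <= 0) return("match score must be positive")
  if (object@redundancy <= 0) return("redundancy fraction must be > 0")
  TRUE
})

#' Construct RCM detection parameters
#' @param word_size,match,mismatch,gap_open,gap_extend,xdrop,min_length,min_score,max_hits,redundancy
#'   see [RcmParams-class].
#' @param sensitive logical; use the short-word preset (word size 5).
#' @return an [RcmParams-class] object.
#' @export
rcmParams <- function(word_size = 11L, match = 2, mismatch = -3,
                      gap_open = -5, gap_extend = -2, xdrop = 20,
                      min_length = 20L, min_score = 30, max_hits = 100L,
                      redundancy = 0.5, sensitive = FALSE) {
  if (sensitive) {
    ## short/degenerate-repeat preset (blastn-short-like scoring): the
    ## high mismatch-to-match ratio keeps extensions from drifting into
    ## flanking random sequence, and the short word seeds matches whose
    ## longest clean run is only ~1/(1-identity) nt.
    if (missing(word_size)) word_size <- 5L
    if (missing(match)) match <- 1
    if (missing(mismatch)) mismatch <- -3
    if (missing(min_score)) min_score <- 15
    if (missing(xdrop)) xdrop <- 10
  }
  new("RcmParams", word_size = as.integer(word_size), match = match,
      mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend,
      xdrop = xdrop, min_length = as.integer(min_length),
      min_score = min_score, max_hits = as.integer(max_hits),
      redundancy = redundancy)
}

setMethod("show", "RcmParams", function(object) {
  cat(sprintf(paste0("RcmParams: word %d, match %+g/%+g, gap %g/%g, ",
                     "xdrop %g, min len %d, min score %g\n"),
              object@word_size, object@match, object@mismatch,
              object@gap_open, object@gap_extend, object@xdrop,
              object@min_length, object@min_score))
})

emptyRcmHits <- function() {
  data.frame(up_start = integer(0), up_end = integer(0),
             down_start = integer(0), down_end = integer(0),
             length = integer(0), identity = numeric(0),
             score = numeric(0), n_gaps = integer(0),
             repeats = character(0))
}

## X-drop extension over a cumulative-score vector. `cs` has length n+1
## with cs[t+1] = score of the first t positions.
extendRight <- function(cs, e0, n, xdrop) {
  if (e0 >= n) return(e0)
  g <- cs[(e0 + 1L):(n + 1L)] - cs[e0 + 1L]   # g[1]: no extension
  mx <- cummax(g)
  viol <- which(mx - g > xdrop)
  lim <- if (length(viol)) viol[1L] - 1L else length(g)
  e0 + which.max(g[seq_len(lim)]) - 1L
}

extendLeft <- function(cs, s0, xdrop) {
  if (s0 <= 1L) return(s0)
  g <- cs[s0] - cs[s0:1L]                     # g[1]: no extension
  mx <- cummax(g)
  viol <- which(mx - g > xdrop)
  lim <- if (length(viol)) viol[1L] - 1L else length(g)
  s0 - which.max(g[seq_len(lim)]) + 1L
}

## Global affine-gap alignment (Gotoh) of two short segments, used to
## re-score chained segment pairs. A gap of length g scores
## gap_open + g * gap_extend. Ties resolve diagonal > up > left.
alignGlobal <- function(x, y, params) {
  xa <- strToChars(x); ya <- strToChars(y)
  n <- length(xa); m <- length(ya)
  NEG <- -1e15
  go <- params@gap_open; ge <- params@gap_extend
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)   # gap in y (moving along x)
  Iy <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L) Ix[i, 1L] <- go + ge * (i - 1L)
  for (j in seq_len(m) + 1L) Iy[1L, j] <- go + ge * (j - 1L)
  sub <- function(a, b)
    if (a == "N" || b == "N" || a != b) params@mismatch else params@match
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub(xa[i], ya[j])
      M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + go + ge,
                                Ix[i, j + 1L] + ge)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + go + ge,
                                Iy[i + 1L, j] + ge)
    }
  }
  ## traceback for column/match/gap counts
  i <- n; j <- m
  state <- which.max(c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L],
                       Iy[n + 1L, m + 1L]))
  score <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L],
             Iy[n + 1L, m + 1L])[state]
  cols <- 0L; nmatch <- 0L; ngaps <- 0L
  ax <- character(0); ay <- character(0)
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (state == 1L) {                       # M
      s <- sub(xa[i], ya[j])
      if (xa[i] == ya[j] && xa[i] != "N") nmatch <- nmatch + 1L
      ax <- c(xa[i], ax); ay <- c(ya[j], ay)
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {                # Ix: gap in y
      ax <- c(xa[i], ax); ay <- c("-", ay)
      ngaps <- ngaps + 1L
      opened <- abs((M[i, j + 1L] + go + ge) -
                    max(M[i, j + 1L] + go + ge, Ix[i, j + 1L] + ge)) < 1e-9
      state <- if (opened) 1L else 2L
      i <- i - 1L
    } else {                                 # Iy: gap in x
      ax <- c("-", ax); ay <- c(ya[j], ay)
      ngaps <- ngaps + 1L
      opened <- abs((M[i + 1L, j] + go + ge) -
                    max(M[i + 1L, j] + go + ge, Iy[i + 1L, j] + ge)) < 1e-9
      state <- if (opened) 1L else 3L
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  list(score = score, cols = cols, nmatch = nmatch, n_gaps = ngaps,
       aligned_x = charsToStr(ax), aligned_y = charsToStr(ay))
}

## Ungapped score / match count of an interval pair of equal width.
ungappedStats <- function(up, rc, u1, u2, r1, params) {
  xa <- strToChars(substr(up, u1, u2))
  ya <- strToChars(substr(rc, r1, r1 + (u2 - u1)))
  eq <- xa == ya & xa != "N" & ya != "N"
  list(score = sum(ifelse(eq, params@match, params@mismatch)),
       nmatch = sum(eq), cols = length(xa))
}

#' Find reverse complementary matches between two introns
#'
#' Aligns `up_intron` against the reverse complement of `down_intron` by
#' seed-and-extend: exact `word_size` seeds (words containing N never
#' seed), ungapped extension along each seeded diagonal under X-drop,
#' chaining of nearby compatible segments re-scored with affine gaps,
#' redundancy resolution (the higher-scoring of two hits sharing more
#' than the `redundancy` fraction of either interval is kept) and
#' filtering by `min_score` / `min_length`. `down_*` coordinates are
#' reported in the original (unreversed) downstream-intron frame.
#' Output order is deterministic: length desc, identity desc, score
#' desc, up_start asc.
#'
#' @param up_intron,down_intron DNA strings (A/C/G/T/N).
#' @param params an [RcmParams-class].
#' @return data.frame of hits: `up_start`, `up_end`, `down_start`,
#'   `down_end` (1-based inclusive, intron-local), `length` (alignment
#'   columns), `identity`, `score`, `n_gaps`, `repeats`.
#' @export
findRCM <- function(up_intron, down_intron, params = rcmParams()) {
  up <- toupper(as.character(up_intron))
  down <- toupper(as.character(down_intron))
  if (!nchar(up) || !nchar(down)) stop("empty intron sequence")
  assertDnaAlphabet(up, "up_intron"); assertDnaAlphabet(down, "down_intron")
  k <- params@word_size
  nA <- nchar(up); nB <- nchar(down)
  if (nA < k || nB < k) return(emptyRcmHits())
  rc <- revComp(down)

  ## seeds: exact k-mer matches between up and revcomp(down)
  sa <- seq_len(nA - k + 1L)
  ka <- substring(up, sa, sa + k - 1L)
  sb <- seq_len(nB - k + 1L)
  kb <- substring(rc, sb, sb + k - 1L)
  va <- !grepl("N", ka, fixed = TRUE)
  vb <- !grepl("N", kb, fixed = TRUE)
  if (!any(va) || !any(vb)) return(emptyRcmHits())
  idx <- split(sb[vb], kb[vb])
  key <- match(ka[va], names(idx))
  keep <- !is.na(key)
  if (!any(keep)) return(emptyRcmHits())
  ia <- sa[va][keep]
  lst <- idx[key[keep]]
  i <- rep.int(ia, lengths(lst))
  j <- unlist(lst, use.names = FALSE)
  d <- j - i

  a <- match(strToChars(up), DNA_BASES)
  b <- match(strToChars(rc), DNA_BASES)

  segs <- vector("list", length(unique(d)))
  si <- 0L
  for (dv in sort(unique(d))) {
    lo <- max(1L, 1L - dv); hi <- min(nA, nB - dv)
    ai <- a[lo:hi]; bi <- b[(lo + dv):(hi + dv)]
    mvec <- !is.na(ai) & !is.na(bi) & ai == bi
    sc <- ifelse(mvec, params@match, params@mismatch)
    cs <- c(0, cumsum(sc))
    cm <- c(0L, cumsum(mvec))
    n <- hi - lo + 1L
    seed_loc <- sort(unique(i[d == dv])) - lo + 1L
    ext <- matrix(0L, length(seed_loc), 2L)
    for (q in seq_along(seed_loc)) {
      s0 <- seed_loc[q]
      ext[q, 1L] <- extendLeft(cs, s0, params@xdrop)
      ext[q, 2L] <- extendRight(cs, s0 + k - 1L, n, params@xdrop)
    }
    ext <- unique(ext)
    si <- si + 1L
    segs[[si]] <- data.frame(
      u1 = lo + ext[, 1L] - 1L, u2 = lo + ext[, 2L] - 1L,
      r1 = lo + ext[, 1L] - 1L + dv, r2 = lo + ext[, 2L] - 1L + dv,
      score = cs[ext[, 2L] + 1L] - cs[ext[, 1L]],
      nmatch = cm[ext[, 2L] + 1L] - cm[ext[, 1L]])
  }
  seg <- do.call(rbind, segs[seq_len(si)])
  seg$cols <- seg$u2 - seg$u1 + 1L
  seg$n_gaps <- 0L
  seg <- unique(seg)

  ## chain compatible nearby segments, re-scoring with affine gaps
  seg <- mergeGappedSegments(seg, up, rc, params)

  seg <- seg[seg$score >= params@min_score &
             seg$cols >= params@min_length, , drop = FALSE]
  if (!nrow(seg)) return(emptyRcmHits())

  ## redundancy resolution: greedy by score
  seg <- seg[order(-seg$score, -seg$cols, seg$u1), , drop = FALSE]
  keep <- logical(nrow(seg))
  for (x in seq_len(nrow(seg))) {
    ok <- TRUE
    for (y in which(keep)) {
      ov_u <- min(seg$u2[x], seg$u2[y]) - max(seg$u1[x], seg$u1[y]) + 1L
      ov_r <- min(seg$r2[x], seg$r2[y]) - max(seg$r1[x], seg$r1[y]) + 1L
      lu_x <- seg$u2[x] - seg$u1[x] + 1L; lu_y <- seg$u2[y] - seg$u1[y] + 1L
      lr_x <- seg$r2[x] - seg$r1[x] + 1L; lr_y <- seg$r2[y] - seg$r1[y] + 1L
      if (ov_u > params@redundancy * min(lu_x, lu_y) ||
          ov_r > params@redundancy * min(lr_x, lr_y)) { ok <- FALSE; break }
    }
    keep[x] <- ok
  }
  seg <- seg[keep, , drop = FALSE]

  hits <- data.frame(
    up_start = seg$u1, up_end = seg$u2,
    down_start = nB - seg$r2 + 1L, down_end = nB - seg$r1 + 1L,
    length = seg$cols, identity = seg$nmatch / seg$cols,
    score = seg$score, n_gaps = seg$n_gaps,
    repeats = rep("", nrow(seg)))
  hits <- hits[order(-hits$length, -hits$identity, -hits$score,
                     hits$up_start), , drop = FALSE]
  rownames(hits) <- NULL
  head(hits, params@max_hits)
}

## Chain segment pairs that advance in both coordinates with a small
## intervening region; accept a join only when the affine-gap global
## alignment of the joined region outscores both parts. Only segments
## above a modest score take part (random-seed debris stays unchained).
mergeGappedSegments <- function(seg, up, rc, params, join_max = 25L,
                                merge_min = 12) {
  active <- seg$score >= merge_min
  rest <- seg[!active, , drop = FALSE]
  seg <- seg[active, , drop = FALSE]
  repeat {
    if (nrow(seg) < 2L) break
    seg <- seg[order(seg$u1, seg$r1), , drop = FALSE]
    done <- TRUE
    for (x in seq_len(nrow(seg) - 1L)) {
      js <- which(seg$u1 > seg$u2[x] &
                  seg$u1 <= seg$u2[x] + 1L + join_max &
                  seg$r1 > seg$r2[x] &
                  seg$r1 <= seg$r2[x] + 1L + join_max)
      js <- js[js > x]
      if (!length(js)) next
      for (y in js) {
        al <- alignGlobal(substr(up, seg$u1[x], seg$u2[y]),
                          substr(rc, seg$r1[x], seg$r2[y]), params)
        if (al$score > max(seg$score[x], seg$score[y])) {
          joined <- data.frame(u1 = seg$u1[x], u2 = seg$u2[y],
                               r1 = seg$r1[x], r2 = seg$r2[y],
                               score = al$score, nmatch = al$nmatch,
                               cols = al$cols, n_gaps = al$n_gaps)
          seg <- rbind(seg[-c(x, y), , drop = FALSE], joined)
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) break
  }
  rbind(seg, rest)
}

#' Recompute the alignment score of a reported hit
#'
#' Independent of the hit list: re-derives the score from the sequences
#' and the reported intervals (ungapped sum for gap-free hits, affine-gap
#' global alignment of the interval pair otherwise).
#'
#' @param hit one row of a [findRCM()] result.
#' @param up_intron,down_intron the sequences given to [findRCM()].
#' @param params the same [RcmParams-class].
#' @return numeric score.
#' @export
rcmHitScore <- function(hit, up_intron, down_intron,
                        params = rcmParams()) {
  up <- toupper(as.character(up_intron))
  rc <- revComp(toupper(as.character(down_intron)))
  nB <- nchar(down_intron)
  r1 <- nB - hit$down_end + 1L
  if (hit$n_gaps == 0L) {
    ungappedStats(up, rc, hit$up_start, hit$up_end, r1, params)$score
  } else {
    alignGlobal(substr(up, hit$up_start, hit$up_end),
                substr(rc, r1, nB - hit$down_start + 1L), params)$score
  }
}

#' Annotate RCM hits with overlapping repeat elements
#'
#' A repeat name is attached to a hit iff its interval overlaps the hit's
#' interval on the same intron by at least one nt. Hit order is
#' unchanged.
#'
#' @param hits a [findRCM()] result.
#' @param up_repeats,down_repeats data.frames with `name`, `start`, `end`
#'   in intron-local 1-based inclusive coordinates (convert genomic BED
#'   upstream).
#' @return `hits` with the `repeats` column filled (comma-separated).
#' @export
annotateRepeats <- function(hits, up_repeats = NULL, down_repeats = NULL) {
  if (!nrow(hits)) return(hits)
  lab <- function(h1, h2, reps) {
    if (is.null(reps) || !nrow(reps)) return(character(0))
    reps$name[reps$start <= h2 & reps$end >= h1]
  }
  hits$repeats <- vapply(seq_len(nrow(hits)), function(r) {
    paste(c(lab(hits$up_start[r], hits$up_end[r], up_repeats),
            lab(hits$down_start[r], hits$down_end[r], down_repeats)),
          collapse = ",")
  }, "")
  hits
}

#' Rank RCM candidates
#'
#' Promising circularization candidates are ranked on length and fraction
#' of complementarity: length desc, identity desc, score desc, up_start
#' asc; the first `top_k` are returned.
#'
#' @param hits a [findRCM()] result.
#' @param top_k number of candidates (<= 0 gives an empty list).
#' @return the top `top_k` rows.
#' @export
rankCandidates <- function(hits, top_k = 5L) {
  if (top_k <= 0L) return(emptyRcmHits())
  hits <- hits[order(-hits$length, -hits$identity, -hits$score,
                     hits$up_start), , drop = FALSE]
  rownames(hits) <- NULL
  head(hits, top_k)
}

#' Extract the flanking introns of a circRNA from a locus sequence
#'
#' The upstream intron is the intron immediately 5' of the circ acceptor,
#' the downstream intron immediately 3' of the donor (transcript
#' orientation). Boundaries are taken from the gap between the
#' transcript exons surrounding the chain; for the synthetic bundles the
#' chain is flanked by annotated introns of the recipe transcripts.
#'
#' @param genome locus sequence (character).
#' @param circ a [CircDef-class].
#' @param introns IRanges of the locus introns (e.g.
#'   `bundle@extras$introns`).
#' @return list with `up` and `down` sequences in transcript orientation.
#' @export
flankingIntrons <- function(genome, circ, introns) {
  ch <- circ@exon_chain
  if (circ@strand == "+") {
    up <- introns[IRanges::end(introns) == min(IRanges::start(ch)) - 1L]
    dn <- introns[IRanges::start(introns) == max(IRanges::end(ch)) + 1L]
    list(up = substr(genome, IRanges::start(up), IRanges::end(up)),
         down = substr(genome, IRanges::start(dn), IRanges::end(dn)))
  } else {
    up <- introns[IRanges::start(introns) == max(IRanges::end(ch)) + 1L]
    dn <- introns[IRanges::end(introns) == min(IRanges::start(ch)) - 1L]
    list(up = revComp(substr(genome, IRanges::start(up),
                             IRanges::end(up))),
         down = revComp(substr(genome, IRanges::start(dn),
                               IRanges::end(dn))))
  }
}

#' Write an RCM table (and optional alignment dump)
#'
#' TSV mirroring the per-hit columns, with a header comment recording the
#' parameter set; optionally a text file with the aligned sequences of
#' each hit.
#'
#' @param hits annotated [findRCM()] result.
#' @param path output TSV.
#' @param params the [RcmParams-class] used (recorded in the header).
#' @param up_intron,down_intron sequences; when given together with
#'   `alignment_path`, a full alignment text dump is written.
#' @param alignment_path optional path for the alignment dump.
#' @export
writeRcmTable <- function(hits, path, params = rcmParams(),
                          up_intron = NULL, down_intron = NULL,
                          alignment_path = NULL) {
  hdr <- sprintf(paste0("# rcm-scan word_size=%d match=%g mismatch=%g ",
                        "gap_open=%g gap_extend=%g xdrop=%g ",
                        "min_length=%d min_score=%g"),
                 params@word_size, params@match, params@mismatch,
                 params@gap_open, params@gap_extend, params@xdrop,
                 params@min_length, params@min_score)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(hits, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  if (!is.null(alignment_path) && !is.null(up_intron) &&
      !is.null(down_intron)) {
    up <- toupper(as.character(up_intron))
    rc <- revComp(toupper(as.character(down_intron)))
    nB <- nchar(down_intron)
    out <- character(0)
    for (r in seq_len(nrow(hits))) {
      r1 <- nB - hits$down_end[r] + 1L
      al <- alignGlobal(substr(up, hits$up_start[r], hits$up_end[r]),
                        substr(rc, r1, nB - hits$down_start[r] + 1L),
                        params)
      mid <- charsToStr(ifelse(strToChars(al$aligned_x) ==
                                 strToChars(al$aligned_y), "|", " "))
      out <- c(out,
               sprintf("RCM %d: up %d-%d / down %d-%d score %g id %.3f",
                       r, hits$up_start[r], hits$up_end[r],
                       hits$down_start[r], hits$down_end[r],
                       hits$score[r], hits$identity[r]),
               paste0("up   ", al$aligned_x), paste0("     ", mid),
               paste0("down ", al$aligned_y), "")
    }
    writeLines(out, alignment_path)
  }
  invisible(path)
}
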