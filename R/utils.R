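#' @keywords internal
"_PACKAGE"

#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnorm setNames
#' @importFrom utils head write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-in / character-out wrapper around
#' [Biostrings::reverseComplement()] used throughout the package.
#'
#' @param x single DNA string (A/C/G/T/N).
#' @return reverse-complemented string.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC fraction of a sequence
#' @param x DNA string.
#' @return fraction of G+C among non-N bases.
#' @export
gcContent <- function(x) {
  b <- strsplit(toupper(as.character(x)), "")[[1]]
  b <- b[b != "N"]
  if (!length(b)) return(NA_real_)
  mean(b %in% c("G", "C"))
}

## Evaluate `expr` under a fixed RNG state without clobbering the caller's
## stream. All generator entry points funnel through this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Random DNA with a target GC content.
randomDna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES[c(1, 2, 3, 4)], n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## character vector <-> string helpers
strToChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
charsToStr <- function(x) paste(x, collapse = "")

## Sort an IRanges by start/end without relying on S4 sort dispatch.
sortRanges <- function(ir) ir[order(IRanges::start(ir), IRanges::end(ir))]

## Circular (1-based) indexing into a string's character vector.
circIndex <- function(i, len) ((i - 1L) %% len) + 1L

assertDnaAlphabet <- function(x, what = "sequence") {
  if (grepl("[^ACGTN]", toupper(x)))
    stop(what, " contains characters outside A/C/G/T/N", call. = FALSE)
  invisible(TRUE)
}

## Substring occurrence check used by oligo-specificity filters.
occursIn <- function(needle, haystacks) {
  any(vapply(haystacks, function(h) grepl(needle, h, fixed = TRUE),
             logical(1)))
}
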