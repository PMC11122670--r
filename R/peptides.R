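## In-silico trypsin digestion, discriminative-peptide selection and
## exact monoisotopic mass / PRM inclusion m/z computation.

## Monoisotopic residue masses (Da). These constants reproduce published
## PRM inclusion lists to 5 decimals; I and L are distinct residues of
## equal mass.
RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

## Named modification deltas (Da). Carbamidomethylation is the usual
## fixed Cys modification of database searches; synthetic standards are
## unmodified, so no modification is ever applied implicitly.
MOD_MASS <- c(carbamidomethyl = 57.021464, oxidation = 15.994915)

assertResidues <- function(peptide) {
  ch <- strToChars(toupper(peptide))
  bad <- setdiff(unique(ch), names(RESIDUE_MASS))
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ch
}

resolveMods <- function(peptide, modifications) {
  if (is.null(modifications) || !length(modifications)) return(0)
  if (is.data.frame(modifications)) {
    pos <- modifications$position
    if (any(pos < 1L | pos > nchar(peptide)))
      stop("modification position outside the peptide", call. = FALSE)
    deltas <- modifications$mod
    if (is.character(deltas)) {
      unknown <- setdiff(deltas, names(MOD_MASS))
      if (length(unknown))
        stop("unknown modification: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      deltas <- MOD_MASS[deltas]
    }
    return(sum(as.numeric(deltas)))
  }
  if (is.character(modifications)) {
    unknown <- setdiff(modifications, names(MOD_MASS))
    if (length(unknown))
      stop("unknown modification: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    return(sum(MOD_MASS[modifications]))
  }
  sum(as.numeric(modifications))
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus any
#' modification deltas. Available named modifications:
#' `carbamidomethyl` (+57.021464) and `oxidation` (+15.994915); none is
#' applied unless requested.
#'
#' @param peptide amino-acid string (standard 20 letters).
#' @param modifications `NULL`, a numeric vector of mass deltas, a
#'   character vector of modification names, or a data.frame with
#'   `position` and `mod` columns.
#' @return neutral monoisotopic mass (Da).
#' @export
monoisotopicMass <- function(peptide, modifications = NULL) {
  ch <- assertResidues(peptide)
  sum(RESIDUE_MASS[ch]) + WATER_MASS + resolveMods(peptide, modifications)
}

#' Precursor m/z of a peptide ion
#'
#' `(M + z * 1.007276) / z`, reported to 5 decimals — the form used for
#' PRM inclusion lists.
#'
#' @inheritParams monoisotopicMass
#' @param charge positive integer charge state.
#' @return m/z (Da per charge), rounded to 5 decimals.
#' @export
peptideMz <- function(peptide, charge, modifications = NULL) {
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  m <- monoisotopicMass(peptide, modifications)
  round((m + charge * PROTON_MASS) / charge, 5L)
}

#' Charge states observable within a full-scan window
#'
#' @inheritParams monoisotopicMass
#' @param scan_range m/z window of the full MS scan (default 350-1500).
#' @param max_charge highest charge considered (default 6).
#' @return ascending integer charges whose m/z falls inside the range.
#' @export
feasibleCharges <- function(peptide, scan_range = c(350, 1500),
                            max_charge = 6L, modifications = NULL) {
  if (scan_range[1] >= scan_range[2]) stop("scan range low must be < high")
  z <- seq_len(max_charge)
  mz <- vapply(z, function(zz) peptideMz(peptide, zz, modifications), 0)
  z[mz >= scan_range[1] & mz <= scan_range[2]]
}

#' In-silico trypsin digestion
#'
#' Cleaves C-terminal to K or R, suppressed before proline when
#' `proline_rule` is on, and enumerates every peptide with up to
#' `max_missed_cleavages` retained internal sites. The protein C-terminus
#' is a valid peptide C-terminus regardless of its residue. Stable
#' order: N- to C-terminal start, then missed-cleavage count.
#'
#' @param protein amino-acid string (standard 20 letters).
#' @param max_missed_cleavages retained internal K/R sites allowed
#'   (default 0).
#' @param min_length shortest peptide reported (default 1).
#' @param proline_rule suppress cleavage before P (default TRUE).
#' @return data.frame: `peptide`, `start`, `end` (1-based residue
#'   coordinates), `missed`.
#' @export
trypsinDigest <- function(protein, max_missed_cleavages = 0L,
                          min_length = 1L, proline_rule = TRUE) {
  ch <- assertResidues(protein)
  n <- length(ch)
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (proline_rule)
    cut_after <- cut_after[ch[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)               # peptide i: bounds[i]+1..bounds[i+1]
  np <- length(bounds) - 1L
  rows <- list(); ri <- 0L
  for (i in seq_len(np)) {
    for (mc in 0:max_missed_cleavages) {
      j <- i + mc
      if (j > np) break
      st <- bounds[i] + 1L; en <- bounds[j + 1L]
      if (en - st + 1L < min_length) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        peptide = charsToStr(ch[st:en]), start = st, end = en,
        missed = mc)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0))
  out <- out[order(out$start, out$missed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tryptic peptides discriminating a circle-specific peptide
#'
#' Digests the circle-specific peptide and removes every peptide that
#' also occurs in the tryptic digest (same parameters) of any linear
#' protein. The survivors are the parallel-reaction-monitoring
#' candidates.
#'
#' @param circ_peptide amino-acid string of the circle-specific ORF.
#' @param linear_proteins character vector of linear proteome entries to
#'   discriminate against.
#' @inheritParams trypsinDigest
#' @return data.frame as [trypsinDigest()], restricted to discriminative
#'   peptides.
#' @export
discriminativePeptides <- function(circ_peptide, linear_proteins,
                                   max_missed_cleavages = 1L,
                                   min_length = 1L, proline_rule = TRUE) {
  if (!nchar(circ_peptide)) stop("empty circ peptide", call. = FALSE)
  dg <- trypsinDigest(circ_peptide, max_missed_cleavages, min_length,
                      proline_rule)
  linear_set <- unique(unlist(lapply(linear_proteins, function(p)
    trypsinDigest(p, max_missed_cleavages, min_length,
                  proline_rule)$peptide)))
  dg[!dg$peptide %in% linear_set, , drop = FALSE]
}

#' PRM inclusion-list targets for a circle-specific peptide
#'
#' Discriminative tryptic peptides with, for each, every charge state
#' whose precursor m/z falls inside the full-scan window. Masses are
#' computed unmodified (inclusion lists target synthetic standards);
#' pass `modifications` to add fixed modifications.
#'
#' @inheritParams discriminativePeptides
#' @param scan_range full MS scan m/z window (default 350-1500).
#' @param modifications applied to every peptide (see
#'   [monoisotopicMass()]).
#' @return data.frame: `peptide`, `missed`, `neutral_mass`, `charge`,
#'   `mz`.
#' @export
prmTargets <- function(circ_peptide, linear_proteins,
                       max_missed_cleavages = 1L, min_length = 5L,
                       proline_rule = TRUE, scan_range = c(350, 1500),
                       modifications = NULL) {
  dg <- discriminativePeptides(circ_peptide, linear_proteins,
                               max_missed_cleavages, min_length,
                               proline_rule)
  rows <- lapply(seq_len(nrow(dg)), function(r) {
    pep <- dg$peptide[r]
    zs <- feasibleCharges(pep, scan_range, modifications = modifications)
    if (!length(zs)) return(NULL)
    data.frame(peptide = pep, missed = dg$missed[r],
               neutral_mass = monoisotopicMass(pep, modifications),
               charge = zs,
               mz = vapply(zs, function(z)
                 peptideMz(pep, z, modifications), 0))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peptide = character(0), missed = integer(0),
                      neutral_mass = numeric(0), charge = integer(0),
                      mz = numeric(0))
  rownames(out) <- NULL
  out
}
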