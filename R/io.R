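## File-format boundary. GFF3 is 1-based inclusive (native to the internal
## frame); BED is 0-based half-open and converted here and only here.

#' Write a single-record FASTA
#' @param sequence DNA string.
#' @param name record name.
#' @param path output file.
#' @export
writeFasta <- function(sequence, name, path) {
  x <- Biostrings::DNAStringSet(setNames(as.character(sequence), name))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

gffAttr <- function(...) {
  kv <- list(...)
  paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = ";")
}

#' Write a LocusModel as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based inclusive). Transcript
#' attributes record `coding` and `canonical` flags so a round-trip
#' reproduces the model exactly.
#'
#' @param locus a [LocusModel-class].
#' @param path output file.
#' @export
writeLocusGFF3 <- function(locus, path) {
  sp <- geneSpan(locus)
  ln <- c("##gff-version 3",
          paste("#! internal frame: 1-based inclusive"))
  gid <- locus@gene_id
  ln <- c(ln, paste(locus@seqname, "circlocus", "gene",
                    IRanges::start(sp), IRanges::end(sp), ".",
                    locus@strand, ".", gffAttr(ID = gid), sep = "\t"))
  for (t in locus@transcripts) {
    tid <- t@transcript_id
    ln <- c(ln, paste(locus@seqname, "circlocus", "mRNA",
                      min(IRanges::start(t@exons)),
                      max(IRanges::end(t@exons)), ".", locus@strand, ".",
                      gffAttr(ID = tid, Parent = gid,
                              coding = tolower(t@coding),
                              canonical = tolower(t@is_canonical)),
                      sep = "\t"))
    for (i in seq_along(t@exons))
      ln <- c(ln, paste(locus@seqname, "circlocus", "exon",
                        IRanges::start(t@exons)[i],
                        IRanges::end(t@exons)[i], ".", locus@strand, ".",
                        gffAttr(ID = sprintf("%s.exon%d", tid, i),
                                Parent = tid), sep = "\t"))
    for (i in seq_along(t@cds))
      ln <- c(ln, paste(locus@seqname, "circlocus", "CDS",
                        IRanges::start(t@cds)[i],
                        IRanges::end(t@cds)[i], ".", locus@strand, "0",
                        gffAttr(ID = sprintf("%s.cds%d", tid, i),
                                Parent = tid), sep = "\t"))
  }
  writeLines(ln, path)
  invisible(path)
}

parseGffAttrs <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(vapply(kv, function(x) x[2], ""),
           vapply(kv, function(x) x[1], ""))
}

#' Parse annotation + sequence into a LocusModel
#'
#' Reads a GFF3 file (1-based inclusive) describing one gene with mRNA,
#' exon and optional CDS children, validates it against the FASTA
#' sequence, and returns the locus model. When no transcript carries a
#' `canonical=true` attribute, the canonical transcript is chosen by
#' longest CDS, then longest transcript, then lexicographic id.
#'
#' @param gff3 path to the GFF3 file.
#' @param fasta path to the FASTA file holding the reference sequence.
#' @return a [LocusModel-class]; the sequence is available via
#'   `attr(, "sequence")`.
#' @export
parseAnnotation <- function(gff3, fasta) {
  seqs <- readFasta(fasta)
  raw <- readLines(gff3)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad))
    stop(sprintf("malformed GFF3 at line %d: expected 9 tab-separated fields",
                 lineno[bad[1]]), call. = FALSE)
  tab <- data.frame(seqid = vapply(f, `[`, "", 1L),
                    type = vapply(f, `[`, "", 3L),
                    start = suppressWarnings(
                      as.integer(vapply(f, `[`, "", 4L))),
                    end = suppressWarnings(
                      as.integer(vapply(f, `[`, "", 5L))),
                    strand = vapply(f, `[`, "", 7L),
                    attrs = vapply(f, `[`, "", 9L))
  bad <- which(is.na(tab$start) | is.na(tab$end))
  if (length(bad))
    stop(sprintf("malformed GFF3 at line %d: non-numeric coordinates",
                 lineno[bad[1]]), call. = FALSE)
  if (!all(tab$seqid %in% names(seqs)))
    stop("GFF3 references sequences absent from the FASTA: ",
         paste(unique(setdiff(tab$seqid, names(seqs))), collapse = ", "),
         call. = FALSE)
  seqlen <- nchar(seqs[tab$seqid[1]])
  bad <- which(tab$start < 1L | tab$end > seqlen | tab$start > tab$end)
  if (length(bad))
    stop(sprintf("feature outside sequence bounds at line %d",
                 lineno[bad[1]]), call. = FALSE)

  attrs <- lapply(tab$attrs, parseGffAttrs)
  gene_row <- which(tab$type == "gene")
  if (length(gene_row) != 1L)
    stop("expected exactly one gene feature", call. = FALSE)
  gene_id <- attrs[[gene_row]][["ID"]]
  mrna_rows <- which(tab$type == "mRNA")
  if (!length(mrna_rows)) stop("no mRNA features found", call. = FALSE)

  txs <- lapply(mrna_rows, function(i) {
    tid <- attrs[[i]][["ID"]]
    kids <- which(vapply(attrs, function(a)
      identical(unname(a["Parent"]), tid), NA))
    ex <- kids[tab$type[kids] == "exon"]
    cd <- kids[tab$type[kids] == "CDS"]
    if (!length(ex)) stop("transcript ", tid, " has no exons",
                          call. = FALSE)
    transcriptModel(
      tid, IRanges::IRanges(tab$start[ex], tab$end[ex]),
      cds = IRanges::IRanges(tab$start[cd], tab$end[cd]),
      coding = identical(unname(attrs[[i]]["coding"]), "true") ||
        length(cd) > 0L,
      is_canonical = identical(unname(attrs[[i]]["canonical"]), "true"))
  })
  locus <- locusModel(gene_id, tab$seqid[gene_row], tab$strand[gene_row],
                      txs)
  attr(locus, "sequence") <- unname(seqs[tab$seqid[gene_row]])
  locus
}

#' Write intervals as BED6
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention on output.
#'
#' @param df data.frame with columns `start`, `end` (1-based inclusive)
#'   and optionally `name`, `score`, `strand`.
#' @param seqname chromosome column value.
#' @param path output file.
#' @export
writeBed6 <- function(df, seqname, path) {
  n <- nrow(df)
  out <- data.frame(chrom = rep(seqname, n), start = df$start - 1L,
                    end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0L,
                    strand = if ("strand" %in% names(df)) df$strand
                             else "+")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into 1-based inclusive intervals
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `name`, `score`, `strand`.
#' @export
readBed6 <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file must have >= 3 columns")
  data.frame(chrom = tab[[1]], start = tab[[2]] + 1L, end = tab[[3]],
             name = if (ncol(tab) >= 4) tab[[4]] else ".",
             score = if (ncol(tab) >= 5) tab[[5]] else 0L,
             strand = if (ncol(tab) >= 6) tab[[6]] else "+")
}

#' Write a CircDef as BED6
#'
#' One row per chain exon; the name column carries the exon-chain string
#' `acceptor|donor|i/n` so the circle is reconstructible.
#' @param circ a [CircDef-class].
#' @param path output file.
#' @export
writeCircBed <- function(circ, path) {
  ch <- circ@exon_chain
  df <- data.frame(start = IRanges::start(ch), end = IRanges::end(ch),
                   name = sprintf("circ:%d-%d:%d/%d", circ@acceptor_pos,
                                  circ@donor_pos, seq_along(ch),
                                  length(ch)),
                   score = 0L, strand = circ@strand)
  writeBed6(df, circ@seqname, path)
}

#' Read a CircDef from a BED6 file
#' @param path BED file written by [writeCircBed()].
#' @return a [CircDef-class].
#' @export
readCircBed <- function(path) {
  tab <- readBed6(path)
  circDef(tab$chrom[1], tab$strand[1],
          IRanges::IRanges(tab$start, tab$end))
}

#' Write / read a Ct table as TSV
#' @param ct data.frame (`sample`, `condition`, `target`, `ct`).
#' @param path file path.
#' @export
writeCtTsv <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCtTsv
#' @export
readCtTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a synthetic bundle to disk
#'
#' Emits locus FASTA, GFF3, circRNA BED6, repeat BED6, Ct TSV and a YAML
#' manifest recording the generating spec for provenance.
#'
#' @param bundle a [SyntheticLocusBundle-class].
#' @param dir output directory (created if absent).
#' @return named list of written paths.
#' @export
writeLocusBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(fasta = file.path(dir, "locus.fa"),
            gff3 = file.path(dir, "locus.gff3"),
            circ_bed = file.path(dir, "circ.bed"),
            repeat_bed = file.path(dir, "repeats.bed"),
            ct = file.path(dir, "ct.tsv"),
            manifest = file.path(dir, "manifest.yaml"))
  writeFasta(bundle@genome, bundle@locus@seqname, p$fasta)
  writeLocusGFF3(bundle@locus, p$gff3)
  writeCircBed(bundle@circ, p$circ_bed)
  if (nrow(bundle@repeats)) {
    writeBed6(bundle@repeats, bundle@locus@seqname, p$repeat_bed)
  } else {
    p$repeat_bed <- NULL
  }
  writeCtTsv(bundle@ct_table, p$ct)
  sp <- bundle@spec
  yaml::write_yaml(list(
    seed = sp@seed, n_exons = sp@n_exons,
    exon_lengths = sp@exon_lengths, intron_lengths = sp@intron_lengths,
    gc_content = sp@gc_content, circ_exon_range = sp@circ_exon_range,
    planted_rcms = if (nrow(sp@planted_rcms)) as.list(sp@planted_rcms)
                   else NULL,
    plant_sine_bed = sp@plant_sine_bed,
    cryptic_ag_offset = sp@cryptic_ag_offset), p$manifest)
  p
}
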