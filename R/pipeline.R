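## Umbrella "characterize this circRNA locus" pipeline: locus -> RCM ->
## circle -> peptides -> quant, each stage behind the corresponding
## module function, with one TSV per stage plus a machine-readable
## summary. Identical config + seed gives byte-identical outputs.

PIPELINE_KEYS <- c("fasta", "gff3", "circ_bed", "repeat_bed",
                   "mirna_fasta", "ct_tsv", "bundle", "out_dir", "seed",
                   "stages", "rcm_params", "digest", "shrna", "primers",
                   "protected", "quant_targets", "linear_protein")

#' Derive the introns flanking a circRNA from the transcript annotation
#'
#' The upstream flanking intron runs from the closest transcript exon
#' boundary 5' of the backsplice acceptor to the acceptor; the
#' downstream intron from the donor to the closest exon boundary 3' of
#' it (transcript orientation).
#'
#' @param locus a [LocusModel-class].
#' @param circ a [CircDef-class].
#' @return IRanges of length 2 (upstream, downstream flanking intron, in
#'   genomic coordinates).
#' @export
deriveFlankingIntrons <- function(locus, circ) {
  ex_start <- unlist(lapply(locus@transcripts,
                            function(t) IRanges::start(t@exons)))
  ex_end <- unlist(lapply(locus@transcripts,
                          function(t) IRanges::end(t@exons)))
  if (circ@strand == "+") {
    left <- ex_end[ex_end < circ@acceptor_pos]
    right <- ex_start[ex_start > circ@donor_pos]
    if (!length(left) || !length(right))
      stop("cannot derive flanking introns from the annotation")
    IRanges::IRanges(c(max(left) + 1L, circ@donor_pos + 1L),
                     c(circ@acceptor_pos - 1L, min(right) - 1L))
  } else {
    left <- ex_end[ex_end < circ@donor_pos]
    right <- ex_start[ex_start > circ@acceptor_pos]
    if (!length(left) || !length(right))
      stop("cannot derive flanking introns from the annotation")
    IRanges::IRanges(c(max(left) + 1L, circ@acceptor_pos + 1L),
                     c(circ@donor_pos - 1L, min(right) - 1L))
  }
}

stageHeader <- function(stage, desc) {
  sprintf("# circlocus %s: %s", stage, desc)
}

writeStageTsv <- function(df, path, header) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the end-to-end circRNA locus characterization pipeline
#'
#' Executes the enabled stages in dependency order on either a
#' [SyntheticLocusBundle-class] (`config$bundle`) or on input files
#' (`fasta`, `gff3`, `circ_bed`, optional `repeat_bed`, `mirna_fasta`,
#' `ct_tsv`), writing one TSV per stage and a JSON summary to
#' `config$out_dir`. Unknown config keys are rejected and referenced
#' files are checked before any stage runs; a stage failure aborts with
#' the stage name and leaves a `FAILED_<stage>` marker.
#'
#' @param config named list (or path to a YAML file with the same keys).
#'   Recognized keys: input paths as above, `bundle`, `out_dir`, `seed`,
#'   `stages` (named logical: locus, rcm, circle, peptides, quant),
#'   `rcm_params` ([RcmParams-class]), `digest`, `shrna`, `primers`
#'   (list with `fwd`, `rev`), `protected`, `quant_targets` (list with
#'   `circ`, `linear`), `linear_protein`.
#' @return (invisibly) the summary list.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stages <- utils::modifyList(
    list(locus = TRUE, rcm = TRUE, circle = TRUE, peptides = TRUE,
         quant = TRUE),
    as.list(config$stages %||% list()))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- validate + load inputs before any stage runs
  bundle <- config$bundle
  if (is.null(bundle)) {
    for (key in c("fasta", "gff3", "circ_bed")) {
      if (is.null(config[[key]]))
        stop("config is missing required input: ", key)
      if (!file.exists(config[[key]]))
        stop("input file does not exist: ", config[[key]])
    }
    for (key in c("repeat_bed", "mirna_fasta", "ct_tsv"))
      if (!is.null(config[[key]]) && !file.exists(config[[key]]))
        stop("input file does not exist: ", config[[key]])
    locus <- parseAnnotation(config$gff3, config$fasta)
    genome <- attr(locus, "sequence")
    circ <- readCircBed(config$circ_bed)
    introns <- deriveFlankingIntrons(locus, circ)
    repeats <- if (!is.null(config$repeat_bed)) readBed6(config$repeat_bed)
               else data.frame()
    ct <- if (!is.null(config$ct_tsv)) readCtTsv(config$ct_tsv) else NULL
    mrnas <- vapply(locus@transcripts, function(t)
      spliceSequence(genome, t@exons, locus@strand), "")
    linear_protein <- config$linear_protein
  } else {
    locus <- bundle@locus
    genome <- bundle@genome
    circ <- bundle@circ
    introns <- IRanges::IRanges(
      c(IRanges::start(bundle@extras$up_intron),
        IRanges::start(bundle@extras$down_intron)),
      c(IRanges::end(bundle@extras$up_intron),
        IRanges::end(bundle@extras$down_intron)))
    repeats <- bundle@repeats
    ct <- bundle@ct_table
    mrnas <- bundle@extras$mrnas
    linear_protein <- config$linear_protein %||%
      bundle@extras$linear_protein
  }
  mirnas <- if (!is.null(config$mirna_fasta)) readFasta(config$mirna_fasta)
            else NULL

  summary <- list(schema = "circlocus-summary-1",
                  seed = config$seed %||% NA)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(out_dir, paste0("FAILED_", name)))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## ---- locus stage: knockout feasibility
  if (isTRUE(stages$locus)) run_stage("locus", function() {
    usage <- spliceSiteUsage(locus, circ, protected = config$protected)
    writeStageTsv(usage$table, file.path(out_dir, "ko_feasibility.tsv"),
                  stageHeader("ko-feasibility",
                              paste("verdict:", usage$verdict)))
    summary$ko_verdict <<- usage$verdict
    summary$ko_table <<- usage$table
  })

  ## ---- rcm stage
  if (isTRUE(stages$rcm)) run_stage("rcm", function() {
    params <- config$rcm_params %||% rcmParams(sensitive = TRUE)
    fl <- flankingIntrons(genome, circ, introns)
    hits <- findRCM(fl$up, fl$down, params)
    if (nrow(repeats)) {
      up_iv <- introns[1L]; dn_iv <- introns[2L]
      tolocal <- function(iv) data.frame(
        name = repeats$name,
        start = repeats$start - IRanges::start(iv) + 1L,
        end = repeats$end - IRanges::start(iv) + 1L)
      hits <- annotateRepeats(hits, tolocal(up_iv), tolocal(dn_iv))
    }
    top <- rankCandidates(hits, top_k = min(nrow(hits), 5L))
    writeRcmTable(hits, file.path(out_dir, "rcm_hits.tsv"), params,
                  fl$up, fl$down,
                  alignment_path = file.path(out_dir,
                                             "rcm_alignments.txt"))
    summary$n_rcm_hits <<- nrow(hits)
    summary$top_rcms <<- top
  })

  ## ---- circle stage: shRNA design, ORFs, seed sites, primers
  circle <- NULL
  if (isTRUE(stages$circle) || isTRUE(stages$peptides))
    circle <- buildCircle(genome, circ)
  if (isTRUE(stages$circle)) run_stage("circle", function() {
    sh_par <- config$shrna %||% list()
    oligos <- designJunctionShrna(
      circle, mrnas, length = sh_par$length %||% 19L,
      min_arm = sh_par$min_arm %||% 5L,
      gc_range = sh_par$gc_range %||% c(0.3, 0.6))
    writeStageTsv(oligos, file.path(out_dir, "junction_shrna.tsv"),
                  stageHeader("design-shrna",
                              sprintf("circle %d nt", circleLength(circle))))
    orfs <- findCircularOrfs(circle)
    writeStageTsv(orfs, file.path(out_dir, "circular_orfs.tsv"),
                  stageHeader("orfs", "circular-topology ORFs"))
    summary$circle_length <<- circleLength(circle)
    summary$shrna <<- oligos
    spanning <- orfs[orfs$spans_junction &
                     orfs$classification == "terminated", , drop = FALSE]
    summary$junction_orfs <<- spanning[order(-spanning$aa_length), ,
                                       drop = FALSE]
    if (!is.null(mirnas)) {
      sites <- scanSeedSites(circle, mirnas)
      writeStageTsv(sites, file.path(out_dir, "seed_sites.tsv"),
                    stageHeader("seed-scan", "canonical seed classes"))
      summary$seed_sites <<- sites
    }
    if (!is.null(config$primers)) {
      pr <- checkDivergentPrimers(config$primers$fwd, config$primers$rev,
                                  circle, mrnas)
      summary$primer_check <<- pr
    }
  })

  ## ---- peptides stage: discriminative PRM targets
  if (isTRUE(stages$peptides)) run_stage("peptides", function() {
    orfs <- findCircularOrfs(circle)
    spanning <- orfs[orfs$spans_junction &
                     orfs$classification == "terminated", , drop = FALSE]
    if (!nrow(spanning) || is.null(linear_protein)) {
      summary$prm_targets <<- NULL
      return(invisible(NULL))
    }
    best <- spanning[which.max(spanning$aa_length), ]
    dg <- config$digest %||% list()
    prm <- prmTargets(best$peptide, linear_protein,
                      max_missed_cleavages = dg$max_missed_cleavages %||% 1L,
                      min_length = dg$min_length %||% 5L,
                      proline_rule = dg$proline_rule %||% TRUE)
    writeStageTsv(prm, file.path(out_dir, "prm_targets.tsv"),
                  stageHeader("prm-targets",
                              sprintf("circ ORF %d aa", best$aa_length)))
    summary$circ_orf_aa <<- best$aa_length
    summary$n_terminus_shared <<-
      compareNTerminus(best$peptide, linear_protein)$shared_prefix_len
    summary$prm_targets <<- prm
  })

  ## ---- quant stage
  if (isTRUE(stages$quant) && !is.null(ct)) run_stage("quant", function() {
    qt <- config$quant_targets %||% list(circ = "circ", linear = "linear")
    cv <- relativeExpression(ct, qt$circ)
    lv <- relativeExpression(ct, qt$linear)
    ratio <- circLinearRatio(cv, lv)
    writeStageTsv(cv, file.path(out_dir, "qpcr_circ.tsv"),
                  stageHeader("qpcr-norm",
                              "dCt vs mean(HK1,HK2); ref condition mean = 1"))
    writeStageTsv(lv, file.path(out_dir, "qpcr_linear.tsv"),
                  stageHeader("qpcr-norm",
                              "dCt vs mean(HK1,HK2); ref condition mean = 1"))
    summary$circ_linear_ratio <<- ratio$per_condition
  })

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
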