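## Relative qPCR quantification normalized to the arithmetic-mean Ct of
## two housekeepers (the geometric mean of their linear abundances), with
## circular-to-linear ratio reporting. Amplification efficiency is fixed
## at 2 per cycle; no standard-curve correction and no inferential
## statistics here.

#' Relative expression from a Ct table
#'
#' Technical replicates (same sample and target) are averaged on the Ct
#' scale first. Then `dCt = Ct_target - mean(Ct_hk1, Ct_hk2)` per sample,
#' `rel = 2^(-dCt)`, and values are rescaled so the mean over the
#' reference condition equals 1.
#'
#' @param ct data.frame with columns `sample`, `target`, `ct` and
#'   optionally `condition` (defaults to the sample id).
#' @param target target id to quantify.
#' @param housekeepers pair of housekeeper target ids (default
#'   `c("HK1", "HK2")`).
#' @param reference_condition condition whose mean is set to 1; default
#'   the first condition in table order.
#' @return data.frame: `sample`, `condition`, `delta_ct`, `rel_expr`
#'   (unscaled `2^-dCt`), `norm_expr` (rescaled).
#' @export
relativeExpression <- function(ct, target, housekeepers = c("HK1", "HK2"),
                               reference_condition = NULL) {
  stopifnot(all(c("sample", "target", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  if (!"condition" %in% names(ct)) ct$condition <- ct$sample
  ## average technical replicates on the Ct scale
  agg <- stats::aggregate(ct ~ sample + condition + target, data = ct,
                          FUN = mean)
  samples <- unique(agg[, c("sample", "condition")])
  rows <- lapply(seq_len(nrow(samples)), function(r) {
    sm <- samples$sample[r]
    sub <- agg[agg$sample == sm, ]
    hk <- sub$ct[match(housekeepers, sub$target)]
    if (anyNA(hk))
      stop("housekeeper(s) missing in sample ", sm, call. = FALSE)
    tg <- sub$ct[match(target, sub$target)]
    if (is.na(tg))
      stop("target ", target, " missing in sample ", sm, call. = FALSE)
    dct <- tg - mean(hk)
    data.frame(sample = sm, condition = samples$condition[r],
               delta_ct = dct, rel_expr = 2^(-dct))
  })
  out <- do.call(rbind, rows)
  if (is.null(reference_condition))
    reference_condition <- out$condition[1L]
  ref <- out$rel_expr[out$condition == reference_condition]
  if (!length(ref))
    stop("reference condition not present: ", reference_condition,
         call. = FALSE)
  out$norm_expr <- out$rel_expr / mean(ref)
  rownames(out) <- NULL
  out
}

#' Circular-to-linear expression ratio
#'
#' Elementwise per-sample ratio of two normalized expression tables plus
#' a per-condition predominance flag (`mean ratio > 1` marks the circle
#' as the main transcriptional output in that condition). Samples with a
#' zero linear value are flagged and their ratio omitted.
#'
#' @param circ_values,linear_values outputs of [relativeExpression()] for
#'   the circular and linear targets over the same samples.
#' @return list with `per_sample` (`sample`, `condition`, `ratio`,
#'   `zero_linear`) and `per_condition` (`condition`, `mean_ratio`,
#'   `circ_predominant`).
#' @export
circLinearRatio <- function(circ_values, linear_values) {
  m <- merge(circ_values[, c("sample", "condition", "norm_expr")],
             linear_values[, c("sample", "norm_expr")],
             by = "sample", suffixes = c("_circ", "_linear"))
  m$zero_linear <- m$norm_expr_linear == 0
  m$ratio <- ifelse(m$zero_linear, NA_real_,
                    m$norm_expr_circ / m$norm_expr_linear)
  per_sample <- m[order(m$condition, m$sample),
                  c("sample", "condition", "ratio", "zero_linear")]
  rownames(per_sample) <- NULL
  agg <- stats::aggregate(ratio ~ condition, data = per_sample,
                          FUN = mean, na.action = stats::na.omit)
  names(agg)[2] <- "mean_ratio"
  agg$circ_predominant <- agg$mean_ratio > 1
  list(per_sample = per_sample, per_condition = agg)
}
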