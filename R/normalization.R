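#' Per-sample normalization factor from a reference-gene pair
#'
#' The normalization factor (NF) for a sample is the arithmetic mean of the
#' Cq values of the two chosen reference genes in that sample — on the
#' linear scale this is the geometric mean of their abundances. Samples
#' missing either gene's Cq are omitted with a message.
#'
#' @param agg A `cq_aggregate`.
#' @param pair Character vector of two gene ids. Passing the same gene twice
#'   degenerates to that gene's Cq and raises a warning.
#' @return Object of class `normalization_factor`: list with `pair`, `nf`
#'   (named numeric vector, cycles, one per usable sample) and `groups`.
#' @examples
#' # a sample where the pair reads Cq 20 and 22 gets NF 21
#' @export
normalization_factor <- function(agg, pair) {
  stopifnot(inherits(agg, "cq_aggregate"), length(pair) == 2L)
  if (pair[1L] == pair[2L])
    warning("degenerate pair: the same gene twice; NF equals its Cq")
  missing_g <- setdiff(unique(pair), rownames(agg$cq))
  if (length(missing_g))
    stop_refstab("pair gene(s) absent from the Cq matrix: %s",
                 paste(missing_g, collapse = ", "),
                 class = "refstab_validation_error")
  cq_a <- agg$cq[pair[1L], ]
  cq_b <- agg$cq[pair[2L], ]
  usable <- is.finite(cq_a) & is.finite(cq_b)
  if (any(!usable))
    message(sprintf("normalization_factor: %d sample(s) missing a pair gene, omitted: %s",
                    sum(!usable),
                    paste(colnames(agg$cq)[!usable], collapse = ", ")))
  nf <- (cq_a[usable] + cq_b[usable]) / 2
  structure(list(pair = sort(pair), nf = nf,
                 groups = agg$groups[names(nf)]),
            class = "normalization_factor")
}

#' @export
print.normalization_factor <- function(x, ...) {
  cat(sprintf("NF from %s/%s over %d sample(s)\n",
              x$pair[1L], x$pair[2L], length(x$nf)))
  print(round(x$nf, 3))
  invisible(x)
}

#' Relative target-gene expression by the 2^-ddCt method
#'
#' Quantifies a target gene relative to the normalization factor and the
#' calibrator group: per sample, dCq is the target Cq minus the NF; ddCq
#' re-centers dCq on the mean over calibrator-group samples; the fold change
#' is `2^-ddCq`. The calibrator group therefore has geometric-mean fold
#' change 1 and plots around 1 with its spread intact. Group means, SDs and
#' an exact two-sided Mann-Whitney p-value between the two groups' fold
#' changes are reported.
#'
#' @param agg A `cq_aggregate` containing the target gene.
#' @param target Target gene id.
#' @param nf A `normalization_factor`.
#' @param calibrator Calibrator group label.
#' @return Object of class `fold_change_result`: list with `method =
#'   "qpcr_nf"`, `fc` (named per-sample fold changes), `groups`,
#'   `group_stats` (data.frame of mean, sd, n per group), `p_value`,
#'   `calibrator`, `target`.
#' @export
ddct_fold_change <- function(agg, target, nf, calibrator) {
  stopifnot(inherits(agg, "cq_aggregate"),
            inherits(nf, "normalization_factor"))
  if (!target %in% rownames(agg$cq))
    stop_refstab("target gene '%s' absent from the Cq matrix", target,
                 class = "refstab_validation_error")
  samples <- intersect(colnames(agg$cq), names(nf$nf))
  groups <- agg$groups[samples]
  if (!calibrator %in% groups)
    stop_refstab("calibrator group '%s' empty or unknown", calibrator,
                 class = "refstab_validation_error")
  dcq <- agg$cq[target, samples] - nf$nf[samples]
  ddcq <- dcq - mean(dcq[groups == calibrator])
  fc <- 2^(-ddcq)
  fold_change_result("qpcr_nf", fc, groups, calibrator, target)
}

#' Per-sample RNA-Seq fold changes from normalized counts
#'
#' Divides each sample's normalized count of the target gene by the mean
#' normalized count over calibrator-group samples, so the calibrator group
#' has mean fold change 1 by construction. This mirrors the qPCR fold
#' changes on the count scale for cross-method comparison.
#'
#' @param norm_counts Gene-by-sample matrix of normalized counts.
#' @param target Target gene id (row name).
#' @param groups Group map (named vector sample -> group).
#' @param calibrator Calibrator group label.
#' @return A `fold_change_result` with `method = "rnaseq_counts"`.
#' @export
rnaseq_fold_change <- function(norm_counts, target, groups, calibrator) {
  gm <- as_group_map(groups)
  if (!target %in% rownames(norm_counts))
    stop_refstab("target gene '%s' absent from the count matrix", target,
                 class = "refstab_validation_error")
  gm <- gm[colnames(norm_counts)]
  if (!calibrator %in% gm)
    stop_refstab("calibrator group '%s' empty or unknown", calibrator,
                 class = "refstab_validation_error")
  x <- norm_counts[target, ]
  cal_mean <- mean(x[gm == calibrator])
  if (cal_mean == 0)
    stop_refstab("calibrator-group mean count is 0 for '%s'", target,
                 class = "refstab_undefined_fc_error")
  fold_change_result("rnaseq_counts", x / cal_mean, gm, calibrator, target)
}

## shared constructor: per-group stats + two-group Mann-Whitney p
fold_change_result <- function(method, fc, groups, calibrator, target) {
  lv <- unique(groups)
  stats_df <- data.frame(
    group = lv,
    mean_fc = vapply(lv, function(g) mean(fc[groups == g]), 0),
    sd_fc = vapply(lv, function(g) stats::sd(fc[groups == g]), 0),
    n = vapply(lv, function(g) sum(groups == g), 0L),
    stringsAsFactors = FALSE)
  p <- if (length(lv) == 2L && all(table(groups) >= 2L))
    mann_whitney_exact(fc[groups == lv[1L]], fc[groups == lv[2L]])$p_value
  else NA_real_
  structure(list(method = method, target = target, fc = fc, groups = groups,
                 group_stats = stats_df, p_value = p,
                 calibrator = calibrator),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("%s fold changes for %s (calibrator '%s')\n",
              if (x$method == "qpcr_nf") "qPCR (2^-ddCt)" else "RNA-Seq",
              x$target, x$calibrator))
  df <- x$group_stats
  df$mean_fc <- round(df$mean_fc, 3); df$sd_fc <- round(df$sd_fc, 3)
  print(df, row.names = FALSE)
  if (!is.na(x$p_value))
    cat(sprintf("Mann-Whitney p = %.4g\n", x$p_value))
  invisible(x)
}
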