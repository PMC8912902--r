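#' Linearized expression from Cq values
#'
#' Converts a gene-by-sample Cq matrix to the linear scale as `2^-Cq`: one
#' cycle difference corresponds to a 2-fold abundance difference. Used for
#' coefficient-of-variation screening, where the raw (uncalibrated) linear
#' quantities are required.
#'
#' @param agg A `cq_aggregate` (see [aggregate_replicates()]) or a numeric
#'   gene-by-sample Cq matrix.
#' @return A list of class `rel_quantity`: `values` (gene x sample matrix of
#'   positive reals), `mode = "linearized"`, `groups`.
#' @export
linearize <- function(agg) {
  m <- if (inherits(agg, "cq_aggregate")) agg$cq else as.matrix(agg)
  groups <- if (inherits(agg, "cq_aggregate")) agg$groups else NULL
  if (any(!is.finite(m)))
    stop_refstab("non-finite Cq in aggregated matrix",
                 class = "refstab_validation_error")
  structure(list(values = 2^(-m), mode = "linearized", groups = groups,
                 calibrator = NULL),
            class = "rel_quantity")
}

#' Calibrated relative expression (2^-dCq)
#'
#' Expresses each gene's abundance relative to the calibrator group: per
#' gene, dCq is the Cq minus the mean Cq over calibrator-group samples and
#' the relative quantity is `2^-dCq`. By construction the geometric mean of
#' the calibrator-group entries is 1 for every gene, so raw expression
#' profiles plot around 1 in the calibrator with their biological spread
#' intact.
#'
#' @param agg A `cq_aggregate`.
#' @param calibrator Group label used as the reference condition.
#' @return A `rel_quantity` with `mode = "calibrated"`.
#' @export
relative_quantity <- function(agg, calibrator) {
  stopifnot(inherits(agg, "cq_aggregate"))
  groups <- agg$groups[colnames(agg$cq)]
  if (!calibrator %in% groups)
    stop_refstab("unknown calibrator group '%s'", calibrator,
                 class = "refstab_validation_error")
  cal_cols <- which(groups == calibrator)
  cal_mean <- rowMeans(agg$cq[, cal_cols, drop = FALSE])
  dcq <- agg$cq - cal_mean
  structure(list(values = 2^(-dcq), mode = "calibrated", groups = agg$groups,
                 calibrator = calibrator),
            class = "rel_quantity")
}

#' @export
print.rel_quantity <- function(x, ...) {
  cat(sprintf("Relative quantities (%s): %d gene(s) x %d sample(s)%s\n",
              x$mode, nrow(x$values), ncol(x$values),
              if (is.null(x$calibrator)) ""
              else sprintf(", calibrator '%s'", x$calibrator)))
  invisible(x)
}

#' Coefficient-of-variation screen on linearized expression
#'
#' Computes each gene's CV% — 100 times the sample standard deviation over
#' the mean of its linearized (`2^-Cq`) quantities across all samples pooled
#' — ranks genes by ascending CV, and flags genes whose CV exceeds the gate
#' (default 50%) for exclusion: such genes vary too much overall to be
#' useful reference candidates and can destabilize the model-based ranking.
#'
#' @param rq A `rel_quantity` in linearized mode.
#' @param gate Exclusion gate in percent; strict (`CV > gate` excludes).
#' @return data.frame with columns `gene`, `cv_percent`, `rank`, `excluded`.
#' @export
cv_analysis <- function(rq, gate = 50) {
  stopifnot(inherits(rq, "rel_quantity"))
  if (!identical(rq$mode, "linearized"))
    stop_refstab("cv_analysis expects linearized quantities (2^-Cq)",
                 class = "refstab_validation_error")
  v <- rq$values
  if (ncol(v) < 3L)
    stop_refstab("CV analysis needs at least 3 samples",
                 class = "refstab_validation_error")
  mu <- rowMeans(v)
  if (any(mu == 0))
    stop_refstab("zero mean expression for gene(s): %s",
                 paste(rownames(v)[mu == 0], collapse = ", "),
                 class = "refstab_undefined_cv_error")
  s <- apply(v, 1L, stats::sd)
  cv <- 100 * s / mu
  data.frame(gene = rownames(v), cv_percent = cv,
             rank = rank(cv, ties.method = "min"),
             excluded = cv > gate,
             row.names = NULL, stringsAsFactors = FALSE)
}
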