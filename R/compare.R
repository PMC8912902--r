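#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on
#' (number of groups - 1) degrees of freedom, via [stats::kruskal.test()].
#' Identical values in every group yield H = 0, p = 1 — a degenerate but
#' valid outcome, not an error.
#'
#' @param samples List of numeric vectors, one per group.
#' @return List with `h` (tie-corrected statistic), `p_value`, `df`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$h  # 7.2
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2L)
    stop_refstab("need >= 2 groups", class = "refstab_validation_error")
  if (any(lengths(samples) < 2L))
    stop_refstab("each group needs >= 2 values",
                 class = "refstab_validation_error")
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  if (length(unique(x)) == 1L)
    return(list(h = 0, p_value = 1, df = length(samples) - 1L))
  kt <- stats::kruskal.test(x, g)
  list(h = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Dunn's control-versus-others post test
#'
#' Rank-based multiple comparisons following Kruskal-Wallis, comparing each
#' group against a designated control on the pooled mid-ranks. The z
#' statistic for comparison group j is the difference of mean pooled ranks
#' divided by its null standard error with tie correction
#' (sum of t^3 - t over tied sets); the two-sided raw p comes from the
#' standard normal, and p-values are adjusted across the planned
#' control-versus-others family (default Bonferroni).
#'
#' @param samples List of numeric vectors, one per group; names are used as
#'   group labels.
#' @param control Index (or name) of the control group.
#' @param adjust Multiplicity adjustment: `"bonferroni"` (default),
#'   `"sidak"` or `"none"`, applied over the (number of groups - 1) planned
#'   comparisons.
#' @return data.frame with one row per non-control group: `comparison`,
#'   `z`, `p_raw`, `p_adjusted`.
#' @export
dunns_posthoc <- function(samples, control = 1L,
                          adjust = c("bonferroni", "sidak", "none")) {
  adjust <- match.arg(adjust)
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  if (is.character(control)) control <- match(control, names(samples))
  if (is.na(control) || control < 1L || control > length(samples))
    stop_refstab("control group index out of range",
                 class = "refstab_validation_error")
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab)
  var_unit <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n_g <- lengths(samples)
  others <- setdiff(seq_along(samples), control)
  z <- (rbar[control] - rbar[others]) /
    sqrt(var_unit * (1 / n_g[control] + 1 / n_g[others]))
  z <- unname(z)
  p_raw <- 2 * stats::pnorm(-abs(z))
  m <- length(others)
  p_adj <- switch(adjust,
                  bonferroni = pmin(1, m * p_raw),
                  sidak = 1 - (1 - p_raw)^m,
                  none = p_raw)
  data.frame(comparison = sprintf("%s vs %s", names(samples)[control],
                                  names(samples)[others]),
             z = z, p_raw = p_raw, p_adjusted = p_adj,
             stringsAsFactors = FALSE)
}

#' Compare fold-change distributions across normalization methods
#'
#' Given the same target quantified under several normalization strategies
#' (e.g. conventional NF, RNA-Seq-derived NF, RNA-Seq normalized counts),
#' tests whether the fold-change distributions differ: a tie-corrected
#' Kruskal-Wallis test across all methods followed by Dunn's post test of
#' each method against the control method. The calibrator group is omitted
#' — its fold changes sit at 1 by construction under every method, so
#' testing it is redundant.
#'
#' @param fc_list Named list of `fold_change_result` objects (same target,
#'   same samples) or of plain numeric vectors.
#' @param control Index or name of the control method (default the first).
#' @param adjust Multiplicity adjustment passed to [dunns_posthoc()].
#' @return Object of class `comparison_result`: list with `target`,
#'   `kruskal` (H, p), `dunn` (data.frame of planned comparisons) and
#'   `methods`.
#' @export
compare_fold_changes <- function(fc_list, control = 1L,
                                 adjust = "bonferroni") {
  vals <- lapply(fc_list, function(f) {
    if (inherits(f, "fold_change_result"))
      unname(f$fc[f$groups != f$calibrator])
    else as.numeric(f)
  })
  if (is.null(names(vals)))
    names(vals) <- paste0("method", seq_along(vals))
  target <- if (inherits(fc_list[[1L]], "fold_change_result"))
    fc_list[[1L]]$target else NA_character_
  kw <- kruskal_wallis(vals)
  dunn <- dunns_posthoc(vals, control = control, adjust = adjust)
  structure(list(target = target, kruskal = kw, dunn = dunn,
                 methods = names(vals)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Cross-method fold-change comparison%s\n",
              if (is.na(x$target)) "" else sprintf(" for %s", x$target)))
  cat(sprintf("Kruskal-Wallis: H = %.3f, p = %.4g\n",
              x$kruskal$h, x$kruskal$p_value))
  df <- x$dunn
  df$z <- round(df$z, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
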