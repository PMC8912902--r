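## enumeration of group assignments is reused heavily across genes/targets
.combn_cache <- new.env(parent = emptyenv())

combn_cached <- function(n, k) {
  key <- sprintf("%d_%d", n, k)
  if (is.null(.combn_cache[[key]]))
    .combn_cache[[key]] <- utils::combn(n, k)
  .combn_cache[[key]]
}

#' Exact two-sided Mann-Whitney U test
#'
#' Rank-sum test between two independent samples, designed for the small
#' group sizes typical of qPCR experiments. For combined n at or below
#' `exact_limit` the p-value comes from the full permutation distribution of
#' the mid-rank sum over all choose(n1+n2, n1) group assignments — ties are
#' handled by permuting the mid-ranks themselves, so exactness is preserved.
#' Above the limit a normal approximation with tie and continuity correction
#' is used.
#'
#' The two-sided p is twice the smaller tail probability, capped at 1.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_limit Largest combined sample size for which the permutation
#'   distribution is enumerated (default 20).
#' @return List with `u` (U statistic for `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.100
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 20L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 2L || n2 < 2L)
    stop_refstab("each group needs >= 2 values",
                 class = "refstab_validation_error")
  r <- rank(c(x, y))                     # mid-ranks under ties
  w_obs <- sum(r[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  if (n <= exact_limit) {
    cmb <- combn_cached(n, n1)
    ws <- colSums(matrix(r[cmb], nrow = n1))
    eps <- 1e-9                          # mid-ranks are halves; guard rounding
    p <- min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
    list(u = u_obs, p_value = p, method = "exact")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(u = u_obs, p_value = unname(wt$p.value), method = "normal_approx")
  }
}

#' Per-gene intrinsic-variation testing between two groups
#'
#' Tests each candidate reference gene for statistically significant
#' expression variation between the two experimental groups using the exact
#' two-sided Mann-Whitney U test on its relative quantities. Suited to the
#' reduced sample sizes of qPCR designs, where normality cannot be assumed.
#' Significance is reported as a flag only — a significant gene is not
#' automatically removed from stability ranking.
#'
#' @param rq A `rel_quantity` (either mode; ranks are invariant to the
#'   monotone 2^-x transform, so the result does not depend on the mode or
#'   calibrator).
#' @param groups Optional group map (named vector sample -> group); defaults
#'   to the map carried by `rq`.
#' @param alpha Significance level for flagging, default 0.05.
#' @return data.frame with columns `gene`, `p_value`, `significant`.
#' @export
intrinsic_variation_test <- function(rq, groups = NULL, alpha = 0.05) {
  stopifnot(inherits(rq, "rel_quantity"))
  gm <- as_group_map(if (is.null(groups)) rq$groups else groups)
  gm <- gm[colnames(rq$values)]
  lv <- unique(gm)
  if (length(lv) != 2L)
    stop_refstab("intrinsic_variation_test needs exactly 2 groups (got %d); use kruskal_wallis() for more",
                 length(lv), class = "refstab_validation_error")
  check_group_sizes(gm)
  i1 <- which(gm == lv[1L]); i2 <- which(gm == lv[2L])
  p <- apply(rq$values, 1L, function(v)
    mann_whitney_exact(v[i1], v[i2])$p_value)
  data.frame(gene = rownames(rq$values), p_value = p,
             significant = p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
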