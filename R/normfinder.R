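#' Model-based reference-gene stability estimation (NormFinder)
#'
#' Fits a two-way variance-components decomposition of Cq values to rank
#' candidate reference genes by expression stability. Cq is already a
#' log2-scale quantity, so the Cq values feed the model directly; the sign
#' flip relative to abundance affects neither variances nor the magnitude of
#' group differences.
#'
#' Within each experimental group the model separates a gene effect, a
#' sample (loading) effect and residual noise by double centering; the
#' residual mean square is bias-corrected into an intragroup variance
#' estimate per gene and group (negative method-of-moments estimates are
#' clipped at zero, as they can occur at small sample sizes). Systematic
#' gene-by-group expression differences are captured as intergroup
#' deviations, shrunken towards zero in proportion to their sampling noise
#' via an empirical-Bayes variance. Each gene's stability value combines the
#' magnitude of its shrunken intergroup deviation with its intragroup
#' sampling variability, averaged over groups — lower is more stable.
#'
#' The estimator requires at least 3 genes (its bias correction carries a
#' k/(k-2) factor), at least 2 groups, and at least 2 samples per group.
#'
#' @param agg A `cq_aggregate` (see [aggregate_replicates()]) or a numeric
#'   gene-by-sample Cq matrix.
#' @param groups Group map (named vector sample -> group); defaults to the
#'   map carried by `agg`.
#' @param genes Optional character vector restricting the fit to a subset of
#'   eligible genes (e.g. after the CV gate).
#' @return An object of class `normfinder`: list with
#'   \describe{
#'     \item{stability}{named vector of stability values S, one per gene}
#'     \item{rank}{ascending ranks by S (1 = most stable)}
#'     \item{sigma2}{k x G matrix of bias-corrected intragroup variances}
#'     \item{d, d_shrunk}{k x G matrices of raw and shrunken intergroup
#'       deviations (rows sum to zero across groups, columns across genes)}
#'     \item{gamma2}{the empirical-Bayes variance of intergroup deviations}
#'     \item{n_g}{group sizes}
#'   }
#'   with `print`, `summary`, `coef` and `plot` methods; pass the fit to
#'   [normfinder_best_pair()] for the two-gene combination search.
#' @seealso [normfinder_best_pair()], [stability_report()]
#' @export
normfinder <- function(agg, groups = NULL, genes = NULL) {
  y <- if (inherits(agg, "cq_aggregate")) agg$cq else as.matrix(agg)
  gm <- as_group_map(if (is.null(groups)) {
    if (!inherits(agg, "cq_aggregate"))
      stop_refstab("groups required when agg is a plain matrix",
                   class = "refstab_validation_error")
    agg$groups
  } else groups)
  gm <- gm[colnames(y)]
  if (anyNA(gm))
    stop_refstab("sample(s) missing from the group map",
                 class = "refstab_validation_error")
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(y))
    if (length(missing_g))
      stop_refstab("gene(s) not in the Cq matrix: %s",
                   paste(missing_g, collapse = ", "),
                   class = "refstab_validation_error")
    y <- y[genes, , drop = FALSE]
  }
  k <- nrow(y)
  if (k < 3L)
    stop_refstab("the stability estimator needs k >= 3 genes (got %d)", k,
                 class = "refstab_estimator_error")
  lv <- unique(gm)
  G <- length(lv)
  if (G < 2L)
    stop_refstab("at least 2 groups required",
                 class = "refstab_validation_error")
  check_group_sizes(gm)
  n_g <- stats::setNames(as.integer(table(gm)[lv]), lv)

  sigma2 <- s_naive <- a_eff <- matrix(NA_real_, k, G,
                                       dimnames = list(rownames(y), lv))
  for (g in seq_along(lv)) {
    Yg <- y[, gm == lv[g], drop = FALSE]
    n <- ncol(Yg)
    gene_mean <- rowMeans(Yg)
    samp_mean <- colMeans(Yg)
    grand <- mean(Yg)
    resid <- Yg - outer(gene_mean, rep(1, n)) -
      outer(rep(1, k), samp_mean) + grand
    shat2 <- rowSums(resid^2) / (n - 1)
    Sg <- sum(shat2)
    s_naive[, g] <- shat2
    sigma2[, g] <- pmax((shat2 - Sg / (k * (k - 1))) * k / (k - 2), 0)
    a_eff[, g] <- gene_mean - grand
  }
  d <- a_eff - rowMeans(a_eff)
  v <- sweep(sigma2, 2L, n_g, "/")          # sampling variance of d per cell
  gamma2 <- max(sum(d^2) / ((G - 1) * (k - 1)) - mean(v), 0)
  shrink <- ifelse(gamma2 + v > 0, gamma2 / (gamma2 + v), 0)
  d_shrunk <- d * shrink
  rho <- abs(d_shrunk) + sqrt(v * shrink)
  S <- rowMeans(rho)
  structure(list(stability = S,
                 rank = rank(S, ties.method = "min"),
                 sigma2 = sigma2, s_naive = s_naive,
                 d = d, d_shrunk = d_shrunk,
                 gamma2 = gamma2, n_g = n_g, groups = gm,
                 call = match.call()),
            class = "normfinder")
}

#' Best reference-gene pair by grouped stability
#'
#' Searches all unordered pairs of genes in a fitted stability model for the
#' combination whose averaged signal is most stable: averaging two genes
#' halves opposing intergroup deviations and reduces sampling variance, so
#' the best pair often beats the single best gene. The pair deviation is the
#' mean of the two shrunken deviations; the pair sampling variance is the
#' mean intragroup variance over the two genes divided by twice the group
#' size, shrunken exactly as in the single-gene stability value.
#'
#' @param fit A `normfinder` object.
#' @param genes Optional subset of eligible genes to search within.
#' @return List with `pair` (character vector of the two gene ids, in gene-id
#'   order), `stability` (the grouped stability of the winning pair) and
#'   `all_pairs` (data.frame of every pair and its grouped stability). Ties
#'   are broken lexicographically by gene id.
#' @export
normfinder_best_pair <- function(fit, genes = NULL) {
  stopifnot(inherits(fit, "normfinder"))
  ids <- names(fit$stability)
  if (!is.null(genes)) ids <- intersect(ids, genes)
  if (length(ids) < 2L)
    stop_refstab("best-pair search needs >= 2 eligible genes",
                 class = "refstab_validation_error")
  ids <- sort(ids)
  gamma2 <- fit$gamma2
  n_g <- fit$n_g[colnames(fit$sigma2)]
  pairs <- utils::combn(ids, 2L)
  s_pair <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    d_pair <- (fit$d_shrunk[a, ] + fit$d_shrunk[b, ]) / 2
    v_pair <- (fit$sigma2[a, ] + fit$sigma2[b, ]) / (4 * n_g)
    shrink <- ifelse(gamma2 + v_pair > 0, gamma2 / (gamma2 + v_pair), 0)
    s_pair[p] <- mean(abs(d_pair) + sqrt(v_pair * shrink))
  }
  best <- which.min(s_pair)   # first minimum = lexicographic tie-break
  list(pair = pairs[, best],
       stability = s_pair[best],
       all_pairs = data.frame(gene_a = pairs[1L, ], gene_b = pairs[2L, ],
                              grouped_stability = s_pair,
                              stringsAsFactors = FALSE))
}

#' @export
print.normfinder <- function(x, digits = 3L, ...) {
  cat(sprintf("Stability model: %d genes, %d groups (n = %s), gamma^2 = %.4g\n",
              length(x$stability), length(x$n_g),
              paste(x$n_g, collapse = "/"), x$gamma2))
  ord <- order(x$stability)
  out <- data.frame(stability = round(x$stability[ord], digits),
                    rank = x$rank[ord])
  print(out)
  invisible(x)
}

#' @export
summary.normfinder <- function(object, ...) {
  bp <- normfinder_best_pair(object)
  structure(list(fit = object, best_pair = bp), class = "summary.normfinder")
}

#' @export
print.summary.normfinder <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Best pair: %s/%s — grouped stability %.3f\n",
              x$best_pair$pair[1L], x$best_pair$pair[2L],
              x$best_pair$stability))
  invisible(x)
}

#' @export
coef.normfinder <- function(object, ...) object$stability

#' @export
plot.normfinder <- function(x, ...) {
  ord <- order(x$stability)
  graphics::barplot(x$stability[ord], las = 2,
                    ylab = "Stability value S (lower = more stable)",
                    main = "Reference-gene stability", ...)
  invisible(x)
}
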