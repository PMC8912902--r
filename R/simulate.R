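#' Configuration for a synthetic Cq dataset
#'
#' Describes the generative model for quantification-cycle data:
#' \deqn{y_{igjr} = \mu_i + \delta_{ig} + b_{gj} + e_{igj} + t_{igjr}}
#' where \eqn{\mu_i} is the gene baseline (cycles), \eqn{\delta_{ig}} a
#' gene-by-group shift (zero-sum across groups; zero for planted-stable
#' genes), \eqn{b_{gj} \sim N(0, \sigma_s^2)} a per-sample loading effect
#' shared by all genes of the sample, \eqn{e_{igj} \sim N(0, \sigma_{b,i}^2)}
#' biological noise, and \eqn{t_{igjr} \sim N(0, \sigma_t^2)} technical
#' replicate noise. Gaussian noise on the Cq (log2) scale matches the
#' variance-components model the stability estimator assumes.
#'
#' @param baseline Named numeric vector of per-gene baseline Cq (cycles).
#' @param group_shift Gene-by-group matrix of shifts \eqn{\delta_{ig}}
#'   (cycles); rows must sum to zero. Default all zero across `groups`.
#' @param bio_sd Per-gene biological SD (cycles); scalar recycled.
#' @param loading_sd Per-sample loading-effect SD (cycles), shared across
#'   genes within a sample.
#' @param tech_sd Technical replicate SD (cycles).
#' @param n_per_group Named integer vector of samples per group.
#' @param replicates Technical replicates per sample (>= 2).
#' @param seed Integer seed.
#' @return A validated list of class `cq_sim_config`.
#' @export
cq_sim_config <- function(baseline,
                          group_shift = NULL,
                          bio_sd = 0.1,
                          loading_sd = 0.2,
                          tech_sd = 0.05,
                          n_per_group = c(WT = 7L, KO = 7L),
                          replicates = 3L,
                          seed = 1L) {
  genes <- names(baseline)
  if (is.null(genes)) stop_refstab("baseline must be named by gene",
                                   class = "refstab_validation_error")
  grps <- names(n_per_group)
  if (is.null(grps)) stop_refstab("n_per_group must be named by group",
                                  class = "refstab_validation_error")
  if (is.null(group_shift))
    group_shift <- matrix(0, length(genes), length(grps),
                          dimnames = list(genes, grps))
  group_shift <- group_shift[genes, grps, drop = FALSE]
  if (any(abs(rowSums(group_shift)) > 1e-8))
    stop_refstab("group_shift rows must sum to zero",
                 class = "refstab_validation_error")
  bio_sd <- rep_len(bio_sd, length(genes)); names(bio_sd) <- genes
  if (any(c(bio_sd, loading_sd, tech_sd) < 0))
    stop_refstab("SDs must be >= 0", class = "refstab_validation_error")
  if (replicates < 2L)
    stop_refstab("need >= 2 technical replicates",
                 class = "refstab_validation_error")
  structure(list(baseline = baseline, group_shift = group_shift,
                 bio_sd = bio_sd, loading_sd = loading_sd,
                 tech_sd = tech_sd, n_per_group = n_per_group,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "cq_sim_config")
}

#' Simulate a long-format Cq dataset with known ground truth
#'
#' Draws a seeded, reproducible technical-replicate Cq table from the model
#' described in [cq_sim_config()], together with the ground truth needed to
#' verify downstream recovery: the planted-stable gene set (zero group shift
#' and baseline biological noise), the planted-unstable set with its
#' mechanism (group shift vs inflated noise), and every model parameter.
#'
#' @param cfg A `cq_sim_config`.
#' @return List with `cq` (a `cq_table`) and `truth` (list of `stable_genes`,
#'   `unstable_genes`, `mechanism`, `delta`, `bio_sd`, `config`).
#' @export
simulate_cq_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "cq_sim_config"))
  set.seed(cfg$seed)
  genes <- names(cfg$baseline)
  grps <- names(cfg$n_per_group)
  rows <- vector("list", sum(cfg$n_per_group))
  s_idx <- 0L
  for (g in grps) {
    for (j in seq_len(cfg$n_per_group[[g]])) {
      s_idx <- s_idx + 1L
      sample_id <- sprintf("%s_%02d", g, j)
      b <- stats::rnorm(1L, 0, cfg$loading_sd)
      e <- stats::rnorm(length(genes), 0, cfg$bio_sd)
      mu <- cfg$baseline + cfg$group_shift[, g] + b + e
      t_noise <- stats::rnorm(length(genes) * cfg$replicates, 0, cfg$tech_sd)
      rows[[s_idx]] <- data.frame(
        gene = rep(genes, each = cfg$replicates),
        sample = sample_id, group = g,
        replicate = rep(seq_len(cfg$replicates), times = length(genes)),
        cq = rep(mu, each = cfg$replicates) + t_noise,
        stringsAsFactors = FALSE)
    }
  }
  cq <- validate_cq_table(do.call(rbind, rows))
  shifted <- rowSums(abs(cfg$group_shift)) > 0
  noisy <- cfg$bio_sd > min(cfg$bio_sd)
  mechanism <- ifelse(shifted, "shift", ifelse(noisy, "noise", "stable"))
  truth <- list(stable_genes = genes[mechanism == "stable"],
                unstable_genes = genes[mechanism != "stable"],
                mechanism = stats::setNames(mechanism, genes),
                delta = cfg$group_shift, bio_sd = cfg$bio_sd,
                config = cfg)
  list(cq = cq, truth = truth)
}

#' Configuration for a synthetic RNA-Seq count matrix
#'
#' @param mean_expr Named per-gene mean expression on the normalized-count
#'   scale (\eqn{q_i > 0}).
#' @param dispersion Per-gene negative-binomial dispersion \eqn{\alpha_i \ge
#'   0}; 0 degenerates to Poisson. Scalar recycled.
#' @param size_factors Per-sample library size factors \eqn{s_j > 0}; one
#'   per sample (length must equal the total sample count).
#' @param log2_effects Gene-by-group matrix of planted log2 effects
#'   \eqn{\theta_{ig}}; default zero.
#' @param n_per_group Named samples per group.
#' @param seed Integer seed.
#' @return A validated list of class `count_sim_config`.
#' @export
count_sim_config <- function(mean_expr, dispersion = 0.05,
                             size_factors = NULL,
                             log2_effects = NULL,
                             n_per_group = c(WT = 4L, KO = 4L),
                             seed = 1L) {
  genes <- names(mean_expr)
  if (is.null(genes)) stop_refstab("mean_expr must be named by gene",
                                   class = "refstab_validation_error")
  if (any(mean_expr <= 0)) stop_refstab("mean_expr must be > 0",
                                        class = "refstab_validation_error")
  dispersion <- rep_len(dispersion, length(genes)); names(dispersion) <- genes
  if (any(dispersion < 0)) stop_refstab("dispersion must be >= 0",
                                        class = "refstab_validation_error")
  n_tot <- sum(n_per_group)
  if (is.null(size_factors)) size_factors <- rep(1, n_tot)
  if (length(size_factors) != n_tot || any(size_factors <= 0))
    stop_refstab("size_factors: one positive value per sample required",
                 class = "refstab_validation_error")
  grps <- names(n_per_group)
  if (is.null(log2_effects))
    log2_effects <- matrix(0, length(genes), length(grps),
                           dimnames = list(genes, grps))
  log2_effects <- log2_effects[genes, grps, drop = FALSE]
  structure(list(mean_expr = mean_expr, dispersion = dispersion,
                 size_factors = size_factors, log2_effects = log2_effects,
                 n_per_group = n_per_group, seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a negative-binomial count matrix with known ground truth
#'
#' Counts are drawn as NB with mean \eqn{q_i s_j 2^{\theta_{ig}}} and
#' dispersion \eqn{\alpha_i} (variance \eqn{\mu + \alpha \mu^2}); zero
#' dispersion uses Poisson sampling.
#'
#' @param cfg A `count_sim_config`.
#' @return List with `counts` (integer gene-by-sample matrix), `groups`
#'   (named map) and `truth` (per-gene \eqn{\theta}, \eqn{\alpha}, `q`,
#'   size factors, DE gene set).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "count_sim_config"))
  set.seed(cfg$seed)
  genes <- names(cfg$mean_expr)
  grps <- names(cfg$n_per_group)
  group_of <- rep(grps, times = cfg$n_per_group)
  samples <- unlist(lapply(grps, function(g)
    sprintf("%s_%02d", g, seq_len(cfg$n_per_group[[g]]))))
  counts <- matrix(0L, length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    mu <- cfg$mean_expr * cfg$size_factors[j] *
      2^cfg$log2_effects[, group_of[j]]
    counts[, j] <- ifelse(cfg$dispersion == 0,
                          stats::rpois(length(mu), mu),
                          stats::rnbinom(length(mu),
                                         mu = mu,
                                         size = 1 / pmax(cfg$dispersion, 1e-12)))
  }
  storage.mode(counts) <- "integer"
  de <- genes[apply(cfg$log2_effects, 1L, function(th) any(th != th[1L]))]
  list(counts = counts,
       groups = stats::setNames(group_of, samples),
       truth = list(theta = cfg$log2_effects, alpha = cfg$dispersion,
                    q = cfg$mean_expr, size_factors = cfg$size_factors,
                    de_genes = de, config = cfg))
}

#' Emulate a DESeq2-style results table from a count matrix
#'
#' Produces the per-gene summary table the candidate screen consumes,
#' using the median-of-ratios size factors: each sample's factor is the
#' median across genes of its count divided by the gene's geometric mean
#' over samples (genes positive in every sample). The differential test is
#' a deliberately transparent surrogate — Welch's t on `log2(normalized
#' count + 0.5)` with Benjamini-Hochberg adjustment — because the screen's
#' fidelity depends on the table's schema and the filters, not on the DE
#' engine. The dispersion column is a method-of-moments estimate
#' `max((var - mean) / mean^2, 0)` on normalized counts, overridable with
#' the simulation's true dispersions for exactness.
#'
#' @param counts Integer gene-by-sample count matrix.
#' @param groups Group map (named vector sample -> group); exactly 2 groups.
#'   The log2 fold change is second group over first, in order of
#'   appearance.
#' @param true_dispersion Optional named per-gene dispersion overriding the
#'   moment estimate.
#' @param pseudo_count Added before log transforms, default 0.5.
#' @return List with `results` (data.frame: `gene`, `base_mean`, `log2fc`,
#'   `pvalue`, `padj`, `dispersion`, `cv_from_disp`), `size_factors` and
#'   `norm_counts`.
#' @export
deseq_like_results <- function(counts, groups, true_dispersion = NULL,
                               pseudo_count = 0.5) {
  gm <- as_group_map(groups)[colnames(counts)]
  lv <- unique(gm)
  if (length(lv) != 2L)
    stop_refstab("exactly 2 groups required",
                 class = "refstab_validation_error")
  check_group_sizes(gm)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop_refstab("no gene positive in all samples; size factors undefined",
                 class = "refstab_size_factor_error")
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2L,
              function(col) stats::median(exp(log(col) - log_geo)))
  nc <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(nc)
  m1 <- rowMeans(nc[, gm == lv[1L], drop = FALSE])
  m2 <- rowMeans(nc[, gm == lv[2L], drop = FALSE])
  log2fc <- log2((m2 + pseudo_count) / (m1 + pseudo_count))
  lx <- log2(nc + pseudo_count)
  pvalue <- apply(lx, 1L, function(v) {
    a <- v[gm == lv[1L]]; b <- v[gm == lv[2L]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  })
  padj <- stats::p.adjust(pvalue, method = "BH")
  disp <- apply(nc, 1L, function(v) {
    mu <- mean(v)
    if (mu == 0) return(NA_real_)
    max((stats::var(v) - mu) / mu^2, 0)
  })
  if (!is.null(true_dispersion)) {
    idx <- match(rownames(counts), names(true_dispersion))
    disp[!is.na(idx)] <- true_dispersion[idx[!is.na(idx)]]
  }
  results <- data.frame(gene = rownames(counts), base_mean = base_mean,
                        log2fc = log2fc, pvalue = pvalue, padj = padj,
                        dispersion = disp,
                        row.names = NULL, stringsAsFactors = FALSE)
  results <- compute_cv_from_dispersion(results)
  list(results = results, size_factors = sf, norm_counts = nc)
}
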