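#' Aggregate technical replicates into per-sample Cq values
#'
#' Collapses the technical replicates of each (gene, sample) cell to a single
#' Cq, applying a replicate-consistency rule: the arithmetic mean of the
#' replicates represents the biological sample, and a replicate standard
#' deviation above `sd_threshold` marks the cell as inconsistent. In that case
#' exactly one outlier Cq — the replicate farthest from the within-cell median,
#' ties broken by the lowest replicate index — is removed, leaving at least
#' duplicate values. If the remaining replicates are consistent
#' (SD below the threshold) the cell is flagged `outlier_dropped` and the mean
#' of the retained replicates is used; otherwise the cell keeps the mean over
#' all original replicates and is flagged `inconsistent` so that downstream
#' steps may exclude it explicitly.
#'
#' @param cq A `cq_table` (see [read_cq_table()] / [validate_cq_table()]).
#' @param sd_threshold Replicate SD above which a cell is treated as
#'   inconsistent. Default 0.20 cycles; the comparison is strict (`> 0.20`
#'   triggers the rule).
#'
#' @return An object of class `cq_aggregate`: a list with
#'   \describe{
#'     \item{cq}{numeric matrix of mean Cq, genes in rows, samples in columns}
#'     \item{sd}{matrix of the SD of the retained replicates}
#'     \item{flag}{character matrix, each cell one of `"ok"`,
#'       `"outlier_dropped"`, `"inconsistent"`}
#'     \item{groups}{named character vector mapping sample to group}
#'   }
#'
#' @examples
#' cq <- validate_cq_table(data.frame(
#'   gene = "G1", sample = "s1", group = "WT",
#'   replicate = 1:3, cq = c(20.00, 20.10, 20.90)))
#' agg <- aggregate_replicates(cq)
#' agg$cq["G1", "s1"]    # 20.05: the 20.90 outlier was dropped
#' agg$flag["G1", "s1"]
#' @export
aggregate_replicates <- function(cq, sd_threshold = 0.20) {
  stopifnot(inherits(cq, "cq_table") || is.data.frame(cq))
  genes <- unique(cq$gene)
  samples <- unique(cq$sample)
  n_rep <- table(factor(cq$gene, genes), factor(cq$sample, samples))
  if (any(n_rep > 0 & n_rep < 2))
    stop_refstab("each (gene, sample) cell needs >= 2 replicates",
                 class = "refstab_validation_error")
  mk <- function(x) matrix(x, length(genes), length(samples),
                           dimnames = list(genes, samples))
  mean_m <- mk(NA_real_); sd_m <- mk(NA_real_); flag_m <- mk(NA_character_)
  idx <- split(seq_len(nrow(cq)), list(factor(cq$gene, genes),
                                       factor(cq$sample, samples)),
               sep = "\r", drop = TRUE)
  for (nm in names(idx)) {
    rows <- idx[[nm]]
    vals <- cq$cq[rows]
    reps <- cq$replicate[rows]
    gs <- strsplit(nm, "\r", fixed = TRUE)[[1L]]
    s_all <- stats::sd(vals)
    if (s_all <= sd_threshold) {
      mean_m[gs[1], gs[2]] <- mean(vals)
      sd_m[gs[1], gs[2]] <- s_all
      flag_m[gs[1], gs[2]] <- "ok"
    } else {
      dist <- abs(vals - stats::median(vals))
      drop_i <- order(-dist, reps)[1L]   # farthest first, ties -> lowest index
      kept <- vals[-drop_i]
      s_kept <- stats::sd(kept)
      if (s_kept < sd_threshold) {
        mean_m[gs[1], gs[2]] <- mean(kept)
        sd_m[gs[1], gs[2]] <- s_kept
        flag_m[gs[1], gs[2]] <- "outlier_dropped"
      } else {
        mean_m[gs[1], gs[2]] <- mean(vals)
        sd_m[gs[1], gs[2]] <- s_all
        flag_m[gs[1], gs[2]] <- "inconsistent"
      }
    }
  }
  structure(list(cq = mean_m, sd = sd_m, flag = flag_m,
                 groups = cq_groups(cq), sd_threshold = sd_threshold),
            class = "cq_aggregate")
}

#' @export
print.cq_aggregate <- function(x, ...) {
  cat(sprintf("Aggregated Cq: %d gene(s) x %d sample(s), %d group(s)\n",
              nrow(x$cq), ncol(x$cq), length(unique(x$groups))))
  tab <- table(factor(x$flag, c("ok", "outlier_dropped", "inconsistent")))
  cat(sprintf("  flags: %d ok, %d outlier_dropped, %d inconsistent (SD threshold %.2f)\n",
              tab["ok"], tab["outlier_dropped"], tab["inconsistent"],
              x$sd_threshold))
  invisible(x)
}

#' Write an aggregated Cq matrix as wide CSV plus a flags sidecar
#'
#' @param agg A `cq_aggregate`.
#' @param path Output CSV path for the gene-by-sample mean Cq matrix; the
#'   flags matrix is written next to it with suffix `"_flags"`.
#' @return Invisibly, the two paths written.
#' @export
write_aggregated_cq <- function(agg, path) {
  utils::write.csv(agg$cq, path)
  flags_path <- sub("(\\.[^.]+)?$", "_flags\\1", path)
  utils::write.csv(agg$flag, flags_path)
  invisible(c(path, flags_path))
}
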