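#' Full reference-gene stability report
#'
#' Runs the complete candidate-validation stage on an aggregated Cq dataset:
#' coefficient-of-variation analysis on linearized expression with the
#' exclusion gate, per-gene intrinsic-variation testing between the two
#' groups (exact Mann-Whitney; reported as a flag, never an exclusion), the
#' model-based stability fit on the genes passing the CV gate, and the
#' best-pair search restricted to eligible genes. A per-sample normalization
#' factor preview for the winning pair is attached.
#'
#' @param agg A `cq_aggregate`.
#' @param genes Optional character vector restricting the report to the
#'   candidate reference genes (target genes measured on the same plates
#'   must not enter the stability fit).
#' @param cv_gate CV% exclusion gate, default 50 (strict).
#' @param alpha Flagging level for the intrinsic-variation test.
#' @return An object of class `stability_report`: data.frame with one row
#'   per gene (`gene`, `cv_percent`, `cv_rank`, `intrinsic_p`,
#'   `intrinsic_significant`, `stability`, `stability_rank`, `status`), plus
#'   attributes `best_pair`, `grouped_stability`, `nf_preview` and `fit`.
#' @export
stability_report <- function(agg, genes = NULL, cv_gate = 50, alpha = 0.05) {
  stopifnot(inherits(agg, "cq_aggregate"))
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(agg$cq))
    if (length(missing_g))
      stop_refstab("gene(s) absent from the Cq matrix: %s",
                   paste(missing_g, collapse = ", "),
                   class = "refstab_validation_error")
    agg$cq <- agg$cq[genes, , drop = FALSE]
    agg$sd <- agg$sd[genes, , drop = FALSE]
    agg$flag <- agg$flag[genes, , drop = FALSE]
  }
  lin <- linearize(agg)
  cv <- cv_analysis(lin, gate = cv_gate)
  two_groups <- length(unique(agg$groups)) == 2L
  iv <- if (two_groups) intrinsic_variation_test(lin, alpha = alpha)
        else data.frame(gene = cv$gene, p_value = NA_real_,
                        significant = NA)
  eligible <- cv$gene[!cv$excluded]
  fit <- normfinder(agg, genes = eligible)
  bp <- normfinder_best_pair(fit)
  nf <- normalization_factor(agg, bp$pair)
  out <- data.frame(gene = cv$gene,
                    cv_percent = cv$cv_percent,
                    cv_rank = cv$rank,
                    intrinsic_p = iv$p_value[match(cv$gene, iv$gene)],
                    intrinsic_significant = iv$significant[match(cv$gene, iv$gene)],
                    stability = unname(fit$stability[cv$gene]),
                    stability_rank = unname(fit$rank[cv$gene]),
                    status = ifelse(cv$excluded, "excluded_cv", "eligible"),
                    stringsAsFactors = FALSE)
  out <- out[order(is.na(out$stability), out$stability, out$cv_percent), ]
  rownames(out) <- NULL
  structure(out, best_pair = bp$pair, grouped_stability = bp$stability,
            nf_preview = nf, fit = fit, cv_gate = cv_gate,
            class = c("stability_report", "data.frame"))
}

#' @export
print.stability_report <- function(x, digits = 3L, ...) {
  cat(sprintf("Reference-gene stability report (%d genes; CV gate %g%%)\n",
              nrow(x), attr(x, "cv_gate")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df)
  cat(sprintf("Best pair: %s/%s — grouped stability %.3f\n",
              attr(x, "best_pair")[1L], attr(x, "best_pair")[2L],
              attr(x, "grouped_stability")))
  invisible(x)
}

#' Write a stability report as CSV with a best-pair footer
#'
#' @param report A `stability_report`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_stability_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  footer <- sprintf("# Best pair: %s/%s,Grouped stability: %.3f",
                    attr(report, "best_pair")[1L],
                    attr(report, "best_pair")[2L],
                    attr(report, "grouped_stability"))
  cat(footer, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
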