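#' Read a DESeq2-style results table
#'
#' @param path CSV/TSV file with one row per gene.
#' @param columns Named character vector mapping the fields `gene`,
#'   `base_mean`, `log2fc`, `padj`, `dispersion` to the file's column names.
#'   Defaults to the DESeq2 export names (`baseMean`, `log2FoldChange`, ...).
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A data.frame with columns `gene`, `base_mean`, `log2fc`, `padj`,
#'   `dispersion` (and `cv_from_disp` if present in the file).
#' @export
read_deseq_results <- function(path,
                               columns = c(gene = "gene",
                                           base_mean = "baseMean",
                                           log2fc = "log2FoldChange",
                                           padj = "padj",
                                           dispersion = "dispersion"),
                               sep = NULL) {
  if (!file.exists(path))
    stop_refstab("file not found: %s", path, class = "refstab_io_error")
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  defaults <- c(gene = "gene", base_mean = "baseMean",
                log2fc = "log2FoldChange", padj = "padj",
                dispersion = "dispersion")
  defaults[names(columns)] <- columns
  columns <- defaults
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols))
    stop_refstab("missing required column(s): %s",
                 paste(missing_cols, collapse = ", "),
                 class = "refstab_format_error")
  out <- data.frame(gene = as.character(raw[[columns["gene"]]]),
                    base_mean = as.numeric(raw[[columns["base_mean"]]]),
                    log2fc = as.numeric(raw[[columns["log2fc"]]]),
                    padj = as.numeric(raw[[columns["padj"]]]),
                    dispersion = as.numeric(raw[[columns["dispersion"]]]),
                    stringsAsFactors = FALSE)
  if ("cv_from_disp" %in% names(raw)) out$cv_from_disp <- raw$cv_from_disp
  if (anyDuplicated(out$gene))
    stop_refstab("duplicated gene ids in results table",
                 class = "refstab_validation_error")
  out
}

#' Expression-variability proxy from the negative-binomial dispersion
#'
#' The per-gene NB dispersion estimated by an RNA-Seq fit approximates the
#' squared biological coefficient of variation, so `100 * sqrt(dispersion)`
#' is a CV-like percentage used to screen candidate reference genes for
#' moderate, non-trivial variability.
#'
#' @param table Results data.frame with a `dispersion` column.
#' @return The table with a `cv_from_disp` column added (percent); missing
#'   dispersions propagate as missing CV.
#' @examples
#' compute_cv_from_dispersion(data.frame(gene = "g", base_mean = 600,
#'   log2fc = 0, padj = 0.8, dispersion = 0.0225))$cv_from_disp  # 15
#' @export
compute_cv_from_dispersion <- function(table) {
  if (!"dispersion" %in% names(table))
    stop_refstab("dispersion column required",
                 class = "refstab_validation_error")
  if (any(table$dispersion < 0, na.rm = TRUE))
    stop_refstab("negative dispersion encountered",
                 class = "refstab_validation_error")
  table$cv_from_disp <- 100 * sqrt(table$dispersion)
  table
}

#' Filter candidate reference genes from an RNA-Seq results table
#'
#' Applies four conjunctive filters selecting genes that are (i) not
#' differentially expressed (`padj` strictly above `padj_floor`), (ii) of
#' negligible fold change (`|log2fc|` within `lfc_window`, inclusive),
#' (iii) of moderate dispersion-based variability (`cv_from_disp` inside
#' `cv_range`, inclusive), and (iv) expressed highly enough for qPCR
#' detection (`base_mean >= basemean_floor`). Genes with missing `padj`
#' (e.g. removed by independent filtering) cannot affirmatively satisfy the
#' first criterion and are excluded.
#'
#' @param table Results data.frame with `cv_from_disp` computed
#'   (see [compute_cv_from_dispersion()]).
#' @param padj_floor Adjusted-p floor, default 0.05 (strict `>`).
#' @param lfc_window Half-width of the log2 fold-change window, default 0.1.
#' @param cv_range Length-2 inclusive range for `cv_from_disp`, default
#'   `c(10, 20)` percent.
#' @param basemean_floor Minimum mean normalized count, default 500.
#' @return The retained rows, in the input order. An empty result raises a
#'   warning, not an error.
#' @export
filter_reference_candidates <- function(table, padj_floor = 0.05,
                                        lfc_window = 0.1,
                                        cv_range = c(10, 20),
                                        basemean_floor = 500) {
  if (!"cv_from_disp" %in% names(table))
    stop_refstab("cv_from_disp not computed; call compute_cv_from_dispersion() first",
                 class = "refstab_validation_error")
  keep <- !is.na(table$padj) & table$padj > padj_floor &
    table$log2fc >= -lfc_window & table$log2fc <= lfc_window &
    !is.na(table$cv_from_disp) &
    table$cv_from_disp >= cv_range[1L] & table$cv_from_disp <= cv_range[2L] &
    table$base_mean >= basemean_floor
  out <- table[which(keep), , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no genes passed the reference-candidate filters")
  rownames(out) <- NULL
  out
}

#' Quartile-stratified selection of a candidate panel
#'
#' Ranks the filtered pool by mean expression (`base_mean`), partitions the
#' ranks into four quartiles, and draws a fixed number of genes from each so
#' the panel spans low through high expression. The default allocation
#' 3/3/3/1 yields a 10-gene panel.
#'
#' @param pool Filtered results data.frame (see
#'   [filter_reference_candidates()]).
#' @param allocation Integer vector of length 4: genes to draw per quartile.
#' @param strategy `"random"` (seeded uniform sampling without replacement)
#'   or `"lowest_cv"` (smallest `cv_from_disp`, ties by gene id).
#' @param seed Integer seed for the random strategy.
#' @param q1_lowest If `TRUE` (default) quartile 1 holds the lowest
#'   `base_mean` ranks.
#' @return A data.frame of the selected rows with a `quartile` column
#'   (`"Q1"`..`"Q4"`), plus attributes `strategy` and `seed`.
#' @export
select_panel <- function(pool, allocation = c(3L, 3L, 3L, 1L),
                         strategy = c("random", "lowest_cv"), seed = 1L,
                         q1_lowest = TRUE) {
  strategy <- match.arg(strategy)
  if (length(allocation) != 4L)
    stop_refstab("allocation must have length 4",
                 class = "refstab_validation_error")
  n <- nrow(pool)
  if (n < sum(allocation))
    stop_refstab("pool (%d genes) smaller than total allocation (%d)",
                 n, sum(allocation), class = "refstab_selection_error")
  ord <- order(pool$base_mean, pool$gene)
  if (!q1_lowest) ord <- rev(ord)
  ranks <- integer(n); ranks[ord] <- seq_len(n)
  # rank quartiles; remainder ranks go to the lower quartiles
  qsize <- n %/% 4L + as.integer(1:4 <= n %% 4L)
  quartile <- rep(1:4, times = qsize)[ranks]
  picked <- vector("list", 4L)
  if (strategy == "random") {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  for (q in 1:4) {
    in_q <- which(quartile == q)
    if (length(in_q) < allocation[q])
      stop_refstab("quartile Q%d holds %d gene(s), fewer than its allocation %d",
                   q, length(in_q), allocation[q],
                   class = "refstab_selection_error")
    picked[[q]] <- if (allocation[q] == 0L) integer(0)
    else if (strategy == "random") in_q[sample.int(length(in_q), allocation[q])]
    else in_q[order(pool$cv_from_disp[in_q], pool$gene[in_q])[seq_len(allocation[q])]]
  }
  out <- pool[unlist(picked), , drop = FALSE]
  out$quartile <- paste0("Q", rep(1:4, times = vapply(picked, length, 1L)))
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy
  attr(out, "seed") <- if (strategy == "random") seed else NA_integer_
  out
}

#' Select differentially expressed target genes
#'
#' Retains significantly regulated genes (`padj < padj_ceiling`) whose log2
#' fold change exceeds `+lfc_cut` (up list) or falls below `-lfc_cut` (down
#' list), both strictly, then draws `n_per_direction` genes from each list
#' with a seeded uniform sample.
#'
#' @param table Results data.frame.
#' @param padj_ceiling Significance ceiling, default 0.05 (strict `<`).
#' @param lfc_cut Fold-change cut in log2 units, default 0.6 (strict).
#' @param n_per_direction Genes to draw per direction, default 3.
#' @param seed Integer seed.
#' @return List with elements `up` and `down` (character gene ids) and the
#'   full passing pools `up_pool`, `down_pool`.
#' @export
select_targets <- function(table, padj_ceiling = 0.05, lfc_cut = 0.6,
                           n_per_direction = 3L, seed = 1L) {
  sig <- !is.na(table$padj) & table$padj < padj_ceiling
  up_pool <- table$gene[sig & table$log2fc > lfc_cut]
  down_pool <- table$gene[sig & table$log2fc < -lfc_cut]
  if (length(up_pool) < n_per_direction)
    stop_refstab("only %d upregulated gene(s) pass; %d requested",
                 length(up_pool), n_per_direction,
                 class = "refstab_selection_error")
  if (length(down_pool) < n_per_direction)
    stop_refstab("only %d downregulated gene(s) pass; %d requested",
                 length(down_pool), n_per_direction,
                 class = "refstab_selection_error")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  list(up = sort(sample(up_pool, n_per_direction)),
       down = sort(sample(down_pool, n_per_direction)),
       up_pool = up_pool, down_pool = down_pool)
}
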