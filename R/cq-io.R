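#' Read a long-format Cq table
#'
#' Reads raw technical-replicate quantification-cycle (Cq) measurements from a
#' delimited text file. The table must be in long format with one row per
#' technical replicate, carrying the gene, the biological sample, the
#' experimental group of that sample, a replicate index, and the Cq value.
#'
#' Rows with an empty or non-numeric Cq cell are dropped with a message giving
#' the count: an undetermined well is a routine qPCR outcome, not an error.
#' Structural problems (missing columns, duplicated replicates, a sample
#' assigned to two groups) are errors.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param columns Named character vector mapping the required fields
#'   (`gene`, `sample`, `group`, `replicate`, `cq`) to the column names used
#'   in the file. Defaults to those names themselves.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` are read as tab-delimited, anything else as CSV).
#'
#' @return A `data.frame` of class `cq_table` with columns `gene`, `sample`,
#'   `group`, `replicate` and `cq`, validated so that each
#'   (gene, sample, replicate) triple is unique and each sample belongs to
#'   exactly one group. The number of dropped blank-Cq rows is attached as
#'   attribute `n_dropped`.
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(gene = "ACTB", sample = "s1", group = "WT",
#'                      replicate = 1:3, cq = c(20.1, 20.2, 20.15)),
#'           tf, row.names = FALSE)
#' cq <- read_cq_table(tf)
#' nrow(cq)
#' @export
read_cq_table <- function(path,
                          columns = c(gene = "gene", sample = "sample",
                                      group = "group", replicate = "replicate",
                                      cq = "cq"),
                          sep = NULL) {
  if (!file.exists(path))
    stop_refstab("file not found: %s", path, class = "refstab_io_error")
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"")
  required <- c("gene", "sample", "group", "replicate", "cq")
  defaults <- stats::setNames(required, required)
  defaults[names(columns)] <- columns
  columns <- defaults
  missing_cols <- setdiff(unname(columns[required]), names(raw))
  if (length(missing_cols))
    stop_refstab("missing required column(s): %s",
                 paste(missing_cols, collapse = ", "),
                 class = "refstab_format_error")
  df <- data.frame(gene = raw[[columns["gene"]]],
                   sample = raw[[columns["sample"]]],
                   group = raw[[columns["group"]]],
                   replicate = as.integer(raw[[columns["replicate"]]]),
                   cq = suppressWarnings(as.numeric(raw[[columns["cq"]]])),
                   stringsAsFactors = FALSE)
  blank <- is.na(df$cq) | !is.finite(df$cq)
  if (any(blank)) {
    message(sprintf("read_cq_table: dropped %d row(s) with empty or non-numeric Cq",
                    sum(blank)))
    df <- df[!blank, , drop = FALSE]
  }
  out <- validate_cq_table(df)
  attr(out, "n_dropped") <- sum(blank)
  out
}

#' Construct and validate a Cq table from a data frame
#'
#' @param df A data.frame with columns `gene`, `sample`, `group`, `replicate`
#'   and `cq` (one row per technical replicate).
#' @return The validated data.frame with class `cq_table`.
#' @export
validate_cq_table <- function(df) {
  needed <- c("gene", "sample", "group", "replicate", "cq")
  if (!all(needed %in% names(df)))
    stop_refstab("cq table needs columns: %s", paste(needed, collapse = ", "),
                 class = "refstab_format_error")
  if (any(!is.finite(df$cq)) || any(df$cq <= 0))
    stop_refstab("all cq values must be finite and > 0",
                 class = "refstab_validation_error")
  key <- paste(df$gene, df$sample, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop_refstab("duplicate (gene, sample, replicate) rows present",
                 class = "refstab_validation_error")
  smp_grp <- unique(df[, c("sample", "group")])
  if (anyDuplicated(smp_grp$sample))
    stop_refstab("sample(s) mapped to more than one group: %s",
                 paste(unique(smp_grp$sample[duplicated(smp_grp$sample)]),
                       collapse = ", "),
                 class = "refstab_validation_error")
  rownames(df) <- NULL
  class(df) <- c("cq_table", "data.frame")
  df
}

#' Group map of a Cq table
#'
#' @param cq A `cq_table`.
#' @return Named character vector mapping sample id to group label.
#' @export
cq_groups <- function(cq) {
  smp <- unique(cq[, c("sample", "group")])
  stats::setNames(as.character(smp$group), as.character(smp$sample))
}
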