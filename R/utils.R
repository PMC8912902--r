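#' @keywords internal
"_PACKAGE"

## internal helpers shared across the pipeline

stop_refstab <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "refstab_error")))
}

## group map: named character vector sample_id -> group label
as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    nm <- intersect(c("sample", "sample_id"), names(groups))
    gm <- intersect(c("group"), names(groups))
    if (length(nm) == 0L || length(gm) == 0L)
      stop_refstab("group map data.frame needs 'sample' and 'group' columns",
                   class = "refstab_validation_error")
    out <- as.character(groups[[gm[1L]]])
    names(out) <- as.character(groups[[nm[1L]]])
    return(out)
  }
  if (is.factor(groups)) groups <- as.character(groups)
  if (is.null(names(groups)))
    stop_refstab("group map must be named by sample id",
                 class = "refstab_validation_error")
  groups
}

check_group_sizes <- function(gm, min_per_group = 2L) {
  tab <- table(gm)
  if (any(tab < min_per_group))
    stop_refstab("every group needs >= %d samples (violated by: %s)",
                 min_per_group,
                 paste(names(tab)[tab < min_per_group], collapse = ", "),
                 class = "refstab_validation_error")
  invisible(tab)
}

## geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))
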