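#' Filter low-fraction haplotype calls as PCR/sequencing artifacts
#'
#' Chimeric molecules formed by PCR template switching, polymerase
#' misincorporations and sequencing errors produce spurious haplotype calls
#' at low frequency. Within each (sample, amplicon, direction class) group
#' the fraction of every haplotype is computed on the group's pre-filter
#' total, and rows with fraction strictly below `threshold` are removed.
#'
#' Filtering is single-pass: fractions are never recomputed on retained
#' totals, matching a one-shot exclusion rule, and retained counts are left
#' unchanged (downstream frequency computations use retained totals). As a
#' consequence the operation is not guaranteed idempotent if fractions are
#' recomputed after filtering. A threshold of `1/n` can only create false
#' negatives in samples carrying more than `n` copies, so the default 0.10
#' suits loci whose copy number rarely exceeds 10; pooling several
#' independent PCRs justifies a lower threshold (e.g. 0.06) because it
#' dilutes chimeras that arise early in any single reaction.
#'
#' @param table an [hc_table()].
#' @param threshold exclusion threshold in (0, 1); default 0.10, or 0.06
#'   when `pooled_replicates = TRUE`.
#' @param pooled_replicates set to `TRUE` when the input pools independent
#'   PCR replicates; only switches the default threshold.
#' @return list with `table` (the filtered [hc_table()]) and `report`, a
#'   list holding `threshold`, `n_excluded`, `n_total` (input rows),
#'   `excluded_fraction` (of total calls, not rows), and `excluded_rows`.
#' @examples
#' tab <- hc_table(data.frame(
#'   sample = "NA18502", amplicon = "F5", direction_class = "forward_partial",
#'   haplotype = c("TCC", "CCC", "CCG"), count = c(182L, 21L, 7L)))
#' filter_fractions(tab, 0.10)$report$excluded_rows$haplotype  # "CCG"
#' @export
filter_fractions <- function(table,
                             threshold = if (pooled_replicates) 0.06 else 0.10,
                             pooled_replicates = FALSE) {
  stopifnot(inherits(table, "hc_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number in (0, 1)", call. = FALSE)
  }
  df <- hc_fractions(table)
  keep <- df$fraction >= threshold | is.na(df$fraction)
  excluded <- df[!keep, , drop = FALSE]
  retained <- df[keep, setdiff(names(df), "fraction"), drop = FALSE]
  report <- list(
    threshold = threshold,
    n_excluded = nrow(excluded),
    n_excluded_calls = sum(excluded$count),
    n_total = nrow(df),
    excluded_fraction = if (sum(df$count) > 0)
      sum(excluded$count) / sum(df$count) else 0,
    excluded_rows = excluded
  )
  list(table = hc_table(retained, provenance = attr(table, "provenance")),
       report = report)
}

#' Write a filter report as TSV
#'
#' @param report the `report` element returned by [filter_fractions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold\t%g", report$threshold), con)
  writeLines(sprintf("# n_excluded\t%d", report$n_excluded), con)
  writeLines(sprintf("# n_total\t%d", report$n_total), con)
  writeLines(sprintf("# excluded_call_fraction\t%.6f",
                     report$excluded_fraction), con)
  utils::write.table(report$excluded_rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
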