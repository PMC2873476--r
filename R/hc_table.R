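#' Haplotype-call (HC) tables
#'
#' An HC table tabulates, per sample, amplicon and direction class, how many
#' reads supported each haplotype string. It is the central intermediate of
#' the pipeline: produced by [call_haplotypes()], cleaned by
#' [filter_fractions()], and consumed by the copy-number and merge modules.
#'
#' `direction_class` is one of
#' * `"full"` — the read spanned every MSV of its amplicon;
#' * `"forward_partial"` — the read spanned exactly the amplicon's
#'   forward-read MSV set;
#' * `"reverse_partial"` — likewise for the reverse-read set.
#'
#' @param records data.frame with columns `sample`, `amplicon`,
#'   `direction_class`, `haplotype`, `count`.
#' @param provenance free-text run label stored as an attribute.
#' @return a data.frame of class `hc_table`.
#' @export
hc_table <- function(records = data.frame(sample = character(),
                                          amplicon = character(),
                                          direction_class = character(),
                                          haplotype = character(),
                                          count = integer()),
                     provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("sample", "amplicon", "direction_class", "haplotype", "count")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("hc_table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- records[needed]
  rownames(records) <- NULL
  records$haplotype <- toupper(records$haplotype)
  records$count <- as.integer(records$count)
  validate_hc_table(records)
  structure(records, class = c("hc_table", "data.frame"),
            provenance = provenance)
}

validate_hc_table <- function(records) {
  if (nrow(records) == 0L) return(invisible(records))
  if (any(is.na(records$count)) || any(records$count < 1L)) {
    stop("hc_table counts must be positive integers", call. = FALSE)
  }
  ok_class <- c("full", "forward_partial", "reverse_partial")
  bad <- setdiff(unique(records$direction_class), ok_class)
  if (length(bad)) {
    stop("invalid direction_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- do.call(paste, c(records[c("sample", "amplicon", "direction_class",
                                    "haplotype")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop("duplicate hc_table row(s), e.g. ",
         paste(dup$sample[1], dup$amplicon[1], dup$direction_class[1],
               dup$haplotype[1]), call. = FALSE)
  }
  invisible(records)
}

#' @export
print.hc_table <- function(x, ...) {
  cat(sprintf("<hc_table> %d rows, %d samples, %d amplicons%s\n", nrow(x),
              length(unique(x$sample)), length(unique(x$amplicon)),
              if (nzchar(attr(x, "provenance") %||% ""))
                paste0("  [", attr(x, "provenance"), "]") else ""))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Read / write HC tables as TSV
#'
#' Plain UTF-8 TSV with header
#' `sample  amplicon  direction_class  haplotype  count`; counts are plain
#' integers and decimals use dots (counts printed with European thousands
#' separators in source tables must be normalized before import).
#' `read_hc_table(write_hc_table(x, path))` is the identity.
#'
#' @param table an [hc_table()].
#' @param path file path.
#' @return `write_hc_table` returns `path` invisibly; `read_hc_table`
#'   returns an [hc_table()].
#' @export
write_hc_table <- function(table, path) {
  stopifnot(inherits(table, "hc_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hc_table
#' @param provenance run label to attach; defaults to the file name.
#' @export
read_hc_table <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("HC table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "character", "integer"))
  hc_table(df, provenance = provenance)
}

#' Per-group haplotype fractions
#'
#' Adds a `fraction` column: each row's count divided by the total count of
#' its (sample, amplicon, direction_class) group.
#'
#' @param table an [hc_table()].
#' @return the table with an extra `fraction` column (plain data.frame).
#' @export
hc_fractions <- function(table) {
  df <- as.data.frame(table)
  if (nrow(df) == 0L) {
    df$fraction <- numeric()
    return(df)
  }
  key <- interaction(df$sample, df$amplicon, df$direction_class, drop = TRUE)
  totals <- tapply(df$count, key, sum)
  df$fraction <- df$count / as.numeric(totals[as.character(key)])
  df
}
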