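#' Read sequencing reads from FASTA or FASTQ
#'
#' Thin wrapper around Biostrings readers. The dialect is detected from the
#' first non-empty byte (`>` FASTA, `@` FASTQ); gzip input is handled
#' transparently. FASTQ input is returned as a
#' [Biostrings::QualityScaledDNAStringSet] (qualities retained, though the
#' caller ignores them), FASTA as a plain [Biostrings::DNAStringSet].
#' An empty file yields an empty set, not an error.
#'
#' @param path path to a FASTA/FASTQ file, optionally gzipped.
#' @return a `DNAStringSet` (FASTA) or `QualityScaledDNAStringSet` (FASTQ),
#'   named by read id.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  first <- ""
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) break
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1L, 1L); break }
  }
  if (first == "") {
    return(Biostrings::DNAStringSet())
  }
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                stop("file '", path, "' is neither FASTA nor FASTQ ",
                     "(first record starts with '", first, "')",
                     call. = FALSE))
  reads <- tryCatch({
    if (fmt == "fastq") {
      # Biostrings warns that FASTQ metadata columns are dropped; the ids
      # are all we keep anyway
      withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path),
        warning = function(w) {
          if (grepl("metadata columns", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    } else {
      Biostrings::readDNAStringSet(path, format = "fasta")
    }
  }, error = function(e) {
    stop("failed to parse ", fmt, " file '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  # keep only the id token of the description line
  names(reads) <- sub("\\s.*$", "", names(reads))
  reads
}

#' Write reads to FASTQ
#'
#' Reads without qualities are written with a constant Q30-equivalent
#' quality string.
#'
#' @param reads a `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @param path output path (`.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!methods::is(reads, "QualityScaledDNAStringSet")) {
    quals <- Biostrings::PhredQuality(
      vapply(Biostrings::width(reads),
             function(w) paste(rep("?", w), collapse = ""), character(1)))
    reads <- Biostrings::QualityScaledDNAStringSet(reads, quals)
  }
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              compress = grepl("\\.gz$", path),
                              qualities = methods::slot(reads, "quality"))
  invisible(path)
}
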