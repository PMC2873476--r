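#' Bundled beta-defensin (DEFB) amplicon panel
#'
#' Six amplicons (F2, F4-F8) covering 26 MSVs of the copy-number variable
#' beta-defensin cluster at 8p23.1, totalling 1,498 bp of amplicon
#' sequence (~17 MSV/kb). The MSV structure — amplicon membership, allele
#' sets, the split forward (MSVs 6-8) / reverse (MSVs 7-10a) read coverage
#' of the 340-bp F5 amplicon — mirrors the published haplotype tables.
#' The reference sequences and MSV offsets themselves are synthetic,
#' deterministically generated stand-ins, since the original primer and
#' coordinate tables are not redistributed; genomic positions are included
#' only for MSV9a and MSV10a, whose hg18 coordinates are published.
#'
#' @return an [amplicon_panel()].
#' @export
defb_panel <- function() {
  load_panel(system.file("extdata", "defb_panel.yaml", package = "amplihap",
                         mustWork = TRUE))
}

#' Published haplotype-call count tables
#'
#' `defb_hc_run1()` returns the haplotype-call counts of the first
#' sequencing run — 11 lymphoblastoid cell line samples, amplicons F2 and
#' F4-F8, with F5 tabulated as separate forward (MSVs 6-8) and reverse
#' (MSVs 7-10a) partial calls. It includes the 7-call F5-forward CCG
#' haplotype of NA18502 that the 0.10 fraction filter excludes.
#' `defb_hc_run2_f5()` returns the ultra-deep second-run F5 counts for
#' NA12760 and NA18502 (>10,000 forward and >20,000 reverse calls per
#' sample) that confirmed the questionable CTGGGAC and CCGGGAC haplotypes.
#' Counts are normalized to plain integers (the source tables use European
#' thousands separators) and haplotype strings to uppercase.
#'
#' @return an [hc_table()].
#' @export
defb_hc_run1 <- function() {
  read_hc_table(system.file("extdata", "hc_run1.tsv", package = "amplihap",
                            mustWork = TRUE), provenance = "run1")
}

#' @rdname defb_hc_run1
#' @export
defb_hc_run2_f5 <- function() {
  read_hc_table(system.file("extdata", "hc_run2_f5.tsv",
                            package = "amplihap", mustWork = TRUE),
                provenance = "run2")
}

#' External copy-number measurements
#'
#' Absolute DEFB copy numbers per diploid genome for the 11 samples as
#' measured by orthogonal experimental methods (MAPH/REDVR, two paralog
#' ratio test variants, MLPA), consumed by [compare_external()]. Missing
#' measurements are simply absent rows.
#'
#' @return data.frame with columns `sample`, `method`, `cn`.
#' @export
defb_external_cn <- function() {
  utils::read.table(system.file("extdata", "external_cn.tsv",
                                package = "amplihap", mustWork = TRUE),
                    sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric"))
}

#' All bundled fixture tables at once
#'
#' @return list with `panel`, `hc_run1`, `hc_run2_f5`, `external_cn`.
#' @export
make_fixture_tables <- function() {
  list(panel = defb_panel(),
       hc_run1 = defb_hc_run1(),
       hc_run2_f5 = defb_hc_run2_f5(),
       external_cn = defb_external_cn())
}

#' Per-sample F5 directional tables for merging
#'
#' Combines run 1 with the ultra-deep run 2: for the two samples re-sequenced
#' at high depth (NA12760, NA18502) the run-2 F5 counts replace the run-1
#' ones, and run-1 F5 calls are fraction-filtered at `threshold` first.
#' This is the per-sample input from which the complete F5 haplotype
#' catalogue is built.
#'
#' @param threshold artifact filter threshold applied to the run-1 calls
#'   (default 0.10; run-2 samples are deep enough that their minor
#'   haplotypes all clear it).
#' @return named list (by sample) with elements `fwd` and `rev`
#'   (data.frames `haplotype`, `count`).
#' @export
defb_f5_directional <- function(threshold = 0.10) {
  run1 <- filter_fractions(defb_hc_run1(), threshold)$table
  run2 <- defb_hc_run2_f5()
  deep <- unique(run2$sample)
  df1 <- as.data.frame(run1)
  df1 <- df1[df1$amplicon == "F5" & !df1$sample %in% deep, , drop = FALSE]
  df <- rbind(df1, as.data.frame(run2))
  out <- lapply(split(df, df$sample), function(g) {
    list(fwd = g[g$direction_class == "forward_partial",
                 c("haplotype", "count")],
         rev = g[g$direction_class == "reverse_partial",
                 c("haplotype", "count")])
  })
  out
}
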