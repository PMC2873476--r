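# Small panels built in code for unit tests.

# Single-amplicon panel with two MSVs; reference generated deterministically.
tiny_panel <- function(seed = 7) {
  set.seed(seed)
  len <- 120
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  chars[31] <- "G"; chars[30] <- "T"; chars[32] <- "T"   # MSV at offset 30
  chars[81] <- "A"; chars[80] <- "C"; chars[82] <- "C"   # MSV at offset 80
  amplicon_panel(
    amplicons = list(A1 = list(
      amplicon_id = "A1", reference_seq = paste(chars, collapse = ""),
      length = len, msv_ids = c("M1", "M2"),
      forward_set = c("M1", "M2"), reverse_set = c("M1", "M2"))),
    msvs = list(
      M1 = list(msv_id = "M1", amplicon_id = "A1", offset = 30L,
                alleles = c("G", "C"), genomic_positions = numeric(),
                rsid = NA_character_, novelty = "known"),
      M2 = list(msv_id = "M2", amplicon_id = "A1", offset = 80L,
                alleles = c("A", "T"), genomic_positions = numeric(),
                rsid = NA_character_, novelty = "known")))
}

# Panel whose MSV sits inside a reference poly-A run of length 5, for the
# homopolymer-undercall rescue rule.
homopolymer_panel <- function(seed = 11) {
  set.seed(seed)
  len <- 100
  chars <- sample(c("C", "G", "T"), len, replace = TRUE)  # no stray A runs
  chars[48:52] <- "A"                                     # poly-A run
  chars[79] <- "G"; chars[80] <- "C"; chars[81] <- "G"    # isolated MSV2
  amplicon_panel(
    amplicons = list(H1 = list(
      amplicon_id = "H1", reference_seq = paste(chars, collapse = ""),
      length = len, msv_ids = c("M1", "M2"),
      forward_set = c("M1", "M2"), reverse_set = c("M1", "M2"))),
    msvs = list(
      M1 = list(msv_id = "M1", amplicon_id = "H1", offset = 49L,
                alleles = c("A", "G"), genomic_positions = numeric(),
                rsid = NA_character_, novelty = "known"),
      M2 = list(msv_id = "M2", amplicon_id = "H1", offset = 79L,
                alleles = c("C", "T"), genomic_positions = numeric(),
                rsid = NA_character_, novelty = "known")))
}

# Substitute alleles into a panel reference (test-side re-implementation,
# deliberately simpler than the package's: no indel alleles).
hap_seq <- function(panel, amplicon_id, haplotype) {
  amp <- panel$amplicons[[amplicon_id]]
  msvs <- panel_msvs(panel, amplicon_id)
  chars <- strsplit(amp$reference_seq, "")[[1]]
  alleles <- strsplit(haplotype, "")[[1]]
  chars[msvs$offset + 1] <- alleles
  paste(chars, collapse = "")
}

# F5 forward/reverse direction tables for one sample of an hc_table.
f5_dirs <- function(table, sample_id) {
  df <- as.data.frame(table)
  df <- df[df$sample == sample_id & df$amplicon == "F5", ]
  list(fwd = df[df$direction_class == "forward_partial",
                c("haplotype", "count")],
       rev = df[df$direction_class == "reverse_partial",
                c("haplotype", "count")])
}
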