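#' Simulation configuration
#'
#' Parameters of the pyrosequencing-style amplicon read simulator. The
#' defaults emulate the study conditions of a flow-based pyrosequencing
#' amplicon run:
#' reads of about 225 b (normal length model, truncated to
#' `[min_length, amplicon length]`), a small substitution error rate,
#' occasional single-base indels inside homopolymer runs of length >= 3
#' (the characteristic pyrosequencing flow artifact), PCR template-switch
#' chimeras, a reverse:forward depth skew, and a truncation process that
#' produces the short reads exercising the partial-span omission rule.
#'
#' @param reads_per_amplicon reads generated per amplicon (default 2000).
#' @param error_rate per-base substitution probability (default 0.004,
#'   i.e. ~99.6% per-base accuracy typical of the platform).
#' @param homopolymer_indel_rate per-run probability of a single-base
#'   insertion or deletion in each homopolymer run of length >= 3
#'   (default 0.002).
#' @param chimera_rate probability that a read derives from a PCR
#'   template-switch product of two copies (default 0.01).
#' @param direction_skew expected reverse:forward read ratio (default 1.0;
#'   1.7 reproduces the skew observed on real amplicon data).
#' @param truncation_rate probability that a read is heavily truncated, its
#'   length drawn uniformly from `[min_length, read_length_mean]`
#'   (default 0.05).
#' @param read_length_mean,read_length_sd normal length model (default
#'   225 b, sd 15).
#' @param min_length shortest read emitted (default 40 b).
#' @param seed RNG seed; fixed seed + fixed config gives byte-identical
#'   output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(reads_per_amplicon = 2000L,
                       error_rate = 0.004,
                       homopolymer_indel_rate = 0.002,
                       chimera_rate = 0.01,
                       direction_skew = 1.0,
                       truncation_rate = 0.05,
                       read_length_mean = 225,
                       read_length_sd = 15,
                       min_length = 40L,
                       seed = 1L) {
  rates <- c(error_rate = error_rate,
             homopolymer_indel_rate = homopolymer_indel_rate,
             chimera_rate = chimera_rate, truncation_rate = truncation_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(reads_per_amplicon >= 1L, direction_skew > 0)
  structure(list(reads_per_amplicon = as.integer(reads_per_amplicon),
                 error_rate = error_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 chimera_rate = chimera_rate,
                 direction_skew = direction_skew,
                 truncation_rate = truncation_rate,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 min_length = as.integer(min_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth sample for simulation
#'
#' A simulated diploid sample is a copy composition per amplicon: a named
#' integer vector mapping each haplotype string (over the amplicon's full
#' MSV set) to its copy count. The total copy count is the sample's diploid
#' CN and must be the same for every amplicon of a single-locus model
#' (every repeat unit carries every amplicon).
#'
#' @param sample_id sample label.
#' @param composition named list: amplicon id -> named integer vector
#'   (haplotype string -> copies >= 1).
#' @return list of class `sim_sample` with `diploid_cn`.
#' @export
sim_sample <- function(sample_id, composition) {
  stopifnot(is.list(composition), length(composition) >= 1L)
  cns <- vapply(composition, sum, numeric(1))
  if (length(unique(cns)) != 1L) {
    stop("all amplicons of a sample must share the same total copy number",
         call. = FALSE)
  }
  if (cns[1] < 2) stop("diploid copy number must be >= 2", call. = FALSE)
  if (any(unlist(composition) < 1)) {
    stop("haplotype copy counts must be >= 1", call. = FALSE)
  }
  structure(list(sample_id = sample_id, composition = composition,
                 diploid_cn = as.integer(cns[1])),
            class = "sim_sample")
}

# Substitute MSV alleles into the amplicon reference; "-" alleles delete
# the base. Offsets are applied back-to-front so earlier offsets stay valid.
.instantiate_haplotype <- function(panel, amplicon_id, haplotype) {
  msvs <- panel_msvs(panel, amplicon_id)
  hap <- toupper(haplotype)
  if (nchar(hap) != nrow(msvs)) {
    stop(sprintf(
      "haplotype '%s' has %d alleles but amplicon '%s' declares %d MSVs",
      haplotype, nchar(hap), amplicon_id, nrow(msvs)), call. = FALSE)
  }
  alleles <- strsplit(hap, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(msvs))) {
    if (!alleles[i] %in% msvs$alleles[[i]]) {
      stop(sprintf("allele '%s' not declared for %s (amplicon %s)",
                   alleles[i], msvs$msv_id[i], amplicon_id), call. = FALSE)
    }
  }
  chars <- strsplit(panel$amplicons[[amplicon_id]]$reference_seq, "",
                    fixed = TRUE)[[1L]]
  for (i in rev(seq_len(nrow(msvs)))) {
    pos <- msvs$offset[i] + 1L
    if (alleles[i] == "-") chars <- chars[-pos] else chars[pos] <- alleles[i]
  }
  paste(chars, collapse = "")
}

.rand_base_not <- function(b) {
  sample(setdiff(c("A", "C", "G", "T"), b), 1L)
}

.apply_substitutions <- function(chars, rate) {
  hits <- which(stats::runif(length(chars)) < rate)
  for (h in hits) chars[h] <- .rand_base_not(chars[h])
  chars
}

# One single-base insertion or deletion per affected homopolymer run >= 3.
.apply_homopolymer_indels <- function(chars, rate) {
  if (rate <= 0 || length(chars) < 3L) return(chars)
  r <- rle(chars)
  runs <- which(r$lengths >= 3L)
  if (!length(runs)) return(chars)
  hit <- runs[stats::runif(length(runs)) < rate]
  if (!length(hit)) return(chars)
  ends <- cumsum(r$lengths)
  out <- chars
  for (k in rev(hit)) {            # back-to-front keeps positions valid
    pos <- ends[k]
    if (stats::runif(1) < 0.5) {
      out <- out[-pos]                        # deletion
    } else {
      out <- append(out, r$values[k], after = pos)  # insertion
    }
  }
  out
}

#' Simulate pyrosequencing-style amplicon reads with ground truth
#'
#' For every amplicon in the sample's composition, `reads_per_amplicon`
#' reads are generated: a source copy is drawn proportional to copy counts;
#' with probability `chimera_rate` a template switch at a breakpoint
#' uniform over the gaps between consecutive MSVs joins the source's prefix
#' to a different copy's suffix (switches between identical bases are
#' invisible, so only inter-MSV breakpoints matter); the read direction is
#' drawn from the configured skew; the read is clipped to a length from the
#' (occasionally truncated) length model, from the 5' end for forward and
#' the 3' end for reverse reads; substitution errors and homopolymer indels
#' are applied; reverse reads are emitted as the reverse complement.
#'
#' @param sample a [sim_sample()].
#' @param panel an [amplicon_panel()]; every composition haplotype must
#'   instantiate against it (checked before any read is generated).
#' @param cfg a [sim_config()].
#' @return list with `reads` (a `QualityScaledDNAStringSet` with constant
#'   Q30 qualities) and `truth`, a data.frame with one row per read:
#'   `read_id`, `amplicon`, `hap1`, `hap2` (chimeras only), `is_chimera`,
#'   `breakpoint` (0-based offset of the switch), `direction`, `length`.
#' @export
simulate_reads <- function(sample, panel, cfg = sim_config()) {
  stopifnot(inherits(sample, "sim_sample"), inherits(cfg, "sim_config"))
  # validate and instantiate all haplotypes up front
  templates <- lapply(names(sample$composition), function(aid) {
    if (is.null(panel$amplicons[[aid]])) {
      stop("composition references unknown amplicon '", aid, "'",
           call. = FALSE)
    }
    comp <- sample$composition[[aid]]
    vapply(names(comp), function(h) .instantiate_haplotype(panel, aid, h),
           character(1))
  })
  names(templates) <- names(sample$composition)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  seqs <- character(0)
  truth <- list()
  p_rev <- cfg$direction_skew / (1 + cfg$direction_skew)
  rid <- 0L
  for (aid in names(sample$composition)) {
    comp <- sample$composition[[aid]]
    haps <- names(comp)
    copies <- rep(seq_along(haps), comp)   # one entry per physical copy
    tpl <- templates[[aid]]
    offs <- panel_msvs(panel, aid)$offset
    # chimera breakpoints: one slot per gap between consecutive MSVs;
    # the switch lands midway through the gap
    bp_slots <- if (length(offs) >= 2L)
      floor((offs[-length(offs)] + offs[-1L]) / 2) else integer()
    for (r in seq_len(cfg$reads_per_amplicon)) {
      rid <- rid + 1L
      slot <- sample.int(length(copies), 1L)
      ci <- copies[slot]
      is_chim <- length(copies) > 1L && length(bp_slots) > 0L &&
        stats::runif(1) < cfg$chimera_rate
      hap2 <- NA_character_
      bp <- NA_integer_
      if (is_chim) {
        others <- copies[-slot]               # a different physical copy
        cj <- others[sample.int(length(others), 1L)]
        bp <- bp_slots[sample.int(length(bp_slots), 1L)]
        template <- paste0(substr(tpl[ci], 1L, bp),
                           substr(tpl[cj], bp + 1L, nchar(tpl[cj])))
        hap2 <- haps[cj]
      } else {
        template <- tpl[ci]
      }
      tlen <- nchar(template)
      if (stats::runif(1) < cfg$truncation_rate) {
        len <- floor(stats::runif(1, cfg$min_length,
                                  min(cfg$read_length_mean, tlen) + 1))
      } else {
        len <- round(stats::rnorm(1, cfg$read_length_mean,
                                  cfg$read_length_sd))
      }
      len <- max(cfg$min_length, min(tlen, len))
      direction <- if (stats::runif(1) < p_rev) "-" else "+"
      raw <- if (direction == "+") substr(template, 1L, len)
             else substr(template, tlen - len + 1L, tlen)
      if (cfg$error_rate > 0 || cfg$homopolymer_indel_rate > 0) {
        chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
        chars <- .apply_substitutions(chars, cfg$error_rate)
        chars <- .apply_homopolymer_indels(chars, cfg$homopolymer_indel_rate)
        seq <- paste(chars, collapse = "")
      } else {
        seq <- raw
      }
      if (direction == "-") {
        seq <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      }
      name <- sprintf("%s_%s_%06d", sample$sample_id, aid, rid)
      seqs[name] <- seq
      truth[[rid]] <- data.frame(read_id = name, amplicon = aid,
                                 hap1 = haps[ci], hap2 = hap2,
                                 is_chimera = is_chim, breakpoint = bp,
                                 direction = direction,
                                 length = nchar(seq),
                                 stringsAsFactors = FALSE)
    }
  }
  reads <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::PhredQuality(
    vapply(nchar(seqs), function(w) paste(rep("?", w), collapse = ""),
           character(1)))
  list(reads = Biostrings::QualityScaledDNAStringSet(reads, quals),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Write simulation truth table as TSV
#'
#' @param truth the `truth` element of [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
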