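test_that("a perfect read and its reverse complement assign with identity 1", {
  p <- defb_panel()
  ref <- p$amplicons$F2$reference_seq
  fwd <- align_read(ref, p)
  expect_true(fwd$assigned)
  expect_equal(fwd$amplicon, "F2")
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$identity, 1)
  rev <- align_read(revcomp(ref), p)
  expect_equal(rev$amplicon, "F2")
  expect_equal(rev$strand, "-")
  expect_equal(rev$identity, 1)
})

test_that("too-short and heavily mutated reads are unassigned", {
  p <- defb_panel()
  short <- align_read("ACGTACGTAC", p)
  expect_false(short$assigned)
  expect_equal(short$reason, "too_short")

  set.seed(5)
  ref <- strsplit(p$amplicons$F2$reference_seq, "")[[1]]
  hit <- sample(seq_along(ref), round(0.3 * length(ref)))
  for (h in hit) ref[h] <- sample(setdiff(c("A", "C", "G", "T"), ref[h]), 1)
  mut <- align_read(paste(ref, collapse = ""), p, min_identity = 0.9)
  expect_false(mut$assigned)
  expect_equal(mut$reason, "low_identity")
})

test_that("alignment scores match an exhaustive dynamic-programming oracle", {
  set.seed(99)
  for (rep in 1:25) {
    ref <- random_dna(sample(40:60, 1))
    panel <- amplicon_panel(
      amplicons = list(A1 = list(
        amplicon_id = "A1", reference_seq = ref, length = nchar(ref),
        msv_ids = "M1", forward_set = "M1", reverse_set = "M1")),
      msvs = list(M1 = list(msv_id = "M1", amplicon_id = "A1", offset = 10L,
                            alleles = c("A", "C", "G", "T"))))
    # reads: substrings with substitutions and small indels, or random
    read <- if (rep %% 5 == 0) {
      random_dna(sample(40:55, 1))
    } else {
      s <- substr(ref, sample(1:5, 1), nchar(ref) - sample(0:5, 1))
      ch <- strsplit(s, "")[[1]]
      for (h in sample(seq_along(ch), sample(0:3, 1))) {
        ch[h] <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.5) ch <- ch[-sample(seq_along(ch), 1)]      # deletion
      if (runif(1) < 0.5) {                                        # insertion
        at <- sample(seq_along(ch), 1)
        ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = at)
      }
      paste(ch, collapse = "")
    }
    got <- align_read(read, panel, min_identity = 0, min_length = 10)
    expect_equal(got$score, oracle_best_score(read, panel),
                 info = sprintf("rep %d", rep))
  }
})

test_that("haplotype extraction reads alleles at MSV offsets on both strands", {
  p <- defb_panel()
  seq_ga <- hap_seq(p, "F2", "GA")
  hc <- extract_haplotype(align_read(seq_ga, p), p)
  expect_equal(hc$direction_class, "full")
  expect_equal(hc$haplotype, "GA")
  seq_cg <- hap_seq(p, "F2", "CG")
  hc2 <- extract_haplotype(align_read(seq_cg, p), p)
  expect_equal(hc2$haplotype, "CG")
  # strand invariance on the alternative haplotype
  hc3 <- extract_haplotype(align_read(revcomp(seq_cg), p), p)
  expect_equal(hc3$haplotype, "CG")
})

test_that("F5 partial-span reads classify by direction and orientation", {
  p <- defb_panel()
  full <- hap_seq(p, "F5", "TCCGGGC")
  # forward read covering MSVs 6-8 only (first 225 b)
  fwd <- extract_haplotype(align_read(substr(full, 1, 225), p), p)
  expect_equal(fwd$direction_class, "forward_partial")
  expect_equal(fwd$haplotype, "TCC")
  # reverse read covering MSVs 7-10a only (last 225 b, reverse strand)
  rev <- extract_haplotype(
    align_read(revcomp(substr(full, 340 - 225 + 1, 340)), p), p)
  expect_equal(rev$direction_class, "reverse_partial")
  expect_equal(rev$haplotype, "CCGGGC")
  # a mid-amplicon fragment covering only MSVs 7-8 spans no declared set
  mid <- extract_haplotype(align_read(substr(full, 120, 230), p), p)
  expect_true(is.na(mid$direction_class))
  expect_equal(mid$omit_reason, "span")
  # orientation must agree: a reverse-strand read covering only the
  # forward set is omitted
  wrong <- extract_haplotype(align_read(revcomp(substr(full, 1, 225)), p), p)
  expect_true(is.na(wrong$direction_class))
})

test_that("single-base gaps in homopolymer runs are realigned off the MSV", {
  hp <- homopolymer_panel()
  ref <- hp$amplicons$H1$reference_seq
  # drop one A from the poly-A run: a flow undercall, allele stays A
  undercall <- paste0(substr(ref, 1, 49), substr(ref, 51, 100))
  hc <- extract_haplotype(align_read(undercall, hp, min_length = 30), hp)
  expect_equal(hc$haplotype, paste0("A", substr(ref, 80, 80)))
  # the isolated MSV2 has no homopolymer context: deleting it omits the read
  drop2 <- paste0(substr(ref, 1, 79), substr(ref, 81, 100))
  hc2 <- extract_haplotype(align_read(drop2, hp, min_length = 30), hp)
  expect_true(is.na(hc2$direction_class))
  expect_equal(hc2$omit_reason, "gap")
})

test_that("strand invariance holds across simulated reads", {
  p <- panel_subset(defb_panel(), c("F2", "F4"))
  samp <- sim_sample("SI", list(F2 = c(GA = 1, CG = 1),
                                F4 = c(TAC = 1, CAT = 1)))
  sim <- simulate_reads(samp, p, sim_config(reads_per_amplicon = 60,
                                            error_rate = 0.003,
                                            seed = 21))
  asg <- amplihap:::align_reads(sim$reads, p)
  keep <- which(asg$assigned)[1:30]
  rc <- Biostrings::reverseComplement(sim$reads[keep])
  asg_rc <- amplihap:::align_reads(rc, p)
  for (i in seq_along(keep)) {
    a <- extract_haplotype(asg[keep[i], , drop = FALSE], p)
    b <- extract_haplotype(asg_rc[i, , drop = FALSE], p)
    expect_equal(a$haplotype, b$haplotype)
  }
})

test_that("call_haplotypes obeys the conservation laws and labels amplicons", {
  p <- panel_subset(defb_panel(), c("F2", "F7"))
  samp <- sim_sample("SC", list(F2 = c(GA = 1, CA = 1),
                                F7 = c(TCG = 1, TTA = 1)))
  sim <- simulate_reads(samp, p, sim_config(reads_per_amplicon = 300,
                                            error_rate = 0.004,
                                            truncation_rate = 0.1,
                                            seed = 31))
  res <- call_haplotypes(sim$reads, p, "SC")
  st <- res$stats
  expect_equal(st$n_reads, length(sim$reads))
  expect_equal(st$n_reads, st$n_assigned + st$n_unassigned)
  expect_equal(sum(res$table$count) + st$n_omitted_span, st$n_assigned)
  # truth labels: calls appear only under the amplicon their reads came from
  tab <- as.data.frame(res$table)
  expect_setequal(unique(tab$amplicon), c("F2", "F7"))
  f2 <- tab[tab$amplicon == "F2", ]
  expect_setequal(f2$haplotype[f2$count > 5], c("GA", "CA"))
  f7 <- tab[tab$amplicon == "F7", ]
  expect_setequal(f7$haplotype[f7$count > 5], c("TCG", "TTA"))
})

test_that("ten identical reads give one row with count 10 and full assembly", {
  p <- defb_panel()
  reads <- Biostrings::DNAStringSet(rep(p$amplicons$F2$reference_seq, 10))
  names(reads) <- paste0("r", 1:10)
  res <- call_haplotypes(reads, p, "S")
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$table$count, 10L)
  expect_equal(res$stats$assembly_fraction, 1)
})

test_that("noiseless equal-copy haplotypes split counts binomially", {
  p <- panel_subset(defb_panel(), "F2")
  samp <- sim_sample("SB", list(F2 = c(GA = 1, CA = 1)))
  sim <- simulate_reads(samp, p, sim_config(reads_per_amplicon = 1000,
                                            error_rate = 0,
                                            homopolymer_indel_rate = 0,
                                            chimera_rate = 0,
                                            truncation_rate = 0,
                                            seed = 77))
  res <- call_haplotypes(sim$reads, p, "SB")
  tab <- as.data.frame(res$table)
  expect_setequal(tab$haplotype, c("GA", "CA"))
  n <- sum(tab$count)
  # binomial oracle: |count - n/2| within 3 sd of Binomial(n, 1/2)
  expect_lt(abs(tab$count[1] - n / 2), 3 * sqrt(n * 0.25))
})
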