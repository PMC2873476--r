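test_that("a single forward/reverse pair concatenates with flow 1", {
  res <- merge_directional(data.frame(haplotype = "TCC", count = 100L),
                           data.frame(haplotype = "CCGGGC", count = 180L),
                           overlap = 2)
  expect_equal(nrow(res), 1L)
  expect_equal(res$haplotype, "TCCGGGC")
  expect_equal(res$flow, 1)
  expect_equal(attr(res, "mismatch"), 0)
  # mixed-case reverse strings are display conventions only
  res2 <- merge_directional(data.frame(haplotype = "TCC", count = 1L),
                            data.frame(haplotype = "CCGgGc", count = 1L),
                            overlap = 2)
  expect_equal(res2$haplotype, "TCCGGGC")
})

test_that("the questionable minor haplotype CTGGGAC emerges from the merge", {
  # NA12760-like: CTG pairs only with the TG-overlap reverse haplotype
  fwd <- data.frame(haplotype = c("TCC", "CCC", "CTG"),
                    count = c(795L, 181L, 184L))
  rev <- data.frame(haplotype = c("CCGGGC", "CCGGAC", "TGGGAC"),
                    count = c(1566L, 339L, 459L))
  res <- merge_directional(fwd, rev, overlap = 2)
  expect_equal(nrow(res), 3L)
  expect_true("CTGGGAC" %in% res$haplotype)
  expect_setequal(res$haplotype, c("TCCGGGC", "CCCGGAC", "CTGGGAC"))
})

test_that("forward mass splits across compatible reverse haplotypes", {
  # NA15029: TCC must feed both CC-overlap reverse haplotypes
  fwd <- data.frame(haplotype = c("TCC", "CTG"), count = c(767L, 475L))
  rev <- data.frame(haplotype = c("CCGGGC", "CCAGGC", "TGGGAC"),
                    count = c(1046L, 431L, 913L))
  res <- merge_directional(fwd, rev, overlap = 2)
  expect_equal(nrow(res), 3L)
  expect_setequal(res$haplotype, c("TCCGGGC", "TCCAGGC", "CTGGGAC"))
  tcc_rows <- res[startsWith(res$haplotype, "TCC"), ]
  expect_equal(sum(tcc_rows$flow), 767 / 1242, tolerance = 1e-6)
  # flows approximate the reverse-side frequencies on the split arcs
  expect_equal(res$flow[res$haplotype == "TCCAGGC"], 431 / 2390,
               tolerance = 0.01)
})

test_that("orphan directional haplotypes raise an informative error", {
  fwd <- data.frame(haplotype = c("TCC", "CCC"), count = c(9L, 1L))
  rev <- data.frame(haplotype = c("CCGGGC", "CGGGAC"), count = c(9L, 1L))
  expect_error(merge_directional(fwd, rev, overlap = 2), "CGGGAC")
})

test_that("minimum support matches exhaustive search on random instances", {
  set.seed(515)
  for (rep in 1:15) {
    nf <- sample(2:4, 1)
    nr <- sample(2:5, 1)
    # overlap alphabet of size 2 gives realistic arc sparsity; make sure
    # every overlap value occurs on both sides (no orphans)
    fov <- sample(c("AC", "GT"), nf, replace = TRUE)
    rov <- sample(c("AC", "GT"), nr, replace = TRUE)
    for (v in setdiff(fov, rov)) rov[sample.int(nr, 1)] <- v
    for (v in setdiff(rov, fov)) fov[sample.int(nf, 1)] <- v
    for (v in setdiff(fov, rov)) rov[sample.int(nr, 1)] <- v
    fwd <- data.frame(
      haplotype = paste0(sample(c("A", "C", "G", "T"), nf), fov),
      count = sample.int(900L, nf))
    rev <- data.frame(
      haplotype = paste0(rov,
                         vapply(seq_len(nr), function(i)
                           paste(sample(c("A", "C", "G", "T"), 3, TRUE),
                                 collapse = ""), character(1))),
      count = sample.int(900L, nr))
    if (anyDuplicated(fwd$haplotype) || anyDuplicated(rev$haplotype)) next
    got <- merge_directional(fwd, rev, overlap = 2, slack = 2)
    sf <- fwd$count / sum(fwd$count)
    sr <- rev$count / sum(rev$count)
    arcs <- expand.grid(i = seq_len(nf), j = seq_len(nr))
    arcs <- arcs[substr(fwd$haplotype[arcs$i], 2, 3) ==
                 substr(rev$haplotype[arcs$j], 1, 2), ]
    want <- oracle_min_support(sf, sr, arcs)
    expect_equal(nrow(got), want$support_size,
                 info = sprintf("rep %d support", rep))
    expect_equal(sum(got$flow), want$flow, tolerance = 1e-9,
                 info = sprintf("rep %d flow", rep))
  }
})

test_that("merge output respects overlap consistency and flow conservation", {
  dirs <- defb_f5_directional()
  for (sid in names(dirs)) {
    res <- suppressWarnings(
      merge_directional(dirs[[sid]]$fwd, dirs[[sid]]$rev, overlap = 2))
    # overlap alleles of each complete haplotype match both parents
    expect_true(all(substr(res$fwd, 2, 3) == substr(res$rev, 1, 2)))
    expect_true(all(res$haplotype ==
                      paste0(res$fwd, substr(res$rev, 3, 8))))
    expect_true(all(res$flow > 0))
    # transported mass cannot exceed either margin
    expect_lte(sum(res$flow), 1 + 1e-9)
    expect_equal(sum(res$flow) + attr(res, "mismatch") / 2, 1,
                 tolerance = 1e-9)
  }
})

test_that("noiseless simulated F5 reads round-trip through the merge", {
  p <- panel_subset(defb_panel(), "F5")
  truth_haps <- c(TCCGGGC = 2, CTGGGAC = 1, CCCGGAC = 2)
  samp <- sim_sample("RT", list(F5 = truth_haps))
  sim <- simulate_reads(samp, p, sim_config(reads_per_amplicon = 1500,
                                            error_rate = 0,
                                            homopolymer_indel_rate = 0,
                                            chimera_rate = 0,
                                            truncation_rate = 0,
                                            seed = 88))
  res <- call_haplotypes(sim$reads, p, "RT")
  d <- f5_dirs(res$table, "RT")
  merged <- merge_directional(d$fwd, d$rev, overlap = 2)
  expect_setequal(merged$haplotype, names(truth_haps))
  # flows approximate the true copy fractions
  expect_equal(merged$flow[match(names(truth_haps), merged$haplotype)],
               unname(truth_haps) / 5, tolerance = 0.08)
})

test_that("collapse_panel unions haplotypes across samples", {
  m1 <- merge_directional(data.frame(haplotype = "TCC", count = 10L),
                          data.frame(haplotype = "CCGGGC", count = 9L),
                          overlap = 2)
  m2 <- merge_directional(data.frame(haplotype = c("TCC", "CCC"),
                                     count = c(6L, 4L)),
                          data.frame(haplotype = c("CCGGGC", "CCGGAC"),
                                     count = c(6L, 4L)),
                          overlap = 2)
  cat_ <- collapse_panel(list(S1 = m1, S2 = m2))
  expect_equal(nrow(cat_), 2L)   # TCCGGGC shared between samples: one row
  expect_setequal(cat_$haplotype, c("TCCGGGC", "CCCGGAC"))
  expect_equal(cat_$n_samples[cat_$haplotype == "TCCGGGC"], 2L)
  one <- collapse_panel(list(S1 = m1))
  expect_equal(nrow(one), 1L)
})

test_that("long-range joins pick modal haplotypes in panel order", {
  p <- defb_panel()
  tab <- filter_fractions(defb_hc_run1(), 0.10)$table
  res <- long_range_join(tab, p, samples = "C0913")
  expect_equal(res$joined$haplotype,
               "CA|TAC|TCCGGGC|CCTCG|TCG|CTACCG")
  expect_false(res$joined$ambiguous)
  # samples lacking an amplicon are excluded with a reason
  res2 <- long_range_join(tab, p, samples = c("C0913", "NA19140"))
  expect_equal(res2$excluded$sample, "NA19140")
  expect_match(res2$excluded$reason, "missing amplicon")
  # modal tie: two joined strings, flagged ambiguous
  tie <- hc_table(data.frame(sample = "T", amplicon = "F2",
                             direction_class = "full",
                             haplotype = c("GA", "CA"), count = c(5L, 5L)))
  res3 <- long_range_join(tie, p, samples = "T", amplicons = "F2")
  expect_equal(nrow(res3$joined), 2L)
  expect_true(all(res3$joined$ambiguous))
})
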