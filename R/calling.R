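#' Semi-global alignment scoring used for read assignment
#'
#' Reads are assigned by semi-global (fitting) alignment: the read is aligned
#' end-to-end against the best-matching window of each amplicon reference,
#' with free end gaps on the reference side only. Scoring is match +1,
#' mismatch -1, and an affine gap penalty of -2 for the first gapped base and
#' -1 for each additional base of the same gap. Identity is the fraction of
#' matching columns over all alignment columns (gaps included).
#'
#' @keywords internal
#' @name alignment-scoring
NULL

.ALIGN_DEFAULTS <- list(min_identity = 0.90, min_length = 40L)

.subst_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

.identity_of <- function(aln) {
  ni <- Biostrings::nindel(aln)
  cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ni)[, "WidthSum"] +
    Biostrings::deletion(ni)[, "WidthSum"]
  Biostrings::nmatch(aln) / cols
}

# Vectorized assignment of many reads against a panel.
# Returns a data.frame with one row per read:
#   read_id, assigned, reason, amplicon, strand, score, identity,
#   aligned_view (read bases in full reference coordinates, "-" for
#   deletions and for uncovered flanks), subj_start, subj_end
align_reads <- function(reads, panel,
                        min_identity = .ALIGN_DEFAULTS$min_identity,
                        min_length = .ALIGN_DEFAULTS$min_length) {
  if (length(panel$amplicons) == 0L) stop("empty panel", call. = FALSE)
  if (!methods::is(reads, "DNAStringSet")) {
    reads <- Biostrings::DNAStringSet(reads)
  }
  n <- length(reads)
  ids <- names(reads) %||% as.character(seq_len(n))
  out <- data.frame(read_id = ids, assigned = FALSE, reason = NA_character_,
                    amplicon = NA_character_, strand = NA_character_,
                    score = NA_real_, identity = NA_real_,
                    aligned_view = NA_character_,
                    subj_start = NA_integer_, subj_end = NA_integer_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  short <- Biostrings::width(reads) < min_length
  out$reason[short] <- "too_short"
  idx <- which(!short)
  if (length(idx) == 0L) return(out)

  sm <- .subst_matrix()
  amp_ids <- sort(names(panel$amplicons))
  pats <- list(`+` = reads[idx],
               `-` = Biostrings::reverseComplement(reads[idx]))
  combos <- expand.grid(amplicon = amp_ids, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  scores <- matrix(-Inf, nrow = length(idx), ncol = nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    subj <- Biostrings::DNAString(
      panel$amplicons[[combos$amplicon[ci]]]$reference_seq)
    scores[, ci] <- Biostrings::pairwiseAlignment(
      pats[[combos$strand[ci]]], subj, type = "global-local",
      substitutionMatrix = sm, gapOpening = 1, gapExtension = 1,
      scoreOnly = TRUE)
  }
  best_score <- apply(scores, 1L, max)

  # candidate set per read: all combos within 1e-9 of the best score; ties
  # resolved by identity, then amplicon id, then "+" strand
  tol <- 1e-9
  cand <- scores >= best_score - tol
  pick <- integer(length(idx))
  unique_cand <- rowSums(cand) == 1L
  pick[unique_cand] <- apply(cand[unique_cand, , drop = FALSE], 1L, which)

  tie_rows <- which(!unique_cand)
  if (length(tie_rows)) {
    combo_order <- order(combos$amplicon, combos$strand != "+")
    for (r in tie_rows) {
      tied <- which(cand[r, ])
      idents <- vapply(tied, function(ci) {
        subj <- Biostrings::DNAString(
          panel$amplicons[[combos$amplicon[ci]]]$reference_seq)
        .identity_of(Biostrings::pairwiseAlignment(
          pats[[combos$strand[ci]]][r], subj, type = "global-local",
          substitutionMatrix = sm, gapOpening = 1, gapExtension = 1))
      }, numeric(1))
      ord <- order(-idents, match(tied, combo_order))
      pick[r] <- tied[ord[1L]]
    }
  }

  # full alignments per winning combo
  for (ci in sort(unique(pick))) {
    rows <- which(pick == ci)
    subj <- Biostrings::DNAString(
      panel$amplicons[[combos$amplicon[ci]]]$reference_seq)
    for (chunk in split(rows, ceiling(seq_along(rows) / 5000))) {
      aln <- Biostrings::pairwiseAlignment(
        pats[[combos$strand[ci]]][chunk], subj, type = "global-local",
        substitutionMatrix = sm, gapOpening = 1, gapExtension = 1)
      rng <- methods::slot(Biostrings::subject(aln), "range")
      orows <- idx[chunk]
      out$amplicon[orows] <- combos$amplicon[ci]
      out$strand[orows] <- combos$strand[ci]
      out$score[orows] <- Biostrings::score(aln)
      out$identity[orows] <- .identity_of(aln)
      out$aligned_view[orows] <- as.character(Biostrings::aligned(aln))
      out$subj_start[orows] <- IRanges::start(rng)
      out$subj_end[orows] <- IRanges::end(rng)
    }
  }
  assigned <- !is.na(out$identity) & out$identity >= min_identity
  out$assigned <- assigned
  out$reason[!assigned & is.na(out$reason)] <- "low_identity"
  out
}

#' Assign a single read to an amplicon and strand
#'
#' Aligns the read (and its reverse complement) semi-globally against every
#' amplicon reference and returns the best assignment, or an unassigned
#' record when the best identity falls below `min_identity` or the read is
#' shorter than `min_length`. Ties on score are broken by higher identity,
#' then lexicographic amplicon id, then the `+` strand.
#'
#' @param read a single DNA sequence (character or `DNAString`).
#' @param panel an [amplicon_panel()].
#' @param min_identity minimum alignment identity to accept (default 0.90).
#' @param min_length minimum read length in bases (default 40); shorter
#'   reads are unassigned with reason `"too_short"`.
#' @return a one-row data.frame with columns `read_id`, `assigned`,
#'   `reason`, `amplicon`, `strand`, `score`, `identity`, plus the aligned
#'   read view used by [extract_haplotype()].
#' @seealso [alignment-scoring] for the scoring scheme.
#' @export
align_read <- function(read, panel,
                       min_identity = .ALIGN_DEFAULTS$min_identity,
                       min_length = .ALIGN_DEFAULTS$min_length) {
  reads <- Biostrings::DNAStringSet(as.character(read))
  if (is.null(names(reads))) names(reads) <- "read1"
  align_reads(reads, panel, min_identity = min_identity,
              min_length = min_length)
}

# Homopolymer rescue: a read gap at an MSV that sits inside a reference
# homopolymer run of length >= 3 is attributed to a pyrosequencing flow
# undercall and realigned away from the MSV (the allele becomes the run
# base), provided the read carries at least (run length - 1) copies of the
# base across the fully covered run.
.homopolymer_rescue <- function(ref_seq, offset, view, subj_start, subj_end) {
  b <- substr(ref_seq, offset + 1L, offset + 1L)
  lo <- offset + 1L
  while (lo > 1L && substr(ref_seq, lo - 1L, lo - 1L) == b) lo <- lo - 1L
  hi <- offset + 1L
  while (hi < nchar(ref_seq) && substr(ref_seq, hi + 1L, hi + 1L) == b) {
    hi <- hi + 1L
  }
  run_len <- hi - lo + 1L
  if (run_len < 3L) return(NA_character_)
  if (lo < subj_start || hi > subj_end) return(NA_character_)
  run_bases <- strsplit(substr(view, lo, hi), "", fixed = TRUE)[[1L]]
  if (sum(run_bases == b) >= run_len - 1L) b else NA_character_
}

# Vectorized haplotype extraction for assigned reads. Returns a data.frame
# (direction_class, haplotype, omit_reason) parallel to asg rows.
.extract_batch <- function(asg, panel) {
  n <- nrow(asg)
  res <- data.frame(direction_class = rep(NA_character_, n),
                    haplotype = NA_character_,
                    omit_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (aid in unique(asg$amplicon)) {
    rows <- which(asg$amplicon == aid)
    amp <- panel$amplicons[[aid]]
    msvs <- panel_msvs(panel, aid)
    k <- nrow(msvs)
    pos <- msvs$offset + 1L
    views <- asg$aligned_view[rows]
    # allele matrix: reads x msvs; NA = not covered
    am <- matrix(NA_character_, nrow = length(rows), ncol = k)
    for (j in seq_len(k)) {
      covered <- asg$subj_start[rows] <= pos[j] & asg$subj_end[rows] >= pos[j]
      am[covered, j] <- substr(views[covered], pos[j], pos[j])
    }
    gap_fail <- rep(FALSE, length(rows))
    for (j in seq_len(k)) {
      gaps <- which(!is.na(am[, j]) & am[, j] == "-")
      if (!length(gaps)) next
      if ("-" %in% msvs$alleles[[j]]) next  # declared indel allele
      for (g in gaps) {
        rescue <- .homopolymer_rescue(amp$reference_seq, msvs$offset[j],
                                      views[g], asg$subj_start[rows[g]],
                                      asg$subj_end[rows[g]])
        if (is.na(rescue)) {
          am[g, j] <- NA_character_
          gap_fail[g] <- TRUE
        } else {
          am[g, j] <- rescue
        }
      }
    }
    covered_mat <- !is.na(am)
    fwd_cols <- match(amp$forward_set, msvs$msv_id)
    rev_cols <- match(amp$reverse_set, msvs$msv_id)
    full <- rowSums(covered_mat) == k
    fwd_ok <- !full & asg$strand[rows] == "+" &
      rowSums(covered_mat[, fwd_cols, drop = FALSE]) == length(fwd_cols)
    rev_ok <- !full & !fwd_ok & asg$strand[rows] == "-" &
      rowSums(covered_mat[, rev_cols, drop = FALSE]) == length(rev_cols)
    paste_cols <- function(m) do.call(paste0, asplit(m, 2L))
    if (any(full)) {
      res$direction_class[rows[full]] <- "full"
      res$haplotype[rows[full]] <- paste_cols(am[full, , drop = FALSE])
    }
    if (any(fwd_ok)) {
      res$direction_class[rows[fwd_ok]] <- "forward_partial"
      res$haplotype[rows[fwd_ok]] <-
        paste_cols(am[fwd_ok, fwd_cols, drop = FALSE])
    }
    if (any(rev_ok)) {
      res$direction_class[rows[rev_ok]] <- "reverse_partial"
      res$haplotype[rows[rev_ok]] <-
        paste_cols(am[rev_ok, rev_cols, drop = FALSE])
    }
    omitted <- !(full | fwd_ok | rev_ok)
    res$omit_reason[rows[omitted]] <- ifelse(gap_fail[omitted], "gap", "span")
  }
  res$haplotype <- toupper(res$haplotype)
  res
}

#' Extract a haplotype call from an aligned read
#'
#' Reads the aligned base at every MSV position of the assigned amplicon and
#' classifies the call:
#' * `full` when all of the amplicon's MSVs are covered;
#' * `forward_partial` / `reverse_partial` when the read covers (at least)
#'   the amplicon's forward/reverse MSV set and its strand agrees with that
#'   direction — a read covering a strict superset of a direction set is
#'   truncated to the largest declared set it fully covers;
#' * otherwise the call is omitted (`direction_class = NA`): reads that do
#'   not span a declared MSV set carry less information and are dropped
#'   rather than tabulated.
#'
#' A read gap at an MSV yields the gap allele `-` if the panel declares an
#' indel allele there. Otherwise, if the MSV lies in a reference homopolymer
#' run of length >= 3 and the read looks like a single-base flow undercall,
#' the gap is realigned away from the MSV (the allele becomes the run base);
#' failing that the call is omitted. Alleles are always reported on the
#' plus strand of the reference, in panel MSV order, so a read and its
#' reverse complement give the same haplotype string.
#'
#' @param asg a one-row assignment as returned by [align_read()].
#' @param panel an [amplicon_panel()].
#' @return list with `direction_class` (or `NA` if omitted), `haplotype`
#'   (string, or `NA`), and `omit_reason` (`NA`, `"span"` or `"gap"`).
#' @export
extract_haplotype <- function(asg, panel) {
  stopifnot(nrow(asg) == 1L)
  if (!isTRUE(asg$assigned)) {
    stop("extract_haplotype() requires an assigned read", call. = FALSE)
  }
  as.list(.extract_batch(asg, panel))
}

#' Call haplotypes for a set of reads
#'
#' Runs the read-assignment and allele-extraction steps over a read set and
#' tabulates haplotype calls per (sample, amplicon, direction class).
#'
#' The returned `stats` obey the conservation laws
#' `n_reads = n_assigned + n_unassigned` and
#' `sum(counts) + n_omitted_span = n_assigned`; `assembly_fraction` is
#' `n_assigned / n_reads`.
#'
#' @param reads a `DNAStringSet` (see [read_sequences()]).
#' @param panel an [amplicon_panel()].
#' @param sample_id sample label recorded in the HC table.
#' @param min_identity,min_length see [align_read()].
#' @return list with `table` (an [hc_table()]) and `stats`.
#' @export
call_haplotypes <- function(reads, panel, sample_id,
                            min_identity = .ALIGN_DEFAULTS$min_identity,
                            min_length = .ALIGN_DEFAULTS$min_length) {
  asg <- align_reads(reads, panel, min_identity = min_identity,
                     min_length = min_length)
  n_reads <- nrow(asg)
  assigned <- asg[asg$assigned, , drop = FALSE]
  if (nrow(assigned)) {
    hc <- .extract_batch(assigned, panel)
    ok <- !is.na(hc$direction_class)
    n_omitted <- sum(!ok)
    if (any(ok)) {
      calls <- data.frame(sample = sample_id,
                          amplicon = assigned$amplicon[ok],
                          direction_class = hc$direction_class[ok],
                          haplotype = hc$haplotype[ok],
                          stringsAsFactors = FALSE)
      agg <- stats::aggregate(list(count = rep(1L, nrow(calls))),
                              calls, FUN = sum)
      table <- hc_table(agg, provenance = sample_id)
    } else {
      table <- hc_table(provenance = sample_id)
    }
  } else {
    n_omitted <- 0L
    table <- hc_table(provenance = sample_id)
  }
  stats <- list(n_reads = n_reads,
                n_assigned = nrow(assigned),
                n_unassigned = n_reads - nrow(assigned),
                n_omitted_span = n_omitted,
                assembly_fraction = if (n_reads > 0)
                  nrow(assigned) / n_reads else NA_real_)
  list(table = table, stats = stats)
}
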