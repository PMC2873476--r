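#' Minimal copy number from haplotype-call counts
#'
#' At a multicopy locus the haplotype-call counts of a polymorphic amplicon
#' reflect the ratio of per-haplotype copy counts; the observed frequencies
#' `f_i` only determine copy number up to an integer multiple, so the usual
#' summary is the *minimal* copy number: the smallest integer total `n` for
#' which some composition of positive integers `a_1..a_k` (one per
#' haplotype, summing to `n`) reproduces the frequencies within a tolerance.
#'
#' Candidate totals `n = k, k+1, ...` are examined in increasing order; for
#' each, an exact bounded search decides whether any composition with all
#' parts >= 1 keeps every `|f_i - a_i/n|` within `tol` (each `a_i` can only
#' range over the few integers inside `f_i*n +/- tol*n`, so the search is
#' tiny). The first admitting total is returned together with its
#' smallest-deviation composition.
#'
#' For example, counts 528:1566:583 normalize to the call ratio
#' 1 : 2.97 : 1.10, essentially 1:3:1, giving a minimal copy number of 5.
#'
#' @param counts integer vector of haplotype-call counts, length >= 2.
#' @param tol maximum allowed per-haplotype frequency deviation
#'   (default 0.05).
#' @param max_cn largest total copy number considered (default 16).
#' @return list with `n` (minimal CN), `composition` (integer copies per
#'   haplotype, in input order), and `deviation`; or `NULL` when no
#'   `n <= max_cn` fits.
#' @examples
#' minimal_cn(c(528, 1566, 583))$n          # 5, composition 1:3:1
#' minimal_cn(c(225, 1058, 503))$n          # 7, composition 1:4:2
#' @export
minimal_cn <- function(counts, tol = 0.05, max_cn = 16L) {
  if (length(counts) < 2L) {
    stop("minimal_cn() needs at least two haplotype counts", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("counts must be positive", call. = FALSE)
  }
  if (max_cn < length(counts)) {
    stop("max_cn must be at least the number of haplotypes", call. = FALSE)
  }
  .minimal_cn_freq(counts / sum(counts), tol = tol, max_cn = max_cn)
}

# Core integer-ratio fit on frequencies.
.minimal_cn_freq <- function(f, tol, max_cn) {
  k <- length(f)
  eps <- 1e-9
  for (n in k:max_cn) {
    r <- f * n
    lo <- pmax(1, ceiling(r - tol * n - eps))
    hi <- floor(r + tol * n + eps)
    if (any(lo > hi) || sum(lo) > n || sum(hi) < n) next
    a <- .best_composition(r, lo, hi, n)
    if (is.null(a)) next
    dev <- max(abs(f - a / n))
    if (dev <= tol + eps) {
      return(list(n = as.integer(n), composition = as.integer(a),
                  deviation = dev))
    }
  }
  NULL
}

# Smallest-deviation composition with lo <= a <= hi (elementwise) and
# sum(a) = n; depth-first over the (small) per-coordinate ranges, pruning on
# the partial maximum deviation. NULL when infeasible.
.best_composition <- function(r, lo, hi, n) {
  k <- length(r)
  lo_tail <- rev(cumsum(rev(lo)))  # lo_tail[i] = sum(lo[i:k])
  hi_tail <- rev(cumsum(rev(hi)))
  best <- NULL
  best_dev <- Inf
  rec <- function(i, acc, remaining, dev_so_far) {
    if (dev_so_far >= best_dev) return()
    if (i > k) {
      if (remaining == 0) { best <<- acc; best_dev <<- dev_so_far }
      return()
    }
    tail_lo <- if (i < k) lo_tail[i + 1L] else 0
    tail_hi <- if (i < k) hi_tail[i + 1L] else 0
    from <- max(lo[i], remaining - tail_hi)
    to <- min(hi[i], remaining - tail_lo)
    if (from > to) return()
    for (a in from:to) {
      rec(i + 1L, c(acc, a), remaining - a, max(dev_so_far, abs(r[i] - a)))
    }
  }
  rec(1L, numeric(0), n, 0)
  best
}

#' Minimal copy number implied by a two-haplotype call ratio
#'
#' Illustrates how sensitive minimal-CN inference is to the observed ratio:
#' small departures from 1.0 imply very different totals, e.g. a ratio of
#' 1.2 (6:5) indicates 11 copies, 1.25 (5:4) indicates 9, and 1.33 (4:3)
#' indicates 7. The ratio is converted to frequencies
#' `(r/(1+r), 1/(1+r))` and fitted with a tight tolerance.
#'
#' @param ratio haplotype call ratio, oriented so that `ratio >= 1`.
#' @param tol frequency tolerance (default 0.005, tight because the ratio is
#'   taken at face value rather than backed by counts).
#' @param max_cn largest total considered (default 16).
#' @return list with `n`, `p` and `q` (the fitted `p:q` composition,
#'   `p >= q`), or `NULL` if no total fits.
#' @examples
#' ratio_minimal_cn(1.2)$n   # 11 (6:5)
#' ratio_minimal_cn(1.25)$n  # 9  (5:4)
#' @export
ratio_minimal_cn <- function(ratio, tol = 0.005, max_cn = 16L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 1) {
    stop("ratio must be a single number >= 1 (orient the ratio first)",
         call. = FALSE)
  }
  fit <- .minimal_cn_freq(c(ratio / (1 + ratio), 1 / (1 + ratio)),
                          tol = tol, max_cn = max_cn)
  if (is.null(fit)) return(NULL)
  list(n = fit$n, p = fit$composition[1], q = fit$composition[2],
       deviation = fit$deviation)
}

#' Harmonize per-amplicon minimal CN estimates of one sample
#'
#' Different amplicons of the same sample may return different minimal CNs
#' because a minimal CN is only defined up to an integer multiple: an
#' amplicon where two haplotype classes happen to be equally frequent
#' reports 2 even when the sample carries 4 copies. Harmonization scales
#' each estimate by the integer `k >= 1` bringing `k * base_cn` closest to a
#' cross-amplicon consensus (ties prefer the smaller `k`, i.e. the more
#' parsimonious multiple).
#'
#' The consensus is the median of the base CNs of estimates with at least 3
#' haplotypes when any exist (such estimates pin the total much more
#' tightly), otherwise the median of all base CNs.
#'
#' @param estimates data.frame with one row per polymorphic
#'   amplicon/direction group, columns `base_cn` and `k` (number of
#'   haplotypes); typically built by [estimate_cn()].
#' @return the input with columns `multiplier` and `harmonized_cn` added;
#'   the consensus is attached as attribute `"consensus"`.
#' @export
harmonize <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1L,
            all(c("base_cn", "k") %in% names(estimates)))
  rich <- estimates$base_cn[estimates$k >= 3L]
  consensus <- if (length(rich)) stats::median(rich)
               else stats::median(estimates$base_cn)
  estimates$multiplier <- vapply(estimates$base_cn, function(b) {
    ks <- 1:max(1L, ceiling(consensus / b) + 1L)
    dist <- abs(ks * b - consensus)
    as.integer(ks[which.min(dist)])  # which.min takes the smallest k on ties
  }, integer(1))
  estimates$harmonized_cn <- estimates$base_cn * estimates$multiplier
  attr(estimates, "consensus") <- consensus
  estimates
}

round_half_up <- function(x) floor(x + 0.5)

#' Combine harmonized per-amplicon estimates into a sample copy number
#'
#' The sample estimate is the arithmetic mean of the harmonized
#' per-amplicon CNs, rounded half-up. Samples whose amplicons are all
#' monomorphic carry no ratio information and are reported as
#' indeterminate.
#'
#' @param estimates harmonized estimate table (see [harmonize()]); may have
#'   zero rows for a monomorphic-only sample.
#' @param sample_id sample label.
#' @return list of class `sample_cn` with `sample_id`, `estimates`,
#'   `average`, `final_cn` (`NA` when indeterminate) and `indeterminate`.
#' @export
sample_cn <- function(estimates, sample_id = "sample") {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    return(structure(list(sample_id = sample_id, estimates = estimates,
                          average = NA_real_, final_cn = NA_integer_,
                          indeterminate = TRUE), class = "sample_cn"))
  }
  if (!"harmonized_cn" %in% names(estimates)) estimates <- harmonize(estimates)
  avg <- mean(estimates$harmonized_cn)
  structure(list(sample_id = sample_id, estimates = estimates,
                 average = avg,
                 final_cn = as.integer(round_half_up(avg)),
                 indeterminate = FALSE),
            class = "sample_cn")
}

#' @export
print.sample_cn <- function(x, ...) {
  if (x$indeterminate) {
    cat(sprintf("<sample_cn> %s: indeterminate (no polymorphic amplicon; >= 1 per haploid set)\n",
                x$sample_id))
    return(invisible(x))
  }
  ann <- ifelse(x$estimates$multiplier > 1,
                sprintf(" (%dn)", x$estimates$multiplier), "")
  cat(sprintf("<sample_cn> %s: final CN %d (average %.2f)\n",
              x$sample_id, x$final_cn, x$average))
  cat(paste(sprintf("  %-5s %d%s", x$estimates$group,
                    x$estimates$harmonized_cn, ann), collapse = "\n"), "\n")
  invisible(x)
}

#' Compare a sample CN estimate with external measurements
#'
#' External absolute CN measurements (e.g. MLPA or paralog ratio tests) are
#' averaged, rounded half-up, and subtracted from the haplotype-based
#' estimate. Differences of two or more copies are flagged as concordance
#' violations: minimal-CN estimation can disagree with absolute methods by
#' an integer factor, and such samples deserve individual scrutiny.
#'
#' @param s a [sample_cn()] object.
#' @param external data.frame with columns `method` and `cn` (numeric), or
#'   `NULL`.
#' @return list with `external_average`, `external_rounded`, `difference`
#'   (estimate minus rounded external; `NA` when either side is missing)
#'   and `concordance_violation`.
#' @export
compare_external <- function(s, external) {
  stopifnot(inherits(s, "sample_cn"))
  if (is.null(external) || nrow(external) == 0L) {
    return(list(external_average = NA_real_, external_rounded = NA_integer_,
                difference = NA_integer_, concordance_violation = FALSE))
  }
  vals <- external$cn[!is.na(external$cn)]
  if (!length(vals)) {
    return(list(external_average = NA_real_, external_rounded = NA_integer_,
                difference = NA_integer_, concordance_violation = FALSE))
  }
  avg <- mean(vals)
  rounded <- as.integer(round_half_up(avg))
  diff <- if (is.na(s$final_cn)) NA_integer_
          else as.integer(s$final_cn - rounded)
  list(external_average = avg, external_rounded = rounded,
       difference = diff,
       concordance_violation = !is.na(diff) && abs(diff) >= 2L)
}

#' Estimate copy numbers for every sample of an HC table
#'
#' Groups a (filtered) HC table by sample, amplicon and direction class,
#' fits a minimal CN per polymorphic group with [minimal_cn()], harmonizes
#' the per-amplicon estimates and averages them into a per-sample CN.
#' Groups with a single haplotype (monomorphic) contribute no estimate.
#' For split-coverage amplicons the forward and reverse partial groups are
#' estimated separately (labelled e.g. `F5f` and `F5r`), since they measure
#' different MSV subsets.
#'
#' @param table an [hc_table()], normally after [filter_fractions()].
#' @param tol,max_cn passed to [minimal_cn()].
#' @param external optional data.frame of external measurements with
#'   columns `sample`, `method`, `cn`.
#' @return named list of [sample_cn()] objects, one per sample, each with a
#'   `comparison` element when external values were supplied.
#' @export
estimate_cn <- function(table, tol = 0.05, max_cn = 16L, external = NULL) {
  df <- as.data.frame(table)
  out <- list()
  for (sid in unique(df$sample)) {
    sdf <- df[df$sample == sid, , drop = FALSE]
    groups <- unique(sdf[c("amplicon", "direction_class")])
    est_rows <- list()
    for (g in seq_len(nrow(groups))) {
      gdf <- sdf[sdf$amplicon == groups$amplicon[g] &
                 sdf$direction_class == groups$direction_class[g], ,
                 drop = FALSE]
      if (nrow(gdf) < 2L) next  # monomorphic: no ratio information
      fit <- minimal_cn(gdf$count, tol = tol, max_cn = max_cn)
      if (is.null(fit)) next    # no integer total fits within tolerance
      suffix <- switch(groups$direction_class[g],
                       forward_partial = "f", reverse_partial = "r", "")
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        group = paste0(groups$amplicon[g], suffix),
        amplicon = groups$amplicon[g],
        direction_class = groups$direction_class[g],
        k = nrow(gdf),
        base_cn = fit$n,
        deviation = fit$deviation,
        composition = paste(fit$composition, collapse = ":"),
        stringsAsFactors = FALSE)
    }
    est <- if (length(est_rows)) harmonize(do.call(rbind, est_rows)) else NULL
    s <- sample_cn(est, sample_id = sid)
    if (!is.null(external)) {
      s$comparison <- compare_external(
        s, external[external$sample == sid, , drop = FALSE])
    }
    out[[sid]] <- s
  }
  out
}

#' Tabular copy-number report
#'
#' Flattens the result of [estimate_cn()] into one row per sample with one
#' column per amplicon/direction group (harmonized CN, annotated `(kn)`
#' when a multiplier was applied), the average, the final CN, and — when
#' external measurements were supplied — their rounded average and the
#' difference.
#'
#' @param cns result of [estimate_cn()].
#' @return a data.frame.
#' @export
cn_report <- function(cns) {
  groups <- unique(unlist(lapply(cns, function(s)
    if (!is.null(s$estimates)) s$estimates$group)))
  rows <- lapply(cns, function(s) {
    row <- stats::setNames(as.list(rep(NA_character_, length(groups))),
                           groups)
    if (!is.null(s$estimates)) {
      for (i in seq_len(nrow(s$estimates))) {
        e <- s$estimates[i, ]
        row[[e$group]] <- paste0(e$harmonized_cn,
                                 if (e$multiplier > 1)
                                   sprintf(" (%dn)", e$multiplier) else "")
      }
    }
    base <- data.frame(sample = s$sample_id, stringsAsFactors = FALSE)
    base <- cbind(base, as.data.frame(row, stringsAsFactors = FALSE,
                                      check.names = FALSE))
    base$average <- if (s$indeterminate) NA_real_ else round(s$average, 2)
    base$final_cn <- s$final_cn
    if (!is.null(s$comparison)) {
      base$external_avg <- round(s$comparison$external_average, 2)
      base$difference <- s$comparison$difference
      base$flag <- if (isTRUE(s$comparison$concordance_violation))
        "concordance_violation" else ""
    }
    base
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
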