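#' Collapse directional partial haplotypes into complete haplotypes
#'
#' For amplicons longer than the read length, forward reads cover one MSV
#' subset and reverse reads another, with a shared overlap. Observed
#' forward and reverse haplotype frequencies are then two marginal views of
#' the same underlying copy composition, and complete haplotypes are
#' recovered by matching them: a transportation problem whose supplies are
#' the forward frequencies, demands the reverse frequencies, and whose arcs
#' connect only overlap-compatible pairs (the forward string's overlap
#' suffix equals the reverse string's overlap prefix).
#'
#' The parsimony assumption is operationalized as *minimum support*: among
#' arc sets in which every directional haplotype has at least one partner,
#' the smallest set is chosen, and among sets of that size the one
#' transporting the most frequency mass. Each chosen arc becomes one
#' complete haplotype (forward string plus the reverse string beyond the
#' overlap), with the transported mass as its `flow`. The residual L1
#' mismatch between supplies and demands is reported; if it exceeds `slack`
#' the result is flagged (attribute `"flagged"`) — directional sequencing
#' depth skew and sampling noise routinely leave some mismatch, so the
#' flag marks results worth inspecting rather than rejects them.
#' Frequencies (not raw counts) are matched, which neutralizes the
#' direction-specific depth skew of pyrosequencing.
#'
#' Ties are broken deterministically: arcs are ranked by descending
#' `min(supply, demand)`, then lexicographically by haplotype strings, and
#' the first optimal arc set in that enumeration order wins.
#'
#' @param fwd,rev data.frames with columns `haplotype` and `count` (or
#'   `frequency`); frequencies are computed within each direction.
#' @param overlap number of overlapping MSVs (suffix of forward strings,
#'   prefix of reverse strings), or a character vector of overlap MSV ids
#'   (only its length is used).
#' @param slack L1 frequency mismatch above which the result is flagged
#'   (default 0.10).
#' @return data.frame of class `complete_haplotypes` with columns
#'   `haplotype`, `flow`, `fwd`, `rev`; attributes `mismatch` and
#'   `flagged`.
#' @examples
#' fwd <- data.frame(haplotype = c("TCC", "CTG"), count = c(767, 475))
#' rev <- data.frame(haplotype = c("CCGGGC", "CCAGGC", "TGGGAC"),
#'                   count = c(1046, 431, 913))
#' merge_directional(fwd, rev, overlap = 2)
#' @export
merge_directional <- function(fwd, rev, overlap, slack = 0.10) {
  if (is.character(overlap)) overlap <- length(overlap)
  stopifnot(is.numeric(overlap), overlap >= 1)
  fwd <- .dir_freqs(fwd, "forward")
  rev <- .dir_freqs(rev, "reverse")
  if (any(nchar(fwd$haplotype) <= overlap)) {
    stop("forward haplotypes must be longer than the overlap", call. = FALSE)
  }
  if (any(nchar(rev$haplotype) < overlap)) {
    stop("reverse haplotypes must span the overlap", call. = FALSE)
  }
  fsuf <- substr(fwd$haplotype, nchar(fwd$haplotype) - overlap + 1L,
                 nchar(fwd$haplotype))
  rpre <- substr(rev$haplotype, 1L, overlap)
  arcs <- which(outer(fsuf, rpre, `==`), arr.ind = TRUE)
  arcs <- data.frame(i = arcs[, 1L], j = arcs[, 2L])
  orphan_f <- setdiff(seq_len(nrow(fwd)), arcs$i)
  orphan_r <- setdiff(seq_len(nrow(rev)), arcs$j)
  if (length(orphan_f) || length(orphan_r)) {
    stop("directional haplotype(s) without a compatible partner: ",
         paste(c(fwd$haplotype[orphan_f],
                 rev$haplotype[orphan_r]), collapse = ", "),
         " (inconsistent calling or over-filtering?)", call. = FALSE)
  }
  # deterministic arc order for enumeration and tie-breaking
  cap <- pmin(fwd$frequency[arcs$i], rev$frequency[arcs$j])
  ord <- order(-cap, fwd$haplotype[arcs$i], rev$haplotype[arcs$j])
  arcs <- arcs[ord, , drop = FALSE]

  sol <- .min_support_flow(fwd$frequency, rev$frequency, arcs)
  flows <- sol$flows
  keep <- flows > 0
  res <- data.frame(
    haplotype = paste0(fwd$haplotype[arcs$i[sol$support]],
                       substr(rev$haplotype[arcs$j[sol$support]],
                              overlap + 1L,
                              nchar(rev$haplotype[arcs$j[sol$support]]))),
    flow = flows,
    fwd = fwd$haplotype[arcs$i[sol$support]],
    rev = rev$haplotype[arcs$j[sol$support]],
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  res <- res[order(-res$flow, res$haplotype), , drop = FALSE]
  rownames(res) <- NULL
  mismatch <- sum(fwd$frequency) + sum(rev$frequency) - 2 * sum(flows)
  if (mismatch > slack) {
    warning(sprintf(
      "forward/reverse frequency mismatch %.3f exceeds slack %.3f",
      mismatch, slack), call. = FALSE)
  }
  structure(res, class = c("complete_haplotypes", "data.frame"),
            mismatch = mismatch, flagged = mismatch > slack)
}

.dir_freqs <- function(df, what) {
  df <- as.data.frame(df)
  if (!"haplotype" %in% names(df)) {
    stop(what, " table needs a 'haplotype' column", call. = FALSE)
  }
  df$haplotype <- toupper(df$haplotype)
  if (anyDuplicated(df$haplotype)) {
    stop("duplicate ", what, " haplotype strings", call. = FALSE)
  }
  if ("count" %in% names(df)) {
    df$frequency <- df$count / sum(df$count)
  } else if ("frequency" %in% names(df)) {
    df$frequency <- df$frequency / sum(df$frequency)
  } else {
    stop(what, " table needs a 'count' or 'frequency' column", call. = FALSE)
  }
  df
}

# Minimum-support transportation: smallest covering arc subset, then maximum
# transported mass; enumeration order doubles as the deterministic
# tie-break. Exact for the small instances this pipeline sees; instances
# beyond the enumeration cap raise an error.
.min_support_flow <- function(supply, demand, arcs,
                              enum_cap = 2e5) {
  m <- nrow(arcs)
  nf <- length(supply)
  nr <- length(demand)
  full_f <- bitwShiftL(1L, nf) - 1L
  full_r <- bitwShiftL(1L, nr) - 1L
  fmask <- bitwShiftL(1L, arcs$i - 1L)
  rmask <- bitwShiftL(1L, arcs$j - 1L)
  if (nf > 25L || nr > 25L) {
    stop("merge instance too large for exact minimum-support search",
         call. = FALSE)
  }
  best_possible <- min(sum(supply), sum(demand))
  for (s in max(nf, nr):m) {
    if (choose(m, s) > enum_cap) {
      stop(sprintf(
        "minimum-support enumeration too large (%d arcs, support %d)",
        m, s), call. = FALSE)
    }
    subsets <- utils::combn(m, s, simplify = FALSE)
    best <- NULL
    best_flow <- -Inf
    for (sub in subsets) {
      if (Reduce(bitwOr, fmask[sub]) != full_f) next
      if (Reduce(bitwOr, rmask[sub]) != full_r) next
      fl <- .transport_max_flow(supply, demand,
                                arcs$i[sub], arcs$j[sub])
      if (sum(fl) > best_flow + 1e-12) {
        best_flow <- sum(fl)
        best <- list(support = sub, flows = fl)
        if (best_flow >= best_possible - 1e-12) break
      }
    }
    if (!is.null(best)) {
      best$flows <- .ensure_positive_flows(best$flows, arcs$i[best$support],
                                           arcs$j[best$support])
      return(best)
    }
  }
  stop("no covering arc subset found", call. = FALSE)  # unreachable
}

# Maximum flow on the bipartite transportation network restricted to the
# given arcs (source -> supplies -> demands -> sink), by BFS augmenting
# paths in deterministic node order. Returns per-arc flows.
.transport_max_flow <- function(supply, demand, ai, aj) {
  nf <- length(supply)
  nr <- length(demand)
  m <- length(ai)
  flows <- numeric(m)
  used_s <- numeric(nf)
  used_d <- numeric(nr)
  arcs_of_f <- split(seq_len(m), factor(ai, levels = seq_len(nf)))
  arcs_of_r <- split(seq_len(m), factor(aj, levels = seq_len(nr)))
  repeat {
    # BFS from source over residual graph
    pred_f <- rep(NA_integer_, nf)   # arc used to reach fwd node (backward)
    pred_r <- rep(NA_integer_, nr)   # arc used to reach rev node (forward)
    reach_f <- supply - used_s > 1e-15
    origin_f <- which(reach_f)
    reach_r <- rep(FALSE, nr)
    queue_f <- origin_f
    queue_r <- integer()
    done <- NA_integer_
    while (length(queue_f) || length(queue_r)) {
      if (length(queue_f)) {
        fi <- queue_f[1L]; queue_f <- queue_f[-1L]
        for (a in arcs_of_f[[fi]]) {        # forward residual: always open
          rj <- aj[a]
          if (!reach_r[rj]) {
            reach_r[rj] <- TRUE
            pred_r[rj] <- a
            if (demand[rj] - used_d[rj] > 1e-15) { done <- rj; break }
            queue_r <- c(queue_r, rj)
          }
        }
        if (!is.na(done)) break
      } else {
        rj <- queue_r[1L]; queue_r <- queue_r[-1L]
        for (a in arcs_of_r[[rj]]) {        # backward residual: needs flow
          fi2 <- ai[a]
          if (!reach_f[fi2] && flows[a] > 1e-15) {
            reach_f[fi2] <- TRUE
            pred_f[fi2] <- a
            queue_f <- c(queue_f, fi2)
          }
        }
      }
    }
    if (is.na(done)) break
    # trace augmenting path back to an origin supply node
    path_fwd <- integer()   # arcs gaining flow
    path_bwd <- integer()   # arcs losing flow
    rj <- done
    repeat {
      a <- pred_r[rj]
      path_fwd <- c(path_fwd, a)
      fi <- ai[a]
      if (fi %in% origin_f && supply[fi] - used_s[fi] > 1e-15) break
      ab <- pred_f[fi]
      path_bwd <- c(path_bwd, ab)
      rj <- aj[ab]
    }
    fi <- ai[path_fwd[length(path_fwd)]]
    delta <- min(supply[fi] - used_s[fi], demand[done] - used_d[done])
    if (length(path_bwd)) delta <- min(delta, min(flows[path_bwd]))
    flows[path_fwd] <- flows[path_fwd] + delta
    flows[path_bwd] <- flows[path_bwd] - delta
    used_s[fi] <- used_s[fi] + delta
    used_d[done] <- used_d[done] + delta
  }
  flows
}

# A support arc can end with zero flow when its node's mass is fully routed
# elsewhere in the maximum flow; shift a token amount from the largest
# sibling arc so every reported complete haplotype has positive flow.
.ensure_positive_flows <- function(flows, ai, aj) {
  zero <- which(flows <= 0)
  for (z in zero) {
    sib <- which((ai == ai[z] | aj == aj[z]) & flows > 0)
    if (length(sib)) {
      donor <- sib[which.max(flows[sib])]
      eps <- min(flows[donor] / 2, 1e-6)
      flows[donor] <- flows[donor] - eps
      flows[z] <- eps
    }
  }
  flows
}

#' Merge the directional haplotypes of one sample and amplicon
#'
#' Convenience wrapper extracting the `forward_partial` and
#' `reverse_partial` rows of an HC table and running
#' [merge_directional()] with the amplicon's declared overlap.
#'
#' @param table an [hc_table()] (normally filtered).
#' @param panel an [amplicon_panel()].
#' @param amplicon_id split-coverage amplicon to merge.
#' @param sample_id sample to merge.
#' @param slack see [merge_directional()].
#' @return see [merge_directional()].
#' @export
merge_amplicon <- function(table, panel, amplicon_id, sample_id,
                           slack = 0.10) {
  ov <- panel_overlap(panel, amplicon_id)
  if (length(ov) == 0L) {
    stop("amplicon '", amplicon_id, "' has no forward/reverse overlap",
         call. = FALSE)
  }
  df <- as.data.frame(table)
  df <- df[df$sample == sample_id & df$amplicon == amplicon_id, ,
           drop = FALSE]
  fwd <- df[df$direction_class == "forward_partial", , drop = FALSE]
  rev <- df[df$direction_class == "reverse_partial", , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    stop("sample '", sample_id, "' lacks ",
         if (nrow(fwd) == 0L) "forward" else "reverse",
         " partial calls for amplicon '", amplicon_id, "'", call. = FALSE)
  }
  merge_directional(fwd[c("haplotype", "count")],
                    rev[c("haplotype", "count")],
                    overlap = length(ov), slack = slack)
}

#' Union complete haplotypes across samples
#'
#' @param per_sample_merges named list (by sample) of
#'   [merge_directional()] results for one amplicon.
#' @return data.frame with one row per distinct complete haplotype:
#'   `haplotype`, `n_samples`, `total_flow`, `samples`
#'   (comma-separated).
#' @export
collapse_panel <- function(per_sample_merges) {
  rows <- do.call(rbind, lapply(names(per_sample_merges), function(sid) {
    m <- per_sample_merges[[sid]]
    data.frame(sample = sid, haplotype = m$haplotype, flow = m$flow,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(haplotype = character(), n_samples = integer(),
                      total_flow = numeric(), samples = character()))
  }
  agg <- lapply(split(rows, rows$haplotype), function(g) {
    data.frame(haplotype = g$haplotype[1L], n_samples = nrow(g),
               total_flow = sum(g$flow),
               samples = paste(sort(g$sample), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out[order(-out$total_flow, out$haplotype), , drop = FALSE]
}

#' Join modal per-amplicon haplotypes into long-range haplotypes
#'
#' For each sample the most abundant haplotype of every requested amplicon
#' (for split-coverage amplicons, the complete haplotype with the highest
#' merge flow) is selected and the strings are concatenated in panel
#' amplicon order, separated by `|` so amplicon boundaries stay
#' recoverable. Samples missing calls for any requested amplicon are
#' excluded and listed; modal ties yield one joined string per tied
#' haplotype and an `ambiguous` flag.
#'
#' @param table a filtered [hc_table()].
#' @param panel an [amplicon_panel()].
#' @param samples samples to join; default all in the table.
#' @param amplicons amplicons to join; default all in the panel.
#' @param slack passed to [merge_amplicon()] for split amplicons.
#' @return list with `joined` (data.frame: `sample`, `haplotype`,
#'   `ambiguous`), `catalogue` (distinct joined strings with sample
#'   counts) and `excluded` (data.frame: `sample`, `reason`).
#' @export
long_range_join <- function(table, panel,
                            samples = unique(table$sample),
                            amplicons = names(panel$amplicons),
                            slack = 0.10) {
  df <- as.data.frame(table)
  joined <- list()
  excluded <- list()
  for (sid in samples) {
    parts <- list()   # per amplicon: character vector of modal haplotypes
    miss <- NULL
    for (aid in amplicons) {
      amp <- panel$amplicons[[aid]]
      split_amp <- !setequal(amp$forward_set, amp$msv_ids)
      if (split_amp) {
        got <- tryCatch(merge_amplicon(table, panel, aid, sid, slack = slack),
                        error = function(e) NULL)
        if (is.null(got) || nrow(got) == 0L) { miss <- aid; break }
        top <- got$haplotype[got$flow >= max(got$flow) - 1e-12]
      } else {
        g <- df[df$sample == sid & df$amplicon == aid &
                df$direction_class == "full", , drop = FALSE]
        if (nrow(g) == 0L) { miss <- aid; break }
        top <- g$haplotype[g$count == max(g$count)]
      }
      parts[[aid]] <- sort(top)
    }
    if (!is.null(miss)) {
      excluded[[sid]] <- data.frame(sample = sid,
                                    reason = paste0("missing amplicon ", miss),
                                    stringsAsFactors = FALSE)
      next
    }
    combos <- Reduce(function(acc, p) {
      unlist(lapply(acc, function(a) paste(a, p, sep = "|")))
    }, parts[-1L], init = parts[[1L]])
    joined[[sid]] <- data.frame(sample = sid, haplotype = combos,
                                ambiguous = length(combos) > 1L,
                                stringsAsFactors = FALSE)
  }
  joined_df <- if (length(joined)) {
    do.call(rbind, c(joined, list(make.row.names = FALSE)))
  } else {
    data.frame(sample = character(), haplotype = character(),
               ambiguous = logical())
  }
  catalogue <- if (nrow(joined_df)) {
    tab <- table(joined_df$haplotype)
    data.frame(haplotype = names(tab), n_samples = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(haplotype = character(), n_samples = integer())
  }
  catalogue <- catalogue[order(-catalogue$n_samples, catalogue$haplotype), ,
                         drop = FALSE]
  rownames(catalogue) <- NULL
  excluded_df <- if (length(excluded)) {
    do.call(rbind, c(excluded, list(make.row.names = FALSE)))
  } else {
    data.frame(sample = character(), reason = character())
  }
  list(joined = joined_df, catalogue = catalogue, excluded = excluded_df)
}
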