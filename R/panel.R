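#' Amplicon panel data model
#'
#' An `amplicon_panel` bundles the reference sequences of a set of PCR
#' amplicons with the multisite variations (MSVs) they contain. MSVs are
#' polymorphic positions present in several paralogous copies of a
#' copy-number variable locus, so a sample's "genotype" at an MSV is a ratio
#' over all copies rather than a diploid call. The panel is the coordinate
#' frame for read assignment, haplotype-call extraction, and simulation.
#'
#' Each amplicon carries a `forward_set` and `reverse_set`: the subsets of
#' its MSVs reachable by forward and reverse reads. For short amplicons both
#' sets equal the full MSV list; for amplicons longer than the read length
#' (such as F5 of the bundled beta-defensin panel) the two sets differ and
#' must overlap so that directional haplotypes can later be merged.
#'
#' @param amplicons named list of amplicon descriptors (see [load_panel()]
#'   for the fields).
#' @param msvs named list of MSV descriptors.
#' @return an object of class `amplicon_panel`.
#' @seealso [load_panel()], [write_panel()], [defb_panel()]
#' @export
amplicon_panel <- function(amplicons, msvs) {
  panel <- structure(list(amplicons = amplicons, msvs = msvs),
                     class = "amplicon_panel")
  validate_panel(panel)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("<amplicon_panel> %d amplicons, %d MSVs\n",
              length(x$amplicons), length(x$msvs)))
  for (aid in names(x$amplicons)) {
    amp <- x$amplicons[[aid]]
    split <- !setequal(amp$forward_set, amp$msv_ids)
    cat(sprintf("  %-4s %4d bp  %d MSVs%s\n", aid, amp$length,
                length(amp$msv_ids),
                if (split) "  [split fwd/rev coverage]" else ""))
  }
  invisible(x)
}

MSV_NOVELTY <- c("known", "reference_paralog", "novel")

validate_msv <- function(msv, amplicons) {
  stopifnot(is.character(msv$msv_id), length(msv$msv_id) == 1L)
  amp <- amplicons[[msv$amplicon_id]]
  if (is.null(amp)) {
    stop(sprintf("MSV '%s' references unknown amplicon '%s'",
                 msv$msv_id, msv$amplicon_id), call. = FALSE)
  }
  if (!is.numeric(msv$offset) || msv$offset < 0 || msv$offset >= amp$length) {
    stop(sprintf("MSV '%s': offset %s outside amplicon '%s' (length %d)",
                 msv$msv_id, format(msv$offset), msv$amplicon_id, amp$length),
         call. = FALSE)
  }
  if (length(msv$alleles) < 1L) {
    stop(sprintf("MSV '%s': empty allele set", msv$msv_id), call. = FALSE)
  }
  bad <- setdiff(toupper(msv$alleles), c("A", "C", "G", "T", "-"))
  if (length(bad)) {
    stop(sprintf("MSV '%s': invalid allele symbol(s) %s",
                 msv$msv_id, paste(bad, collapse = ",")), call. = FALSE)
  }
  np <- length(msv$genomic_positions)
  if (np > 0 && !np %in% 1:2) {
    stop(sprintf("MSV '%s': genomic_positions must have 1 or 2 entries",
                 msv$msv_id), call. = FALSE)
  }
  if (!is.null(msv$novelty) && !msv$novelty %in% MSV_NOVELTY) {
    stop(sprintf("MSV '%s': novelty must be one of %s", msv$msv_id,
                 paste(MSV_NOVELTY, collapse = "/")), call. = FALSE)
  }
  invisible(msv)
}

validate_panel <- function(panel) {
  stopifnot(is.list(panel$amplicons), is.list(panel$msvs))
  for (aid in names(panel$amplicons)) {
    amp <- panel$amplicons[[aid]]
    if (!nzchar(amp$reference_seq) ||
        grepl("[^ACGTN]", toupper(amp$reference_seq))) {
      stop(sprintf("amplicon '%s': reference_seq must be non-empty DNA", aid),
           call. = FALSE)
    }
    if (amp$length != nchar(amp$reference_seq)) {
      stop(sprintf("amplicon '%s': length %d != reference length %d",
                   aid, amp$length, nchar(amp$reference_seq)), call. = FALSE)
    }
    dangling <- setdiff(amp$msv_ids, names(panel$msvs))
    if (length(dangling)) {
      stop(sprintf("amplicon '%s': undefined MSV id(s): %s",
                   aid, paste(dangling, collapse = ", ")), call. = FALSE)
    }
    if (!setequal(union(amp$forward_set, amp$reverse_set), amp$msv_ids)) {
      stop(sprintf("amplicon '%s': forward_set + reverse_set must cover all MSVs",
                   aid), call. = FALSE)
    }
    if (!setequal(amp$forward_set, amp$msv_ids) &&
        length(intersect(amp$forward_set, amp$reverse_set)) == 0L) {
      stop(sprintf("amplicon '%s': split coverage requires a forward/reverse overlap",
                   aid), call. = FALSE)
    }
    offs <- vapply(panel$msvs[amp$msv_ids], `[[`, numeric(1), "offset")
    if (anyDuplicated(offs)) {
      stop(sprintf("amplicon '%s': duplicate MSV offsets", aid), call. = FALSE)
    }
    if (is.unsorted(offs)) {
      stop(sprintf("amplicon '%s': msv_ids must be listed in offset order", aid),
           call. = FALSE)
    }
  }
  for (mid in names(panel$msvs)) {
    msv <- panel$msvs[[mid]]
    msv$msv_id <- msv$msv_id %||% mid
    validate_msv(msv, panel$amplicons)
  }
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an amplicon panel from a YAML config file
#'
#' The panel file has two top-level maps, `amplicons` and `msvs`:
#'
#' ```yaml
#' amplicons:
#'   F2:
#'     reference: ACGT...        # amplicon reference sequence
#'     msvs: [MSV1, MSV2]        # in offset order
#'     forward_set: [MSV1, MSV2] # optional, defaults to all msvs
#'     reverse_set: [MSV1, MSV2] # optional, defaults to all msvs
#' msvs:
#'   MSV1:
#'     amplicon: F2
#'     offset: 70                # 0-based within the reference
#'     alleles: [G, C]           # "-" marks an indel (gap) allele
#'     rsid: rs2737902           # optional
#'     genomic_positions: [7257301, 7793210]  # 1-based, one per cluster copy
#'     novelty: known            # known | reference_paralog | novel
#' ```
#'
#' Genomic positions are stored 1-based, as printed in genome browsers;
#' all internal offsets are 0-based.
#'
#' @param path path to the YAML panel description.
#' @return a validated [amplicon_panel()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed panel file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  for (field in c("amplicons", "msvs")) {
    if (is.null(raw[[field]])) {
      stop("panel file missing required field '", field, "'", call. = FALSE)
    }
  }
  amplicons <- lapply(names(raw$amplicons), function(aid) {
    a <- raw$amplicons[[aid]]
    if (is.null(a$reference)) {
      stop("amplicon '", aid, "' missing field 'reference'", call. = FALSE)
    }
    if (is.null(a$msvs)) {
      stop("amplicon '", aid, "' missing field 'msvs'", call. = FALSE)
    }
    ref <- toupper(gsub("\\s", "", a$reference))
    list(amplicon_id = aid,
         reference_seq = ref,
         length = nchar(ref),
         msv_ids = as.character(a$msvs),
         forward_set = as.character(a$forward_set %||% a$msvs),
         reverse_set = as.character(a$reverse_set %||% a$msvs))
  })
  names(amplicons) <- names(raw$amplicons)
  msvs <- lapply(names(raw$msvs), function(mid) {
    m <- raw$msvs[[mid]]
    for (field in c("amplicon", "offset", "alleles")) {
      if (is.null(m[[field]])) {
        stop("MSV '", mid, "' missing field '", field, "'", call. = FALSE)
      }
    }
    list(msv_id = mid,
         rsid = m$rsid %||% NA_character_,
         amplicon_id = as.character(m$amplicon),
         offset = as.integer(m$offset),
         genomic_positions = as.numeric(m$genomic_positions %||% numeric()),
         alleles = toupper(as.character(m$alleles)),
         novelty = m$novelty %||% "known")
  })
  names(msvs) <- names(raw$msvs)
  amplicon_panel(amplicons, msvs)
}

#' Write an amplicon panel back to YAML
#'
#' `load_panel(write_panel(panel, path))` round-trips the panel.
#'
#' @param panel an [amplicon_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- list(
    amplicons = lapply(panel$amplicons, function(a) {
      list(reference = a$reference_seq, msvs = a$msv_ids,
           forward_set = a$forward_set, reverse_set = a$reverse_set)
    }),
    msvs = lapply(panel$msvs, function(m) {
      x <- list(amplicon = m$amplicon_id, offset = m$offset,
                alleles = as.list(m$alleles))
      if (!is.na(m$rsid %||% NA)) x$rsid <- m$rsid
      if (length(m$genomic_positions)) {
        x$genomic_positions <- as.list(m$genomic_positions)
      }
      x$novelty <- m$novelty %||% "known"
      x
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' MSVs of one amplicon, in offset order
#'
#' @param panel an [amplicon_panel()].
#' @param amplicon_id amplicon label.
#' @return data.frame with columns `msv_id`, `offset`, and list-column
#'   `alleles`.
#' @export
panel_msvs <- function(panel, amplicon_id) {
  amp <- panel$amplicons[[amplicon_id]]
  if (is.null(amp)) stop("unknown amplicon: ", amplicon_id, call. = FALSE)
  msvs <- panel$msvs[amp$msv_ids]
  data.frame(
    msv_id = vapply(msvs, `[[`, character(1), "msv_id"),
    offset = vapply(msvs, function(m) as.integer(m$offset), integer(1)),
    alleles = I(lapply(msvs, `[[`, "alleles")),
    row.names = NULL
  )
}

#' Forward/reverse overlap MSVs of a split-coverage amplicon
#'
#' @inheritParams panel_msvs
#' @return character vector of MSV ids covered by both read directions, in
#'   offset order.
#' @export
panel_overlap <- function(panel, amplicon_id) {
  amp <- panel$amplicons[[amplicon_id]]
  if (is.null(amp)) stop("unknown amplicon: ", amplicon_id, call. = FALSE)
  intersect(amp$msv_ids, intersect(amp$forward_set, amp$reverse_set))
}

#' MSV density of a panel
#'
#' Number of MSVs per kilobase of amplicon reference sequence, the usual
#' summary used to compare the variability of a targeted region against
#' genome-wide SNP densities.
#'
#' @param panel an [amplicon_panel()].
#' @param amplicon_ids optional subset of amplicons; default all.
#' @return list with `n_msv`, `total_bp` and `density_per_kb`.
#' @export
msv_density <- function(panel, amplicon_ids = names(panel$amplicons)) {
  amps <- panel$amplicons[amplicon_ids]
  n_msv <- sum(vapply(amps, function(a) length(a$msv_ids), integer(1)))
  total_bp <- sum(vapply(amps, function(a) as.integer(a$length), integer(1)))
  list(n_msv = n_msv, total_bp = total_bp,
       density_per_kb = n_msv / (total_bp / 1000))
}

#' Restrict a panel to a subset of amplicons
#'
#' @param panel an [amplicon_panel()].
#' @param amplicon_ids amplicons to keep.
#' @return an [amplicon_panel()] containing only those amplicons and their
#'   MSVs.
#' @export
panel_subset <- function(panel, amplicon_ids) {
  missing <- setdiff(amplicon_ids, names(panel$amplicons))
  if (length(missing)) {
    stop("unknown amplicon(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  amps <- panel$amplicons[amplicon_ids]
  keep_msvs <- unlist(lapply(amps, `[[`, "msv_ids"), use.names = FALSE)
  amplicon_panel(amps, panel$msvs[keep_msvs])
}
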