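#' sdRNA caller parameters
#'
#' Tunable thresholds for [call_loci()]. A position is a candidate locus
#' anchor when its read 5'-end count is a local maximum and at least
#' `peak_fraction * max(start_counts)` on that host. Reads are attributed to a
#' locus when their 5' end lies within `offset_tolerance` nt of the anchor, so
#' locus counts are fragment-species counts, not pileup depth; a candidate is
#' kept only when that attributed support reaches `min_reads`, so the absolute
#' floor is on locus support, not on one position of the jittered 5'-end
#' distribution. A locus within `end_tolerance` nt of a host terminus is labelled
#' 5'/3'-derived.
#'
#' @param min_reads Absolute read-support floor for a locus (reads).
#' @param peak_fraction Anchor floor as a fraction of the host's maximum
#'   start count.
#' @param offset_tolerance Read-start jitter absorbed into a locus (nt).
#' @param end_tolerance Distance from a host terminus within which a locus is
#'   called terminal (nt).
#' @param min_length,max_length Accepted fragment length band (nt).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_reads = 10, peak_fraction = 0.25,
                          offset_tolerance = 3L, end_tolerance = 5L,
                          min_length = 16L, max_length = 32L) {
  stopifnot(min_reads > 0, peak_fraction >= 0, peak_fraction <= 1,
            offset_tolerance >= 0, min_length <= max_length)
  structure(list(min_reads = min_reads, peak_fraction = peak_fraction,
                 offset_tolerance = as.integer(offset_tolerance),
                 end_tolerance = as.integer(end_tolerance),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "caller_params")
}

#' Call sdRNA loci from snoRNA coverage profiles
#'
#' Identifies discrete snoRNA-derived fragment loci: each locus is anchored at
#' a read 5'-end peak, extends by the modal length of the reads starting
#' within `offset_tolerance` of the anchor, and is named after its host
#' snoRNA (see [name_locus()]). Candidate loci are ranked by read support and
#' overlapping candidates resolved by keeping the higher-count one, so loci on
#' one host never overlap. Calling the same profiles twice yields identical
#' loci.
#'
#' @param profiles An `sdrna_profiles` object (see [build_profiles()]).
#' @param ref The `sdrna_reference`; supplies host biotypes and lengths. Only
#'   snoRNA hosts are called.
#' @param params A [caller_params()] list.
#' @return A tibble with one row per locus: `sdrna_id`, `host_id`, `start`,
#'   `end` (0-based half-open on the host), `read_count`, `modal_length`,
#'   `side` (FIVE_PRIME / THREE_PRIME / INTERNAL), ranked by `read_count`
#'   within host.
#' @export
call_loci <- function(profiles, ref, params = caller_params()) {
  stopifnot(inherits(profiles, "sdrna_profiles"),
            inherits(ref, "sdrna_reference"),
            inherits(params, "caller_params"))
  sno_ids <- ref$records$id[ref$records$biotype == "SNORNA"]
  lens <- stats::setNames(ref$records$length, ref$records$id)

  hosts <- intersect(unique(profiles$totals$precursor_id), sno_ids)
  loci <- purrr::map(hosts, function(h) {
    prof <- dplyr::filter(profiles$profile, .data$precursor_id == h)
    starts <- dplyr::filter(profiles$starts, .data$precursor_id == h)
    call_host_loci(h, prof$start_count, starts, unname(lens[h]), params)
  }) |>
    dplyr::bind_rows()

  if (nrow(loci) == 0) {
    return(tibble(sdrna_id = character(), host_id = character(),
                  start = integer(), end = integer(), read_count = numeric(),
                  modal_length = integer(), side = character()))
  }
  loci |>
    dplyr::group_by(.data$host_id) |>
    dplyr::mutate(sdrna_id = name_host_loci(.data$host_id[1], .data$start)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$host_id, dplyr::desc(.data$read_count),
                   .data$start) |>
    dplyr::select("sdrna_id", "host_id", "start", "end", "read_count",
                  "modal_length", "side")
}

# one host: peak finding, modal extent, greedy non-overlap resolution
call_host_loci <- function(host, s, starts, host_len, params) {
  if (length(s) == 0 || max(s) <= 0) return(NULL)
  left <- c(-Inf, s[-length(s)])
  right <- c(s[-1], -Inf)
  # leftmost position of a plateau counts as the peak; the absolute
  # min_reads floor applies to the locus' attributed read support below,
  # the relative floor to the anchor's own start count
  is_peak <- s > left & s >= right & s >= params$peak_fraction * max(s)
  anchors <- which(is_peak) - 1L  # to 0-based
  if (length(anchors) == 0) return(NULL)

  cand <- purrr::map(anchors, function(p) {
    win <- dplyr::filter(starts,
                         abs(.data$start - p) <= params$offset_tolerance)
    if (sum(win$n) < params$min_reads) return(NULL)
    len_spec <- win |>
      dplyr::group_by(.data$read_length) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$read_length)
    modal_len <- len_spec$read_length[1]
    if (modal_len < params$min_length || modal_len > params$max_length ||
        p + modal_len > host_len) {
      return(NULL)
    }
    tibble(host_id = host, start = p, end = p + modal_len,
           read_count = sum(win$n), modal_length = modal_len)
  }) |>
    dplyr::bind_rows()
  if (nrow(cand) == 0) return(NULL)

  cand <- dplyr::arrange(cand, dplyr::desc(.data$read_count), .data$start)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prior <- which(keep)
    clash <- any(cand$start[i] < cand$end[prior] &
                   cand$end[i] > cand$start[prior])
    keep[i] <- !clash
  }
  cand <- cand[keep, , drop = FALSE]
  cand$side <- dplyr::case_when(
    cand$start <= params$end_tolerance ~ "FIVE_PRIME",
    host_len - cand$end <= params$end_tolerance ~ "THREE_PRIME",
    TRUE ~ "INTERNAL"
  )
  cand
}

#' Name an sdRNA locus after its host snoRNA
#'
#' SNORD hosts yield `sdRNA-D<k>`, SNORA hosts `sdRNA-A<k>`; other hosts yield
#' `sdRNA-<host_id>`. When a host carries exactly two loci they are suffixed
#' `-5p`/`-3p` by position; more than two get positional ordinals. Names are
#' deduplicated against `existing`.
#'
#' @param host_id Host snoRNA id.
#' @param n_loci How many loci the host carries.
#' @param rank This locus's rank by position (1 = 5'-most).
#' @param existing Character vector of names already assigned.
#' @return A single sdRNA name.
#' @examples
#' name_locus("SNORD18") # "sdRNA-D18"
#' name_locus("SNORA31") # "sdRNA-A31"
#' name_locus("SNORD62", n_loci = 2, rank = 2) # "sdRNA-D62-3p"
#' @export
name_locus <- function(host_id, n_loci = 1L, rank = 1L,
                       existing = character()) {
  base <- if (grepl("^SNOR[DA]", host_id, ignore.case = TRUE)) {
    sub("^SNOR([DA])", "sdRNA-\\U\\1", host_id, ignore.case = TRUE,
        perl = TRUE)
  } else {
    paste0("sdRNA-", host_id)
  }
  nm <- if (n_loci == 1L) {
    base
  } else if (n_loci == 2L) {
    paste0(base, c("-5p", "-3p")[rank])
  } else {
    paste0(base, "-p", rank)
  }
  while (nm %in% existing) nm <- paste0(nm, "b")
  nm
}

# vectorised naming of all loci on one host, ordered as `start` is
name_host_loci <- function(host, start) {
  rank <- rank(start, ties.method = "first")
  out <- character(length(start))
  seen <- character()
  for (i in order(rank)) {
    out[i] <- name_locus(host, n_loci = length(start), rank = rank[i],
                         existing = seen)
    seen <- c(seen, out[i])
  }
  out
}

#' Write called loci as BED6 (precursor-local coordinates) and TSV
#'
#' @param loci Locus tibble from [call_loci()].
#' @param bed Output BED6 path (name = sdrna_id, score capped at 1000).
#' @param tsv Optional TSV path with all columns.
#' @return `bed`, invisibly.
#' @export
write_loci_bed <- function(loci, bed, tsv = NULL) {
  bed_df <- tibble(
    chrom = loci$host_id,
    start = loci$start,
    end = loci$end,
    name = loci$sdrna_id,
    score = pmin(1000, round(loci$read_count)),
    strand = "+"
  )
  readr::write_tsv(bed_df, bed, col_names = FALSE, progress = FALSE)
  if (!is.null(tsv)) readr::write_tsv(loci, tsv, progress = FALSE)
  invisible(bed)
}
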