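#' Build per-precursor coverage profiles
#'
#' Converts accepted alignments into positional read-start counts and read
#' depth over each precursor, the substrate for sdRNA locus calling. Profiles
#' are built for snoRNAs and miRNA hairpins; mature-miRNA records are skipped
#' (their counts are direct and need no positional decomposition). Depth is
#' accumulated with a difference array, so it is the exact interval-stab count
#' of the alignment set.
#'
#' @param aln An `sdrna_alignments` object.
#' @param ref The `sdrna_reference` the alignments were made against.
#' @param fractional Weight each alignment 1/multiplicity instead of 1, so a
#'   multi-mapped read is split across its placements.
#' @return An `sdrna_profiles` object: list with
#'   `profile` (tibble: precursor_id, position, start_count, depth;
#'   positions 0-based, all positions of each profiled precursor),
#'   `starts` (tibble: precursor_id, start, read_length, n — the joint
#'   start/length spectrum needed for modal fragment extents) and
#'   `totals` (tibble: precursor_id, total_reads).
#' @export
build_profiles <- function(aln, ref, fractional = FALSE) {
  stopifnot(inherits(aln, "sdrna_alignments"), inherits(ref, "sdrna_reference"))
  lens <- stats::setNames(ref$records$length, ref$records$id)
  biotype <- stats::setNames(ref$records$biotype, ref$records$id)

  a <- aln$alignments
  unknown <- setdiff(a$precursor_id, names(lens))
  if (length(unknown) > 0) {
    stop("alignments reference unknown precursor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(a) > 0 && any(a$start < 0 | a$end > lens[a$precursor_id])) {
    stop("alignment interval outside precursor bounds", call. = FALSE)
  }

  a <- a[biotype[a$precursor_id] != "MIRNA_MATURE", , drop = FALSE]
  a$weight <- if (fractional) 1 / a$multiplicity else 1

  empty <- structure(
    list(
      profile = tibble(precursor_id = character(), position = integer(),
                       start_count = numeric(), depth = numeric()),
      starts = tibble(precursor_id = character(), start = integer(),
                      read_length = integer(), n = numeric()),
      totals = tibble(precursor_id = character(), total_reads = numeric()),
      fractional = fractional
    ),
    class = "sdrna_profiles"
  )
  if (nrow(a) == 0) return(empty)

  profile <- a |>
    dplyr::group_by(.data$precursor_id) |>
    dplyr::group_modify(function(d, key) {
      len <- unname(lens[key$precursor_id])
      starts <- numeric(len)
      agg <- stats::aggregate(d$weight, list(pos = d$start), sum)
      starts[agg$pos + 1L] <- agg$x
      # difference array: +w at start, -w just past end, cumsum gives depth
      diffs <- numeric(len + 1L)
      up <- stats::aggregate(d$weight, list(pos = d$start), sum)
      dn <- stats::aggregate(d$weight, list(pos = d$end), sum)
      diffs[up$pos + 1L] <- diffs[up$pos + 1L] + up$x
      diffs[dn$pos + 1L] <- diffs[dn$pos + 1L] - dn$x
      tibble(position = 0:(len - 1L),
             start_count = starts,
             depth = cumsum(diffs)[seq_len(len)])
    }) |>
    dplyr::ungroup()

  starts <- a |>
    dplyr::mutate(read_length = .data$end - .data$start) |>
    dplyr::group_by(.data$precursor_id, .data$start, .data$read_length) |>
    dplyr::summarise(n = sum(.data$weight), .groups = "drop")

  totals <- a |>
    dplyr::group_by(.data$precursor_id) |>
    dplyr::summarise(total_reads = sum(.data$weight), .groups = "drop")

  structure(
    list(profile = profile, starts = starts, totals = totals,
         fractional = fractional),
    class = "sdrna_profiles"
  )
}

#' @export
print.sdrna_profiles <- function(x, ...) {
  cat("<sdrna_profiles> ", nrow(x$totals), " precursors, ",
      round(sum(x$totals$total_reads), 2), " reads",
      if (isTRUE(x$fractional)) " (fractional)", "\n", sep = "")
  invisible(x)
}

#' Write coverage profiles to TSV and a wiggle-like track
#'
#' @param profiles An `sdrna_profiles` object.
#' @param tsv Output TSV path (precursor_id, position, start_count, depth).
#' @param wig Optional path for a fixedStep wiggle track of depth per
#'   precursor, for visual inspection in a genome browser.
#' @return `tsv`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, tsv, wig = NULL) {
  stopifnot(inherits(profiles, "sdrna_profiles"))
  readr::write_tsv(profiles$profile, tsv, progress = FALSE)
  if (!is.null(wig)) {
    chunks <- profiles$profile |>
      dplyr::group_by(.data$precursor_id) |>
      dplyr::group_map(function(d, key) {
        c(sprintf("fixedStep chrom=%s start=1 step=1", key$precursor_id),
          format(d$depth, trim = TRUE))
      })
    writeLines(unlist(chunks), wig)
  }
  invisible(tsv)
}

#' Coverage plot for one precursor
#'
#' Depth as an area and read 5'-end starts as lollipops, on precursor-local
#' coordinates.
#'
#' @param profiles An `sdrna_profiles` object.
#' @param precursor_id Which precursor to draw.
#' @return A ggplot object.
#' @export
plot_coverage <- function(profiles, precursor_id) {
  stopifnot(inherits(profiles, "sdrna_profiles"))
  d <- dplyr::filter(profiles$profile,
                     .data$precursor_id == .env$precursor_id)
  if (nrow(d) == 0) stop("no profile for precursor ", precursor_id,
                         call. = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$depth), fill = "grey80") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, y = 0,
                                       yend = .data$start_count),
                          colour = "firebrick") +
    ggplot2::labs(x = paste0(precursor_id, " position (nt)"),
                  y = "reads",
                  title = paste0("Coverage and read 5' starts: ",
                                 precursor_id)) +
    ggplot2::theme_minimal()
}
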