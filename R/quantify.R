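#' Assemble the feature table for quantification
#'
#' Builds one row per quantifiable feature: every mature miRNA (a whole
#' mature-miRNA record, or an annotated arm interval on a hairpin) and every
#' called sdRNA locus. Each feature carries the counting rule used for it:
#' \describe{
#'   \item{record}{any full-read alignment to the precursor counts (mature
#'     miRNA references);}
#'   \item{arm}{an alignment on the hairpin counts when it overlaps the arm
#'     interval by at least half the read length;}
#'   \item{anchor}{an alignment on the host counts when its 5' end lies within
#'     `offset_tolerance` nt of the locus anchor (sdRNA loci), so sdRNA counts
#'     are fragment-species counts.}
#' }
#'
#' @param ref An `sdrna_reference`.
#' @param loci Locus tibble from [call_loci()] (may have zero rows).
#' @return A tibble: feature_id, feature_type (miRNA/sdRNA), precursor_id,
#'   start, end, count_rule.
#' @export
feature_table <- function(ref, loci) {
  stopifnot(inherits(ref, "sdrna_reference"))
  if (is.null(ref$mature)) {
    mir <- ref$records |>
      dplyr::filter(.data$biotype == "MIRNA_MATURE") |>
      dplyr::transmute(feature_id = .data$id, feature_type = "miRNA",
                       precursor_id = .data$id, start = 0L,
                       end = .data$length, count_rule = "record")
  } else {
    mir <- ref$mature |>
      dplyr::transmute(feature_id = .data$arm_name, feature_type = "miRNA",
                       precursor_id = .data$hairpin_id,
                       start = as.integer(.data$start),
                       end = as.integer(.data$end), count_rule = "arm")
  }
  sd <- tibble(
    feature_id = loci$sdrna_id %||% character(),
    feature_type = rep("sdRNA", nrow(loci)),
    precursor_id = loci$host_id %||% character(),
    start = as.integer(loci$start %||% integer()),
    end = as.integer(loci$end %||% integer()),
    count_rule = rep("anchor", nrow(loci))
  )
  dplyr::bind_rows(mir, sd)
}

# raw counts for one library over the feature table
count_features <- function(features, aln, offset_tolerance = 3L,
                           fractional = FALSE) {
  a <- aln$alignments
  a$weight <- if (fractional) 1 / a$multiplicity else 1
  counts <- purrr::pmap_dbl(
    features[c("precursor_id", "start", "end", "count_rule")],
    function(precursor_id, start, end, count_rule) {
      on_prec <- a[a$precursor_id == precursor_id, , drop = FALSE]
      if (nrow(on_prec) == 0) return(0)
      hit <- switch(
        count_rule,
        record = rep(TRUE, nrow(on_prec)),
        arm = {
          ovl <- pmin(on_prec$end, end) - pmax(on_prec$start, start)
          ovl >= (on_prec$end - on_prec$start) / 2
        },
        anchor = abs(on_prec$start - start) <= offset_tolerance,
        stop("unknown count_rule: ", count_rule)
      )
      sum(on_prec$weight[hit])
    }
  )
  counts
}

#' Quantify features as reads per million in two libraries
#'
#' Computes raw counts and RPM per feature for the wild-type and knockout
#' libraries, with `rpm = raw_count * 1e6 / denominator`. The RPM denominator
#' is either all reads in the library (default) or only aligned reads, a
#' choice the literature leaves open for small RNA libraries.
#'
#' @param features Feature tibble from [feature_table()].
#' @param aln_wt,aln_ko `sdrna_alignments` for the two libraries.
#' @param denominator_mode `"total_reads"` (per million sequenced reads) or
#'   `"aligned_reads"` (per million aligned reads).
#' @param offset_tolerance Read-start tolerance for anchor-rule counting (nt);
#'   keep equal to the caller's `offset_tolerance`.
#' @param fractional Split multi-mapped reads 1/multiplicity.
#' @return A tibble: feature_id, feature_type, raw_wt, raw_ko, rpm_wt, rpm_ko,
#'   with the two library denominators stored in attribute `denominators`.
#' @export
quantify <- function(features, aln_wt, aln_ko,
                     denominator_mode = c("total_reads", "aligned_reads"),
                     offset_tolerance = 3L, fractional = FALSE) {
  denominator_mode <- match.arg(denominator_mode)
  denom <- function(aln) {
    switch(denominator_mode,
           total_reads = aln$total_reads,
           aligned_reads = aln$reads_aligned)
  }
  d_wt <- denom(aln_wt)
  d_ko <- denom(aln_ko)
  if (d_wt <= 0 || d_ko <= 0) {
    stop("zero ", denominator_mode, " denominator in a library",
         call. = FALSE)
  }
  out <- features |>
    dplyr::mutate(
      raw_wt = count_features(features, aln_wt, offset_tolerance, fractional),
      raw_ko = count_features(features, aln_ko, offset_tolerance, fractional),
      rpm_wt = .data$raw_wt * 1e6 / d_wt,
      rpm_ko = .data$raw_ko * 1e6 / d_ko
    ) |>
    dplyr::select("feature_id", "feature_type", "raw_wt", "raw_ko",
                  "rpm_wt", "rpm_ko")
  attr(out, "denominators") <- c(wt = d_wt, ko = d_ko)
  out
}

#' Apply the expression floor
#'
#' Keeps features expressed at `floor` RPM or more in at least one of the two
#' libraries; everything else is excluded from differential classification.
#'
#' @param records Expression tibble from [quantify()].
#' @param floor Minimum RPM in at least one library (default 30).
#' @return The filtered tibble (denominator attribute preserved); kept and
#'   dropped counts per feature type are reported as a message.
#' @export
apply_floor <- function(records, floor = 30) {
  keep <- pmax(records$rpm_wt, records$rpm_ko) >= floor
  types <- sort(unique(records$feature_type))
  message("expression floor (>= ", floor, " RPM in >= 1 library): ",
          paste(vapply(types, function(ty) {
            sel <- records$feature_type == ty
            sprintf("%s %d kept/%d total", ty, sum(keep & sel), sum(sel))
          }, character(1)), collapse = "; "))
  out <- records[keep, , drop = FALSE]
  attr(out, "denominators") <- attr(records, "denominators")
  attr(out, "floor") <- floor
  out
}

#' Write the expression table to TSV
#'
#' @param records Expression tibble (all features, pre-floor).
#' @param path Output TSV path.
#' @param floor RPM floor used for the kept flag column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(records, path, floor = 30) {
  records |>
    dplyr::mutate(kept = pmax(.data$rpm_wt, .data$rpm_ko) >= floor) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
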