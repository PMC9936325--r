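#' Compare two small RNA libraries end to end
#'
#' The full analysis: align both libraries to the precursor reference by
#' perfect full-read matching, pool the alignments to profile snoRNA coverage
#' and call sdRNA loci, quantify every mature miRNA and sdRNA locus in RPM per
#' library, apply the expression floor, classify each expressed feature as
#' up / down / unchanged in the knockout, and summarise the class structure
#' per feature type.
#'
#' sdRNA loci are called on the pooled (WT + KO) alignments so that a locus
#' expressed in only one condition is still quantifiable in both.
#'
#' @param ref An `sdrna_reference` (indexed automatically if needed).
#' @param reads_wt,reads_ko Read tibbles (`read_id`, `seq`), character vectors
#'   of sequences, or paths to FASTQ/FASTA files.
#' @param floor RPM expression floor (default 30).
#' @param up,down Percent-of-WT class thresholds (defaults 150 and 50).
#' @param params [caller_params()] for sdRNA locus calling.
#' @param denominator_mode RPM denominator: `"total_reads"` or
#'   `"aligned_reads"`.
#' @param antisense Also accept reverse-complement placements.
#' @param fractional Split multi-mapped reads 1/multiplicity everywhere.
#' @return An `sdrna_switch` object: list with `alignments` (per-library
#'   `sdrna_alignments`), `profiles`, `loci`, `expression` (all features,
#'   pre-floor), `calls` (floored + classified), `summary`
#'   (an `sdrna_switch_summary`) and the parameters used.
#' @export
compare_libraries <- function(ref, reads_wt, reads_ko,
                              floor = 30, up = 150, down = 50,
                              params = caller_params(),
                              denominator_mode = c("total_reads",
                                                   "aligned_reads"),
                              antisense = FALSE, fractional = FALSE) {
  stopifnot(inherits(ref, "sdrna_reference"))
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(0 < down, down < 100, 100 < up)
  if (is.null(ref$kmers)) ref <- build_index(ref)

  as_aln <- function(reads) {
    if (inherits(reads, "sdrna_alignments")) return(reads)
    if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
      align_library(reads, ref, antisense = antisense)
    } else {
      align_reads(reads, ref, antisense = antisense)
    }
  }
  aln_wt <- as_aln(reads_wt)
  aln_ko <- as_aln(reads_ko)

  pooled <- pool_alignments(aln_wt, aln_ko)
  profiles <- build_profiles(pooled, ref, fractional = fractional)
  loci <- call_loci(profiles, ref, params = params)
  features <- feature_table(ref, loci)
  expression <- quantify(features, aln_wt, aln_ko,
                         denominator_mode = denominator_mode,
                         offset_tolerance = params$offset_tolerance,
                         fractional = fractional)
  calls <- apply_floor(expression, floor = floor) |>
    classify_expression(up = up, down = down)
  summary <- summarize_switch(calls)

  structure(
    list(
      alignments = list(wt = aln_wt, ko = aln_ko),
      profiles = profiles,
      loci = loci,
      expression = expression,
      calls = calls,
      summary = summary,
      params = list(floor = floor, up = up, down = down, caller = params,
                    denominator_mode = denominator_mode,
                    antisense = antisense, fractional = fractional)
    ),
    class = "sdrna_switch"
  )
}

# stack two alignment sets, prefixing read ids so libraries cannot collide
pool_alignments <- function(aln_wt, aln_ko) {
  tag <- function(aln, tag) {
    aln$alignments$read_id <- paste0(tag, ":", aln$alignments$read_id)
    aln
  }
  a <- tag(aln_wt, "wt")
  b <- tag(aln_ko, "ko")
  structure(
    list(
      alignments = dplyr::bind_rows(a$alignments, b$alignments),
      total_reads = a$total_reads + b$total_reads,
      reads_in_length_band = a$reads_in_length_band + b$reads_in_length_band,
      reads_aligned = a$reads_aligned + b$reads_aligned,
      multimapped_reads = a$multimapped_reads + b$multimapped_reads
    ),
    class = "sdrna_alignments"
  )
}

#' @export
print.sdrna_switch <- function(x, ...) {
  cat("<sdrna_switch>\n")
  cat("  WT: ", x$alignments$wt$reads_aligned, "/",
      x$alignments$wt$total_reads, " reads aligned;  KO: ",
      x$alignments$ko$reads_aligned, "/", x$alignments$ko$total_reads,
      "\n", sep = "")
  cat("  sdRNA loci called: ", nrow(x$loci), "\n", sep = "")
  cat("  expressed features (>= ", x$params$floor, " RPM): ",
      nrow(x$calls), "\n", sep = "")
  print(x$summary$by_type)
  invisible(x)
}

#' @rdname compare_libraries
#' @param x An `sdrna_switch` object.
#' @param ... Unused.
#' @export
tidy.sdrna_switch <- function(x, ...) {
  x$calls
}

#' @rdname compare_libraries
#' @export
glance.sdrna_switch <- function(x, ...) {
  x$summary$by_type |>
    tidyr::pivot_wider(
      names_from = "feature_type",
      values_from = -"feature_type",
      names_glue = "{feature_type}_{.value}"
    )
}

#' @rdname compare_libraries
#' @param object An `sdrna_switch` object.
#' @export
autoplot.sdrna_switch <- function(object, ...) {
  autoplot(object$summary, ...)
}

#' Pipeline run configuration
#'
#' Bundles every input path and module parameter for [run_pipeline()].
#'
#' @param mirna_fasta,snorna_fasta,annotations Reference inputs for
#'   [load_reference()] — or supply a ready `reference` object instead.
#' @param reference Optional pre-built `sdrna_reference` (overrides the FASTA
#'   paths).
#' @param wt,ko Read inputs: file paths or read tibbles.
#' @param out_dir Output directory for the artifact set.
#' @inheritParams compare_libraries
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(wt, ko, out_dir,
                            mirna_fasta = NULL, snorna_fasta = NULL,
                            annotations = NULL, reference = NULL,
                            floor = 30, up = 150, down = 50,
                            params = caller_params(),
                            denominator_mode = "total_reads",
                            antisense = FALSE, fractional = FALSE) {
  stopifnot(0 < down, down < 100, 100 < up)
  if (is.null(reference) && (is.null(mirna_fasta) || is.null(snorna_fasta))) {
    stop("supply either `reference` or both FASTA paths", call. = FALSE)
  }
  structure(
    list(wt = wt, ko = ko, out_dir = out_dir,
         mirna_fasta = mirna_fasta, snorna_fasta = snorna_fasta,
         annotations = annotations, reference = reference,
         floor = floor, up = up, down = down, params = params,
         denominator_mode = denominator_mode, antisense = antisense,
         fractional = fractional),
    class = "pipeline_config"
  )
}

#' Run the pipeline and write the full artifact set
#'
#' Executes [compare_libraries()] and writes every stage's table to
#' `out_dir`: alignment TSVs, coverage profile TSV + wiggle track, locus
#' BED6 + TSV, expression TSV, classified calls TSV, a summary JSON, and a
#' manifest of output files with MD5 hashes. Re-running the same
#' configuration reproduces the same hashes.
#'
#' @param config A [pipeline_config()].
#' @return The `sdrna_switch` result, invisibly, with the manifest tibble
#'   attached as attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- config$reference %||%
    load_reference(config$mirna_fasta, config$snorna_fasta,
                   config$annotations)

  res <- compare_libraries(
    ref, config$wt, config$ko,
    floor = config$floor, up = config$up, down = config$down,
    params = config$params, denominator_mode = config$denominator_mode,
    antisense = config$antisense, fractional = config$fractional
  )

  p <- function(f) file.path(config$out_dir, f)
  write_alignments_tsv(res$alignments$wt, p("alignments_wt.tsv"))
  write_alignments_tsv(res$alignments$ko, p("alignments_ko.tsv"))
  write_profiles_tsv(res$profiles, p("profiles.tsv"), wig = p("depth.wig"))
  write_loci_bed(res$loci, p("sdrna_loci.bed"), tsv = p("sdrna_loci.tsv"))
  write_expression_tsv(res$expression, p("expression.tsv"),
                       floor = config$floor)
  readr::write_tsv(res$calls, p("calls.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(by_type = res$summary$by_type,
         top_down = res$summary$top_down,
         top_up = res$summary$top_up,
         params = res$params[c("floor", "up", "down", "denominator_mode")]),
    p("summary.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA
  )

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files)
  )
  readr::write_tsv(manifest, p("manifest.tsv"), progress = FALSE)
  attr(res, "manifest") <- manifest
  invisible(res)
}
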