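#' Align reads by perfect, ungapped, full-read matching
#'
#' Places each read on the precursor reference wherever the entire read matches
#' exactly. Accepted placements are restricted to reads of 16-32 nt; shorter or
#' longer reads, and reads containing any non-ACGT character, are never
#' aligned. No mismatches or indels are tolerated. A read contributes one
#' alignment per distinct placement across the whole reference; `multiplicity`
#' records how many placements that read has in total, so downstream counting
#' can optionally split each read 1/multiplicity.
#'
#' @param reads A character vector of read sequences, or a data frame with
#'   columns `read_id` and `seq`.
#' @param ref An indexed `sdrna_reference` (see [build_index()]).
#' @param antisense Also report reverse-complement placements. Default `FALSE`:
#'   mature small RNAs are sense to their precursor.
#' @return An `sdrna_alignments` object: list with `alignments` (tibble:
#'   read_id, seq, precursor_id, start, end, strand, multiplicity; coordinates
#'   0-based half-open), and counters `total_reads`, `reads_in_length_band`,
#'   `reads_aligned`, `multimapped_reads`.
#' @export
align_reads <- function(reads, ref, antisense = FALSE) {
  stopifnot(inherits(ref, "sdrna_reference"))
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
    reads <- tibble(read_id = ids, seq = unname(reads))
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  reads <- tibble(read_id = as.character(reads$read_id),
                  seq = normalize_seq(reads$seq))

  len <- nchar(reads$seq)
  in_band <- len >= 16L & len <= 32L & is_plain_acgt(reads$seq)

  uniq <- unique(reads$seq[in_band])
  hits <- index_lookup(ref, uniq)
  hits$seq <- uniq[hits$query_index]
  hits$strand <- "SENSE"
  if (antisense) {
    rc <- revcomp(uniq)
    anti <- index_lookup(ref, rc)
    if (nrow(anti) > 0) {
      anti$seq <- uniq[anti$query_index]
      anti$strand <- "ANTISENSE"
      hits <- dplyr::bind_rows(hits, anti)
    }
  }
  hits <- dplyr::select(hits, "seq", "precursor_id", "start", "end", "strand")

  mult <- dplyr::count(hits, .data$seq, name = "multiplicity")
  aln <- reads[in_band, , drop = FALSE] |>
    dplyr::inner_join(hits, by = "seq", relationship = "many-to-many") |>
    dplyr::inner_join(mult, by = "seq") |>
    dplyr::arrange(.data$read_id, .data$precursor_id, .data$start,
                   .data$strand) |>
    dplyr::select("read_id", "seq", "precursor_id", "start", "end",
                  "strand", "multiplicity")

  aligned_ids <- unique(aln$read_id)
  structure(
    list(
      alignments = aln,
      total_reads = nrow(reads),
      reads_in_length_band = sum(in_band),
      reads_aligned = length(aligned_ids),
      multimapped_reads = length(unique(aln$read_id[aln$multiplicity > 1L]))
    ),
    class = "sdrna_alignments"
  )
}

#' Align a FASTQ/FASTA library
#'
#' Reads a sequence file (FASTQ or FASTA, optionally gzip-compressed; base
#' qualities are ignored) and aligns every read with [align_reads()]. Two runs
#' on the same input produce identical alignment tables.
#'
#' @param path Sequence file; format inferred from the extension
#'   (`.fastq`/`.fq`, with or without `.gz`, is FASTQ; anything else FASTA).
#' @inheritParams align_reads
#' @return An `sdrna_alignments` object.
#' @export
align_library <- function(path, ref, antisense = FALSE) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    if (length(lines) %% 4 != 0) {
      stop("truncated FASTQ record ", length(lines) %/% 4 + 1, " in ", path,
           call. = FALSE)
    }
    heads <- lines[seq(1, length(lines), by = 4)]
    seps <- lines[seq(3, length(lines), by = 4)]
    bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
    if (length(bad) > 0) {
      stop("malformed FASTQ record ", bad[1], " in ", path, call. = FALSE)
    }
    reads <- tibble(
      read_id = sub("\\s.*$", "", sub("^@", "", heads)),
      seq = lines[seq(2, length(lines), by = 4)]
    )
  } else {
    set <- tryCatch(
      Biostrings::readBStringSet(path),
      error = function(e) stop("failed to parse FASTA file ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    reads <- tibble(read_id = sub("\\s.*$", "", names(set)),
                    seq = unname(as.character(set)))
  }
  align_reads(reads, ref, antisense = antisense)
}

#' Write an alignment table to TSV
#'
#' @param aln An `sdrna_alignments` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(aln, path) {
  stopifnot(inherits(aln, "sdrna_alignments"))
  readr::write_tsv(dplyr::select(aln$alignments, -"seq"), path,
                   progress = FALSE)
  invisible(path)
}

#' @export
print.sdrna_alignments <- function(x, ...) {
  cat("<sdrna_alignments> ", x$reads_aligned, "/", x$total_reads,
      " reads aligned (", x$reads_in_length_band, " in 16-32 nt band, ",
      x$multimapped_reads, " multimapped; ",
      nrow(x$alignments), " placements)\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname align_reads
#' @param x An `sdrna_alignments` object.
#' @param ... Unused.
#' @export
glance.sdrna_alignments <- function(x, ...) {
  tibble(
    total_reads = x$total_reads,
    reads_in_length_band = x$reads_in_length_band,
    reads_aligned = x$reads_aligned,
    multimapped_reads = x$multimapped_reads,
    n_placements = nrow(x$alignments)
  )
}
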