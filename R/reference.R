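#' Load a combined miRNA + snoRNA precursor reference
#'
#' Parses one FASTA of miRNAs (mature sequences, or hairpins accompanied by a
#' mature-arm annotation table) and one FASTA of snoRNAs into a single
#' validated precursor set. Sequences are uppercased and U is normalised to T,
#' so downstream matching is in DNA space regardless of the input alphabet.
#' snoRNA records outside the 40-350 nt sanity band trigger a warning (the
#' class is canonically 60-300 nt) but are retained.
#'
#' @param mirna_fasta Path to a FASTA of miRNAs. Records are typed
#'   `MIRNA_HAIRPIN` when `annotations` is supplied, `MIRNA_MATURE` otherwise.
#' @param snorna_fasta Path to a FASTA of snoRNAs. SNORD*/SNORA* ids are
#'   subclassed as C/D-box and H/ACA-box respectively.
#' @param annotations Optional path to a TSV with columns
#'   `hairpin_id`, `arm_name`, `start`, `end` (0-based half-open intervals of
#'   mature arms on their hairpin).
#' @return An object of class `sdrna_reference`: a list with
#'   `records` (tibble: id, biotype, subclass, sequence, length),
#'   `mature` (arm annotation tibble or NULL), `sequences` (named character
#'   vector) and, after [build_index()], a `kmers` lookup table.
#' @examples
#' mirna <- tempfile(fileext = ".fa")
#' sno <- tempfile(fileext = ".fa")
#' writeLines(c(">mir-1", "ACGTACGTACGTACGTACGTAC"), mirna)
#' writeLines(c(">SNORD1", paste(rep("ACGGTTCA", 10), collapse = "")), sno)
#' ref <- load_reference(mirna, sno)
#' ref$records
#' @export
load_reference <- function(mirna_fasta, snorna_fasta, annotations = NULL) {
  mir <- read_fasta_records(mirna_fasta)
  sno <- read_fasta_records(snorna_fasta)

  mir_type <- if (is.null(annotations)) "MIRNA_MATURE" else "MIRNA_HAIRPIN"
  records <- dplyr::bind_rows(
    dplyr::mutate(mir, biotype = mir_type, subclass = NA_character_),
    dplyr::mutate(sno, biotype = "SNORNA", subclass = snorna_subclass(.data$id))
  )

  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0) {
    stop("duplicate record id(s) across reference inputs: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  records <- records |>
    dplyr::mutate(
      sequence = normalize_seq(.data$sequence),
      length = nchar(.data$sequence)
    ) |>
    dplyr::select("id", "biotype", "subclass", "sequence", "length")

  out_of_band <- records |>
    dplyr::filter(.data$biotype == "SNORNA",
                  .data$length < 40 | .data$length > 350)
  if (nrow(out_of_band) > 0) {
    warning("snoRNA record(s) outside the 40-350 nt sanity band: ",
            paste(out_of_band$id, collapse = ", "), call. = FALSE)
  }

  mature <- NULL
  if (!is.null(annotations)) {
    mature <- readr::read_tsv(annotations, show_col_types = FALSE,
                              progress = FALSE)
    required <- c("hairpin_id", "arm_name", "start", "end")
    if (!all(required %in% names(mature))) {
      stop("annotation table must have columns: ",
           paste(required, collapse = ", "), call. = FALSE)
    }
    mature <- validate_mature(tibble::as_tibble(mature), records)
  }

  ref <- structure(
    list(
      records = records,
      mature = mature,
      sequences = stats::setNames(records$sequence, records$id),
      kmers = NULL,
      k = NULL
    ),
    class = "sdrna_reference"
  )

  counts <- table(records$biotype)
  message("loaded reference: ",
          paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  ref
}

# Biostrings does the FASTA parsing; names are truncated at first whitespace
read_fasta_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("empty FASTA: ", path, call. = FALSE)
  tibble(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set))
  )
}

snorna_subclass <- function(id) {
  dplyr::case_when(
    grepl("^SNORD", id, ignore.case = TRUE) ~ "CD_BOX",
    grepl("^SNORA", id, ignore.case = TRUE) ~ "HACA_BOX",
    TRUE ~ "UNKNOWN"
  )
}

validate_mature <- function(mature, records) {
  lens <- stats::setNames(records$length, records$id)
  unknown <- setdiff(mature$hairpin_id, records$id)
  if (length(unknown) > 0) {
    stop("mature annotation refers to unknown hairpin(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- mature$start < 0 | mature$end > lens[mature$hairpin_id] |
    mature$start >= mature$end
  if (any(bad)) {
    stop("mature arm interval(s) outside hairpin bounds: ",
         paste(mature$arm_name[bad], collapse = ", "), call. = FALSE)
  }
  mature
}

#' Build the exact-match substring index
#'
#' Indexes every 16-mer of every precursor by its sequence so that any query of
#' 16-32 nt can be resolved to all of its exact sense-strand occurrences: a
#' full-read match must begin with the read's first 16-mer, so candidate
#' placements come from one table lookup and are verified by direct substring
#' comparison. (This also subsumes a word-size-6 seeded search: any exact match
#' of at least 16 nt contains every one of its 6-mers.)
#'
#' @param ref An `sdrna_reference` from [load_reference()].
#' @return The reference with its `kmers` lookup table populated.
#' @export
build_index <- function(ref) {
  stopifnot(inherits(ref, "sdrna_reference"))
  k <- 16L
  per_rec <- purrr::map2(ref$records$id, ref$records$sequence, function(id, s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    starts <- seq_len(n)
    tibble(kmer = substring(s, starts, starts + k - 1L),
           precursor_id = id, pos = starts)
  })
  ref$kmers <- dplyr::bind_rows(per_rec)
  ref$k <- k
  ref
}

# All exact sense-strand occurrences of each query (16-32 nt, ACGT only).
# Returns tibble(query_index, precursor_id, start, end), 0-based half-open.
index_lookup <- function(ref, queries) {
  if (is.null(ref$kmers)) stop("reference has no index; call build_index()",
                               call. = FALSE)
  empty <- tibble(query_index = integer(), precursor_id = character(),
                  start = integer(), end = integer())
  if (length(queries) == 0) return(empty)
  qt <- tibble(query_index = seq_along(queries), q = queries,
               kmer = substr(queries, 1L, ref$k))
  hits <- dplyr::inner_join(qt, ref$kmers, by = "kmer")
  if (nrow(hits) == 0) return(empty)
  qlen <- nchar(hits$q)
  found <- substring(ref$sequences[hits$precursor_id], hits$pos,
                     hits$pos + qlen - 1L) == hits$q
  hits <- hits[found, , drop = FALSE]
  tibble(
    query_index = hits$query_index,
    precursor_id = hits$precursor_id,
    start = hits$pos - 1L,
    end = hits$pos - 1L + nchar(hits$q)
  )
}

#' Write a reference back to FASTA (with an optional manifest)
#'
#' @param ref An `sdrna_reference`.
#' @param fasta Output FASTA path.
#' @param manifest Optional TSV path for (id, biotype, subclass, length).
#' @return `fasta`, invisibly.
#' @export
write_reference_fasta <- function(ref, fasta, manifest = NULL) {
  stopifnot(inherits(ref, "sdrna_reference"))
  writeLines(paste0(">", ref$records$id, "\n", ref$records$sequence), fasta)
  if (!is.null(manifest)) {
    readr::write_tsv(dplyr::select(ref$records, -"sequence"), manifest,
                     progress = FALSE)
  }
  invisible(fasta)
}

#' @export
print.sdrna_reference <- function(x, ...) {
  counts <- table(x$records$biotype)
  cat("<sdrna_reference> ", nrow(x$records), " precursors (",
      paste(names(counts), as.integer(counts), sep = ": ", collapse = ", "),
      ")", if (!is.null(x$kmers)) " [indexed]", "\n", sep = "")
  if (!is.null(x$mature)) {
    cat("  mature arm annotations: ", nrow(x$mature), "\n", sep = "")
  }
  invisible(x)
}
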