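# fixtures are built in code: tiny references, read sets, and an
# index-independent brute-force matcher used as the alignment oracle

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a named character vector as FASTA and return the path
write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

# build an indexed reference from two in-code sequence sets
make_ref <- function(mirna, snorna, annotations = NULL) {
  ann_path <- NULL
  if (!is.null(annotations)) {
    ann_path <- tempfile(fileext = ".tsv")
    readr::write_tsv(annotations, ann_path, progress = FALSE)
  }
  suppressMessages(
    load_reference(write_tmp_fasta(mirna), write_tmp_fasta(snorna), ann_path)
  ) |>
    build_index()
}

# a reference of random precursors, seeded
make_random_ref <- function(n_mirna = 5, n_snorna = 5, len_range = c(60, 200),
                            seed = 1) {
  set.seed(seed)
  mir <- vapply(seq_len(n_mirna),
                function(i) rand_seq(sample(40:90, 1)), character(1))
  names(mir) <- sprintf("mir-%d", seq_len(n_mirna))
  sno <- vapply(seq_len(n_snorna),
                function(i) rand_seq(sample(len_range[1]:len_range[2], 1)),
                character(1))
  names(sno) <- sprintf("SNORD%d", seq_len(n_snorna))
  make_ref(mir, sno)
}

# brute-force full-read matcher: every exact occurrence of `query` in any
# reference sequence, via base gregexpr -- independent of the package's index
naive_hits <- function(ref, query) {
  hits <- lapply(names(ref$sequences), function(id) {
    m <- gregexpr(query, ref$sequences[[id]], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(precursor_id = id, start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + nchar(query))
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(precursor_id = character(), start = integer(),
                      end = integer())
  }
  out[order(out$precursor_id, out$start), , drop = FALSE]
}

# the naive aligner the index must agree with: empty outside 16-32 nt or on N
naive_align <- function(ref, read) {
  if (nchar(read) < 16 || nchar(read) > 32 || grepl("[^ACGT]", read)) {
    return(naive_hits(ref, paste(rep("Z", 40), collapse = "")))
  }
  naive_hits(ref, read)
}

# canonical string form of an alignment set, for set comparisons
aln_key <- function(df) {
  sort(paste(df$precursor_id, df$start, df$end, sep = ":"))
}

# reads as a tibble from a character vector
read_tbl <- function(seqs, prefix = "r") {
  tibble::tibble(read_id = sprintf("%s%05d", prefix, seq_along(seqs)),
                 seq = seqs)
}
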