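# shared internal helpers

#' @importFrom rlang .data .env
#' @importFrom tibble tibble as_tibble
NULL

# uppercase and collapse RNA to DNA alphabet; anything else is left as-is
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

revcomp <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x)
  out[!ok] <- NA_character_
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

is_plain_acgt <- function(x) {
  !grepl("[^ACGT]", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
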