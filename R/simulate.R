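#' Simulation configuration
#'
#' Parameters for the paired-library small RNA simulator. The defaults are the
#' study conditions the pipeline is validated against: 288 miRNA hairpins each
#' expressing one mature arm and 103 snoRNA hosts each carrying one planted
#' fragment window, knockout/wild-type expression ratios centred on 6.4% for
#' miRNAs and 679.3% for sdRNAs, with roughly one feature in ten per type held
#' flat (ratio exactly 1).
#'
#' @param seed Integer seed; every random draw in the simulator flows from it.
#' @param n_mirna Number of miRNA hairpins (one expressed mature arm each).
#' @param n_snorna Number of snoRNA hosts.
#' @param reads_per_library Total reads per library (background included).
#' @param mirna_ko_ratio_mean Mean KO/WT expression ratio for miRNAs.
#' @param sdrna_ko_ratio_mean Mean KO/WT expression ratio for sdRNAs.
#' @param ratio_dispersion Lognormal sigma of per-feature KO/WT ratios.
#' @param abundance_sigma Lognormal sigma of per-feature WT abundances.
#' @param fragment_length_range Planted fragment length band (nt).
#' @param background_fraction Fraction of wild-type reads that are decoys
#'   matching nothing in the reference.
#' @param unchanged_fraction_mirna,unchanged_fraction_sdrna Fraction of
#'   features per type forced to ratio 1 (an exact rounded count, not a
#'   Bernoulli draw, so class counts are stable across seeds).
#' @param mirna_read_share Share of aligned wild-type reads drawn from miRNA
#'   arms (the remainder comes from snoRNA fragment windows).
#' @param second_fragment_prob Probability that a snoRNA host carries a second
#'   planted fragment window.
#' @param end_jitter Maximum 5'/3' end jitter of simulated reads around their
#'   planted fragment (nt); jittered reads stay within the host and the
#'   16-32 nt band.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirna = 288L,
                       n_snorna = 103L,
                       reads_per_library = 1e5,
                       mirna_ko_ratio_mean = 0.064,
                       sdrna_ko_ratio_mean = 6.793,
                       ratio_dispersion = 0.35,
                       abundance_sigma = 1,
                       fragment_length_range = c(20L, 24L),
                       background_fraction = 0.1,
                       unchanged_fraction_mirna = 29 / 288,
                       unchanged_fraction_sdrna = 8 / 103,
                       mirna_read_share = 0.85,
                       second_fragment_prob = 0,
                       end_jitter = 2L) {
  stopifnot(mirna_ko_ratio_mean > 0, sdrna_ko_ratio_mean > 0,
            ratio_dispersion >= 0, reads_per_library > 0,
            background_fraction >= 0, background_fraction < 1,
            unchanged_fraction_mirna >= 0, unchanged_fraction_mirna < 1,
            unchanged_fraction_sdrna >= 0, unchanged_fraction_sdrna < 1,
            mirna_read_share > 0, mirna_read_share < 1,
            fragment_length_range[1] >= 16, fragment_length_range[2] <= 32)
  structure(
    list(seed = as.integer(seed), n_mirna = as.integer(n_mirna),
         n_snorna = as.integer(n_snorna),
         reads_per_library = as.integer(reads_per_library),
         mirna_ko_ratio_mean = mirna_ko_ratio_mean,
         sdrna_ko_ratio_mean = sdrna_ko_ratio_mean,
         ratio_dispersion = ratio_dispersion,
         abundance_sigma = abundance_sigma,
         fragment_length_range = as.integer(fragment_length_range),
         background_fraction = background_fraction,
         unchanged_fraction_mirna = unchanged_fraction_mirna,
         unchanged_fraction_sdrna = unchanged_fraction_sdrna,
         mirna_read_share = mirna_read_share,
         second_fragment_prob = second_fragment_prob,
         end_jitter = as.integer(end_jitter)),
    class = "sim_config"
  )
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a miRNA + snoRNA precursor reference with planted fragments
#'
#' Generates random snoRNA sequences (lengths uniform on 60-300 nt) and miRNA
#' hairpins with designated 20-23 nt mature arms at the hairpin termini. Each
#' snoRNA receives one planted fragment window (optionally a second,
#' non-overlapping one). Sequences are rejection-resampled until every planted
#' fragment — mature arm or snoRNA window — occurs exactly once in the whole
#' reference, so a read drawn from a planted fragment has multiplicity 1 by
#' construction.
#'
#' @param config A [sim_config()].
#' @return A list: `reference` (an `sdrna_reference` with hairpin arm
#'   annotations) and `truth` (tibble: feature_id, feature_type,
#'   precursor_id, start, end, seq — every plantable feature).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  # hairpins: 5p arm | loop | 3p arm; one arm (chosen later) is expressed
  hairpins <- purrr::map(seq_len(config$n_mirna), function(i) {
    arm5 <- sample(20:23, 1)
    arm3 <- sample(20:23, 1)
    loop <- sample(12:20, 1)
    seq <- random_seq(arm5 + loop + arm3)
    len <- nchar(seq)
    list(
      id = sprintf("sim-mir-%d", i),
      sequence = seq,
      arms = tibble(
        hairpin_id = sprintf("sim-mir-%d", i),
        arm_name = sprintf("sim-miR-%d-%s", i, c("5p", "3p")),
        start = c(0L, len - arm3),
        end = c(arm5, len)
      )
    )
  })

  frag_band <- config$fragment_length_range
  snornas <- purrr::map(seq_len(config$n_snorna), function(i) {
    len <- sample(60:300, 1)
    n_frag <- 1L + stats::rbinom(1, 1, config$second_fragment_prob)
    # windows kept >= 10 nt apart so two loci on one host never overlap
    repeat {
      w_len <- sample(frag_band[1]:frag_band[2], n_frag, replace = TRUE)
      w_start <- vapply(w_len, function(l) sample(0:(len - l), 1), integer(1))
      if (n_frag == 1L ||
          min(abs(diff(sort(w_start)))) >= max(w_len) + 10L) break
    }
    list(
      id = sprintf("SNOR%s%d", sample(c("D", "A"), 1), i),
      length = len,
      sequence = random_seq(len),
      windows = tibble(start = as.integer(w_start),
                       end = as.integer(w_start + w_len))
    )
  })

  records <- dplyr::bind_rows(
    tibble(id = purrr::map_chr(hairpins, "id"),
           biotype = "MIRNA_HAIRPIN", subclass = NA_character_,
           sequence = purrr::map_chr(hairpins, "sequence")),
    tibble(id = purrr::map_chr(snornas, "id"),
           biotype = "SNORNA",
           subclass = snorna_subclass(purrr::map_chr(snornas, "id")),
           sequence = purrr::map_chr(snornas, "sequence"))
  )
  records$length <- nchar(records$sequence)
  mature <- dplyr::bind_rows(purrr::map(hairpins, "arms"))

  # expressed features: one arm per hairpin, every snoRNA window
  expressed_arm <- mature |>
    dplyr::group_by(.data$hairpin_id) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup()
  truth <- dplyr::bind_rows(
    tibble(feature_id = expressed_arm$arm_name, feature_type = "miRNA",
           precursor_id = expressed_arm$hairpin_id,
           start = expressed_arm$start, end = expressed_arm$end),
    purrr::map2(snornas, purrr::map_chr(snornas, "id"), function(s, id) {
      tibble(feature_id = NA_character_, feature_type = "sdRNA",
             precursor_id = id, start = s$windows$start, end = s$windows$end)
    }) |> dplyr::bind_rows()
  )
  seqs <- stats::setNames(records$sequence, records$id)
  truth$seq <- substr(seqs[truth$precursor_id], truth$start + 1L, truth$end)
  truth$feature_id[truth$feature_type == "sdRNA"] <-
    sprintf("frag-%s-%d", truth$precursor_id[truth$feature_type == "sdRNA"],
            truth$start[truth$feature_type == "sdRNA"])

  # multiplicity-1 screening: resample any host whose planted fragment
  # recurs anywhere in the reference (vanishingly rare for random sequence)
  for (attempt in 1:20) {
    all_seq <- paste(records$sequence, collapse = "#")
    n_occ <- vapply(truth$seq, function(q) {
      m <- gregexpr(q, all_seq, fixed = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }, integer(1))
    if (all(n_occ == 1L)) break
    if (attempt == 20) {
      stop("could not plant unique fragments; enlarge the sequence space",
           call. = FALSE)
    }
    bad_hosts <- unique(truth$precursor_id[n_occ != 1L])
    for (h in bad_hosts) {
      i <- which(records$id == h)
      records$sequence[i] <- random_seq(records$length[i])
    }
    seqs <- stats::setNames(records$sequence, records$id)
    truth$seq <- substr(seqs[truth$precursor_id], truth$start + 1L, truth$end)
  }

  reference <- structure(
    list(records = dplyr::select(records, "id", "biotype", "subclass",
                                 "sequence", "length"),
         mature = mature,
         sequences = stats::setNames(records$sequence, records$id),
         kmers = NULL, k = NULL),
    class = "sdrna_reference"
  )
  list(reference = reference, truth = truth)
}

#' Simulate paired wild-type / knockout libraries with known truth
#'
#' Draws per-feature wild-type abundances (lognormal, normalised within
#' feature type and weighted by `mirna_read_share`), assigns each feature a
#' KO/WT ratio (lognormal around the type mean, with an exact rounded count of
#' features per type forced to ratio 1), and samples reads multinomially.
#' Knockout expected counts are wild-type expected counts times the planted
#' ratio, and decoy background fills both libraries to exactly
#' `reads_per_library` reads, so both RPM denominators are equal and the
#' realised percent-of-WT of a feature is centred on its planted ratio.
#' Read sequences are the planted fragment with up to `end_jitter` nt of end
#' jitter (staying inside the host and the 16-32 nt band); decoys are random
#' sequences verified to match nowhere in the reference.
#'
#' @param ref The `sdrna_reference` from [simulate_reference()].
#' @param truth The truth tibble from [simulate_reference()].
#' @param config The same [sim_config()].
#' @return A list: `wt` and `ko` (read tibbles: read_id, seq), and `truth`
#'   with planted ratios, realised counts, realised percent-of-WT and the
#'   true class appended.
#' @export
simulate_libraries <- function(ref, truth, config) {
  stopifnot(inherits(ref, "sdrna_reference"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  if (is.null(ref$kmers)) ref <- build_index(ref)

  n <- nrow(truth)
  is_mir <- truth$feature_type == "miRNA"
  type_share <- ifelse(is_mir, config$mirna_read_share,
                       1 - config$mirna_read_share)
  w_raw <- stats::rlnorm(n, 0, config$abundance_sigma)
  w <- numeric(n)
  for (ty in c(TRUE, FALSE)) {
    sel <- is_mir == ty
    w[sel] <- type_share[sel] * w_raw[sel] / sum(w_raw[sel])
  }

  ratio_mean <- ifelse(is_mir, config$mirna_ko_ratio_mean,
                       config$sdrna_ko_ratio_mean)
  s <- config$ratio_dispersion
  ratio <- stats::rlnorm(n, log(ratio_mean) - s^2 / 2, s)
  forced <- logical(n)
  for (ty in c(TRUE, FALSE)) {
    sel <- which(is_mir == ty)
    frac <- if (ty) config$unchanged_fraction_mirna else
      config$unchanged_fraction_sdrna
    k <- round(length(sel) * frac)
    if (k > 0) forced[sample(sel, k)] <- TRUE
  }
  ratio[forced] <- 1

  n_lib <- config$reads_per_library
  aligned_wt <- n_lib - round(config$background_fraction * n_lib)
  wt_counts <- as.integer(stats::rmultinom(1, aligned_wt, w))

  ko_expect <- (w / sum(w)) * aligned_wt * ratio
  ko_scale <- min(1, (n_lib - 1) / sum(ko_expect))
  if (ko_scale < 1) {
    warning("knockout aligned mass exceeds library size; ",
            "ratios rescaled by ", signif(ko_scale, 3), call. = FALSE)
    ko_expect <- ko_expect * ko_scale
  }
  ko_aligned <- round(sum(ko_expect))
  ko_counts <- as.integer(stats::rmultinom(1, ko_aligned,
                                           ko_expect / sum(ko_expect)))

  host_len <- stats::setNames(ref$records$length, ref$records$id)
  feature_reads <- function(counts) {
    idx <- rep.int(seq_len(n), counts)
    m <- length(idx)
    if (m == 0) return(character())
    j <- config$end_jitter
    jit <- function() {
      if (j == 0L) return(rep(0L, m))
      sample(seq(-j, j), m, replace = TRUE,
             prob = stats::dnorm(seq(-j, j), 0, 1))
    }
    j5 <- jit()
    j3 <- jit()
    st <- truth$start[idx] + j5
    en <- truth$end[idx] + j3
    len_ok <- (en - st) >= 16L & (en - st) <= 32L
    bounds_ok <- st >= 0L & en <= host_len[truth$precursor_id[idx]]
    bad <- !(len_ok & bounds_ok)
    st[bad] <- truth$start[idx][bad]
    en[bad] <- truth$end[idx][bad]
    substr(ref$sequences[truth$precursor_id[idx]], st + 1L, en)
  }

  decoys <- function(m) {
    if (m == 0) return(character())
    out <- character(0)
    for (attempt in 1:50) {
      need <- m - length(out)
      if (need == 0) break
      lens <- sample(16:32, need, replace = TRUE)
      cand <- vapply(lens, random_seq, character(1))
      hits <- index_lookup(ref, cand)
      out <- c(out, cand[!(seq_along(cand) %in% hits$query_index)])
    }
    if (length(out) < m) stop("could not generate unalignable decoys",
                              call. = FALSE)
    out
  }

  make_lib <- function(counts, aligned_total, tag) {
    seqs <- c(feature_reads(counts), decoys(n_lib - aligned_total))
    seqs <- seqs[sample.int(length(seqs))]
    tibble(read_id = sprintf("%s_%07d", tag, seq_along(seqs)), seq = seqs)
  }
  wt <- make_lib(wt_counts, sum(wt_counts), "WT")
  ko <- make_lib(ko_counts, sum(ko_counts), "KO")

  truth_out <- truth |>
    dplyr::mutate(
      wt_weight = w,
      ko_ratio = ratio,
      forced_unchanged = forced,
      wt_count = wt_counts,
      ko_count = ko_counts,
      true_percent_of_wt = 100 * ratio,
      realized_percent_of_wt = ifelse(wt_counts == 0,
                                      ifelse(ko_counts == 0, NA_real_, Inf),
                                      100 * ko_counts / wt_counts),
      true_class = dplyr::case_when(
        100 * ratio >= 150 ~ "UP",
        100 * ratio <= 50 ~ "DOWN",
        TRUE ~ "UNCHANGED"
      )
    )
  list(wt = wt, ko = ko, truth = truth_out)
}

#' Write a read tibble as FASTQ
#'
#' Emits fixed maximum base qualities ('I'): the aligner is quality-blind, so
#' simulated qualities carry no information.
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param path Output path; `.gz` suffix writes gzip-compressed.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
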