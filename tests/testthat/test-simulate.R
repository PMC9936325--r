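small_cfg <- function(...) {
  sim_config(seed = 71, n_mirna = 10, n_snorna = 5,
             reads_per_library = 5000, ...)
}

test_that("the simulated reference has the configured structure", {
  sim <- simulate_reference(small_cfg())
  rec <- sim$reference$records
  expect_equal(nrow(rec), 15)
  expect_equal(sum(rec$biotype == "MIRNA_HAIRPIN"), 10)
  expect_equal(sum(rec$biotype == "SNORNA"), 5)
  sno_len <- rec$length[rec$biotype == "SNORNA"]
  expect_true(all(sno_len >= 60 & sno_len <= 300))
  expect_gte(sum(sim$truth$feature_type == "sdRNA"), 5)
  # one expressed arm per hairpin, annotated on both arms
  expect_equal(sum(sim$truth$feature_type == "miRNA"), 10)
  expect_equal(nrow(sim$reference$mature), 20)
  arm_len <- sim$reference$mature$end - sim$reference$mature$start
  expect_true(all(arm_len >= 20 & arm_len <= 23))
})

test_that("planted fragments occur exactly once in the reference", {
  sim <- simulate_reference(small_cfg())
  ref <- build_index(sim$reference)
  res <- align_reads(read_tbl(sim$truth$seq), ref)
  expect_equal(res$reads_aligned, nrow(sim$truth))
  expect_true(all(res$alignments$multiplicity == 1L))
  # and each lands back on its own planted interval
  expect_equal(res$alignments$precursor_id, sim$truth$precursor_id)
  expect_equal(res$alignments$start, sim$truth$start)
})

test_that("the simulator is deterministic end to end under one seed", {
  a <- simulate_reference(small_cfg())
  b <- simulate_reference(small_cfg())
  expect_identical(a$reference$records, b$reference$records)
  fa_a <- tempfile(fileext = ".fa")
  fa_b <- tempfile(fileext = ".fa")
  write_reference_fasta(a$reference, fa_a)
  write_reference_fasta(b$reference, fa_b)
  expect_identical(unname(tools::md5sum(fa_a)), unname(tools::md5sum(fa_b)))

  la <- suppressWarnings(simulate_libraries(a$reference, a$truth, small_cfg()))
  lb <- suppressWarnings(simulate_libraries(b$reference, b$truth, small_cfg()))
  expect_identical(la$wt, lb$wt)
  expect_identical(la$ko, lb$ko)
  expect_identical(la$truth, lb$truth)
})

test_that("library sizes are exact and background never aligns", {
  cfg <- small_cfg(background_fraction = 0.2)
  sim <- simulate_reference(cfg)
  libs <- suppressWarnings(simulate_libraries(sim$reference, sim$truth, cfg))
  expect_equal(nrow(libs$wt), 5000)
  expect_equal(nrow(libs$ko), 5000)

  ref <- build_index(sim$reference)
  aln <- align_reads(libs$wt, ref)
  expect_equal(aln$reads_aligned, sum(libs$truth$wt_count))
  expect_equal(aln$total_reads - aln$reads_aligned, round(0.2 * 5000))
})

test_that("zero background means every read aligns", {
  cfg <- small_cfg(background_fraction = 0)
  sim <- simulate_reference(cfg)
  libs <- suppressWarnings(
    simulate_libraries(sim$reference, sim$truth, cfg)
  )
  aln <- align_reads(libs$wt, build_index(sim$reference))
  expect_equal(aln$reads_aligned, aln$total_reads)
})

test_that("unit ratios with no dispersion yield no differential calls", {
  cfg <- sim_config(seed = 72, n_mirna = 10, n_snorna = 5,
                    reads_per_library = 2e4,
                    mirna_ko_ratio_mean = 1, sdrna_ko_ratio_mean = 1,
                    ratio_dispersion = 0, abundance_sigma = 0,
                    unchanged_fraction_mirna = 0,
                    unchanged_fraction_sdrna = 0)
  sim <- simulate_reference(cfg)
  libs <- suppressWarnings(simulate_libraries(sim$reference, sim$truth, cfg))
  res <- suppressMessages(
    compare_libraries(sim$reference, libs$wt, libs$ko)
  )
  s <- res$summary$by_type
  expect_equal(sum(s$n_up), 0)
  expect_equal(sum(s$n_down), 0)
  expect_equal(sum(s$n_unchanged), sum(s$n_expressed))
})

test_that("a second fragment window can be planted and recovered", {
  cfg <- sim_config(seed = 73, n_mirna = 5, n_snorna = 6,
                    reads_per_library = 2e4, second_fragment_prob = 1)
  sim <- simulate_reference(cfg)
  expect_equal(sum(sim$truth$feature_type == "sdRNA"), 12)
  per_host <- table(sim$truth$precursor_id[sim$truth$feature_type == "sdRNA"])
  expect_true(all(per_host == 2))

  libs <- suppressWarnings(simulate_libraries(sim$reference, sim$truth, cfg))
  res <- suppressMessages(compare_libraries(sim$reference, libs$wt, libs$ko))
  # every called anchor is a planted window start
  expect_true(all(paste(res$loci$host_id, res$loci$start) %in%
                    paste(sim$truth$precursor_id, sim$truth$start)))
  # hosts where both windows were called use the positional arm suffixes
  paired <- names(which(table(res$loci$host_id) == 2))
  expect_gt(length(paired), 0)
  expect_true(all(grepl("-(5p|3p)$",
                        res$loci$sdrna_id[res$loci$host_id %in% paired])))
})
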