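pad_junk <- function(n) rep("ACGT", n) # counted in totals, never aligned

test_that("RPM is definitional: count x 1e6 / library total", {
  set.seed(51)
  mir_seq <- rand_seq(22)
  ref <- make_ref(c(`mir-a` = mir_seq), c(SNORD1 = rand_seq(100)))
  # 30 aligned reads in a 1000-read library -> 30000 RPM
  aln_wt <- align_reads(read_tbl(c(rep(mir_seq, 30), pad_junk(970))), ref)
  aln_ko <- align_reads(read_tbl(c(rep(mir_seq, 60), pad_junk(940))), ref)
  expect_equal(aln_wt$total_reads, 1000)

  expr <- quantify(feature_table(ref, call_loci(
    build_profiles(aln_wt, ref), ref)), aln_wt, aln_ko)
  row <- expr[expr$feature_id == "mir-a", ]
  expect_equal(row$raw_wt, 30)
  expect_equal(row$rpm_wt, 30 * 1e6 / 1000)
  expect_equal(row$rpm_ko, 60 * 1e6 / 1000)
  expect_equal(attr(expr, "denominators"), c(wt = 1000, ko = 1000))
})

test_that("scaling counts and denominator together leaves RPM unchanged", {
  set.seed(52)
  mir_seq <- rand_seq(20)
  ref <- make_ref(c(`mir-a` = mir_seq), c(SNORD1 = rand_seq(100)))
  base <- c(rep(mir_seq, 7), pad_junk(93))
  a1 <- align_reads(read_tbl(base), ref)
  a3 <- align_reads(read_tbl(rep(base, 3)), ref)
  feats <- feature_table(ref, call_loci(build_profiles(a1, ref), ref))
  expect_equal(quantify(feats, a1, a1)$rpm_wt,
               quantify(feats, a3, a3)$rpm_wt)
})

test_that("denominator modes differ exactly by the unaligned mass", {
  set.seed(53)
  mir_seq <- rand_seq(20)
  ref <- make_ref(c(`mir-a` = mir_seq), c(SNORD1 = rand_seq(100)))
  aln <- align_reads(read_tbl(c(rep(mir_seq, 10), pad_junk(40))), ref)
  feats <- feature_table(ref, call_loci(build_profiles(aln, ref), ref))
  total <- quantify(feats, aln, aln, denominator_mode = "total_reads")
  aligned <- quantify(feats, aln, aln, denominator_mode = "aligned_reads")
  expect_equal(total$rpm_wt, 10 * 1e6 / 50)
  expect_equal(aligned$rpm_wt, 10 * 1e6 / 10)

  none <- align_reads(read_tbl(pad_junk(5)), ref)
  expect_error(quantify(feats, none, none,
                        denominator_mode = "aligned_reads"), "denominator")
})

test_that("the expression floor keeps >= 30 RPM in at least one library", {
  rec <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    feature_type = "miRNA",
    raw_wt = 0, raw_ko = 0,
    rpm_wt = c(29.9, 0, 30, 29.9),
    rpm_ko = c(29.9, 30, 0, 30.1)
  )
  kept <- suppressMessages(apply_floor(rec))
  expect_setequal(kept$feature_id, c("b", "c", "d"))

  # monotonicity: raising the floor never enlarges the kept set
  set.seed(54)
  rnd <- tibble::tibble(
    feature_id = as.character(1:200), feature_type = "miRNA",
    raw_wt = 0, raw_ko = 0,
    rpm_wt = stats::rlnorm(200, 3, 1.5), rpm_ko = stats::rlnorm(200, 3, 1.5)
  )
  floors <- c(0, 1, 10, 30, 100, 1000)
  kept_n <- vapply(floors, function(f) {
    nrow(suppressMessages(apply_floor(rnd, floor = f)))
  }, numeric(1))
  expect_true(all(diff(kept_n) <= 0))
  expect_equal(kept_n[1], 200)
})

test_that("hairpin reads are attributed to arms by half-read overlap", {
  set.seed(55)
  hp <- rand_seq(60) # arm5 = [0, 22)
  ann <- tibble::tibble(hairpin_id = "hp1", arm_name = c("hp1-5p", "hp1-3p"),
                        start = c(0L, 40L), end = c(22L, 60L))
  ref <- make_ref(c(hp1 = hp), c(SNORD1 = rand_seq(100)), annotations = ann)
  reads <- c(
    rep(substr(hp, 3, 24), 5),  # [2, 24): 20/22 nt inside the 5p arm
    rep(substr(hp, 19, 38), 4), # [18, 38): only 4/20 nt inside -> loop read
    rep(substr(hp, 41, 60), 3)  # [40, 60): fully inside the 3p arm
  )
  aln <- align_reads(read_tbl(reads), ref)
  expr <- quantify(feature_table(ref, call_loci(
    build_profiles(aln, ref), ref)), aln, aln)
  expect_equal(expr$raw_wt[expr$feature_id == "hp1-5p"], 5)
  expect_equal(expr$raw_wt[expr$feature_id == "hp1-3p"], 3)
})

test_that("sdRNA locus counts are anchored fragment-species counts", {
  set.seed(56)
  sno_seq <- rand_seq(120)
  ref <- make_ref(c(`mir-a` = rand_seq(22)), c(SNORD4 = sno_seq))
  reads_wt <- c(rep(substr(sno_seq, 31, 52), 40), # anchor 30
                rep(substr(sno_seq, 33, 54), 6),  # start 32: within +/-3
                rep(substr(sno_seq, 61, 82), 9))  # start 60: outside, no peak
  aln_wt <- align_reads(read_tbl(reads_wt), ref)
  aln_ko <- align_reads(read_tbl(rep(substr(sno_seq, 31, 52), 10)), ref)
  loci <- call_loci(build_profiles(
    sdrnaswitch:::pool_alignments(aln_wt, aln_ko), ref), ref)
  expect_equal(nrow(loci), 1)
  expr <- quantify(feature_table(ref, loci), aln_wt, aln_ko)
  sd_row <- expr[expr$feature_type == "sdRNA", ]
  expect_equal(sd_row$raw_wt, 46) # 40 at the anchor + 6 within tolerance
  expect_equal(sd_row$raw_ko, 10)
})

test_that("fractional counting splits a shared read across features", {
  set.seed(57)
  motif <- rand_seq(20)
  ref <- make_ref(c(`mir-a` = motif, `mir-b` = motif),
                  c(SNORD1 = rand_seq(100)))
  aln <- align_reads(read_tbl(rep(motif, 4)), ref)
  feats <- feature_table(ref, call_loci(build_profiles(aln, ref), ref))
  whole <- quantify(feats, aln, aln)
  frac <- quantify(feats, aln, aln, fractional = TRUE)
  expect_equal(whole$raw_wt[whole$feature_id == "mir-a"], 4)
  expect_equal(frac$raw_wt[frac$feature_id == "mir-a"], 2)
  expect_equal(sum(frac$raw_wt), 4)
})
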