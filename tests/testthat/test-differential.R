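records_at <- function(percent, rpm_wt = 100) {
  tibble::tibble(
    feature_id = sprintf("f%03d", seq_along(percent)),
    feature_type = "miRNA",
    raw_wt = rpm_wt, raw_ko = rpm_wt * percent / 100,
    rpm_wt = rpm_wt, rpm_ko = rpm_wt * percent / 100
  )
}

test_that("threshold boundaries are classified bit-exactly", {
  grid <- c(49.99, 50, 50.01, 100, 149.99, 150, 150.01)
  calls <- classify_expression(records_at(grid))
  expect_equal(calls$call, c("DOWN", "DOWN", "UNCHANGED", "UNCHANGED",
                             "UNCHANGED", "UP", "UP"))
  expect_equal(calls$percent_of_wt, grid)
})

test_that("a wild-type zero is UP with an infinite percent", {
  rec <- tibble::tibble(feature_id = "f", feature_type = "sdRNA",
                        raw_wt = 0, raw_ko = 6,
                        rpm_wt = 0, rpm_ko = 60)
  call <- classify_expression(rec)
  expect_equal(call$call, "UP")
  expect_equal(call$percent_of_wt, Inf)
  expect_error(
    classify_expression(dplyr::mutate(rec, rpm_ko = 0, raw_ko = 0)),
    "floored"
  )
})

test_that("every expressed feature receives exactly one class", {
  set.seed(61)
  percents <- c(stats::rlnorm(300, log(100), 1.5), 50, 150, 0.01)
  calls <- classify_expression(records_at(percents))
  expect_true(all(calls$call %in% c("UP", "DOWN", "UNCHANGED")))
  expect_equal(
    (calls$percent_of_wt >= 150) + (calls$percent_of_wt <= 50) +
      (calls$percent_of_wt > 50 & calls$percent_of_wt < 150),
    rep(1, nrow(calls))
  )
})

test_that("swapping the libraries mirrors the classification", {
  set.seed(62)
  percents <- stats::rlnorm(200, log(100), 1.2)
  # away from both thresholds AND their mirror images (1e4/150, 1e4/50),
  # where swapping wild type and knockout crosses a class boundary
  away <- percents < 49 | (percents > 68 & percents < 148) | percents > 202
  rec <- records_at(percents[away])
  fwd <- classify_expression(rec)
  swapped <- dplyr::rename(rec, rpm_wt = "rpm_ko", rpm_ko = "rpm_wt",
                           raw_wt = "raw_ko", raw_ko = "raw_wt")
  rev <- classify_expression(swapped)
  expect_equal(sum(fwd$call == "UP"), sum(rev$call == "DOWN"))
  expect_equal(sum(fwd$call == "DOWN"), sum(rev$call == "UP"))
  expect_equal(rev$percent_of_wt, 1e4 / fwd$percent_of_wt)
})

test_that("class means are arithmetic means of member percentages", {
  calls <- classify_expression(records_at(c(5, 7.8, 100, 200, 700)))
  s <- summarize_switch(calls)$by_type
  expect_equal(s$mean_percent_of_wt_down, 6.4)
  expect_equal(s$mean_percent_of_wt_up, 450)
  expect_equal(s$n_expressed, 5)
  expect_equal(s$n_up + s$n_down + s$n_unchanged, s$n_expressed)
})

test_that("summary counts partition the expressed set per type", {
  set.seed(63)
  percents <- c(rep(300, 3), rep(10, 2), rep(100, 5))
  calls <- classify_expression(records_at(percents))
  s <- summarize_switch(calls)$by_type
  expect_equal(c(s$n_up, s$n_down, s$n_unchanged), c(3, 2, 5))
  expect_equal(s$n_expressed, 10)
})

test_that("infinite percents are excluded from the UP mean and counted", {
  rec <- dplyr::bind_rows(records_at(c(200, 400)),
                          tibble::tibble(feature_id = "inf1",
                                         feature_type = "miRNA",
                                         raw_wt = 0, raw_ko = 5,
                                         rpm_wt = 0, rpm_ko = 50))
  s <- summarize_switch(classify_expression(rec))$by_type
  expect_equal(s$n_up, 3)
  expect_equal(s$mean_percent_of_wt_up, 300)
  expect_equal(s$n_up_infinite, 1)
})

test_that("top lists rank by absolute log2 effect with id tie-breaks", {
  rec <- records_at(c(4, 25, 2500, 400, 100.5))
  rec$feature_id <- c("down_big", "down_small", "up_big", "up_small", "flat")
  s <- summarize_switch(classify_expression(rec), n_top = 2)
  expect_equal(s$top_down$feature_id, c("down_big", "down_small"))
  expect_equal(s$top_up$feature_id, c("up_big", "up_small"))

  ties <- records_at(c(25, 25, 400, 400))
  ties$feature_id <- c("b", "a", "d", "c")
  s2 <- summarize_switch(classify_expression(ties))
  expect_equal(s2$top_down$feature_id, c("a", "b"))
  expect_equal(s2$top_up$feature_id, c("c", "d"))
})

test_that("an empty call set summarises to an empty table", {
  s <- summarize_switch(classify_expression(records_at(numeric(0))))
  expect_equal(nrow(s$by_type), 0)
})
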