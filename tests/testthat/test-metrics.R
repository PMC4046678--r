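test_that("expected length reproduces the published per-group arithmetic", {
  expect_equal(round(expected_length(70.30, 129), 2), 71.40)
  expect_equal(round(expected_length(52.13, 26), 2), 56.30)
  expect_equal(expected_length(10, 2), 30)
  expect_error(expected_length(10, 1), "at least 2")
})

test_that("genome coverage totals match the published map summary", {
  tbl <- pmax_map_summary()
  cov <- genome_coverage(tbl)
  tot <- cov$totals
  expect_equal(round(tot$ge[tot$map == "sexavg"], 1), 865.6, tolerance = 0.05)
  expect_equal(round(100 * tot$coverage[tot$map == "sexavg"], 1), 96.1, tolerance = 0.05)
  expect_equal(round(tot$ge[tot$map == "female"], 1), 954.7, tolerance = 0.1)
  expect_equal(round(tot$fm_ratio[1], 2), 1.15)
  # per-LG expected lengths are never below observed, coverage in (0, 1]
  expect_true(all(cov$per_lg$ge_sexavg >= cov$per_lg$len_sexavg))
  expect_true(all(tot$coverage > 0 & tot$coverage <= 1))
  # trivial single-group identity
  one <- genome_coverage(tibble::tibble(lg = 1, n_markers = 1000, len_sexavg = 50))
  expect_equal(one$totals$coverage, 1, tolerance = 0.003)
})

test_that("female-to-male ratios match published per-group values", {
  expect_equal(round(fm_ratio(77.13, 36.34), 2), 2.12)
  expect_equal(round(fm_ratio(43.18, 58.91), 2), 0.73)
  expect_equal(fm_ratio(50, 50), 1)
  expect_warning(r0 <- fm_ratio(10, 0), "infinite")
  expect_identical(r0, Inf)
})

test_that("interval statistics reproduce every published average-interval cell", {
  tbl <- pmax_map_summary()
  means <- tbl$len_sexavg / tbl$n_intervals
  published <- c(0.99, 1.20, 1.14, 1.41, 1.28, 1.68, 1.94, 2.14, 2.36,
                 2.61, 2.30, 2.42, 3.46, 3.07)
  expect_equal(round(means, 2), published)
  expect_equal(round(mean(means), 2), 2.00)
  # and the sub-1-cM fraction of non-zero intervals
  expect_gte(sum(tbl$n_0_1) / sum(tbl$n_intervals), 0.49)
})

test_that("interval_stats summarises an ordered map correctly", {
  map <- tibble::tibble(
    lg = rep(1:2, c(4, 3)),
    marker_id = paste0("m", 1:7),
    cm_sexavg = c(0, 0, 1.5, 4, 0, 2, 2)
  )
  st <- interval_stats(map)
  expect_equal(st$per_lg$n_nonzero, c(2L, 1L))
  expect_equal(st$per_lg$mean_nonzero, c(4 / 2, 2))
  expect_equal(st$overall$mean_nonzero_unweighted, 2)
  expect_equal(st$per_lg$bin_1_2, c(1L, 1L))
  expect_equal(st$per_lg$bin_2_3, c(1L, 0L))
  all_zero <- tibble::tibble(lg = 1, marker_id = c("a", "b"), cm_sexavg = c(0, 0))
  expect_warning(z <- interval_stats(all_zero), "undefined")
  expect_true(is.na(z$per_lg$mean_nonzero))
})

test_that("standardised intervals sum to 100 per group and sex", {
  ds <- small_sim()
  tm <- attr(ds, "truth")
  map <- tm |> dplyr::rename(marker_id = "marker_id")
  std <- standardized_intervals(map)
  sums <- std |>
    dplyr::group_by(lg) |>
    dplyr::summarise(f = sum(std_female), m = sum(std_male))
  expect_equal(sums$f, rep(100, nrow(sums)), tolerance = 1e-9)
  expect_equal(sums$m, rep(100, nrow(sums)), tolerance = 1e-9)
})

test_that("piecewise regression recovers constructed slopes and flags exact ratios", {
  # cumulative female coordinate exactly twice the male coordinate:
  # female-on-male slope 2, male-on-female 0.5
  cm <- cumsum(c(2, 4, 1, 6, 3, 5, 2, 4, 3, 6))
  iv <- tibble::tibble(
    lg = 1, interval = 1:10,
    female = 2 * c(cm[1], diff(cm)), male = c(cm[1], diff(cm)),
    std_female = 2 * c(cm[1], diff(cm)), std_male = c(cm[1], diff(cm)),
    cum_std_female = 2 * cm, cum_std_male = cm,
    fm_ratio = 2
  )
  bp <- tibble::tibble(lg = 1, bp1 = 4, bp2 = 8)
  res <- suppressWarnings(piecewise_slope_test(iv, bp))
  expect_equal(res$slope_female_on_male, rep(2, 3), tolerance = 1e-9)
  expect_equal(res$slope, rep(0.5, 3), tolerance = 1e-9)
  # identical maps: slope 1 with p = 1 against H0 slope = 1
  iv2 <- iv |>
    dplyr::mutate(female = male, std_female = std_male,
                  cum_std_female = cum_std_male)
  res2 <- suppressWarnings(piecewise_slope_test(iv2, bp))
  expect_equal(res2$slope, rep(1, 3), tolerance = 1e-9)
  expect_true(all(res2$p_vs_1 > 0.999 | is.na(res2$p_vs_1)))
})

test_that("male centromeric suppression yields middle slope < 1, outer > 1", {
  # construct cumulative positions from a suppressed-male warp directly
  u <- seq(0, 1, length.out = 21)
  mal_pos <- pearlmap:::warp_male(u, 0.5, 0.7)
  fem_pos <- pearlmap:::warp_female(u, 0.5, 0.7)
  dif_f <- diff(fem_pos) * 100; dif_m <- diff(mal_pos) * 100
  cum_f <- fem_pos[-1] * 100; cum_m <- mal_pos[-1] * 100
  iv <- tibble::tibble(
    lg = 1, interval = 1:20,
    female = dif_f, male = dif_m,
    std_female = dif_f, std_male = dif_m,
    cum_std_female = cum_f, cum_std_male = cum_m,
    fm_ratio = dif_f / dif_m
  )
  res <- piecewise_slope_test(iv)
  expect_lt(res$slope[res$group == "middle"], 1)
  expect_gt(res$slope[res$group == "left"], 1)
  expect_gt(res$slope[res$group == "right"], 1)
})
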