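test_that("sex-heterogeneity LRT matches direct evaluation and is symmetric", {
  r <- sex_heterogeneity_test(10, 50, 2, 50)
  expect_equal(round(r$chi2, 3), 6.550)
  expect_equal(r$p, pchisq(r$chi2, 1, lower.tail = FALSE))
  expect_lt(abs(r$p - 0.0105), 5e-4)
  # symmetric in the sex labels
  r2 <- sex_heterogeneity_test(2, 50, 10, 50)
  expect_equal(r$chi2, r2$chi2)
  # zero iff the two MLEs coincide
  expect_equal(sex_heterogeneity_test(5, 50, 10, 100)$chi2, 0)
  expect_equal(sex_heterogeneity_test(5, 50, 10, 100)$p, 1)
  expect_gt(sex_heterogeneity_test(5, 50, 11, 100)$chi2, 0)
  # untestable when a sex has no meioses
  expect_false(sex_heterogeneity_test(0, 0, 3, 10)$tested)
})

test_that("heterogeneity chi2 is non-negative over random counts", {
  set.seed(42)
  for (i in 1:200) {
    nf <- sample(1:80, 1); nm <- sample(1:80, 1)
    r <- sex_heterogeneity_test(rbinom(1, nf, runif(1, 0, .5)), nf,
                                rbinom(1, nm, runif(1, 0, .5)), nm)
    expect_gte(r$chi2, 0)
  }
})

test_that("family M-test matches a brute-force likelihood computation", {
  fits <- tibble::tibble(family = c("a", "b"), R = c(5, 30), N = c(100, 100))
  res <- family_m_test(fits)
  # independent oracle: direct natural-log profile likelihoods
  lnl <- function(R, N) {
    th <- R / N
    R * log(th) + (N - R) * log(1 - th) - N * log(0.5)
  }
  pooled_th <- 35 / 200
  lnl_pool <- 35 * log(pooled_th) + 165 * log(1 - pooled_th) - 200 * log(0.5)
  m_oracle <- 2 * (lnl(5, 100) + lnl(30, 100) - lnl_pool)
  expect_equal(res$m_stat, m_oracle, tolerance = 1e-9)
  expect_equal(res$df, 1L)
  # identical families: M = 0
  same <- tibble::tibble(family = c("a", "b", "c"), R = c(4, 4, 4), N = c(40, 40, 40))
  expect_equal(family_m_test(same)$m_stat, 0, tolerance = 1e-12)
  expect_error(family_m_test(tibble::tibble(family = "a", R = 1, N = 10)),
               "at least 2")
})

test_that("segregation G matches direct evaluation", {
  expect_equal(segregation_g(10, 10), 0)
  expect_equal(round(segregation_g(15, 5), 3), 5.232)
  expect_equal(segregation_g(0, 20), 2 * 20 * log(2))
  expect_error(segregation_g(0, 0), "at least one")
})

test_that("G partition is additive, non-negative, and cancels opposing distortions", {
  opp <- tibble::tibble(parent_id = c("p1", "p2"), n_a = c(15, 5), n_b = c(5, 15))
  r <- g_partition(opp)
  expect_equal(round(r$g_total, 3), 10.465)
  expect_equal(r$g_pooled, 0)
  expect_equal(r$g_het, r$g_total)
  same <- tibble::tibble(parent_id = c("p1", "p2"), n_a = c(15, 15), n_b = c(5, 5))
  r2 <- g_partition(same)
  expect_equal(r2$g_pooled, segregation_g(30, 10))
  expect_equal(r2$g_het, 0, tolerance = 1e-9)
  expect_equal(r2$direction, 1)
  one <- g_partition(tibble::tibble(parent_id = "p", n_a = 12, n_b = 3))
  expect_equal(one$g_het, 0)
  # partition non-negativity on random tables
  set.seed(9)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    tr <- tibble::tibble(parent_id = letters[1:k],
                         n_a = rbinom(k, 30, 0.5), n_b = rbinom(k, 30, 0.5))
    tr <- tr[tr$n_a + tr$n_b > 0, ]
    rr <- g_partition(tr)
    expect_gte(rr$g_total - rr$g_pooled, -1e-9)
  }
})

test_that("BH step-up matches the worked example and a brute-force rule", {
  p <- c(0.001, 0.01, 0.02, 0.03, 0.04)
  r <- bh_fdr(p, 0.05)
  expect_true(all(r$pass))
  expect_equal(round(r$p_adjusted, 4), c(0.005, 0.025, 0.0333, 0.0375, 0.04))
  expect_equal(r$alpha_corrected, 0.04)
  expect_false(any(bh_fdr(rep(1, 10))$pass))
  expect_true(bh_fdr(0.04, 0.05)$pass)
  # brute force: largest k with p_(k) <= k alpha / m
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^2
    r <- bh_fdr(p, 0.05)
    srt <- sort(p)
    k <- max(c(0, which(srt <= seq_along(srt) * 0.05 / length(p))))
    pass_brute <- if (k == 0) rep(FALSE, length(p)) else p <= srt[k]
    expect_identical(r$pass, pass_brute)
  }
})

test_that("pooled heterogeneity sums chi-squares with summed df", {
  it <- dplyr::bind_cols(
    tibble::tibble(R_f = c(10, 4), N_f = c(50, 40), R_m = c(2, 4), N_m = c(50, 40)),
    sex_heterogeneity_test(c(10, 4), c(50, 40), c(2, 4), c(50, 40))
  )
  pooled <- pool_heterogeneity(it, scope = "LG1")
  expect_equal(pooled$chi2, sum(it$chi2))
  expect_equal(pooled$df, 2L)
  expect_equal(pooled$p, pchisq(pooled$chi2, 2, lower.tail = FALSE))
})
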