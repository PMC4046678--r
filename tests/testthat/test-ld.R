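test_that("haplotype EM equals direct counting without double heterozygotes", {
  cnt <- matrix(0, 3, 3)
  cnt[1, 1] <- 30; cnt[1, 2] <- 10; cnt[3, 3] <- 20; cnt[2, 1] <- 8
  f <- haplotype_freq_em(cnt)
  n2 <- 2 * sum(cnt)
  expect_equal(unname(f["AB"]), (2 * 30 + 10 + 8) / n2)
  expect_equal(unname(f["ab"]), (2 * 20) / n2)
  expect_equal(sum(f), 1)
})

test_that("haplotype EM matches a 1-D likelihood grid oracle", {
  set.seed(21)
  loglik <- function(fAB, counts, pA, pB) {
    # free parameter fAB determines all four frequencies given margins
    fAb <- pA - fAB; faB <- pB - fAB; fab <- 1 - pA - pB + fAB
    if (min(fAb, faB, fab, fAB) < 0) return(-Inf)
    g <- matrix(0, 3, 3)
    probs <- function(x, y) c(x * x, 2 * x * y, y * y)
    ll <- 0
    for (a in 1:3) for (b in 1:3) {
      if (counts[a, b] == 0) next
      p <- switch(paste(a, b),
        "1 1" = fAB^2, "1 2" = 2 * fAB * fAb, "1 3" = fAb^2,
        "2 1" = 2 * fAB * faB, "2 2" = 2 * fAB * fab + 2 * fAb * faB,
        "2 3" = 2 * fAb * fab, "3 1" = faB^2, "3 2" = 2 * faB * fab,
        "3 3" = fab^2)
      ll <- ll + counts[a, b] * log(max(p, 1e-300))
    }
    ll
  }
  for (rep in 1:10) {
    counts <- matrix(rpois(9, 8), 3, 3)
    f <- tryCatch(haplotype_freq_em(counts), error = function(e) NULL)
    if (is.null(f)) next
    n <- sum(counts)
    pA <- (2 * sum(counts[1, ]) + sum(counts[2, ])) / (2 * n)
    pB <- (2 * sum(counts[, 1]) + sum(counts[, 2])) / (2 * n)
    grid <- seq(max(0, pA + pB - 1), min(pA, pB), length.out = 20001)
    lls <- vapply(grid, loglik, 0, counts = counts, pA = pA, pB = pB)
    expect_lt(abs(f[["AB"]] - grid[which.max(lls)]), 1e-3)
    # and the EM solution is a likelihood optimum to first order
    expect_gte(loglik(f[["AB"]], counts, pA, pB), max(lls) - 1e-6)
  }
})

test_that("perfect coupling gives complementary haplotypes and full LD", {
  cnt <- matrix(0, 3, 3); cnt[1, 1] <- 25; cnt[2, 2] <- 50; cnt[3, 3] <- 25
  f <- haplotype_freq_em(cnt)
  expect_equal(unname(f["AB"] + f["ab"]), 1, tolerance = 1e-6)
  ld <- pair_ld(f)
  expect_equal(ld$D_prime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
})

test_that("LD coefficients match direct evaluation", {
  f <- c(AB = 0.4, Ab = 0.1, aB = 0.1, ab = 0.4)
  ld <- pair_ld(f)
  expect_equal(ld$D, 0.15)
  expect_equal(ld$D_prime, 0.6)
  expect_equal(ld$r2, 0.36)
  # independence
  f0 <- c(AB = 0.35, Ab = 0.35, aB = 0.15, ab = 0.15)
  ld0 <- pair_ld(f0)
  expect_equal(ld0$D, 0, tolerance = 1e-12)
  expect_equal(ld0$r2, 0, tolerance = 1e-12)
  expect_error(pair_ld(c(AB = 0.6, Ab = 0.4, aB = 0, ab = 0)), "undefined")
  # D' = 1 whenever a haplotype class is absent
  f1 <- c(AB = 0.5, Ab = 0.3, aB = 0.2, ab = 0)
  expect_equal(pair_ld(f1)$D_prime, 1, tolerance = 1e-9)
})

test_that("the vectorised scan agrees with the single-pair EM", {
  ds <- small_sim()
  sub <- ds$markers$marker_id[c(1, 2, 5, 11, 25)]
  sc <- ld_scan(ds, pairs = data.frame(i = rep(sub[1], 4), j = sub[-1]))
  for (k in seq_len(nrow(sc))) {
    g1 <- ds$geno[, sc$marker_i[k]]; g2 <- ds$geno[, sc$marker_j[k]]
    ok <- !is.na(g1) & !is.na(g2)
    cnt <- as.matrix(table(factor(g1[ok], 0:2), factor(g2[ok], 0:2)))
    f <- haplotype_freq_em(cnt)
    expect_equal(sc$r2[k], pair_ld(f)$r2, tolerance = 1e-6)
  }
})

test_that("decay table bins syntenic pairs and keeps unmapped pairs out", {
  ld <- tibble::tibble(
    marker_i = c("a", "a", "b", "x"), marker_j = c("b", "c", "c", "a"),
    D = 0.1, D_prime = c(0.9, 0.5, 0.4, 0.8), r2 = c(0.8, 0.3, 0.2, 0.5),
    n = 100L
  )
  map <- tibble::tibble(lg = c(1L, 1L, 2L), marker_id = c("a", "b", "c"),
                        cm_sexavg = c(0, 0, 10))
  dt <- decay_table(ld, map)
  # a-b syntenic at distance 0; a-c and b-c non-syntenic; x unmapped
  expect_equal(dt$decay$n[dt$decay$bin == "0"], 1)
  expect_equal(sum(dt$decay$n), 1)
  expect_equal(dt$overall$n_nonsyntenic, 2)
  expect_equal(dt$overall$n_pairs, 4)
})

test_that("LD decays with map distance on simulated data", {
  ds <- small_sim()
  tm <- attr(ds, "truth")
  ld <- ld_scan(ds)
  map <- tm
  dt <- decay_table(ld, map)
  d <- dt$decay[dt$decay$n >= 25, ]
  # monotone decrease up to Monte-Carlo noise: rank correlation negative
  # and the closest bin clearly exceeds the farthest
  expect_lt(cor(seq_len(nrow(d)), d$r2_mean, method = "kendall"), 0)
  expect_gt(d$r2_mean[1], d$r2_mean[nrow(d)])
  # non-syntenic background is below the tightest syntenic bin
  expect_lt(dt$overall$r2_mean_nonsyntenic, d$r2_mean[1])
})
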