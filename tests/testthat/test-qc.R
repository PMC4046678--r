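test_that("allele statistics count alleles and calls correctly", {
  col <- c(rep(0L, 50), rep(1L, 40), rep(2L, 10))
  st <- allele_stats(col)
  expect_equal(st$maf, (2 * 10 + 40) / 200)
  expect_equal(allele_stats(rep(0L, 100))$maf, 0)
  st2 <- allele_stats(c(rep(0L, 99), NA))
  expect_equal(st2$call_rate, 0.99)
  expect_error(allele_stats(c(NA_integer_, NA_integer_)), "all-missing")
})

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(5, 0, 0), 1)   # monomorphic
  # modal heterozygote count in a balanced sample includes all terms
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  # oracle: enumerate all heterozygote counts for n <= 30
  oracle <- function(naa, nab, nbb) {
    na <- 2 * naa + nab; nb <- 2 * nbb + nab; n <- naa + nab + nbb
    hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
    pr <- vapply(hets, function(h) {
      exp(lfactorial(n) - lfactorial((na - h) / 2) - lfactorial(h) -
            lfactorial((nb - h) / 2) + h * log(2) -
            (lfactorial(2 * n) - lfactorial(na) - lfactorial(nb)))
    }, 0)
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nab, hets)] + 1e-12])
  }
  set.seed(3)
  for (i in 1:50) {
    naa <- sample(0:12, 1); nab <- sample(0:12, 1); nbb <- sample(0:12, 1)
    if (naa + nab + nbb == 0) next
    expect_equal(hwe_exact_test(naa, nab, nbb), oracle(naa, nab, nbb),
                 tolerance = 1e-9)
  }
})

test_that("Mendelian check flags impossible trios only", {
  ped <- tibble::tibble(
    family = "f1", id = c("s", "d", "k1", "k2", "k3"),
    sire = c(NA, NA, "s", "s", "s"), dam = c(NA, NA, "d", "d", "d"),
    sex = c("male", "female", "unknown", "unknown", "unknown")
  )
  geno <- rbind(
    s = c(0L, 0L, NA), d = c(2L, 1L, 0L),
    k1 = c(0L, 2L, 1L),   # m1: AAxBB -> AA impossible; m2: AAxAB -> BB impossible
    k2 = c(1L, 1L, 2L),   # m3 parent missing: unconstrained
    k3 = c(1L, 0L, 0L)
  )
  colnames(geno) <- c("m1", "m2", "m3")
  ds <- make_trio_dataset(geno, ped)
  mc <- mendelian_check(ds)
  expect_equal(nrow(mc$conflicts), 2)
  expect_setequal(mc$conflicts$marker_id, c("m1", "m2"))
  expect_true(all(mc$conflicts$id == "k1"))
  expect_equal(mc$per_marker$n_mendel_errors, c(1L, 1L, 0L))
})

test_that("duplicate detection flags identical and near-identical columns", {
  set.seed(5)
  a <- sample(0:2, 300, replace = TRUE, prob = c(.25, .5, .25))
  b <- a; b[1] <- (a[1] + 1L) %% 3L      # 299/300 concordant
  c_ <- sample(0:2, 300, replace = TRUE, prob = c(.25, .5, .25))
  geno <- cbind(m1 = a, m2 = a, m3 = b, m4 = c_)
  storage.mode(geno) <- "integer"
  rownames(geno) <- paste0("i", 1:300)
  ped <- tibble::tibble(family = "f", id = rownames(geno),
                        sire = NA_character_, dam = NA_character_, sex = "unknown")
  ds <- make_trio_dataset(geno, ped)
  dup <- duplicate_marker_detect(ds)
  expect_true(any(dup$marker_i == "m1" & dup$marker_j == "m2" & dup$concordance == 1))
  expect_true(any(dup$marker_j == "m3" & dup$concordance >= 0.99))
  expect_false("m4" %in% c(dup$marker_j))
  # independent columns under HWE p=0.5 concord at ~0.375, far below threshold
  conc_expect <- sum((c(.25, .5, .25))^2)
  tab <- mean(a == c_)
  expect_lt(abs(tab - conc_expect), 0.1)
})

test_that("apply_qc enforces the published thresholds and is idempotent", {
  ds <- small_sim()
  # degrade marker 1 to low MAF and marker 2 to low call rate
  g <- ds$geno
  g[, 1] <- 0L; g[sample(nrow(g), 3), 1] <- 1L        # maf ~ 0.005
  g[seq_len(ceiling(0.12 * nrow(g))), 2] <- NA        # call rate ~ 0.88
  ds2 <- linkage_dataset(ds$pedigree, ds$markers, g)
  res <- apply_qc(ds2)
  expect_false(res$report$pass[1])
  expect_equal(res$report$reason[1], "low_maf")
  expect_false(res$report$pass[2])
  expect_equal(res$report$reason[2], "low_call_rate")
  # idempotent: re-filtering removes nothing
  res2 <- apply_qc(res$dataset)
  expect_true(all(res2$report$pass))
  expect_identical(dim(res2$dataset$geno), dim(res$dataset$geno))
})

test_that("clean simulated data passes QC untouched", {
  res <- apply_qc(small_sim())
  expect_true(all(res$report$pass))
})
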