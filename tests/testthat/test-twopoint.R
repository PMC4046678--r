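test_that("phase-known estimates match the closed form", {
  r <- theta_phase_known(2, 20)
  expect_equal(r$theta, 0.1)
  expect_equal(round(r$lod, 3), 3.197)
  r0 <- theta_phase_known(0, 20)
  expect_equal(r0$theta, 0)
  expect_equal(r0$lod, 20 * log10(2))
  r5 <- theta_phase_known(10, 20)
  expect_equal(r5$theta, 0.5)
  expect_equal(r5$lod, 0)
  # vectorised
  rv <- theta_phase_known(c(2, 0, 10), c(20, 20, 20))
  expect_equal(rv$lod, c(r$lod, r0$lod, r5$lod))
})

test_that("phase-unknown mixture behaves at its analytic landmarks", {
  # a single phase-unknown meiosis is uninformative
  r1 <- theta_phase_unknown(0, 1)
  expect_equal(r1$theta, 0.5)
  expect_equal(r1$lod, 0, tolerance = 1e-9)
  # n = 10, k = 0: L(0)/L(0.5) = 0.5 / 0.5^10 = 512
  r2 <- theta_phase_unknown(0, 10)
  expect_equal(r2$theta, 0, tolerance = 1e-5)
  expect_equal(r2$lod, log10(512), tolerance = 1e-6)
  # phase-flip symmetry: (k, n) and (n - k, n) are the same likelihood
  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:30, 2); k <- c(sample(0:n[1], 1), sample(0:n[2], 1))
    a <- theta_phase_unknown(k, n)
    b <- theta_phase_unknown(n - k, n)
    expect_equal(a$lod, b$lod, tolerance = 1e-9)
    expect_equal(a$theta, b$theta, tolerance = 1e-6)
  }
})

test_that("joint estimation reduces to the phase-known form without mixtures", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  # find an adjacent pair with phase-resolved coverage
  cnt <- NULL
  for (i in 1:9) {
    cand <- pearlmap:::pair_counts(ms, i, i + 1)
    if (cand$N >= 10) { cnt <- cand; break }
  }
  expect_false(is.null(cnt))
  est <- pearlmap:::maximize_twopoint(cnt$R, cnt$N, integer(), integer())
  ck <- theta_phase_known(cnt$R, cnt$N)
  expect_equal(est$theta, ck$theta, tolerance = 1e-5)
  expect_equal(est$lod, ck$lod, tolerance = 1e-6)
})

test_that("simulated linked pairs recover the true fraction", {
  # direct gamete simulation: two markers 10 cM (male map) apart
  set.seed(77)
  n <- 5000
  th_true <- pearlmap:::haldane_theta(10)
  o <- pearlmap:::sim_gamete_origins(list(c(0, 10)), n)
  rec <- mean(o[, 1] != o[, 2])
  se <- sqrt(th_true * (1 - th_true) / n)
  expect_lt(abs(rec - th_true), 3 * se)
  est <- theta_phase_known(sum(o[, 1] != o[, 2]), n)
  expect_lt(abs(est$theta - th_true), 3 * se)
})

test_that("the all-pairs scan agrees with per-pair joint maximisation", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  sc <- two_point_scan(ms, lod_floor = 0.5)
  expect_true(all(sc$lod >= 0.5))
  expect_true(all(sc$theta >= 0 & sc$theta <= 0.5))
  top <- sc[order(-sc$lod)[1:8], ]
  for (k in seq_len(nrow(top))) {
    ref <- combine_two_point(ms, top$marker_i[k], top$marker_j[k])
    expect_equal(top$theta[k], ref$theta, tolerance = 1e-4)
    expect_equal(top$lod[k], ref$lod, tolerance = 1e-4)
    expect_equal(top$n_known[k], ref$n_known)
    expect_equal(top$n_unknown[k], ref$n_unknown)
  }
})

test_that("sex-restricted estimates use only the corresponding parents", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  tp <- combine_two_point(ms, ms$marker_ids[1], ms$marker_ids[2])
  # joint pooled counts are the sum of the sex-restricted counts
  f <- pearlmap:::pair_counts(ms, 1, 2, sex = "female")
  m <- pearlmap:::pair_counts(ms, 1, 2, sex = "male")
  a <- pearlmap:::pair_counts(ms, 1, 2)
  expect_equal(a$N, f$N + m$N)
  expect_equal(a$R, f$R + m$R)
  expect_equal(sort(c(f$n, m$n)), sort(a$n))
})

test_that("markers below the informativeness floor are excluded from the scan", {
  ds <- small_sim()
  # silence one marker almost completely
  g <- ds$geno
  g[seq_len(nrow(g) - 5), 3] <- NA
  ds2 <- linkage_dataset(ds$pedigree, ds$markers, g)
  ms <- meiosis_set(ds2)
  sc <- two_point_scan(ms, min_inf = 10)
  excl <- attr(sc, "excluded_markers")
  expect_true(ds$markers$marker_id[3] %in% excl)
  expect_false(ds$markers$marker_id[3] %in% c(sc$marker_i, sc$marker_j))
})

test_that("meiosis records satisfy their defining invariants", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  rec <- enumerate_meioses(ms)
  expect_gt(nrow(rec), 0)
  # parent heterozygous at every informative record
  idx <- cbind(match(rec$parent_id, rownames(ds$geno)),
               match(rec$marker_id, colnames(ds$geno)))
  expect_true(all(ds$geno[idx] == 1L, na.rm = TRUE))
  # phase-known records only for parents whose parents are genotyped
  ped <- ds$pedigree
  has_gp <- !is.na(ped$sire[match(rec$parent_id, ped$id)])
  expect_true(all(!rec$phase_known[!has_gp]))
  expect_true(all(unlist(ms$trans) %in% c(0L, 1L, NA)))
})
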