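test_that("two-marker multipoint reduces to the two-point LOD", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  pair <- ms$marker_ids[1:2]
  tp <- combine_two_point(ms, pair[1], pair[2])
  ll_hat <- multipoint_loglik(ms, pair, thetas = tp$theta)
  ll_null <- multipoint_loglik(ms, pair, thetas = 0.4999999)
  # the profiled two-point LOD equals the multipoint likelihood gap
  expect_equal(ll_hat - ll_null, tp$lod, tolerance = 0.02)
})

test_that("phase-known closed form matches the multipoint evaluator", {
  # minimal constructed family: grandparents force phase, 20 meioses, R=2
  n <- 20
  ped <- tibble::tibble(
    family = "f",
    id = c("gs", "gd", "p", "mate", paste0("k", 1:n)),
    sire = c(NA, NA, "gs", NA, rep("p", n)),
    dam = c(NA, NA, "gd", NA, rep("mate", n)),
    sex = c("male", "female", "male", "female", rep("unknown", n))
  )
  # phase: A from grandsire, B from granddam at both markers
  kid_m1 <- c(rep(0L, 18), 1L, 1L)   # transmitted B (origin 1) for last two
  kid_m2 <- rep(0L, 20)              # transmitted A (origin 0) everywhere
  geno <- rbind(
    gs = c(0L, 0L), gd = c(2L, 2L), p = c(1L, 1L), mate = c(0L, 0L),
    matrix(c(kid_m1, kid_m2), ncol = 2, dimnames = list(paste0("k", 1:n), NULL))
  )
  colnames(geno) <- c("m1", "m2")
  ds <- make_trio_dataset(geno, ped)
  ms <- meiosis_set(ds)
  rec <- enumerate_meioses(ms)
  expect_true(all(rec$phase_known[rec$parent_id == "p"]))
  # R = 2 recombinants out of 20
  ll_hat <- multipoint_loglik(ms, c("m1", "m2"), thetas = 0.1)
  ll_null <- multipoint_loglik(ms, c("m1", "m2"), thetas = 0.4999999)
  expect_equal(ll_hat - ll_null, theta_phase_known(2, 20)$lod, tolerance = 1e-4)
})

test_that("multipoint likelihood is invariant to order reversal", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  ord <- attr(ds, "truth")$marker_id[1:6]
  th <- rep(0.05, 5)
  expect_equal(multipoint_loglik(ms, ord, thetas = th),
               multipoint_loglik(ms, rev(ord), thetas = rev(th)),
               tolerance = 1e-9)
  expect_equal(pearlmap:::score_order(ms, ord),
               pearlmap:::score_order(ms, rev(ord)), tolerance = 1e-6)
})

test_that("exact phase summation matches a naive enumeration oracle", {
  cfg <- sim_config(seed = 19, n_lg = 1, markers_per_lg = 3,
                    n_f2 = c(6L, 5L, 4L, 4L, 4L, 4L, 5L, 5L),
                    lg_length_range = c(30, 40))
  ds <- simulate_dataset(cfg)
  ms <- meiosis_set(ds)
  ord <- ms$marker_ids
  for (th in list(c(0.1, 0.2), c(0.05, 0.4), c(0.3, 0.3))) {
    expect_equal(multipoint_loglik(ms, ord, thetas = th),
                 naive_multipoint(ms, ord, th), tolerance = 1e-9)
  }
})

test_that("unknown markers in an order are an error", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  expect_error(multipoint_loglik(ms, c(ms$marker_ids[1], "nope"), thetas = 0.1),
               "unknown marker")
  expect_error(pearlmap:::profile_order(ms, "nope"), "unknown marker")
})

test_that("build recovers a 3-marker order with framework support", {
  # ~5 cM intervals (theta about 0.05) across the study's family design
  cfg <- sim_config(seed = 31, n_lg = 1, markers_per_lg = 3,
                    lg_length_range = c(10, 10), warp_strength = 0)
  ds <- simulate_dataset(cfg)
  ms <- meiosis_set(ds)
  bm <- build_map(ms, ms$marker_ids, lg = 1L)
  ord <- bm$marker_id
  truth <- attr(ds, "truth")$marker_id
  expect_true(identical(ord, truth) || identical(ord, rev(truth)))
  expect_true(all(bm$tier == "LOD3"))
  expect_equal(bm$cm_sexavg[1], 0)
  expect_true(all(diff(bm$cm_sexavg) >= 0))
  # exhaustive oracle: no permutation beats the built order
  perms <- pearlmap:::all_perms(3)
  lls <- vapply(perms, function(p) pearlmap:::score_order(ms, truth[p]), 0)
  expect_gte(pearlmap:::score_order(ms, ord), max(lls) - 1e-6)
})

test_that("single-marker groups give trivial maps", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  bm <- build_map(ms, ms$marker_ids[1], lg = 9L)
  expect_equal(nrow(bm), 1)
  expect_equal(bm$cm_sexavg, 0)
  expect_equal(bm$lg, 9L)
})

test_that("window refinement corrects swaps, is a fixpoint, and caps at group size", {
  cfg <- sim_config(seed = 57, n_lg = 1, markers_per_lg = 6,
                    lg_length_range = c(60, 60))
  ds <- simulate_dataset(cfg)
  ms <- meiosis_set(ds)
  truth <- attr(ds, "truth")$marker_id
  swapped <- truth[c(1, 2, 4, 3, 5, 6)]
  fixed <- pearlmap:::flips_order(ms, swapped, window = 5)
  expect_gte(pearlmap:::score_order(ms, fixed),
             pearlmap:::score_order(ms, truth) - 1e-6)
  # already-optimal order unchanged
  again <- pearlmap:::flips_order(ms, fixed, window = 5)
  expect_identical(again, fixed)
  # window >= group size: exhaustive search over all permutations
  exh <- pearlmap:::flips_order(ms, swapped, window = 10)
  perms <- pearlmap:::all_perms(6)
  best <- max(vapply(perms, function(p) pearlmap:::score_order(ms, truth[p]), 0))
  expect_gte(pearlmap:::score_order(ms, exh), best - 1e-6)
})

test_that("singleton origin switches are flagged by definition", {
  og <- list(
    origins = rbind(c(0L, 0L, 0L, 1L, 0L, 0L),
                    c(0L, 0L, 0L, 1L, 1L, 1L)),
    parent_id = c("p", "p"), sex = c("male", "male"), family = c("f", "f")
  )
  rownames(og$origins) <- c("k1", "k2")
  fl <- pearlmap:::origin_singletons(og, paste0("m", 1:6))
  # gamete 1: 000100 -> marker 4 flagged; gamete 2: 000111 -> single crossover
  expect_equal(nrow(fl), 1)
  expect_equal(fl$marker_id, "m4")
  expect_equal(fl$offspring_id, "k1")
})

test_that("sex positions at a fixed order match the per-sex data", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  tm <- attr(ds, "truth")
  ord <- tm$marker_id[tm$lg == 1]
  map <- tibble::tibble(lg = 1L, rank = seq_along(ord), marker_id = ord,
                        tier = "LOD3", cm_sexavg = 0, cm_female = 0, cm_male = 0)
  class(map) <- c("pearl_map", class(map))
  out <- sex_specific_positions(map, ms)
  expect_true(all(diff(out$cm_female) >= 0))
  expect_true(all(diff(out$cm_male) >= 0))
  expect_equal(out$cm_female[1], 0)
  # female map longer than male on average under the 1.15 ratio design
  expect_gt(max(out$cm_female) + max(out$cm_male), 0)
})

test_that("interval sex counts are integer and sum across sexes", {
  ds <- small_sim()
  ms <- meiosis_set(ds)
  tm <- attr(ds, "truth")
  map <- tibble::tibble(lg = tm$lg, marker_id = tm$marker_id)
  isc <- interval_sex_counts(map, ms)
  expect_equal(nrow(isc), nrow(tm) - 3)
  expect_true(all(isc$R_f <= isc$N_f & isc$R_m <= isc$N_m))
  expect_true(all(isc$N_f + isc$N_m >= 0))
})
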