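test_that("truth maps honour the configured design exactly", {
  cfg <- sim_config(seed = 3, n_lg = 4, markers_per_lg = 12)
  tm <- simulate_truth_map(cfg)
  expect_equal(nrow(tm), 48)
  expect_equal(dplyr::n_distinct(tm$lg), 4)
  # strictly increasing positions per sex per group
  by_lg <- split(tm, tm$lg)
  for (d in by_lg) {
    expect_true(all(diff(d$cm_sexavg) > 0))
    expect_true(all(diff(d$cm_female) > 0))
    expect_true(all(diff(d$cm_male) > 0))
    len <- max(d$cm_sexavg)
    expect_gte(len, 48 * 0.99); expect_lte(len, 76 / 0.99)
  }
  # total female:male ratio is the configured value by construction
  ratio <- sum(tapply(tm$cm_female, tm$lg, max)) / sum(tapply(tm$cm_male, tm$lg, max))
  expect_equal(ratio, 1.15, tolerance = 0.01)
  # zero warp strength collapses the three maps
  tm0 <- simulate_truth_map(sim_config(seed = 3, n_lg = 2, markers_per_lg = 8,
                                       warp_strength = 0, fm_ratio = 1))
  expect_equal(tm0$cm_female, tm0$cm_male, tolerance = 1e-12)
  expect_equal(tm0$cm_female, tm0$cm_sexavg, tolerance = 1e-12)
})

test_that("the default pedigree matches the mapping-family design", {
  ds <- simulate_dataset(sim_config(seed = 5, n_lg = 1, markers_per_lg = 3))
  ped <- ds$pedigree
  expect_equal(nrow(ped), 351)
  expect_equal(sum(grepl("^F0_", ped$id)), 14)
  expect_equal(sum(grepl("^F2_", ped$id)), 219)
  expect_equal(nrow(ped) - 14 - 219, 118) # genotyped F1 + unknown-ancestry parents
  fams <- table(ped$family[grepl("^F2_", ped$id)])
  expect_equal(length(fams), 8)
  expect_true(all(fams >= 14 & fams <= 99))
  expect_equal(sum(fams), 219)
  # two-generation families have parents of unknown ancestry
  unk <- ped[grepl("^U", ped$id), ]
  expect_equal(nrow(unk), 4)
  expect_true(all(is.na(unk$sire)))
})

test_that("simulated genotypes are Mendelian-consistent when error-free", {
  ds <- small_sim()
  expect_equal(nrow(mendelian_check(ds)$conflicts), 0)
})

test_that("same seed gives byte-identical emitted files", {
  cfg <- sim_config(seed = 12, n_lg = 2, markers_per_lg = 6,
                    n_f2 = c(20L, 15L, 14L, 14L, 14L, 14L, 14L, 14L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_dataset(simulate_dataset(cfg), d1)
  emit_dataset(simulate_dataset(cfg), d2)
  for (f in c("genotypes.ped", "markers.map", "pedigree.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("crossover process reproduces the Haldane fraction", {
  set.seed(123)
  n <- 10000
  o <- pearlmap:::sim_gamete_origins(list(c(0, 10)), n)
  rec <- mean(o[, 1] != o[, 2])
  expected <- 0.5 * (1 - exp(-0.2))
  expect_lt(abs(rec - expected), 3 * sqrt(expected * (1 - expected) / n))
  # zero-length map: no recombinant gametes
  o0 <- pearlmap:::sim_gamete_origins(list(c(5, 5, 5)), 200)
  expect_true(all(o0[, 1] == o0[, 2] & o0[, 2] == o0[, 3]))
})

test_that("viability distortion skews transmissions at the selected locus", {
  cfg <- sim_config(seed = 9, n_lg = 1, markers_per_lg = 4,
                    lg_length_range = c(40, 40),
                    distortion = tibble::tibble(marker = 2L, genotype = 2L, s = 0.9))
  ds <- simulate_dataset(cfg)
  # pooled transmission counts show decisive distortion at the selected
  # locus, pushed away from the disfavoured B allele, and none elsewhere
  tc <- transmission_counts(meiosis_set(ds))
  ids <- ds$markers$marker_id
  gp <- g_partition(tc[tc$marker_id == ids[2], ])
  expect_lt(gp$p_pooled, 1e-6)
  expect_equal(gp$direction, 1)
  gp0 <- g_partition(tc[tc$marker_id == ids[4], ])
  expect_gt(gp0$p_pooled, 0.001)
})

test_that("injected genotyping errors are recorded and flaggable", {
  cfg <- sim_config(seed = 8, n_lg = 1, markers_per_lg = 8,
                    lg_length_range = c(50, 50), error_rate = 0.01)
  ds <- simulate_dataset(cfg)
  err <- attr(ds, "injected_errors")
  expect_gt(nrow(err), 0)
  # errors create Mendelian conflicts at plausible rates
  mc <- mendelian_check(ds)
  expect_gt(nrow(mc$conflicts), 0)
})

test_that("truth files parse back into an equivalent dataset", {
  ds <- small_sim()
  dir <- withr::local_tempdir()
  paths <- emit_dataset(ds, dir)
  truth <- readr::read_tsv(paths["truth"], show_col_types = FALSE)
  expect_equal(nrow(truth), ncol(ds$geno))
  qc <- apply_qc(read_genotypes(paths["ped"], paths["map"]))
  expect_true(all(qc$report$pass))
})
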