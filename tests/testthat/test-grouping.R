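test_that("default layers decrease in stringency", {
  ly <- autogroup_layers()
  expect_equal(nrow(ly), 5)
  expect_true(all(diff(ly$min_lod) < 0))
  expect_true(all(diff(ly$min_inf) < 0))
  expect_true(all(diff(ly$max_groups) > 0))
  expect_true(all(diff(ly$min_ratio) < 0))
})

test_that("single-linkage seeding recovers clearly separated clusters", {
  pairs <- tibble::tibble(
    marker_i = c("A", "A", "B", "D"),
    marker_j = c("B", "C", "C", "E"),
    theta = 0.01, lod = 20
  )
  info <- tibble::tibble(marker_id = c("A", "B", "C", "D", "E"),
                         n_inf_known = 100L, n_inf_unknown = 100L)
  gr <- group_markers(pairs, info)
  expect_equal(sum(is.na(gr$group)), 0)
  # group 1 is the larger cluster
  expect_equal(sort(gr$marker_id[gr$group == 1]), c("A", "B", "C"))
  expect_equal(sort(gr$marker_id[gr$group == 2]), c("D", "E"))
})

test_that("a marker splitting its links between two groups is deferred", {
  # two tight clusters plus marker X linked equally to both
  pairs <- tibble::tibble(
    marker_i = c("A", "B", "D", "E", "X", "X"),
    marker_j = c("B", "C", "E", "F", "A", "D"),
    theta = c(rep(0.01, 4), 0.2, 0.2),
    lod = c(rep(120, 4), 60, 60)
  )
  info <- tibble::tibble(marker_id = c(LETTERS[1:6], "X"),
                         n_inf_known = 200L, n_inf_unknown = 200L)
  gr <- group_markers(pairs, info)
  # X has a 0.5 share to each group: below every ratio threshold until
  # layer 5 (0.5), where it finally joins one of them
  expect_false(is.na(gr$group[gr$marker_id == "X"]))
  expect_equal(gr$layer[gr$marker_id == "X"], 5L)
  gx <- gr$group[gr$marker_id == "X"]
  expect_true(gx %in% gr$group[gr$marker_id %in% LETTERS[1:6]])
})

test_that("an isolated spurious link cannot fuse two chromosomes", {
  # two chains plus one strong spurious cross link
  chain <- function(ids, lod) tibble::tibble(
    marker_i = head(ids, -1), marker_j = tail(ids, -1), theta = 0.02, lod = lod)
  a <- paste0("a", 1:6); b <- paste0("b", 1:6)
  # spurious cross-chromosome pairs sit in the heavy null tail of the
  # phase-mixture LOD: moderate LOD at a loose fraction
  pairs <- dplyr::bind_rows(
    chain(a, 60), chain(b, 60),
    tibble::tibble(marker_i = "a3", marker_j = "b4", theta = 0.28, lod = 6)
  )
  info <- tibble::tibble(marker_id = c(a, b), n_inf_known = 200L, n_inf_unknown = 0L)
  gr <- group_markers(pairs, info)
  ga <- unique(gr$group[gr$marker_id %in% a])
  gb <- unique(gr$group[gr$marker_id %in% b])
  expect_length(ga, 1); expect_length(gb, 1)
  expect_false(ga == gb)
})

test_that("grouping recovers simulated linkage groups exactly", {
  cfg <- sim_config(seed = 77, n_lg = 3, markers_per_lg = 40,
                    lg_length_range = c(50, 60))
  ds <- simulate_dataset(cfg)
  ms <- meiosis_set(apply_qc(ds)$dataset)
  sc <- two_point_scan(ms)
  gr <- group_markers(sc, ms$marker_info)
  truth <- attr(ds, "truth")
  got <- gr$group[!is.na(gr$group)]
  want <- truth$lg[match(gr$marker_id[!is.na(gr$group)], truth$marker_id)]
  expect_equal(adjusted_rand(got, want), 1.0)
  expect_lte(sum(is.na(gr$group)), 2)
})

test_that("haplogroups are threshold-graph components with informative primaries", {
  pairs <- tibble::tibble(
    marker_i = c("A", "B", "A", "C"),
    marker_j = c("B", "C", "C", "D"),
    theta = c(0.02, 0.02, 0.04, 0.05),
    lod = c(30, 30, 30, 30)
  )
  info <- tibble::tibble(marker_id = c("A", "B", "C", "D"),
                         n_inf_known = c(50L, 80L, 60L, 10L),
                         n_inf_unknown = 0L)
  hg <- find_haplogroups(c("A", "B", "C", "D"), pairs, info)
  # chain A-B, B-C tight; A-C loose but same component; D separate
  expect_equal(dplyr::n_distinct(hg$haplogroup[hg$marker_id %in% c("A", "B", "C")]), 1)
  expect_false(hg$haplogroup[hg$marker_id == "D"] %in%
                 hg$haplogroup[hg$marker_id != "D"])
  expect_equal(hg$marker_id[hg$primary & hg$marker_id != "D"], "B")
  # theta above 0.03 between two markers keeps them in separate haplogroups
  p2 <- tibble::tibble(marker_i = "A", marker_j = "B", theta = 0.05, lod = 30)
  hg2 <- find_haplogroups(c("A", "B"), p2, info)
  expect_equal(dplyr::n_distinct(hg2$haplogroup), 2)
})
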