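#' Run the full mapping pipeline
#'
#' QC, meiosis extraction, two-point scan, layered grouping, per-group
#' haplogroup collapsing and hierarchical ordering with window refinement
#' and double-recombinant audit, sex-specific maps, map metrics,
#' heterochiasmy / distortion tests and (optionally) LD decay, with full
#' marker-attrition accounting. Every stage is deterministic given the
#' input dataset.
#'
#' @param dataset A `linkage_dataset`.
#' @param stages Character subset of
#'   `c("qc", "map", "metrics", "tests", "ld")`; later stages require the
#'   map stage.
#' @param qc A [qc_config()].
#' @param layers Grouping layers ([autogroup_layers()]).
#' @param min_inf Minimum informative meioses per marker (default 10).
#' @param lod_floor Two-point reporting floor.
#' @param tier_lods,window Map-building controls (see [build_map()]).
#' @param haplogroup_lod,haplogroup_theta Haplogroup thresholds.
#' @param fdr_alpha FDR level for the test stages.
#' @param ld_founders_only Compute LD on founders only.
#' @param tol Multipoint profiling tolerance.
#' @return A list of class `pearl_run`: `qc`, `map`, `groups`,
#'   `haplogroups`, `metrics`, `tests`, `ld`, `attrition`, `summary`,
#'   `skipped`.
#' @export
run_pipeline <- function(dataset,
                         stages = c("qc", "map", "metrics", "tests", "ld"),
                         qc = qc_config(),
                         layers = autogroup_layers(),
                         min_inf = 10,
                         lod_floor = 0.1,
                         tier_lods = c(3, 2, 1),
                         window = 5,
                         haplogroup_lod = 3,
                         haplogroup_theta = 0.03,
                         fdr_alpha = 0.05,
                         ld_founders_only = FALSE,
                         tol = 1e-4) {
  out <- structure(list(), class = "pearl_run")
  n_input <- ncol(dataset$geno)
  n_qc_failed <- 0L
  if ("qc" %in% stages) {
    qcres <- apply_qc(dataset, qc)
    out$qc <- qcres$report
    n_qc_failed <- sum(!qcres$report$pass)
    dataset <- qcres$dataset
  }
  if (!("map" %in% stages)) {
    out$skipped <- setdiff(c("map", "metrics", "tests", "ld"), character())
    out$attrition <- tibble::tibble(n_input = n_input, n_qc_failed = n_qc_failed)
    return(out)
  }
  mset <- meiosis_set(dataset)
  pairs <- two_point_scan(mset, lod_floor = lod_floor, min_inf = min_inf)
  low_inf <- attr(pairs, "excluded_markers")
  info <- mset$marker_info[!(mset$marker_info$marker_id %in% low_inf), ]
  groups <- group_markers(pairs, info, layers)
  out$groups <- groups
  ungrouped <- groups$marker_id[is.na(groups$group)]
  hg_all <- list(); maps <- list(); dropped <- list(); flags <- list()
  for (g in sort(unique(groups$group[!is.na(groups$group)]))) {
    members <- groups$marker_id[!is.na(groups$group) & groups$group == g]
    hg <- find_haplogroups(members, pairs, info, haplogroup_lod, haplogroup_theta)
    hg$lg <- g
    hg_all[[g]] <- hg
    bm <- build_map(mset, members, hg, lg = g, tier_lods = tier_lods,
                    window = window, tol = tol, pairs = pairs)
    aud <- chrompic_audit(bm, mset, window = window, tol = tol, pairs = pairs)
    maps[[g]] <- aud$map
    flags[[g]] <- aud$flags
    if (length(attr(bm, "unplaced")) > 0) {
      dropped[[paste0("u", g)]] <- tibble::tibble(
        marker_id = attr(bm, "unplaced"), reason = "ambiguous_position")
    }
    if (nrow(aud$dropped) > 0) dropped[[paste0("d", g)]] <- aud$dropped
  }
  map <- dplyr::bind_rows(maps)
  class(map) <- c("pearl_map", class(tibble::tibble()))
  map <- sex_specific_positions(map, mset, tol = tol)
  out$map <- map
  out$haplogroups <- dplyr::bind_rows(hg_all)
  out$chrompic_flags <- dplyr::bind_rows(flags)
  dropped_tbl <- dplyr::bind_rows(dropped)
  ambiguous <- dropped_tbl$marker_id[dropped_tbl$reason == "ambiguous_position"]
  n_dropped <- sum(dropped_tbl$reason == "unresolved_double_recombinant")
  grouped_unmapped <- setdiff(
    groups$marker_id[!is.na(groups$group)], map$marker_id)
  grouped_unmapped <- setdiff(grouped_unmapped, dropped_tbl$marker_id)
  grouped_unmapped <- union(grouped_unmapped, ambiguous)
  dropped_tbl <- dropped_tbl[dropped_tbl$reason != "ambiguous_position", ]
  out$attrition <- tibble::tibble(
    n_input = n_input,
    n_qc_failed = n_qc_failed,
    n_low_meioses = length(low_inf),
    n_ungrouped = length(ungrouped),
    n_grouped_unmapped = length(grouped_unmapped),
    n_dropped_double_recomb = n_dropped,
    n_mapped = nrow(map)
  )
  out$dropped <- dplyr::bind_rows(
    if (n_qc_failed > 0) tibble::tibble(marker_id = out$qc$marker_id[!out$qc$pass],
                                        reason = out$qc$reason[!out$qc$pass]),
    tibble::tibble(marker_id = low_inf, reason = rep("low_meioses", length(low_inf))),
    tibble::tibble(marker_id = ungrouped, reason = rep("ungrouped", length(ungrouped))),
    tibble::tibble(marker_id = grouped_unmapped,
                   reason = rep("grouped_unmapped", length(grouped_unmapped))),
    dropped_tbl
  )
  if ("metrics" %in% stages) {
    ist <- interval_stats(map)
    per_lg <- map |>
      dplyr::group_by(lg = .data$lg) |>
      dplyr::summarise(n_markers = dplyr::n(),
                       len_sexavg = max(.data$cm_sexavg),
                       len_female = max(.data$cm_female),
                       len_male = max(.data$cm_male), .groups = "drop")
    cov <- genome_coverage(per_lg)
    std <- standardized_intervals(map)
    slopes <- tryCatch(piecewise_slope_test(std), error = function(e) NULL)
    out$metrics <- list(
      coverage = cov, intervals = ist, standardized = std, slopes = slopes,
      fm_ratio_per_lg = per_lg |>
        dplyr::mutate(fm_ratio = fm_ratio(.data$len_female, .data$len_male)),
      fm_ratio_total = fm_ratio(sum(per_lg$len_female), sum(per_lg$len_male))
    )
    out$summary <- table1_summary(map)
  }
  if ("tests" %in% stages) {
    isc <- interval_sex_counts(map, mset)
    het <- dplyr::bind_cols(isc, sex_heterogeneity_test(isc$R_f, isc$N_f, isc$R_m, isc$N_m))
    fdr <- bh_fdr(het$p[het$tested], fdr_alpha)
    het$q_pass <- FALSE
    het$q_pass[het$tested] <- fdr$pass
    per_lg_het <- purrr::map_dfr(unique(het$lg), function(g)
      pool_heterogeneity(het[het$lg == g, ], scope = paste0("LG", g)))
    genome_het <- pool_heterogeneity(het, scope = "genome")
    tc <- transmission_counts(mset)
    tc <- tc[tc$marker_id %in% map$marker_id, ]
    dist <- tc |>
      dplyr::group_by(marker_id = .data$marker_id) |>
      dplyr::group_modify(~ g_partition(.x)) |>
      dplyr::ungroup()
    dfdr <- bh_fdr(dist$p_pooled, fdr_alpha)
    dist$q_pass <- dfdr$pass
    fam <- interval_family_counts(map, mset)
    mtest <- fam |>
      dplyr::group_by(lg = .data$lg, interval = .data$interval) |>
      dplyr::group_modify(function(d, key) {
        d <- d[d$N > 0, ]
        if (nrow(d) < 2) return(tibble::tibble(m_stat = NA_real_, df = NA_integer_, p = NA_real_))
        r <- family_m_test(d[, c("family", "R", "N")])
        tibble::tibble(m_stat = r$m_stat, df = r$df, p = r$p)
      }) |>
      dplyr::ungroup()
    mfdr <- bh_fdr(mtest$p[!is.na(mtest$p)], fdr_alpha)
    mtest$q_pass <- FALSE
    mtest$q_pass[!is.na(mtest$p)] <- mfdr$pass
    out$tests <- list(
      sex_heterogeneity = het,
      sex_heterogeneity_per_lg = dplyr::bind_rows(per_lg_het, genome_het),
      distortion = dist,
      distortion_alpha = dfdr$alpha_corrected,
      m_test = mtest
    )
  }
  if ("ld" %in% stages) {
    ld <- ld_scan(dataset, founders_only = ld_founders_only)
    out$ld <- c(list(pairs = ld), decay_table(ld, map))
  }
  out$skipped <- setdiff(c("qc", "map", "metrics", "tests", "ld"), stages)
  out
}

#' @export
print.pearl_run <- function(x, ...) {
  cat("<pearl_run>\n")
  if (!is.null(x$attrition)) {
    cat("  markers:", x$attrition$n_input)
    if (!is.null(x$attrition$n_mapped)) cat(" in,", x$attrition$n_mapped, "mapped")
    cat("\n")
  }
  if (!is.null(x$map)) cat("  linkage groups:", dplyr::n_distinct(x$map$lg), "\n")
  if (length(x$skipped)) cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Per-linkage-group map summary table
#'
#' One row per linkage group with mapped SNP count, the observed
#' sex-average/female/male lengths and expected (inflated) lengths, the
#' female:male ratio, mean non-zero intervals per sex (with SD) and the
#' sex-average interval histogram, plus a totals row (counts and lengths
#' summed; average intervals averaged unweighted across groups; coverage
#' = observed/expected totals).
#'
#' @param map A `pearl_map` with sex positions filled.
#' @return A tibble; the totals row has `lg = NA`.
#' @export
table1_summary <- function(map) {
  per_lg <- purrr::map_dfr(sort(unique(map$lg)), function(g) {
    d <- map[map$lg == g, ]
    iv <- list(sexavg = diff(d$cm_sexavg), female = diff(d$cm_female), male = diff(d$cm_male))
    nz <- lapply(iv, function(x) x[x > 0])
    tibble::tibble(
      lg = g, n_snps = nrow(d),
      len_sexavg = max(d$cm_sexavg), len_female = max(d$cm_female), len_male = max(d$cm_male),
      ge_sexavg = expected_length(max(d$cm_sexavg), nrow(d)),
      ge_female = expected_length(max(d$cm_female), nrow(d)),
      ge_male = expected_length(max(d$cm_male), nrow(d)),
      fm_ratio = fm_ratio(max(d$cm_female), max(d$cm_male)),
      int_sexavg = mean(nz$sexavg), int_sexavg_sd = sd(nz$sexavg),
      int_female = mean(nz$female), int_female_sd = sd(nz$female),
      int_male = mean(nz$male), int_male_sd = sd(nz$male),
      n_intervals = length(nz$sexavg),
      n_0_1 = sum(nz$sexavg <= 1), n_1_2 = sum(nz$sexavg > 1 & nz$sexavg <= 2),
      n_2_3 = sum(nz$sexavg > 2 & nz$sexavg <= 3), n_gt3 = sum(nz$sexavg > 3)
    )
  })
  totals <- tibble::tibble(
    lg = NA_integer_, n_snps = sum(per_lg$n_snps),
    len_sexavg = sum(per_lg$len_sexavg), len_female = sum(per_lg$len_female),
    len_male = sum(per_lg$len_male),
    ge_sexavg = sum(per_lg$ge_sexavg), ge_female = sum(per_lg$ge_female),
    ge_male = sum(per_lg$ge_male),
    fm_ratio = sum(per_lg$len_female) / sum(per_lg$len_male),
    int_sexavg = mean(per_lg$int_sexavg), int_sexavg_sd = NA_real_,
    int_female = mean(per_lg$int_female), int_female_sd = NA_real_,
    int_male = mean(per_lg$int_male), int_male_sd = NA_real_,
    n_intervals = sum(per_lg$n_intervals),
    n_0_1 = sum(per_lg$n_0_1), n_1_2 = sum(per_lg$n_1_2),
    n_2_3 = sum(per_lg$n_2_3), n_gt3 = sum(per_lg$n_gt3)
  )
  dplyr::bind_rows(per_lg, totals)
}
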