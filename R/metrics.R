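#' Expected linkage-group length
#'
#' Inflates an observed linkage-group length for chromosome ends not spanned
#' by markers: `Ge = L * (m + 1) / (m - 1)`, with `m` the number of mapped
#' loci on the group.
#'
#' @param length_cm Observed group length(s) in cM.
#' @param n_markers Number of mapped markers per group; must be `>= 2`.
#' @return Expected length(s) in cM.
#' @examples
#' expected_length(70.30, 129) # 71.40
#' @export
expected_length <- function(length_cm, n_markers) {
  if (any(n_markers < 2)) stop("expected_length() needs at least 2 markers per group", call. = FALSE)
  if (any(length_cm < 0)) stop("negative observed length", call. = FALSE)
  length_cm * (n_markers + 1) / (n_markers - 1)
}

#' Genome length and coverage from per-group map summaries
#'
#' Computes, for each of the sex-average, female and male maps present in the
#' input, the observed genome length `Goa` (sum of observed group lengths),
#' the expected genome length `Ge` (sum of per-group inflated lengths) and
#' the coverage `Coa = Goa / Ge`.
#'
#' @param per_lg A data frame with one row per linkage group: a `lg` column,
#'   an `n_markers` column, and one or more of `len_sexavg`, `len_female`,
#'   `len_male` (observed lengths, cM).
#' @return A list with `per_lg` (input plus `ge_*` columns) and `totals`
#'   (tibble with one row per map: `map`, `goa`, `ge`, `coverage`,
#'   `fm_ratio` where both sex maps are present).
#' @examples
#' tbl <- tibble::tibble(lg = 1:2, n_markers = c(10, 5),
#'                       len_sexavg = c(50, 40))
#' genome_coverage(tbl)$totals
#' @export
genome_coverage <- function(per_lg) {
  stopifnot(is.data.frame(per_lg), nrow(per_lg) >= 1,
            all(c("lg", "n_markers") %in% names(per_lg)))
  maps <- intersect(c("len_sexavg", "len_female", "len_male"), names(per_lg))
  if (length(maps) == 0) stop("no length columns (len_sexavg/len_female/len_male) found", call. = FALSE)
  out <- tibble::as_tibble(per_lg)
  for (col in maps) {
    out[[sub("^len_", "ge_", col)]] <- expected_length(out[[col]], out$n_markers)
  }
  totals <- purrr::map_dfr(maps, function(col) {
    tibble::tibble(
      map = sub("^len_", "", col),
      goa = sum(out[[col]]),
      ge = sum(out[[sub("^len_", "ge_", col)]]),
      coverage = sum(out[[col]]) / sum(out[[sub("^len_", "ge_", col)]])
    )
  })
  if (all(c("len_female", "len_male") %in% maps)) {
    totals$fm_ratio <- ifelse(
      totals$map == "female" | totals$map == "male" | totals$map == "sexavg",
      sum(out$len_female) / sum(out$len_male), NA_real_
    )
  }
  list(per_lg = out, totals = totals)
}

#' Female-to-male map-length ratio
#'
#' @param female_cm,male_cm Map lengths in cM.
#' @return `R = Xf / Xm`; `Inf` (with a warning) when the male length is 0.
#' @examples
#' fm_ratio(77.13, 36.34) # 2.12
#' @export
fm_ratio <- function(female_cm, male_cm) {
  out <- female_cm / male_cm
  if (any(male_cm == 0)) {
    warning("male map length of 0; ratio is infinite", call. = FALSE)
    out[male_cm == 0] <- Inf
  }
  out
}

#' Marker-interval statistics for an ordered map
#'
#' Per linkage group: the mean non-zero interval (group length divided by the
#' number of non-zero intervals), the median interval including zeros, and a
#' histogram of non-zero intervals over the bins 0-1, 1-2, 2-3 and > 3 cM.
#' The overall mean is the unweighted mean of the per-group means (this is
#' the convention under which a dense published map's per-group averages
#' aggregate to the printed overall average; the pooled mean is also
#' reported).
#'
#' @param map An ordered-map tibble with columns `lg`, `cm_sexavg` (or a
#'   column named by `position`), ordered within group.
#' @param position Name of the position column to summarise.
#' @return A list with `per_lg` and `overall` tibbles.
#' @export
interval_stats <- function(map, position = "cm_sexavg") {
  stopifnot(is.data.frame(map), "lg" %in% names(map), position %in% names(map))
  per_lg <- map |>
    dplyr::group_by(.data$lg) |>
    dplyr::arrange(.data[[position]], .by_group = TRUE) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      length_cm = max(.data[[position]]) - min(.data[[position]]),
      intervals = list(diff(.data[[position]])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_intervals = purrr::map_int(.data$intervals, length),
      n_nonzero = purrr::map_int(.data$intervals, ~ sum(.x > 0)),
      mean_nonzero = ifelse(.data$n_nonzero > 0, .data$length_cm / .data$n_nonzero, NA_real_),
      median_all = purrr::map_dbl(.data$intervals, ~ if (length(.x)) median(.x) else NA_real_),
      bin_0_1 = purrr::map_int(.data$intervals, ~ sum(.x > 0 & .x <= 1)),
      bin_1_2 = purrr::map_int(.data$intervals, ~ sum(.x > 1 & .x <= 2)),
      bin_2_3 = purrr::map_int(.data$intervals, ~ sum(.x > 2 & .x <= 3)),
      bin_gt3 = purrr::map_int(.data$intervals, ~ sum(.x > 3))
    ) |>
    dplyr::select(-"intervals")
  if (any(per_lg$n_nonzero == 0 & per_lg$n_intervals > 0)) {
    warning("linkage group(s) with only zero-length intervals; mean undefined", call. = FALSE)
  }
  all_int <- unlist(map |>
    dplyr::group_by(.data$lg) |>
    dplyr::arrange(.data[[position]], .by_group = TRUE) |>
    dplyr::group_map(~ diff(.x[[position]])))
  overall <- tibble::tibble(
    mean_nonzero_unweighted = mean(per_lg$mean_nonzero, na.rm = TRUE),
    mean_nonzero_pooled = if (any(all_int > 0)) sum(all_int) / sum(all_int > 0) else NA_real_,
    median_all = if (length(all_int)) median(all_int) else NA_real_,
    n_nonzero = sum(all_int > 0),
    frac_below_1cm = if (any(all_int > 0)) mean(all_int[all_int > 0] <= 1) else NA_real_
  )
  list(per_lg = per_lg, overall = overall)
}

#' Standardised per-sex marker intervals
#'
#' Expresses each adjacent interval as a percentage of its linkage group's
#' per-sex length: `100 * interval / LG length`. Standardised intervals sum
#' to 100 within each (group, sex).
#'
#' @param map Ordered-map tibble with `lg`, `marker_id`, `cm_female`,
#'   `cm_male` columns (positions along the fixed sex-average order).
#' @return Tibble with one row per interval: `lg`, `interval` (index),
#'   `female`, `male` (cM), `std_female`, `std_male`,
#'   `cum_std_female`, `cum_std_male`, `fm_ratio`.
#' @export
standardized_intervals <- function(map) {
  stopifnot(all(c("lg", "cm_female", "cm_male") %in% names(map)))
  map |>
    dplyr::group_by(.data$lg) |>
    dplyr::arrange(dplyr::row_number(), .by_group = TRUE) |>
    dplyr::reframe(
      interval = seq_len(dplyr::n() - 1),
      female = diff(.data$cm_female),
      male = diff(.data$cm_male)
    ) |>
    dplyr::group_by(.data$lg) |>
    dplyr::mutate(
      std_female = 100 * .data$female / sum(.data$female),
      std_male = 100 * .data$male / sum(.data$male),
      cum_std_female = cumsum(.data$std_female),
      cum_std_male = cumsum(.data$std_male),
      fm_ratio = .data$female / .data$male
    ) |>
    dplyr::ungroup()
}

#' Piecewise slope comparison of female and male standardised positions
#'
#' Within each linkage group the cumulative standardised female and male
#' positions are split at two breakpoints into left / middle / right groups
#' (two groups when only one breakpoint is given) and an ordinary
#' least-squares line is fitted within each. The primary `slope` regresses
#' the male coordinate on the female coordinate, the orientation in which
#' centromeric male suppression produces a middle slope below 1 and
#' telomeric male inflation produces outer slopes above 1; the reverse
#' orientation is reported as `slope_female_on_male`. Each slope carries a
#' standard error and a two-sided t-test of H0: slope = 1.
#'
#' @param intervals Output of [standardized_intervals()].
#' @param breakpoints Either a data frame with columns `lg`, `bp1`, `bp2`
#'   (interval indices; `bp2` may be `NA` for a 2-group split) or `NULL`, in
#'   which case breakpoints minimising the total within-group residual sum
#'   of squares of the primary regression are chosen per group (an automatic
#'   stand-in for breakpoints otherwise assigned by eye).
#' @param min_points Minimum number of points per group for a test
#'   (default 3); smaller groups are flagged and untested.
#' @return Tibble: `lg`, `group` (left/middle/right), `n`, `slope`, `se`,
#'   `p_vs_1`, `slope_female_on_male`, `tested`.
#' @export
piecewise_slope_test <- function(intervals, breakpoints = NULL, min_points = 3) {
  stopifnot(all(c("lg", "cum_std_female", "cum_std_male") %in% names(intervals)))
  lgs <- unique(intervals$lg)
  purrr::map_dfr(lgs, function(g) {
    d <- intervals[intervals$lg == g, ]
    x <- c(0, d$cum_std_female)
    y <- c(0, d$cum_std_male)
    n <- length(x)
    if (is.null(breakpoints)) {
      bp <- auto_breakpoints(x, y, min_points)
    } else {
      row <- breakpoints[breakpoints$lg == g, , drop = FALSE]
      if (nrow(row) != 1) stop("no breakpoint row for group ", g, call. = FALSE)
      bp <- c(row$bp1[[1]], if (!is.na(row$bp2[[1]])) row$bp2[[1]])
    }
    cuts <- c(0, bp, n)
    labels <- if (length(bp) == 2) c("left", "middle", "right") else c("left", "right")
    purrr::map_dfr(seq_along(labels), function(k) {
      idx <- (cuts[k] + 1):cuts[k + 1]
      xs <- x[idx]; ys <- y[idx]
      if (length(idx) < min_points || sd(xs) == 0 || sd(ys) == 0) {
        return(tibble::tibble(lg = g, group = labels[k], n = length(idx),
                              slope = NA_real_, se = NA_real_, p_vs_1 = NA_real_,
                              slope_female_on_male = NA_real_, tested = FALSE))
      }
      fit <- lm(ys ~ xs)
      sl <- coef(fit)[[2]]
      se <- sqrt(vcov(fit)[2, 2])
      p <- if (se < 1e-12) {
        if (abs(sl - 1) < 1e-9) 1 else 0
      } else {
        2 * pt(abs((sl - 1) / se), df = length(idx) - 2, lower.tail = FALSE)
      }
      fit2 <- lm(xs ~ ys)
      tibble::tibble(lg = g, group = labels[k], n = length(idx), slope = sl,
                     se = se, p_vs_1 = p,
                     slope_female_on_male = coef(fit2)[[2]], tested = TRUE)
    })
  })
}

# Exhaustive search over breakpoint pairs minimising total RSS of the three
# male-on-female segment fits.
auto_breakpoints <- function(x, y, min_points = 3) {
  n <- length(x)
  seg_rss <- function(idx) {
    xs <- x[idx]; ys <- y[idx]
    if (sd(xs) == 0) return(sum((ys - mean(ys))^2))
    sum(lm(ys ~ xs)$residuals^2)
  }
  best <- NULL; best_rss <- Inf
  for (b1 in min_points:(n - 2 * min_points)) {
    for (b2 in (b1 + min_points):(n - min_points)) {
      rss <- seg_rss(1:b1) + seg_rss((b1 + 1):b2) + seg_rss((b2 + 1):n)
      if (rss < best_rss) { best_rss <- rss; best <- c(b1, b2) }
    }
  }
  if (is.null(best)) stop("too few intervals for automatic breakpoints", call. = FALSE)
  best
}
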