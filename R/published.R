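#' Published per-linkage-group summary of the P. maxima SNP linkage map
#'
#' The printed per-group summary statistics of the published silver-lipped
#' pearl oyster (*Pinctada maxima*) SNP linkage map: mapped SNP counts,
#' observed sex-average/female/male group lengths, and the non-zero
#' sex-average interval counts with their size histogram. These printed
#' values serve as reference inputs for the genome-length, coverage and
#' heterochiasmy arithmetic (e.g. [genome_coverage()], [fm_ratio()],
#' [interval_stats()]); they are not outputs of this package.
#'
#' @return Tibble with one row per linkage group: `lg`, `n_snps`,
#'   `len_sexavg`, `len_female`, `len_male` (cM), `n_intervals` (non-zero
#'   sex-average intervals) and the interval histogram counts `n_0_1`,
#'   `n_1_2`, `n_2_3`, `n_gt3`.
#' @export
pmax_map_summary <- function() {
  tibble::tribble(
    ~lg, ~n_snps, ~len_sexavg, ~len_female, ~len_male, ~n_intervals, ~n_0_1, ~n_1_2, ~n_2_3, ~n_gt3,
    1L, 129L, 70.30, 65.53, 75.29, 71L, 49L, 14L, 4L, 4L,
    2L, 129L, 66.27, 65.12, 66.02, 55L, 33L, 11L, 6L, 5L,
    3L, 97L, 59.36, 63.96, 55.25, 52L, 31L, 12L, 4L, 5L,
    4L, 89L, 71.86, 76.94, 83.76, 51L, 27L, 14L, 4L, 6L,
    5L, 82L, 60.02, 66.78, 61.63, 47L, 24L, 15L, 4L, 4L,
    6L, 46L, 50.35, 57.52, 47.35, 30L, 12L, 11L, 2L, 5L,
    7L, 46L, 52.33, 68.90, 45.13, 27L, 13L, 5L, 5L, 4L,
    8L, 55L, 59.98, 68.53, 49.12, 28L, 8L, 12L, 4L, 4L,
    9L, 53L, 54.18, 43.18, 58.91, 23L, 9L, 7L, 1L, 6L,
    10L, 40L, 75.56, 83.88, 74.40, 29L, 10L, 8L, 2L, 9L,
    11L, 34L, 48.29, 59.08, 33.20, 21L, 8L, 5L, 3L, 5L,
    12L, 34L, 55.68, 58.78, 52.49, 23L, 8L, 6L, 4L, 5L,
    13L, 27L, 55.36, 77.13, 36.34, 16L, 3L, 4L, 2L, 7L,
    14L, 26L, 52.13, 60.52, 55.96, 17L, 6L, 3L, 2L, 6L
  ) |>
    dplyr::rename(n_markers = "n_snps") |>
    dplyr::mutate(n_snps = .data$n_markers, .after = "lg")
}
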