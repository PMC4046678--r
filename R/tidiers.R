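#' Tidy an ordered map
#'
#' @param x A `pearl_map`.
#' @param ... Unused.
#' @return One row per mapped marker.
#' @export
tidy.pearl_map <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Per-linkage-group glance at an ordered map
#'
#' @param x A `pearl_map`.
#' @param ... Unused.
#' @return One row per linkage group: marker count, lengths per sex,
#'   female:male ratio and framework (LOD3) marker count.
#' @export
glance.pearl_map <- function(x, ...) {
  x |>
    dplyr::group_by(lg = .data$lg) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      n_framework = sum(.data$tier == "LOD3", na.rm = TRUE),
      len_sexavg = max(.data$cm_sexavg),
      len_female = max(.data$cm_female),
      len_male = max(.data$cm_male),
      fm_ratio = max(.data$cm_female) / max(.data$cm_male),
      .groups = "drop"
    )
}

#' @export
tidy.pearl_run <- function(x, ...) {
  if (is.null(x$map)) stop("run has no map stage", call. = FALSE)
  tidy.pearl_map(x$map)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pearl_run`.
#' @param ... Unused.
#' @return The attrition accounting with total map length and coverage.
#' @export
glance.pearl_run <- function(x, ...) {
  out <- x$attrition
  if (!is.null(x$metrics)) {
    tot <- x$metrics$coverage$totals
    out$length_sexavg <- tot$goa[tot$map == "sexavg"]
    out$coverage_sexavg <- tot$coverage[tot$map == "sexavg"]
    out$fm_ratio <- x$metrics$fm_ratio_total
  }
  out
}
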