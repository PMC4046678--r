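#' Kosambi map function
#'
#' Convert a recombination fraction to a Kosambi map distance,
#' `d = 25 * ln((1 + 2 theta) / (1 - 2 theta))` cM, or back via
#' `theta = 0.5 * tanh(d / 50)`. The Kosambi function allows partial
#' crossover interference and is the transform used for all map distances
#' in this package.
#'
#' @param theta Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in centimorgans, `d >= 0`.
#' @return `kosambi_cm()` returns distances in cM; `kosambi_theta()` returns
#'   recombination fractions.
#' @examples
#' kosambi_cm(0.2)            # 21.182 cM
#' kosambi_theta(kosambi_cm(0.3))
#' @export
kosambi_cm <- function(theta) {
  if (any(!is.na(theta) & (theta < 0 | theta >= 0.5))) {
    stop("kosambi_cm() is undefined for theta outside [0, 0.5)", call. = FALSE)
  }
  25 * log((1 + 2 * theta) / (1 - 2 * theta))
}

#' @rdname kosambi_cm
#' @export
kosambi_theta <- function(d) {
  if (any(!is.na(d) & d < 0)) stop("negative map distance", call. = FALSE)
  0.5 * tanh(d / 50)
}

# Haldane transforms: the simulator's no-interference crossover process makes
# observed fractions follow Haldane, so these are needed for its truth checks.
haldane_theta <- function(d) 0.5 * (1 - exp(-d / 50))
haldane_cm <- function(theta) -50 * log(1 - 2 * theta)
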