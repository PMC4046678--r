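# Natural-log binomial kernel R*ln(theta) + (N-R)*ln(1-theta) with 0*ln(0)=0.
binom_kernel <- function(R, N, theta) {
  t1 <- ifelse(R > 0, R * log(theta), 0)
  t2 <- ifelse(N - R > 0, (N - R) * log(1 - theta), 0)
  t1 + t2
}

#' Sex-specific recombination heterogeneity test
#'
#' A 1-df likelihood-ratio goodness-of-fit test of equal female and male
#' recombination fractions for an interval:
#' `chi2 = 2 * [l(theta_f) + l(theta_m) - l(theta_joint)]` with `l` the
#' natural-log binomial kernel and each fraction at its MLE (`R/N`). The
#' test is symmetric in the sex labels and is 0 exactly when the two MLEs
#' coincide. Vectorised over intervals.
#'
#' @param R_f,N_f Recombinant and informative meiosis counts for dams.
#' @param R_m,N_m The same for sires.
#' @return Tibble: `theta_f`, `theta_m`, `theta_joint`, `chi2`, `df`, `p`,
#'   `tested` (FALSE where a sex has no meioses).
#' @examples
#' sex_heterogeneity_test(10, 50, 2, 50) # chi2 = 6.550
#' @export
sex_heterogeneity_test <- function(R_f, N_f, R_m, N_m) {
  n <- max(length(R_f), length(N_f), length(R_m), length(N_m))
  R_f <- rep_len(R_f, n); N_f <- rep_len(N_f, n)
  R_m <- rep_len(R_m, n); N_m <- rep_len(N_m, n)
  tested <- N_f >= 1 & N_m >= 1
  tf <- ifelse(N_f > 0, R_f / N_f, NA_real_)
  tm <- ifelse(N_m > 0, R_m / N_m, NA_real_)
  tj <- ifelse(N_f + N_m > 0, (R_f + R_m) / (N_f + N_m), NA_real_)
  chi2 <- 2 * (binom_kernel(R_f, N_f, tf) + binom_kernel(R_m, N_m, tm) -
                 binom_kernel(R_f + R_m, N_f + N_m, tj))
  chi2 <- pmax(chi2, 0)
  chi2[chi2 < 1e-9] <- 0
  chi2[!tested] <- NA_real_
  tibble::tibble(
    theta_f = tf, theta_m = tm, theta_joint = tj,
    chi2 = chi2, df = 1L,
    p = pchisq(chi2, df = 1, lower.tail = FALSE),
    tested = tested
  )
}

#' Pool interval-level heterogeneity statistics to a wider scope
#'
#' Sums interval chi-squares with summed degrees of freedom (the reported
#' scope-level test) and also reports the 1-df test on the pooled counts.
#'
#' @param interval_tests Output of [sex_heterogeneity_test()] with count
#'   columns `R_f`, `N_f`, `R_m`, `N_m` attached (e.g. from
#'   [interval_sex_counts()]).
#' @param scope Label for the pooled scope (e.g. a linkage group or
#'   `"genome"`).
#' @return One-row tibble with `chi2`, `df`, `p` (summed form) and
#'   `chi2_pooled`, `p_pooled` (1-df on pooled counts).
#' @export
pool_heterogeneity <- function(interval_tests, scope = "genome") {
  stopifnot(all(c("chi2", "R_f", "N_f", "R_m", "N_m") %in% names(interval_tests)))
  ok <- interval_tests$tested
  pooled <- sex_heterogeneity_test(sum(interval_tests$R_f[ok]), sum(interval_tests$N_f[ok]),
                                   sum(interval_tests$R_m[ok]), sum(interval_tests$N_m[ok]))
  tibble::tibble(
    scope = scope,
    chi2 = sum(interval_tests$chi2[ok]),
    df = sum(ok),
    p = pchisq(sum(interval_tests$chi2[ok]), df = sum(ok), lower.tail = FALSE),
    chi2_pooled = pooled$chi2, p_pooled = pooled$p
  )
}

#' Family heterogeneity M-test for a marker pair
#'
#' Tests whether per-family recombination fractions for a marker pair are
#' homogeneous: `M = 2 ln(10) * (sum_i Zmax_i - Zmax_total)`, where
#' `Zmax_i` is family *i*'s maximum two-point LOD and `Zmax_total` the
#' maximum LOD under a common fraction, with `df = n_families - 1`.
#'
#' @param fits Data frame with one row per family: columns `family`, `R`,
#'   `N` (phase-resolved recombinant / informative counts).
#' @return One-row tibble: `zmax_i` (list of per-family LODs),
#'   `zmax_total`, `m_stat`, `df`, `p`.
#' @export
family_m_test <- function(fits) {
  stopifnot(is.data.frame(fits), all(c("family", "R", "N") %in% names(fits)))
  fits <- fits[fits$N > 0, ]
  if (nrow(fits) < 2) stop("family_m_test() needs at least 2 families with informative meioses", call. = FALSE)
  zi <- theta_phase_known(fits$R, fits$N)$lod
  pooled <- theta_phase_known(sum(fits$R), sum(fits$N))
  m <- max(0, 2 * log(10) * (sum(zi) - pooled$lod))
  df <- nrow(fits) - 1L
  tibble::tibble(
    families = list(setNames(zi, fits$family)),
    zmax_total = pooled$lod,
    m_stat = m, df = df,
    p = pchisq(m, df = df, lower.tail = FALSE)
  )
}

#' Segregation-distortion G value for one heterozygous parent
#'
#' Likelihood-ratio goodness-of-fit of transmitted allele counts to the
#' Mendelian 1:1 expectation:
#' `G = 2 * [n_a ln(n_a/E) + n_b ln(n_b/E)]`, `E = (n_a + n_b)/2`,
#' with `0 * ln(0) = 0`; 1 df. Vectorised.
#'
#' @param n_a,n_b Transmission counts of the two alleles.
#' @return G value(s).
#' @examples
#' segregation_g(15, 5) # 5.232
#' @export
segregation_g <- function(n_a, n_b) {
  if (any(n_a + n_b < 1)) stop("needs at least one transmission", call. = FALSE)
  e <- (n_a + n_b) / 2
  term <- function(n) ifelse(n > 0, n * log(n / e), 0)
  2 * (term(n_a) + term(n_b))
}

#' Total / pooled / heterogeneity G partition for one marker
#'
#' Partitions the distortion evidence across the informative parents of a
#' marker: `G_total` is the sum of per-parent G values (df = number of
#' parents), `G_pooled` the G value of the summed allele counts (df = 1),
#' and `G_het = G_total - G_pooled` (df = parents - 1) measures
#' between-parent heterogeneity. Opposing per-parent distortions cancel in
#' the pooled component but remain in the heterogeneity component.
#'
#' @param transmissions Data frame with one row per informative parent:
#'   columns `parent_id`, `n_a`, `n_b`.
#' @return One-row tibble with the three G values, degrees of freedom,
#'   p-values and the pooled distortion direction (+1 toward allele A,
#'   -1 toward allele B, 0 balanced).
#' @export
g_partition <- function(transmissions) {
  stopifnot(is.data.frame(transmissions), all(c("n_a", "n_b") %in% names(transmissions)))
  tr <- transmissions[transmissions$n_a + transmissions$n_b > 0, ]
  if (nrow(tr) < 1) stop("no informative parent", call. = FALSE)
  g_i <- segregation_g(tr$n_a, tr$n_b)
  g_total <- sum(g_i)
  g_pooled <- segregation_g(sum(tr$n_a), sum(tr$n_b))
  g_het <- max(0, g_total - g_pooled)
  k <- nrow(tr)
  tibble::tibble(
    n_parents = k,
    g_total = g_total, df_total = k,
    p_total = pchisq(g_total, df = k, lower.tail = FALSE),
    g_pooled = g_pooled, df_pooled = 1L,
    p_pooled = pchisq(g_pooled, df = 1, lower.tail = FALSE),
    g_het = g_het, df_het = k - 1L,
    p_het = if (k > 1) pchisq(g_het, df = k - 1, lower.tail = FALSE) else NA_real_,
    direction = sign(sum(tr$n_a) - sum(tr$n_b))
  )
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR at level `alpha`; reports pass/fail flags, BH-adjusted
#' p-values, and the realised per-test alpha cut-off (the largest passing
#' raw p-value, the "corrected alpha" of the step-up rule; 0 when nothing
#' passes).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `pass` (logical), `p_adjusted`, and `alpha_corrected`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- p.adjust(p, method = "BH")
  pass <- !is.na(adj) & adj <= alpha
  list(
    pass = pass,
    p_adjusted = adj,
    alpha_corrected = if (any(pass)) max(p[pass]) else 0
  )
}
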