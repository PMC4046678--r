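#' Two-point estimate from phase-known counts
#'
#' Closed-form MLE and LOD for a recombinant count among phase-known
#' meioses: `theta_hat = min(R/N, 0.5)` and
#' `lod = log10[theta^R (1-theta)^(N-R) / 0.5^N]` with `0^0 = 1`.
#' Vectorised.
#'
#' @param R Recombinant counts.
#' @param N Informative meiosis counts (`N >= 1`).
#' @return Tibble with `theta` and `lod`.
#' @examples
#' theta_phase_known(2, 20)  # theta 0.10, lod 3.197
#' @export
theta_phase_known <- function(R, N) {
  stopifnot(all(N >= 1), all(R >= 0 & R <= N))
  theta <- pmin(R / N, 0.5)
  t1 <- ifelse(R > 0, R * log10(theta), 0)
  t2 <- ifelse(N - R > 0, (N - R) * log10(1 - theta), 0)
  tibble::tibble(theta = theta, lod = pmax(t1 + t2 + N * log10(2), 0))
}

# Natural-log joint likelihood difference from theta = 0.5 for pooled
# phase-known counts (R, N) plus per-parent phase-unknown mixtures (k, n).
twopoint_lldiff <- function(theta, R, N, k, n) {
  ll <- 0
  if (N > 0) {
    ll <- ll + (if (R > 0) R * log(2 * theta) else 0) +
      (if (N - R > 0) (N - R) * log(2 * (1 - theta)) else 0)
  }
  if (length(k) > 0) {
    # mixture at theta = 0.5 is 0.5 * (2 * 0.5^n) = 0.5^n
    mix <- 0.5 * (theta^k * (1 - theta)^(n - k) + theta^(n - k) * (1 - theta)^k)
    ll <- ll + sum(log(mix) - n * log(0.5))
  }
  ll
}

# Maximise the joint two-point likelihood on [0, 0.5]; ties resolved
# toward 0.5. Returns list(theta, lod).
maximize_twopoint <- function(R, N, k = integer(), n = integer(), tol = 1e-6) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  if (N + sum(n) == 0) return(list(theta = NA_real_, lod = NA_real_))
  f <- function(th) twopoint_lldiff(th, R, N, k, n)
  opt <- optimize(f, c(1e-9, 0.5 - 1e-9), maximum = TRUE, tol = tol)
  cand_th <- c(opt$maximum, 0, 0.5)
  cand_ll <- c(opt$objective, if (R == 0 && all(k == 0 | k == n)) f(1e-12) else -Inf, 0)
  best <- which.max(cand_ll + 1e-12 * (cand_th == 0.5)) # ties -> 0.5
  theta <- cand_th[best]
  lod <- max(cand_ll[best], 0) / log(10)
  if (lod < 1e-9) theta <- 0.5
  if (theta < 1e-6 && best == 1) theta <- 0
  list(theta = theta, lod = lod)
}

#' Two-point estimate from phase-unknown transmissions
#'
#' Maximises, over `theta` in `[0, 0.5]`, the product over parents of the
#' phase mixture `0.5 * [theta^k (1-theta)^(n-k) + theta^(n-k) (1-theta)^k]`,
#' where `k` counts recombinants under one arbitrary per-parent phase
#' assignment out of `n` co-informative meioses. The likelihood is
#' invariant to flipping any parent's phase (`k -> n - k`). A parent with
#' a single meiosis is uninformative.
#'
#' @param k,n Integer vectors, one entry per parent.
#' @param tol Optimisation tolerance on theta.
#' @return Tibble with `theta` and `lod`.
#' @examples
#' theta_phase_unknown(0, 10) # theta 0, lod = log10(512)
#' @export
theta_phase_unknown <- function(k, n, tol = 1e-6) {
  stopifnot(length(k) == length(n), all(k >= 0 & k <= n))
  out <- maximize_twopoint(0, 0, k, n, tol)
  tibble::tibble(theta = out$theta, lod = out$lod)
}

# Vectorised golden-section maximisation of the joint two-point
# likelihood for q pairs at once. R, N: length-q pooled phase-known
# counts; K, Nn: parents x q mixture counts.
vec_maximize_twopoint <- function(R, N, K, Nn, tol = 1e-6) {
  q <- length(R)
  p <- nrow(K)
  ll <- function(th) {
    t1 <- ifelse(R > 0, R * log(2 * th), 0)
    t2 <- ifelse(N - R > 0, (N - R) * log(2 * (1 - th)), 0)
    if (p == 0) return(t1 + t2)
    Th <- matrix(th, p, q, byrow = TRUE)
    mix <- log(0.5 * (Th^K * (1 - Th)^(Nn - K) + Th^(Nn - K) * (1 - Th)^K)) +
      Nn * log(2)
    mix[Nn == 0] <- 0
    t1 + t2 + colSums(mix)
  }
  gr <- (sqrt(5) - 1) / 2
  a <- rep(1e-9, q); b <- rep(0.5 - 1e-9, q)
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- ll(c1); fd <- ll(d1)
  while (max(b - a) > tol) {
    left <- fc > fd
    b[left] <- d1[left]; d1[left] <- c1[left]; fd[left] <- fc[left]
    c1[left] <- b[left] - gr * (b[left] - a[left])
    a[!left] <- c1[!left]; c1[!left] <- d1[!left]; fc[!left] <- fd[!left]
    d1[!left] <- a[!left] + gr * (b[!left] - a[!left])
    newpt <- ifelse(left, c1, d1)
    fnew <- ll(newpt)
    fc[left] <- fnew[left]; fd[!left] <- fnew[!left]
  }
  th_hat <- (a + b) / 2
  ll_hat <- ll(th_hat)
  lod <- pmax(ll_hat, 0) / log(10)
  theta <- ifelse(lod < 1e-9, 0.5, ifelse(th_hat < 1e-6, 0, th_hat))
  list(theta = theta, lod = lod)
}

# Pooled phase-known counts and per-parent mixture counts for one marker
# pair, optionally restricted by parent sex.
pair_counts <- function(mset, i, j, sex = NULL) {
  R <- 0L; N <- 0L; k <- integer(); n <- integer()
  rows <- seq_len(nrow(mset$parents))
  if (!is.null(sex)) rows <- rows[mset$parents$sex == sex]
  for (r in rows) {
    p <- mset$parents$parent_id[r]
    tr <- mset$trans[[p]]
    ti <- tr[, i]; tj <- tr[, j]
    ok <- !is.na(ti) & !is.na(tj)
    if (!any(ok)) next
    ph <- mset$phase[[p]]
    if (!is.na(ph[i]) && !is.na(ph[j])) {
      oi <- (ti[ok] + ph[i]) %% 2L
      oj <- (tj[ok] + ph[j]) %% 2L
      R <- R + sum(oi != oj)
      N <- N + sum(ok)
    } else {
      k <- c(k, sum(ti[ok] != tj[ok]))
      n <- c(n, sum(ok))
    }
  }
  list(R = R, N = N, k = k, n = n)
}

#' Joint two-point estimate for a marker pair
#'
#' Combines phase-known binomial kernels (pooled over parents with
#' resolved phase at both markers) and per-parent phase-unknown mixture
#' kernels into a single likelihood, maximised jointly for the sex-average
#' estimate and separately over dams and sires for the sex-specific ones.
#'
#' @param mset A [meiosis_set()].
#' @param marker_i,marker_j Marker ids.
#' @param min_inf Minimum co-informative meioses below which the pair is
#'   flagged excluded (default 10).
#' @param tol Optimisation tolerance.
#' @return One-row tibble: `marker_i`, `marker_j`, `theta`, `lod`,
#'   `theta_f`, `theta_m`, `n_known`, `n_unknown`, `r_count`, `excluded`.
#' @export
combine_two_point <- function(mset, marker_i, marker_j, min_inf = 10, tol = 1e-6) {
  i <- match(marker_i, mset$marker_ids)
  j <- match(marker_j, mset$marker_ids)
  if (is.na(i) || is.na(j)) stop("unknown marker id", call. = FALSE)
  all_c <- pair_counts(mset, i, j)
  fem <- pair_counts(mset, i, j, sex = "female")
  mal <- pair_counts(mset, i, j, sex = "male")
  est <- maximize_twopoint(all_c$R, all_c$N, all_c$k, all_c$n, tol)
  est_f <- maximize_twopoint(fem$R, fem$N, fem$k, fem$n, tol)
  est_m <- maximize_twopoint(mal$R, mal$N, mal$k, mal$n, tol)
  n_tot <- all_c$N + sum(all_c$n)
  tibble::tibble(
    marker_i = marker_i, marker_j = marker_j,
    theta = est$theta, lod = est$lod,
    theta_f = est_f$theta, theta_m = est_m$theta,
    n_known = all_c$N, n_unknown = sum(all_c$n),
    r_count = all_c$R,
    excluded = n_tot < min_inf
  )
}

#' All-pairs two-point scan
#'
#' Computes joint sex-average two-point estimates for every marker pair,
#' using a coarse likelihood grid to screen out unlinked pairs and exact
#' 1-D maximisation (tolerance `tol`) for every pair whose screened LOD
#' reaches `lod_floor`. Pairs below the floor are omitted from the output
#' (their LOD is indistinguishable from 0 at the reporting floor).
#'
#' @param mset A [meiosis_set()].
#' @param lod_floor Reporting floor for pairs (default 0.1).
#' @param min_inf Per-marker informative-meiosis threshold: markers with
#'   fewer than this many informative meioses (phase-known plus
#'   phase-unknown) are excluded from the scan entirely (default 10).
#' @param tol Optimisation tolerance for refined pairs.
#' @return Tibble of pairs (`marker_i`, `marker_j`, `theta`, `lod`,
#'   `n_known`, `n_unknown`, `r_count`), with the excluded marker ids in
#'   attribute `excluded_markers`.
#' @export
two_point_scan <- function(mset, lod_floor = 0.1, min_inf = 10, tol = 1e-6) {
  info <- mset$marker_info
  keep <- info$n_inf_known + info$n_inf_unknown >= min_inf
  excluded <- info$marker_id[!keep]
  ids <- info$marker_id[keep]
  m <- length(ids)
  col_idx <- match(ids, mset$marker_ids)
  if (m < 2) {
    out <- tibble::tibble(marker_i = character(), marker_j = character(),
                          theta = double(), lod = double(), n_known = integer(),
                          n_unknown = integer(), r_count = integer())
    attr(out, "excluded_markers") <- excluded
    return(out)
  }
  ut <- which(upper.tri(matrix(0, m, m)))
  ii <- row(matrix(0, m, m))[ut]
  jj <- col(matrix(0, m, m))[ut]

  # phase-known pooled counts via crossproducts over origin indicators
  R_v <- numeric(length(ut)); N_v <- numeric(length(ut))
  grid <- c(0.02, 0.05, 0.10, 0.16, 0.24, 0.33, 0.42)
  acc <- matrix(0, length(ut), length(grid))
  max_n <- max(vapply(mset$trans, nrow, 0L))
  luts <- lapply(grid, function(th) {
    n_i <- rep(0:max_n, each = max_n + 1)
    k_i <- rep(0:max_n, times = max_n + 1)
    val <- ifelse(k_i > n_i, NA_real_,
                  log(0.5 * (th^k_i * (1 - th)^(n_i - k_i) + th^(n_i - k_i) * (1 - th)^k_i)) -
                    n_i * log(0.5))
    matrix(val, max_n + 1, max_n + 1, byrow = TRUE) # [n+1, k+1]
  })
  for (r in seq_len(nrow(mset$parents))) {
    p <- mset$parents$parent_id[r]
    tr <- mset$trans[[p]][, col_idx, drop = FALSE]
    ph <- mset$phase[[p]][col_idx]
    known <- !is.na(ph)
    orig <- tr
    if (any(known)) orig[, known] <- sweep(tr[, known, drop = FALSE], 2, ph[known], `+`) %% 2L
    orig[, !known] <- NA_integer_
    O1 <- (orig == 1L); O1[is.na(O1)] <- FALSE
    O0 <- (orig == 0L); O0[is.na(O0)] <- FALSE
    obs <- O1 + O0
    R_v <- R_v + (crossprod(O1, O0) + crossprod(O0, O1))[ut]
    N_v <- N_v + crossprod(obs, obs)[ut]
    # mixture contribution where relative phase is not resolved
    T1 <- (tr == 1L); T1[is.na(T1)] <- FALSE
    T0 <- (tr == 0L); T0[is.na(T0)] <- FALSE
    tobs <- T1 + T0
    kmat <- crossprod(T1, T0) + crossprod(T0, T1)
    nmat <- crossprod(tobs, tobs)
    kv <- kmat[ut]; nv <- nmat[ut]
    res <- known[ii] & known[jj]
    nv[res] <- 0L; kv[res] <- 0L
    has <- nv > 0L
    if (any(has)) {
      for (gix in seq_along(grid)) {
        acc[has, gix] <- acc[has, gix] + luts[[gix]][cbind(nv[has] + 1L, kv[has] + 1L)]
      }
    }
  }
  known_ll <- vapply(grid, function(th) {
    R_v * log(2 * th) + (N_v - R_v) * log(2 * (1 - th))
  }, numeric(length(ut)))
  lod_grid <- apply((acc + known_ll) / log(10), 1, max)
  lod_grid <- pmax(lod_grid, theta_phase_known(pmin(R_v, floor(N_v / 2)), pmax(N_v, 1))$lod * (N_v > 0))
  cand <- which(lod_grid >= lod_floor)
  if (length(cand) == 0) {
    out <- tibble::tibble(marker_i = character(), marker_j = character(),
                          theta = double(), lod = double(), n_known = integer(),
                          n_unknown = integer(), r_count = integer())
    attr(out, "excluded_markers") <- excluded
    return(out)
  }
  # per-parent mixture counts for the candidate pairs only
  kc <- matrix(0L, nrow(mset$parents), length(cand))
  nc <- matrix(0L, nrow(mset$parents), length(cand))
  for (r in seq_len(nrow(mset$parents))) {
    p <- mset$parents$parent_id[r]
    tr <- mset$trans[[p]][, col_idx, drop = FALSE]
    ph <- mset$phase[[p]][col_idx]
    known <- !is.na(ph)
    ti <- tr[, ii[cand], drop = FALSE]; tj <- tr[, jj[cand], drop = FALSE]
    ok <- !is.na(ti) & !is.na(tj)
    res <- known[ii[cand]] & known[jj[cand]]
    nc[r, ] <- ifelse(res, 0L, colSums(ok))
    kc[r, ] <- ifelse(res, 0L, colSums(ok & ti != tj, na.rm = TRUE))
  }
  n_unk <- colSums(nc)
  est <- vec_maximize_twopoint(R_v[cand], N_v[cand], kc, nc, tol)
  out <- tibble::tibble(
    marker_i = ids[ii[cand]], marker_j = ids[jj[cand]],
    theta = est$theta,
    lod = est$lod,
    n_known = as.integer(N_v[cand]),
    n_unknown = as.integer(n_unk),
    r_count = as.integer(R_v[cand])
  )
  out <- out[out$lod >= lod_floor, ]
  attr(out, "excluded_markers") <- excluded
  out
}
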