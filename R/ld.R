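#' EM haplotype-frequency estimation for a marker pair
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased
#' genotype counts under HWE. All genotype combinations except the double
#' heterozygote resolve to known gametes; the coupling/repulsion split of
#' double heterozygotes is iterated by EM (convergence when the largest
#' frequency change drops below `tol`; the likelihood is unimodal in this
#' one-parameter family so restarts are unnecessary).
#'
#' @param counts 3x3 matrix of genotype counts, rows = marker 1 genotype
#'   (AA, AB, BB), columns = marker 2.
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @return Named numeric: `p_AB`, `p_Ab`, `p_aB`, `p_ab` (upper-case =
#'   allele A at the first locus / allele A at the second), summing to 1,
#'   with the iteration count as attribute `iterations`. Monomorphic
#'   markers give an error.
#' @export
haplotype_freq_em <- function(counts, tol = 1e-8, max_iter = 200) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(3, 3)), sum(counts) >= 1)
  n <- sum(counts)
  p1 <- (2 * sum(counts[1, ]) + sum(counts[2, ])) / (2 * n) # allele A freq, locus 1
  p2 <- (2 * sum(counts[, 1]) + sum(counts[, 2])) / (2 * n)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    stop("monomorphic marker: LD undefined", call. = FALSE)
  }
  # known gamete counts; h holds AB/Ab/aB/ab as locus-A-allele indicators
  base <- c(
    AB = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
    Ab = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    aB = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    ab = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
  )
  dh <- counts[2, 2]
  f <- c(AB = p1 * p2, Ab = p1 * (1 - p2), aB = (1 - p1) * p2, ab = (1 - p1) * (1 - p2))
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    pc <- if (denom > 0) unname(f["AB"] * f["ab"] / denom) else 0.5
    cnt <- base + dh * c(pc, 1 - pc, 1 - pc, pc)
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || it >= max_iter) break
  }
  attr(f, "iterations") <- it
  f
}

#' LD coefficients from haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; `D' = |D| / Dmax` with
#' `Dmax = min(p_A p_b, p_a p_B)` for positive `D` and
#' `min(p_A p_B, p_a p_b)` otherwise; `r2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param freqs Named frequencies as returned by [haplotype_freq_em()].
#' @return One-row tibble: `D`, `D_prime`, `r2`.
#' @examples
#' pair_ld(c(AB = .4, Ab = .1, aB = .1, ab = .4)) # D .15, D' 0.6, r2 0.36
#' @export
pair_ld <- function(freqs) {
  pA <- freqs[["AB"]] + freqs[["Ab"]]
  pB <- freqs[["AB"]] + freqs[["aB"]]
  if (any(c(pA, 1 - pA, pB, 1 - pB) == 0)) {
    stop("allele frequency of 0: LD undefined", call. = FALSE)
  }
  D <- freqs[["AB"]] - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  tibble::tibble(
    D = D,
    D_prime = if (D == 0) 0 else abs(D) / dmax,
    r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB))
  )
}

#' Pairwise LD scan over a dataset
#'
#' Vectorised EM over all (or selected) marker pairs from unphased
#' genotypes. By default all genotyped individuals enter (family structure
#' inflates LD; pass `founders_only = TRUE` to restrict to individuals
#' without genotyped parents).
#'
#' @param dataset A `linkage_dataset`.
#' @param pairs Optional two-column matrix/data frame of marker ids to
#'   restrict to; default all pairs.
#' @param founders_only Restrict to pedigree founders.
#' @param tol,max_iter EM controls.
#' @return Tibble: `marker_i`, `marker_j`, `D`, `D_prime`, `r2`, `n`
#'   (individuals complete for the pair). Monomorphic markers are skipped.
#' @export
ld_scan <- function(dataset, pairs = NULL, founders_only = FALSE,
                    tol = 1e-8, max_iter = 200) {
  g <- dataset$geno
  if (founders_only) {
    ped <- dataset$pedigree
    keep <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
    g <- g[intersect(rownames(g), keep), , drop = FALSE]
  }
  stats <- colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
  poly <- stats > 0 & stats < 1
  g <- g[, poly, drop = FALSE]
  ids <- colnames(g)
  m <- length(ids)
  if (is.null(pairs)) {
    ut <- which(upper.tri(matrix(0, m, m)))
    pi_ <- row(matrix(0, m, m))[ut]; pj_ <- col(matrix(0, m, m))[ut]
  } else {
    pi_ <- match(pairs[[1]], ids); pj_ <- match(pairs[[2]], ids)
    ok <- !is.na(pi_) & !is.na(pj_)
    pi_ <- pi_[ok]; pj_ <- pj_[ok]
  }
  if (length(pi_) == 0) {
    return(tibble::tibble(marker_i = character(), marker_j = character(),
                          D = double(), D_prime = double(), r2 = double(), n = integer()))
  }
  ind <- lapply(0:2, function(k) (!is.na(g) & g == k) * 1)
  cnt <- vector("list", 9)
  dim9 <- 1L
  for (a in 0:2) for (b in 0:2) {
    cnt[[a * 3 + b + 1]] <- crossprod(ind[[a + 1]], ind[[b + 1]])
  }
  getc <- function(a, b) cnt[[a * 3 + b + 1]][cbind(pi_, pj_)]
  n_pair <- Reduce(`+`, lapply(0:8, function(x) cnt[[x + 1]]))[cbind(pi_, pj_)]
  base_AB <- 2 * getc(0, 0) + getc(0, 1) + getc(1, 0)
  base_Ab <- 2 * getc(0, 2) + getc(0, 1) + getc(1, 2)
  base_aB <- 2 * getc(2, 0) + getc(2, 1) + getc(1, 0)
  base_ab <- 2 * getc(2, 2) + getc(2, 1) + getc(1, 2)
  dh <- getc(1, 1)
  tot <- 2 * n_pair
  pA <- (base_AB + base_Ab + dh) / tot
  pB <- (base_AB + base_aB + dh) / tot
  fAB <- pA * pB; fAb <- pA * (1 - pB); faB <- (1 - pA) * pB; fab <- (1 - pA) * (1 - pB)
  for (it in seq_len(max_iter)) {
    denom <- fAB * fab + fAb * faB
    pc <- ifelse(denom > 0, fAB * fab / denom, 0.5)
    nAB <- (base_AB + dh * pc) / tot
    nAb <- (base_Ab + dh * (1 - pc)) / tot
    naB <- (base_aB + dh * (1 - pc)) / tot
    nab <- (base_ab + dh * pc) / tot
    delta <- pmax(abs(nAB - fAB), abs(nAb - fAb), abs(naB - faB), abs(nab - fab))
    fAB <- nAB; fAb <- nAb; faB <- naB; fab <- nab
    if (max(delta) < tol) break
  }
  pA <- fAB + fAb; pB <- fAB + faB
  D <- fAB - pA * pB
  dmax <- ifelse(D > 0, pmin(pA * (1 - pB), (1 - pA) * pB), pmin(pA * pB, (1 - pA) * (1 - pB)))
  valid <- pA > 0 & pA < 1 & pB > 0 & pB < 1 & n_pair > 0
  tibble::tibble(
    marker_i = ids[pi_], marker_j = ids[pj_],
    D = D,
    D_prime = ifelse(D == 0, 0, abs(D) / dmax),
    r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
    n = as.integer(n_pair)
  )[valid, ]
}

ld_bins <- function() {
  tibble::tibble(
    bin = c("0", "0-1", "1-2", "2-5", "5-10", "10-20", "20-50", ">50"),
    lo = c(-1, 0, 1, 2, 5, 10, 20, 50),
    hi = c(0, 1, 2, 5, 10, 20, 50, Inf)
  )
}

#' LD decay over map distance
#'
#' Bins syntenic pairs (both markers on the same linkage group) by
#' sex-average map distance into the bins 0, 0-1, 1-2, 2-5, 5-10, 10-20,
#' 20-50 and > 50 cM (bin "0" holds pairs mapped to identical positions;
#' the others are left-exclusive), and summarises non-syntenic pairs
#' separately as a decile histogram of the LD estimates. Pairs involving
#' unmapped markers are excluded from the syntenic bins but retained in
#' the overall summary.
#'
#' @param ld A [ld_scan()] tibble.
#' @param map A `pearl_map` providing `lg` and `cm_sexavg` per marker.
#' @return List: `decay` (per-bin `n`, mean/SD/median of `r2` and
#'   `D_prime`), `nonsyntenic` (decile histogram tibble), `overall`
#'   (one-row summary of all pairs).
#' @export
decay_table <- function(ld, map) {
  pos <- setNames(map$cm_sexavg, map$marker_id)
  grp <- setNames(map$lg, map$marker_id)
  li <- grp[ld$marker_i]; lj <- grp[ld$marker_j]
  mapped <- !is.na(li) & !is.na(lj)
  syn <- mapped & li == lj
  dist <- abs(pos[ld$marker_i] - pos[ld$marker_j])
  bins <- ld_bins()
  decay <- purrr::map_dfr(seq_len(nrow(bins)), function(b) {
    sel <- if (bins$bin[b] == "0") syn & dist == 0 else
      syn & dist > bins$lo[b] & dist <= bins$hi[b]
    tibble::tibble(
      bin = bins$bin[b], n = sum(sel),
      r2_mean = mean(ld$r2[sel]), r2_sd = sd(ld$r2[sel]),
      r2_median = median(ld$r2[sel]),
      dprime_mean = mean(ld$D_prime[sel]), dprime_sd = sd(ld$D_prime[sel]),
      dprime_median = median(ld$D_prime[sel])
    )
  })
  decile_hist <- function(x) {
    brk <- c(-1e-12, seq(0.1, 0.9, by = 0.1), 1 + 1e-12)
    lab <- c("0-0.1", "0.1-0.2", "0.2-0.3", "0.3-0.4", "0.4-0.5",
             "0.5-0.6", "0.6-0.7", "0.7-0.8", "0.8-0.9", "0.9-1")
    tibble::tibble(
      range = c("0", lab),
      n = c(sum(x == 0), as.vector(table(cut(x[x > 0], brk, labels = lab))))
    )
  }
  ns <- ld[mapped & !syn, ]
  nonsyn <- dplyr::full_join(
    decile_hist(ns$r2) |> dplyr::rename(n_r2 = "n"),
    decile_hist(ns$D_prime) |> dplyr::rename(n_dprime = "n"),
    by = "range"
  )
  overall <- tibble::tibble(
    n_pairs = nrow(ld), n_syntenic = sum(syn), n_nonsyntenic = sum(mapped & !syn),
    r2_mean_nonsyntenic = mean(ns$r2), dprime_mean_nonsyntenic = mean(ns$D_prime)
  )
  list(decay = decay, nonsyntenic = nonsyn, overall = overall)
}
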