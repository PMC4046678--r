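#' Per-marker allele statistics
#'
#' Minor allele frequency (over non-missing calls) and call rate for every
#' marker of a dataset, or for a single genotype column.
#'
#' @param dataset A `linkage_dataset`, or an integer vector of 0/1/2/NA
#'   calls for a single marker.
#' @return Tibble with `marker_id`, `maf`, `call_rate`.
#' @export
allele_stats <- function(dataset) {
  g <- if (inherits(dataset, "linkage_dataset")) dataset$geno else
    matrix(dataset, ncol = 1, dimnames = list(NULL, "marker"))
  n_obs <- colSums(!is.na(g))
  if (any(n_obs == 0)) {
    stop("all-missing genotype column: ", colnames(g)[n_obs == 0][1], call. = FALSE)
  }
  p_b <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  tibble::tibble(
    marker_id = colnames(g),
    maf = unname(pmin(p_b, 1 - p_b)),
    call_rate = unname(n_obs / nrow(g))
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' The exact conditional test: given the observed allele counts, the
#' p-value is the probability mass of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Monomorphic markers return 1. Vectorised over markers.
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @return p-value(s).
#' @examples
#' hwe_exact_test(1, 0, 1) # 1/3
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  mapply(function(naa, nab, nbb) {
    n <- naa + nab + nbb
    stopifnot(n >= 1, naa >= 0, nab >= 0, nbb >= 0)
    n_a <- 2 * naa + nab
    n_b <- 2 * nbb + nab
    minor <- min(n_a, n_b)
    if (minor == 0) return(1)
    hets <- seq(minor %% 2, minor, by = 2)
    # log conditional probability of each heterozygote count given allele counts
    logp <- lfactorial(n) - lfactorial((n_a - hets) / 2) - lfactorial(hets) -
      lfactorial((n_b - hets) / 2) + hets * log(2) +
      lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    sum(p[p <= p[match(nab, hets)] * (1 + 1e-12)])
  }, n_aa, n_ab, n_bb)
}

# Allowed offspring genotype sets for each ordered parent genotype pair.
# Index by parent genotypes 0/1/2; NA parent genotype is non-constraining.
mendel_allowed <- local({
  allowed <- array(FALSE, dim = c(3, 3, 3))
  gametes <- list(`0` = 0, `1` = c(0, 1), `2` = 1) # allele-B dose transmitted
  for (p1 in 0:2) for (p2 in 0:2) {
    kids <- unique(outer(gametes[[p1 + 1]], gametes[[p2 + 1]], `+`))
    allowed[p1 + 1, p2 + 1, kids + 1] <- TRUE
  }
  allowed
})

#' Mendelian-inheritance check
#'
#' Flags every (offspring, marker) genotype that is impossible given the
#' two parental genotypes; a missing parent genotype places no constraint.
#'
#' @param dataset A `linkage_dataset`.
#' @return List with `conflicts` (tibble `id`, `marker_id`, plus the trio
#'   genotypes), `per_marker` and `per_individual` count tibbles.
#' @export
mendelian_check <- function(dataset) {
  ped <- dataset$pedigree
  g <- dataset$geno
  kids <- ped[!is.na(ped$sire) & !is.na(ped$dam) &
                ped$id %in% rownames(g) &
                ped$sire %in% rownames(g) & ped$dam %in% rownames(g), ]
  conflicts <- NULL
  if (nrow(kids) > 0) {
    go <- g[kids$id, , drop = FALSE]
    gs <- g[kids$sire, , drop = FALSE]
    gd <- g[kids$dam, , drop = FALSE]
    ok <- is.na(go) | is.na(gs) | is.na(gd)
    idx <- !ok
    bad <- idx & !mendel_allowed[cbind(as.vector(gs) + 1, as.vector(gd) + 1, as.vector(go) + 1)]
    bad[is.na(bad)] <- FALSE
    w <- which(matrix(bad, nrow(go), ncol(go)), arr.ind = TRUE)
    conflicts <- tibble::tibble(
      id = kids$id[w[, 1]],
      marker_id = colnames(g)[w[, 2]],
      offspring = go[w], sire = gs[w], dam = gd[w]
    )
  } else {
    conflicts <- tibble::tibble(id = character(), marker_id = character(),
                                offspring = integer(), sire = integer(), dam = integer())
  }
  per_marker <- tibble::tibble(marker_id = colnames(g)) |>
    dplyr::left_join(dplyr::count(conflicts, .data$marker_id, name = "n_mendel_errors"),
                     by = "marker_id") |>
    dplyr::mutate(n_mendel_errors = dplyr::coalesce(.data$n_mendel_errors, 0L))
  per_individual <- dplyr::count(conflicts, .data$id, name = "n_mendel_errors")
  list(conflicts = conflicts, per_marker = per_marker, per_individual = per_individual)
}

#' Detect duplicated markers
#'
#' Flags marker pairs whose genotype concordance over individuals
#' non-missing in both is at least `threshold`; the later marker (file
#' order) is flagged as a duplicate of the earlier.
#'
#' @param dataset A `linkage_dataset`.
#' @param threshold Concordance threshold (default 0.99).
#' @param min_shared Minimum shared non-missing calls for a comparison
#'   (default 20).
#' @return Tibble `marker_i`, `marker_j`, `concordance`, `n_shared` with
#'   `marker_j` the flagged duplicate.
#' @export
duplicate_marker_detect <- function(dataset, threshold = 0.99, min_shared = 20) {
  g <- dataset$geno
  m <- ncol(g)
  ind <- array(0, dim = c(nrow(g), m, 3))
  for (k in 0:2) ind[, , k + 1] <- (!is.na(g) & g == k) * 1
  shared <- crossprod(!is.na(g) * 1)
  agree <- crossprod(ind[, , 1]) + crossprod(ind[, , 2]) + crossprod(ind[, , 3])
  conc <- agree / shared
  hit <- which(upper.tri(conc) & conc >= threshold & shared >= min_shared, arr.ind = TRUE)
  tibble::tibble(
    marker_i = colnames(g)[hit[, 1]],
    marker_j = colnames(g)[hit[, 2]],
    concordance = conc[hit],
    n_shared = shared[hit]
  )
}

#' QC threshold configuration
#'
#' Defaults reflect the published inclusion rules: MAF > 0.01, call rate
#' > 0.90, Mendelian consistency and no duplicated clustering patterns; the
#' HWE cut-off was never published and defaults to 1e-3, computed on
#' pedigree founders by default since descendant genotypes are
#' non-independent under the family structure.
#'
#' @param maf_min,cr_min,hwe_min,dup_threshold Thresholds.
#' @param hwe_scope `"founders"` (default: individuals without genotyped
#'   parents, the only HWE-independent draws) or `"founders_f1"` (adds the
#'   F1 generation for power, at the cost of sib-cluster correlation).
#' @param max_mendel Markers with more conflicts than this are excluded
#'   (default 0); with `mendel_to_missing = TRUE` conflicting offspring
#'   calls are first set to missing (mirroring correction of erroneous
#'   calls) and only markers still in conflict are excluded.
#' @param mendel_to_missing Logical (default TRUE).
#' @return A list of thresholds.
#' @export
qc_config <- function(maf_min = 0.01, cr_min = 0.90, hwe_min = 1e-3,
                      dup_threshold = 0.99, max_mendel = 0,
                      mendel_to_missing = TRUE,
                      hwe_scope = c("founders", "founders_f1")) {
  list(maf_min = maf_min, cr_min = cr_min, hwe_min = hwe_min,
       dup_threshold = dup_threshold, max_mendel = max_mendel,
       mendel_to_missing = mendel_to_missing,
       hwe_scope = match.arg(hwe_scope))
}

#' Apply marker-level data-integrity filters
#'
#' Retains markers passing all configured rules and reports per-marker
#' diagnostics. The filter is idempotent: re-filtering the filtered
#' dataset removes nothing.
#'
#' @param dataset A `linkage_dataset`.
#' @param config See [qc_config()].
#' @return List with `dataset` (filtered) and `report` (tibble of
#'   `marker_id`, `maf`, `call_rate`, `hwe_p`, `n_mendel_errors`,
#'   `duplicate_of`, `pass`, `reason`).
#' @export
apply_qc <- function(dataset, config = qc_config()) {
  stats <- allele_stats(dataset)
  ped <- dataset$pedigree
  founders <- if (identical(config$hwe_scope, "founders_f1")) {
    ped$id[ped$generation %in% c("F0", "F1")]
  } else {
    ped$id[is.na(ped$sire) & is.na(ped$dam)]
  }
  gf <- dataset$geno[intersect(rownames(dataset$geno), founders), , drop = FALSE]
  hwe_p <- hwe_exact_test(colSums(gf == 0, na.rm = TRUE),
                          colSums(gf == 1, na.rm = TRUE),
                          colSums(gf == 2, na.rm = TRUE))
  mend <- mendelian_check(dataset)
  if (config$mendel_to_missing && nrow(mend$conflicts) > 0) {
    dataset$geno[cbind(match(mend$conflicts$id, rownames(dataset$geno)),
                       match(mend$conflicts$marker_id, colnames(dataset$geno)))] <- NA_integer_
    mend_after <- mendelian_check(dataset)
  } else {
    mend_after <- mend
  }
  dup <- duplicate_marker_detect(dataset, config$dup_threshold)
  report <- stats |>
    dplyr::mutate(
      hwe_p = hwe_p,
      n_mendel_errors = mend$per_marker$n_mendel_errors,
      duplicate_of = dup$marker_i[match(.data$marker_id, dup$marker_j)],
      unresolved_mendel = mend_after$per_marker$n_mendel_errors
    ) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$maf <= config$maf_min ~ "low_maf",
        .data$call_rate <= config$cr_min ~ "low_call_rate",
        .data$hwe_p < config$hwe_min ~ "hwe",
        .data$unresolved_mendel > config$max_mendel ~ "mendel",
        !is.na(.data$duplicate_of) ~ "duplicate",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$reason)
    ) |>
    dplyr::select(-"unresolved_mendel")
  keep <- report$marker_id[report$pass]
  filtered <- dataset
  filtered$geno <- dataset$geno[, keep, drop = FALSE]
  filtered$markers <- dataset$markers[match(keep, dataset$markers$marker_id), ]
  list(dataset = filtered, report = report)
}
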