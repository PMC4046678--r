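# Transmission coding: for each (parent, offspring, marker) where the
# parent is heterozygous and its contribution is deducible from the mate
# and offspring genotypes, `trans` holds the B-dose the parent transmitted
# (0 = allele A, 1 = allele B); NA elsewhere. `phase` holds, per parent
# and marker, which allele sits on the sire-side haplotype (0 = A, 1 = B)
# when the parent's own genotyped parents force it, so that the
# grandparental origin of a transmission is origin = (trans + phase) mod 2.

# Deducible parental contribution for het parent; gm/gc are mate/child
# genotype matrices (B-dose 0/1/2, NA missing).
deduce_trans <- function(gp, gm, gc) {
  t <- matrix(NA_integer_, nrow(gc), ncol(gc))
  het <- !is.na(gp) & gp == 1L
  # homozygous child: parent's contribution is forced (and mate-checked)
  mate_ok0 <- is.na(gm) | gm != 2L # mate can contribute A
  mate_ok1 <- is.na(gm) | gm != 0L # mate can contribute B
  t[het & !is.na(gc) & gc == 0L & mate_ok0] <- 0L
  t[het & !is.na(gc) & gc == 2L & mate_ok1] <- 1L
  # het child: deducible only when the mate is homozygous
  t[het & !is.na(gc) & gc == 1L & !is.na(gm) & gm == 0L] <- 1L
  t[het & !is.na(gc) & gc == 1L & !is.na(gm) & gm == 2L] <- 0L
  t
}

# Phase (sire-side allele B-dose) for het parents from grandparental
# genotypes: unique iff exactly one of the assignments (A from sire,
# B from dam) / (B from sire, A from dam) is compatible.
deduce_phase <- function(gp, gs, gd) {
  can_give <- function(g, allele) is.na(g) | (allele == 0L & g != 2L) | (allele == 1L & g != 0L)
  het <- !is.na(gp) & gp == 1L
  asn1 <- can_give(gs, 0L) & can_give(gd, 1L) # A on sire side
  asn2 <- can_give(gs, 1L) & can_give(gd, 0L) # B on sire side
  phase <- rep(NA_integer_, length(gp))
  phase[het & asn1 & !asn2] <- 0L
  phase[het & asn2 & !asn1] <- 1L
  phase
}

#' Extract informative meioses from a dataset
#'
#' Builds the per-parent transmission and phase structures behind all
#' linkage computations: one transmission per (parent, offspring, marker)
#' where the parent is heterozygous and its contribution is deducible, and
#' a per-marker phase (which allele lies on the sire-side haplotype) where
#' the parent's own genotyped parents force it. A transmission is
#' phase-known at a marker exactly when that phase is resolved.
#'
#' @param dataset A `linkage_dataset`.
#' @return An object of class `meiosis_set`: `parents` tibble
#'   (`parent_id`, `sex`, `family`, `n_offspring`), `trans` and `phase`
#'   lists keyed by parent, `marker_ids`, and `marker_info` tibble
#'   (`marker_id`, `n_inf_known`, `n_inf_unknown`).
#' @export
meiosis_set <- function(dataset) {
  ped <- dataset$pedigree
  g <- dataset$geno
  kids <- ped[ped$id %in% rownames(g) & (!is.na(ped$sire) | !is.na(ped$dam)), ]
  roles <- dplyr::bind_rows(
    tibble::tibble(parent = kids$sire, mate = kids$dam, child = kids$id, sex = "male"),
    tibble::tibble(parent = kids$dam, mate = kids$sire, child = kids$id, sex = "female")
  )
  roles <- roles[!is.na(roles$parent) & roles$parent %in% rownames(g), ]
  parents <- unique(roles[, c("parent", "sex")])
  trans <- list(); phase <- list()
  for (r in seq_len(nrow(parents))) {
    p <- parents$parent[r]
    sub <- roles[roles$parent == p & roles$sex == parents$sex[r], ]
    gp <- matrix(g[p, ], nrow(sub), ncol(g), byrow = TRUE)
    gm <- matrix(NA_integer_, nrow(sub), ncol(g))
    has_mate <- !is.na(sub$mate) & sub$mate %in% rownames(g)
    if (any(has_mate)) gm[has_mate, ] <- g[sub$mate[has_mate], , drop = FALSE]
    gc <- g[sub$child, , drop = FALSE]
    tr <- deduce_trans(gp, gm, gc)
    dimnames(tr) <- list(sub$child, colnames(g))
    trans[[p]] <- tr
    i <- match(p, ped$id)
    gs <- if (!is.na(ped$sire[i]) && ped$sire[i] %in% rownames(g)) g[ped$sire[i], ] else rep(NA_integer_, ncol(g))
    gd <- if (!is.na(ped$dam[i]) && ped$dam[i] %in% rownames(g)) g[ped$dam[i], ] else rep(NA_integer_, ncol(g))
    phase[[p]] <- deduce_phase(g[p, ], gs, gd)
  }
  n_known <- rep(0L, ncol(g)); n_unknown <- rep(0L, ncol(g))
  for (p in names(trans)) {
    obs <- colSums(!is.na(trans[[p]]))
    known <- !is.na(phase[[p]])
    n_known <- n_known + ifelse(known, obs, 0L)
    n_unknown <- n_unknown + ifelse(known, 0L, obs)
  }
  parent_tbl <- tibble::tibble(
    parent_id = parents$parent,
    sex = parents$sex,
    family = ped$family[match(parents$parent, ped$id)],
    n_offspring = vapply(trans[parents$parent], nrow, 0L)
  )
  # order-independent caches for the likelihood kernels: reference-phase
  # origins (true origins at resolved columns, raw transmissions under an
  # arbitrary reference flip elsewhere), the gamete-row -> parent map and
  # the per-parent resolved-column indicator
  ref <- do.call(rbind, lapply(parents$parent, function(p) {
    tr <- trans[[p]]
    ph <- phase[[p]]
    known <- !is.na(ph)
    o <- tr
    if (any(known)) {
      o[, known] <- sweep(tr[, known, drop = FALSE], 2,
                          ph[known], `+`) %% 2L
    }
    o
  }))
  row_parent <- rep(seq_len(nrow(parents)),
                    vapply(trans[parents$parent], nrow, 0L))
  resolved_cols <- do.call(rbind, lapply(parents$parent,
                                         function(p) !is.na(phase[[p]])))
  resolved <- ref
  for (r in seq_len(nrow(parents))) {
    rows <- which(row_parent == r)
    resolved[rows, !resolved_cols[r, ]] <- NA_integer_
  }
  structure(list(
    parents = parent_tbl, trans = trans, phase = phase,
    marker_ids = colnames(g),
    marker_info = tibble::tibble(marker_id = colnames(g),
                                 n_inf_known = n_known, n_inf_unknown = n_unknown),
    ref_origins = ref, row_parent = row_parent, resolved_cols = resolved_cols,
    resolved_origins = resolved
  ), class = "meiosis_set")
}

#' @export
print.meiosis_set <- function(x, ...) {
  cat("<meiosis_set> ", nrow(x$parents), " informative parents, ",
      length(x$marker_ids), " markers; per-marker informative meioses: ",
      "phase-known median ", median(x$marker_info$n_inf_known),
      ", phase-unknown median ", median(x$marker_info$n_inf_unknown), "\n", sep = "")
  invisible(x)
}

#' Enumerate informative meioses as records
#'
#' Materialises one row per informative (parent, offspring, marker)
#' transmission, with the transmitted allele and whether the grandparental
#' phase is resolved at that marker.
#'
#' @param dataset A `linkage_dataset` or a prebuilt [meiosis_set()].
#' @return Tibble: `parent_id`, `parent_sex`, `offspring_id`, `marker_id`,
#'   `transmitted` ("allele_a"/"allele_b"), `phase_known`.
#' @export
enumerate_meioses <- function(dataset) {
  ms <- if (inherits(dataset, "meiosis_set")) dataset else meiosis_set(dataset)
  purrr::map_dfr(ms$parents$parent_id, function(p) {
    tr <- ms$trans[[p]]
    w <- which(!is.na(tr), arr.ind = TRUE)
    if (nrow(w) == 0) return(NULL)
    tibble::tibble(
      parent_id = p,
      parent_sex = ms$parents$sex[match(p, ms$parents$parent_id)],
      offspring_id = rownames(tr)[w[, 1]],
      marker_id = colnames(tr)[w[, 2]],
      transmitted = c("allele_a", "allele_b")[tr[w] + 1L],
      phase_known = !is.na(ms$phase[[p]][w[, 2]])
    )
  })
}

#' Per-parent transmission counts for distortion testing
#'
#' @param mset A [meiosis_set()].
#' @return Tibble: `marker_id`, `parent_id`, `family`, `sex`, `n_a`, `n_b`.
#' @export
transmission_counts <- function(mset) {
  purrr::map_dfr(seq_len(nrow(mset$parents)), function(r) {
    p <- mset$parents$parent_id[r]
    tr <- mset$trans[[p]]
    tibble::tibble(
      marker_id = colnames(tr),
      parent_id = p,
      family = mset$parents$family[r],
      sex = mset$parents$sex[r],
      n_a = colSums(tr == 0L, na.rm = TRUE),
      n_b = colSums(tr == 1L, na.rm = TRUE)
    )
  }) |>
    dplyr::filter(.data$n_a + .data$n_b > 0)
}
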