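# R-side wrappers around the C++ multipoint kernel plus an exact
# phase-enumeration evaluator for small scopes.

mp_args <- function(mset) {
  ord <- mset$parents$parent_id
  list(
    trans = unname(mset$trans[ord]),
    phase = unname(mset$phase[ord]),
    sex_code = ifelse(mset$parents$sex == "female", 0L, 1L)
  )
}

sex_int <- function(sex) switch(sex, both = -1L, female = 0L, male = 1L)

sex_rows <- function(mset, sex) {
  if (sex == "both") return(seq_along(mset$row_parent))
  which(mset$parents$sex[mset$row_parent] == sex)
}

# Profiled (EM) multipoint log10-likelihood for a marker order: pooled
# phase-resolved spans plus per-parent phase-mixture span classes (see
# the kernel notes in src/multipoint.cpp). Returns list(loglik10, thetas,
# cover).
profile_order <- function(mset, order, sex = "both", thetas = NULL,
                          tol = 1e-4, maxit = 200) {
  ord0 <- match(order, mset$marker_ids) - 1L
  if (anyNA(ord0)) stop("order contains unknown marker(s): ",
                        paste(order[is.na(ord0)], collapse = ", "), call. = FALSE)
  .mp_fit(mset$ref_origins, mset$row_parent, mset$resolved_cols,
          sex_rows(mset, sex), ord0,
          if (is.null(thetas)) numeric(0) else thetas, tol, maxit)
}

# Likelihood used for order comparisons (insertions, window permutations,
# exhaustive searches): the full profiled kernel. Candidate positions are
# restricted to the neighbourhood of a marker's strongest two-point
# partners during construction (see eval_insert), because the phase-
# mixture terms alone cannot veto a long-range misplacement: a junction
# between two distant blocks lets every parent re-fit its flip bit there.
score_order <- function(mset, order, tol = 1e-4) {
  profile_order(mset, order, tol = tol)$loglik10
}

# Anchored grandparental-origin matrix for all gametes along an order.
anchored_origins <- function(mset, order, resolved_only = FALSE) {
  ord0 <- match(order, mset$marker_ids) - 1L
  if (anyNA(ord0)) stop("order contains unknown marker(s)", call. = FALSE)
  a <- mp_args(mset)
  og <- .mp_origins(a$trans, a$phase, ord0, resolved_only)
  rownames(og$origins) <- unlist(lapply(a$trans, rownames), use.names = FALSE)
  og$parent_id <- mset$parents$parent_id[og$parent]
  og$sex <- mset$parents$sex[og$parent]
  og$family <- mset$parents$family[og$parent]
  og
}

# Natural-log likelihood of one origin matrix given interval thetas,
# summing over consecutive observed marker pairs per gamete (Markov model:
# unobserved markers marginalise out into composed span fractions).
span_ll_matrix <- function(O, thetas) {
  m <- ncol(O)
  if (m < 2 || nrow(O) == 0) return(0)
  cumq <- c(1, cumprod(pmax(1 - 2 * pmin(thetas, 0.49999), 1e-12)))
  tO <- t(O)
  obs <- which(!is.na(tO))
  if (length(obs) < 2) return(0)
  gam <- (obs - 1L) %/% m
  keep <- gam[-1] == gam[-length(gam)]
  if (!any(keep)) return(0)
  i1 <- obs[-length(obs)][keep]; i2 <- obs[-1][keep]
  j1 <- (i1 - 1L) %% m + 1L; j2 <- (i2 - 1L) %% m + 1L
  rec <- tO[i1] != tO[i2]
  r <- pmin(pmax(0.5 * (1 - cumq[j2] / cumq[j1]), 1e-12), 0.5)
  sum(log(ifelse(rec, r, 1 - r)))
}

# Greedy anchored phases for one parent in R (mirrors the C++ rule).
anchor_parent_r <- function(trc, ph) {
  no <- nrow(trc); m <- ncol(trc)
  O <- matrix(NA_integer_, no, m)
  for (t in seq_len(m)) {
    col <- trc[, t]
    if (all(is.na(col))) next
    if (!is.na(ph[t])) { O[, t] <- (col + ph[t]) %% 2L; next }
    flip <- 0L
    for (tp in rev(seq_len(t - 1))) {
      ok <- !is.na(col) & !is.na(O[, tp])
      if (any(ok)) {
        flip <- as.integer(2 * sum(col[ok] != O[ok, tp]) > sum(ok))
        break
      }
    }
    O[, t] <- (col + flip) %% 2L
  }
  O
}

#' Multipoint log-likelihood of a marker order
#'
#' Log10 likelihood of all transmissions under a no-interference Markov
#' model along the given order. With `thetas = NULL` the interval
#' recombination fractions are profiled at their MLEs (EM) using
#' deterministically anchored phases for parents whose grandparental phase
#' is unresolved. With `thetas` supplied the likelihood is evaluated
#' exactly: parents with at most `phase_cap` unresolved heterozygous
#' markers in the scope are summed over all their phase assignments;
#' parents beyond the cap use the anchored assignment (a documented
#' approximation that coincides with the exact sum as offspring counts
#' grow).
#'
#' @param mset A [meiosis_set()].
#' @param order Character vector of marker ids.
#' @param thetas Optional interval fractions (length `length(order) - 1`).
#' @param sex `"both"`, `"female"` (dams only) or `"male"`.
#' @param phase_cap Exact phase-enumeration cap per parent (default 12).
#' @return The log10 likelihood; when profiling, the fitted `thetas` are
#'   attached as an attribute.
#' @export
multipoint_loglik <- function(mset, order, thetas = NULL, sex = "both",
                              phase_cap = 12) {
  if (is.null(thetas)) {
    prof <- profile_order(mset, order, sex = sex)
    out <- prof$loglik10
    attr(out, "thetas") <- prof$thetas
    return(out)
  }
  ord <- match(order, mset$marker_ids)
  if (anyNA(ord)) stop("order contains unknown marker(s)", call. = FALSE)
  stopifnot(length(thetas) == length(order) - 1)
  rows <- seq_len(nrow(mset$parents))
  if (sex != "both") rows <- rows[mset$parents$sex == sex]
  total <- 0
  for (r in rows) {
    p <- mset$parents$parent_id[r]
    trc <- mset$trans[[p]][, ord, drop = FALSE]
    ph <- mset$phase[[p]][ord]
    informative <- colSums(!is.na(trc)) > 0
    unres <- informative & is.na(ph)
    h <- sum(unres)
    if (h == 0 || h > phase_cap) {
      total <- total + span_ll_matrix(anchor_parent_r(trc, ph), thetas)
    } else {
      O <- matrix(NA_integer_, nrow(trc), ncol(trc))
      res <- informative & !is.na(ph)
      if (any(res)) O[, res] <- sweep(trc[, res, drop = FALSE], 2, ph[res], `+`) %% 2L
      u_idx <- which(unres)
      lls <- vapply(seq_len(2^h) - 1L, function(code) {
        phi <- as.integer(intToBits(code)[seq_len(h)])
        O[, u_idx] <- sweep(trc[, u_idx, drop = FALSE], 2, phi, `+`) %% 2L
        span_ll_matrix(O, thetas)
      }, 0)
      mx <- max(lls)
      total <- total + mx + log(mean(exp(lls - mx)))
    }
  }
  total / log(10)
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", factorial(n))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, ifelse(s >= i, s + 1L, s))
    }
  }
  out
}

# One full FLIPS pass over raw marker orders: every window of `window`
# consecutive markers is permuted exhaustively and the best order adopted;
# sweeps repeat until none improves the likelihood.
flips_order <- function(mset, order, window = 5, tol = 1e-4, eps = 1e-6) {
  m <- length(order)
  w <- min(window, m)
  if (w < 2) return(order)
  perms <- all_perms(w)
  perms <- perms[!vapply(perms, function(p) all(p == seq_len(w)), TRUE)]
  cur_ll <- score_order(mset, order, tol)
  repeat {
    improved <- FALSE
    for (s in seq_len(m - w + 1)) {
      idx <- s:(s + w - 1)
      lls <- vapply(perms, function(p) {
        cand <- order
        cand[idx] <- order[idx][p]
        score_order(mset, cand, tol)
      }, 0)
      best <- which.max(lls)
      if (lls[best] > cur_ll + eps) {
        order[idx] <- order[idx][perms[[best]]]
        cur_ll <- lls[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  order
}

# Likelihood of inserting `cand` into `order`; returns the best slot, the
# placement LOD gap (best minus second best) and the best ll. When a lod
# lookup for the candidate is supplied, only slots flanking its strongest
# linked partners are evaluated - linkage localises the marker, and
# evaluating remote slots would let the phase-mixture likelihood reward
# spurious long-range joins.
eval_insert <- function(mset, order, cand, tol = 1e-4, partner_lods = NULL,
                        n_partners = 2, flank = 1, link_min = 3) {
  slots <- seq_len(length(order) + 1)
  if (!is.null(partner_lods)) {
    pl <- partner_lods[order]
    pl[is.na(pl)] <- 0
    top <- order(-pl)[seq_len(min(n_partners, length(pl)))]
    top <- top[pl[top] >= link_min]
    if (length(top) == 0) return(NULL) # no decisively linked anchor placed
    slots <- sort(unique(unlist(lapply(top, function(p)
      max(1, p - flank):min(length(order) + 1, p + flank + 1)))))
  }
  lls <- vapply(slots, function(s) {
    score_order(mset, append(order, cand, after = s - 1), tol)
  }, 0)
  srt <- sort(lls, decreasing = TRUE)
  list(pos = slots[which.max(lls)],
       delta = if (length(lls) > 1) srt[1] - srt[2] else Inf,
       ll = srt[1], lls = lls)
}

# symmetric lod lookup built from a two-point scan
pair_lod_lookup <- function(pairs, markers) {
  lk <- lapply(setNames(markers, markers), function(mk) {
    sub <- pairs[pairs$marker_i == mk | pairs$marker_j == mk, ]
    other <- ifelse(sub$marker_i == mk, sub$marker_j, sub$marker_i)
    setNames(sub$lod, other)
  })
  lk
}

# Distance-matrix seriation: classical multidimensional scaling of the
# pairwise Kosambi distances (linked pairs only; unlinked pairs get a
# ceiling) onto one axis. The resulting order is globally consistent -
# no reversed or translocated arms - with only local noise, which the
# likelihood refinement then removes.
seriation_order <- function(markers, pairs, lod_min = 3, cap_cm = 45) {
  m <- length(markers)
  D <- matrix(cap_cm, m, m, dimnames = list(markers, markers))
  diag(D) <- 0
  sub <- pairs[pairs$marker_i %in% markers & pairs$marker_j %in% markers &
                 pairs$lod >= lod_min, ]
  if (nrow(sub) > 0) {
    d <- pmin(kosambi_cm(pmin(sub$theta, 0.45)), cap_cm)
    D[cbind(sub$marker_i, sub$marker_j)] <- d
    D[cbind(sub$marker_j, sub$marker_i)] <- d
  }
  ax <- tryCatch(cmdscale(as.dist(D), k = 1), error = function(e) NULL)
  if (is.null(ax) || nrow(ax) < m) return(markers)
  rownames(ax)[order(ax[, 1])]
}

# Junction repair: a freshly grown arm can come out reversed relative to
# the rest of the map (the window refinement cannot reverse a long
# segment). At every interval whose fitted fraction looks junction-like,
# try reversing the prefix or the suffix and keep any improvement.
repair_junctions <- function(mset, order, tol = 1e-4, theta_cut = 0.15) {
  m <- length(order)
  if (m < 4) return(order)
  repeat {
    pr <- profile_order(mset, order, tol = tol)
    jx <- which(pr$thetas > theta_cut)
    improved <- FALSE
    cur <- score_order(mset, order, tol)
    for (j in jx) {
      for (cand in list(c(rev(order[1:j]), order[(j + 1):m]),
                        c(order[1:j], rev(order[(j + 1):m])))) {
        s <- score_order(mset, cand, tol)
        if (s > cur + 1e-6) {
          order <- cand
          cur <- s
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  order
}

# single-marker re-insertion sweeps: pulls markers displaced beyond the
# window's reach back to their best slot; likelihood never decreases
polish_order <- function(mset, order, lods = NULL, tol = 1e-4, max_sweeps = 4) {
  for (s in seq_len(max_sweeps)) {
    improved <- FALSE
    cur <- score_order(mset, order, tol)
    for (mk in order) {
      reduced <- setdiff(order, mk)
      ev <- eval_insert(mset, reduced, mk, tol,
                        partner_lods = if (is.null(lods)) NULL else lods[[mk]])
      if (is.null(ev)) next
      if (ev$ll > cur + 1e-6) {
        order <- append(reduced, mk, after = ev$pos - 1)
        cur <- ev$ll
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  order
}

finalize_map <- function(mset, order, tiers, lg, tol = 1e-4) {
  prof <- profile_order(mset, order, tol = tol)
  th <- pmin(prof$thetas, 0.49999)
  pos <- c(0, cumsum(kosambi_cm(th)))
  info <- mset$marker_info
  i <- match(order, info$marker_id)
  out <- tibble::tibble(
    lg = lg, rank = seq_along(order), marker_id = order,
    tier = unname(tiers[order]),
    cm_sexavg = pos, cm_female = NA_real_, cm_male = NA_real_,
    n_inf_known = info$n_inf_known[i], n_inf_unknown = info$n_inf_unknown[i]
  )
  class(out) <- c("pearl_map", class(out))
  attr(out, "thetas") <- prof$thetas
  attr(out, "loglik10") <- prof$loglik10
  out
}

#' Build an ordered map for one linkage group
#'
#' Hierarchical likelihood ordering: starting from the two most
#' informative framework (haplogroup-primary) markers, candidates are
#' inserted in descending order of phase-known informative meioses. A
#' candidate is fixed in a pass with threshold T (3, 2, then 1) only if
#' its best insertion position beats the second-best by at least T LOD;
#' remaining markers are finally placed at their single most likely
#' position (tier BEST) provided that position is unambiguous (gap to the
#' runner-up at least `best_min`); markers without a unique position are
#' left unplaced (attribute `unplaced`), mirroring the grouped-but-
#' unmapped class of low-information markers. Non-primary haplogroup
#' members enter from the LOD2 pass onward. After every pass the order is
#' refined with a moving five-marker permutation window
#' ([flips_refine()]).
#'
#' @param mset A [meiosis_set()].
#' @param markers Marker ids of the group.
#' @param haplogroups Optional [find_haplogroups()] tibble for the group;
#'   when absent (or when fewer than two primaries exist) all group
#'   markers are framework candidates.
#' @param lg Integer label for the group.
#' @param tier_lods Placement thresholds for the hierarchical passes.
#' @param window FLIPS window size.
#' @param tol EM profiling tolerance (log10 units).
#' @param best_min Minimum LOD gap between the best and second-best
#'   position for a tier-BEST placement (default 0.5).
#' @param pairs Optional [two_point_scan()] tibble; when given, candidate
#'   slots are restricted to the neighbourhood of each marker's strongest
#'   linked partners.
#' @return A single-LG `pearl_map` tibble (sex-average positions; see
#'   [sex_specific_positions()] for the sex maps), with profiling
#'   attributes and a `build_log` attribute recording every placement.
#' @export
build_map <- function(mset, markers, haplogroups = NULL, lg = 1L,
                      tier_lods = c(3, 2, 1), window = 5, tol = 1e-4,
                      best_min = 0.5, pairs = NULL) {
  markers <- unique(markers)
  info <- mset$marker_info
  known <- setNames(info$n_inf_known, info$marker_id)
  tot <- setNames(info$n_inf_known + info$n_inf_unknown, info$marker_id)
  by_info <- function(ids) ids[order(-known[ids], -tot[ids], ids)]
  tiers <- setNames(rep(NA_character_, length(markers)), markers)
  if (length(markers) == 1) {
    tiers[markers] <- "LOD3"
    return(finalize_map(mset, markers, tiers, lg, tol))
  }
  primaries <- if (!is.null(haplogroups)) {
    intersect(markers, haplogroups$marker_id[haplogroups$primary])
  } else markers
  if (length(primaries) < 2) primaries <- markers
  lods <- if (!is.null(pairs)) pair_lod_lookup(pairs, markers) else NULL
  # skeleton: seriation when pairwise estimates are available, refined by
  # window permutations and re-insertion sweeps before tiers are assigned
  order <- if (!is.null(pairs) && length(markers) > 3) {
    seriation_order(markers, pairs)
  } else {
    by_info(markers)
  }
  order <- flips_order(mset, order, window, tol)
  order <- polish_order(mset, order, lods, tol)
  order <- repair_junctions(mset, order, tol)
  # hierarchical placement support: each marker, most informative first,
  # is removed and re-inserted; the LOD gap between its best and
  # second-best position sets its tier (3/2/1, then BEST), and markers
  # without a unique position are left unmapped
  log_rows <- list()
  unplaced <- character()
  for (cand in by_info(order)) {
    if (length(order) <= 2) {
      tiers[cand] <- "LOD3"
      next
    }
    reduced <- setdiff(order, cand)
    ev <- eval_insert(mset, reduced, cand, tol,
                      partner_lods = if (is.null(lods)) NULL else lods[[cand]])
    if (is.null(ev)) {
      unplaced <- c(unplaced, cand)
      order <- reduced
      next
    }
    gap <- ev$delta
    tier <- if (gap >= tier_lods[1]) "LOD3" else if (gap >= tier_lods[2]) "LOD2"
      else if (gap >= tier_lods[3]) "LOD1" else if (gap >= best_min) "BEST" else NA
    if (is.na(tier)) {
      unplaced <- c(unplaced, cand)
      order <- reduced
      next
    }
    tiers[cand] <- tier
    order <- append(reduced, cand, after = ev$pos - 1)
    log_rows[[length(log_rows) + 1]] <- tibble::tibble(
      marker_id = cand, tier = tier, delta_lod = gap)
  }
  order <- repair_junctions(mset, order, tol)
  order <- polish_order(mset, order, lods, tol)
  # small groups admit a full permutation search (window >= group size)
  final_window <- if (length(order) <= 7) length(order) else window
  order <- flips_order(mset, order, final_window, tol)
  out <- finalize_map(mset, order, tiers, lg, tol)
  attr(out, "build_log") <- dplyr::bind_rows(log_rows)
  attr(out, "unplaced") <- unplaced
  out
}

#' Refine marker order with a moving permutation window
#'
#' Every window of `window` consecutive markers is permuted exhaustively
#' and the best-likelihood order adopted; full sweeps repeat until a sweep
#' changes nothing (the likelihood strictly increases, so this
#' terminates). A window at least as large as the group is a single
#' exhaustive permutation search.
#'
#' @param map A single-LG `pearl_map`.
#' @param mset The [meiosis_set()] it was built from.
#' @param window Window size (default 5).
#' @param tol Profiling tolerance.
#' @return The refined `pearl_map` (sex-average positions recomputed; sex
#'   positions are cleared if the order changed).
#' @export
flips_refine <- function(map, mset, window = 5, tol = 1e-4) {
  stopifnot(length(unique(map$lg)) == 1)
  order <- map$marker_id
  new_order <- flips_order(mset, order, window, tol)
  tiers <- setNames(map$tier, map$marker_id)
  out <- finalize_map(mset, new_order, tiers, map$lg[1], tol)
  if (identical(new_order, order)) {
    out$cm_female <- map$cm_female
    out$cm_male <- map$cm_male
  }
  out
}

# Singleton origin switches (possible false double recombinants): one
# row per flagged (gamete, marker), plus per-marker counts of observed
# singletons, of consecutive-observed triples centred on the marker, and
# the expected singleton count under the fitted interval fractions.
origin_singletons <- function(og, order, thetas = NULL) {
  O <- og$origins
  m <- ncol(O)
  tO <- t(O)
  obs <- which(!is.na(tO))
  gam <- (obs - 1L) %/% m
  n_triples <- rep(0, m); e_single <- rep(0, m)
  if (length(obs) >= 3) {
    i <- seq_len(length(obs) - 2)
    same <- gam[i] == gam[i + 2]
    v0 <- tO[obs[i]]; v1 <- tO[obs[i + 1]]; v2 <- tO[obs[i + 2]]
    hit <- same & v0 == v2 & v1 != v0
    w <- which(hit)
    flags <- tibble::tibble(
      row = gam[w] + 1L,
      pos = (obs[w + 1] - 1L) %% m + 1L
    )
    centre <- (obs[i + 1][same] - 1L) %% m + 1L
    n_triples <- tabulate(centre, nbins = m)
    if (!is.null(thetas) && m >= 3) {
      cumq <- c(1, cumprod(pmax(1 - 2 * pmin(thetas, 0.49999), 1e-12)))
      p1 <- (obs[i][same] - 1L) %% m + 1L
      p3 <- (obs[i + 2][same] - 1L) %% m + 1L
      thl <- 0.5 * (1 - cumq[centre] / cumq[p1])
      thr <- 0.5 * (1 - cumq[p3] / cumq[centre])
      e_single <- as.vector(tapply(thl * thr, factor(centre, levels = seq_len(m)), sum))
      e_single[is.na(e_single)] <- 0
    }
  } else {
    flags <- tibble::tibble(row = integer(), pos = integer())
  }
  out <- tibble::tibble(
    parent_id = og$parent_id[flags$row],
    offspring_id = rownames(og$origins)[flags$row],
    marker_id = order[flags$pos]
  )
  attr(out, "per_marker") <- tibble::tibble(
    marker_id = order,
    n_singletons = tabulate(flags$pos, nbins = m),
    n_triples = n_triples,
    expected = e_single
  )
  out
}

#' Double-recombinant audit of an ordered map
#'
#' Reconstructs each phase-resolvable gamete's grandparental-origin string
#' along the map order and flags every marker that is a singleton origin
#' switch (opposite origin on both flanking observed markers of the same
#' gamete) - the classic signature of a genotyping error or a misplaced
#' marker. Genuine double recombinants occur at a rate set by the flanking
#' interval fractions, so a marker is re-tested only when its singleton
#' count exceeds a Poisson upper bound on that expectation (with floor
#' `min_flags`); re-tested markers are re-inserted at their most likely
#' position and dropped if the excess singletons persist, after which the
#' order is re-refined.
#'
#' @param map A single-LG `pearl_map`.
#' @param mset The [meiosis_set()].
#' @param min_flags Floor on the re-test threshold (default 2).
#' @param window,tol Passed to the refinement.
#' @param pairs Optional [two_point_scan()] tibble for partner-pruned
#'   re-insertion.
#' @return List: `map` (audited), `flags` (tibble of flagged
#'   parent/offspring/marker), `dropped` (tibble `marker_id`, `reason`).
#' @export
chrompic_audit <- function(map, mset, min_flags = 2, window = 5, tol = 1e-4,
                           pairs = NULL) {
  stopifnot(length(unique(map$lg)) == 1)
  order <- map$marker_id
  tiers <- setNames(map$tier, map$marker_id)
  lods <- if (!is.null(pairs)) pair_lod_lookup(pairs, order) else NULL
  thetas <- attr(map, "thetas")
  if (is.null(thetas)) thetas <- profile_order(mset, order, tol = tol)$thetas
  og <- anchored_origins(mset, order)
  flags <- origin_singletons(og, order, thetas)
  pm <- attr(flags, "per_marker")
  # a marker is suspect when its singleton count exceeds a Poisson upper
  # bound on the genuine double-recombinant count implied by the map
  limit <- pmax(min_flags, stats::qpois(0.995, pm$expected) + 1L)
  suspects <- pm$marker_id[pm$n_singletons >= limit]
  counts <- setNames(pm$n_singletons, pm$marker_id)
  dropped <- character()
  for (mk in suspects[order(-counts[suspects])]) {
    if (length(order) <= 3) break
    reduced <- setdiff(order, mk)
    ev <- eval_insert(mset, reduced, mk, tol,
                      partner_lods = if (is.null(lods)) NULL else lods[[mk]])
    if (is.null(ev)) next
    cand_order <- append(reduced, mk, after = ev$pos - 1)
    prof2 <- profile_order(mset, cand_order, tol = tol)
    og2 <- anchored_origins(mset, cand_order)
    flags2 <- origin_singletons(og2, cand_order, prof2$thetas)
    pm2 <- attr(flags2, "per_marker")
    r2 <- pm2[pm2$marker_id == mk, ]
    if (r2$n_singletons >= max(min_flags, stats::qpois(0.995, r2$expected) + 1L)) {
      order <- reduced
      dropped <- c(dropped, mk)
    } else {
      order <- cand_order
    }
  }
  if (length(dropped) > 0) order <- flips_order(mset, order, window, tol)
  out <- finalize_map(mset, order, tiers, map$lg[1], tol)
  list(
    map = out,
    flags = flags,
    per_marker = pm,
    dropped = tibble::tibble(marker_id = dropped,
                             reason = rep("unresolved_double_recombinant", length(dropped)))
  )
}

#' Sex-specific map positions at a fixed order
#'
#' Recomputes interval recombination fractions separately from dam and
#' sire meioses at the fixed sex-average order (no re-ordering) and
#' accumulates Kosambi positions per sex; the sex-average positions are
#' also refreshed. Intervals with no informative meioses for a sex - or
#' fewer than `min_cover`, where a fraction estimate is meaningless - get
#' distance 0 and are recorded in the `uncovered` attribute.
#'
#' @param map A `pearl_map` (one or more linkage groups).
#' @param mset The [meiosis_set()].
#' @param tol Profiling tolerance.
#' @param min_cover Minimum per-sex informative meioses for an interval.
#' @return The map with `cm_female` and `cm_male` filled.
#' @export
sex_specific_positions <- function(map, mset, tol = 1e-4, min_cover = 8) {
  uncovered <- list()
  out <- map |>
    dplyr::group_by(.data$lg) |>
    dplyr::group_modify(function(d, key) {
      ord <- d$marker_id
      if (length(ord) == 1) {
        d$cm_sexavg <- 0; d$cm_female <- 0; d$cm_male <- 0
        return(d)
      }
      pa <- profile_order(mset, ord, sex = "both", tol = tol)
      pf <- profile_order(mset, ord, sex = "female", tol = tol)
      pm <- profile_order(mset, ord, sex = "male", tol = tol)
      for (sx in c("female", "male")) {
        pr <- if (sx == "female") pf else pm
        if (any(pr$cover < min_cover)) {
          uncovered[[length(uncovered) + 1]] <<- tibble::tibble(
            lg = key$lg, interval = which(pr$cover < min_cover), sex = sx)
        }
      }
      thf <- ifelse(pf$cover >= min_cover, pf$thetas, 0)
      thm <- ifelse(pm$cover >= min_cover, pm$thetas, 0)
      d$cm_sexavg <- c(0, cumsum(kosambi_cm(pmin(pa$thetas, 0.49999))))
      d$cm_female <- c(0, cumsum(kosambi_cm(pmin(thf, 0.49999))))
      d$cm_male <- c(0, cumsum(kosambi_cm(pmin(thm, 0.49999))))
      d
    }) |>
    dplyr::ungroup()
  class(out) <- c("pearl_map", class(out))
  attr(out, "uncovered") <- dplyr::bind_rows(uncovered)
  out
}

#' Integer per-sex recombination counts for adjacent map intervals
#'
#' Counts recombinant and co-informative phase-resolved (known plus
#' anchored) meioses per adjacent interval, split by parent sex; the
#' integer counts feed the binomial-kernel heterogeneity tests.
#'
#' @param map A `pearl_map`.
#' @param mset The [meiosis_set()].
#' @return Tibble: `lg`, `interval`, `marker_left`, `marker_right`,
#'   `R_f`, `N_f`, `R_m`, `N_m`.
#' @export
interval_sex_counts <- function(map, mset) {
  purrr::map_dfr(unique(map$lg), function(g) {
    ord <- map$marker_id[map$lg == g]
    if (length(ord) < 2) return(NULL)
    og <- anchored_origins(mset, ord)
    O <- og$origins
    A <- O[, -ncol(O), drop = FALSE]; B <- O[, -1, drop = FALSE]
    both <- !is.na(A) & !is.na(B)
    mism <- both & (A != B)
    fem <- og$sex == "female"
    tibble::tibble(
      lg = g, interval = seq_len(ncol(O) - 1),
      marker_left = ord[-length(ord)], marker_right = ord[-1],
      R_f = colSums(mism[fem, , drop = FALSE]),
      N_f = colSums(both[fem, , drop = FALSE]),
      R_m = colSums(mism[!fem, , drop = FALSE]),
      N_m = colSums(both[!fem, , drop = FALSE])
    )
  })
}

#' Per-family recombination counts for adjacent map intervals
#'
#' @param map A `pearl_map`.
#' @param mset The [meiosis_set()].
#' @param sex Restrict to dams/sires, or `"both"`.
#' @return Tibble: `lg`, `interval`, `family`, `R`, `N`.
#' @export
interval_family_counts <- function(map, mset, sex = "both") {
  purrr::map_dfr(unique(map$lg), function(g) {
    ord <- map$marker_id[map$lg == g]
    if (length(ord) < 2) return(NULL)
    og <- anchored_origins(mset, ord)
    keep <- if (sex == "both") rep(TRUE, length(og$sex)) else og$sex == sex
    O <- og$origins[keep, , drop = FALSE]
    fam <- og$family[keep]
    A <- O[, -ncol(O), drop = FALSE]; B <- O[, -1, drop = FALSE]
    both <- !is.na(A) & !is.na(B)
    mism <- both & (A != B)
    purrr::map_dfr(unique(fam), function(f) {
      tibble::tibble(
        lg = g, interval = seq_len(ncol(O) - 1), family = f,
        R = colSums(mism[fam == f, , drop = FALSE]),
        N = colSums(both[fam == f, , drop = FALSE])
      )
    })
  })
}
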