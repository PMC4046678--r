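#' Simulation configuration for the mapping-family design
#'
#' Defaults emulate the study design the package targets: 14 linkage
#' groups of 48-76 cM; eight families (six three-generation phase-known
#' and two two-generation phase-unknown) built from 14 F0 founders, 118
#' genotyped F1 and 219 F2 offspring with 14-99 offspring per family and
#' consecutive families sharing a grandparental couple; a female:male
#' total map-length ratio of 1.15 with male recombination suppressed
#' around the centromere and inflated towards the telomeres (the female
#' map warped oppositely); call rate above 99% (missing rate 0.006) and
#' founder minor allele frequencies well above 0.01.
#'
#' @param seed Integer seed; every output is reproducible from it.
#' @param n_lg Number of linkage groups.
#' @param markers_per_lg Markers per group (default 83, giving a study-like
#'   1,162-marker panel).
#' @param lg_length_range Sex-average group length range, cM.
#' @param n_f2 Offspring per family; must have `n_families` entries.
#' @param n_f1_extra Genotyped F1 sibs per founder couple in addition to
#'   the mapping parents (default fills the design to 118 F1).
#' @param n_families Total families; the last `n_unknown_families` are
#'   two-generation (parents of unknown ancestry, hence phase-unknown).
#' @param n_unknown_families Number of two-generation families.
#' @param fm_ratio Female:male total map-length ratio.
#' @param centromere Centromere position per group as a fraction of group
#'   length; recycled. Default 0.5 with mild per-group jitter.
#' @param warp_strength Strength of the sex-specific warp in `[0, 1)`;
#'   0 gives identical female/male/sex-average positions.
#' @param missing_rate Per-call missingness probability.
#' @param error_rate Per-call genotyping error (random allele flip).
#' @param distortion Optional tibble `marker` (index into the panel),
#'   `genotype` (0/1/2) and `s` (viability selection coefficient):
#'   offspring carrying that genotype are rejected and redrawn with
#'   probability `s`.
#' @param maf_range Founder allele-frequency range for the minor allele.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_lg = 14L,
                       markers_per_lg = 83L,
                       lg_length_range = c(48, 76),
                       n_f2 = c(99L, 26L, 20L, 18L, 14L, 14L, 14L, 14L),
                       n_f1_extra = NULL,
                       n_families = 8L,
                       n_unknown_families = 2L,
                       fm_ratio = 1.15,
                       centromere = NULL,
                       warp_strength = 0.6,
                       missing_rate = 0.006,
                       error_rate = 0,
                       distortion = NULL,
                       maf_range = c(0.2, 0.5)) {
  stopifnot(length(n_f2) == n_families, all(n_f2 >= 1),
            warp_strength >= 0, warp_strength < 1,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1, fm_ratio > 0)
  structure(list(
    seed = as.integer(seed), n_lg = as.integer(n_lg),
    markers_per_lg = as.integer(markers_per_lg),
    lg_length_range = lg_length_range, n_f2 = as.integer(n_f2),
    n_f1_extra = n_f1_extra, n_families = as.integer(n_families),
    n_unknown_families = as.integer(n_unknown_families),
    fm_ratio = fm_ratio, centromere = centromere,
    warp_strength = warp_strength, missing_rate = missing_rate,
    error_rate = error_rate, distortion = distortion, maf_range = maf_range
  ), class = "sim_config")
}

# Monotone [0,1] -> [0,1] warps. The male warp has near-zero slope at the
# centromere (cubic plateau); the female warp has its steepest slope there.
warp_male <- function(u, c, w) {
  base <- ((u - c)^3 + c^3) / ((1 - c)^3 + c^3)
  (1 - w) * u + w * base
}
warp_female <- function(u, c, w, k = 6) {
  base <- (atan(k * (u - c)) + atan(k * c)) / (atan(k * (1 - c)) + atan(k * c))
  (1 - w) * u + w * base
}

#' Simulate a ground-truth map
#'
#' Draws per-group sex-average marker positions (uniform jitter with fixed
#' ends) and derives female and male positions by strictly monotone warps
#' around the centromere, scaled so that the total female:male length
#' ratio equals the configured value exactly.
#'
#' @param config A [sim_config()].
#' @return Tibble (class `truth_map`): `lg`, `marker_id`, `cm_sexavg`,
#'   `cm_female`, `cm_male`, `centromere`.
#' @export
simulate_truth_map <- function(config) {
  set.seed(config$seed)
  n_lg <- config$n_lg
  m <- config$markers_per_lg
  lens <- runif(n_lg, config$lg_length_range[1], config$lg_length_range[2])
  centro <- if (is.null(config$centromere)) runif(n_lg, 0.38, 0.62) else
    rep_len(config$centromere, n_lg)
  ratio <- config$fm_ratio
  purrr::map_dfr(seq_len(n_lg), function(g) {
    # jittered even grid: dense maps have near-regular spacing, and short
    # intervals keep the no-interference crossover process close to the
    # Kosambi scale used downstream
    u <- if (m == 1) 0.5 else {
      grid <- seq(0, 1, length.out = m)
      jit <- c(0, runif(max(m - 2, 0), -0.4, 0.4) / (m - 1), 0)
      sort(pmin(pmax(grid + jit, 0), 1))
    }
    if (m > 1) u <- (u + seq(0, 1e-6 * (m - 1), length.out = m)) / (1 + 1e-6 * (m - 1))
    L <- lens[g]
    L_m <- 2 * L / (1 + ratio)
    L_f <- ratio * L_m
    w <- config$warp_strength
    fem <- L_f * warp_female(u, centro[g], w)
    mal <- L_m * warp_male(u, centro[g], w)
    tibble::tibble(
      lg = g,
      marker_id = sprintf("M%02d_%03d", g, seq_len(m)),
      cm_sexavg = (fem + mal) / 2,
      cm_female = fem,
      cm_male = mal,
      centromere = centro[g]
    )
  }) |>
    structure(class = c("truth_map", class(tibble::tibble())))
}

# One gamete per call: no-interference crossover process on the parent's
# sex-specific map. pos: marker positions (cM) per LG list; returns a
# logical matrix (n_gametes x n_markers) of haplotype origins.
sim_gamete_origins <- function(pos_list, n) {
  do.call(cbind, lapply(pos_list, function(pos) {
    L <- max(pos) - min(pos)
    start <- matrix(rbinom(n, 1, 0.5), n, 1)
    n_xo <- rpois(n, L / 100)
    orig <- matrix(0L, n, length(pos))
    for (i in seq_len(n)) {
      if (n_xo[i] == 0) { orig[i, ] <- start[i]; next }
      xo <- sort(runif(n_xo[i], min(pos), max(pos)))
      orig[i, ] <- (start[i] + findInterval(pos, xo, left.open = TRUE)) %% 2L
    }
    orig
  }))
}

#' Simulate pedigree genotypes from a truth map
#'
#' Founders are drawn in Hardy-Weinberg proportions at configured allele
#' frequencies; every meiosis generates a gamete by a Poisson
#' (no-interference) crossover process on the transmitting parent's
#' sex-specific map; offspring genotypes are composed from the transmitted
#' haplotypes. Missingness, genotyping error (allele flips) and optional
#' post-zygotic viability distortion are applied afterwards. The full
#' gamete origin strings and founder phases are retained as attributes for
#' audits.
#'
#' @param truth A [simulate_truth_map()] result.
#' @param config The same [sim_config()].
#' @return A [linkage_dataset()] with attributes `truth` (the truth map)
#'   and `origins` (list of per-parent gamete origin matrices).
#' @export
simulate_pedigree_genotypes <- function(truth, config) {
  set.seed(config$seed + 1L)
  m_total <- nrow(truth)
  lgs <- split(seq_len(m_total), truth$lg)
  pos_f <- lapply(lgs, function(i) truth$cm_female[i])
  pos_m <- lapply(lgs, function(i) truth$cm_male[i])
  freqs <- runif(m_total, config$maf_range[1], config$maf_range[2])

  n_fam <- config$n_families
  n_known <- n_fam - config$n_unknown_families
  n_couples <- n_known + 1L

  draw_founder_haps <- function(n) {
    # two haplotypes per founder; entries are allele-B indicators
    lapply(seq_len(n), function(i)
      rbind(rbinom(m_total, 1, freqs), rbinom(m_total, 1, freqs)))
  }

  new_gamete <- function(haps, sex) {
    pos <- if (sex == "female") pos_f else pos_m
    orig <- sim_gamete_origins(pos, 1)[1, ]
    list(allele = ifelse(orig == 0L, haps[1, ], haps[2, ]), origin = orig)
  }

  ped_rows <- list(); hap_store <- list(); origin_store <- list()
  add_ind <- function(fam, id, sire, dam, sex, haps) {
    ped_rows[[length(ped_rows) + 1]] <<- tibble::tibble(
      family = fam, id = id, sire = sire, dam = dam, sex = sex)
    hap_store[[id]] <<- haps
  }
  record_origin <- function(parent, child, origin) {
    origin_store[[parent]] <<- rbind(origin_store[[parent]], origin)
    rownames(origin_store[[parent]])[nrow(origin_store[[parent]])] <<- child
  }
  breed <- function(fam, sire_id, dam_id, child_id, child_sex) {
    gs <- new_gamete(hap_store[[sire_id]], "male")
    gd <- new_gamete(hap_store[[dam_id]], "female")
    add_ind(fam, child_id, sire_id, dam_id, child_sex,
            rbind(gs$allele, gd$allele))
    record_origin(sire_id, child_id, gs$origin)
    record_origin(dam_id, child_id, gd$origin)
  }

  # F0 couples; couple i supplies F1 sibs, shared between consecutive families
  f0_haps <- draw_founder_haps(2 * n_couples)
  for (cp in seq_len(n_couples)) {
    add_ind("founders", sprintf("F0_%02dM", cp), NA_character_, NA_character_, "male", f0_haps[[2 * cp - 1]])
    add_ind("founders", sprintf("F0_%02dF", cp), NA_character_, NA_character_, "female", f0_haps[[2 * cp]])
  }
  n_f1_target <- if (is.null(config$n_f1_extra)) 118L - 2L * config$n_unknown_families else NA
  f1_per_couple <- if (is.null(config$n_f1_extra)) {
    base <- n_f1_target %/% n_couples
    extra <- n_f1_target %% n_couples
    rep(base, n_couples) + c(rep(1L, extra), rep(0L, n_couples - extra))
  } else rep(config$n_f1_extra + 2L, n_couples)
  f1_ids <- vector("list", n_couples)
  for (cp in seq_len(n_couples)) {
    ids <- sprintf("F1_%02d_%02d", cp, seq_len(f1_per_couple[cp]))
    for (k in seq_along(ids)) {
      breed("founders", sprintf("F0_%02dM", cp), sprintf("F0_%02dF", cp), ids[k], "unknown")
    }
    f1_ids[[cp]] <- ids
  }

  # three-generation families: sire from couple i, dam from couple i+1
  fam_names <- sprintf("FAM%02d", seq_len(n_fam))
  for (i in seq_len(n_known)) {
    sire <- f1_ids[[i]][1]
    dam <- f1_ids[[i + 1]][2]
    rowi <- which(vapply(ped_rows, function(r) r$id == sire, TRUE))
    ped_rows[[rowi]]$sex <- "male"; ped_rows[[rowi]]$family <- fam_names[i]
    rowd <- which(vapply(ped_rows, function(r) r$id == dam, TRUE))
    ped_rows[[rowd]]$sex <- "female"; ped_rows[[rowd]]$family <- fam_names[i]
    for (k in seq_len(config$n_f2[i])) {
      breed(fam_names[i], sire, dam, sprintf("F2_%02d_%03d", i, k), "unknown")
    }
  }
  # two-generation families: parents of unknown ancestry (phase unknown)
  unk_haps <- draw_founder_haps(2 * config$n_unknown_families)
  for (j in seq_len(config$n_unknown_families)) {
    i <- n_known + j
    sire <- sprintf("U%02dM", j); dam <- sprintf("U%02dF", j)
    add_ind(fam_names[i], sire, NA_character_, NA_character_, "male", unk_haps[[2 * j - 1]])
    add_ind(fam_names[i], dam, NA_character_, NA_character_, "female", unk_haps[[2 * j]])
    for (k in seq_len(config$n_f2[i])) {
      breed(fam_names[i], sire, dam, sprintf("F2_%02d_%03d", i, k), "unknown")
    }
  }

  ped <- dplyr::bind_rows(ped_rows)
  geno <- t(vapply(ped$id, function(id) as.integer(colSums(hap_store[[id]])), integer(m_total)))
  dimnames(geno) <- list(ped$id, truth$marker_id)

  # post-zygotic viability distortion: reject and redraw carriers
  if (!is.null(config$distortion) && nrow(config$distortion) > 0) {
    for (r in seq_len(nrow(config$distortion))) {
      loc <- config$distortion$marker[r]
      gt <- config$distortion$genotype[r]
      s <- config$distortion$s[r]
      kids <- ped$id[!is.na(ped$sire) & grepl("^F2_", ped$id)]
      for (id in kids) {
        i <- match(id, ped$id)
        while (geno[id, loc] == gt && runif(1) < s) {
          gs <- new_gamete(hap_store[[ped$sire[i]]], "male")
          gd <- new_gamete(hap_store[[ped$dam[i]]], "female")
          hap_store[[id]] <- rbind(gs$allele, gd$allele)
          geno[id, ] <- colSums(hap_store[[id]])
          origin_store[[ped$sire[i]]][id, ] <- gs$origin
          origin_store[[ped$dam[i]]][id, ] <- gd$origin
        }
      }
    }
  }

  # genotyping error: random allele flip, then missingness
  if (config$error_rate > 0) {
    flip <- matrix(runif(length(geno)) < config$error_rate, nrow(geno))
    hom_shift <- matrix(sample(c(-1L, 1L), length(geno), replace = TRUE), nrow(geno))
    new_g <- geno
    new_g[flip & geno == 1L] <- ifelse(hom_shift[flip & geno == 1L] > 0, 2L, 0L)
    new_g[flip & geno == 0L] <- 1L
    new_g[flip & geno == 2L] <- 1L
    attr(new_g, "errors") <- which(flip & new_g != geno, arr.ind = TRUE)
    geno2 <- new_g
  } else {
    geno2 <- geno
    attr(geno2, "errors") <- NULL
  }
  err <- attr(geno2, "errors")
  if (config$missing_rate > 0) {
    geno2[matrix(runif(length(geno2)) < config$missing_rate, nrow(geno2))] <- NA_integer_
  }

  markers <- tibble::tibble(marker_id = truth$marker_id, allele_a = "A", allele_b = "B",
                            source_contig = NA_character_, gene_label = NA_character_)
  ds <- linkage_dataset(ped, markers, geno2)
  attr(ds, "truth") <- truth
  attr(ds, "origins") <- origin_store
  attr(ds, "injected_errors") <- err
  attr(ds, "config") <- config
  ds
}

#' Simulate a complete dataset in one call
#'
#' @param config A [sim_config()].
#' @return A `linkage_dataset` with truth attributes (see
#'   [simulate_pedigree_genotypes()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  simulate_pedigree_genotypes(simulate_truth_map(config), config)
}

#' Write a simulated dataset and its ground truth to files
#'
#' Emits the PED/MAP pair and pedigree TSV via the package readers'
#' dialect, a truth TSV (marker, linkage group, true sex-average / female /
#' male positions) and a JSON echo of the configuration.
#'
#' @param dataset A simulated `linkage_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
emit_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    ped = file.path(dir, "genotypes.ped"),
    map = file.path(dir, "markers.map"),
    pedigree = file.path(dir, "pedigree.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  write_ped_map(dataset, paths["ped"], paths["map"])
  write_pedigree(dataset$pedigree, paths["pedigree"])
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) readr::write_tsv(truth, paths["truth"], progress = FALSE)
  cfg <- attr(dataset, "config")
  if (!is.null(cfg)) jsonlite::write_json(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                                          paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
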