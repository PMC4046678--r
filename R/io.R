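# Genotype calls are stored as an integer matrix (individuals x markers):
# 0 = AA, 1 = AB, 2 = BB, NA = missing, with allele A/B defined per marker
# by the marker table. Heterozygotes are order-insensitive on input.

norm_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("F", "2", "FEMALE") ~ "female",
    x %in% c("M", "1", "MALE") ~ "male",
    x %in% c("U", "0", "UNKNOWN", "", ".", NA) ~ "unknown",
    TRUE ~ NA_character_
  )
}

norm_parent <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("0", ".", "", "NA")] <- NA_character_
  x
}

# Generation from parent depth, capped at F2.
infer_generations <- function(ped) {
  depth <- setNames(rep(NA_integer_, nrow(ped)), ped$id)
  get_depth <- function(id, seen = character()) {
    if (!is.na(depth[[id]])) return(depth[[id]])
    if (id %in% seen) stop("pedigree cycle involving individual '", id, "'", call. = FALSE)
    i <- match(id, ped$id)
    parents <- c(ped$sire[i], ped$dam[i])
    parents <- parents[!is.na(parents)]
    d <- if (length(parents) == 0) 0L else 1L + max(vapply(parents, get_depth, 0L, seen = c(seen, id)))
    depth[[id]] <<- d
    d
  }
  for (id in ped$id) get_depth(id)
  paste0("F", pmin(depth[ped$id], 2L))
}

validate_pedigree <- function(ped) {
  stopifnot(all(c("family", "id", "sire", "dam", "sex") %in% names(ped)))
  if (anyDuplicated(ped$id)) {
    stop("duplicated individual id(s): ", paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "), call. = FALSE)
  }
  for (col in c("sire", "dam")) {
    bad <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("row ", i, " (individual '", ped$id[i], "'): ", col, " '", ped[[col]][i],
           "' does not resolve to a pedigree individual", call. = FALSE)
    }
  }
  ped$generation <- infer_generations(ped)
  ped
}

#' Read a pedigree file
#'
#' Whitespace- or tab-delimited file with columns family, id, sire, dam,
#' sex (in that order; a header line is detected and skipped). `0` or `.`
#' marks an unknown parent; sexes `1/2/M/F/U/0` are normalised to
#' female/male/unknown. Generations (F0/F1/F2) are inferred from parent
#' depth. Unresolved parent ids and ancestry cycles are structural errors.
#'
#' @param path File path.
#' @return A validated pedigree tibble with columns `family`, `id`,
#'   `sire`, `dam`, `sex`, `generation`.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family", "id", "sire", "dam", "sex"),
                           comment.char = "#")
  if (nrow(raw) > 0 && tolower(raw$id[1]) == "id") raw <- raw[-1, , drop = FALSE]
  ped <- tibble::tibble(
    family = raw$family, id = raw$id,
    sire = norm_parent(raw$sire), dam = norm_parent(raw$dam),
    sex = norm_sex(raw$sex)
  )
  if (anyNA(ped$sex)) stop("unrecognised sex code in pedigree", call. = FALSE)
  validate_pedigree(ped)
}

#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  out$sex <- c(female = "F", male = "M", unknown = "U")[out$sex]
  utils::write.table(out[, c("family", "id", "sire", "dam", "sex")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a linkage dataset
#'
#' Bundles a validated pedigree, a marker table and a genotype matrix into
#' the container the rest of the pipeline consumes.
#'
#' @param pedigree Pedigree tibble (see [read_pedigree()]).
#' @param markers Tibble with columns `marker_id`, `allele_a`, `allele_b`
#'   and optionally `source_contig`, `gene_label`.
#' @param geno Integer matrix individuals x markers with entries
#'   0 (AA), 1 (AB), 2 (BB) or NA; dimnames must name pedigree individuals
#'   and marker ids.
#' @return An object of class `linkage_dataset`.
#' @export
linkage_dataset <- function(pedigree, markers, geno) {
  pedigree <- validate_pedigree(pedigree)
  stopifnot(is.matrix(geno), all(c("marker_id", "allele_a", "allele_b") %in% names(markers)))
  if (anyDuplicated(markers$marker_id)) stop("duplicated marker ids", call. = FALSE)
  if (any(markers$allele_a == markers$allele_b)) stop("marker with identical alleles", call. = FALSE)
  if (!all(rownames(geno) %in% pedigree$id)) {
    stop("genotype rows not in pedigree: ",
         paste(head(setdiff(rownames(geno), pedigree$id), 3), collapse = ", "), call. = FALSE)
  }
  if (!identical(colnames(geno), markers$marker_id)) {
    stop("genotype columns must match the marker table order", call. = FALSE)
  }
  if (!all(geno %in% c(0L, 1L, 2L, NA))) stop("genotype calls outside {0,1,2,NA}", call. = FALSE)
  if (!("source_contig" %in% names(markers))) markers$source_contig <- NA_character_
  if (!("gene_label" %in% names(markers))) markers$gene_label <- NA_character_
  structure(list(pedigree = pedigree, markers = tibble::as_tibble(markers), geno = geno),
            class = "linkage_dataset")
}

#' @export
print.linkage_dataset <- function(x, ...) {
  cat("<linkage_dataset> ", nrow(x$geno), " genotyped individuals (",
      nrow(x$pedigree), " in pedigree), ", ncol(x$geno), " markers, ",
      dplyr::n_distinct(x$pedigree$family), " families\n", sep = "")
  invisible(x)
}

#' Long-format genotype calls
#'
#' @param dataset A `linkage_dataset`.
#' @return Tibble with `id`, `marker_id`, `call` in {AA, AB, BB, NA}.
#' @export
genotypes_tbl <- function(dataset) {
  g <- dataset$geno
  tibble::tibble(
    id = rep(rownames(g), times = ncol(g)),
    marker_id = rep(colnames(g), each = nrow(g)),
    call = c("AA", "AB", "BB")[as.vector(g) + 1L]
  )
}

#' Read PED/MAP genotype files
#'
#' The MAP file has one marker per line: `marker_id [allele_a allele_b]
#' [...]`; further columns are ignored on input (alleles default to the
#' sorted symbols observed in the PED file when absent). The PED file has
#' columns family, id, sire, dam, sex followed by two allele columns per
#' marker, with `0 0` denoting a missing call. Calls are normalised to
#' AA/AB/BB relative to the marker's allele order; heterozygote order is
#' ignored.
#'
#' @param ped_path,map_path File paths.
#' @return A [linkage_dataset()].
#' @export
read_genotypes <- function(ped_path, map_path) {
  map_lines <- strsplit(trimws(readLines(map_path)), "\\s+")
  map_lines <- map_lines[vapply(map_lines, function(x) length(x) > 0 && nzchar(x[1]), TRUE)]
  markers <- tibble::tibble(
    marker_id = vapply(map_lines, `[`, "", 1),
    allele_a = vapply(map_lines, function(x) if (length(x) >= 3) x[2] else NA_character_, ""),
    allele_b = vapply(map_lines, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
  )
  rows <- strsplit(trimws(readLines(ped_path)), "\\s+")
  rows <- rows[vapply(rows, length, 0L) > 0]
  want <- 5 + 2 * nrow(markers)
  lens <- vapply(rows, length, 0L)
  if (any(lens != want)) {
    stop("ragged PED row ", which(lens != want)[1], ": expected ", want,
         " fields, found ", lens[lens != want][1], call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  ped <- tibble::tibble(
    family = mat[, 1], id = mat[, 2],
    sire = norm_parent(mat[, 3]), dam = norm_parent(mat[, 4]),
    sex = norm_sex(mat[, 5])
  )
  a1 <- mat[, 5 + 2 * seq_len(nrow(markers)) - 1, drop = FALSE]
  a2 <- mat[, 5 + 2 * seq_len(nrow(markers)), drop = FALSE]
  geno <- matrix(NA_integer_, nrow = nrow(ped), ncol = nrow(markers),
                 dimnames = list(ped$id, markers$marker_id))
  errors <- character()
  for (j in seq_len(nrow(markers))) {
    if (is.na(markers$allele_a[j])) {
      seen <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
      if (length(seen) > 2) {
        errors <- c(errors, paste0(markers$marker_id[j], ": more than two alleles (",
                                   paste(seen, collapse = ","), ")"))
        next
      }
      markers$allele_a[j] <- if (length(seen) >= 1) seen[1] else "A"
      markers$allele_b[j] <- if (length(seen) >= 2) seen[2] else "B"
      if (markers$allele_a[j] == markers$allele_b[j]) markers$allele_b[j] <- paste0(seen[1], "'")
    }
    ok <- c("0", markers$allele_a[j], markers$allele_b[j])
    bad <- !(a1[, j] %in% ok) | !(a2[, j] %in% ok)
    if (any(bad)) {
      errors <- c(errors, paste0(markers$marker_id[j], ": allele symbol(s) ",
                                 paste(unique(c(a1[bad, j], a2[bad, j])), collapse = ","),
                                 " not in {", markers$allele_a[j], ",", markers$allele_b[j], ",0}"))
      next
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] == markers$allele_b[j]) + (a2[, j] == markers$allele_b[j])
    geno[miss, j] <- NA_integer_
  }
  if (length(errors) > 0) {
    stop("per-marker allele errors:\n  ", paste(errors, collapse = "\n  "), call. = FALSE)
  }
  linkage_dataset(ped, markers, geno)
}

#' @rdname read_genotypes
#' @param tsv_path A single TSV with an `id` column and one column per
#'   marker holding AA/AB/BB/NA calls.
#' @param pedigree A pedigree tibble for the same individuals.
#' @export
read_genotypes_tsv <- function(tsv_path, pedigree) {
  tbl <- readr::read_tsv(tsv_path, col_types = readr::cols(.default = "c"), progress = FALSE)
  stopifnot("id" %in% names(tbl))
  marker_ids <- setdiff(names(tbl), "id")
  geno <- matrix(NA_integer_, nrow(tbl), length(marker_ids),
                 dimnames = list(tbl$id, marker_ids))
  for (j in seq_along(marker_ids)) {
    v <- tbl[[marker_ids[j]]]
    bad <- !(v %in% c("AA", "AB", "BA", "BB", NA, "NA"))
    if (any(bad)) stop(marker_ids[j], ": call '", v[bad][1], "' not in {AA,AB,BB,NA}", call. = FALSE)
    geno[, j] <- dplyr::case_match(v, "AA" ~ 0L, c("AB", "BA") ~ 1L, "BB" ~ 2L, .default = NA_integer_)
  }
  markers <- tibble::tibble(marker_id = marker_ids, allele_a = "A", allele_b = "B")
  linkage_dataset(pedigree, markers, geno)
}

#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  mk <- dataset$markers
  utils::write.table(mk[, c("marker_id", "allele_a", "allele_b")], map_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ped <- dataset$pedigree[match(rownames(dataset$geno), dataset$pedigree$id), ]
  g <- dataset$geno
  n <- nrow(g); m <- ncol(g)
  a1 <- matrix(rep(mk$allele_a, each = n), n, m)
  a2 <- matrix(rep(mk$allele_b, each = n), n, m)
  first <- ifelse(is.na(g), "0", ifelse(g <= 1, a1, a2))
  second <- ifelse(is.na(g), "0", ifelse(g >= 1, a2, a1))
  inter <- matrix(paste(first, second), n, m)
  lines <- paste(ped$family, ped$id,
                 ifelse(is.na(ped$sire), "0", ped$sire),
                 ifelse(is.na(ped$dam), "0", ped$dam),
                 c(female = "F", male = "M", unknown = "U")[ped$sex],
                 apply(inter, 1, paste, collapse = " "))
  writeLines(lines, ped_path)
  invisible(ped_path)
}

map_tsv_cols <- c("lg", "rank", "marker_id", "tier", "cm_sexavg", "cm_female",
                  "cm_male", "n_inf_known", "n_inf_unknown", "gene_label")

#' Write / read an ordered map as TSV
#'
#' Columns: LG, rank, marker_id, placement tier (LOD3/LOD2/LOD1/BEST) and
#' Kosambi cM positions for the sex-average, female and male maps, plus
#' phase-known / phase-unknown informative meiosis counts and an optional
#' gene label. Positions are written with 2 decimal places and start at 0
#' per linkage group; a write/read cycle is the identity on maps already at
#' that precision.
#'
#' @param map An ordered-map tibble (class `pearl_map`).
#' @param path File path.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(is.data.frame(map))
  missing_cols <- setdiff(setdiff(map_tsv_cols, c("n_inf_known", "n_inf_unknown", "gene_label")), names(map))
  if (length(missing_cols) > 0) {
    stop("map is not finalized; missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(map)
  for (col in c("n_inf_known", "n_inf_unknown")) if (!col %in% names(out)) out[[col]] <- NA_integer_
  if (!"gene_label" %in% names(out)) out$gene_label <- NA_character_
  out <- out[, map_tsv_cols]
  for (col in c("cm_sexavg", "cm_female", "cm_male")) out[[col]] <- sprintf("%.2f", out[[col]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    lg = "i", rank = "i", marker_id = "c", tier = "c",
    cm_sexavg = "d", cm_female = "d", cm_male = "d",
    n_inf_known = "i", n_inf_unknown = "i", gene_label = "c"
  ), progress = FALSE)
  class(out) <- c("pearl_map", class(out))
  out
}
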