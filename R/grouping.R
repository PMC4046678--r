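#' Default layered grouping parameters
#'
#' Five layers of decreasing stringency, each a 4-tuple: minimum pairwise
#' LOD for a link to qualify, minimum informative meioses for a marker to
#' participate, the maximum number of groups a marker may show qualified
#' links to, and the minimum linkage ratio (share of its qualifying links
#' falling in the best group). Layer five is the final inclusion cut-off.
#'
#' @return Tibble with columns `layer`, `min_lod`, `min_inf`,
#'   `max_groups`, `min_ratio`.
#' @export
autogroup_layers <- function() {
  tibble::tibble(
    layer = 1:5,
    min_lod = c(100, 50, 20, 10, 5),
    min_inf = c(2, 1.5, 1, 0.5, 0.1),
    max_groups = c(2L, 5L, 8L, 10L, 15L),
    min_ratio = c(0.9, 0.8, 0.7, 0.6, 0.5)
  )
}

#' Layered linkage-group formation
#'
#' Iterative grouping through layers of decreasing stringency. Within each
#' layer, unassigned markers are repeatedly assigned to the existing group
#' holding the largest share of their qualifying links into groups,
#' provided they link to at most `max_groups` groups and the best group
#' holds at least `min_ratio` of those links (counting links into any
#' group, so a freshly seeded group absorbs its neighbours chainwise
#' within a layer); markers whose qualifying links connect only other
#' unassigned markers then seed new groups by single linkage (at layer one
#' this is the only seeding source, since no groups exist yet). Markers
#' failing all five layers remain unassigned. Groups are numbered in order
#' of decreasing marker count.
#'
#' @param pairs A [two_point_scan()] tibble (needs `marker_i`, `marker_j`,
#'   `lod`).
#' @param marker_info Tibble `marker_id`, `n_inf_known`, `n_inf_unknown`
#'   for all markers entering grouping (e.g. `mset$marker_info` filtered to
#'   the scan's markers).
#' @param layers See [autogroup_layers()].
#' @param merge_min_lod,merge_max_theta Only links at least this strong
#'   and this tight count as merge support (defaults 6 and 0.25; spurious
#'   cross-chromosome pairs top out well below LOD 5 under the study's
#'   sample sizes, while fragments of one chromosome bridge at
#'   adjacent-pair strength).
#' @param min_merge_links Two groups connected by at least this many
#'   marker-disjoint qualifying links at the current layer are merged
#'   (default 2; a single spurious high-LOD pair, or one promiscuous
#'   marker, then cannot fuse two chromosomes, while split fragments of
#'   one chromosome share many disjoint links and fuse as stringency
#'   relaxes).
#' @return Tibble `marker_id`, `group` (integer, `NA` when unassigned),
#'   `layer` (layer at which the marker entered its group).
#' @export
group_markers <- function(pairs, marker_info, layers = autogroup_layers(),
                          min_merge_links = 2L, merge_min_lod = 6,
                          merge_max_theta = 0.25) {
  ids <- marker_info$marker_id
  n_inf <- marker_info$n_inf_known + marker_info$n_inf_unknown
  names(n_inf) <- ids
  assign <- setNames(rep(NA_integer_, length(ids)), ids)
  at_layer <- setNames(rep(NA_integer_, length(ids)), ids)
  next_group <- 1L
  edges_all <- pairs[pairs$marker_i %in% ids & pairs$marker_j %in% ids, ]
  for (l in seq_len(nrow(layers))) {
    par <- layers[l, ]
    elig <- n_inf >= par$min_inf
    qual <- edges_all[edges_all$lod >= par$min_lod &
                        elig[edges_all$marker_i] & elig[edges_all$marker_j], ]
    if (nrow(qual) == 0) next
    nb <- split(c(qual$marker_j, qual$marker_i), c(qual$marker_i, qual$marker_j))
    repeat {
      repeat {
        changed <- FALSE
        todo <- names(nb)[is.na(assign[names(nb)])]
        for (mk in todo) {
          grp <- assign[nb[[mk]]]
          shares <- table(grp[!is.na(grp)])
          if (length(shares) == 0) next
          if (length(shares) > par$max_groups) next
          best <- which.max(shares)
          if (shares[best] / sum(shares) >= par$min_ratio) {
            assign[mk] <- as.integer(names(shares)[best])
            at_layer[mk] <- l
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      # merge groups supported by at least min_merge_links qualifying links
      # merge support must be decisive linkage: the null tail of the
      # phase-mixture LOD is heavy (spurious cross-chromosome pairs reach
      # LOD 5-6 at theta 0.15-0.45), while genuine links bridging a split
      # group are adjacent-strength (LOD tens at small theta)
      decisive <- qual$lod >= merge_min_lod & qual$theta <= merge_max_theta
      gi <- assign[qual$marker_i]; gj <- assign[qual$marker_j]
      cross <- decisive & !is.na(gi) & !is.na(gj) & gi != gj
      merged <- FALSE
      if (any(cross)) {
        key <- paste(pmin(gi[cross], gj[cross]), pmax(gi[cross], gj[cross]))
        # support links must not share a marker: a single promiscuous
        # marker (or one spurious pair) cannot fuse two chromosomes
        mi <- qual$marker_i[cross]; mj <- qual$marker_j[cross]
        support <- vapply(split(seq_along(key), key), function(idx) {
          used <- character(); links <- 0L
          for (x in idx[order(-qual$lod[cross][idx])]) {
            if (mi[x] %in% used || mj[x] %in% used) next
            used <- c(used, mi[x], mj[x]); links <- links + 1L
          }
          links
        }, 0L)
        strong <- names(support)[support >= min_merge_links]
        if (length(strong) > 0) {
          ed <- do.call(rbind, strsplit(strong, " "))
          gg <- igraph::graph_from_data_frame(as.data.frame(ed), directed = FALSE)
          cmp <- igraph::components(gg)
          for (cid in seq_len(cmp$no)) {
            mem <- as.integer(names(cmp$membership)[cmp$membership == cid])
            if (length(mem) >= 2) {
              assign[assign %in% mem] <- min(mem)
              merged <- TRUE
            }
          }
        }
      }
      # seed new groups among still-unassigned markers
      un <- qual[is.na(assign[qual$marker_i]) & is.na(assign[qual$marker_j]), ]
      seeded <- FALSE
      if (nrow(un) > 0) {
        g <- igraph::graph_from_data_frame(un[, c("marker_i", "marker_j")], directed = FALSE)
        comp <- igraph::components(g)
        for (cid in seq_len(comp$no)) {
          members <- names(comp$membership)[comp$membership == cid]
          if (length(members) >= 2) {
            assign[members] <- next_group
            at_layer[members] <- l
            next_group <- next_group + 1L
            seeded <- TRUE
          }
        }
      }
      if (!merged && !seeded) break
    }
  }
  # renumber by decreasing group size
  sizes <- sort(table(assign), decreasing = TRUE)
  renum <- setNames(seq_along(sizes), names(sizes))
  tibble::tibble(
    marker_id = ids,
    group = unname(renum[as.character(assign[ids])]),
    layer = unname(at_layer[ids])
  )
}

#' Haplogroups of tightly linked markers
#'
#' Connected components of the graph whose edges join marker pairs with
#' `lod >= lod_min` and `theta <= theta_max` (defaults 3.0 and 0.03). The
#' pairwise criterion is not transitive, so components are used as the
#' grouping semantics. Each haplogroup's primary is its most informative
#' member (ties broken lexicographically); primaries form the framework
#' candidate set for map building.
#'
#' @param markers Marker ids of one linkage group.
#' @param pairs A [two_point_scan()] tibble with `theta` and `lod`.
#' @param marker_info Informative-meiosis counts (`mset$marker_info`).
#' @param lod_min,theta_max Tight-linkage thresholds.
#' @return Tibble `marker_id`, `haplogroup` (integer), `primary` (logical).
#' @export
find_haplogroups <- function(markers, pairs, marker_info,
                             lod_min = 3, theta_max = 0.03) {
  ed <- pairs[pairs$marker_i %in% markers & pairs$marker_j %in% markers &
                pairs$lod >= lod_min & pairs$theta <= theta_max, ]
  g <- igraph::graph_from_data_frame(ed[, c("marker_i", "marker_j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = markers))
  comp <- igraph::components(g)
  n_inf <- setNames(marker_info$n_inf_known + marker_info$n_inf_unknown,
                    marker_info$marker_id)
  out <- tibble::tibble(
    marker_id = names(comp$membership),
    haplogroup = unname(comp$membership)
  )
  out |>
    dplyr::group_by(.data$haplogroup) |>
    dplyr::mutate(primary = {
      inf <- dplyr::coalesce(n_inf[.data$marker_id], 0)
      seq_along(.data$marker_id) == order(-inf, .data$marker_id)[1]
    }) |>
    dplyr::ungroup()
}
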