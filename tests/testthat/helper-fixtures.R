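# Shared fixtures: tiny deterministic datasets built in code.

# A minimal three-generation family: grandparents with fixed genotypes,
# two F1 parents, `n_off` F2 offspring with genotypes supplied per marker.
make_trio_dataset <- function(geno, pedigree = NULL) {
  ids <- rownames(geno)
  if (is.null(pedigree)) stop("pedigree required")
  markers <- tibble::tibble(
    marker_id = colnames(geno), allele_a = "A", allele_b = "B"
  )
  linkage_dataset(pedigree, markers, geno)
}

# Small simulated dataset cached per session (3 LGs x 10 markers,
# reduced families) used by several suites.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7, n_lg = 3, markers_per_lg = 10,
                        n_f2 = c(30L, 20L, 15L, 15L, 14L, 14L, 14L, 14L))
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

# Adjusted Rand index by the closed-form contingency formula (independent
# of any clustering package).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Brute-force multipoint likelihood at fixed thetas: loops over every
# phase assignment of every parent, every gamete and every consecutive
# observed marker pair. Deliberately naive.
naive_multipoint <- function(mset, order, thetas, sex = "both") {
  ord <- match(order, mset$marker_ids)
  rows <- seq_len(nrow(mset$parents))
  if (sex != "both") rows <- rows[mset$parents$sex == sex]
  span_r <- function(j1, j2) {
    0.5 * (1 - prod(1 - 2 * thetas[j1:(j2 - 1)]))
  }
  total <- 0
  for (r in rows) {
    p <- mset$parents$parent_id[r]
    trc <- mset$trans[[p]][, ord, drop = FALSE]
    ph <- mset$phase[[p]][ord]
    inf <- colSums(!is.na(trc)) > 0
    unres <- which(inf & is.na(ph))
    h <- length(unres)
    liks <- numeric(0)
    for (code in seq_len(2^h) - 1) {
      phi <- ph
      phi[unres] <- as.integer(intToBits(code)[seq_len(h)])
      phi[is.na(phi)] <- 0L
      ll <- 0
      for (i in seq_len(nrow(trc))) {
        prev <- NA
        for (t in seq_along(ord)) {
          if (is.na(trc[i, t])) next
          o <- (trc[i, t] + phi[t]) %% 2
          if (!is.na(prev)) {
            rr <- span_r(prev_t, t)
            rr <- min(max(rr, 1e-12), 0.5)
            ll <- ll + log(if (o != prev) rr else 1 - rr)
          }
          prev <- o; prev_t <- t
        }
      }
      liks <- c(liks, ll)
    }
    mx <- max(liks)
    total <- total + mx + log(mean(exp(liks - mx)))
  }
  total / log(10)
}
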