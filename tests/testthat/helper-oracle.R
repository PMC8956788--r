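# Independent brute-force oracles, written with explicit base-R loops so
# they share no code path with the package's pipeline.

# Recompute SRR, RRw, Cwt and CPI from a raw (species, lake, country)
# triple table by direct enumeration.
oracle_cpi <- function(triples, registry, status, k = 8) {
  triples <- unique(triples[, c("species", "lake", "country")])
  weights <- c(ET = 7, EXw = 6, CR = 5, DD = 5, NE = 5,
               EN = 4, VU = 3, NT = 2, LC = 1)
  rows <- list()
  for (ctry in unique(triples$country)) {
    sub <- triples[triples$country == ctry, , drop = FALSE]
    lakes <- unique(sub$lake)
    wt <- length(lakes)
    for (lk in lakes) {
      # summation in sorted-species order, the same well-defined order the
      # pipeline's grouped sums use, so agreement can be checked exactly
      sp <- sort(unique(sub$species[sub$lake == lk]))
      srr_terms <- numeric(0)
      wt_terms <- numeric(0)
      for (s in sp) {
        ws <- length(unique(sub$lake[sub$species == s]))
        srr_terms <- c(srr_terms, 1 - ws / wt)
        cat_i <- status$category[match(s, status$species)]
        if (is.na(cat_i) || !cat_i %in% names(weights)) cat_i <- "NE"
        wt_terms <- c(wt_terms, weights[[cat_i]])
      }
      rrw <- sum(srr_terms)
      cwt <- sum(wt_terms)
      area <- registry$area_km2[registry$canonical_name == lk &
                                  registry$country == ctry]
      rows[[length(rows) + 1]] <- data.frame(
        lake = lk, country = ctry, richness = length(sp),
        cwt = cwt, rrw = rrw, area_km2 = area,
        cpi = cwt * rrw / (area * k)
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$country, out$lake), , drop = FALSE]
}

# Exhaustive two-sided rank-sum p over all choose(n, n1) group assignments.
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  rk <- rank(pooled)
  offset <- n1 * (n1 + 1) / 2
  w_obs <- sum(rk[seq_len(n1)]) - offset
  mu <- n1 * (n - n1) / 2
  ws <- utils::combn(n, n1, FUN = function(idx) sum(rk[idx]) - offset)
  list(w = w_obs,
       p = mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9))
}

# Exhaustive species accumulation: average cumulative distinct-species
# count over all orderings of the units' species sets.
oracle_accumulation <- function(species_sets) {
  n <- length(species_sets)
  perms <- permutations_of(n)
  acc <- matrix(0, nrow = nrow(perms), ncol = n)
  for (i in seq_len(nrow(perms))) {
    seen <- character(0)
    for (j in seq_len(n)) {
      seen <- union(seen, species_sets[[perms[i, j]]])
      acc[i, j] <- length(seen)
    }
  }
  list(mean = colMeans(acc), sd = apply(acc, 2, stats::sd))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Canonical records for an in-memory raw occurrence table.
records_of <- function(occ) as_occurrence_records(occ)

# Full package-side chain from raw tables to classified results.
pipeline_results <- function(dataset, k = 8, threshold = 0.5) {
  filt <- filter_records(records_of(dataset$occurrences), dataset$registry)
  units <- build_units(filt$records, dataset$registry)
  score_units(units, dataset$status, k = k, threshold = threshold)
}

# Distinct survivor triples as the oracle consumes them.
triples_of <- function(dataset) {
  filt <- filter_records(records_of(dataset$occurrences), dataset$registry)
  data.frame(species = filt$records$species,
             lake = filt$records$waterbody,
             country = filt$records$country)
}
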