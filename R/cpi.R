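#' Conservation Priority Index per lake-country unit
#'
#' Combines the conservation score, the waterbody relative rarity and the
#' surface area of the national portion of the lake into the index
#' \deqn{CPI_w = \frac{C_{wt} \times RR_w}{A_w \times k}}
#' with \eqn{A_w} the surface area in km^2 and \eqn{k} a scaling constant
#' reflecting the number of IUCN weight levels considered (default 8).
#' Area acts as a cost penalty so the index is not automatically higher for
#' larger, richer lakes. The index is 0 exactly when the unit's relative
#' rarity is 0 — in particular for any lake that is its country's only
#' assessed waterbody.
#'
#' @param scores Output of [conservation_score()].
#' @param rarities Output of [unit_rarity()].
#' @param units Unit table from [build_units()] (source of `area_km2`).
#' @param k Positive scaling constant, default 8.
#' @return Tibble `lake`, `country`, `richness`, `cwt`, `rrw`, `area_km2`,
#'   `cpi`, `richness_density` (distinct species per km^2). Units with
#'   missing or non-positive area are excluded with a warning.
#' @export
compute_cpi <- function(scores, rarities, units, k = 8) {
  stopifnot(is.numeric(k), length(k) == 1, k > 0)
  res <- units[, c("lake", "country", "area_km2")] |>
    dplyr::inner_join(scores[, c("lake", "country", "richness", "cwt")],
                      by = c("lake", "country")) |>
    dplyr::inner_join(rarities, by = c("lake", "country"))
  bad <- is.na(res$area_km2) | res$area_km2 <= 0
  if (any(bad)) {
    warning("cpirank: excluding ", sum(bad),
            " unit(s) with missing or non-positive surface area: ",
            paste(res$lake[bad], collapse = ", "), call. = FALSE)
    res <- res[!bad, , drop = FALSE]
  }
  res$cpi <- (res$cwt * res$rrw) / (res$area_km2 * k)
  res$richness_density <- res$richness / res$area_km2
  dplyr::arrange(
    res[, c("lake", "country", "richness", "cwt", "rrw", "area_km2",
            "cpi", "richness_density")],
    .data$country, .data$lake
  )
}

#' Classify units into high and low conservation priority
#'
#' A unit is high priority when its CPI strictly exceeds the threshold;
#' otherwise low. A CPI exactly at the threshold is classified low, since
#' high priority is defined by strict inequality.
#'
#' @param results Output of [compute_cpi()].
#' @param threshold Classification cut point, default 0.5.
#' @return `results` with a `priority_class` factor (`low` < `high`).
#' @export
classify_priority <- function(results, threshold = 0.5) {
  results$priority_class <- factor(
    ifelse(results$cpi > threshold, "high", "low"),
    levels = c("low", "high")
  )
  results
}

#' Rank units by conservation priority
#'
#' Deterministic league table: descending CPI, ties broken by descending
#' conservation score, then ascending area (the cheaper unit first), then
#' lake name.
#'
#' @param results Output of [compute_cpi()] (classified or not).
#' @return The results ordered by priority with a `rank` column.
#' @export
rank_units <- function(results) {
  out <- dplyr::arrange(results, dplyr::desc(.data$cpi),
                        dplyr::desc(.data$cwt), .data$area_km2, .data$lake)
  out$rank <- seq_len(nrow(out))
  out
}

#' Run the scoring chain from analysis units to classified CPI results
#'
#' Convenience wrapper: species rarity, unit rarity, conservation score,
#' CPI, priority classification.
#'
#' @inheritParams compute_cpi
#' @inheritParams classify_priority
#' @param units Unit table from [build_units()].
#' @param status Species status tibble.
#' @param weights IUCN weight vector.
#' @return Classified CPI results (see [compute_cpi()], [classify_priority()]).
#' @export
score_units <- function(units, status, k = 8, threshold = 0.5,
                        weights = iucn_weights()) {
  rar <- species_rarity(units)
  rrw <- unit_rarity(units, rar)
  sc <- conservation_score(units, status, weights)
  classify_priority(compute_cpi(sc, rrw, units, k = k), threshold = threshold)
}
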