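#' Species relative rarity within each country
#'
#' For every (species, country) pair present in the data, computes
#' \deqn{SRR = 1 - W_s / W_t}
#' where \eqn{W_s} is the number of assessed lakes in the country where the
#' species occurs and \eqn{W_t} is the total number of assessed lakes in
#' that country (lakes that survived the filtering pipeline). SRR is 0 for a
#' ubiquitous species (or whenever a country has a single assessed lake) and
#' approaches 1 for a species confined to one lake among many.
#'
#' @param units Unit table from [build_units()] (or any tibble with `lake`,
#'   `country` and a `species` list-column).
#' @return Tibble with one row per (species, country): `species`, `country`,
#'   `ws`, `wt`, `srr`.
#' @export
species_rarity <- function(units) {
  long <- unit_species_long(units)
  wt_tab <- units |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(wt = dplyr::n_distinct(.data$lake), .groups = "drop")
  long |>
    dplyr::distinct(.data$species, .data$lake, .data$country) |>
    dplyr::group_by(.data$species, .data$country) |>
    dplyr::summarise(ws = dplyr::n_distinct(.data$lake), .groups = "drop") |>
    dplyr::left_join(wt_tab, by = "country") |>
    dplyr::mutate(srr = 1 - .data$ws / .data$wt) |>
    dplyr::arrange(.data$country, .data$species)
}

#' Waterbody relative rarity
#'
#' The relative rarity of a lake-country unit is the plain sum of the
#' species relative rarities (SRR) of its distinct species:
#' \deqn{RR_w = \sum SRR.}
#' It is 0 exactly when every species in the unit occurs in all assessed
#' lakes of the country.
#'
#' @param units Unit table from [build_units()].
#' @param rarities Output of [species_rarity()] for the same units; computed
#'   on the fly when omitted.
#' @return Tibble `lake`, `country`, `rrw`.
#' @export
unit_rarity <- function(units, rarities = species_rarity(units)) {
  if (nrow(units) == 0) {
    return(tibble::tibble(lake = character(), country = character(),
                          rrw = numeric()))
  }
  long <- unit_species_long(units)
  joined <- dplyr::left_join(long, rarities,
                             by = c("species", "country"))
  if (anyNA(joined$srr)) {
    stop("cpirank internal error: species without a rarity entry: ",
         paste(unique(joined$species[is.na(joined$srr)]), collapse = ", "),
         call. = FALSE)
  }
  out <- joined |>
    dplyr::group_by(.data$lake, .data$country) |>
    dplyr::summarise(rrw = sum(.data$srr), .groups = "drop")
  # units with an empty species set contribute an empty sum
  dplyr::left_join(units[, c("lake", "country")], out,
                   by = c("lake", "country")) |>
    dplyr::mutate(rrw = dplyr::coalesce(.data$rrw, 0)) |>
    dplyr::arrange(.data$country, .data$lake)
}
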