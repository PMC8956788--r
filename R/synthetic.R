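#' Default IUCN category mix for synthetic communities
#'
#' Category probabilities matching the empirical composition of a large
#' continental lake-fish assessment: about two thirds least concern, with
#' not-evaluated and data-deficient species the next largest groups and a
#' small extinct tail.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_iucn_mix <- function() {
  counts <- c(LC = 1269, NE = 209, DD = 160, CR = 92, VU = 81,
              EN = 45, NT = 39, ET = 2, EXw = 0)
  counts / sum(counts)
}

#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the statistical structure the index assumes:
#' several countries, a right-skewed (log-normal) lake-area distribution, a
#' power-law species-area relationship with multiplicative noise, a mix of
#' single-lake endemics and widespread species (no cross-country species),
#' and an IUCN category mix dominated by least concern.
#'
#' @param n_countries Number of countries.
#' @param lakes_per_country Integer range `c(min, max)` of lakes drawn per
#'   country.
#' @param area_meanlog,area_sdlog Log-normal surface-area parameters (km^2).
#' @param species_pool_size Total species-name budget across the dataset.
#' @param richness_area_exponent Power-law exponent z of richness ~ area^z.
#' @param richness_coef Baseline richness of a 1 km^2 lake.
#' @param richness_noise_sdlog Log-normal sd of multiplicative richness noise.
#' @param endemism_fraction Probability a species is confined to one lake.
#' @param iucn_mix Named category probabilities, see [default_iucn_mix()].
#' @param duplicate_fraction Fraction of extra duplicated occurrence rows.
#' @param seed Integer seed.
#' @return A validated config list of class `cpi_synth_config`.
#' @export
synthetic_config <- function(n_countries = 5,
                             lakes_per_country = c(3, 10),
                             area_meanlog = 3,
                             area_sdlog = 1.5,
                             species_pool_size = 3000,
                             richness_area_exponent = 0.3,
                             richness_coef = 3,
                             richness_noise_sdlog = 0.2,
                             endemism_fraction = 0.3,
                             iucn_mix = default_iucn_mix(),
                             duplicate_fraction = 0.1,
                             seed = 1L) {
  cfg <- list(n_countries = as.integer(n_countries),
              lakes_per_country = as.integer(lakes_per_country),
              area_meanlog = area_meanlog, area_sdlog = area_sdlog,
              species_pool_size = as.integer(species_pool_size),
              richness_area_exponent = richness_area_exponent,
              richness_coef = richness_coef,
              richness_noise_sdlog = richness_noise_sdlog,
              endemism_fraction = endemism_fraction,
              iucn_mix = iucn_mix,
              duplicate_fraction = duplicate_fraction,
              seed = as.integer(seed))
  if (cfg$n_countries < 1 || any(cfg$lakes_per_country < 1) ||
      cfg$lakes_per_country[1] > cfg$lakes_per_country[2]) {
    stop("cpirank config error: invalid country/lake counts", call. = FALSE)
  }
  if (cfg$richness_area_exponent < 0 || cfg$richness_coef <= 0) {
    stop("cpirank config error: richness-area rule needs z >= 0, coef > 0",
         call. = FALSE)
  }
  if (cfg$endemism_fraction < 0 || cfg$endemism_fraction > 1) {
    stop("cpirank config error: endemism_fraction must be in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(cfg$iucn_mix) - 1) > 1e-8 || any(cfg$iucn_mix < 0)) {
    stop("cpirank config error: iucn_mix probabilities must sum to 1",
         call. = FALSE)
  }
  unknown <- setdiff(names(cfg$iucn_mix), names(iucn_weights()))
  if (length(unknown) > 0) {
    stop("cpirank config error: unknown IUCN categories in mix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "cpi_synth_config")
}

#' Generate a synthetic occurrence dataset, status table, and registry
#'
#' Draws lakes with log-normal areas, sets per-lake target richness by a
#' noisy power law in area, then fills the targets with species that are
#' either single-lake endemics or widespread within their country
#' (occupying a random subset of at least two lakes). Every species'
#' IUCN category is drawn from the configured mix. Fully deterministic
#' given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `occurrences` (GBIF-style columns: scientificName,
#'   country, waterBody, decimalLatitude, decimalLongitude, locality),
#'   `status` (species, category), and `registry` (canonical_name, country,
#'   area_km2, synonyms).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "cpi_synth_config"))
  set.seed(config$seed)
  species_counter <- 0L
  new_species <- function(n = 1L) {
    ids <- species_counter + seq_len(n)
    species_counter <<- species_counter + n
    if (species_counter > config$species_pool_size) {
      stop("cpirank config error: species pool (",
           config$species_pool_size,
           ") too small for the requested richness", call. = FALSE)
    }
    sprintf("Lacuspis fictus%04d", ids)
  }

  registry_rows <- list()
  triples <- list()
  for (ci in seq_len(config$n_countries)) {
    country <- sprintf("Country %02d", ci)
    n_lakes <- sample(seq(config$lakes_per_country[1],
                          config$lakes_per_country[2]), 1)
    lakes <- sprintf("Lake %02d-%02d", ci, seq_len(n_lakes))
    areas <- stats::rlnorm(n_lakes, config$area_meanlog, config$area_sdlog)
    registry_rows[[ci]] <- tibble::tibble(
      canonical_name = lakes, country = country,
      area_km2 = round(areas, 3), synonyms = ""
    )
    target <- pmax(1L, as.integer(round(
      config$richness_coef * areas^config$richness_area_exponent *
        stats::rlnorm(n_lakes, 0, config$richness_noise_sdlog)
    )))
    demand <- target
    occ_lakes <- character(0); occ_species <- character(0)
    while (any(demand > 0)) {
      endemic <- n_lakes == 1 ||
        stats::runif(1) < config$endemism_fraction
      if (endemic) {
        lk <- which.max(demand + stats::runif(n_lakes) * 0.5)
        chosen <- lk
      } else {
        s <- sample(2:n_lakes, 1)
        # favour lakes with unmet demand, random tie-break
        chosen <- order(demand + stats::runif(n_lakes) * 0.5,
                        decreasing = TRUE)[seq_len(s)]
      }
      sp <- new_species()
      occ_lakes <- c(occ_lakes, lakes[chosen])
      occ_species <- c(occ_species, rep(sp, length(chosen)))
      demand[chosen] <- demand[chosen] - 1L
    }
    triples[[ci]] <- tibble::tibble(species = occ_species,
                                    lake = occ_lakes, country = country)
  }
  registry <- dplyr::bind_rows(registry_rows)
  long <- dplyr::bind_rows(triples)

  # raw occurrence rows: one per triple plus a duplicated fraction
  n_dup <- round(config$duplicate_fraction * nrow(long))
  if (n_dup > 0) {
    long <- dplyr::bind_rows(long, long[sample(nrow(long), n_dup,
                                               replace = TRUE), ])
  }
  lake_pos <- registry
  lake_pos$lat <- stats::runif(nrow(registry), -30, 30)
  lake_pos$lon <- stats::runif(nrow(registry), -20, 50)
  pos <- match(paste(long$lake, long$country),
               paste(lake_pos$canonical_name, lake_pos$country))
  occurrences <- tibble::tibble(
    scientificName = long$species,
    country = long$country,
    waterBody = long$lake,
    decimalLatitude = round(lake_pos$lat[pos] +
                              stats::rnorm(nrow(long), 0, 0.01), 5),
    decimalLongitude = round(lake_pos$lon[pos] +
                               stats::rnorm(nrow(long), 0, 0.01), 5),
    locality = paste("near", long$lake)
  )

  all_species <- sort(unique(long$species))
  status <- tibble::tibble(
    species = all_species,
    category = sample(names(config$iucn_mix), length(all_species),
                      replace = TRUE, prob = config$iucn_mix)
  )
  list(occurrences = occurrences, status = status, registry = registry)
}

#' Hand-computable two-lake fixture
#'
#' One country with two lakes: Lake A (10 km^2) holds a least-concern and a
#' critically endangered species; Lake B (2 km^2) holds the same critically
#' endangered species plus an endangered one and one absent from the status
#' table (defaulting to not evaluated). The full chain is checkable by
#' hand: with two assessed lakes each single-lake species has SRR = 0.5 and
#' the shared species 0, so RRw(A) = 0.5 and RRw(B) = 1.0; the conservation
#' scores are Cwt(A) = 1 + 5 = 6 and Cwt(B) = 5 + 4 + 5 = 14; with k = 8,
#' CPI(A) = 6 x 0.5 / (10 x 8) = 0.0375 (low priority) and
#' CPI(B) = 14 x 1.0 / (2 x 8) = 0.875 (high priority).
#'
#' @return List with `occurrences`, `status`, `registry` in the same schemas
#'   as [generate_dataset()].
#' @export
worked_fixture <- function() {
  occurrences <- tibble::tibble(
    scientificName = c("Fictus unus", "Fictus duo",
                       "Fictus duo", "Fictus tres", "Fictus quattuor"),
    country = "Aquitania",
    waterBody = c("Lake A", "Lake A", "Lake B", "Lake B", "Lake B"),
    decimalLatitude = c(-1.2, -1.2, -1.8, -1.8, -1.8),
    decimalLongitude = c(30.1, 30.1, 30.6, 30.6, 30.6),
    locality = NA_character_
  )
  status <- tibble::tibble(
    species = c("Fictus unus", "Fictus duo", "Fictus tres"),
    category = c("LC", "CR", "EN")
  )
  registry <- tibble::tibble(
    canonical_name = c("Lake A", "Lake B"),
    country = "Aquitania",
    area_km2 = c(10, 2),
    synonyms = c("lac A", "")
  )
  list(occurrences = occurrences, status = status, registry = registry)
}

#' Inject filterable corruption into an occurrence table
#'
#' Appends corrupted copies of existing rows so the cleaning pipeline's
#' stages have something to remove: rows whose species name is truncated to
#' an incomplete "Genus spp." epithet, and rows stripped of waterbody,
#' coordinates, and locality. Because the corruption is additive, filtering
#' a dirtied table recovers exactly the original rows.
#'
#' @param occurrences Occurrence table (schema of [generate_dataset()]).
#' @param frac_spp_epithets Fraction (of the original row count) of
#'   appended incomplete-epithet rows.
#' @param frac_missing_waterbody Fraction of appended unresolvable rows.
#' @param seed Integer seed.
#' @return The dirtied occurrence table (original rows first).
#' @export
inject_noise <- function(occurrences, frac_spp_epithets = 0,
                         frac_missing_waterbody = 0, seed = 1L) {
  stopifnot(frac_spp_epithets >= 0, frac_spp_epithets <= 1,
            frac_missing_waterbody >= 0, frac_missing_waterbody <= 1)
  set.seed(seed)
  n <- nrow(occurrences)
  out <- occurrences
  k1 <- round(frac_spp_epithets * n)
  if (k1 > 0) {
    bad <- occurrences[sample(n, k1, replace = TRUE), ]
    genus <- vapply(strsplit(bad$scientificName, " "), `[`, "", 1)
    bad$scientificName <- paste(genus, "spp.")
    out <- dplyr::bind_rows(out, bad)
  }
  k2 <- round(frac_missing_waterbody * n)
  if (k2 > 0) {
    bad <- occurrences[sample(n, k2, replace = TRUE), ]
    bad$waterBody <- NA_character_
    bad$decimalLatitude <- NA_real_
    bad$decimalLongitude <- NA_real_
    bad$locality <- NA_character_
    out <- dplyr::bind_rows(out, bad)
  }
  out
}
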