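#' Read an occurrence table into the canonical record schema
#'
#' Reads a delimited occurrence table (GBIF-style Darwin Core columns or any
#' dialect thereof) and maps it onto the canonical record schema used by the
#' filtering pipeline: `species`, `country`, `waterbody`, `latitude`,
#' `longitude`, `locality`. Fields are whitespace-trimmed and common missing
#' markers (`""`, `"NA"`, `"N/A"`) are normalised to `NA`.
#'
#' @param path Path to a delimited text file (UTF-8).
#' @param column_map Named character vector mapping canonical names to source
#'   column names, e.g. `c(species = "scientificName", country = "country")`.
#'   `species` and `country` are mandatory; `waterbody`, `latitude`,
#'   `longitude` and `locality` are optional. Defaults cover the common
#'   Darwin-Core spellings.
#' @param delim Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A tibble with one row per input row and the canonical columns
#'   (missing optional columns are created as `NA`), plus a `.row_id` column
#'   preserving the source row number for override tables.
#' @export
load_occurrences <- function(path,
                             column_map = c(species = "scientificName",
                                            country = "country",
                                            waterbody = "waterBody",
                                            latitude = "decimalLatitude",
                                            longitude = "decimalLongitude",
                                            locality = "locality"),
                             delim = ",") {
  if (!file.exists(path)) {
    stop("cpirank input error: cannot read occurrence file '", path, "'",
         call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  as_occurrence_records(raw, column_map)
}

#' Coerce a data frame to the canonical occurrence-record schema
#'
#' @param df A data frame holding raw occurrence rows.
#' @inheritParams load_occurrences
#' @return A tibble in the canonical record schema (see [load_occurrences()]).
#' @export
as_occurrence_records <- function(df,
                                  column_map = c(species = "scientificName",
                                                 country = "country",
                                                 waterbody = "waterBody",
                                                 latitude = "decimalLatitude",
                                                 longitude = "decimalLongitude",
                                                 locality = "locality")) {
  mandatory <- c("species", "country")
  for (field in mandatory) {
    src <- column_map[[field]]
    if (is.null(src) || !src %in% names(df)) {
      stop("cpirank schema error: missing mandatory column '",
           if (is.null(src)) field else src, "' (", field, ")", call. = FALSE)
    }
  }
  pick <- function(field, as_num = FALSE) {
    src <- column_map[[field]]
    if (is.null(src) || !src %in% names(df)) {
      if (as_num) rep(NA_real_, nrow(df)) else rep(NA_character_, nrow(df))
    } else if (as_num) {
      suppressWarnings(as.numeric(df[[src]]))
    } else {
      as.character(df[[src]])
    }
  }
  out <- tibble::tibble(
    .row_id   = seq_len(nrow(df)),
    species   = clean_string(pick("species")),
    country   = clean_string(pick("country")),
    waterbody = clean_string(pick("waterbody")),
    latitude  = pick("latitude", as_num = TRUE),
    longitude = pick("longitude", as_num = TRUE),
    locality  = clean_string(pick("locality"))
  )
  out
}

# Trim whitespace, collapse internal runs, normalise missing markers to NA.
clean_string <- function(x) {
  x <- trimws(gsub("[[:space:]]+", " ", as.character(x)))
  x[x %in% c("", "NA", "N/A", "na", "n/a")] <- NA_character_
  x
}

# Case-insensitive, accent-folding key for name matching (GBIF dialect
# noise). Transliteration can leave stray marks (e.g. "É" -> "'E"), so
# everything outside [a-z0-9 ] is removed after folding.
fold_name <- function(x) {
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
  gsub("[^a-z0-9 ]", "", x)
}

#' Read a lake registry
#'
#' The registry maps each (lake, country) unit of analysis to the surface
#' area of its national portion, with pipe-separated name synonyms used to
#' harmonise vernacular or non-English lake names (e.g. "lac Edouard" to
#' "Lake Edward").
#'
#' @param path CSV with columns `canonical_name`, `country`, `area_km2`,
#'   `synonyms` (pipe-separated, may be empty).
#' @return A validated registry tibble.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) {
    stop("cpirank input error: cannot read registry file '", path, "'",
         call. = FALSE)
  }
  reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_registry(reg)
}

#' Validate a lake registry table
#'
#' Checks the registry invariants: positive areas, unique
#' (canonical_name, country) pairs, and synonyms that resolve to exactly one
#' canonical lake name.
#'
#' @param registry Data frame with columns `canonical_name`, `country`,
#'   `area_km2` and optionally `synonyms`.
#' @return The registry as a tibble with a normalised `synonyms` column.
#' @export
validate_registry <- function(registry) {
  needed <- c("canonical_name", "country", "area_km2")
  miss <- setdiff(needed, names(registry))
  if (length(miss) > 0) {
    stop("cpirank schema error: registry missing column(s) ",
         paste0("'", miss, "'", collapse = ", "), call. = FALSE)
  }
  reg <- tibble::as_tibble(registry)
  reg$canonical_name <- clean_string(reg$canonical_name)
  reg$country <- clean_string(reg$country)
  reg$area_km2 <- as.numeric(reg$area_km2)
  if (!"synonyms" %in% names(reg)) reg$synonyms <- ""
  reg$synonyms[is.na(reg$synonyms)] <- ""
  if (any(is.na(reg$area_km2)) || any(reg$area_km2 <= 0)) {
    stop("cpirank schema error: registry areas must be positive (area_km2)",
         call. = FALSE)
  }
  if (anyDuplicated(reg[c("canonical_name", "country")]) > 0) {
    stop("cpirank schema error: duplicated (canonical_name, country) in registry",
         call. = FALSE)
  }
  syn <- registry_synonym_table(reg)
  dup <- syn$key[duplicated(syn$key)]
  if (length(dup) > 0) {
    stop("cpirank schema error: registry synonym(s) map to more than one lake: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  reg
}

# Long table mapping folded synonym (and folded canonical name) -> canonical.
registry_synonym_table <- function(registry) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    syns <- strsplit(registry$synonyms[i], "|", fixed = TRUE)[[1]]
    syns <- syns[nzchar(trimws(syns))]
    tibble::tibble(
      key = unique(fold_name(c(registry$canonical_name[i], syns))),
      canonical_name = registry$canonical_name[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::distinct(out, .data$key, .data$canonical_name)
}

# TRUE for names lacking a clean specific epithet: single-word names and
# placeholder epithets ("Oreochromis sp.", "Thoracochromis spp.", "... cf.").
incomplete_epithet <- function(species) {
  sp <- trimws(species)
  bad <- is.na(sp) | !grepl("[[:space:]]", sp)
  bad | grepl("(^|[[:space:]])(sp|spp|cf|aff)\\.?$", sp, ignore.case = TRUE)
}

#' Filter occurrence records through the cleaning pipeline
#'
#' Applies the record-cleaning stages in a fixed order, each stage emitting a
#' retention report:
#'
#' 1. `incomplete_epithet`: drop names with incomplete scientific epithets
#'    ("Oreochromis spp.", single-word names).
#' 2. `unresolved_waterbody`: drop records with no waterbody that cannot be
#'    resolved from coordinates via the optional `point_lookup` bounding-box
#'    table.
#' 3. `harmonize_names`: rewrite waterbody names to canonical English
#'    registry names via the synonym map (not a dropping stage).
#' 4. `unknown_lake`: drop records whose waterbody has no registry entry in
#'    any country (no determinable surface area).
#' 5. `country_mismatch`: drop records whose country conflicts with the
#'    registry's (lake, country) pairs.
#'
#' Filtering is total (an empty survivor set is valid) and idempotent.
#'
#' @param records Canonical occurrence records (see [load_occurrences()]).
#' @param registry Validated lake registry (see [validate_registry()]).
#' @param overrides Optional manual-correction table with columns `.row_id`,
#'   `waterbody` (and optionally `country`), applied before filtering; stands
#'   in for expert coordinate-based relocation of misassigned records.
#' @param point_lookup Optional bounding-box table with columns `lat_min`,
#'   `lat_max`, `lon_min`, `lon_max`, `waterbody` used to resolve
#'   coordinates-only records at stage 2.
#' @param drop_incomplete_epithets Apply stage 1 (default `TRUE`).
#' @return A list with `records` (survivors, waterbody harmonised) and
#'   `report` (one row per stage: `stage`, `records_in`, `records_out`,
#'   `dropped`, `reason`).
#' @export
filter_records <- function(records, registry, overrides = NULL,
                           point_lookup = NULL,
                           drop_incomplete_epithets = TRUE) {
  registry <- validate_registry(registry)
  recs <- tibble::as_tibble(records)
  if (!is.null(overrides) && nrow(overrides) > 0) {
    recs <- apply_overrides(recs, overrides)
  }

  report <- list()
  log_stage <- function(stage, n_in, n_out, reason) {
    report[[length(report) + 1]] <<- tibble::tibble(
      stage = stage, records_in = n_in, records_out = n_out,
      dropped = n_in - n_out, reason = reason
    )
  }

  # Stage 1: incomplete scientific epithets
  n_in <- nrow(recs)
  if (drop_incomplete_epithets) {
    recs <- recs[!incomplete_epithet(recs$species), , drop = FALSE]
  }
  log_stage("incomplete_epithet", n_in, nrow(recs),
            "species name lacks a complete specific epithet")

  # Stage 2: records with no waterbody; resolve via point lookup if supplied
  n_in <- nrow(recs)
  missing_wb <- is.na(recs$waterbody)
  if (any(missing_wb) && !is.null(point_lookup) && nrow(point_lookup) > 0) {
    idx <- which(missing_wb & !is.na(recs$latitude) & !is.na(recs$longitude))
    for (i in idx) {
      hit <- which(point_lookup$lat_min <= recs$latitude[i] &
                   point_lookup$lat_max >= recs$latitude[i] &
                   point_lookup$lon_min <= recs$longitude[i] &
                   point_lookup$lon_max >= recs$longitude[i])
      if (length(hit) >= 1) {
        recs$waterbody[i] <- point_lookup$waterbody[hit[1]]
      }
    }
    missing_wb <- is.na(recs$waterbody)
  }
  recs <- recs[!missing_wb, , drop = FALSE]
  log_stage("unresolved_waterbody", n_in, nrow(recs),
            "no waterbody and no resolvable coordinates/locality")

  # Stage 3: harmonize lake nomenclature to canonical English names
  n_in <- nrow(recs)
  syn <- registry_synonym_table(registry)
  key <- fold_name(recs$waterbody)
  hit <- match(key, syn$key)
  recs$waterbody <- ifelse(is.na(hit), recs$waterbody, syn$canonical_name[hit])
  log_stage("harmonize_names", n_in, nrow(recs),
            "waterbody names mapped to canonical English names (no drops)")

  # Stage 4: waterbody absent from registry (no determinable area)
  n_in <- nrow(recs)
  known <- fold_name(recs$waterbody) %in% fold_name(registry$canonical_name)
  recs <- recs[known, , drop = FALSE]
  log_stage("unknown_lake", n_in, nrow(recs),
            "waterbody has no registry entry / no determinable surface area")

  # Stage 5: record country conflicts with registry (lake, country) pairs
  n_in <- nrow(recs)
  reg_key <- paste(fold_name(registry$canonical_name),
                   fold_name(registry$country), sep = "\r")
  rec_key <- paste(fold_name(recs$waterbody),
                   fold_name(recs$country), sep = "\r")
  recs <- recs[rec_key %in% reg_key, , drop = FALSE]
  log_stage("country_mismatch", n_in, nrow(recs),
            "record country conflicts with registry (lake, country) pairs")

  list(records = recs, report = dplyr::bind_rows(report))
}

#' Apply a manual override table to occurrence records
#'
#' Relocates individual records (by `.row_id`) to a corrected waterbody
#' and/or country before filtering, mirroring expert coordinate-based
#' corrections of misassigned records.
#'
#' @param records Canonical occurrence records.
#' @param overrides Data frame with `.row_id` and `waterbody`, optionally
#'   `country`.
#' @return Records with overrides applied.
#' @export
apply_overrides <- function(records, overrides) {
  if (!all(c(".row_id", "waterbody") %in% names(overrides))) {
    stop("cpirank schema error: overrides need columns '.row_id' and 'waterbody'",
         call. = FALSE)
  }
  idx <- match(overrides$.row_id, records$.row_id)
  ok <- !is.na(idx)
  records$waterbody[idx[ok]] <- clean_string(overrides$waterbody[ok])
  if ("country" %in% names(overrides)) {
    has_ctry <- ok & !is.na(overrides$country)
    records$country[idx[has_ctry]] <- clean_string(overrides$country[has_ctry])
  }
  records
}

#' Build lake-country analysis units from filtered records
#'
#' Aggregates surviving, harmonised records into the unit of analysis: the
#' national portion of a lake. Richness and all downstream scores are based
#' on distinct species sets, not record counts.
#'
#' @param records Survivors of [filter_records()].
#' @param registry Validated lake registry.
#' @return A tibble with one row per observed (lake, country):
#'   `lake`, `country`, `area_km2`, `richness`, `n_records`, and a `species`
#'   list-column of distinct species names (sorted).
#' @export
build_units <- function(records, registry) {
  registry <- validate_registry(registry)
  if (nrow(records) == 0) {
    return(tibble::tibble(lake = character(), country = character(),
                          area_km2 = numeric(), richness = integer(),
                          n_records = integer(), species = list()))
  }
  units <- records |>
    dplyr::group_by(lake = .data$waterbody, country = .data$country) |>
    dplyr::summarise(
      richness = dplyr::n_distinct(.data$species),
      n_records = dplyr::n(),
      species = list(sort(unique(.data$species))),
      .groups = "drop"
    )
  reg_key <- paste(fold_name(registry$canonical_name),
                   fold_name(registry$country), sep = "\r")
  unit_key <- paste(fold_name(units$lake), fold_name(units$country), sep = "\r")
  hit <- match(unit_key, reg_key)
  if (anyNA(hit)) {
    stop("cpirank internal error: unit(s) missing from registry after filtering: ",
         paste(units$lake[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  units$area_km2 <- registry$area_km2[hit]
  dplyr::arrange(
    units[, c("lake", "country", "area_km2", "richness", "n_records", "species")],
    .data$country, .data$lake
  )
}

#' Long (species, lake, country) view of analysis units
#'
#' @param units Unit table from [build_units()].
#' @return Tibble with one row per distinct (species, lake, country) triple.
#' @export
unit_species_long <- function(units) {
  if (nrow(units) == 0) {
    return(tibble::tibble(species = character(), lake = character(),
                          country = character()))
  }
  tidyr::unnest(units[, c("lake", "country", "species")],
                cols = "species")[, c("species", "lake", "country")]
}
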