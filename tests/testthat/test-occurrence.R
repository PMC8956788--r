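# Record loading, cleaning stages, and unit construction.

make_registry <- function() {
  tibble::tibble(
    canonical_name = c("Lake Edward", "Lake Victoria", "Lake Kivu"),
    country = c("Uganda", "Uganda", "Rwanda"),
    area_km2 = c(645, 31000, 1000),
    synonyms = c("lac Edouard|Lake Rutanzige", "Victoria Nyanza", "")
  )
}

ten_record_fixture <- function() {
  tibble::tibble(
    scientificName = c("Lates niloticus", "Oreochromis spp.",
                       "Haplochromis eduardii", "Thoracochromis spp.",
                       "Lates niloticus", "Clarias gariepinus",
                       "Bagrus docmak", "Oreochromis niloticus",
                       "Protopterus aethiopicus", "Synodontis victoriae"),
    country = c("Uganda", "Uganda", "Uganda", "Uganda", "Uganda",
                "Uganda", "Uganda", "Uganda", "Uganda", "Uganda"),
    waterBody = c("Lake Victoria", "Lake Victoria", "lac Edouard",
                  "Lake Edward", NA, "Lake Nowhere", "Lake Edward",
                  "Lake Victoria", "Lake Victoria", "Lake Victoria"),
    decimalLatitude = rep(NA_real_, 10),
    decimalLongitude = rep(NA_real_, 10),
    locality = rep(NA_character_, 10)
  )
}

test_that("delimited tables load into the canonical schema with trimming", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,country,waterBody",
    "  Lates niloticus ,Uganda,Lake Victoria",
    "Clarias gariepinus,Uganda,Lake Edward",
    "Bagrus docmak,Uganda,"
  ), path)
  recs <- load_occurrences(path)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$species[1], "Lates niloticus")
  expect_true(is.na(recs$waterbody[3]))
  expect_true(all(is.na(recs$latitude)))
})

test_that("a missing mandatory column raises a schema error naming it", {
  df <- tibble::tibble(scientificName = "Lates niloticus")
  expect_error(as_occurrence_records(df), "country")
  expect_error(as_occurrence_records(tibble::tibble(country = "Uganda")),
               "species")
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(load_occurrences(path), "input error")
})

test_that("filter stages drop the right records and account for every row", {
  recs <- as_occurrence_records(ten_record_fixture())
  out <- filter_records(recs, make_registry())
  expect_equal(nrow(out$records), 6)
  # conservation: drops + survivors = input
  expect_equal(sum(out$report$dropped) + nrow(out$records), nrow(recs))
  # stage-by-stage composition
  expect_equal(out$report$records_in[-1], out$report$records_out[-nrow(out$report)])
  drops <- setNames(out$report$dropped, out$report$stage)
  expect_equal(unname(drops["incomplete_epithet"]), 2)
  expect_equal(unname(drops["unresolved_waterbody"]), 1)
  expect_equal(unname(drops["unknown_lake"]), 1)
  # harmonization: synonym rewritten to the canonical English name
  expect_true("Lake Edward" %in% out$records$waterbody)
  expect_false("lac Edouard" %in% out$records$waterbody)
})

test_that("filtering is idempotent", {
  recs <- as_occurrence_records(ten_record_fixture())
  once <- filter_records(recs, make_registry())
  twice <- filter_records(once$records, make_registry())
  expect_equal(twice$records, once$records)
  expect_equal(sum(twice$report$dropped), 0)
})

test_that("synonym matching is case-insensitive and accent-folding", {
  reg <- make_registry()
  recs <- as_occurrence_records(tibble::tibble(
    scientificName = c("Lates niloticus", "Lates niloticus"),
    country = "Uganda",
    waterBody = c("LAC EDOUARD", "lac Édouard")
  ))
  out <- filter_records(recs, reg)
  expect_equal(out$records$waterbody, c("Lake Edward", "Lake Edward"))
})

test_that("country conflicts with the registry pairing are dropped", {
  recs <- as_occurrence_records(tibble::tibble(
    scientificName = c("Lates niloticus", "Lates niloticus"),
    country = c("Rwanda", "Uganda"),
    waterBody = c("Lake Victoria", "Lake Victoria")
  ))
  out <- filter_records(recs, make_registry())
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$country, "Uganda")
  expect_equal(out$report$dropped[out$report$stage == "country_mismatch"], 1)
})

test_that("override tables relocate records before filtering", {
  recs <- as_occurrence_records(tibble::tibble(
    scientificName = c("Haplochromis eduardii", "Lates niloticus"),
    country = "Uganda",
    waterBody = c("Lake Victoria", "Lake Victoria")
  ))
  ov <- tibble::tibble(.row_id = 1L, waterbody = "Lake Edward")
  out <- filter_records(recs, make_registry(), overrides = ov)
  expect_equal(sort(out$records$waterbody), c("Lake Edward", "Lake Victoria"))
})

test_that("coordinates-only records resolve through the point lookup", {
  recs <- as_occurrence_records(tibble::tibble(
    scientificName = "Lates niloticus", country = "Uganda",
    waterBody = NA_character_,
    decimalLatitude = -0.3, decimalLongitude = 29.7
  ))
  lookup <- tibble::tibble(lat_min = -1, lat_max = 0,
                           lon_min = 29, lon_max = 30,
                           waterbody = "Lake Edward")
  with_lookup <- filter_records(recs, make_registry(), point_lookup = lookup)
  expect_equal(with_lookup$records$waterbody, "Lake Edward")
  without <- filter_records(recs, make_registry())
  expect_equal(nrow(without$records), 0)
})

test_that("units deduplicate species and carry country-specific areas", {
  reg <- tibble::tibble(
    canonical_name = c("Lake Victoria", "Lake Victoria", "Lake Kivu"),
    country = c("Uganda", "Tanzania", "Rwanda"),
    area_km2 = c(31000, 35000, 1000),
    synonyms = ""
  )
  recs <- as_occurrence_records(tibble::tibble(
    scientificName = c("Lates niloticus", "Lates niloticus",
                       "Lates niloticus", "Clarias gariepinus"),
    country = c("Uganda", "Uganda", "Tanzania", "Rwanda"),
    waterBody = c("Lake Victoria", "Lake Victoria", "Lake Victoria",
                  "Lake Kivu")
  ))
  units <- build_units(filter_records(recs, reg)$records, reg)
  expect_equal(nrow(units), 3)  # shared lake -> one unit per country
  ug <- units[units$country == "Uganda", ]
  expect_equal(ug$richness, 1)       # duplicate record counted once
  expect_equal(ug$n_records, 2)
  expect_equal(ug$area_km2, 31000)
  expect_equal(units$area_km2[units$country == "Tanzania"], 35000)
})

test_that("unit species sets are invariant to input row order", {
  occ <- ten_record_fixture()
  reg <- make_registry()
  set.seed(42)
  shuffled <- occ[sample(nrow(occ)), ]
  u1 <- build_units(filter_records(as_occurrence_records(occ), reg)$records, reg)
  u2 <- build_units(filter_records(as_occurrence_records(shuffled), reg)$records,
                    reg)
  expect_equal(u1[, c("lake", "country", "area_km2", "richness", "species")],
               u2[, c("lake", "country", "area_km2", "richness", "species")])
})

test_that("registry invariants are enforced", {
  bad_area <- make_registry()
  bad_area$area_km2[1] <- -5
  expect_error(validate_registry(bad_area), "positive")
  dup <- make_registry()[c(1, 1), ]
  expect_error(validate_registry(dup), "duplicated")
  ambiguous <- make_registry()
  ambiguous$synonyms[3] <- "lac Edouard"
  expect_error(validate_registry(ambiguous), "more than one")
})
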