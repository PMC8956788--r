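#' Default IUCN Red List category weights
#'
#' Threat weights used in the conservation score: extinct categories weigh
#' most, least concern weighs least, and data-deficient / not-evaluated
#' species are weighted like critically endangered on the precautionary
#' principle that their status is unknown.
#'
#' @return Named integer vector: ET=7, EXw=6, CR=5, DD=5, NE=5, EN=4, VU=3,
#'   NT=2, LC=1.
#' @export
iucn_weights <- function() {
  c(ET = 7L, EXw = 6L, CR = 5L, DD = 5L, NE = 5L,
    EN = 4L, VU = 3L, NT = 2L, LC = 1L)
}

#' Normalise a raw IUCN category code
#'
#' Total function mapping raw Red List codes (any case, legacy codes
#' included) onto the canonical category set
#' \{ET, EXw, CR, DD, NE, EN, VU, NT, LC\}. Legacy "LR/nt" becomes NT (and
#' "LR/lc" becomes LC, "LR/cd" NT); standard EX / EW map to the extinct
#' labels ET / EXw; anything unknown or missing becomes NE (not evaluated).
#'
#' @param raw_code Character vector of raw category codes.
#' @return Character vector of canonical categories, same length.
#' @export
normalize_status <- function(raw_code) {
  x <- toupper(trimws(as.character(raw_code)))
  out <- rep("NE", length(x))
  canonical <- c("ET", "EXW", "CR", "DD", "NE", "EN", "VU", "NT", "LC")
  hit <- match(x, canonical)
  out[!is.na(hit)] <- c("ET", "EXw", "CR", "DD", "NE",
                        "EN", "VU", "NT", "LC")[hit[!is.na(hit)]]
  out[x == "EX"] <- "ET"
  out[x == "EW"] <- "EXw"
  out[x %in% c("LR/NT", "LR/CD")] <- "NT"
  out[x == "LR/LC"] <- "LC"
  out
}

#' Load a species status table
#'
#' @param path CSV with columns `species`, `category` (raw IUCN codes).
#' @return Tibble `species`, `category` with categories normalised.
#' @export
load_status <- function(path) {
  if (!file.exists(path)) {
    stop("cpirank input error: cannot read status file '", path, "'",
         call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species", "category") %in% names(tab))) {
    stop("cpirank schema error: status table needs columns 'species', 'category'",
         call. = FALSE)
  }
  tibble::tibble(species = clean_string(tab$species),
                 category = normalize_status(tab$category))
}

#' Resolve the IUCN category of each species
#'
#' Species absent from the status table default to NE (not evaluated),
#' keeping the pipeline total while weighting unknown-status species as
#' high-concern.
#'
#' @param species Character vector of species names.
#' @param status Tibble `species`, `category` (normalised).
#' @return Character vector of canonical categories.
#' @export
resolve_status <- function(species, status) {
  hit <- match(fold_name(species), fold_name(status$species))
  out <- ifelse(is.na(hit), "NE", status$category[hit])
  normalize_status(out)
}

#' Per-unit conservation score (IUCN total weighting)
#'
#' For each lake-country unit, counts its distinct species per IUCN
#' category and computes the conservation score
#' \deqn{C_{wt} = \sum_{\mathrm{categories}} n_{\mathrm{cat}} \times w_{\mathrm{cat}},}
#' the category counts times the category weights, summed over categories.
#' Since the minimum weight is 1, \eqn{C_{wt}} is always at least the unit's
#' richness, with equality when all species are least concern.
#'
#' @param units Unit table from [build_units()].
#' @param status Status tibble (`species`, `category`); missing species
#'   default to NE.
#' @param weights Named weight vector; defaults to [iucn_weights()].
#' @return Tibble with `lake`, `country`, `richness`, one `n_<category>`
#'   count column per weighted category, and `cwt`.
#' @export
conservation_score <- function(units, status, weights = iucn_weights()) {
  cats <- names(weights)
  if (nrow(units) == 0) {
    empty <- tibble::tibble(lake = character(), country = character(),
                            richness = integer())
    for (cc in cats) empty[[paste0("n_", cc)]] <- integer()
    empty$cwt <- integer()
    return(empty)
  }
  long <- unit_species_long(units)
  long$category <- resolve_status(long$species, status)
  counts <- long |>
    dplyr::count(.data$lake, .data$country, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  for (cc in cats) {
    col <- paste0("n_", cc)
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  count_mat <- as.matrix(counts[, paste0("n_", cats)])
  counts$cwt <- as.integer(count_mat %*% weights[cats])
  out <- dplyr::left_join(units[, c("lake", "country", "richness")], counts,
                          by = c("lake", "country"))
  n_cols <- paste0("n_", cats)
  out[n_cols] <- lapply(out[n_cols], function(v) dplyr::coalesce(v, 0L))
  out$cwt <- dplyr::coalesce(out$cwt, 0L)
  dplyr::arrange(out[, c("lake", "country", "richness", n_cols, "cwt")],
                 .data$country, .data$lake)
}
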