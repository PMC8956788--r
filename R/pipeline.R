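#' Run the full conservation-prioritization workflow
#'
#' Wires all stages end to end: record cleaning with per-stage retention
#' accounting, unit construction, rarity and conservation scoring, CPI
#' computation and classification, descriptive statistics, and (optionally)
#' the two tree-ensemble priority classifiers. All randomness flows from
#' one root seed.
#'
#' @param occurrences Occurrence table (raw GBIF-style tibble) or path to a
#'   delimited file.
#' @param registry Lake registry tibble or CSV path.
#' @param status Species status tibble or CSV path.
#' @param overrides Optional manual-correction table (see [filter_records()]).
#' @param k CPI scaling constant, default 8.
#' @param threshold Priority classification cut point, default 0.5.
#' @param seed Root seed for the stochastic stages.
#' @param n_permutations Accumulation-curve permutations, default 100.
#' @param train_fraction Train share for the models, default 0.7.
#' @param models Fit the random-forest and boosted-tree classifiers
#'   (default `TRUE`; skipped with a message when the classes are too
#'   imbalanced to split).
#' @param outdir Optional directory; when given, all tables are written as
#'   CSV plus a JSON manifest of stage record counts.
#' @return List: `filter_report`, `units`, `species_rarity`, `unit_rarity`,
#'   `scores`, `results` (ranked, classified CPI table), `correlations`,
#'   `group_comparison`, `accumulation`, `model_reports`, `importances`,
#'   `manifest`.
#' @export
run_cpi <- function(occurrences, registry, status, overrides = NULL,
                    k = 8, threshold = 0.5, seed = 1L,
                    n_permutations = 100, train_fraction = 0.7,
                    models = TRUE, outdir = NULL) {
  if (is.character(occurrences)) occurrences <- load_occurrences(occurrences)
  else occurrences <- as_occurrence_records(occurrences)
  if (is.character(registry)) registry <- load_registry(registry)
  else registry <- validate_registry(registry)
  if (is.character(status)) status <- load_status(status)
  else status <- tibble::tibble(species = clean_string(status$species),
                                category = normalize_status(status$category))

  filt <- filter_records(occurrences, registry, overrides = overrides)
  units <- build_units(filt$records, registry)
  rar <- species_rarity(units)
  rrw <- unit_rarity(units, rar)
  scores <- conservation_score(units, status)
  results <- compute_cpi(scores, rrw, units, k = k)
  results <- classify_priority(results, threshold = threshold)
  results <- rank_units(results)

  correlations <- if (nrow(results) >= 3) {
    correlation_matrix(results)
  } else NULL
  group_comparison <- if (all(c("low", "high") %in%
                              results$priority_class)) {
    compare_groups(results$area_km2, results$priority_class)
  } else NULL
  accumulation <- if (nrow(units) >= 1) {
    accumulation_curve(units, n_permutations = n_permutations, seed = seed)
  } else NULL

  model_reports <- NULL; importances <- NULL
  if (isTRUE(models)) {
    tab <- table(results$priority_class)
    if (length(tab) == 2 && all(tab >= 4)) {
      feats <- build_features(results)
      spl <- split_data(feats, train_fraction = train_fraction, seed = seed)
      rf <- fit_random_forest(spl$train, seed = seed)
      gbt <- fit_gradient_boosting(spl$train, seed = seed)
      model_reports <- list(rf = evaluate_model(rf, spl$test),
                            gbt = evaluate_model(gbt, spl$test))
      importances <- list(rf = rf$importance, gbt = gbt$importance)
    } else {
      message("cpirank: skipping models (need >= 4 units per priority class)")
    }
  }

  manifest <- list(
    records_in = nrow(occurrences),
    records_surviving = nrow(filt$records),
    records_dropped = sum(filt$report$dropped),
    stage_drops = stats::setNames(as.list(filt$report$dropped),
                                  filt$report$stage),
    n_units = nrow(units),
    n_species = length(unique(unlist(units$species))),
    n_countries = length(unique(units$country)),
    n_high_priority = sum(results$priority_class == "high"),
    n_low_priority = sum(results$priority_class == "low"),
    k = k, threshold = threshold, seed = seed
  )

  out <- list(filter_report = filt$report, units = units,
              species_rarity = rar, unit_rarity = rrw, scores = scores,
              results = results, correlations = correlations,
              group_comparison = group_comparison,
              accumulation = accumulation,
              model_reports = model_reports, importances = importances,
              manifest = manifest)
  if (!is.null(outdir)) write_cpi_artifacts(out, outdir)
  out
}

#' Write workflow artifacts to a directory
#'
#' @param run Output of [run_cpi()].
#' @param outdir Directory path (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_cpi_artifacts <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(outdir, name))
  }
  w(run$filter_report, "filter_report.csv")
  units_flat <- run$units
  units_flat$species <- vapply(units_flat$species, paste, "", collapse = "|")
  w(units_flat, "units.csv")
  w(run$species_rarity, "species_rarity.csv")
  w(run$unit_rarity, "unit_rarity.csv")
  w(run$scores, "conservation_scores.csv")
  w(run$results, "results.csv")
  if (!is.null(run$correlations)) w(run$correlations, "correlations.csv")
  if (!is.null(run$accumulation)) w(run$accumulation, "accumulation_curve.csv")
  extras <- list(manifest = run$manifest)
  if (!is.null(run$group_comparison)) {
    extras$group_comparison <- run$group_comparison
  }
  if (!is.null(run$model_reports)) {
    extras$model_reports <- lapply(run$model_reports, function(m) {
      m$confusion <- as.list(as.data.frame(m$confusion))
      m
    })
    for (nm in names(run$importances)) {
      w(run$importances[[nm]], paste0("importance_", nm, ".csv"))
    }
  }
  jsonlite::write_json(extras, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
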