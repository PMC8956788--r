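#' Pairwise Pearson correlations among index variables
#'
#' Computes all pairwise Pearson correlations among the requested numeric
#' columns of a CPI results table, with the degrees of freedom (n - 2) and
#' two-sided p-value of each test.
#'
#' @param results CPI results table (or any data frame).
#' @param variables Character vector of numeric column names; defaults to
#'   the four index variables: richness, conservation score, surface area,
#'   relative rarity.
#' @return Tibble `var1`, `var2`, `r`, `df`, `p_value`, one row per
#'   unordered pair.
#' @export
correlation_matrix <- function(results,
                               variables = c("richness", "cwt",
                                             "area_km2", "rrw")) {
  miss <- setdiff(variables, names(results))
  if (length(miss) > 0) {
    stop("cpirank schema error: missing variable(s) ",
         paste0("'", miss, "'", collapse = ", "), call. = FALSE)
  }
  if (nrow(results) < 3) {
    stop("cpirank analysis error: need at least 3 units for correlations",
         call. = FALSE)
  }
  pairs <- utils::combn(variables, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1, j]; v2 <- pairs[2, j]
    ct <- stats::cor.test(results[[v1]], results[[v2]], method = "pearson")
    tibble::tibble(var1 = v1, var2 = v2,
                   r = unname(ct$estimate),
                   df = unname(ct$parameter),
                   p_value = ct$p.value)
  })
  dplyr::bind_rows(rows)
}

# All n! orderings of 1..n as a matrix, one ordering per row.
all_orderings <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_orderings(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)), deparse.level = 0)
  }))
}

# Rank-sum machinery: Mann-Whitney U for group x, tie-corrected normal
# approximation z (no continuity correction, the effect-size convention).
rank_sum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2  # U statistic for x
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else 0
  list(w = w, z = z, sigma2 = sigma2, n1 = n1, n2 = n2)
}

# Exhaustive two-sided p of the U statistic over all group assignments,
# measured as distance from the null mean (handles ties). Feasible for
# n1 + n2 <= 12 (choose(12, 6) = 924 assignments).
rank_sum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  rk <- rank(pooled)
  offset <- n1 * (n1 + 1) / 2
  w_obs <- sum(rk[seq_len(n1)]) - offset
  mu <- n1 * (n - n1) / 2
  ws <- utils::combn(n, n1, FUN = function(idx) sum(rk[idx]) - offset)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Two-group rank-sum comparison with effect size
#'
#' Compares the values of a numeric variable between two priority classes
#' with the unpaired two-sample rank-sum (Mann-Whitney) test and reports
#' the effect size
#' \deqn{r = |z| / \sqrt{n_1 + n_2}}
#' computed from the tie-corrected normal deviate z. The p-value uses the
#' tie-corrected normal approximation, except for small samples
#' (n1 + n2 <= 12 under `p_method = "auto"`) where the exact null
#' distribution of the statistic is enumerated instead. The statistic W is
#' the Mann-Whitney U of the first group, so 0 <= W <= n1 * n2.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of length `length(values)` with
#'   exactly two levels; the first level encountered (or the first factor
#'   level) is group 1.
#' @param p_method `"auto"` (exact enumeration when n1 + n2 <= 12, normal
#'   approximation otherwise), `"normal"`, or `"exact"`.
#' @return List with `statistic_w`, `z`, `p_value`, `p_method`,
#'   `effect_size_r`, `n1`, `n2`, `median1`, `median2`, `group1`, `group2`.
#' @export
compare_groups <- function(values, groups,
                           p_method = c("auto", "normal", "exact")) {
  p_method <- match.arg(p_method)
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  if (length(lev) != 2) {
    stop("cpirank analysis error: compare_groups needs exactly two non-empty groups",
         call. = FALSE)
  }
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (length(x) == 0 || length(y) == 0) {
    stop("cpirank analysis error: a comparison group is empty", call. = FALSE)
  }
  rs <- rank_sum_z(x, y)
  use_exact <- p_method == "exact" ||
    (p_method == "auto" && (rs$n1 + rs$n2) <= 12)
  p <- if (use_exact) {
    rank_sum_exact_p(x, y)
  } else {
    2 * stats::pnorm(-abs(rs$z))
  }
  list(statistic_w = rs$w, z = rs$z, p_value = min(1, p),
       p_method = if (use_exact) "exact" else "normal",
       effect_size_r = abs(rs$z) / sqrt(rs$n1 + rs$n2),
       n1 = rs$n1, n2 = rs$n2,
       median1 = stats::median(x), median2 = stats::median(y),
       group1 = lev[1], group2 = lev[2])
}

#' Species accumulation curve over lake-country units
#'
#' Expected cumulative number of distinct species as units are added in
#' random order, with the standard deviation over permutations. Used to
#' judge whether the assessed units capture most of the regional species
#' pool (the curve flattening indicates saturation).
#'
#' @param units Unit table from [build_units()].
#' @param n_permutations Number of random site orderings, default 100.
#' @param seed Integer seed for reproducibility.
#' @return Tibble `sites` (1..N), `mean_richness`, `sd`. The final mean
#'   always equals the total number of distinct species.
#' @export
accumulation_curve <- function(units, n_permutations = 100, seed = 1L) {
  if (nrow(units) == 0) {
    stop("cpirank analysis error: need at least one unit", call. = FALSE)
  }
  long <- unit_species_long(units)
  long$unit <- paste(long$lake, long$country, sep = " / ")
  comm <- table(long$unit, long$species)
  comm <- matrix(as.integer(comm > 0), nrow = nrow(comm),
                 dimnames = dimnames(comm))
  if (nrow(comm) == 1) {
    return(tibble::tibble(sites = 1L, mean_richness = sum(comm[1, ] > 0),
                          sd = 0))
  }
  set.seed(seed)
  n <- nrow(comm)
  # small site counts: average over the complete set of orderings so the
  # curve is the exact expectation; otherwise seeded random orders
  perm <- if (factorial(n) <= n_permutations) {
    all_orderings(n)
  } else {
    t(replicate(n_permutations, sample.int(n)))
  }
  sa <- suppressWarnings(suppressMessages(
    vegan::specaccum(comm, method = "random", permutations = perm)
  ))
  tibble::tibble(sites = as.integer(sa$sites),
                 mean_richness = as.numeric(sa$richness),
                 sd = as.numeric(sa$sd))
}
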