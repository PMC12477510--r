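#' Round half away from zero
#'
#' Reporting convention for percentages and index values: half-up rounding to
#' a fixed number of decimals (so 43.75 -> 43.8), unlike base `round()`'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize one indicator onto the 0-100 scale
#'
#' Two strategies are available. `"minmax"` maps the observed minimum to 0 and
#' the observed maximum to 100, linearly in between — reproducible from the
#' analysis set alone, but dependent on which countries are loaded.
#' `"fixed"` linearly maps the indicator's declared natural bounds (e.g.
#' \[0, 1\] for a parity ratio) onto \[0, 100\], clipping values outside the
#' declared range. Indicators scored `direction = "lower"` are reversed after
#' mapping so that 100 is always best. Missing values stay missing.
#'
#' @param values Numeric vector of raw per-country values (may contain `NA`).
#' @param definition One row of a catalog's `entries` tibble (or a list with
#'   `id`, `direction`, `raw_min`, `raw_max`).
#' @param strategy `"minmax"` or `"fixed"`.
#' @return Numeric vector in \[0, 100\] with `NA` preserved.
#' @export
normalize_indicator <- function(values, definition,
                                strategy = c("minmax", "fixed")) {
  strategy <- match.arg(strategy)
  obs <- values[!is.na(values)]
  if (strategy == "minmax") {
    if (length(unique(obs)) < 2L) {
      stop("cannot min-max normalize indicator '", definition$id,
           "': fewer than 2 distinct observed values", call. = FALSE)
    }
    lo <- min(obs)
    hi <- max(obs)
  } else {
    lo <- definition$raw_min
    hi <- definition$raw_max
    if (is.na(lo) || is.na(hi)) {
      stop("indicator '", definition$id,
           "' has no declared raw_range; fixed-bounds normalization ",
           "needs one", call. = FALSE)
    }
  }
  out <- 100 * (values - lo) / (hi - lo)
  if (strategy == "fixed") out <- pmin(pmax(out, 0), 100)
  if (identical(definition$direction, "lower")) out <- 100 - out
  out
}

#' Build maturity profiles for a set of countries
#'
#' Runs the index-construction stage: normalizes every catalog indicator onto
#' 0-100, averages constituent indicators into the 7 subcomponent scores, and
#' computes the overall digital maturity index as the unweighted mean of all
#' 14 normalized indicators (not the mean of the subcomponent scores).
#'
#' The overall index follows a complete-case rule: it is reported only for
#' countries with all 14 indicators present (`complete = TRUE`), and is `NA`
#' otherwise. Subcomponent scores tolerate partial data — the score is the
#' mean of the non-missing constituents, `NA` only when all constituents are
#' missing — with `partial = TRUE` flagging any country whose reported
#' subcomponent scores rest on incomplete constituents.
#'
#' @param records Country-record tibble from [load_country_table()] or
#'   [generate_countries()].
#' @param catalog An `indicator_catalog`.
#' @param normalization `"minmax"` (default) or `"fixed"`. With `"fixed"`,
#'   indicators lacking a declared range fall back to min-max.
#' @return A tibble of maturity profiles: `country_id`, `region`, one
#'   normalized column per indicator, `sub_<subcomponent>` score columns,
#'   `index`, `complete`, `partial`.
#' @export
build_profiles <- function(records, catalog = default_catalog(),
                           normalization = c("minmax", "fixed")) {
  normalization <- match.arg(normalization)
  entries <- catalog$entries
  norm <- tibble::tibble(country_id = records$country_id,
                         region = records$region)
  for (k in seq_len(nrow(entries))) {
    def <- entries[k, ]
    strat <- normalization
    if (strat == "fixed" && is.na(def$raw_min)) strat <- "minmax"
    norm[[def$id]] <- normalize_indicator(records[[def$id]], def, strat)
  }
  nm <- as.matrix(norm[, entries$id, drop = FALSE])
  scores <- compute_subcomponent_scores(nm, catalog)
  for (s in catalog$subcomponents) {
    norm[[paste0("sub_", s)]] <- scores[, s]
  }
  norm$index <- compute_index(nm, catalog)
  norm$complete <- rowSums(is.na(nm)) == 0L
  norm$partial <- !norm$complete & rowSums(!is.na(nm)) > 0L
  norm
}

#' Subcomponent scores from a normalized-indicator matrix
#'
#' Each subcomponent score is the arithmetic mean of its non-missing
#' constituent normalized indicators; `NA` when all constituents are missing.
#'
#' @param normalized Matrix of normalized values, columns named by indicator
#'   id, one row per country.
#' @param catalog An `indicator_catalog`.
#' @return Matrix with one column per subcomponent.
#' @export
compute_subcomponent_scores <- function(normalized, catalog) {
  out <- sapply(catalog$subcomponents, function(s) {
    ids <- catalog$entries$id[catalog$entries$subcomponent == s]
    block <- normalized[, ids, drop = FALSE]
    v <- rowMeans(block, na.rm = TRUE)
    v[rowSums(!is.na(block)) == 0L] <- NA_real_
    v
  })
  out <- matrix(out, nrow = nrow(normalized),
                dimnames = list(NULL, catalog$subcomponents))
  out
}

#' Overall digital maturity index from a normalized-indicator matrix
#'
#' The unweighted mean of all catalog indicators, reported only for complete
#' cases (every indicator present); `NA` otherwise.
#'
#' @param normalized Matrix of normalized values, columns named by indicator id.
#' @param catalog An `indicator_catalog`.
#' @return Numeric vector, one index per row.
#' @export
compute_index <- function(normalized, catalog) {
  m <- normalized[, catalog$entries$id, drop = FALSE]
  idx <- rowMeans(m)
  idx[rowSums(is.na(m)) > 0L] <- NA_real_
  idx
}

#' Profile missing indicator data
#'
#' Counts countries missing at least one catalog indicator, overall, by WHO
#' region and by subcomponent (a country is missing for a subcomponent when at
#' least one of that subcomponent's indicators is missing). Percentages are
#' rounded half-up to one decimal.
#'
#' @param records Country-record tibble.
#' @param catalog An `indicator_catalog`.
#' @return A list of class `missingness_summary`: `n_total`, `n_missing_any`,
#'   `pct_missing_any`, `by_region` (tibble: region, missing, total, pct) and
#'   `by_subcomponent` (tibble: subcomponent, missing, total, pct).
#' @export
summarize_missingness <- function(records, catalog = default_catalog()) {
  if (nrow(records) == 0L) stop("records must be non-empty", call. = FALSE)
  ids <- catalog$entries$id
  miss <- is.na(as.matrix(records[, ids, drop = FALSE]))
  missing_any <- rowSums(miss) > 0L
  n <- nrow(records)

  by_region <- tibble::tibble(region = records$region,
                              missing_any = missing_any) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(missing = sum(.data$missing_any),
                     total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(pct = round_half_up(100 * .data$missing / .data$total, 1))

  by_sub <- dplyr::bind_rows(lapply(catalog$subcomponents, function(s) {
    sub_ids <- ids[catalog$entries$subcomponent == s]
    m <- sum(rowSums(miss[, sub_ids, drop = FALSE]) > 0L)
    tibble::tibble(subcomponent = s, missing = m, total = n,
                   pct = round_half_up(100 * m / n, 1))
  }))

  structure(
    list(
      n_total = n,
      n_missing_any = sum(missing_any),
      pct_missing_any = round_half_up(100 * mean(missing_any), 1),
      by_region = by_region,
      by_subcomponent = by_sub
    ),
    class = "missingness_summary"
  )
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat("<missingness_summary> ", x$n_missing_any, "/", x$n_total,
      " countries (", x$pct_missing_any, "%) missing >= 1 indicator\n",
      sep = "")
  cat("by region:\n"); print(x$by_region)
  cat("by subcomponent:\n"); print(x$by_subcomponent)
  invisible(x)
}

#' Flatten a missingness summary to one table
#'
#' @param x A `missingness_summary`.
#' @return A tibble with columns `stratum`, `level`, `missing`, `total`,
#'   `pct`, combining the overall, regional and subcomponent breakdowns.
#' @export
missingness_table <- function(x) {
  dplyr::bind_rows(
    tibble::tibble(stratum = "overall", level = "all",
                   missing = x$n_missing_any, total = x$n_total,
                   pct = x$pct_missing_any),
    dplyr::mutate(dplyr::rename(x$by_region, level = "region"),
                  stratum = "region", .before = 1),
    dplyr::mutate(dplyr::rename(x$by_subcomponent, level = "subcomponent"),
                  stratum = "subcomponent", .before = 1)
  )
}
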