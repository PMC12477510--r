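maturity_types <- function() c("emerging", "transitioner", "advanced", "leader")

#' Derive quartile country-type boundaries from observed indices
#'
#' Cuts the observed digital maturity indices at their 25th, 50th and 75th
#' percentiles (linear-interpolation quantiles, the default "type 7"
#' convention) to form four ordered, non-overlapping maturity types:
#' emerging, transitioner, advanced, leader. Bounds are kept at full
#' precision internally; reports round to one decimal.
#'
#' @param indices Numeric vector of at least 4 index values (NAs dropped).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()].
#' @return An object of class `type_boundaries`: a tibble with columns
#'   `country_type`, `low`, `high` ordered from emerging to leader.
#' @export
derive_boundaries <- function(indices, quantile_type = 7) {
  indices <- indices[!is.na(indices)]
  if (length(indices) < 4L) {
    stop("need >= 4 index values to derive quartile boundaries", call. = FALSE)
  }
  if (length(unique(indices)) == 1L) {
    stop("all index values identical: quartiles are degenerate", call. = FALSE)
  }
  q <- stats::quantile(indices, probs = c(0, 0.25, 0.5, 0.75, 1),
                       type = quantile_type, names = FALSE)
  structure(
    tibble::tibble(
      country_type = maturity_types(),
      low = q[1:4],
      high = q[2:5]
    ),
    class = c("type_boundaries", "tbl_df", "tbl", "data.frame")
  )
}

#' Published country-type boundary preset
#'
#' The quartile boundaries of the digital maturity index reported for the
#' 109-country 2023 analysis: emerging 27.9-60.3, transitioner 60.4-69.8,
#' advanced 69.9-78.3, leader 78.4-92.7. Bundling them as a named preset lets
#' new data be classified against the published cut points without the study
#' dataset. The printed intervals are adjacent at one-decimal resolution;
#' classification treats each printed upper bound as the (inclusive) cut.
#'
#' @return A `type_boundaries` object.
#' @export
paper2023_boundaries <- function() {
  structure(
    tibble::tibble(
      country_type = maturity_types(),
      low = c(27.9, 60.4, 69.9, 78.4),
      high = c(60.3, 69.8, 78.3, 92.7)
    ),
    class = c("type_boundaries", "tbl_df", "tbl", "data.frame")
  )
}

#' Classify index values into country types
#'
#' Assigns the maturity type whose interval contains each index. Intervals
#' are upper-inclusive: a value exactly at a cut point belongs to the lower
#' type. Values below the lowest bound or above the highest are labelled
#' `"out-of-range"` rather than silently clamped. For boundary presets whose
#' printed intervals are adjacent at one-decimal resolution (e.g.
#' 60.3 | 60.4), a value falling in the one-decimal gap is assigned to the
#' type above it, i.e. each type's printed upper bound acts as the inclusive
#' cut point.
#'
#' @param index Numeric vector of index values.
#' @param boundaries A `type_boundaries` object.
#' @return Character vector of type labels (or `"out-of-range"`), same length
#'   as `index`; `NA` stays `NA`.
#' @export
classify_index <- function(index, boundaries) {
  stopifnot(inherits(boundaries, "type_boundaries"))
  cuts <- boundaries$high[1:3]
  lo <- boundaries$low[1]
  hi <- boundaries$high[4]
  out <- rep(NA_character_, length(index))
  ok <- !is.na(index)
  inr <- ok & index >= lo & index <= hi
  out[ok & !inr] <- "out-of-range"
  # findInterval with upper-inclusive cuts: count cuts strictly below value
  bin <- findInterval(index[inr], cuts, left.open = TRUE) + 1L
  out[inr] <- maturity_types()[bin]
  out
}

#' Type complete-case countries from their maturity profiles
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param boundaries `"derive"` (default: quartiles of the supplied
#'   complete-case indices), `"paper2023"` (the published preset), or a
#'   `type_boundaries` object.
#' @return A tibble of typed countries: `country_id`, `region`, `index`,
#'   `country_type` — complete cases only.
#' @export
classify_countries <- function(profiles, boundaries = "derive") {
  cc <- profiles[profiles$complete, , drop = FALSE]
  if (is.character(boundaries)) {
    boundaries <- switch(boundaries,
      derive = derive_boundaries(cc$index),
      paper2023 = paper2023_boundaries(),
      stop("unknown boundaries preset: ", boundaries, call. = FALSE)
    )
  }
  tibble::tibble(
    country_id = cc$country_id,
    region = cc$region,
    index = cc$index,
    country_type = classify_index(cc$index, boundaries)
  )
}

#' Region-by-type contingency table and regional mean indices
#'
#' @param typed Typed-country tibble from [classify_countries()].
#' @return A list with `counts` (tibble: region x country_type cell counts,
#'   wide) and `region_means` (tibble: region, n, mean_index to one decimal).
#' @export
summarize_types_by_region <- function(typed) {
  if (nrow(typed) == 0L) stop("typed must be non-empty", call. = FALSE)
  counts <- typed |>
    dplyr::count(.data$region, .data$country_type) |>
    tidyr::pivot_wider(names_from = "country_type", values_from = "n",
                       values_fill = 0L)
  for (ty in maturity_types()) {
    if (!ty %in% names(counts)) counts[[ty]] <- 0L
  }
  counts <- counts[, c("region", intersect(
    c(maturity_types(), "out-of-range"), names(counts)))]
  means <- typed |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_index = round_half_up(mean(.data$index), 1),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_index))
  list(counts = counts, region_means = means)
}
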