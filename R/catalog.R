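#' WHO regions used for stratified reporting
#'
#' The closed six-value set of World Health Organization administrative
#' regions. All region fields in country tables must resolve (possibly via
#' [region_aliases()]) to one of these.
#'
#' @return Character vector of the six region names.
#' @export
who_regions <- function() {
  c("African", "Americas", "South-East Asia", "European",
    "Eastern Mediterranean", "Western Pacific")
}

#' Region alias map
#'
#' Common regional-office codes and spellings mapped onto the canonical six
#' WHO region names, applied when loading country tables.
#'
#' @return Named character vector: names are accepted aliases, values the
#'   canonical region.
#' @export
region_aliases <- function() {
  c(
    "AFRO" = "African", "AFR" = "African", "African Region" = "African",
    "AMRO" = "Americas", "AMR" = "Americas", "PAHO" = "Americas",
    "Region of the Americas" = "Americas",
    "SEARO" = "South-East Asia", "SEAR" = "South-East Asia",
    "South-East Asia Region" = "South-East Asia",
    "EURO" = "European", "EUR" = "European", "European Region" = "European",
    "EMRO" = "Eastern Mediterranean", "EMR" = "Eastern Mediterranean",
    "Eastern Mediterranean Region" = "Eastern Mediterranean",
    "WPRO" = "Western Pacific", "WPR" = "Western Pacific",
    "Western Pacific Region" = "Western Pacific"
  )
}

#' Read an indicator catalog from a YAML file
#'
#' An indicator catalog declares the indicators that make up the digital
#' maturity index, the subcomponent each belongs to, its scoring direction and
#' (optionally) its natural bounds. The catalog is configuration, not code:
#' the bundled default ([default_catalog()]) carries the standard 14-indicator
#' / 7-subcomponent set, but any catalog can be supplied when `strict = FALSE`.
#'
#' @param path Path to a YAML file with top-level keys `subcomponents` (ordered
#'   list of names) and `indicators` (list of entries with `id`,
#'   `subcomponent`, `direction`, optional `raw_range` and `label`).
#' @param strict If `TRUE` (default), enforce the canonical shape: exactly 14
#'   indicators over exactly 7 subcomponents. Set `FALSE` to allow expanded or
#'   reduced catalogs.
#' @return An object of class `indicator_catalog`: a list with `entries`
#'   (a tibble with one row per indicator) and `subcomponents` (ordered
#'   character vector).
#' @export
read_catalog <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  entries <- dplyr::bind_rows(lapply(raw$indicators, function(e) {
    rng <- e$raw_range
    tibble::tibble(
      id = e$id,
      label = e$label %||% e$id,
      subcomponent = e$subcomponent,
      direction = e$direction %||% "higher",
      raw_min = if (is.null(rng)) NA_real_ else as.numeric(rng[[1]]),
      raw_max = if (is.null(rng)) NA_real_ else as.numeric(rng[[2]])
    )
  }))
  catalog <- structure(
    list(entries = entries, subcomponents = as.character(raw$subcomponents)),
    class = "indicator_catalog"
  )
  validate_catalog(catalog, strict = strict)
  catalog
}

#' The bundled default indicator catalog
#'
#' The standard 14-indicator catalog spanning infrastructure (3 indicators),
#' workforce (1), leadership and governance (1), strategy and investment (2),
#' legislation, policy and compliance (4), gender diversity (2) and consumer
#' readiness (1).
#'
#' @return An `indicator_catalog`.
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "catalog.yml", package = "digimaturity"),
               strict = TRUE)
}

#' Validate an indicator catalog
#'
#' Checks structural invariants: unique indicator ids, every indicator mapped
#' to a declared subcomponent, valid directions and bounds. Under
#' `strict = TRUE` additionally requires exactly 14 indicators and exactly 7
#' subcomponents each with at least one indicator.
#'
#' @param catalog An `indicator_catalog`.
#' @param strict Enforce the canonical 14/7 shape.
#' @return The catalog, invisibly, if valid; otherwise an error.
#' @export
validate_catalog <- function(catalog, strict = TRUE) {
  entries <- catalog$entries
  if (anyDuplicated(entries$id)) {
    stop("duplicate indicator ids in catalog: ",
         paste(unique(entries$id[duplicated(entries$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_sub <- setdiff(entries$subcomponent, catalog$subcomponents)
  if (length(bad_sub)) {
    stop("indicator subcomponent(s) not declared: ",
         paste(bad_sub, collapse = ", "), call. = FALSE)
  }
  if (!all(entries$direction %in% c("higher", "lower"))) {
    stop("indicator direction must be 'higher' or 'lower'", call. = FALSE)
  }
  has_rng <- !is.na(entries$raw_min)
  if (any(has_rng & !(entries$raw_max > entries$raw_min))) {
    stop("declared raw_range must have max > min", call. = FALSE)
  }
  if (strict) {
    if (nrow(entries) != 14L) {
      stop("strict catalog must have exactly 14 indicators, got ",
           nrow(entries), call. = FALSE)
    }
    if (length(catalog$subcomponents) != 7L) {
      stop("strict catalog must have exactly 7 subcomponents, got ",
           length(catalog$subcomponents), call. = FALSE)
    }
    if (any(!catalog$subcomponents %in% entries$subcomponent)) {
      stop("strict catalog: every subcomponent needs >= 1 indicator",
           call. = FALSE)
    }
  }
  invisible(catalog)
}

#' @export
print.indicator_catalog <- function(x, ...) {
  counts <- table(factor(x$entries$subcomponent, levels = x$subcomponents))
  cat("<indicator_catalog> ", nrow(x$entries), " indicators, ",
      length(x$subcomponents), " subcomponents\n", sep = "")
  for (s in x$subcomponents) {
    cat("  ", s, ": ", counts[[s]], "\n", sep = "")
  }
  invisible(x)
}

# reserved (non-indicator) columns in a country table
reserved_columns <- function() {
  c("country_id", "region", "health_expenditure", "performance_index")
}

#' Load a country table
#'
#' Reads a delimited (CSV) country table and validates it against an indicator
#' catalog. The table must carry a `country_id` column; `region`,
#' `health_expenditure` and `performance_index` are recognized when present,
#' and every remaining column must match a catalog indicator id. Empty cells
#' and `NA` are read as missing; unparseable numeric cells become missing with
#' a warning. Region values are canonicalized through [region_aliases()].
#' Lines starting with `#` (e.g. a run-manifest digest header) are skipped.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @param catalog An `indicator_catalog`; defaults to [default_catalog()].
#' @return A tibble of country records, one row per input row (order
#'   preserved), with columns `country_id`, `region`, one column per catalog
#'   indicator, `health_expenditure` and `performance_index`.
#' @export
load_country_table <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), comment = "#",
                         progress = FALSE, show_col_types = FALSE)
  if (!"country_id" %in% names(tab)) {
    stop("country table must have a 'country_id' column", call. = FALSE)
  }
  ids <- catalog$entries$id
  unknown <- setdiff(names(tab), c(reserved_columns(), ids))
  if (length(unknown)) {
    stop("unknown indicator column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      warning(sum(bad), " unparseable value(s) in column '", col,
              "' set to missing", call. = FALSE)
    }
    out
  }

  rec <- tibble::tibble(country_id = tab$country_id)
  if ("region" %in% names(tab)) {
    region <- tab$region
    alias <- region_aliases()
    hit <- region %in% names(alias)
    region[hit] <- alias[region[hit]]
    bad <- !is.na(region) & !region %in% who_regions()
    if (any(bad)) {
      stop("unrecognized region value(s): ",
           paste(unique(region[bad]), collapse = ", "), call. = FALSE)
    }
    rec$region <- region
  } else {
    rec$region <- NA_character_
  }
  for (id in ids) {
    rec[[id]] <- if (id %in% names(tab)) parse_num(tab[[id]], id) else NA_real_
  }
  for (col in c("health_expenditure", "performance_index")) {
    rec[[col]] <- if (col %in% names(tab)) parse_num(tab[[col]], col) else NA_real_
  }
  if (any(!is.na(rec$health_expenditure) & rec$health_expenditure <= 0)) {
    stop("health_expenditure must be > 0 where present", call. = FALSE)
  }
  pi_ok <- is.na(rec$performance_index) |
    (rec$performance_index >= 0 & rec$performance_index <= 100)
  if (!all(pi_ok)) {
    stop("performance_index must lie in [0, 100] where present", call. = FALSE)
  }
  rec
}

#' Write a results table to CSV
#'
#' Serializes any of the pipeline's tabular results (country records, maturity
#' profiles, typed countries, quadrant assignments, ...) as UTF-8 CSV with a
#' stable column order. Missing values are written as empty cells (never 0),
#' so a write/load round trip reproduces values exactly.
#'
#' @param records A non-empty data frame.
#' @param path Output file path.
#' @param digest Optional manifest digest; when supplied it is written as a
#'   `# manifest: <digest>` comment line above the header.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, digest = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  if (!is.null(digest)) {
    writeLines(paste0("# manifest: ", digest), path)
    readr::write_csv(records, path, na = "", append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(records, path, na = "")
  }
  invisible(path)
}

#' Load a results table written by [write_results_table()]
#'
#' @param path CSV file path.
#' @return A tibble with column types guessed from content; `# manifest`
#'   header lines are skipped.
#' @export
load_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_csv(path, na = c("", "NA"), comment = "#",
                  progress = FALSE, show_col_types = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
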