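#' Run the full digital-maturity analysis pipeline
#'
#' Wires every stage end to end: load (or simulate) a country table, build
#' maturity profiles, summarize missingness, type countries by index
#' quartile, correlate maturity with primary health care performance, fit the
#' two log-expenditure regressions and assign spending-efficiency quadrants.
#' All stage outputs are written as CSV under `out_dir`, each carrying the
#' run-manifest digest in a `# manifest:` header comment; the JSON manifest
#' itself (config snapshot, input digest, seed, stage timings, output
#' digests) is written last. Re-running with an identical configuration and
#' input reproduces identical outputs.
#'
#' If the input has no usable performance index, the association,
#' performance-regression and quadrant stages are skipped with a warning and
#' the maturity-only stages still run.
#'
#' @param config A list (or path to a YAML file holding one) with elements:
#'   `input` (country CSV path; omit to simulate), `simulate` (list with
#'   optional `n` and `preset = "paper-shape"`), `catalog` (YAML path;
#'   omit for the bundled default), `normalization` (`"minmax"`/`"fixed"`),
#'   `boundaries` (`"derive"`/`"paper2023"`), `ci_method`
#'   (`"fisher"`/`"bootstrap"`), `level`, `log_base` (`"natural"`/`"10"`),
#'   `seed`, `out_dir`.
#' @return Invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(input = NULL, simulate = list(), catalog = NULL,
         normalization = "minmax", boundaries = "derive",
         ci_method = "fisher", level = 0.95, log_base = "natural",
         seed = 1L, out_dir = "."),
    config
  )
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- if (is.null(cfg$catalog)) default_catalog() else
    read_catalog(cfg$catalog, strict = FALSE)

  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  input_digest <- NA_character_
  if (!is.null(cfg$input)) {
    input_digest <- unname(tools::md5sum(cfg$input))
    records <- stage("load", load_country_table(cfg$input, catalog))
  } else {
    sim_cfg <- if (identical(cfg$simulate$preset, "paper-shape")) {
      paper_shape_preset(n_countries = cfg$simulate$n %||% 194)
    } else {
      synthetic_config(n_countries = cfg$simulate$n %||% 109)
    }
    records <- stage("simulate",
                     generate_countries(sim_cfg, seed = cfg$seed,
                                        catalog = catalog)$records)
  }

  # digest identifies the run: config snapshot + input digest + seed
  snap <- cfg[setdiff(names(cfg), "out_dir")]
  digest <- config_digest(list(config = snap, input_md5 = input_digest))

  profiles <- stage("profiles",
                    build_profiles(records, catalog, cfg$normalization))
  missing <- stage("missingness", summarize_missingness(records, catalog))
  typed <- stage("typing", classify_countries(profiles, cfg$boundaries))

  have_perf <- any(!is.na(records$performance_index[profiles$complete]))
  assoc <- quads <- NULL
  fits <- list()

  # both regressions use the same country set: complete-case countries with
  # positive expenditure (and, when present, a performance index)
  model_set <- profiles |>
    dplyr::filter(.data$complete) |>
    dplyr::select("country_id", "index") |>
    dplyr::inner_join(
      dplyr::select(records, "country_id", "health_expenditure",
                    "performance_index"),
      by = "country_id"
    ) |>
    dplyr::filter(!is.na(.data$health_expenditure))
  if (have_perf) {
    model_set <- dplyr::filter(model_set, !is.na(.data$performance_index))
  }

  if (nrow(model_set) >= 3) {
    fits$maturity <- stage("fit_maturity",
      fit_loglinear(model_set$index, model_set$health_expenditure,
                    log_base = cfg$log_base,
                    country_id = model_set$country_id,
                    outcome_name = "maturity"))
  }
  if (have_perf) {
    pairs <- scatter_table(profiles, records, typed)
    assoc <- stage("association",
                   spearman_with_ci(pairs$index, pairs$performance_index,
                                    level = cfg$level,
                                    method = cfg$ci_method,
                                    seed = cfg$seed))
    fits$performance <- stage("fit_performance",
      fit_loglinear(model_set$performance_index,
                    model_set$health_expenditure,
                    log_base = cfg$log_base,
                    country_id = model_set$country_id,
                    outcome_name = "performance"))
    quads <- stage("quadrants",
                   assign_quadrants(fits$maturity, fits$performance))
  } else {
    warning("no performance index available: association, performance ",
            "regression and quadrant stages skipped", call. = FALSE)
  }

  paths <- list()
  wrt <- function(tag, tab) {
    p <- file.path(cfg$out_dir, paste0(tag, ".csv"))
    write_results_table(tab, p, digest = digest)
    paths[[tag]] <<- p
  }
  wrt("countries", records)
  wrt("profiles", profiles)
  wrt("missingness", missingness_table(missing))
  wrt("typed", typed)
  if (length(fits)) {
    wrt("fits", dplyr::bind_rows(lapply(fits, function(f) tibble::tibble(
      outcome = f$outcome_name, beta0 = f$beta0, beta1 = f$beta1, n = f$n,
      r_squared = f$r_squared, shapiro_w = f$shapiro_w,
      shapiro_p = f$shapiro_p, log_base = f$log_base))))
  }
  if (have_perf) {
    wrt("association", tibble::tibble(
      rho = assoc$rho, ci_low = assoc$ci_low, ci_high = assoc$ci_high,
      n = assoc$n, level = assoc$level, method = assoc$method))
    wrt("quadrants", quads)
  }

  manifest <- list(
    digest = digest,
    config = snap,
    input_md5 = input_digest,
    seed = cfg$seed,
    timings = timings,
    outputs = lapply(paths, function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null", na = "null")

  invisible(list(records = records, profiles = profiles, missingness = missing,
                 typed = typed, association = assoc, fits = fits,
                 quadrants = quads, manifest = manifest,
                 manifest_path = manifest_path, outputs = paths))
}

# stable digest of an R object via serialization to canonical JSON + md5
config_digest <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}
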