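#' Fit a log-expenditure regression for an index
#'
#' Ordinary least squares of a 0-100 index on log current health expenditure
#' per capita, `I_i = beta0 + beta1 * log(HE_i) + e_i` — the expenditure is
#' log-transformed to reduce skew. The fit is validated (not gated) with a
#' Shapiro-Wilk test of residual normality.
#'
#' @param outcome Numeric vector of per-country index values.
#' @param expenditure Numeric vector of health expenditure per capita (US$),
#'   all strictly positive.
#' @param log_base `"natural"` (default) or `"10"`. Predictions are invariant
#'   to the base; the slope is per unit log-expenditure in the chosen base.
#' @param country_id Optional country identifiers (used in error messages and
#'   attached to residuals).
#' @param outcome_name Label for the outcome (e.g. `"maturity"`,
#'   `"performance"`).
#' @return An object of class `loglinear_fit`: list with `beta0`, `beta1`,
#'   `n`, `r_squared`, `shapiro_w`, `shapiro_p`, `log_base`, `outcome_name`,
#'   and a `table` tibble (`country_id`, `observed`, `log_expenditure`,
#'   `fitted`, `residual`). Pairs with a missing member are dropped.
#' @export
fit_loglinear <- function(outcome, expenditure,
                          log_base = c("natural", "10"),
                          country_id = NULL, outcome_name = "index") {
  log_base <- match.arg(log_base)
  if (is.null(country_id)) country_id <- as.character(seq_along(outcome))
  stopifnot(length(outcome) == length(expenditure),
            length(country_id) == length(outcome))
  ok <- !is.na(outcome) & !is.na(expenditure)
  bad_he <- ok & expenditure <= 0
  if (any(bad_he)) {
    stop("non-positive health expenditure for: ",
         paste(country_id[bad_he], collapse = ", "), call. = FALSE)
  }
  outcome <- outcome[ok]; expenditure <- expenditure[ok]
  country_id <- country_id[ok]
  n <- length(outcome)
  if (n < 3L) stop("need >= 3 complete (index, expenditure) pairs",
                   call. = FALSE)
  u <- if (log_base == "natural") log(expenditure) else log10(expenditure)
  fit <- stats::lm(outcome ~ u)
  res <- stats::residuals(fit)
  sst <- sum((outcome - mean(outcome))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  sw <- if (stats::sd(res) > 0) stats::shapiro.test(res) else
    list(statistic = NA_real_, p.value = NA_real_)
  structure(
    list(
      outcome_name = outcome_name,
      beta0 = unname(stats::coef(fit)[1]),
      beta1 = unname(stats::coef(fit)[2]),
      n = n,
      r_squared = r2,
      shapiro_w = unname(sw$statistic),
      shapiro_p = sw$p.value,
      log_base = log_base,
      table = tibble::tibble(
        country_id = country_id,
        observed = outcome,
        log_expenditure = u,
        fitted = unname(stats::fitted(fit)),
        residual = unname(res)
      )
    ),
    class = "loglinear_fit"
  )
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf(
    "<loglinear_fit> %s = %.3f + %.3f * log(HE)  [n = %d, R^2 = %.3f]\n",
    x$outcome_name, x$beta0, x$beta1, x$n, x$r_squared))
  cat(sprintf("  Shapiro-Wilk on residuals: W = %.3f, p = %.3g\n",
              x$shapiro_w, x$shapiro_p))
  invisible(x)
}

#' Predict an index from health expenditure
#'
#' Evaluates `beta0 + beta1 * log(HE)` from a fitted log-linear model. The
#' prediction is not clipped to the index's 0-100 scale, but a warning is
#' issued when it falls outside it.
#'
#' @param fit A `loglinear_fit`.
#' @param expenditure Health expenditure per capita (US$), strictly positive.
#' @return Numeric vector of predicted index values.
#' @export
predict_index <- function(fit, expenditure) {
  if (any(is.na(expenditure)) || any(expenditure <= 0)) {
    stop("expenditure must be positive and non-missing", call. = FALSE)
  }
  u <- if (fit$log_base == "natural") log(expenditure) else log10(expenditure)
  pred <- fit$beta0 + fit$beta1 * u
  if (any(pred < 0 | pred > 100)) {
    warning("prediction outside the [0, 100] index scale", call. = FALSE)
  }
  pred
}

#' Shapiro-Wilk normality check for model residuals
#'
#' @param residuals Numeric vector, 3 <= n <= 5000.
#' @param alpha Significance level for the pass flag (pass = fail-to-reject).
#' @return A list with `w`, `p_value` and logical `pass`. Constant residuals
#'   make W undefined and are reported as an error.
#' @export
validate_normality <- function(residuals, alpha = 0.05) {
  n <- length(residuals)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n, call. = FALSE)
  }
  if (stats::sd(residuals) == 0) {
    stop("residuals are constant: W is undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(residuals)
  list(w = unname(sw$statistic), p_value = sw$p.value,
       pass = sw$p.value >= alpha)
}

#' Assign spending-efficiency quadrants from paired residuals
#'
#' Pairs each country's residual digital maturity index (observed minus
#' predicted from expenditure) with its residual performance index and maps
#' the sign pair to a quadrant: `high-high` (+,+), `high-low` (+,-),
#' `low-high` (-,+), `low-low` (-,-). A country above both best-fit lines
#' (`high-high`) spends efficiently on both fronts. Zero residuals land on
#' the "high" side and are flagged `on_boundary`.
#'
#' @param maturity_fit,performance_fit `loglinear_fit` objects over the same
#'   country set.
#' @return A tibble: `country_id`, `residual_maturity`,
#'   `residual_performance`, `quadrant`, `on_boundary`.
#' @export
assign_quadrants <- function(maturity_fit, performance_fit) {
  a <- maturity_fit$table
  b <- performance_fit$table
  if (!setequal(a$country_id, b$country_id)) {
    only_a <- setdiff(a$country_id, b$country_id)
    only_b <- setdiff(b$country_id, a$country_id)
    stop("fits cover different countries; only in maturity fit: ",
         paste(only_a, collapse = ", "), "; only in performance fit: ",
         paste(only_b, collapse = ", "), call. = FALSE)
  }
  b <- b[match(a$country_id, b$country_id), ]
  high_m <- a$residual >= 0
  high_p <- b$residual >= 0
  tibble::tibble(
    country_id = a$country_id,
    residual_maturity = a$residual,
    residual_performance = b$residual,
    quadrant = paste0(ifelse(high_m, "high", "low"), "-",
                      ifelse(high_p, "high", "low")),
    on_boundary = a$residual == 0 | b$residual == 0
  )
}

#' Cross-tabulate efficiency quadrants against country types
#'
#' @param assignments Quadrant tibble from [assign_quadrants()].
#' @param typed Typed-country tibble from [classify_countries()].
#' @return A list with `overall` (quadrant x country_type count tibble, wide)
#'   and `by_region` (the same split by WHO region; rows sum to `overall`).
#' @export
efficiency_report <- function(assignments, typed) {
  joined <- dplyr::inner_join(
    assignments,
    dplyr::select(typed, "country_id", "region", "country_type"),
    by = "country_id"
  )
  if (nrow(joined) != nrow(assignments)) {
    stop("assignments and typed countries are not aligned", call. = FALSE)
  }
  wide <- function(d, keys) {
    d |>
      dplyr::count(dplyr::across(dplyr::all_of(c(keys, "country_type")))) |>
      tidyr::pivot_wider(names_from = "country_type", values_from = "n",
                         values_fill = 0L)
  }
  list(overall = wide(joined, "quadrant"),
       by_region = wide(joined, c("region", "quadrant")))
}
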