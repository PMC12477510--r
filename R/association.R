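#' Spearman rank correlation with a confidence interval
#'
#' Computes Spearman's rho between two per-country vectors on average ranks
#' (midranks for ties), dropping pairs with a missing member, and attaches a
#' confidence interval by one of two methods: the Fisher z-transform
#' (`atanh(rho) +/- z * 1/sqrt(n - 3)`, back-transformed) or a nonparametric
#' bootstrap percentile interval over paired resamples.
#'
#' @param x,y Numeric vectors of equal length.
#' @param level Confidence level (default 0.95).
#' @param method `"fisher"` (closed form, default) or `"bootstrap"`.
#' @param B Number of bootstrap resamples (bootstrap method only).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `correlation_result`: a list with `rho`,
#'   `ci_low`, `ci_high`, `n` (complete pairs used), `n_dropped`, `level` and
#'   `method`.
#' @export
spearman_with_ci <- function(x, y, level = 0.95,
                             method = c("fisher", "bootstrap"),
                             B = 2000, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " pair(s) with missing values dropped")
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y: rank correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "fisher") {
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  } else {
    set.seed(seed)
    boot <- replicate(B, {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[i]) == 0 || stats::var(y[i]) == 0) NA_real_
      else stats::cor(x[i], y[i], method = "spearman")
    })
    ci <- stats::quantile(boot, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    # a percentile interval need not bracket the point estimate exactly at
    # small B, but must as an interval remain inside [-1, 1]
    ci <- pmin(pmax(ci, -1), 1)
  }
  structure(
    list(rho = rho, ci_low = ci[1], ci_high = ci[2], n = n,
         n_dropped = n_dropped, level = level, method = method),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.2f (%d%% CI %.2f to %.2f), n = %d, %s\n",
              x$rho, round(100 * x$level), x$ci_low, x$ci_high, x$n,
              x$method))
  invisible(x)
}

#' Paired maturity-performance table for plotting and export
#'
#' One row per complete-case country with its digital maturity index, primary
#' health care performance index, WHO region and (optionally) maturity type —
#' the data behind the maturity-versus-performance scatter.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param records Country-record tibble (source of `performance_index`).
#' @param typed Optional typed-country tibble from [classify_countries()].
#' @return A tibble with columns `country_id`, `region`, `index`,
#'   `performance_index` and, when `typed` is given, `country_type`;
#'   complete-case countries with a performance index only.
#' @export
scatter_table <- function(profiles, records, typed = NULL) {
  out <- profiles |>
    dplyr::filter(.data$complete) |>
    dplyr::select("country_id", "region", "index") |>
    dplyr::inner_join(
      dplyr::select(records, "country_id", "performance_index"),
      by = "country_id"
    ) |>
    dplyr::filter(!is.na(.data$performance_index))
  if (!is.null(typed)) {
    out <- dplyr::left_join(
      out, dplyr::select(typed, "country_id", "country_type"),
      by = "country_id"
    )
  }
  out
}
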