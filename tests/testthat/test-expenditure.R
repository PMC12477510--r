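test_that("a noiseless log-linear relationship is recovered exactly", {
  x <- c(50, 120, 300, 700, 1500, 2900, 4100, 6000, 8000, 10000)
  y <- 2 + 3 * log(x)
  fit <- fit_loglinear(y, x)
  expect_equal(fit$beta0, 2, tolerance = 1e-10)
  expect_equal(fit$beta1, 3, tolerance = 1e-10)
  expect_true(all(abs(fit$table$residual) < 1e-10))
})

test_that("a constant outcome gives zero slope and intercept at the mean", {
  fit <- fit_loglinear(rep(55, 6), c(100, 200, 400, 800, 1600, 3200))
  expect_equal(fit$beta1, 0, tolerance = 1e-12)
  expect_equal(fit$beta0, 55, tolerance = 1e-12)
})

test_that("the five-point toy slope matches the closed-form OLS oracle", {
  x <- c(100, 200, 400, 800, 1600)
  y <- c(40, 50, 55, 70, 80)
  u <- log(x)
  slope <- sum((u - mean(u)) * (y - mean(y))) / sum((u - mean(u))^2)
  fit <- fit_loglinear(y, x)
  expect_equal(fit$beta1, slope, tolerance = 1e-10)
  expect_equal(fit$beta0, mean(y) - slope * mean(u), tolerance = 1e-10)
})

test_that("residual identities hold: defn to 1e-9, zero sum to 1e-6", {
  set.seed(19)
  x <- exp(rnorm(60, 6, 1))
  y <- 20 + 8 * log(x) + rnorm(60, sd = 5)
  fit <- fit_loglinear(y, x)
  manual <- fit$table$observed - (fit$beta0 + fit$beta1 * log(x))
  expect_lt(max(abs(fit$table$residual - manual)), 1e-9)
  expect_lt(abs(sum(fit$table$residual)), 1e-6)
  expect_equal(fit$table$fitted + fit$table$residual, fit$table$observed)
})

test_that("non-positive expenditure is rejected naming the country", {
  expect_error(
    fit_loglinear(c(10, 20, 30), c(100, -5, 300),
                  country_id = c("AAA", "BBB", "CCC")),
    "BBB"
  )
  expect_error(fit_loglinear(c(1, 2), c(10, 20)), ">= 3")
})

test_that("predictions follow the fitted line in either log base", {
  fit <- list(beta0 = 10, beta1 = 5, log_base = "natural")
  class(fit) <- "loglinear_fit"
  expect_equal(predict_index(fit, exp(2)), 20)
  flat <- list(beta0 = 42, beta1 = 0, log_base = "natural")
  class(flat) <- "loglinear_fit"
  expect_equal(predict_index(flat, c(1, 100, 1e6)), rep(42, 3))
  expect_error(predict_index(fit, -1), "positive")
  expect_warning(predict_index(fit, exp(50)), "0, 100")

  # base choice does not change predictions from a consistently fitted model
  set.seed(2)
  x <- exp(rnorm(30, 6, 1))
  y <- 15 + 7 * log(x) + rnorm(30)
  f_nat <- fit_loglinear(y, x, log_base = "natural")
  f_10 <- fit_loglinear(y, x, log_base = "10")
  expect_equal(predict_index(f_nat, c(200, 2000)),
               predict_index(f_10, c(200, 2000)), tolerance = 1e-9)
  # positive slope -> monotone increasing prediction
  expect_true(diff(predict_index(f_nat, c(500, 5000))) > 0)
})

test_that("normality validation has near-nominal size on Gaussian residuals", {
  set.seed(41)
  rejections <- sum(replicate(200, {
    validate_normality(rnorm(109))$p_value < 0.05
  }))
  expect_lte(rejections, 18)   # ~5% nominal; binomial slack over 200 draws
})

test_that("normality validation rejects strongly skewed residuals", {
  set.seed(43)
  power <- mean(replicate(100, {
    validate_normality(rexp(109) - 1)$p_value < 0.05
  }))
  expect_gte(power, 0.95)
})

test_that("normality validation rejects degenerate or out-of-range input", {
  expect_error(validate_normality(rep(1.5, 20)), "constant")
  expect_error(validate_normality(c(1, 2)), "3 <= n")
  r <- validate_normality(rnorm(50, 0, 1))
  expect_true(r$w > 0 && r$w <= 1)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

make_fit <- function(ids, residuals, outcome = "maturity") {
  structure(list(
    outcome_name = outcome, beta0 = 0, beta1 = 0, n = length(ids),
    r_squared = NA_real_, shapiro_w = NA_real_, shapiro_p = NA_real_,
    log_base = "natural",
    table = tibble::tibble(country_id = ids, observed = residuals,
                           log_expenditure = 0, fitted = 0,
                           residual = residuals)
  ), class = "loglinear_fit")
}

test_that("residual sign pairs map to the four quadrants", {
  m <- make_fit(c("A", "B", "C", "D"), c(3.2, -0.1, 0, -4))
  p <- make_fit(c("A", "B", "C", "D"), c(5.0, 0.1, -2, -1), "performance")
  q <- assign_quadrants(m, p)
  expect_equal(q$quadrant, c("high-high", "low-high", "high-low", "low-low"))
  expect_equal(q$on_boundary, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("quadrant assignment rejects mismatched country sets", {
  m <- make_fit(c("A", "B", "C"), c(1, -1, 2))
  p <- make_fit(c("A", "B", "D"), c(1, -1, 2), "performance")
  expect_error(assign_quadrants(m, p), "D")
})

test_that("quadrant counts match a sign-counting oracle on synthetic runs", {
  g <- generate_countries(paper_shape_preset(), seed = 5)
  prof <- build_profiles(g$records)
  st <- scatter_table(prof, g$records)
  rec <- g$records[match(st$country_id, g$records$country_id), ]
  fm <- fit_loglinear(st$index, rec$health_expenditure,
                      country_id = st$country_id, outcome_name = "maturity")
  fp <- fit_loglinear(st$performance_index, rec$health_expenditure,
                      country_id = st$country_id, outcome_name = "performance")
  q <- assign_quadrants(fm, fp)
  expect_equal(nrow(q), nrow(st))
  oracle <- table(paste0(ifelse(fm$table$residual >= 0, "high", "low"), "-",
                         ifelse(fp$table$residual >= 0, "high", "low")))
  expect_equal(as.list(table(q$quadrant)), as.list(oracle))
})

test_that("quadrants are invariant to country order and to common shifts", {
  ids <- sprintf("K%02d", 1:20)
  set.seed(3)
  rm_ <- rnorm(20); rp_ <- rnorm(20)
  m <- make_fit(ids, rm_); p <- make_fit(ids, rp_, "performance")
  q1 <- assign_quadrants(m, p)
  perm <- sample(20)
  m2 <- make_fit(ids[perm], rm_[perm])
  q2 <- assign_quadrants(m2, p)
  expect_equal(q2$quadrant[match(q1$country_id, q2$country_id)], q1$quadrant)
  # adding the same constant to observed and predicted leaves residuals,
  # hence quadrants, unchanged
  m3 <- m
  m3$table$observed <- m3$table$observed + 100
  m3$table$fitted <- m3$table$fitted + 100
  m3$table$residual <- m3$table$observed - m3$table$fitted
  expect_equal(assign_quadrants(m3, p)$quadrant, q1$quadrant)
})

test_that("efficiency report cross-tabulates and conserves counts", {
  ids <- sprintf("K%d", 1:6)
  m <- make_fit(ids, c(1, 2, -1, -2, 1, -1))
  p <- make_fit(ids, c(1, -2, 1, -1, 2, -3), "performance")
  q <- assign_quadrants(m, p)
  typed <- tibble::tibble(
    country_id = ids,
    region = rep(c("African", "European"), 3),
    index = c(50, 60, 70, 80, 55, 65),
    country_type = c("emerging", "transitioner", "advanced", "leader",
                     "emerging", "transitioner")
  )
  rep_ <- efficiency_report(q, typed)
  expect_equal(sum(as.matrix(rep_$overall[, -1])), 6)
  # hand count: K1 high-high/emerging, K5 high-high/emerging
  hh <- rep_$overall[rep_$overall$quadrant == "high-high", ]
  expect_equal(hh$emerging, 2L)
  # per-region tables sum to the overall table
  expect_equal(sum(as.matrix(rep_$by_region[, -(1:2)])), 6)
  for (qd in rep_$overall$quadrant) {
    n_overall <- sum(as.matrix(rep_$overall[rep_$overall$quadrant == qd, -1]))
    n_regions <- sum(as.matrix(
      rep_$by_region[rep_$by_region$quadrant == qd, -(1:2)]))
    expect_equal(n_regions, n_overall)
  }
})

test_that("all-positive residual pairs concentrate in one quadrant row", {
  ids <- letters[1:5]
  q <- assign_quadrants(make_fit(ids, 1:5),
                        make_fit(ids, 5:1, "performance"))
  expect_true(all(q$quadrant == "high-high"))
})
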