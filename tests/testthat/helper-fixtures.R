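# Shared fixtures: tiny country tables built in code against the default
# catalog. No files are stored; everything is generated at test time.

catalog <- digimaturity::default_catalog()
ind_ids <- catalog$entries$id

# one country row: all 14 indicators = `value` (scalar or named overrides)
make_country <- function(country_id, region = "European", value = 50,
                         overrides = NULL, he = NA_real_, perf = NA_real_) {
  row <- tibble::tibble(country_id = country_id, region = region)
  for (id in ind_ids) row[[id]] <- value
  for (id in names(overrides)) row[[id]] <- overrides[[id]]
  row$health_expenditure <- he
  row$performance_index <- perf
  row
}

# n countries with indicator values drawn from a matrix (n x 14)
make_records <- function(values, regions = "European",
                         he = NA_real_, perf = NA_real_) {
  n <- nrow(values)
  rec <- tibble::tibble(
    country_id = sprintf("C%03d", seq_len(n)),
    region = rep_len(regions, n)
  )
  for (k in seq_along(ind_ids)) rec[[ind_ids[k]]] <- values[, k]
  rec$health_expenditure <- rep_len(he, n)
  rec$performance_index <- rep_len(perf, n)
  rec
}

# independent Spearman oracle: midranks by pairwise counting, then the
# explicit Pearson sum formula on those ranks
brute_spearman <- function(x, y) {
  brute_rank <- function(v) {
    sapply(seq_along(v), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    })
  }
  r <- brute_rank(x); s <- brute_rank(y)
  n <- length(r)
  num <- sum((r - mean(r)) * (s - mean(s)))
  den <- sqrt(sum((r - mean(r))^2) * sum((s - mean(s))^2))
  num / den
}

# independent OLS oracle: normal equations solved explicitly
brute_ols <- function(y, u) {
  n <- length(y)
  X <- cbind(1, u)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(beta0 = beta[1], beta1 = beta[2])
}
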