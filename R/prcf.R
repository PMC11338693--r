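#' Bartlett significance band for correlation coefficients
#'
#' Approximate 95% band for the correlation coefficients of a series with
#' `n` effective observations: \eqn{2/\sqrt{n}}.
#'
#' @param n Effective series length (number of growth-rate observations);
#'   must be >= 4.
#' @return Positive scalar band half-width.
#' @export
bartlett_band <- function(n) {
  if (n < 4) stop("need n >= 4 for a meaningful Bartlett band")
  2 / sqrt(n)
}

# residual-on-residual partial correlation of y with x, controlling for the
# columns of Z (ordinary least squares with intercept). Z = NULL gives the
# plain Pearson correlation.
partial_cor <- function(y, x, Z = NULL) {
  if (is.null(Z) || NCOL(Z) == 0) return(stats::cor(y, x))
  Z <- as.matrix(Z)
  ry <- stats::lm.fit(cbind(1, Z), y)$residuals
  rx <- stats::lm.fit(cbind(1, Z), x)$residuals
  stats::cor(ry, rx)
}

#' Partial rate correlation function (PRCF)
#'
#' Diagnoses the order of density-dependent feedback in a population time
#' series. With \eqn{X_t = \ln N_t} and realized growth rate
#' \eqn{R_t = X_t - X_{t-1}}, the PRCF at lag 1 is the Pearson correlation of
#' \eqn{R_t} with \eqn{X_{t-1}}; at lag \eqn{d \ge 2} it is the partial
#' correlation of \eqn{R_t} with \eqn{X_{t-d}} controlling for the
#' intermediate lags \eqn{X_{t-1}, \dots, X_{t-(d-1)}} (computed by
#' correlating the residuals of the two controlling regressions, which is
#' numerically stable for the short series typical of monitoring data). The
#' first lag whose coefficient is significantly negative by Bartlett's
#' criterion estimates the feedback order: lag 1 indicates direct density
#' dependence, lag 2 or more the delayed feedback typical of cyclic
#' dynamics.
#'
#' The series must be consecutive (one observation per time step). Zeros are
#' handled by the same policy as [growth_rates()] before logs are taken.
#'
#' @param n_t Numeric vector of non-negative abundances (one per year).
#' @param max_lag Largest lag to evaluate; default `floor(length/3)` capped
#'   at 5. Truncated with a warning if the series is too short.
#' @param zero_policy,constant Passed to the zero-handling step; see
#'   [growth_rates()]. `"drop"` is refused (it would break consecutiveness).
#' @param series_id Optional label carried into the result.
#' @return An object of class `"prcf"`: list with `series_id`, `n`
#'   (number of growth-rate observations), `max_lag`, `coefficients`
#'   (PRCF(1..max_lag)), `band` (Bartlett half-width `2/sqrt(n)`),
#'   `regression_residuals` (residuals of the OLS fit of R_t on X_{t-1}),
#'   `mean_abs_residual`, `inferred_order` (smallest lag with a significant
#'   negative coefficient, or `NA`), and `argmin_lag` (lag of the most
#'   negative coefficient).
#' @export
prcf <- function(n_t, max_lag = NULL, zero_policy = "half_min", constant = 0.5,
                 series_id = "series") {
  if (anyNA(n_t)) stop("series has gaps (NA); split into consecutive runs first")
  if (identical(zero_policy, "drop")) {
    stop("zero_policy 'drop' breaks consecutiveness; use 'half_min' or 'fixed'")
  }
  x <- log(apply_zero_policy(n_t, zero_policy, constant, label = series_id))
  T_len <- length(x)
  cap <- max(1L, min(5L, floor(T_len / 3)))
  if (is.null(max_lag)) max_lag <- cap
  # need at least 4 rate observations for the Bartlett band, and lag d
  # leaves T - d usable rows for a regression with d + 1 coefficients
  if (T_len < 5) stop("series too short for the PRCF (need length >= 5)")
  feasible <- floor((T_len - 2) / 2)
  if (max_lag > feasible) {
    warning(sprintf("series too short for max_lag = %d; truncating to %d",
                    max_lag, feasible))
    max_lag <- feasible
  }
  r_t <- diff(x)              # R_t for t = 2..T
  n_eff <- length(r_t)
  coefs <- numeric(max_lag)
  for (d in seq_len(max_lag)) {
    # rows t = d+1 .. T
    tt <- (d + 1):T_len
    y <- x[tt] - x[tt - 1]
    xd <- x[tt - d]
    Z <- if (d >= 2) sapply(1:(d - 1), function(j) x[tt - j]) else NULL
    coefs[d] <- partial_cor(y, xd, Z)
  }
  # residuals of the lag-1 rate regression R_t ~ X_{t-1}
  fit1 <- stats::lm.fit(cbind(1, x[1:(T_len - 1)]), r_t)
  band <- bartlett_band(n_eff)
  sig_neg <- which(coefs < 0 & abs(coefs) > band)
  structure(list(
    series_id = series_id,
    n = n_eff,
    max_lag = max_lag,
    coefficients = stats::setNames(coefs, paste0("lag", seq_len(max_lag))),
    band = band,
    regression_residuals = unname(fit1$residuals),
    mean_abs_residual = mean(abs(fit1$residuals)),
    inferred_order = if (length(sig_neg)) min(sig_neg) else NA_integer_,
    argmin_lag = which.min(coefs)
  ), class = "prcf")
}

#' @export
print.prcf <- function(x, ...) {
  cat(sprintf("PRCF for %s (n = %d rate observations, band = +/-%.3f)\n",
              x$series_id, x$n, x$band))
  print(round(x$coefficients, 3))
  cat(sprintf("inferred order: %s; most negative at lag %d\n",
              ifelse(is.na(x$inferred_order), "none", x$inferred_order),
              x$argmin_lag))
  invisible(x)
}

#' Summarize feedback order across many series
#'
#' Tabulates the PRCF diagnosis for a collection of series: per series the
#' inferred order (first significantly negative lag) and the lag of the most
#' negative coefficient, plus aggregate counts — in particular how many
#' series have their most negative coefficient at lag 1, the usual headline
#' statistic for direct density dependence.
#'
#' @param results List of `"prcf"` objects.
#' @return List with `per_series` (data frame: `series_id`, `n`,
#'   `inferred_order`, `argmin_lag`, `prcf1`, `significant1`),
#'   `n_series`, `n_argmin_lag1`, `count_by_order` (table over inferred
#'   orders, `NA` = none significant) and `count_by_argmin`.
#' @export
classify_feedback <- function(results) {
  if (!length(results)) stop("need at least one PRCF result")
  per <- do.call(rbind, lapply(results, function(r) {
    data.frame(series_id = r$series_id, n = r$n,
               inferred_order = r$inferred_order,
               argmin_lag = r$argmin_lag,
               prcf1 = unname(r$coefficients[1]),
               significant1 = r$coefficients[1] < 0 &&
                 abs(r$coefficients[1]) > r$band,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(
    per_series = per,
    n_series = nrow(per),
    n_argmin_lag1 = sum(per$argmin_lag == 1L),
    count_by_order = table(factor(per$inferred_order,
                                  levels = c(sort(unique(stats::na.omit(per$inferred_order)))),
                                  exclude = NULL), useNA = "ifany"),
    count_by_argmin = table(per$argmin_lag)
  )
}
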