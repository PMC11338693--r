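#' Effort-corrected snow-track abundance index
#'
#' The abundance index for one transect visit is the number of track
#' crossings divided by survey effort, where effort is transect length (km)
#' times the number of days since the last snowfall over which tracks could
#' accumulate:
#' \deqn{\mathrm{index} = \frac{\mathrm{tracks}}{\mathrm{length} \times \mathrm{days}}}
#' Units are tracks km^-1 day^-1. The index scales exactly as 1/length and
#' 1/days, so doubling either effort term halves the index.
#'
#' @param tracks Non-negative integer count of track crossings.
#' @param length_km Transect length in km; must be > 0.
#' @param days_since_snow Days since last snowfall; must be > 0.
#' @return Numeric index (vectorized over its arguments).
#' @export
abundance_index <- function(tracks, length_km, days_since_snow) {
  if (any(length_km <= 0)) stop("length_km must be > 0")
  if (any(days_since_snow <= 0)) stop("days_since_snow must be > 0")
  if (any(tracks < 0)) stop("tracks must be >= 0")
  tracks / (length_km * days_since_snow)
}

#' Cluster transects into proximity groups
#'
#' Transects are grouped by k-means on their (unique) centroid coordinates,
#' with k = round(number of unique transects / `target_group_size`). The
#' assignment depends only on location, so it is identical across years.
#' Transects are processed in `transect_id` order and the k-means seed is
#' fixed, making the assignment reproducible.
#'
#' @param transects Data frame with columns `transect_id`, `x_km`, `y_km`
#'   (additional columns, e.g. yearly records, are allowed; coordinates must
#'   be constant within a transect id).
#' @param target_group_size Desired transects per group (default 10).
#' @param seed Integer seed for k-means initialisation.
#' @return Data frame `transect_id`, `group_id` with one row per unique
#'   transect. Group ids are zero-padded labels ordered by group centre
#'   northing.
#' @export
cluster_transects <- function(transects, target_group_size = 10, seed = 1L) {
  stopifnot(all(c("transect_id", "x_km", "y_km") %in% names(transects)))
  u <- unique(transects[, c("transect_id", "x_km", "y_km")])
  u <- u[order(u$transect_id), , drop = FALSE]
  if (anyDuplicated(u$transect_id)) {
    stop("transect coordinates must be constant within transect_id")
  }
  n <- nrow(u)
  k <- max(1L, as.integer(round(n / target_group_size)))
  if (n < target_group_size || k == 1L) {
    if (n < target_group_size) {
      warning("fewer transects than target_group_size; forming a single group")
    }
    cl <- rep(1L, n)
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    km <- stats::kmeans(as.matrix(u[, c("x_km", "y_km")]), centers = k,
                        nstart = 25, iter.max = 100)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    cl <- km$cluster
  }
  # stable labels: order groups south to north by mean northing
  ord <- rank(tapply(u$y_km, cl, mean), ties.method = "first")
  lab <- sprintf("G%0*d", nchar(as.character(max(ord))), ord[as.character(cl)])
  data.frame(transect_id = u$transect_id, group_id = lab,
             stringsAsFactors = FALSE)
}

#' Per-group annual mean abundance-index series
#'
#' Averages the per-visit abundance indices of a group's member transects
#' within each year. Years in which no member transect was surveyed are
#' simply absent, which splits a group's series into consecutive runs; runs
#' are labelled `series_id = <group_id>.<run>` so that downstream analyses
#' (growth rates, PRCF) never bridge a gap.
#'
#' @param records Data frame of transect visits with columns `transect_id`,
#'   `year`, `tracks`, `length_km`, `days_since_snow`.
#' @param assignment Data frame `transect_id`, `group_id` as returned by
#'   [cluster_transects()]; must cover every record.
#' @return Data frame `group_id`, `series_id`, `year`, `mean_index`, ordered
#'   by group and year.
#' @export
group_mean_series <- function(records, assignment) {
  miss <- setdiff(records$transect_id, assignment$transect_id)
  if (length(miss)) {
    stop("assignment does not cover transect(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  idx <- abundance_index(records$tracks, records$length_km, records$days_since_snow)
  gid <- assignment$group_id[match(records$transect_id, assignment$transect_id)]
  agg <- stats::aggregate(idx, by = list(group_id = gid, year = records$year), FUN = mean)
  names(agg)[3] <- "mean_index"
  agg <- agg[order(agg$group_id, agg$year), , drop = FALSE]
  # split each group's series at year gaps into consecutive runs
  run <- unlist(lapply(split(agg$year, agg$group_id), function(yrs) {
    cumsum(c(1L, diff(yrs) != 1L))
  }), use.names = FALSE)
  agg$series_id <- paste0(agg$group_id, ".", run)
  rownames(agg) <- NULL
  agg[, c("group_id", "series_id", "year", "mean_index")]
}

# Shared zero-handling before taking logs of an index series. "half_min" adds
# half the smallest positive value in the series to every value; "fixed" adds
# `constant`; "drop" removes zero years (breaking consecutiveness, so it is
# not used ahead of the PRCF).
apply_zero_policy <- function(x, zero_policy = c("half_min", "fixed", "drop"),
                              constant = 0.5, label = "series") {
  zero_policy <- match.arg(zero_policy)
  if (all(x == 0)) stop("all-zero series: ", label)
  if (!any(x == 0)) return(x)
  switch(zero_policy,
    half_min = x + min(x[x > 0]) / 2,
    fixed = x + constant,
    drop = x[x > 0]
  )
}

#' Annual population growth rates from an index series
#'
#' The realized (instantaneous) growth rate between consecutive years is
#' \eqn{R_t = \ln(N_t / N_{t-1})}. Because group mean indices can be zero in
#' crash years, a zero-handling policy is applied to the whole series before
#' taking logs (default: add half the smallest positive value).
#'
#' @param series Data frame for a single consecutive run with columns `year`
#'   (strictly increasing by 1) and `mean_index`, e.g. one `series_id` slice
#'   of [group_mean_series()] output.
#' @param zero_policy One of `"half_min"`, `"fixed"`, `"drop"`.
#' @param constant Additive constant for `zero_policy = "fixed"`.
#' @return The input with a `growth_rate` column; `NA` for the first year.
#' @export
growth_rates <- function(series, zero_policy = "half_min", constant = 0.5) {
  stopifnot(all(c("year", "mean_index") %in% names(series)))
  series <- series[order(series$year), , drop = FALSE]
  if (nrow(series) >= 2 && any(diff(series$year) != 1)) {
    stop("growth_rates requires a consecutive run of years; split at gaps first")
  }
  n_adj <- apply_zero_policy(series$mean_index, zero_policy, constant,
                             label = if (!is.null(series$series_id)) series$series_id[1] else "series")
  if (zero_policy == "drop" && length(n_adj) != nrow(series)) {
    series <- series[series$mean_index > 0, , drop = FALSE]
  }
  lx <- log(n_adj)
  series$growth_rate <- c(NA_real_, diff(lx))
  series
}

#' Filter series runs by minimum length
#'
#' Keeps only consecutive runs with strictly more than `min_steps`
#' observations (a run of exactly `min_steps` years is excluded).
#'
#' @param series Data frame with a `series_id` column (e.g.
#'   [group_mean_series()] output).
#' @param min_steps Threshold; default 3, so runs need >= 4 years.
#' @return The filtered data frame (possibly zero rows).
#' @export
eligible_series <- function(series, min_steps = 3) {
  if (nrow(series) == 0) return(series)
  len <- table(series$series_id)
  keep <- names(len)[len > min_steps]
  out <- series[series$series_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
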