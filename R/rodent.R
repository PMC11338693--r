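#' Municipality-level microtine rodent abundance index
#'
#' The index for a municipality-year is the proportion of rodent survey line
#' transects on which live microtine rodents were detected. Detections are
#' presence/absence per line, so the index lies in [0, 1] and is a
#' conservative relative abundance proxy.
#'
#' @param surveys Data frame with columns `municipality_id`, `year`,
#'   `lines_total` (>= 1) and `lines_with_detection`
#'   (0 <= detections <= total). Extra columns (e.g. centroids) are carried
#'   through.
#' @return The input with an `index` column appended.
#' @export
municipality_index <- function(surveys) {
  need <- c("municipality_id", "year", "lines_total", "lines_with_detection")
  stopifnot(all(need %in% names(surveys)))
  if (any(surveys$lines_total < 1)) stop("lines_total must be >= 1")
  if (any(surveys$lines_with_detection < 0 |
          surveys$lines_with_detection > surveys$lines_total)) {
    stop("lines_with_detection must lie in [0, lines_total]")
  }
  surveys$index <- surveys$lines_with_detection / surveys$lines_total
  surveys
}

#' Inverse-distance-weighted interpolation onto a raster
#'
#' Each cell centre takes the weighted mean of the `n_neighbors` nearest data
#' points, with weights \eqn{w_i = d_i^{-p}}. A cell whose centre coincides
#' with a data point (distance < 1e-9 km) takes that point's value exactly,
#' making IDW an exact interpolator; predicted values never leave the range
#' of the data.
#'
#' @param points Data frame with columns `x_km`, `y_km`, `value`.
#' @param grid A [marten_raster()] defining the output geometry (its values
#'   are ignored).
#' @param power Positive IDW exponent; default 2 (the common GIS default).
#' @param n_neighbors Number of nearest points used per cell; default 12,
#'   capped at the number of points.
#' @return A [marten_raster()] with interpolated values.
#' @export
idw_interpolate <- function(points, grid, power = 2, n_neighbors = 12) {
  stopifnot(all(c("x_km", "y_km", "value") %in% names(points)))
  if (nrow(points) == 0) stop("need at least one data point")
  if (power <= 0) stop("power must be > 0")
  k <- min(n_neighbors, nrow(points))
  cc <- raster_cell_centres(grid)
  d2 <- outer(cc$x_km, points$x_km, "-")^2 + outer(cc$y_km, points$y_km, "-")^2
  vals <- apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    d <- sqrt(row[nn])
    if (d[1] < 1e-9) return(points$value[nn[1]])
    w <- d^(-power)
    sum(w * points$value[nn]) / sum(w)
  })
  out <- grid
  out$values <- matrix(vals, nrow = grid$nrow, ncol = grid$ncol, byrow = TRUE)
  out
}

#' Validate the rodent presence index against snap-trap catches
#'
#' Pearson correlation between a municipality's annual presence-proportion
#' index and an independent snap-trap series (catches per 100 trap-days),
#' with the two-sided p-value from the t transform with n - 2 degrees of
#' freedom.
#'
#' @param index_series,trap_series Paired numeric vectors over the same
#'   years, length >= 3, no missing values.
#' @return List with `r`, `r_squared`, `p_value`, `n`.
#' @export
validate_against_traps <- function(index_series, trap_series) {
  stopifnot(length(index_series) == length(trap_series))
  if (anyNA(index_series) || anyNA(trap_series)) stop("series must be complete")
  n <- length(index_series)
  if (n < 3) stop("need at least 3 paired years")
  if (stats::sd(index_series) == 0 || stats::sd(trap_series) == 0) {
    stop("zero variance in one of the series")
  }
  r <- stats::cor(index_series, trap_series)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, r_squared = r^2,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Annual rodent-index rasters and transect extractions
#'
#' Convenience wrapper for the per-year workflow: compute the municipality
#' presence index, interpolate it with IDW from the municipality centroids,
#' and extract the surface value at each transect centroid. The extracted
#' value for survey year `t` is matched downstream to marten surveys of
#' January year `t + 1` (prey abundance the previous autumn).
#'
#' @param surveys Rodent survey data frame (see [municipality_index()]) with
#'   centroid columns `centroid_x_km`, `centroid_y_km`.
#' @param transects Data frame with `transect_id`, `x_km`, `y_km` (unique
#'   transects).
#' @param grid A [marten_raster()] grid geometry.
#' @param power,n_neighbors Passed to [idw_interpolate()].
#' @return List with `rasters` (named by year) and `extractions` (data frame
#'   `transect_id`, `rodent_year`, `rodent_index`).
#' @export
rodent_surfaces <- function(surveys, transects, grid, power = 2, n_neighbors = 12) {
  surveys <- municipality_index(surveys)
  years <- sort(unique(surveys$year))
  rasters <- list()
  ext <- list()
  for (yr in years) {
    s <- surveys[surveys$year == yr, , drop = FALSE]
    pts <- data.frame(x_km = s$centroid_x_km, y_km = s$centroid_y_km,
                      value = s$index)
    ras <- idw_interpolate(pts, grid, power = power, n_neighbors = n_neighbors)
    rasters[[as.character(yr)]] <- ras
    ext[[as.character(yr)]] <- data.frame(
      transect_id = transects$transect_id,
      rodent_year = yr,
      rodent_index = extract_at(ras, transects$x_km, transects$y_km),
      stringsAsFactors = FALSE
    )
  }
  list(rasters = rasters, extractions = do.call(rbind, ext))
}
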