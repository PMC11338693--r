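#' Mean elevation within home-range-sized grid cells
#'
#' Overlays the study region with a square grid whose cell area matches an
#' average pine marten home range (7.17 km^2, side ~2.678 km), computes the
#' mean of the DEM pixels whose centres fall in each cell, and assigns every
#' transect the mean of its containing cell. Smoothing elevation to the
#' home-range scale matches the scale at which the animal experiences
#' topography rather than the 50-m pixel.
#'
#' @param dem A [marten_raster()] digital elevation model (metres).
#' @param centroids Data frame with `x_km`, `y_km` transect centroids; must
#'   lie within the DEM extent.
#' @param cell_area_km2 Area of the overlay cell; default 7.17.
#' @return Numeric vector of mean elevations, one per centroid row.
#' @export
mean_elevation_at <- function(dem, centroids, cell_area_km2 = 7.17) {
  stopifnot(cell_area_km2 > 0)
  side <- sqrt(cell_area_km2)
  xmax <- dem$xmin + dem$ncol * dem$dx
  ymax <- dem$ymin + dem$nrow * dem$dy
  if (any(centroids$x_km < dem$xmin | centroids$x_km >= xmax |
          centroids$y_km < dem$ymin | centroids$y_km >= ymax)) {
    stop("transect centroid outside DEM extent")
  }
  # overlay grid anchored at the DEM's south-west corner
  cellkey <- function(x, y) {
    paste(floor((x - dem$xmin) / side), floor((y - dem$ymin) / side))
  }
  px <- raster_cell_centres(dem)
  px$value <- as.vector(t(dem$values))      # row-major from NW, matches centres
  px <- px[!is.na(px$value), , drop = FALSE]
  means <- tapply(px$value, cellkey(px$x_km, px$y_km), mean)
  out <- means[cellkey(centroids$x_km, centroids$y_km)]
  if (anyNA(out)) stop("overlay cell without DEM pixels under a centroid")
  as.numeric(out)
}

#' Size-weighted Gaussian kernel density of habitat patches
#'
#' Evaluates \eqn{\rho(u) = \sum_i s_i \, K_h(\lVert u - c_i \rVert)} on a
#' raster grid, where \eqn{c_i} are patch geometric centres, \eqn{s_i} patch
#' sizes (area-like weights) and \eqn{K_h} an isotropic planar Gaussian
#' kernel with bandwidth `bandwidth_km`. The surface integrates to the total
#' patch size, so values are size per km^2.
#'
#' @param patches Data frame with `x_km`, `y_km`, `size` (> 0). A `class`
#'   column may be present; filter before calling.
#' @param grid A [marten_raster()] geometry.
#' @param bandwidth_km Gaussian kernel SD in km; default 5.
#' @return A [marten_raster()] of densities.
#' @export
patch_kernel_density <- function(patches, grid, bandwidth_km = 5) {
  stopifnot(all(c("x_km", "y_km", "size") %in% names(patches)))
  if (nrow(patches) == 0) stop("need at least one patch")
  if (any(patches$size <= 0)) stop("patch sizes must be > 0")
  if (bandwidth_km <= 0) stop("bandwidth must be > 0")
  h2 <- bandwidth_km^2
  cc <- raster_cell_centres(grid)
  d2 <- outer(cc$x_km, patches$x_km, "-")^2 + outer(cc$y_km, patches$y_km, "-")^2
  dens <- as.vector(exp(-d2 / (2 * h2)) %*% patches$size) / (2 * pi * h2)
  out <- grid
  out$values <- matrix(dens, nrow = grid$nrow, ncol = grid$ncol, byrow = TRUE)
  out
}

#' z-transform a covariate
#'
#' Centres and scales to sample mean 0, SD 1 (denominator n - 1), keeping
#' the constants for the inverse transform.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return List with `z`, `center`, `scale`.
#' @export
z_standardize <- function(values) {
  if (anyNA(values)) stop("missing values in covariate")
  m <- mean(values)
  s <- stats::sd(values)
  if (length(values) < 2 || s == 0) stop("covariate has zero variance")
  list(z = (values - m) / s, center = m, scale = s)
}

#' Pairwise collinearity screen
#'
#' Pearson correlation matrix of the continuous covariates with flags for
#' any pair at or above the threshold (default |r| >= 0.6, the usual rule of
#' thumb below which collinearity is considered tolerable in these models).
#'
#' @param table Data frame of numeric covariate columns, >= 3 rows.
#' @param threshold Flagging threshold on |r|.
#' @return List with `correlations` (matrix) and `flagged` (data frame
#'   `var1`, `var2`, `r`; zero rows when the screen passes).
#' @export
collinearity_screen <- function(table, threshold = 0.6) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[, num, drop = FALSE]
  if (nrow(table) < 3) stop("need at least 3 rows")
  cm <- stats::cor(as.matrix(table))
  pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(
    var1 = rownames(cm)[pairs[, 1]],
    var2 = colnames(cm)[pairs[, 2]],
    r = cm[pairs],
    stringsAsFactors = FALSE
  )
  list(correlations = cm, flagged = flagged)
}
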