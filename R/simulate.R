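#' Configuration for a synthetic monitoring study system
#'
#' Bundles every parameter of the synthetic world generator. Defaults emulate
#' the boreal study system the package targets: a ~28,000 km^2 region with a
#' south-to-north elevation/productivity gradient, 19 municipalities, 593
#' snow transects surveyed each January over 2003-2014 (each transect
#' surveyed in a given winter with probability `survey_prob`, matching an
#' annual mean of ~278 surveyed transects), cyclic microtine rodent dynamics
#' whose amplitude grows with elevation, autumn rodent line-transect surveys
#' in 2006-2013, and marten track counts generated from a negative-binomial
#' model with log-effort offsets.
#'
#' `true_delta` defaults to the coefficient magnitudes reported for boreal
#' pine marten abundance (positive effects of prey, elevation, snow and
#' mature spruce density; a negative effect of agricultural density), so the
#' default world reproduces effects of realistic size. The rodent
#' autoregression defaults to a second-order process with a 3-5 year cycle.
#'
#' @param region_width_km,region_height_km Region dimensions (km).
#' @param n_municipalities Number of municipalities (centroids drawn
#'   uniformly; membership by nearest centroid, i.e. Voronoi cells).
#' @param n_transects Number of unique snow transects.
#' @param years Inclusive integer range of marten survey years (January).
#' @param rodent_years Autumn rodent survey years; default runs from the
#'   fourth study year to the year before the last, reproducing the 2006-2013
#'   window under the default `years`.
#' @param survey_prob Probability a transect is surveyed in a given year.
#' @param elevation_base_m,elevation_gradient Elevation at the southern edge
#'   and its increase per km northing (m/km).
#' @param elevation_noise_sd SD (m) of smooth terrain relief added to the
#'   gradient.
#' @param rodent_ar_params Named or positional `(a0, b1, b2)` log-scale
#'   autoregression coefficients of the rodent dynamics (see
#'   [simulate_population_series()]).
#' @param rodent_noise_sd SD of the shared (regionally synchronous) process
#'   noise on the log scale.
#' @param rodent_local_sd SD of municipality-level log-scale noise around the
#'   shared cycle.
#' @param amplitude_elevation_slope Log-linear scaling of cycle amplitude
#'   with standardized municipality elevation: amplitude multiplier
#'   `exp(slope * z_elev)`.
#' @param detection_slope Logistic slope of per-line rodent detection
#'   probability versus centred log rodent abundance.
#' @param n_lines_per_municipality Rodent survey lines per municipality-year.
#' @param true_delta Length-7 vector: abundance-model intercept and slopes
#'   (rodent, elevation, rodent x elevation, snow, spruce, agri) on
#'   standardized covariates.
#' @param nb_dispersion Negative-binomial dispersion theta (> 0); variance is
#'   `mu + mu^2/theta`.
#' @param year_effect_sd SD of the year random intercept in the track model.
#' @param group_effect_sd SD of an optional group-level intercept added to
#'   the track model; the default 0 keeps the generating process identical to
#'   the abundance model (no group term), while positive values let users
#'   study robustness to unmodelled spatial heterogeneity.
#' @param length_mean_km,length_sd_km Transect length distribution
#'   (truncated normal, > 0.5 km); defaults 2.93 and 0.51.
#' @param days_mean,days_sd Days-since-snowfall distribution (truncated
#'   normal, >= 1); defaults 3.70 and 1.65.
#' @param snow_base_cm,snow_elev_slope,snow_noise_sd Snow depth model:
#'   `base + slope * elevation_m + noise`, floored at 0.
#' @param n_spruce_patches,n_agri_patches Numbers of mature-spruce and
#'   agricultural patches; agricultural patches concentrate in the southern
#'   lowlands.
#' @param dem_cell_km DEM pixel size (km).
#' @param raster_dx_km,raster_dy_km Rodent interpolation grid resolution;
#'   defaults 1.9 x 3.0 km.
#' @param seed Integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(region_width_km = 140, region_height_km = 200,
                       n_municipalities = 19, n_transects = 593,
                       years = 2003:2014, rodent_years = NULL,
                       survey_prob = 0.47,
                       elevation_base_m = 200, elevation_gradient = 4,
                       elevation_noise_sd = 150,
                       rodent_ar_params = c(a0 = 1.65, b1 = -0.5, b2 = -0.6),
                       rodent_noise_sd = 0.2, rodent_local_sd = 0.05,
                       amplitude_elevation_slope = 0.5,
                       detection_slope = 1.5, n_lines_per_municipality = 82,
                       true_delta = c(intercept = -3.4, rodent = 0.566,
                                      elevation = 0.425,
                                      rodent_x_elevation = 0.160,
                                      snow = 0.463, spruce = 0.369,
                                      agri = -0.129),
                       nb_dispersion = 2, year_effect_sd = 0.3,
                       group_effect_sd = 0,
                       length_mean_km = 2.93, length_sd_km = 0.51,
                       days_mean = 3.70, days_sd = 1.65,
                       snow_base_cm = 30, snow_elev_slope = 0.03,
                       snow_noise_sd = 12,
                       n_spruce_patches = 150, n_agri_patches = 120,
                       dem_cell_km = 1, raster_dx_km = 1.9, raster_dy_km = 3.0,
                       seed = 1L) {
  years <- sort(unique(as.integer(years)))
  if (length(years) < 5) stop("years must span at least 5 years")
  if (is.null(rodent_years)) {
    rodent_years <- (min(years) + 3):(max(years) - 1)
  }
  stopifnot(region_width_km > 0, region_height_km > 0,
            n_transects >= n_municipalities,
            rodent_noise_sd > 0, rodent_local_sd >= 0, nb_dispersion > 0,
            year_effect_sd >= 0, group_effect_sd >= 0,
            length(true_delta) == 7)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Simulate a Gompertz-type log-linear population series
#'
#' Simulates log abundance under the discrete-time log-linear feedback model
#' \deqn{x_t = a_0 + (1 + b_1) x_{t-1} + b_2 x_{t-2} + \varepsilon_t,
#'   \quad \varepsilon_t \sim N(0, \sigma^2),}
#' the standard density-dependence skeleton for which the PRCF diagnoses the
#' feedback order: `b1 < 0` with `b2 = 0` gives direct (first-order) density
#' dependence, while a sufficiently negative `b2` produces the delayed
#' feedback of cyclic dynamics (periods of 3-6 years for the defaults used
#' here).
#'
#' @param order 1 or 2; for order 1, `b2` must be 0.
#' @param params Numeric `(a0, b1, b2)` (a length-2 vector is taken as
#'   `(a0, b1)` with `b2 = 0`).
#' @param noise_sd Process noise SD (>= 0).
#' @param length Series length (>= 10).
#' @param seed Integer seed; the series is deterministic given it. `NULL`
#'   uses the current RNG stream.
#' @param x0 Starting value(s); defaults to the deterministic equilibrium
#'   `a0 / (-b1 - b2)` when feedback is present, else 0.
#' @return Numeric vector `x[1..length]` of log abundances.
#' @export
simulate_population_series <- function(order = 1, params, noise_sd, length,
                                       seed = NULL, x0 = NULL) {
  if (length < 10) stop("length must be >= 10")
  params <- unname(params)
  a0 <- params[1]; b1 <- params[2]
  b2 <- if (base::length(params) >= 3) params[3] else 0
  if (!all(is.finite(c(a0, b1, b2, noise_sd)))) stop("non-finite parameters")
  if (order == 1 && b2 != 0) stop("order 1 requires b2 = 0")
  # characteristic roots of x_t = (1+b1) x_{t-1} + b2 x_{t-2}
  roots <- polyroot(c(-b2, -(1 + b1), 1))
  if (any(Mod(roots) >= 1)) {
    warning("feedback parameters imply a non-stationary (divergent) process")
  }
  if (is.null(x0)) {
    denom <- -(b1 + b2)
    x0 <- if (abs(denom) > 1e-12) a0 / denom else 0
  }
  x0 <- rep(x0, length.out = 2)
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(length, 0, noise_sd)
  x <- numeric(length)
  xm1 <- x0[2]; xm2 <- x0[1]
  for (t in seq_len(length)) {
    x[t] <- a0 + (1 + b1) * xm1 + b2 * xm2 + eps[t]
    xm2 <- xm1; xm1 <- x[t]
  }
  x
}

# truncated-normal draw by resampling (moments are the *parent* moments, per
# the survey effort summaries the generator emulates)
rtruncnorm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

#' Build a complete synthetic study system
#'
#' Generates, from a [sim_config()], everything the analysis pipeline
#' consumes: a DEM with a south-north gradient plus smooth relief;
#' municipality centroids (membership = nearest centroid, i.e. a Voronoi
#' partition); per-municipality cyclic rodent log-abundance series sharing a
#' regionally synchronous cycle whose amplitude scales with elevation;
#' a transect network with truncated-normal survey effort; spruce and
#' agricultural patches (the latter concentrated in the southern lowlands);
#' snow depths increasing with elevation; autumn rodent line-transect surveys
#' with a snap-trap validation series; and negative-binomial marten track
#' counts generated from the abundance model with known coefficients.
#'
#' The generating covariates actually used to simulate the counts are kept
#' in `truth` (standardized design matrix and row key), so parameter
#' recovery can be checked without the attenuation introduced by the
#' pipeline's own raster-based covariate reconstruction.
#'
#' @param config A [sim_config()].
#' @return A list of class `"marten_world"` with elements `config`,
#'   `transects` (visit-level records), `municipalities`, `rodent_truth`,
#'   `rodent_surveys`, `snap_traps`, `patches`, `elevation` (a
#'   [marten_raster()]) and `truth`.
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$region_width_km <= 0 || cfg$region_height_km <= 0) {
    stop("degenerate region")
  }
  set.seed(cfg$seed)

  ## --- municipalities ------------------------------------------------
  mun <- data.frame(
    municipality_id = sprintf("M%02d", seq_len(cfg$n_municipalities)),
    centroid_x_km = stats::runif(cfg$n_municipalities, 0, cfg$region_width_km),
    centroid_y_km = stats::runif(cfg$n_municipalities, 0, cfg$region_height_km),
    stringsAsFactors = FALSE
  )
  mun$elevation_m <- cfg$elevation_base_m +
    cfg$elevation_gradient * mun$centroid_y_km
  mun$z_elev <- if (cfg$n_municipalities > 1) {
    (mun$elevation_m - mean(mun$elevation_m)) / stats::sd(mun$elevation_m)
  } else 0

  ## --- elevation model: gradient + smooth random relief --------------
  n_hills <- 20
  hills <- data.frame(
    x = stats::runif(n_hills, 0, cfg$region_width_km),
    y = stats::runif(n_hills, 0, cfg$region_height_km),
    amp = stats::rnorm(n_hills, 0, cfg$elevation_noise_sd),
    width = stats::runif(n_hills, 8, 25)
  )
  elev_fun <- function(x, y) {
    base <- cfg$elevation_base_m + cfg$elevation_gradient * y
    rel <- rep(0, length(x))
    for (i in seq_len(n_hills)) {
      d2 <- (x - hills$x[i])^2 + (y - hills$y[i])^2
      rel <- rel + hills$amp[i] * exp(-d2 / (2 * hills$width[i]^2))
    }
    pmax(0, base + rel)
  }
  dem <- marten_raster(0, 0, cfg$dem_cell_km, cfg$dem_cell_km,
                       ncol = ceiling(cfg$region_width_km / cfg$dem_cell_km),
                       nrow = ceiling(cfg$region_height_km / cfg$dem_cell_km))
  cc <- raster_cell_centres(dem)
  dem$values <- matrix(elev_fun(cc$x_km, cc$y_km),
                       nrow = dem$nrow, ncol = dem$ncol, byrow = TRUE)

  ## --- rodent dynamics ----------------------------------------------
  rodent_year_range <- (min(cfg$years) - 1):max(cfg$years)
  n_ry <- length(rodent_year_range)
  a0 <- unname(cfg$rodent_ar_params[1]); b1 <- unname(cfg$rodent_ar_params[2])
  b2 <- unname(cfg$rodent_ar_params[3])
  eq <- a0 / (-(b1 + b2))
  burn <- 20
  regional <- simulate_population_series(
    order = 2, params = c(a0, b1, b2), noise_sd = cfg$rodent_noise_sd,
    length = n_ry + burn, seed = cfg$seed + 101L
  )[burn + seq_len(n_ry)]
  dev <- regional - eq
  set.seed(cfg$seed + 102L)
  amp <- exp(cfg$amplitude_elevation_slope * mun$z_elev)
  rodent_truth <- do.call(rbind, lapply(seq_len(cfg$n_municipalities), function(m) {
    data.frame(municipality_id = mun$municipality_id[m],
               year = rodent_year_range,
               log_abundance = eq + amp[m] * dev +
                 stats::rnorm(n_ry, 0, cfg$rodent_local_sd),
               stringsAsFactors = FALSE)
  }))

  ## --- transect network ----------------------------------------------
  set.seed(cfg$seed + 103L)
  loc <- data.frame(
    transect_id = sprintf("T%04d", seq_len(cfg$n_transects)),
    x_km = stats::runif(cfg$n_transects, 0, cfg$region_width_km),
    y_km = stats::runif(cfg$n_transects, 0, cfg$region_height_km),
    length_km = rtruncnorm(cfg$n_transects, cfg$length_mean_km,
                           cfg$length_sd_km, lower = 0.5),
    stringsAsFactors = FALSE
  )
  d2m <- outer(loc$x_km, mun$centroid_x_km, "-")^2 +
    outer(loc$y_km, mun$centroid_y_km, "-")^2
  loc$municipality_id <- mun$municipality_id[max.col(-d2m)]

  visits <- expand.grid(transect_id = loc$transect_id, year = cfg$years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  visits <- visits[stats::runif(nrow(visits)) < cfg$survey_prob, , drop = FALSE]
  # every transect contributes at least one visit
  missing_t <- setdiff(loc$transect_id, visits$transect_id)
  if (length(missing_t)) {
    visits <- rbind(visits, data.frame(
      transect_id = missing_t,
      year = sample(cfg$years, length(missing_t), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  visits <- merge(visits, loc, by = "transect_id")
  visits <- visits[order(visits$transect_id, visits$year), , drop = FALSE]
  visits$days_since_snow <- rtruncnorm(nrow(visits), cfg$days_mean,
                                       cfg$days_sd, lower = 1)
  elev_cells <- mean_elevation_at(dem, visits)
  visits$elevation_m <- elev_cells
  visits$snow_cm <- pmax(0, cfg$snow_base_cm +
                           cfg$snow_elev_slope * visits$elevation_m +
                           stats::rnorm(nrow(visits), 0, cfg$snow_noise_sd))

  ## --- habitat patches ------------------------------------------------
  set.seed(cfg$seed + 104L)
  patches <- rbind(
    data.frame(class = "spruce",
               x_km = stats::runif(cfg$n_spruce_patches, 0, cfg$region_width_km),
               y_km = stats::runif(cfg$n_spruce_patches, 0, cfg$region_height_km),
               size = exp(stats::rnorm(cfg$n_spruce_patches, 0, 0.5)),
               stringsAsFactors = FALSE),
    data.frame(class = "agriculture",
               x_km = stats::runif(cfg$n_agri_patches, 0, cfg$region_width_km),
               y_km = cfg$region_height_km *
                 stats::rbeta(cfg$n_agri_patches, 1.3, 3.5),
               size = exp(stats::rnorm(cfg$n_agri_patches, 0.5, 0.5)),
               stringsAsFactors = FALSE)
  )

  world <- structure(list(
    config = cfg, transects = visits, municipalities = mun,
    rodent_truth = rodent_truth, patches = patches, elevation = dem,
    truth = list(equilibrium_log_abundance = eq,
                 amplitude_multiplier = stats::setNames(amp, mun$municipality_id))
  ), class = "marten_world")

  world <- simulate_rodent_surveys(world,
                                   n_lines_per_municipality = cfg$n_lines_per_municipality,
                                   detection_slope = cfg$detection_slope,
                                   seed = cfg$seed + 105L)
  world <- simulate_marten_tracks(world, true_delta = cfg$true_delta,
                                  nb_dispersion = cfg$nb_dispersion,
                                  year_effect_sd = cfg$year_effect_sd,
                                  group_effect_sd = cfg$group_effect_sd,
                                  seed = cfg$seed + 106L)
  world
}

#' @export
print.marten_world <- function(x, ...) {
  cat(sprintf("<marten_world> %d transects, %d visits over %d-%d, %d municipalities\n",
              length(unique(x$transects$transect_id)), nrow(x$transects),
              min(x$config$years), max(x$config$years),
              nrow(x$municipalities)))
  invisible(x)
}

# standardized design matrix for the abundance model from world components;
# rows are the visit records with a lagged rodent value available.
abundance_design <- function(world, rodent_values = NULL) {
  v <- world$transects
  rt <- world$rodent_truth
  if (is.null(rodent_values)) {
    key <- paste(v$municipality_id, v$year - 1L)
    rodent_values <- rt$log_abundance[match(key, paste(rt$municipality_id, rt$year))]
  }
  keep <- !is.na(rodent_values)
  v <- v[keep, , drop = FALSE]
  rodent_values <- rodent_values[keep]
  spruce <- kernel_density_at(world$patches[world$patches$class == "spruce", ],
                              v$x_km, v$y_km)
  agri <- kernel_density_at(world$patches[world$patches$class == "agriculture", ],
                            v$x_km, v$y_km)
  raw <- data.frame(rodent = rodent_values, elevation = v$elevation_m,
                    snow = v$snow_cm, spruce = spruce, agri = agri)
  z <- as.data.frame(lapply(raw, function(col) z_standardize(col)$z))
  Z <- cbind(rodent = z$rodent, elevation = z$elevation,
             rodent_x_elevation = z$rodent * z$elevation,
             snow = z$snow, spruce = z$spruce, agri = z$agri)
  list(rows = v, Z = Z, raw = raw)
}

# exact kernel-density evaluation at points (same kernel as
# patch_kernel_density, default 5 km bandwidth)
kernel_density_at <- function(patches, x, y, bandwidth_km = 5) {
  h2 <- bandwidth_km^2
  d2 <- outer(x, patches$x_km, "-")^2 + outer(y, patches$y_km, "-")^2
  as.vector(exp(-d2 / (2 * h2)) %*% patches$size) / (2 * pi * h2)
}

#' Simulate negative-binomial marten track counts
#'
#' Draws track counts for every transect visit from the abundance model used
#' downstream: \eqn{y \sim \mathrm{NB}(\mu, \theta)} with
#' \eqn{\log \mu = \log(\mathrm{length}) + \log(\mathrm{days}) + \delta_0 +
#' \delta^\top z + v_{year}}, where \eqn{z} are the standardized covariates
#' (lagged rodent abundance, elevation, their interaction, snow depth,
#' spruce density, agricultural density) and
#' \eqn{v_{year} \sim N(0, \sigma_y^2)}. Realized year (and optional group)
#' effects are centred to mean zero so the intercept is a well-defined
#' recovery target. Visits in years without a lagged rodent value get `NA`
#' counts (they fall outside the generating model).
#'
#' @param world A `"marten_world"` (tracks are overwritten).
#' @param true_delta Length-7 coefficient vector (intercept first).
#' @param nb_dispersion Theta > 0; `Inf` gives the Poisson limit.
#' @param year_effect_sd,group_effect_sd Random-intercept SDs.
#' @param seed Integer seed.
#' @return The world with `transects$tracks` filled and
#'   `truth$delta`, `truth$theta`, `truth$v_year`, `truth$design` set.
#' @export
simulate_marten_tracks <- function(world, true_delta, nb_dispersion,
                                   year_effect_sd = 0, group_effect_sd = 0,
                                   seed = 1L) {
  stopifnot(length(true_delta) == 7)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  des <- abundance_design(world)
  v <- des$rows
  if (nrow(v) == 0) stop("no visits with a lagged rodent covariate")
  set.seed(seed)
  yrs <- sort(unique(v$year))
  v_year <- stats::rnorm(length(yrs), 0, year_effect_sd)
  v_year <- stats::setNames(v_year - mean(v_year), yrs)
  u_mun <- 0
  if (group_effect_sd > 0) {
    ids <- world$municipalities$municipality_id
    u <- stats::rnorm(length(ids), 0, group_effect_sd)
    u_mun <- stats::setNames(u - mean(u), ids)
  }
  eta <- log(v$length_km) + log(v$days_since_snow) +
    true_delta[1] + as.vector(des$Z %*% true_delta[-1]) +
    v_year[as.character(v$year)] +
    (if (group_effect_sd > 0) u_mun[v$municipality_id] else 0)
  mu <- exp(eta)
  counts <- if (is.finite(nb_dispersion)) {
    stats::rnbinom(length(mu), mu = mu, size = nb_dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  key_all <- paste(world$transects$transect_id, world$transects$year)
  key_v <- paste(v$transect_id, v$year)
  world$transects$tracks <- NA_integer_
  world$transects$tracks[match(key_v, key_all)] <- counts
  world$truth$delta <- true_delta
  world$truth$theta <- nb_dispersion
  world$truth$v_year <- v_year
  world$truth$design <- des
  world
}

#' Simulate autumn rodent line-transect surveys and snap-trap catches
#'
#' For each municipality and rodent survey year, each of
#' `n_lines_per_municipality` line transects independently detects rodent
#' presence with probability
#' `plogis(detection_slope * (x_mt - mean_t(x_m)))`, a logistic link between
#' log abundance and the chance a walked line encounters a live rodent.
#' A snap-trap validation series (catches per 100 trap-days) is generated
#' for the highest-elevation municipality — where cycle amplitude, and hence
#' the validation signal, is strongest, matching the mountain-area trapping
#' programmes such series come from — as a noisy exponential transform of
#' its true log abundance.
#'
#' @param world A `"marten_world"`.
#' @param n_lines_per_municipality Lines per municipality-year (>= 1).
#' @param detection_slope Logistic slope (0 gives detection probability 0.5
#'   everywhere).
#' @param seed Integer seed.
#' @param snap_trap_scale Expected catches per 100 trap-days at the average
#'   abundance of the designated municipality.
#' @param snap_trap_noise_sd Log-scale SD of the snap-trap observation noise.
#' @return The world with `rodent_surveys` (municipality_id, year,
#'   lines_total, lines_with_detection, centroid coordinates) and
#'   `snap_traps` (year, catches_per_100td) set.
#' @export
simulate_rodent_surveys <- function(world, n_lines_per_municipality = 82,
                                    detection_slope = 1.5, seed = 1L,
                                    snap_trap_scale = 5,
                                    snap_trap_noise_sd = 0.15) {
  if (n_lines_per_municipality < 1) stop("need at least one line per municipality")
  cfg <- world$config
  rt <- world$rodent_truth
  rt <- rt[rt$year %in% cfg$rodent_years, , drop = FALSE]
  set.seed(seed)
  surveys <- do.call(rbind, lapply(split(rt, rt$municipality_id), function(d) {
    p <- stats::plogis(detection_slope * (d$log_abundance - mean(d$log_abundance)))
    data.frame(municipality_id = d$municipality_id, year = d$year,
               lines_total = n_lines_per_municipality,
               lines_with_detection = stats::rbinom(nrow(d),
                                                    n_lines_per_municipality, p),
               stringsAsFactors = FALSE)
  }))
  rownames(surveys) <- NULL
  mi <- match(surveys$municipality_id, world$municipalities$municipality_id)
  surveys$centroid_x_km <- world$municipalities$centroid_x_km[mi]
  surveys$centroid_y_km <- world$municipalities$centroid_y_km[mi]
  world$rodent_surveys <- surveys

  target <- world$municipalities$municipality_id[
    which.max(world$municipalities$elevation_m)]
  d <- rt[rt$municipality_id == target, , drop = FALSE]
  world$snap_traps <- data.frame(
    municipality_id = target, year = d$year,
    catches_per_100td = snap_trap_scale *
      exp(d$log_abundance - mean(d$log_abundance) +
            stats::rnorm(nrow(d), 0, snap_trap_noise_sd)),
    stringsAsFactors = FALSE
  )
  world
}

#' Write a synthetic world to plain-text files
#'
#' Writes `transects.csv`, `municipalities.geojson` (centroid points),
#' `rodent_surveys.csv`, `snap_traps.csv`, `patches.csv`, `elevation.asc`
#' and `truth.yaml` under `dir`.
#'
#' @param world A `"marten_world"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- world$transects[, c("transect_id", "year", "x_km", "y_km", "length_km",
                            "days_since_snow", "tracks", "snow_cm",
                            "municipality_id")]
  utils::write.csv(tr, file.path(dir, "transects.csv"), row.names = FALSE)
  utils::write.csv(world$rodent_surveys, file.path(dir, "rodent_surveys.csv"),
                   row.names = FALSE)
  utils::write.csv(world$snap_traps, file.path(dir, "snap_traps.csv"),
                   row.names = FALSE)
  utils::write.csv(world$patches, file.path(dir, "patches.csv"),
                   row.names = FALSE)
  write_asc(world$elevation, file.path(dir, "elevation.asc"))
  feat <- lapply(seq_len(nrow(world$municipalities)), function(i) {
    m <- world$municipalities[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(m$centroid_x_km, m$centroid_y_km)),
         properties = list(municipality_id = m$municipality_id,
                           elevation_m = m$elevation_m))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       file.path(dir, "municipalities.geojson"),
                       auto_unbox = TRUE, digits = NA)
  truth <- list(seed = world$config$seed,
                true_delta = as.list(world$config$true_delta),
                nb_dispersion = world$config$nb_dispersion,
                year_effect_sd = world$config$year_effect_sd,
                rodent_ar_params = as.list(world$config$rodent_ar_params),
                equilibrium_log_abundance = world$truth$equilibrium_log_abundance)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
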