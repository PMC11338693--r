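tiny_config <- function(...) {
  defaults <- list(region_width_km = 40, region_height_km = 60,
                   n_municipalities = 3, n_transects = 30, years = 2003:2008,
                   n_lines_per_municipality = 20, n_spruce_patches = 15,
                   n_agri_patches = 10, dem_cell_km = 2, seed = 7)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("population series simulator matches its recursion", {
  # zero feedback, zero noise, x0 = 1 -> constant at 1 (the unit root
  # triggers the non-stationarity warning by design)
  x <- suppressWarnings(
    simulate_population_series(1, c(0, 0), 0, 20, seed = 1, x0 = 1))
  expect_equal(x, rep(1, 20))
  # deterministic given seed
  a <- simulate_population_series(2, c(0.2, -0.1, -0.6), 0.3, 50, seed = 9)
  expect_identical(a, simulate_population_series(2, c(0.2, -0.1, -0.6), 0.3, 50,
                                                 seed = 9))
  # recursion satisfied exactly given the same noise stream
  set.seed(31); eps <- rnorm(15, 0, 0.4)
  x <- simulate_population_series(1, c(0.5, -0.3), 0.4, 15, seed = 31)
  x0 <- 0.5 / 0.3
  manual <- Reduce(function(prev, e) 0.5 + 0.7 * prev + e, eps,
                   accumulate = TRUE, init = x0)[-1]
  expect_equal(x, manual)
  expect_error(simulate_population_series(1, c(0, -0.2, -0.3), 0.2, 20), "b2")
  expect_error(simulate_population_series(1, c(NA, 0), 0.2, 20), "non-finite")
  expect_error(simulate_population_series(1, c(0, 0), 0.2, 5), "length")
  expect_warning(simulate_population_series(1, c(0, 0.2), 0.1, 20),
                 "non-stationary")
})

test_that("strong direct feedback yields negatively autocorrelated growth rates", {
  neg <- vapply(1:100, function(s) {
    x <- simulate_population_series(1, c(0, -0.6), 0.2, 30, seed = s)
    r <- diff(x)
    cor(r[-1], r[-length(r)]) < 0
  }, logical(1))
  expect_gte(sum(neg), 95)
})

test_that("delayed feedback produces a spectral peak at the analytic period", {
  # AR(2) pseudo-period from cos(w) = phi1 (1 - phi2) / (-4 phi2)
  analytic_period <- function(b1, b2) {
    phi1 <- 1 + b1; phi2 <- b2
    2 * pi / acos(phi1 * (1 - phi2) / (-4 * phi2))
  }
  peak_period <- function(b1, b2, s) {
    x <- simulate_population_series(2, c(0, b1, b2), 0.2, 200, seed = s)
    sp <- spec.pgram(x, spans = c(5, 5), detrend = TRUE, plot = FALSE)
    1 / sp$freq[which.max(sp$spec)]
  }
  # default rodent dynamics: 5.1-year cycle, inside the 3-6 year band
  expect_equal(analytic_period(-0.5, -0.6), 5.10, tolerance = 0.01)
  p1 <- vapply(1:20, function(s) peak_period(-0.5, -0.6, s), numeric(1))
  expect_gt(median(p1), 4.5)
  expect_lt(median(p1), 6)
  expect_gte(mean(p1 >= 3.5 & p1 <= 7), 0.9)
  # weaker direct feedback pushes the cycle period out to ~6.8 years
  expect_equal(analytic_period(-0.1, -0.6), 6.78, tolerance = 0.01)
  p2 <- vapply(1:20, function(s) peak_period(-0.1, -0.6, s), numeric(1))
  expect_gt(median(p2), 6)
  expect_lt(median(p2), 8)
  expect_gte(mean(p2 >= 5 & p2 <= 10), 0.9)
})

test_that("world generation is deterministic and respects its config", {
  w1 <- build_world(tiny_config())
  w2 <- build_world(tiny_config())
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))

  # every transect centroid inside the region
  expect_true(all(w1$transects$x_km >= 0 & w1$transects$x_km <= 40))
  expect_true(all(w1$transects$y_km >= 0 & w1$transects$y_km <= 60))
  # every municipality has every rodent year
  tab <- table(w1$rodent_truth$municipality_id)
  expect_true(all(tab == length((min(2003:2008) - 1):2008)))
  # effort invariants
  expect_true(all(w1$transects$length_km > 0.5))
  expect_true(all(w1$transects$days_since_snow >= 1))

  # single municipality: all transects share one rodent series
  w3 <- build_world(sim_config(region_width_km = 40, region_height_km = 60,
                               n_municipalities = 1, n_transects = 20,
                               years = 2003:2008, dem_cell_km = 2, seed = 2))
  expect_true(all(w3$transects$municipality_id == "M01"))
  expect_equal(length(unique(w3$rodent_truth$municipality_id)), 1)
})

test_that("transect effort matches the monitoring design moments", {
  w <- build_world(sim_config(region_width_km = 80, region_height_km = 120,
                              n_municipalities = 5, n_transects = 600,
                              years = 2003:2008, dem_cell_km = 2, seed = 17))
  loc <- unique(w$transects[, c("transect_id", "length_km")])
  expect_equal(mean(loc$length_km), 2.93, tolerance = 0.1 / 2.93)
  # the floor at 1 day shifts the truncated-normal mean up by ~0.18
  expect_gt(mean(w$transects$days_since_snow), 3.55)
  expect_lt(mean(w$transects$days_since_snow), 4.1)
})

test_that("rodent cycle amplitude increases with municipality elevation", {
  # noise-free municipality level: variance ordering is exact
  w <- build_world(tiny_config(rodent_local_sd = 1e-12,
                               amplitude_elevation_slope = 0.5))
  v <- tapply(w$rodent_truth$log_abundance, w$rodent_truth$municipality_id, var)
  elev <- w$municipalities$elevation_m[match(names(v),
                                             w$municipalities$municipality_id)]
  expect_equal(order(v), order(elev))
  expect_equal(unname(cor(log(v[order(elev)]),
                          0.5 * 2 * sort(w$municipalities$z_elev))), 1,
               tolerance = 1e-6)
})

test_that("track counts follow the effort offsets in the Poisson limit", {
  w <- build_world(tiny_config(n_transects = 200, survey_prob = 1))
  delta0 <- c(0, 0, 0, 0, 0, 0, 0)
  w0 <- simulate_marten_tracks(w, delta0, nb_dispersion = Inf,
                               year_effect_sd = 0, seed = 5)
  # offset-only model: E[count] = length * days
  mu <- w0$transects$length_km * w0$transects$days_since_snow
  expect_equal(mean(w0$transects$tracks) / mean(mu), 1, tolerance = 0.05)
  # doubling both effort terms multiplies expected counts by 4
  w2 <- w
  w2$transects$length_km <- w$transects$length_km * 2
  w2$transects$days_since_snow <- w$transects$days_since_snow * 2
  w2 <- simulate_marten_tracks(w2, delta0, nb_dispersion = Inf,
                               year_effect_sd = 0, seed = 5)
  expect_equal(mean(w2$transects$tracks) / mean(w0$transects$tracks), 4,
               tolerance = 0.1)
  # identical counts on repeat call with the same seed
  w0b <- simulate_marten_tracks(w, delta0, nb_dispersion = Inf,
                                year_effect_sd = 0, seed = 5)
  expect_identical(w0$transects$tracks, w0b$transects$tracks)
  expect_error(simulate_marten_tracks(w, delta0, nb_dispersion = -1), "dispersion")
})

test_that("an agricultural avoidance effect shows up in binned mean counts", {
  w <- build_world(sim_config(region_width_km = 80, region_height_km = 120,
                              n_municipalities = 5, n_transects = 500,
                              years = 2003:2008, survey_prob = 1,
                              dem_cell_km = 2, seed = 23))
  delta <- c(0, 0, 0, 0, 0, 0, -0.5)
  w <- simulate_marten_tracks(w, delta, nb_dispersion = Inf,
                              year_effect_sd = 0, seed = 3)
  des <- w$truth$design
  counts <- w$transects$tracks[match(paste(des$rows$transect_id, des$rows$year),
                                     paste(w$transects$transect_id,
                                           w$transects$year))]
  rate <- counts / (des$rows$length_km * des$rows$days_since_snow)
  q <- cut(des$Z[, "agri"], quantile(des$Z[, "agri"], 0:4 / 4),
           include.lowest = TRUE)
  bin_means <- tapply(rate, q, mean)
  expect_true(all(diff(bin_means) < 0))
})

test_that("rodent surveys respond to abundance through the detection slope", {
  w <- small_world()
  # slope 0: every line detects with probability one half
  w0 <- simulate_rodent_surveys(w, n_lines_per_municipality = 50,
                                detection_slope = 0, seed = 4)
  prop_year <- tapply(w0$rodent_surveys$lines_with_detection /
                        w0$rodent_surveys$lines_total,
                      w0$rodent_surveys$year, mean)
  expect_true(all(abs(prop_year - 0.5) < 0.12))
  # saturating slope: near 1 in peak years, near 0 in crashes
  ws <- simulate_rodent_surveys(w, n_lines_per_municipality = 50,
                                detection_slope = 60, seed = 4)
  p <- ws$rodent_surveys$lines_with_detection / ws$rodent_surveys$lines_total
  expect_gt(max(p), 0.95)
  expect_lt(min(p), 0.05)
  expect_error(simulate_rodent_surveys(w, n_lines_per_municipality = 0),
               "at least one")
})

test_that("presence proportion tracks the snap-trap validation series", {
  w <- small_world()
  target <- w$snap_traps$municipality_id[1]
  s <- municipality_index(w$rodent_surveys)
  s <- s[s$municipality_id == target, ]
  m <- merge(s[, c("year", "index")], w$snap_traps[, c("year", "catches_per_100td")])
  v <- validate_against_traps(m$index, m$catches_per_100td)
  expect_gt(v$r, 0.6)
})

test_that("worlds round-trip through plain-text files", {
  w <- build_world(tiny_config())
  dir <- tempfile("world")
  write_world(w, dir)
  expect_setequal(list.files(dir),
                  c("transects.csv", "municipalities.geojson",
                    "rodent_surveys.csv", "snap_traps.csv", "patches.csv",
                    "elevation.asc", "truth.yaml"))
  w2 <- read_world_dir(dir)
  expect_equal(w2$transects$tracks, w$transects$tracks)
  expect_equal(w2$municipalities$centroid_x_km, w$municipalities$centroid_x_km)
  expect_equal(w2$elevation$values, w$elevation$values, tolerance = 1e-6)
  expect_equal(nrow(validate_inputs(list(
    transects = file.path(dir, "transects.csv"),
    rodent_surveys = file.path(dir, "rodent_surveys.csv"),
    patches = file.path(dir, "patches.csv"),
    elevation = file.path(dir, "elevation.asc")))), 0)
})
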