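# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# a compact study system: 5 municipalities, 60 transects, 10 winters
small_world <- function() {
  if (is.null(.fixture_env$small_world)) {
    .fixture_env$small_world <- build_world(sim_config(
      region_width_km = 60, region_height_km = 100,
      n_municipalities = 5, n_transects = 60, years = 2003:2012,
      n_lines_per_municipality = 30, n_spruce_patches = 40,
      n_agri_patches = 30, dem_cell_km = 2, seed = 101
    ))
  }
  .fixture_env$small_world
}

# balanced panel used for sampler validation (known coefficients)
recovery_world <- function() {
  if (is.null(.fixture_env$recovery_world)) {
    .fixture_env$recovery_world <- build_world(sim_config(
      years = 2003:2026, n_transects = 125, survey_prob = 1, seed = 1
    ))
  }
  .fixture_env$recovery_world
}

# model-ready abundance data frame built from a world's generating design
abundance_truth_data <- function(world) {
  des <- world$truth$design
  d <- as.data.frame(des$Z)
  key <- paste(des$rows$transect_id, des$rows$year)
  allkey <- paste(world$transects$transect_id, world$transects$year)
  d$tracks <- world$transects$tracks[match(key, allkey)]
  d$year <- des$rows$year
  d$offset_log <- log(des$rows$length_km) + log(des$rows$days_since_snow)
  d
}

# brute-force partial correlation of the first two variables of `m` given
# the rest, from the inverse of the full correlation matrix
partial_cor_matrix_oracle <- function(m) {
  P <- solve(stats::cor(m))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}
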