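#' Run the full population-dynamics analysis
#'
#' Orchestrates the whole pipeline on a synthetic world (or data read with
#' [read_world_dir()]): per-visit abundance indices; proximity clustering of
#' transects; group-mean annual index series split into consecutive runs;
#' growth rates; PRCF feedback diagnosis of every eligible series; annual
#' IDW rodent surfaces with extraction at transect centroids and snap-trap
#' validation; landscape covariates (home-range-scale elevation, spruce and
#' agricultural kernel densities) with z-standardization and a collinearity
#' screen; and the two Bayesian mixed models. The rodent covariate for a
#' January survey of year `t` is the interpolated index from autumn `t - 1`.
#'
#' The growth-rate response is computed on the group-mean index series (the
#' same series the PRCF consumes); group-level covariates are the means of
#' the member transects surveyed that year.
#'
#' @param world A `"marten_world"` (from [build_world()] or
#'   [read_world_dir()]).
#' @param target_group_size,min_steps,zero_policy Index-stage settings (see
#'   [cluster_transects()], [eligible_series()], [growth_rates()]).
#' @param power,n_neighbors IDW settings.
#' @param bandwidth_km Kernel-density bandwidth for patch covariates.
#' @param chains,iterations,warmup,seed MCMC settings for both models.
#' @param out_dir Optional directory; when given, stage outputs (CSV/ASC)
#'   and the report JSON are written under it.
#' @return A list of class `"marten_report"` with elements `assignment`,
#'   `series`, `prcf_summary`, `rodent` (rasters + extractions +
#'   `validation`), `covariates` (table + collinearity screen), `growth_fit`,
#'   `abundance_fit`, and `report` (plain-list mirror of the headline
#'   results: feedback classification counts, both coefficient tables with
#'   80% CRI and excludes-zero flags, validation r^2).
#' @export
run_all <- function(world, target_group_size = 10, min_steps = 3,
                    zero_policy = "half_min", power = 2, n_neighbors = 12,
                    bandwidth_km = 5, chains = 4, iterations = 6000,
                    warmup = 3000, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(world, "marten_world"))
  tr <- world$transects
  message(sprintf("[indices] %d visit records, %d transects", nrow(tr),
                  length(unique(tr$transect_id))))

  ## ---- indices -------------------------------------------------------
  assignment <- cluster_transects(tr, target_group_size = target_group_size,
                                  seed = seed)
  series <- group_mean_series(tr, assignment)
  series <- do.call(rbind, lapply(split(series, series$series_id), function(s) {
    # an all-zero run carries no growth information; keep it with NA rates
    if (all(s$mean_index == 0)) {
      s$growth_rate <- NA_real_
      return(s)
    }
    growth_rates(s, zero_policy = zero_policy)
  }))
  rownames(series) <- NULL
  eligible <- eligible_series(series, min_steps = min_steps)
  message(sprintf("[indices] %d groups; %d eligible series runs",
                  length(unique(assignment$group_id)),
                  length(unique(eligible$series_id))))

  ## ---- PRCF ----------------------------------------------------------
  ## runs of 4 years yield only 3 growth rates, too few for the Bartlett
  ## band; the feedback diagnosis covers runs of >= 5 years
  runs <- split(eligible, eligible$series_id)
  runs <- runs[vapply(runs, function(s) nrow(s) >= 5 && any(s$mean_index > 0),
                      logical(1))]
  prcf_results <- lapply(runs, function(s) {
    prcf(s$mean_index[order(s$year)], zero_policy = zero_policy,
         series_id = s$series_id[1])
  })
  prcf_summary <- classify_feedback(prcf_results)
  message(sprintf("[prcf] %d/%d series with most negative coefficient at lag 1",
                  prcf_summary$n_argmin_lag1, prcf_summary$n_series))

  ## ---- rodent surfaces ----------------------------------------------
  cfg <- world$config
  grid <- marten_raster(0, 0, cfg$raster_dx_km, cfg$raster_dy_km,
                        ncol = ceiling(cfg$region_width_km / cfg$raster_dx_km),
                        nrow = ceiling(cfg$region_height_km / cfg$raster_dy_km))
  uniq <- unique(tr[, c("transect_id", "x_km", "y_km")])
  rodent <- rodent_surfaces(world$rodent_surveys, uniq, grid,
                            power = power, n_neighbors = n_neighbors)
  sur <- municipality_index(world$rodent_surveys)
  target <- world$snap_traps$municipality_id[1]
  vs <- merge(sur[sur$municipality_id == target,
                  c("year", "index")],
              world$snap_traps[, c("year", "catches_per_100td")], by = "year")
  rodent$validation <- validate_against_traps(vs$index, vs$catches_per_100td)
  message(sprintf("[rodent] %d annual surfaces; validation r^2 = %.3f",
                  length(rodent$rasters), rodent$validation$r_squared))

  ## ---- landscape covariates ------------------------------------------
  spruce_ras <- patch_kernel_density(
    world$patches[world$patches$class == "spruce", ], grid,
    bandwidth_km = bandwidth_km)
  agri_ras <- patch_kernel_density(
    world$patches[world$patches$class == "agriculture", ], grid,
    bandwidth_km = bandwidth_km)
  uniq$elevation_m <- mean_elevation_at(world$elevation, uniq)
  uniq$spruce_density <- extract_at(spruce_ras, uniq$x_km, uniq$y_km)
  uniq$agri_density <- extract_at(agri_ras, uniq$x_km, uniq$y_km)

  cov_tab <- merge(tr[, c("transect_id", "year", "length_km",
                          "days_since_snow", "tracks", "snow_cm")],
                   uniq, by = "transect_id")
  # pair January year t with the autumn t-1 rodent surface
  ext <- rodent$extractions
  key <- paste(cov_tab$transect_id, cov_tab$year - 1L)
  cov_tab$rodent_index <- ext$rodent_index[match(key, paste(ext$transect_id,
                                                            ext$rodent_year))]
  model_rows <- cov_tab[!is.na(cov_tab$rodent_index) & !is.na(cov_tab$tracks), ,
                        drop = FALSE]
  message(sprintf("[covariates] %d model rows over %d-%d", nrow(model_rows),
                  min(model_rows$year), max(model_rows$year)))

  screen <- collinearity_screen(model_rows[, c("rodent_index", "elevation_m",
                                               "snow_cm", "spruce_density",
                                               "agri_density")])

  ## ---- abundance model -----------------------------------------------
  ab <- model_rows
  zc <- lapply(ab[, c("rodent_index", "elevation_m", "snow_cm",
                      "spruce_density", "agri_density")], z_standardize)
  ab_data <- data.frame(
    tracks = ab$tracks,
    rodent = zc$rodent_index$z, elevation = zc$elevation_m$z,
    rodent_x_elevation = zc$rodent_index$z * zc$elevation_m$z,
    snow = zc$snow_cm$z, spruce = zc$spruce_density$z,
    agri = zc$agri_density$z,
    year = ab$year,
    offset_log = log(ab$length_km) + log(ab$days_since_snow)
  )
  message("[glmm] fitting abundance model (negative binomial)")
  abundance_fit <- fit_model(abundance_model_spec(), ab_data, chains = chains,
                             iterations = iterations, warmup = warmup,
                             seed = seed)

  ## ---- growth model --------------------------------------------------
  gidx <- assignment$group_id[match(model_rows$transect_id,
                                    assignment$transect_id)]
  gcov <- stats::aggregate(
    model_rows[, c("rodent_index", "elevation_m", "snow_cm")],
    by = list(group_id = gidx, year = model_rows$year), FUN = mean)
  growth_rows <- merge(series[!is.na(series$growth_rate),
                              c("group_id", "series_id", "year", "growth_rate")],
                       gcov, by = c("group_id", "year"))
  zg <- lapply(growth_rows[, c("rodent_index", "elevation_m", "snow_cm")],
               z_standardize)
  gr_data <- data.frame(
    growth_rate = growth_rows$growth_rate,
    rodent = zg$rodent_index$z, elevation = zg$elevation_m$z,
    rodent_x_elevation = zg$rodent_index$z * zg$elevation_m$z,
    snow = zg$snow_cm$z,
    group_id = growth_rows$group_id
  )
  message(sprintf("[glmm] fitting growth model on %d group-years", nrow(gr_data)))
  growth_fit <- fit_model(growth_model_spec(), gr_data, chains = chains,
                          iterations = iterations, warmup = warmup,
                          seed = seed + 1L)

  coef_table <- function(fit, keep) {
    s <- fit$summary
    s[s$parameter %in% keep, c("parameter", "mean", "cri_lower", "cri_upper",
                               "excludes_zero", "rhat"), drop = FALSE]
  }
  report <- list(
    seed = seed,
    n_series = prcf_summary$n_series,
    n_argmin_lag1 = prcf_summary$n_argmin_lag1,
    feedback_counts = as.list(prcf_summary$count_by_argmin),
    validation_r_squared = rodent$validation$r_squared,
    validation_p = rodent$validation$p_value,
    collinearity_flags = nrow(screen$flagged),
    growth_coefficients = coef_table(growth_fit,
                                     c("(Intercept)",
                                       growth_model_spec()$fixed)),
    abundance_coefficients = coef_table(abundance_fit,
                                        c("(Intercept)",
                                          abundance_model_spec()$fixed))
  )

  out <- structure(list(assignment = assignment, series = series,
                        eligible = eligible, prcf_results = prcf_results,
                        prcf_summary = prcf_summary, rodent = rodent,
                        covariates = list(table = cov_tab, screen = screen),
                        growth_data = gr_data, abundance_data = ab_data,
                        growth_fit = growth_fit, abundance_fit = abundance_fit,
                        report = report),
                   class = "marten_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.marten_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("Feedback diagnosis: %d of %d series with most negative PRCF at lag 1\n",
              r$n_argmin_lag1, r$n_series))
  cat(sprintf("Rodent index validation: r^2 = %.3f (p = %.3g)\n",
              r$validation_r_squared, r$validation_p))
  cat("Abundance model coefficients (80% CRI):\n")
  print(r$abundance_coefficients, row.names = FALSE, digits = 3)
  cat("Growth model coefficients (80% CRI):\n")
  print(r$growth_coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write pipeline artifacts under a run directory
#'
#' Writes the group assignment, group series, per-series PRCF diagnoses and
#' covariate table as CSV, each annual rodent raster as an ESRI ASCII grid,
#' and the headline report as `report.json`.
#'
#' @param result A `"marten_report"` from [run_all()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$assignment, file.path(out_dir, "group_assignment.csv"),
                   row.names = FALSE)
  utils::write.csv(result$series, file.path(out_dir, "group_series.csv"),
                   row.names = FALSE)
  utils::write.csv(result$prcf_summary$per_series,
                   file.path(out_dir, "prcf_results.csv"), row.names = FALSE)
  utils::write.csv(result$covariates$table,
                   file.path(out_dir, "covariates.csv"), row.names = FALSE)
  for (yr in names(result$rodent$rasters)) {
    write_asc(result$rodent$rasters[[yr]],
              file.path(out_dir, sprintf("rodent_index_%s.asc", yr)))
  }
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Read a written world directory back into a world object
#'
#' Counterpart of [write_world()]; reconstructs the pieces the pipeline
#' needs from `transects.csv`, `municipalities.geojson`,
#' `rodent_surveys.csv`, `snap_traps.csv`, `patches.csv`, `elevation.asc`
#' and `truth.yaml`.
#'
#' @param dir Directory written by [write_world()].
#' @param config Optional [sim_config()] describing the geometry; defaults
#'   are inferred from the files (region extent from the DEM, years from the
#'   transect records).
#' @return A `"marten_world"`.
#' @export
read_world_dir <- function(dir, config = NULL) {
  tr <- utils::read.csv(file.path(dir, "transects.csv"),
                        stringsAsFactors = FALSE)
  sur <- utils::read.csv(file.path(dir, "rodent_surveys.csv"),
                         stringsAsFactors = FALSE)
  snap <- utils::read.csv(file.path(dir, "snap_traps.csv"),
                          stringsAsFactors = FALSE)
  patches <- utils::read.csv(file.path(dir, "patches.csv"),
                             stringsAsFactors = FALSE)
  dem <- read_asc(file.path(dir, "elevation.asc"))
  gj <- jsonlite::read_json(file.path(dir, "municipalities.geojson"))
  mun <- do.call(rbind, lapply(gj$features, function(f) {
    data.frame(municipality_id = f$properties$municipality_id,
               centroid_x_km = f$geometry$coordinates[[1]],
               centroid_y_km = f$geometry$coordinates[[2]],
               elevation_m = f$properties$elevation_m,
               stringsAsFactors = FALSE)
  }))
  if (is.null(config)) {
    config <- sim_config(
      region_width_km = dem$ncol * dem$dx, region_height_km = dem$nrow * dem$dy,
      n_municipalities = nrow(mun),
      n_transects = length(unique(tr$transect_id)),
      years = sort(unique(tr$year)),
      rodent_years = sort(unique(sur$year))
    )
  }
  structure(list(config = config, transects = tr, municipalities = mun,
                 rodent_truth = NULL, rodent_surveys = sur, snap_traps = snap,
                 patches = patches, elevation = dem, truth = list()),
            class = "marten_world")
}

#' Validate pipeline input files
#'
#' Schema and sanity checks for the plain-text inputs: required columns,
#' strictly positive effort fields, non-negative counts, detection counts
#' within line totals, readable DEM. Issues are returned as a machine-
#' readable data frame; `fatal = TRUE` rows would abort [run_all()].
#'
#' @param paths Named list/vector with any of `transects`, `rodent_surveys`,
#'   `snap_traps`, `patches`, `elevation` file paths.
#' @return Data frame with columns `file`, `issue`, `fatal` (zero rows when
#'   everything passes).
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  issues <- list()
  add <- function(file, issue, fatal = TRUE) {
    issues[[length(issues) + 1]] <<- data.frame(file = file, issue = issue,
                                                fatal = fatal,
                                                stringsAsFactors = FALSE)
  }
  check_cols <- function(df, need, file) {
    miss <- setdiff(need, names(df))
    for (m in miss) add(file, sprintf("missing required column '%s'", m))
    length(miss) == 0
  }
  if (!is.null(paths$transects)) {
    f <- paths$transects
    if (!file.exists(f)) {
      add(f, "file not found")
    } else {
      tr <- utils::read.csv(f, stringsAsFactors = FALSE)
      if (check_cols(tr, c("transect_id", "year", "x_km", "y_km", "length_km",
                           "days_since_snow", "tracks", "snow_cm"), f)) {
        bad <- which(tr$length_km <= 0)
        if (length(bad)) add(f, sprintf("non-positive length_km in row(s) %s",
                                        paste(utils::head(bad, 5), collapse = ", ")))
        bad <- which(tr$days_since_snow <= 0)
        if (length(bad)) add(f, sprintf("non-positive days_since_snow in row(s) %s",
                                        paste(utils::head(bad, 5), collapse = ", ")))
        bad <- which(!is.na(tr$tracks) & tr$tracks < 0)
        if (length(bad)) add(f, sprintf("negative tracks in row(s) %s",
                                        paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
  }
  if (!is.null(paths$rodent_surveys)) {
    f <- paths$rodent_surveys
    if (!file.exists(f)) {
      add(f, "file not found")
    } else {
      s <- utils::read.csv(f, stringsAsFactors = FALSE)
      if (check_cols(s, c("municipality_id", "year", "lines_total",
                          "lines_with_detection", "centroid_x_km",
                          "centroid_y_km"), f)) {
        if (any(s$lines_total < 1)) add(f, "lines_total below 1")
        if (any(s$lines_with_detection < 0 |
                s$lines_with_detection > s$lines_total)) {
          add(f, "lines_with_detection outside [0, lines_total]")
        }
      }
    }
  }
  if (!is.null(paths$patches)) {
    f <- paths$patches
    if (!file.exists(f)) {
      add(f, "file not found")
    } else {
      p <- utils::read.csv(f, stringsAsFactors = FALSE)
      if (check_cols(p, c("class", "x_km", "y_km", "size"), f)) {
        if (any(p$size <= 0)) add(f, "non-positive patch size")
      }
    }
  }
  if (!is.null(paths$elevation)) {
    f <- paths$elevation
    if (!file.exists(f)) {
      add(f, "file not found")
    } else {
      ok <- tryCatch({ read_asc(f); TRUE }, error = function(e) FALSE)
      if (!ok) add(f, "unreadable ESRI ASCII grid")
    }
  }
  if (length(issues)) do.call(rbind, issues) else {
    data.frame(file = character(0), issue = character(0), fatal = logical(0),
               stringsAsFactors = FALSE)
  }
}
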