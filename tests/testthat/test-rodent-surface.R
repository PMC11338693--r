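test_that("municipality index is the detection proportion", {
  s <- data.frame(municipality_id = "M1", year = 2006:2008,
                  lines_total = c(10, 10, 8),
                  lines_with_detection = c(0, 10, 3))
  out <- municipality_index(s)
  expect_equal(out$index, c(0, 1, 0.375))
  # duplicating every line leaves the proportion unchanged
  s2 <- s; s2$lines_total <- s$lines_total * 2
  s2$lines_with_detection <- s$lines_with_detection * 2
  expect_equal(municipality_index(s2)$index, out$index)
  expect_error(municipality_index(transform(s, lines_total = 0)), "lines_total")
  expect_error(municipality_index(transform(s, lines_with_detection = 20)),
               "lines_with_detection")
})

test_that("IDW reproduces data points exactly and never extrapolates", {
  grid <- marten_raster(0, 0, 1, 1, ncol = 10, nrow = 10)
  # single point -> constant surface
  one <- data.frame(x_km = 3.5, y_km = 6.5, value = 0.42)
  r1 <- idw_interpolate(one, grid)
  expect_equal(max(abs(r1$values - 0.42)), 0)
  # equal values cancel the weights
  two <- data.frame(x_km = c(2.5, 8.5), y_km = c(2.5, 8.5), value = c(7, 7))
  expect_equal(max(abs(idw_interpolate(two, grid)$values - 7)), 0)
  # exact at a coincident cell centre, bounded by the data range
  pts <- data.frame(x_km = c(0.5, 9.5), y_km = c(0.5, 9.5), value = c(0, 1))
  r <- idw_interpolate(pts, grid)
  expect_equal(extract_at(r, 0.5, 0.5), 0)
  expect_equal(extract_at(r, 9.5, 9.5), 1)
  expect_true(all(r$values >= 0 & r$values <= 1))
  expect_error(idw_interpolate(pts[0, ], grid), "at least one")
  expect_error(idw_interpolate(pts, grid, power = 0), "power")
})

test_that("IDW weights follow the inverse-distance-power formula", {
  # cell centre at distances 1 and 2 km from values 0 and 1, power 2:
  # (1*0 + 0.25*1) / 1.25 = 0.2
  grid <- marten_raster(0, 0, 1, 1, ncol = 1, nrow = 1)  # centre (0.5, 0.5)
  pts <- data.frame(x_km = c(0.5, 0.5), y_km = c(1.5, 2.5), value = c(0, 1))
  expect_equal(idw_interpolate(pts, grid, power = 2)$values[1, 1], 0.2)
  # equidistant cell between 0 and 1 -> 0.5 by symmetry
  pts2 <- data.frame(x_km = c(0.5, 0.5), y_km = c(-0.5, 1.5), value = c(0, 1))
  expect_equal(idw_interpolate(pts2, grid, power = 2)$values[1, 1], 0.5)
})

test_that("extraction uses containing cells with half-open edges", {
  r <- marten_raster(0, 0, 1, 1, ncol = 3, nrow = 3,
                     values = matrix(1:9, 3, 3, byrow = TRUE))
  # cell centres
  expect_equal(extract_at(r, 0.5, 2.5), 1)   # NW cell
  expect_equal(extract_at(r, 2.5, 0.5), 9)   # SE cell
  # a point on the shared vertical edge belongs to the right-hand cell
  expect_equal(extract_at(r, 1, 2.5), 2)
  # a point on the shared horizontal edge belongs to the cell above it
  expect_equal(extract_at(r, 0.5, 1), 4)
  # outside points clamp to the nearest cell, with a warning
  expect_warning(v <- extract_at(r, -5, -5), "outside")
  expect_equal(v, 7)
  expect_error(extract_at(marten_raster(0, 0, 1, 1, 2, 2), 0.5, 0.5),
               "nodata")
})

test_that("ASCII grid round trip preserves geometry and values", {
  r <- marten_raster(10, -5, 1.9, 3.0, ncol = 4, nrow = 3,
                     values = matrix(rnorm(12), 3, 4))
  r$values[2, 3] <- NA
  path <- tempfile(fileext = ".asc")
  write_asc(r, path)
  r2 <- read_asc(path)
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  expect_equal(r2$dx, 1.9)
  expect_equal(r2$dy, 3.0)
  expect_equal(r2$xmin, 10)
  expect_equal(r2$ymin, -5)
})

test_that("trap validation matches a hand-computed Pearson correlation", {
  # brute-force oracle from the definition
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 5, 4, 5)
  v <- validate_against_traps(x, y)
  expect_equal(v$r, pearson(x, y))
  expect_equal(v$r, 6 / sqrt(60))        # = 0.7745967, frozen from the oracle
  expect_equal(v$r_squared, 0.6)
  tt <- v$r * sqrt(3 / (1 - v$r^2))
  expect_equal(v$p_value, 2 * pt(-abs(tt), df = 3))
  expect_equal(validate_against_traps(x, x)$r_squared, 1)
  expect_equal(validate_against_traps(x, -x)$r, -1)
  expect_error(validate_against_traps(x, rep(1, 5)), "variance")
  expect_error(validate_against_traps(1:2, 2:3), "3 paired")
})

test_that("a single-municipality surface reduces extraction to its index", {
  s <- data.frame(municipality_id = "M1", year = 2006,
                  lines_total = 10, lines_with_detection = 4,
                  centroid_x_km = 5, centroid_y_km = 5)
  tr <- data.frame(transect_id = c("t1", "t2"), x_km = c(1, 9), y_km = c(2, 8))
  grid <- marten_raster(0, 0, 1, 1, ncol = 10, nrow = 10)
  out <- rodent_surfaces(s, tr, grid)
  expect_equal(out$extractions$rodent_index, c(0.4, 0.4))
})
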