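#' Planar raster grid
#'
#' A minimal in-memory raster on a planar kilometre coordinate system. Cells
#' are axis-aligned rectangles; `values` is an `nrow x ncol` matrix whose
#' first row is the *northernmost* row (the order in which ESRI ASCII grids
#' are written). `xmin`/`ymin` give the south-west corner of the grid.
#' Cell membership uses half-open intervals `[lo, hi)` in both axes, so a
#' point on a shared edge belongs to exactly one cell.
#'
#' @param xmin,ymin South-west corner of the grid, in km.
#' @param dx,dy Cell size in km along x (easting) and y (northing); both > 0.
#' @param ncol,nrow Grid dimensions.
#' @param values Numeric matrix (`nrow x nrow`), or a single number recycled;
#'   row 1 is the northern row. `NA` encodes nodata.
#' @return An object of class `"marten_raster"`.
#' @export
marten_raster <- function(xmin, ymin, dx, dy, ncol, nrow, values = NA_real_) {
  stopifnot(dx > 0, dy > 0, ncol >= 1, nrow >= 1)
  if (!is.matrix(values)) {
    values <- matrix(as.numeric(values), nrow = nrow, ncol = ncol)
  }
  stopifnot(nrow(values) == nrow, ncol(values) == ncol)
  structure(
    list(xmin = xmin, ymin = ymin, dx = dx, dy = dy,
         ncol = as.integer(ncol), nrow = as.integer(nrow), values = values),
    class = "marten_raster"
  )
}

#' @export
print.marten_raster <- function(x, ...) {
  cat(sprintf("<marten_raster> %d x %d cells of %.3g x %.3g km, extent x [%.3g, %.3g] y [%.3g, %.3g]\n",
              x$nrow, x$ncol, x$dx, x$dy,
              x$xmin, x$xmin + x$ncol * x$dx, x$ymin, x$ymin + x$nrow * x$dy))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#'
#' @param raster A [marten_raster()].
#' @return A data frame with one row per cell (row-major from the north-west
#'   corner): `row`, `col`, `x_km`, `y_km`.
#' @export
raster_cell_centres <- function(raster) {
  cols <- rep(seq_len(raster$ncol), times = raster$nrow)
  rows <- rep(seq_len(raster$nrow), each = raster$ncol)
  data.frame(
    row = rows, col = cols,
    x_km = raster$xmin + (cols - 0.5) * raster$dx,
    # row 1 is the north row
    y_km = raster$ymin + (raster$nrow - rows + 0.5) * raster$dy
  )
}

# row/col of the cell containing each point; points outside the extent are
# clamped to the nearest cell (with a warning from callers that care).
raster_rowcol <- function(raster, x, y) {
  col <- floor((x - raster$xmin) / raster$dx) + 1L
  row_from_south <- floor((y - raster$ymin) / raster$dy) + 1L
  outside <- col < 1L | col > raster$ncol |
    row_from_south < 1L | row_from_south > raster$nrow
  col <- pmin(pmax(col, 1L), raster$ncol)
  row_from_south <- pmin(pmax(row_from_south, 1L), raster$nrow)
  data.frame(row = raster$nrow - row_from_south + 1L, col = col,
             outside = outside)
}

#' Extract raster values at point locations
#'
#' Returns the value of the cell containing each point (no resampling).
#' Points outside the raster extent are assigned the nearest cell and a
#' warning is raised.
#'
#' @param raster A [marten_raster()].
#' @param x,y Point coordinates in km.
#' @return Numeric vector of cell values.
#' @export
extract_at <- function(raster, x, y) {
  stopifnot(length(x) == length(y))
  if (all(is.na(raster$values))) stop("raster contains only nodata cells")
  rc <- raster_rowcol(raster, x, y)
  if (any(rc$outside)) {
    warning(sprintf("%d point(s) outside raster extent; using nearest cell",
                    sum(rc$outside)))
  }
  raster$values[cbind(rc$row, rc$col)]
}

#' Write a raster as an ESRI ASCII grid
#'
#' Square cells are written with `cellsize`; rectangular cells use the
#' `dx`/`dy` extension keywords understood by most GIS readers.
#'
#' @param raster A [marten_raster()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Value used to encode `NA` cells.
#' @export
write_asc <- function(raster, path, nodata = -9999) {
  hdr <- c(
    sprintf("ncols %d", raster$ncol),
    sprintf("nrows %d", raster$nrow),
    sprintf("xllcorner %.10g", raster$xmin),
    sprintf("yllcorner %.10g", raster$ymin)
  )
  if (isTRUE(all.equal(raster$dx, raster$dy))) {
    hdr <- c(hdr, sprintf("cellsize %.10g", raster$dx))
  } else {
    hdr <- c(hdr, sprintf("dx %.10g", raster$dx), sprintf("dy %.10g", raster$dy))
  }
  hdr <- c(hdr, sprintf("NODATA_value %.10g", nodata))
  vals <- raster$values
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_asc()] or a GIS.
#' @return A [marten_raster()].
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  dx <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  dy <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dy
  vals <- t(vapply(lines[i:length(lines)],
                   function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(hdr$ncols), USE.NAMES = FALSE))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  marten_raster(hdr$xllcorner, hdr$yllcorner, dx, dy,
                ncol = hdr$ncols, nrow = hdr$nrows, values = vals)
}
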