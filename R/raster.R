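#' Land-use raster container
#'
#' A `land_raster` is an integer (or numeric) matrix with a cell size in
#' meters and a nodata code. Categorical rasters use integer class codes;
#' `0` marks nodata by default. The container is deliberately light: all
#' heavy lifting works on the underlying matrix.
#'
#' @param x matrix of cell values (row 1 = northernmost row).
#' @param cell_size cell edge length in meters.
#' @param nodata value marking cells outside the study area.
#' @param classes optional named integer vector of legal class codes.
#' @return A `land_raster` object.
#' @examples
#' r <- land_raster(matrix(1L, 4, 4), cell_size = 30)
#' raster_area_km2(r)
#' @export
land_raster <- function(x, cell_size = 30, nodata = 0L, classes = lu_classes()) {
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("`cell_size` must be a positive length in meters", call. = FALSE)
  }
  structure(
    list(values = x, cell_size = as.numeric(cell_size),
         nodata = nodata, classes = classes),
    class = "land_raster"
  )
}

#' The six primary land-use classes
#'
#' Integer codes for the six-class primary legend: cultivated land, woodland,
#' grassland, water, construction land, unused land.
#'
#' @return Named integer vector of length 6.
#' @export
lu_classes <- function() {
  c(cultivated = 1L, woodland = 2L, grassland = 3L,
    water = 4L, construction = 5L, unused = 6L)
}

#' The four PLE space types
#'
#' Codes for production-living-ecological space: living-production (LP),
#' production-ecological (PE), ecological-production (EP), ecological (ECO).
#'
#' @return Named integer vector of length 4.
#' @export
ple_classes <- function() {
  c(LP = 1L, PE = 2L, EP = 3L, ECO = 4L)
}

#' @export
print.land_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<land_raster> %d x %d cells, %g m cells (%.2f x %.2f km)\n",
              d[1], d[2], x$cell_size,
              d[1] * x$cell_size / 1000, d[2] * x$cell_size / 1000))
  vals <- x$values[x$values != x$nodata & !is.na(x$values)]
  if (length(vals) && all(vals == round(vals))) {
    tab <- table(factor(vals, levels = sort(unique(vals))))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$values)

is_land_raster <- function(x) inherits(x, "land_raster")

#' @rdname land_raster
#' @param r a `land_raster`.
#' @export
raster_area_km2 <- function(r) {
  stopifnot(is_land_raster(r))
  n <- sum(r$values != r$nodata, na.rm = TRUE)
  n * (r$cell_size / 1000)^2
}

#' Per-class cell counts of a categorical raster
#'
#' @param r a `land_raster`.
#' @param classes class codes to tabulate; defaults to the raster's legend.
#' @return Named integer vector of counts (zero for absent classes).
#' @export
class_counts <- function(r, classes = r$classes) {
  stopifnot(is_land_raster(r))
  v <- r$values[r$values != r$nodata & !is.na(r$values)]
  out <- table(factor(v, levels = unname(classes)))
  stats::setNames(as.integer(out), names(classes))
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) && a$cell_size == b$cell_size
}

check_same_geometry <- function(a, b) {
  if (!same_geometry(a, b)) {
    stop("rasters have mismatched geometry (dimensions or cell size)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write rasters as ESRI ASCII grid
#'
#' Plain-text raster interchange format (readable by GDAL, ArcGIS, QGIS).
#' Integer-coded rasters round-trip bit-exactly.
#'
#' @param r a `land_raster`.
#' @param path file path (conventionally `.asc`).
#' @param xllcorner,yllcorner coordinates of the lower-left corner, meters.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `land_raster`.
#' @export
write_ascii_grid <- function(r, path, xllcorner = 0, yllcorner = 0) {
  stopifnot(is_land_raster(r))
  d <- dim(r$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.6f", xllcorner),
    sprintf("yllcorner %.6f", yllcorner),
    sprintf("cellsize %.6f", r$cell_size),
    sprintf("NODATA_value %s", format(r$nodata, scientific = FALSE))
  )
  rows <- apply(r$values, 1, function(row)
    paste(format(row, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1])
  val <- kv[, 2]
  ncols <- as.integer(val[key == "ncols"])
  nrows <- as.integer(val[key == "nrows"])
  cell <- as.numeric(val[key == "cellsize"])
  nodata <- as.numeric(val[key == "nodata_value"])
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- matrix(as.numeric(unlist(body)), nrow = nrows, ncol = ncols,
              byrow = TRUE)
  if (all(m == round(m), na.rm = TRUE)) {
    storage.mode(m) <- "integer"
    nodata <- as.integer(nodata)
  }
  land_raster(m, cell_size = cell, nodata = nodata)
}
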