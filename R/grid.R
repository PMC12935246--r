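#' Grid metadata for a north-up raster
#'
#' Describes the geometry shared by every raster layer in an analysis: grid
#' size, cell size, the coordinate of the outer corner of the top-left cell,
#' an opaque CRS tag and the nodata sentinel. Two rasters are combinable iff
#' all fields match exactly; no module resamples silently.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1). Row 1 is the northernmost row.
#' @param cell_size Cell edge length in CRS units (degrees or metres), > 0.
#' @param origin_x,origin_y Coordinates of the outer (north-west) corner of
#'   the top-left cell.
#' @param crs_tag Opaque text label for the coordinate reference system.
#' @param nodata_value Sentinel written to files for masked cells.
#' @return An object of class `grid_meta`.
#' @export
grid_meta <- function(n_rows, n_cols, cell_size = 1, origin_x = 0,
                      origin_y = 0, crs_tag = "unspecified",
                      nodata_value = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0,
            is.finite(origin_x), is.finite(origin_y))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size),
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 crs_tag = as.character(crs_tag),
                 nodata_value = as.numeric(nodata_value)),
            class = "grid_meta")
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(sprintf("grid_meta: %d x %d cells, cell size %g, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_tag))
  invisible(x)
}

#' Test whether two grids share identical geometry
#'
#' @param a,b `grid_meta` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  stopifnot(inherits(a, "grid_meta"), inherits(b, "grid_meta"))
  isTRUE(all.equal(unclass(a), unclass(b)))
}

#' Abort unless two objects share the same grid geometry
#'
#' Downstream modules call this instead of resampling; a mismatch is always a
#' hard error.
#'
#' @param a,b Objects carrying a `meta` field (`grid_cube`, `land_cover_map`)
#'   or bare `grid_meta` objects.
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`.
#' @export
check_same_grid <- function(a, b, what = "inputs") {
  ma <- if (inherits(a, "grid_meta")) a else a$meta
  mb <- if (inherits(b, "grid_meta")) b else b$meta
  if (!same_grid(ma, mb)) {
    stop("grid geometry mismatch between ", what,
         ": grids must be pre-aligned (no implicit resampling)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Monthly raster cube
#'
#' A 3-D stack of monthly rasters with dimensions (time, row, col), a
#' gap-free ordered monthly calendar, grid metadata and units. Masked
#' (nodata) cells are stored as `NA`; `values` must be finite wherever not
#' `NA`.
#'
#' @param values 3-D numeric array `[time, row, col]`; `NA` marks nodata.
#' @param meta A `grid_meta`.
#' @param times Data frame with integer columns `year` and `month` (1-12),
#'   strictly increasing, monthly step with no missing months, one row per
#'   time slice.
#' @param units Unit string (e.g. `"mm"`, `"degC"`).
#' @return An object of class `grid_cube`.
#' @export
grid_cube <- function(values, meta, times, units = "") {
  stopifnot(inherits(meta, "grid_meta"), is.array(values),
            length(dim(values)) == 3L)
  times <- as.data.frame(times)
  stopifnot(all(c("year", "month") %in% names(times)))
  times$year <- as.integer(times$year)
  times$month <- as.integer(times$month)
  if (nrow(times) != dim(values)[1L])
    stop("length(times) must equal the first dimension of values")
  if (dim(values)[2L] != meta$n_rows || dim(values)[3L] != meta$n_cols)
    stop("values spatial dimensions do not match grid_meta")
  if (any(times$month < 1L | times$month > 12L))
    stop("month must be in 1..12")
  idx <- times$year * 12L + (times$month - 1L)
  if (nrow(times) > 1L) {
    d <- diff(idx)
    if (any(d <= 0L)) stop("times must be strictly increasing")
    if (any(d != 1L)) {
      g <- which(d != 1L)[1L]
      gy <- (idx[g] + 1L) %/% 12L
      gm <- (idx[g] + 1L) %% 12L + 1L
      stop(sprintf("missing month %04d-%02d in time axis", gy, gm))
    }
  }
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) stop("non-finite unmasked values in cube")
  structure(list(values = values, meta = meta, times = times,
                 units = as.character(units)),
            class = "grid_cube")
}

#' @export
print.grid_cube <- function(x, ...) {
  n <- nrow(x$times)
  cat(sprintf("grid_cube: %d monthly steps (%04d-%02d .. %04d-%02d), %d x %d cells, units '%s'\n",
              n, x$times$year[1], x$times$month[1],
              x$times$year[n], x$times$month[n],
              x$meta$n_rows, x$meta$n_cols, x$units))
  v <- x$values
  cat(sprintf("  valid cells: %.1f%%; range [%g, %g]\n",
              100 * mean(!is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Number of time steps in a cube
#' @param cube A `grid_cube`.
#' @return Integer count.
#' @export
n_times <- function(cube) nrow(cube$times)

#' Replace the values array of a cube, keeping its calendar and grid
#'
#' @param cube Template `grid_cube`.
#' @param values New array of the same shape (or a matrix recycled over time).
#' @param units Units of the new variable.
#' @return A `grid_cube`.
#' @export
cube_like <- function(cube, values, units = cube$units) {
  grid_cube(values, cube$meta, cube$times, units)
}

#' Static land-cover raster with the six-class scheme
#'
#' Codes: 1 farmland, 2 woodland, 3 grassland, 4 water, 5 construction,
#' 6 ice/bare ground. Classes 1-3 are the vegetated set.
#'
#' @param classes Integer matrix `[row, col]`; `NA` marks nodata.
#' @param meta A `grid_meta`.
#' @return An object of class `land_cover_map`.
#' @export
land_cover_map <- function(classes, meta) {
  stopifnot(inherits(meta, "grid_meta"), is.matrix(classes))
  if (nrow(classes) != meta$n_rows || ncol(classes) != meta$n_cols)
    stop("classes dimensions do not match grid_meta")
  cl <- classes[!is.na(classes)]
  if (length(cl) && !all(cl %in% 1:6))
    stop("land-cover codes must be in 1..6 (or NA)")
  storage.mode(classes) <- "integer"
  structure(list(classes = classes, meta = meta), class = "land_cover_map")
}

#' @export
print.land_cover_map <- function(x, ...) {
  cat(sprintf("land_cover_map: %d x %d cells\n", x$meta$n_rows, x$meta$n_cols))
  print(table(factor(x$classes, levels = 1:6,
                     labels = landcover_class_names())))
  invisible(x)
}

#' Names of the six land-cover classes
#' @return Character vector of length 6 in code order.
#' @export
landcover_class_names <- function() {
  c("farmland", "woodland", "grassland", "water", "construction", "ice_bare")
}

#' Codes of the vegetated land-cover classes
#' @return Integer vector `c(1, 2, 3)`.
#' @export
vegetated_classes <- function() 1:3

#' Latitude of each row's cell centre
#'
#' Assumes `origin_y`/`cell_size` are in degrees with row 1 northernmost.
#'
#' @param meta A `grid_meta`.
#' @return Numeric vector of length `n_rows`.
#' @export
row_latitudes <- function(meta) {
  meta$origin_y - (seq_len(meta$n_rows) - 0.5) * meta$cell_size
}

#' Subset a cube along the time axis
#'
#' @param cube A `grid_cube`.
#' @param idx Integer indices of time steps to keep (must remain gap-free
#'   monthly unless `allow_gaps = TRUE`).
#' @param allow_gaps If `TRUE`, returns a bare list (values, times) instead of
#'   a `grid_cube`, for internal seasonal subsetting.
#' @return A `grid_cube` or a list.
#' @keywords internal
cube_time_subset <- function(cube, idx, allow_gaps = FALSE) {
  v <- cube$values[idx, , , drop = FALSE]
  tt <- cube$times[idx, , drop = FALSE]
  if (allow_gaps) return(list(values = v, times = tt))
  grid_cube(v, cube$meta, tt, cube$units)
}
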