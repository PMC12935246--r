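#' Write a single 2-D field to disk
#'
#' Two plain formats are supported. `"ascii"` is the ESRI ASCII grid
#' (`.asc`): a text header carrying the grid geometry followed by rows from
#' north to south, written at full double precision so a round trip is
#' bit-identical. `"tiff"` writes a two-channel 32-bit TIFF (scaled values +
#' validity mask) with a JSON sidecar (`<path>.json`) holding the grid
#' metadata and the scaling; values round-trip to ~1e-9 relative precision,
#' the mask exactly.
#'
#' @param field Numeric matrix `[row, col]`; `NA` marks nodata.
#' @param meta A [grid_meta()] matching the field's dimensions.
#' @param path Output file path.
#' @param format `"ascii"` or `"tiff"`.
#' @return Invisibly, `path`.
#' @seealso [read_field()], [read_cube()]
#' @export
write_field <- function(field, meta, path, format = c("ascii", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(meta, "grid_meta"), is.matrix(field))
  if (nrow(field) != meta$n_rows || ncol(field) != meta$n_cols)
    stop("field dimensions do not match grid_meta")
  if (format == "ascii") {
    con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
      stop("cannot open '", path, "' for writing: ", conditionMessage(e),
           call. = FALSE))
    on.exit(close(con))
    writeLines(c(
      sprintf("ncols %d", meta$n_cols),
      sprintf("nrows %d", meta$n_rows),
      sprintf("xllcorner %.17g", meta$origin_x),
      sprintf("yllcorner %.17g", meta$origin_y - meta$n_rows * meta$cell_size),
      sprintf("cellsize %.17g", meta$cell_size),
      sprintf("NODATA_value %.17g", meta$nodata_value)), con)
    out <- field
    out[is.na(out)] <- meta$nodata_value
    writeLines(apply(out, 1L, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  } else {
    valid <- !is.na(field)
    fin <- field[valid]
    vmin <- if (length(fin)) min(fin) else 0
    vmax <- if (length(fin)) max(fin) else 1
    span <- if (vmax > vmin) vmax - vmin else 1
    img <- array(0, c(nrow(field), ncol(field), 2L))
    sc <- (field - vmin) / span
    sc[!valid] <- 0
    img[, , 1L] <- sc
    img[, , 2L] <- as.numeric(valid)
    ok <- tryCatch(tiff::writeTIFF(img, path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE),
                   error = function(e)
                     stop("cannot write '", path, "': ",
                          conditionMessage(e), call. = FALSE))
    jsonlite::write_json(
      list(meta = unclass(meta), vmin = vmin, vmax = vmax, span = span),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a single 2-D field written by [write_field()]
#'
#' @param path File path (`.asc` text grid or two-channel TIFF with sidecar).
#' @param format `"ascii"` or `"tiff"`; guessed from the extension when
#'   missing.
#' @return A list with `field` (matrix, `NA` = nodata) and `meta`
#'   ([grid_meta()]). ASCII grids carry no CRS tag, so `crs_tag` is
#'   `"unspecified"`.
#' @export
read_field <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.asc$", path, ignore.case = TRUE)) "ascii" else "tiff"
  }
  format <- match.arg(format, c("ascii", "tiff"))
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (format == "ascii") {
    lines <- readLines(path)
    hdr <- lines[1:6]
    kv <- strsplit(trimws(hdr), "\\s+")
    key <- tolower(vapply(kv, `[`, "", 1L))
    val <- as.numeric(vapply(kv, `[`, "", 2L))
    names(val) <- key
    n_rows <- as.integer(val[["nrows"]]); n_cols <- as.integer(val[["ncols"]])
    cs <- val[["cellsize"]]
    meta <- grid_meta(n_rows, n_cols, cs,
                      origin_x = val[["xllcorner"]],
                      origin_y = val[["yllcorner"]] + n_rows * cs,
                      nodata_value = val[["nodata_value"]])
    body <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
                 quiet = TRUE)
    if (length(body) != n_rows * n_cols)
      stop("'", path, "': expected ", n_rows * n_cols, " cells, got ",
           length(body), call. = FALSE)
    field <- matrix(body, n_rows, n_cols, byrow = TRUE)
    field[field == meta$nodata_value] <- NA_real_
  } else {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("missing metadata sidecar '", side, "'", call. = FALSE)
    sj <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta <- do.call(grid_meta, as.list(sj$meta))
    # two-channel greyscale+mask layout triggers a harmless libtiff notice
    img <- suppressWarnings(tiff::readTIFF(path))
    field <- img[, , 1L] * sj$span + sj$vmin
    field[img[, , 2L] < 0.5] <- NA_real_
  }
  list(field = field, meta = meta)
}

#' Read a gap-free monthly cube from one-file-per-month rasters
#'
#' File order must follow the time axis. Times are taken from `times` when
#' given, otherwise parsed from a `YYYY-MM` (or `YYYY_MM`) token in each file
#' name. All files must share identical grid geometry; a gap in the monthly
#' calendar is a hard error naming the missing month.
#'
#' @param paths Ordered character vector of raster paths.
#' @param units Unit string recorded on the cube.
#' @param times Optional data frame with `year`, `month` columns (one row per
#'   file).
#' @param format Forwarded to [read_field()].
#' @return A [grid_cube()].
#' @export
read_cube <- function(paths, units = "", times = NULL, format = NULL) {
  stopifnot(length(paths) >= 1L)
  if (is.null(times)) {
    m <- regmatches(basename(paths),
                    regexpr("([0-9]{4})[-_]([0-9]{2})", basename(paths)))
    if (length(m) != length(paths))
      stop("cannot parse YYYY-MM from all file names; pass times= explicitly")
    times <- data.frame(year = as.integer(substr(m, 1, 4)),
                        month = as.integer(substr(m, 6, 7)))
  }
  first <- read_field(paths[1L], format)
  meta <- first$meta
  vals <- array(NA_real_,
                c(length(paths), meta$n_rows, meta$n_cols))
  vals[1L, , ] <- first$field
  for (i in seq_along(paths)[-1L]) {
    fi <- read_field(paths[i], format)
    if (!same_grid(fi$meta, meta))
      stop("grid geometry of '", paths[i],
           "' does not match the first file", call. = FALSE)
    vals[i, , ] <- fi$field
  }
  grid_cube(vals, meta, times, units)
}

#' Write every time slice of a cube as one raster per month
#'
#' File names are `<prefix>_YYYY-MM.<ext>`.
#'
#' @param cube A [grid_cube()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param format `"ascii"` or `"tiff"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_cube <- function(cube, dir, prefix, format = c("ascii", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "ascii") "asc" else "tif"
  paths <- file.path(dir, sprintf("%s_%04d-%02d.%s", prefix,
                                  cube$times$year, cube$times$month, ext))
  for (i in seq_len(n_times(cube)))
    write_field(cube$values[i, , ], cube$meta, paths[i], format)
  invisible(paths)
}

#' Read a drought-event catalog
#'
#' A CSV with columns `start_year`, `start_month`, `end_year`, `end_month`,
#' `label`; one row per historical event (multi-year winter events are single
#' rows).
#'
#' @param path CSV path.
#' @return Data frame with integer span columns and a character label.
#' @export
read_event_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_year", "start_month", "end_year", "end_month", "label")
  if (!all(need %in% names(cat)))
    stop("event catalog must have columns: ", paste(need, collapse = ", "))
  for (cc in need[1:4]) cat[[cc]] <- as.integer(cat[[cc]])
  bad <- with(cat, end_year * 12 + end_month < start_year * 12 + start_month)
  if (any(bad)) stop("event ends before it starts: row ", which(bad)[1])
  cat
}

#' Write a drought-event catalog CSV
#' @param catalog Data frame as returned by [make_event_catalog()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_event_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE)
  invisible(path)
}

#' Nearest-neighbour / bilinear resampling utility
#'
#' Provided for pre-aligning inputs only; no module ever calls it implicitly.
#' Maps each target cell centre into the source grid.
#'
#' @param field Source matrix.
#' @param meta Source [grid_meta()].
#' @param target Target [grid_meta()] (same CRS assumed).
#' @param method `"nearest"` or `"bilinear"`.
#' @return Matrix on the target grid (`NA` outside the source extent).
#' @export
resample_field <- function(field, meta, target,
                           method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  # target cell-centre coordinates
  tx <- target$origin_x + (seq_len(target$n_cols) - 0.5) * target$cell_size
  ty <- target$origin_y - (seq_len(target$n_rows) - 0.5) * target$cell_size
  # fractional source indices (1-based, centre of source cell i is i - 0.5)
  cx <- (outer(rep(1, target$n_rows), tx) - meta$origin_x) / meta$cell_size + 0.5
  ry <- (meta$origin_y - outer(ty, rep(1, target$n_cols))) / meta$cell_size + 0.5
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (method == "nearest") {
    ri <- round(ry); ci <- round(cx)
    ok <- ri >= 1 & ri <= meta$n_rows & ci >= 1 & ci <= meta$n_cols
    out[ok] <- field[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(ry); c0 <- floor(cx)
    fr <- ry - r0; fc <- cx - c0
    ok <- r0 >= 1 & r0 + 1 <= meta$n_rows & c0 >= 1 & c0 + 1 <= meta$n_cols
    idx <- which(ok)
    g <- function(dr, dc) field[cbind(r0[idx] + dr, c0[idx] + dc)]
    out[idx] <- g(0, 0) * (1 - fr[idx]) * (1 - fc[idx]) +
      g(0, 1) * (1 - fr[idx]) * fc[idx] +
      g(1, 0) * fr[idx] * (1 - fc[idx]) +
      g(1, 1) * fr[idx] * fc[idx]
  }
  out
}
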