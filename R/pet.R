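#' Monthly potential evapotranspiration by the Thornthwaite method
#'
#' Temperature-only PET, the minimal-input formulation commonly used to build
#' SPEI. Per pixel, the annual heat index is
#' \eqn{I = \sum_m (\bar T_m / 5)^{1.514}} over calendar months whose
#' multi-year mean temperature \eqn{\bar T_m} is positive, the exponent is
#' \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 + 1.792\times10^{-2}
#' I + 0.49239}, and monthly PET (mm) is
#' \eqn{16 (10 T / I)^a \cdot K} with \eqn{K = (N/12)(\mathrm{days}/30)} the
#' day-length/month-length correction at the cell-centre latitude. PET is 0
#' for months with \eqn{T \le 0}.
#'
#' @param temp [grid_cube()] of monthly mean air temperature (degC).
#' @param latitude Optional numeric vector of per-row cell-centre latitudes
#'   (degrees); defaults to [row_latitudes()] of the cube's grid, which
#'   assumes a geographic (degree) grid.
#' @return A [grid_cube()] of PET in mm per month.
#' @export
pet_thornthwaite <- function(temp, latitude = NULL) {
  stopifnot(inherits(temp, "grid_cube"))
  if (is.null(latitude)) latitude <- row_latitudes(temp$meta)
  if (length(latitude) == 1L) latitude <- rep(latitude, temp$meta$n_rows)
  stopifnot(length(latitude) == temp$meta$n_rows)
  if (any(abs(latitude) > 66.5))
    stop("|latitude| > 66.5 degrees: day-length correction undefined ",
         "(polar day/night)", call. = FALSE)
  nr <- temp$meta$n_rows; nc <- temp$meta$n_cols
  mon <- temp$times$month

  # multi-year mean temperature per calendar month -> heat index per pixel
  tbar <- array(NA_real_, c(12L, nr, nc))
  for (m in 1:12) {
    sel <- mon == m
    if (any(sel))
      tbar[m, , ] <- apply(temp$values[sel, , , drop = FALSE], c(2, 3), mean)
  }
  hi <- apply(tbar, c(2, 3), function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) 0 else sum((v / 5)^1.514)
  })
  a <- 6.75e-7 * hi^3 - 7.71e-5 * hi^2 + 1.792e-2 * hi + 0.49239

  kmat <- thornthwaite_correction(latitude)     # [12, n_rows]
  out <- array(NA_real_, dim(temp$values))
  for (i in seq_len(n_times(temp))) {
    tt <- temp$values[i, , ]
    pet <- 16 * (10 * pmax(tt, 0) / hi)^a * kmat[mon[i], ]
    pet[hi == 0] <- 0          # all-frozen climatology: no atmospheric demand
    pet[!is.na(tt) & tt <= 0] <- 0
    pet[is.na(tt)] <- NA_real_
    out[i, , ] <- pet
  }
  cube_like(temp, out, units = "mm")
}

# K = (N/12) * (days/30): mid-month day length N from the sunset hour angle
# at the given latitudes; returns a [12 x length(lat)] matrix.
thornthwaite_correction <- function(lat) {
  days_in_month <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  midday <- cumsum(days_in_month) - days_in_month / 2
  decl <- 0.409 * sin(2 * pi * midday / 365.25 - 1.39)  # solar declination
  phi <- lat * pi / 180
  tt <- -outer(tan(decl), tan(phi))
  tt <- pmin(pmax(tt, -1), 1)
  omega <- acos(tt)
  nday <- 24 * omega / pi
  sweep(nday / 12, 1L, days_in_month / 30, `*`)
}
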