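#' CASA model parameters
#'
#' Parameters of the light-use-efficiency NPP model
#' \eqn{NPP = APAR \times \varepsilon}, with
#' \eqn{\varepsilon = T_1 T_2 W \varepsilon_{max}}. The maximum light-use
#' efficiency is per vegetated land-cover class; defaults (farmland 0.542,
#' woodland 0.692, grassland 0.542 gC/MJ) follow the widely used modified-CASA
#' parameterization for Chinese vegetation and are fully overridable.
#'
#' @param eps_max Named numeric vector (gC/MJ) for classes `farmland`,
#'   `woodland`, `grassland`; all > 0.
#' @param ndvi_bounds Per-class NDVI (min, max) used by the FPAR ramp, as a
#'   named list of length-2 vectors, or `NULL` to derive the 5th/95th
#'   percentile of each class's NDVI record at run time.
#' @param fpar_bounds Length-2 vector `(FPAR_min, FPAR_max)` with
#'   `0 <= min < max <= 1`.
#' @param fpar_mix_alpha Weight in `[0, 1]` of the NDVI-ramp FPAR estimate
#'   versus the simple-ratio estimate (0.5 averages them).
#' @param water_stress_mode `"et_ratio"` (precipitation/PET based, default)
#'   or `"soil_moisture"`.
#' @param rn_a,rn_b Coefficients of the net-radiation proxy
#'   `Rn = PET * (rn_a + rn_b * P/PET)` used by the `et_ratio` mode
#'   (heuristic defaults, see the methods vignette).
#' @return An object of class `casa_params`.
#' @export
casa_params <- function(eps_max = c(farmland = 0.542, woodland = 0.692,
                                    grassland = 0.542),
                        ndvi_bounds = NULL,
                        fpar_bounds = c(0.001, 0.95),
                        fpar_mix_alpha = 0.5,
                        water_stress_mode = c("et_ratio", "soil_moisture"),
                        rn_a = 0.4, rn_b = 0.3) {
  water_stress_mode <- match.arg(water_stress_mode)
  stopifnot(all(eps_max > 0), length(fpar_bounds) == 2L,
            fpar_bounds[1] >= 0, fpar_bounds[1] < fpar_bounds[2],
            fpar_bounds[2] <= 1,
            fpar_mix_alpha >= 0, fpar_mix_alpha <= 1)
  if (!is.null(ndvi_bounds)) {
    for (b in ndvi_bounds) stopifnot(length(b) == 2L, b[1] < b[2])
  }
  structure(list(eps_max = eps_max, ndvi_bounds = ndvi_bounds,
                 fpar_bounds = fpar_bounds, fpar_mix_alpha = fpar_mix_alpha,
                 water_stress_mode = water_stress_mode,
                 rn_a = rn_a, rn_b = rn_b),
            class = "casa_params")
}

# resolve per-class NDVI bounds: configured, or 5th/95th percentile of the
# class's NDVI record
resolve_ndvi_bounds <- function(ndvi, landcover, params) {
  cnames <- landcover_class_names()
  out <- list()
  for (k in vegetated_classes()) {
    nm <- cnames[k]
    if (!is.null(params$ndvi_bounds) && !is.null(params$ndvi_bounds[[nm]])) {
      out[[nm]] <- params$ndvi_bounds[[nm]]
    } else {
      sel <- which(landcover$classes == k)
      if (!length(sel)) next
      flat <- matrix(ndvi$values, n_times(ndvi))
      vals <- flat[, sel, drop = FALSE]
      qs <- stats::quantile(vals, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
      if (qs[1] >= qs[2]) qs <- qs + c(-1e-6, 1e-6)
      out[[nm]] <- qs
    }
  }
  out
}

#' Fraction of absorbed photosynthetically active radiation from NDVI
#'
#' Per vegetated class, FPAR is the `fpar_mix_alpha`-weighted mean of two
#' clamped estimates: the NDVI ramp
#' `(NDVI - NDVI_min)/(NDVI_max - NDVI_min) * (FPAR_max - FPAR_min) +
#' FPAR_min` and the analogous ramp on the simple ratio
#' `SR = (1 + NDVI)/(1 - NDVI)` (NDVI clamped to <= 0.99 first so SR stays
#' defined). Output is within `fpar_bounds` and non-decreasing in NDVI.
#' Non-vegetated cells are masked.
#'
#' @param ndvi NDVI [grid_cube()], values in `[-1, 1]`.
#' @param landcover [land_cover_map()].
#' @param params [casa_params()].
#' @return FPAR [grid_cube()].
#' @export
fpar <- function(ndvi, landcover, params = casa_params()) {
  check_same_grid(ndvi, landcover, "ndvi and landcover")
  if (any(ndvi$values < -1 | ndvi$values > 1, na.rm = TRUE))
    stop("NDVI outside [-1, 1]")
  bounds <- resolve_ndvi_bounds(ndvi, landcover, params)
  f1 <- params$fpar_bounds[1]; f2 <- params$fpar_bounds[2]
  al <- params$fpar_mix_alpha
  cnames <- landcover_class_names()
  out <- array(NA_real_, dim(ndvi$values))
  nt <- n_times(ndvi)
  clamp <- function(x) pmin(pmax(x, f1), f2)
  for (k in vegetated_classes()) {
    nm <- cnames[k]
    if (is.null(bounds[[nm]])) next
    sel <- which(landcover$classes == k)
    if (!length(sel)) next
    nb <- bounds[[nm]]
    sr_min <- (1 + nb[1]) / (1 - min(nb[1], 0.99))
    sr_max <- (1 + nb[2]) / (1 - min(nb[2], 0.99))
    for (i in seq_len(nt)) {
      nd <- ndvi$values[i, , ][sel]
      ramp <- (nd - nb[1]) / (nb[2] - nb[1]) * (f2 - f1) + f1
      sr <- (1 + pmin(nd, 0.99)) / (1 - pmin(nd, 0.99))
      srp <- (sr - sr_min) / (sr_max - sr_min) * (f2 - f1) + f1
      out[i, , ][sel] <- al * clamp(ramp) + (1 - al) * clamp(srp)
    }
  }
  cube_like(ndvi, out, units = "")
}

#' Optimal temperature map
#'
#' Per pixel, the mean air temperature of the calendar month whose multi-year
#' mean NDVI is maximal (ties broken toward the earliest month). Pixels with
#' all-masked NDVI are masked.
#'
#' @param ndvi NDVI [grid_cube()].
#' @param temp Temperature [grid_cube()] on the same grid and calendar.
#' @return Matrix of optimal temperatures (degC).
#' @export
optimal_temperature <- function(ndvi, temp) {
  check_same_grid(ndvi, temp, "ndvi and temp")
  if (!identical(ndvi$times, temp$times))
    stop("ndvi and temp must share the same time axis")
  nr <- ndvi$meta$n_rows; nc <- ndvi$meta$n_cols
  mon <- ndvi$times$month
  nbar <- array(NA_real_, c(12L, nr, nc))
  tbar <- array(NA_real_, c(12L, nr, nc))
  for (m in 1:12) {
    sel <- mon == m
    if (!any(sel)) next
    nbar[m, , ] <- apply(ndvi$values[sel, , , drop = FALSE], c(2, 3), mean)
    tbar[m, , ] <- apply(temp$values[sel, , , drop = FALSE], c(2, 3), mean)
  }
  topt <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    v <- nbar[, r, cc]
    if (all(is.na(v))) next
    m_star <- which.max(v)     # which.max returns the first (earliest) max
    topt[r, cc] <- tbar[m_star, r, cc]
  }
  topt
}

#' Temperature stress scalars T1 and T2
#'
#' `T1 = 0.8 + 0.02 Topt - 0.0005 Topt^2` expresses the suitability of the
#' pixel's optimal temperature itself;
#' `T2 = 1.1814 / (1 + exp(0.2 (Topt - 10 - T))) / (1 + exp(0.3 (-Topt - 10
#' + T)))` penalizes months whose temperature departs from the optimum. Both
#' are clamped to >= 0.
#'
#' @param temp Temperature [grid_cube()].
#' @param topt Optimal-temperature matrix from [optimal_temperature()].
#' @return List of two [grid_cube()]s, `t1` and `t2`.
#' @export
temperature_stress <- function(temp, topt) {
  stopifnot(inherits(temp, "grid_cube"), is.matrix(topt))
  t1m <- pmax(0.8 + 0.02 * topt - 0.0005 * topt^2, 0)
  nt <- n_times(temp)
  t1v <- array(NA_real_, dim(temp$values))
  t2v <- array(NA_real_, dim(temp$values))
  for (i in seq_len(nt)) {
    tt <- temp$values[i, , ]
    t1v[i, , ] <- t1m
    t2 <- 1.1814 / (1 + exp(0.2 * (topt - 10 - tt))) /
      (1 + exp(0.3 * (-topt - 10 + tt)))
    t2v[i, , ] <- pmax(t2, 0)
  }
  list(t1 = cube_like(temp, t1v, units = ""),
       t2 = cube_like(temp, t2v, units = ""))
}

#' Water stress scalar W
#'
#' In `"et_ratio"` mode, `W = 0.5 + 0.5 * EET/PET` with the estimated
#' evapotranspiration from the precipitation/net-radiation coupling
#' `EET = P * Rn * (P^2 + Rn^2 + P*Rn) / ((P + Rn) * (P^2 + Rn^2))` and
#' `Rn = PET * (rn_a + rn_b * P/PET)` (heuristic proxy). In
#' `"soil_moisture"` mode, `W = 0.5 + 0.5 * SM / SM_p95` with the per-pixel
#' 95th percentile. Either way W is clipped to `[0.5, 1]`; months with
#' `PET <= 0` get the fully stressed floor 0.5.
#'
#' @param precip Precipitation [grid_cube()] (mm).
#' @param pet PET [grid_cube()] (mm); required for `et_ratio`.
#' @param sm Soil-moisture [grid_cube()]; required for `soil_moisture`.
#' @param params [casa_params()] (supplies mode and Rn coefficients).
#' @return W [grid_cube()], values in `[0.5, 1]`.
#' @export
water_stress <- function(precip, pet = NULL, sm = NULL,
                         params = casa_params()) {
  mode <- params$water_stress_mode
  if (mode == "et_ratio") {
    stopifnot(!is.null(pet))
    check_same_grid(precip, pet, "precip and pet")
    p <- precip$values
    petv <- pet$values
    rn <- petv * params$rn_a + params$rn_b * p
    eet <- zhou_zhang_eet(p, rn)
    ratio <- ifelse(petv > 0, pmin(eet / petv, 1), 0)
    w <- 0.5 + 0.5 * ratio
  } else {
    stopifnot(!is.null(sm))
    check_same_grid(precip, sm, "precip and sm")
    p95 <- apply(sm$values, c(2, 3), stats::quantile, probs = 0.95,
                 na.rm = TRUE)
    w <- array(NA_real_, dim(sm$values))
    for (i in seq_len(dim(sm$values)[1L])) {
      r <- ifelse(p95 > 0, pmin(sm$values[i, , ] / p95, 1), 0)
      w[i, , ] <- 0.5 + 0.5 * r
    }
  }
  w <- pmin(pmax(w, 0.5), 1)
  cube_like(precip, w, units = "")
}

# Zhou-Zhang evapotranspiration coupling of precipitation and net radiation
zhou_zhang_eet <- function(p, rn) {
  num <- p * rn * (p^2 + rn^2 + p * rn)
  den <- (p + rn) * (p^2 + rn^2)
  out <- ifelse(den > 0, num / den, 0)
  pmax(out, 0)
}

#' Absorbed photosynthetically active radiation
#'
#' `APAR = 0.5 * SOL * FPAR`; the coefficient 0.5 is the fraction of total
#' solar radiation that is photosynthetically active.
#'
#' @param sol Total solar radiation [grid_cube()] (MJ m-2 month-1), >= 0.
#' @param fpar_cube FPAR [grid_cube()] from [fpar()].
#' @return APAR [grid_cube()] (MJ m-2 month-1).
#' @export
apar <- function(sol, fpar_cube) {
  check_same_grid(sol, fpar_cube, "sol and fpar")
  if (any(sol$values < 0, na.rm = TRUE))
    stop("negative solar radiation")
  cube_like(sol, 0.5 * sol$values * fpar_cube$values,
            units = "MJ m-2 month-1")
}

#' Monthly NPP from the CASA factorization
#'
#' `NPP = APAR * T1 * T2 * W * eps_max(class)` per pixel-month, in
#' gC m-2 month-1. Non-vegetated classes are masked. A vegetated class
#' present in the land cover but missing from `eps_max` is a hard error.
#'
#' @param apar_cube APAR [grid_cube()].
#' @param t1,t2 Temperature-stress cubes from [temperature_stress()].
#' @param w Water-stress cube from [water_stress()].
#' @param landcover [land_cover_map()].
#' @param params [casa_params()].
#' @return Monthly NPP [grid_cube()] (class `npp_cube` prepended).
#' @export
npp_monthly <- function(apar_cube, t1, t2, w, landcover,
                        params = casa_params()) {
  for (x in list(t1, t2, w, landcover))
    check_same_grid(apar_cube, x, "CASA inputs")
  cnames <- landcover_class_names()
  present <- intersect(unique(as.vector(landcover$classes)),
                       vegetated_classes())
  missing_eps <- setdiff(cnames[present], names(params$eps_max))
  if (length(missing_eps))
    stop("eps_max missing for vegetated class(es): ",
         paste(missing_eps, collapse = ", "))
  eps_map <- matrix(NA_real_, apar_cube$meta$n_rows, apar_cube$meta$n_cols)
  for (k in present)
    eps_map[landcover$classes == k] <- params$eps_max[[cnames[k]]]
  nt <- n_times(apar_cube)
  out <- array(NA_real_, dim(apar_cube$values))
  for (i in seq_len(nt)) {
    out[i, , ] <- apar_cube$values[i, , ] * t1$values[i, , ] *
      t2$values[i, , ] * w$values[i, , ] * eps_map
  }
  res <- cube_like(apar_cube, out, units = "gC m-2 month-1")
  class(res) <- c("npp_cube", class(res))
  res
}

#' One-call CASA NPP from raw inputs
#'
#' Convenience wrapper chaining [fpar()], [optimal_temperature()],
#' [temperature_stress()], [water_stress()], [apar()] and [npp_monthly()].
#'
#' @param ndvi,temp,sol,precip Input [grid_cube()]s.
#' @param landcover [land_cover_map()].
#' @param pet PET cube; computed by [pet_thornthwaite()] from `temp` when
#'   `NULL`.
#' @param sm Soil moisture cube (only needed for
#'   `water_stress_mode = "soil_moisture"`).
#' @param params [casa_params()].
#' @return Monthly NPP [grid_cube()].
#' @export
casa_npp <- function(ndvi, temp, sol, precip, landcover, pet = NULL,
                     sm = NULL, params = casa_params()) {
  if (is.null(pet)) pet <- pet_thornthwaite(temp)
  fp <- fpar(ndvi, landcover, params)
  topt <- optimal_temperature(ndvi, temp)
  ts <- temperature_stress(temp, topt)
  w <- water_stress(precip, pet, sm, params)
  npp_monthly(apar(sol, fp), ts$t1, ts$t2, w, landcover, params)
}

#' Annual NPP field for one year
#'
#' Per-pixel sum of the 12 monthly NPP values of `year`; a pixel with any
#' masked month is masked. An incomplete year is a hard error.
#'
#' @param npp Monthly NPP [grid_cube()].
#' @param year Calendar year.
#' @return Matrix in gC m-2 a-1.
#' @export
npp_annual <- function(npp, year) {
  sel <- which(npp$times$year == year)
  if (length(sel) != 12L)
    stop("year ", year, " has ", length(sel), " months in the cube; need 12")
  apply(npp$values[sel, , , drop = FALSE], c(2, 3), function(v) {
    if (anyNA(v)) NA_real_ else sum(v)
  })
}

#' Annualize a monthly cube
#'
#' Aggregates each complete calendar year by sum (fluxes: NPP,
#' precipitation, radiation) or mean (states: temperature, indices).
#' Incomplete leading/trailing years are dropped.
#'
#' @param cube Monthly [grid_cube()].
#' @param fun `"sum"` or `"mean"`.
#' @return List with `years` (integer vector) and `values`
#'   (`[year, row, col]` array).
#' @export
annualize <- function(cube, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  yrs <- unique(cube$times$year)
  yrs <- yrs[vapply(yrs, function(y) sum(cube$times$year == y) == 12L,
                    logical(1))]
  out <- array(NA_real_, c(length(yrs), cube$meta$n_rows, cube$meta$n_cols))
  f <- if (fun == "sum") colSums else colMeans
  for (i in seq_along(yrs)) {
    sel <- cube$times$year == yrs[i]
    out[i, , ] <- f(cube$values[sel, , , drop = FALSE], dims = 1L)
  }
  list(years = yrs, values = out)
}

#' Benchmark agreement of class-mean annual NPP against a reference
#'
#' Regresses class-by-year mean annual NPP from the model against the same
#' aggregate of a reference NPP cube and reports R-squared and the
#' regression p-value (the agreement check used to validate a CASA run
#' against an independent NPP product).
#'
#' @param npp Modelled monthly NPP [grid_cube()].
#' @param reference Reference monthly NPP [grid_cube()] on the same grid.
#' @param landcover [land_cover_map()].
#' @return List with `r_squared`, `p_value`, `n` and the fitted `lm` object.
#' @export
benchmark_agreement <- function(npp, reference, landcover) {
  check_same_grid(npp, reference, "npp and reference")
  a1 <- annualize(npp, "sum"); a2 <- annualize(reference, "sum")
  yrs <- intersect(a1$years, a2$years)
  xs <- ys <- numeric(0)
  for (k in vegetated_classes()) {
    sel <- landcover$classes == k
    if (!any(sel, na.rm = TRUE)) next
    for (y in yrs) {
      i1 <- which(a1$years == y); i2 <- which(a2$years == y)
      xs <- c(xs, mean(a1$values[i1, , ][sel], na.rm = TRUE))
      ys <- c(ys, mean(a2$values[i2, , ][sel], na.rm = TRUE))
    }
  }
  fit <- stats::lm(ys ~ xs)
  sm <- summary(fit)
  pv <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  list(r_squared = sm$r.squared, p_value = pv, n = length(xs), fit = fit)
}
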