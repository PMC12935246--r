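#' Configuration for the synthetic monthly-cube generator
#'
#' Defines a 20-year (default 2001-2020, 240 months) monthly scenario on a
#' small grid, with seasonal cycles, prescribed linear trends, gamma-like
#' precipitation, a leaky-bucket soil-moisture recursion coupled to
#' Thornthwaite PET, class-specific NDVI coupled to the 3-month
#' precipitation anomaly, and embedded drought episodes that multiply
#' precipitation by `1 - deficit_fraction` over their span and region.
#' Default climate normals follow a warm-temperate semi-humid setting
#' (mean temperature 10.74 degC, annual precipitation 580.52 mm, trends
#' +0.02 degC/a and +2.65 mm/a).
#'
#' @param n_rows,n_cols Grid size.
#' @param years Length-2 integer vector `(start, end)` of calendar years.
#' @param seed Mandatory RNG seed (integer).
#' @param temp_mean,temp_amp,temp_trend,temp_noise_sd Temperature (degC)
#'   annual mean, seasonal semi-amplitude (July peak), linear trend per year
#'   and white-noise SD.
#' @param precip_annual_mean,precip_trend Annual precipitation total (mm) and
#'   its linear trend (mm/a).
#' @param precip_seasonality Relative summer concentration in `[0, 1)` of the
#'   monthly climatology (0 = uniform across months).
#' @param precip_gamma_shape Gamma shape of monthly precipitation around its
#'   climatological mean; `Inf` makes precipitation deterministic.
#' @param sol_mean,sol_amp,sol_noise_sd Solar radiation (MJ m-2 month-1)
#'   mean, seasonal semi-amplitude (June peak) and noise SD.
#' @param sm_capacity,sm_leak,sm_infil,sm_et Leaky-bucket parameters:
#'   capacity (volumetric fraction), monthly leakage fraction, infiltration
#'   per mm precipitation, depletion per mm PET.
#' @param ndvi_base,ndvi_amp Named-by-class (farmland, woodland, grassland)
#'   seasonal NDVI mean and semi-amplitude.
#' @param ndvi_coupling Per-class sensitivity of NDVI (logit scale) to the
#'   standardized 3-month precipitation anomaly; the generator's ground
#'   truth for coupling-recovery experiments.
#' @param ndvi_noise_sd NDVI white-noise SD.
#' @param noise_corr_len Optional Gaussian-blur correlation length (cells)
#'   applied to all noise fields; 0 = spatially white.
#' @param drought_events List of events, each
#'   `list(start = c(year, month), end = c(year, month), deficit_fraction,
#'   rows = NULL, cols = NULL, label = "...")`; `NULL` rows/cols mean the
#'   whole grid. See [default_drought_events()].
#' @param landcover_layout `"stripes6"` (six equal column bands, classes
#'   1..6) or an explicit integer matrix.
#' @param cell_size,origin_x,origin_y Grid geometry; defaults place the grid
#'   in a mid-latitude band (~34-40 deg N) on a 0.25-degree grid.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_rows = 24, n_cols = 24, years = c(2001, 2020),
                         seed,
                         temp_mean = 10.74, temp_amp = 14,
                         temp_trend = 0.02, temp_noise_sd = 0.8,
                         precip_annual_mean = 580.52, precip_trend = 2.65,
                         precip_seasonality = 0.85,
                         precip_gamma_shape = 2.5,
                         sol_mean = 430, sol_amp = 180, sol_noise_sd = 15,
                         sm_capacity = 0.45, sm_leak = 0.15,
                         sm_infil = 0.003, sm_et = 0.0015,
                         ndvi_base = c(farmland = 0.45, woodland = 0.55,
                                       grassland = 0.40),
                         ndvi_amp = c(farmland = 0.25, woodland = 0.22,
                                      grassland = 0.25),
                         ndvi_coupling = c(farmland = 0.4, woodland = 0.15,
                                           grassland = 0.8),
                         ndvi_noise_sd = 0.02,
                         noise_corr_len = 0,
                         drought_events = default_drought_events(),
                         landcover_layout = "stripes6",
                         cell_size = 0.25, origin_x = 110, origin_y = 40) {
  if (missing(seed)) stop("seed is mandatory in synth_config")
  stopifnot(length(years) == 2L, years[2] >= years[1],
            is.finite(temp_trend), is.finite(precip_trend),
            precip_seasonality >= 0, precip_seasonality < 1)
  for (ev in drought_events) {
    if (!is.null(ev$deficit_fraction) &&
        (ev$deficit_fraction <= 0 || ev$deficit_fraction >= 1))
      stop("deficit_fraction must be in (0, 1)")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Default embedded drought-event calendar
#'
#' Six region-wide events spanning 2001-2020, including multi-season and
#' cross-year winter episodes, in the style of a historical drought catalog.
#'
#' @return List of event specifications for [synth_config()].
#' @export
default_drought_events <- function() {
  ev <- function(sy, sm, ey, em, f, lab)
    list(start = c(sy, sm), end = c(ey, em), deficit_fraction = f,
         rows = NULL, cols = NULL, label = lab)
  list(
    ev(2004, 3, 2004, 5, 0.45, "spring drought 2004"),
    ev(2005, 3, 2005, 8, 0.40, "spring-summer drought 2005"),
    ev(2008, 11, 2009, 8, 0.40, "winter-spring-summer drought 2008-2009"),
    ev(2010, 6, 2010, 11, 0.50, "summer-autumn drought 2010"),
    ev(2013, 12, 2014, 8, 0.45, "winter-spring-summer drought 2013-2014"),
    ev(2017, 10, 2018, 2, 0.40, "autumn-winter drought 2017-2018"))
}

# month index helpers
month_serial <- function(y, m) y * 12L + (m - 1L)

monthly_calendar <- function(years) {
  data.frame(year = rep(years[1]:years[2], each = 12L),
             month = rep(1:12, years[2] - years[1] + 1L))
}

# optional spatial smoothing of a noise matrix (separable gaussian kernel)
blur2d <- function(x, len) {
  if (len <= 0) return(x)
  half <- max(1L, ceiling(2 * len))
  k <- stats::dnorm(-half:half, sd = len)
  k <- k / sum(k)
  pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
  sm_rows <- t(apply(x, 1L, function(r)
    stats::filter(pad(r, half), k, sides = 2)[(half + 1):(half + length(r))]))
  apply(sm_rows, 2L, function(cl)
    stats::filter(pad(cl, half), k, sides = 2)[(half + 1):(half + length(cl))])
}

#' Generate a synthetic monthly climate/NDVI scenario
#'
#' Produces precipitation, temperature, solar radiation, soil moisture and
#' NDVI cubes plus a static land-cover map, with a `truth` record of the
#' structure actually embedded (events, coupling coefficients, trends,
#' event-free precipitation climatology). Identical config (same seed) gives
#' bit-identical output.
#'
#' @param config A [synth_config()].
#' @return List with elements `precip`, `temp`, `sol`, `sm`, `ndvi`
#'   ([grid_cube()]s), `landcover` ([land_cover_map()]), and `truth`
#'   (class `synth_truth`).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(cf$seed)
  times <- monthly_calendar(cf$years)
  nt <- nrow(times); nr <- cf$n_rows; nc <- cf$n_cols
  meta <- grid_meta(nr, nc, cf$cell_size, cf$origin_x, cf$origin_y,
                    crs_tag = "EPSG:4326(synthetic)")
  ser0 <- month_serial(times$year[1], times$month[1])
  for (ev in cf$drought_events) {
    s <- month_serial(ev$start[1], ev$start[2])
    e <- month_serial(ev$end[1], ev$end[2])
    if (s < ser0 || e > month_serial(times$year[nt], times$month[nt]))
      stop("drought event '", ev$label %||% "?",
           "' lies outside the configured time range")
  }
  yrfrac <- (month_serial(times$year, times$month) - ser0) / 12
  noise <- function(sd) {
    if (sd == 0) return(matrix(0, nr, nc))
    blur2d(matrix(stats::rnorm(nr * nc, 0, sd), nr, nc), cf$noise_corr_len)
  }

  # --- temperature ---
  tv <- array(NA_real_, c(nt, nr, nc))
  for (i in seq_len(nt)) {
    seas <- cf$temp_mean + cf$temp_amp * cos(2 * pi * (times$month[i] - 7) / 12)
    tv[i, , ] <- seas + cf$temp_trend * yrfrac[i] + noise(cf$temp_noise_sd)
  }
  temp <- grid_cube(tv, meta, times, "degC")

  # --- precipitation ---
  w <- 1 + cf$precip_seasonality * cos(2 * pi * (1:12 - 7) / 12)
  w <- w / sum(w)                        # monthly share of the annual total
  mu_clim <- matrix(NA_real_, nt, 1)
  pv <- array(NA_real_, c(nt, nr, nc))
  for (i in seq_len(nt)) {
    annual <- cf$precip_annual_mean + cf$precip_trend * yrfrac[i]
    mu <- max(annual, 0) * w[times$month[i]]
    mu_clim[i] <- mu
    if (is.finite(cf$precip_gamma_shape)) {
      pv[i, , ] <- matrix(stats::rgamma(nr * nc, shape = cf$precip_gamma_shape,
                                        scale = mu / cf$precip_gamma_shape),
                          nr, nc)
    } else {
      pv[i, , ] <- mu
    }
  }
  # embed drought episodes
  ser <- month_serial(times$year, times$month)
  for (ev in cf$drought_events) {
    span <- ser >= month_serial(ev$start[1], ev$start[2]) &
            ser <= month_serial(ev$end[1], ev$end[2])
    rows <- ev$rows %||% seq_len(nr)
    cols <- ev$cols %||% seq_len(nc)
    pv[span, rows, cols] <- pv[span, rows, cols] * (1 - ev$deficit_fraction)
  }
  precip <- grid_cube(pv, meta, times, "mm")

  # --- solar radiation ---
  sv <- array(NA_real_, c(nt, nr, nc))
  for (i in seq_len(nt)) {
    seas <- cf$sol_mean + cf$sol_amp * cos(2 * pi * (times$month[i] - 6) / 12)
    sv[i, , ] <- pmax(seas + noise(cf$sol_noise_sd), 0)
  }
  sol <- grid_cube(sv, meta, times, "MJ m-2 month-1")

  # --- soil moisture: leaky bucket driven by P and Thornthwaite PET ---
  pet <- pet_thornthwaite(temp)
  smv <- array(NA_real_, c(nt, nr, nc))
  state <- matrix(cf$sm_capacity / 2, nr, nc)
  for (i in seq_len(nt)) {
    state <- (1 - cf$sm_leak) * state +
      cf$sm_infil * pv[i, , ] - cf$sm_et * pet$values[i, , ]
    state <- pmin(pmax(state, 0), cf$sm_capacity)
    smv[i, , ] <- state
  }
  sm <- grid_cube(smv, meta, times, "m3 m-3")

  # --- land cover ---
  landcover <- make_landcover(cf$landcover_layout, meta)

  # --- NDVI: class-specific logistic response to 3-month P anomaly ---
  p3 <- roll_time(pv, 3L, "sum")
  z3 <- array(0, dim(p3))
  for (m in 1:12) {
    rows <- which(times$month == m)
    X <- matrix(p3[rows, , ], length(rows))
    mu <- colMeans(X, na.rm = TRUE)
    sdv <- apply(X, 2L, stats::sd, na.rm = TRUE)
    # degenerate stratum -> zero anomaly (relative tolerance absorbs the
    # rounding of the cumulative-sum rolling window)
    degen <- is.na(sdv) | sdv <= 1e-9 * pmax(abs(mu), 1)
    sdv[degen] <- Inf
    z <- sweep(sweep(X, 2L, mu, `-`), 2L, sdv, `/`)
    z[is.na(z)] <- 0
    z3[rows, , ] <- array(z, c(length(rows), nr, nc))
  }
  cls <- landcover$classes
  ndvi_v <- array(NA_real_, c(nt, nr, nc))
  lo <- 0.05; hi <- 0.95
  cnames <- landcover_class_names()
  for (i in seq_len(nt)) {
    slice <- matrix(0.02, nr, nc)      # water / construction / ice baseline
    for (k in vegetated_classes()) {
      sel <- which(cls == k)
      if (!length(sel)) next
      base <- cf$ndvi_base[[cnames[k]]] +
        cf$ndvi_amp[[cnames[k]]] * cos(2 * pi * (times$month[i] - 7.5) / 12)
      base <- pmin(pmax(base, lo + 0.01), hi - 0.01)
      eta <- stats::qlogis((base - lo) / (hi - lo)) +
        cf$ndvi_coupling[[cnames[k]]] * z3[i, , ][sel]
      slice[sel] <- lo + (hi - lo) * stats::plogis(eta)
    }
    slice <- slice + noise(cf$ndvi_noise_sd)
    veg <- cls %in% vegetated_classes()
    slice[veg] <- pmin(pmax(slice[veg], 0.01), 0.95)
    slice[!veg] <- pmin(pmax(slice[!veg], 0), 0.05)
    ndvi_v[i, , ] <- slice
  }
  ndvi <- grid_cube(ndvi_v, meta, times, "")

  truth <- structure(list(
    seed = cf$seed,
    events = cf$drought_events,
    ndvi_coupling = cf$ndvi_coupling,
    temp_trend = cf$temp_trend,
    precip_trend = cf$precip_trend,
    precip_monthly_mean = as.numeric(mu_clim),
    times = times), class = "synth_truth")

  list(precip = precip, temp = temp, sol = sol, sm = sm, ndvi = ndvi,
       landcover = landcover, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build the static land-cover map from a layout choice
make_landcover <- function(layout, meta) {
  if (is.matrix(layout)) return(land_cover_map(layout, meta))
  if (identical(layout, "stripes6")) {
    band <- ceiling(seq_len(meta$n_cols) / (meta$n_cols / 6))
    band <- pmin(band, 6L)
    cls <- matrix(rep(band, each = meta$n_rows), meta$n_rows, meta$n_cols)
    return(land_cover_map(cls, meta))
  }
  stop("unknown landcover_layout: ", layout)
}

#' Event catalog from a synthetic truth record
#'
#' One CSV-ready row per embedded drought event with its true span;
#' multi-year (e.g. winter) events stay single rows.
#'
#' @param truth A `synth_truth` from [generate_synthetic()].
#' @return Data frame with columns `start_year`, `start_month`, `end_year`,
#'   `end_month`, `label` (zero rows when no events were embedded).
#' @export
make_event_catalog <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  ev <- truth$events
  out <- data.frame(start_year = integer(0), start_month = integer(0),
                    end_year = integer(0), end_month = integer(0),
                    label = character(0), stringsAsFactors = FALSE)
  for (e in ev) {
    out <- rbind(out, data.frame(
      start_year = e$start[1], start_month = e$start[2],
      end_year = e$end[1], end_month = e$end[2],
      label = e$label %||% "", stringsAsFactors = FALSE))
  }
  out
}

#' Impose a drought response on an NPP cube (scenario builder)
#'
#' Multiplies NPP in drought months by `1 - reduction[severity]` for the
#' given land-cover classes, giving a known ground-truth response for
#' recovery experiments with [delta_npp()].
#'
#' @param npp Monthly NPP [grid_cube()].
#' @param severity Severity cube aligned with `npp`.
#' @param landcover [land_cover_map()].
#' @param reduction Named numeric vector of fractional reductions by severity
#'   label (e.g. `c(mild = 0.05, moderate = 0.15, severe = 0.30,
#'   extreme = 0.50)`).
#' @param classes Land-cover codes to affect (default grassland only).
#' @return The modified NPP cube.
#' @export
impose_drought_response <- function(npp, severity, landcover,
                                    reduction = c(mild = 0.05,
                                                  moderate = 0.15,
                                                  severe = 0.30,
                                                  extreme = 0.50),
                                    classes = 3L) {
  check_same_grid(npp, severity, "npp and severity")
  check_same_grid(npp, landcover, "npp and landcover")
  labs <- severity_labels()
  sel_class <- landcover$classes %in% classes
  out <- npp$values
  for (i in seq_len(n_times(npp))) {
    s <- severity$values[i, , ]
    for (code in 1:4) {
      f <- unname(reduction[labs[code + 1L]])
      if (length(f) != 1L || is.na(f)) next
      hit <- !is.na(s) & s == code & sel_class
      out[i, , ][hit] <- out[i, , ][hit] * (1 - f)
    }
  }
  cube_like(npp, out)
}
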