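#' Drought index cube constructor
#'
#' A [grid_cube()] of standardized drought-index values (unitless, roughly
#' N(0,1) within each calendar-month stratum) carrying the accumulation scale
#' `scale_k` and the index kind. The first `scale_k - 1` time steps are
#' masked because the accumulation window is incomplete there.
#'
#' @param cube A [grid_cube()] of index values.
#' @param scale_k Accumulation scale in months (positive integer).
#' @param index_kind `"spei"` or `"ssmi"`.
#' @return An object of classes `drought_index_cube`, `grid_cube`.
#' @export
drought_index_cube <- function(cube, scale_k, index_kind = c("spei", "ssmi")) {
  index_kind <- match.arg(index_kind)
  stopifnot(inherits(cube, "grid_cube"), scale_k >= 1)
  cube$scale_k <- as.integer(scale_k)
  cube$index_kind <- index_kind
  class(cube) <- c("drought_index_cube", class(cube))
  cube
}

#' @export
print.drought_index_cube <- function(x, ...) {
  cat(sprintf("%s-%d drought index cube\n", toupper(x$index_kind), x$scale_k))
  NextMethod()
}

# k-month backward-looking rolling aggregate along the time axis;
# first k-1 steps NA.
roll_time <- function(values, k, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  if (k == 1L) return(values)
  nt <- dim(values)[1L]
  if (k > nt) stop("accumulation scale k exceeds record length")
  flat <- matrix(values, nt, prod(dim(values)[2:3]))
  cs <- apply(flat, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nt)
  out <- matrix(NA_real_, nt, ncol(flat))
  out[k:nt, ] <- cs[k:nt, , drop = FALSE] -
    rbind(0, cs[seq_len(nt - k), , drop = FALSE])
  if (fun == "mean") out <- out / k
  array(out, dim(values))
}

#' Standardized Precipitation Evapotranspiration Index
#'
#' The k-month accumulated climatic water balance \eqn{D = P - PET} is
#' fitted, per pixel and per calendar-month stratum, with a three-parameter
#' log-logistic distribution estimated by L-moments (unbiased
#' probability-weighted moments). The fitted cumulative probability is mapped
#' to a standard normal deviate with the classical rational approximation
#' (c0 = 2.515517, c1 = 0.802853, c2 = 0.010328, d1 = 1.432788,
#' d2 = 0.189269, d3 = 0.001308). Negative values indicate drier than the
#' stratum's fitted climatology. The fit reference period is the full record.
#'
#' @param precip [grid_cube()] of monthly precipitation (mm).
#' @param pet [grid_cube()] of monthly PET (mm), same grid/calendar.
#' @param scale_k Accumulation scale in months (1, 3, 12, ...).
#' @param prob_clip Fitted probabilities are clipped to
#'   `[prob_clip, 1 - prob_clip]` before the inverse-normal map (tail
#'   safety).
#' @param min_n Minimum valid values per pixel-stratum to attempt the fit;
#'   fewer, or a degenerate (zero-variance) series, masks that pixel-stratum
#'   (counted in a warning).
#' @return A [drought_index_cube()] with `index_kind = "spei"`.
#' @export
spei <- function(precip, pet, scale_k = 1L, prob_clip = 1e-6, min_n = 8L) {
  check_same_grid(precip, pet, "precip and pet")
  if (!identical(precip$times, pet$times))
    stop("precip and pet must share the same time axis")
  d <- precip$values - pet$values
  acc <- roll_time(d, as.integer(scale_k), "sum")
  out <- standardize_loglogistic(acc, precip$times$month, prob_clip, min_n)
  drought_index_cube(cube_like(precip, out, units = ""),
                     scale_k, "spei")
}

# Per calendar-month stratum log-logistic standardization of a [t, r, c]
# array. Returns an array of standard-normal deviates.
standardize_loglogistic <- function(acc, mon, prob_clip, min_n) {
  nt <- dim(acc)[1L]
  np <- prod(dim(acc)[2:3])
  flat <- matrix(acc, nt, np)
  out <- matrix(NA_real_, nt, np)
  n_masked <- 0L
  for (m in sort(unique(mon))) {
    rows <- which(mon == m)
    X <- flat[rows, , drop = FALSE]
    for (j in seq_len(np)) {
      x <- X[, j]
      ok <- !is.na(x)
      xv <- x[ok]
      if (length(xv) < min_n || stats::sd(xv) == 0) {
        if (any(ok)) n_masked <- n_masked + 1L
        next
      }
      p <- stratum_loglogistic_probs(x[ok])
      if (is.null(p)) { n_masked <- n_masked + 1L; next }
      p <- pmin(pmax(p, prob_clip), 1 - prob_clip)
      out[rows[ok], j] <- inv_normal_rational(p)
    }
  }
  if (n_masked > 0L)
    warning(n_masked, " pixel-stratum series were degenerate or too short ",
            "and were masked", call. = FALSE)
  array(out, dim(acc))
}

# Unbiased probability-weighted moments w_s = E[X (1-F)^s], s = 0, 1, 2.
pwm_unbiased <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- seq_len(n)
  w0 <- mean(x)
  w1 <- sum((n - j) / (n - 1) * x) / n
  w2 <- sum((n - j) * (n - j - 1) / ((n - 1) * (n - 2)) * x) / n
  c(w0 = w0, w1 = w1, w2 = w2)
}

# Cumulative probabilities of a stratum's values under its fitted
# log-logistic. Prefers a fit whose support contains every sample point; if
# the direct fit is invalid the mirrored series is fitted and the
# probabilities flipped (the log-logistic only represents positive L-skew).
# Sample points that still fall outside the fitted support receive
# Gringorten plotting-position probabilities, and monotonicity in the data
# is enforced, so ranks are always preserved. Returns NULL when no fit is
# possible.
stratum_loglogistic_probs <- function(xv) {
  n <- length(xv)
  par_d <- fit_loglogistic_lmom(xv)
  par_m <- fit_loglogistic_lmom(-xv)
  ok_d <- !is.null(par_d) && par_d$loc < min(xv)
  ok_m <- !is.null(par_m) && par_m$loc < min(-xv)
  use_d <- ok_d || (!ok_m && !is.null(par_d))
  if (use_d) {
    p <- ploglogistic(xv, par_d)
  } else if (!is.null(par_m)) {
    p <- 1 - ploglogistic(-xv, par_m)
  } else {
    return(NULL)
  }
  pp <- (rank(xv, ties.method = "average") - 0.44) / (n + 0.12)
  bad <- p <= 0 | p >= 1
  p[bad] <- pp[bad]
  # tail safety: within the fit reference sample, shrink fitted tail
  # probabilities toward half the plotting position, so a short record
  # cannot assign quasi-impossible probabilities to observed values
  p <- pmax(p, pp / 2)
  p <- pmin(p, 1 - (1 - pp) / 2)
  # guard rank order across the fallback boundary
  ord <- order(xv, xv)  # stable
  p[ord] <- cummax(p[ord])
  p
}

# Three-parameter log-logistic fit by L-moments; returns
# list(shape beta, scale alpha, loc gamma) or NULL when invalid.
fit_loglogistic_lmom <- function(x) {
  w <- pwm_unbiased(x)
  denom <- 6 * w["w1"] - w["w0"] - 6 * w["w2"]
  if (!is.finite(denom) || denom == 0) return(NULL)
  beta <- (2 * w["w1"] - w["w0"]) / denom
  if (!is.finite(beta) || beta <= 1) return(NULL)  # mean must exist
  g1 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (w["w0"] - 2 * w["w1"]) * beta / g1
  if (!is.finite(alpha) || alpha <= 0) return(NULL)
  gam <- w["w0"] - alpha * g1
  list(shape = unname(beta), scale = unname(alpha), loc = unname(gam))
}

# CDF of the 3-parameter log-logistic.
ploglogistic <- function(x, par) {
  z <- x - par$loc
  p <- numeric(length(x))
  pos <- z > 0
  p[pos] <- 1 / (1 + (par$scale / z[pos])^par$shape)
  p[!pos] <- 0
  p
}

# Rational approximation to the standard normal quantile of p
# (Abramowitz-Stegun 26.2.23 form), symmetric around 0.5.
inv_normal_rational <- function(p) {
  c0 <- 2.515517; c1 <- 0.802853; c2 <- 0.010328
  d1 <- 1.432788; d2 <- 0.189269; d3 <- 0.001308
  q <- ifelse(p <= 0.5, p, 1 - p)
  w <- sqrt(-2 * log(q))
  t <- w - (c0 + c1 * w + c2 * w^2) / (1 + d1 * w + d2 * w^2 + d3 * w^3)
  ifelse(p <= 0.5, -t, t)
}

#' Standardized Soil Moisture Index
#'
#' The k-month rolling mean of soil moisture is standardized as
#' \eqn{SSMI = (SM - \overline{SM}) / \sigma}, where the mean and standard
#' deviation are taken over the multi-year record at the same accumulation
#' scale. By default the standardization stratum is the calendar month, so
#' each month's output has mean 0 and SD 1 exactly over the record;
#' `stratum = "all"` standardizes against the whole series instead.
#'
#' @param sm [grid_cube()] of surface soil moisture (volumetric fraction).
#' @param scale_k Accumulation scale in months.
#' @param stratum `"month"` (default) or `"all"`.
#' @return A [drought_index_cube()] with `index_kind = "ssmi"`.
#' @export
ssmi <- function(sm, scale_k = 1L, stratum = c("month", "all")) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(sm, "grid_cube"))
  if (length(unique(sm$times$year)) < 2L)
    stop("SSMI needs at least 2 years of data")
  acc <- roll_time(sm$values, as.integer(scale_k), "mean")
  nt <- dim(acc)[1L]
  np <- prod(dim(acc)[2:3])
  flat <- matrix(acc, nt, np)
  out <- matrix(NA_real_, nt, np)
  groups <- if (stratum == "month") sm$times$month else rep(1L, nt)
  n_degen <- 0L
  for (g in unique(groups)) {
    rows <- which(groups == g)
    X <- flat[rows, , drop = FALSE]
    mu <- colMeans(X, na.rm = TRUE)
    sdv <- apply(X, 2L, stats::sd, na.rm = TRUE)
    z <- sweep(sweep(X, 2L, mu, `-`), 2L, sdv, `/`)
    degen <- !is.na(sdv) & sdv == 0
    z[, degen] <- NA_real_
    n_degen <- n_degen + sum(degen)
    out[rows, ] <- z
  }
  if (n_degen > 0L)
    warning(n_degen, " zero-variance pixel strata masked in SSMI",
            call. = FALSE)
  drought_index_cube(cube_like(sm, array(out, dim(acc)), units = ""),
                     scale_k, "ssmi")
}

#' Drought severity classification
#'
#' Maps index values to categorical severity codes 0 none, 1 mild,
#' 2 moderate, 3 severe, 4 extreme. The SPEI scheme uses
#' no drought for SPEI > -0.5, mild (-1, -0.5], moderate (-1.5, -1],
#' severe (-2, -1.5], extreme <= -2. The SSMI scheme differs only in the
#' mild/no-drought boundary: no drought for SSMI > 0, mild (-1, 0].
#' All boundaries are closed on the dry side.
#'
#' @param index A [drought_index_cube()] (or bare [grid_cube()]).
#' @param scheme `"spei_table"` or `"ssmi_table"`; defaults to the cube's
#'   `index_kind` when present.
#' @return A [grid_cube()] of integer severity codes (class `severity_cube`
#'   prepended), `NA` where the index is masked.
#' @export
classify_severity <- function(index, scheme = NULL) {
  if (is.null(scheme)) {
    if (!is.null(index$index_kind))
      scheme <- paste0(index$index_kind, "_table")
    else stop("scheme must be given for a bare cube")
  }
  scheme <- match.arg(scheme, c("spei_table", "ssmi_table"))
  mild_upper <- if (scheme == "spei_table") -0.5 else 0
  v <- index$values
  code <- array(NA_integer_, dim(v))
  ok <- !is.na(v)
  x <- v[ok]
  code[ok] <- ifelse(x <= -2, 4L,
              ifelse(x <= -1.5, 3L,
              ifelse(x <= -1, 2L,
              ifelse(x <= mild_upper, 1L, 0L))))
  out <- cube_like(index, code, units = "severity")
  class(out) <- c("severity_cube", class(out))
  out$scheme <- scheme
  out
}

#' Severity level labels
#' @return Character vector for codes 0..4.
#' @export
severity_labels <- function() {
  c("none", "mild", "moderate", "severe", "extreme")
}

#' Drought frequency index map
#'
#' \eqn{DFI = 100 \cdot m / M} per pixel, where m counts months with index
#' value at or below `threshold` and M is the number of considered
#' (non-masked) months, optionally restricted to a calendar-month subset.
#'
#' @param index A [drought_index_cube()].
#' @param threshold Drought threshold on the index (default -1; set -0.5 to
#'   include mild droughts).
#' @param month_subset Optional integer vector of calendar months (1-12).
#' @return Matrix of percentages in `[0, 100]` (`NA` where no months are
#'   valid at a pixel).
#' @export
drought_frequency <- function(index, threshold = -1, month_subset = NULL) {
  v <- index$values
  if (!is.null(month_subset)) {
    month_subset <- as.integer(month_subset)
    if (!length(month_subset) || !all(month_subset %in% 1:12))
      stop("month_subset must be a non-empty subset of 1..12")
    v <- v[index$times$month %in% month_subset, , , drop = FALSE]
    if (dim(v)[1L] == 0L) stop("month_subset selects no time steps")
  }
  m <- apply(v, c(2, 3), function(x) sum(x <= threshold, na.rm = TRUE))
  M <- apply(v, c(2, 3), function(x) sum(!is.na(x)))
  out <- 100 * m / M
  out[M == 0] <- NA_real_
  out
}

#' Aridity-index classification
#'
#' Classes: humid (AI < 1), semi-humid (1 <= AI < 1.5),
#' semi-arid (1.5 <= AI < 4), arid (AI >= 4).
#'
#' @param ai Numeric matrix of aridity-index values (>= 0; `NA` = nodata).
#' @return List with `classes` (integer matrix, codes 1-4), `labels`, and
#'   `fractions` (named area fraction per class over valid cells, summing
#'   to 1).
#' @export
classify_aridity <- function(ai) {
  stopifnot(is.matrix(ai))
  if (any(ai < 0, na.rm = TRUE)) stop("aridity index must be >= 0")
  cl <- array(NA_integer_, dim(ai))
  ok <- !is.na(ai)
  x <- ai[ok]
  cl[ok] <- ifelse(x >= 4, 4L, ifelse(x >= 1.5, 3L, ifelse(x >= 1, 2L, 1L)))
  labs <- c("humid", "semi_humid", "semi_arid", "arid")
  frac <- as.numeric(table(factor(cl[ok], levels = 1:4))) / sum(ok)
  names(frac) <- labs
  list(classes = cl, labels = labs, fractions = frac)
}

#' Drought-area time series by severity
#'
#' For each month, the fraction of valid pixels at each severity level
#' (including "none"); rows sum to 1 over valid pixels.
#'
#' @param severity A severity cube from [classify_severity()].
#' @return Data frame with `year`, `month` and one fraction column per
#'   severity level.
#' @export
drought_area_series <- function(severity) {
  nt <- n_times(severity)
  out <- matrix(NA_real_, nt, 5L)
  for (i in seq_len(nt)) {
    s <- severity$values[i, , ]
    nvalid <- sum(!is.na(s))
    if (nvalid > 0)
      out[i, ] <- tabulate(s + 1L, 5L)[1:5] / nvalid
  }
  colnames(out) <- severity_labels()
  cbind(severity$times, as.data.frame(out))
}

#' Months belonging to a meteorological season
#'
#' Spring = MAM, summer = JJA, autumn = SON, winter = DJF (December counted
#' toward the following year's winter).
#'
#' @param season One of `"spring"`, `"summer"`, `"autumn"`, `"winter"`.
#' @return Integer vector of calendar months.
#' @export
season_months <- function(season = c("spring", "summer", "autumn", "winter")) {
  switch(match.arg(season),
         spring = 3:5, summer = 6:8, autumn = 9:11, winter = c(12L, 1L, 2L))
}
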