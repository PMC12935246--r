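#' Per-pixel Pearson correlation of two aligned arrays
#'
#' Standard product-moment correlation per pixel across the first (time)
#' dimension; significance from `t = r sqrt((n-2)/(1-r^2))` with `n - 2`
#' degrees of freedom. Zero-variance pixels are masked.
#'
#' @param a,b `[time, row, col]` arrays of equal shape (e.g. annualized
#'   cubes).
#' @return Object of class `correlation_field`: matrices `r`, `p`, `n_eff`,
#'   plus `kind = "pearson"` and empty `controls`.
#' @export
pearson_map <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 3L)
  nr <- dim(a)[2L]; nc <- dim(a)[3L]
  rm_ <- pm <- nm <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    x <- a[, r, cc]; y <- b[, r, cc]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    rv <- stats::cor(x[ok], y[ok])
    rm_[r, cc] <- rv
    nm[r, cc] <- n
    pm[r, cc] <- r_to_p(rv, n, 0L)
  }
  correlation_field(rm_, pm, nm, "pearson", character(0))
}

# two-sided p-value of a (partial) correlation with q controls
r_to_p <- function(r, n, q) {
  df <- n - 2L - q
  if (df < 1L) return(NA_real_)
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  tt <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tt), df)
}

correlation_field <- function(r, p, n_eff, kind, controls) {
  structure(list(r = r, p = p, n_eff = n_eff, kind = kind,
                 controls = controls),
            class = "correlation_field")
}

#' @export
print.correlation_field <- function(x, ...) {
  cat(sprintf("correlation_field (%s%s): mean r = %.3f over %d valid pixels\n",
              x$kind,
              if (length(x$controls)) paste0(" | ",
                paste(x$controls, collapse = ", ")) else "",
              mean(x$r, na.rm = TRUE), sum(!is.na(x$r))))
  invisible(x)
}

#' Per-pixel partial correlation with one or more controls
#'
#' The partial correlation of `target` and `driver` given the control
#' series is read off the inverse of the joint correlation matrix,
#' `r = -Omega_ij / sqrt(Omega_ii Omega_jj)`; significance uses
#' `df = n - 2 - #controls`. Pixels with a singular correlation matrix are
#' masked. Controls that are constant (zero variance) at a pixel are
#' dropped there, so all-degenerate controls reduce to plain Pearson.
#'
#' @param target,driver `[time, row, col]` arrays.
#' @param controls List of `[time, row, col]` arrays (1-3 controls).
#' @param control_names Labels recorded on the result.
#' @return A `correlation_field` with `kind = "partial"`.
#' @export
partial_map <- function(target, driver, controls,
                        control_names = paste0("control",
                                               seq_along(controls))) {
  if (!is.list(controls)) controls <- list(controls)
  stopifnot(length(controls) >= 1L, length(controls) <= 3L)
  for (ctl in controls) stopifnot(identical(dim(ctl), dim(target)))
  stopifnot(identical(dim(target), dim(driver)))
  nr <- dim(target)[2L]; nc <- dim(target)[3L]
  rm_ <- pm <- nm <- matrix(NA_real_, nr, nc)
  n_singular <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    x <- target[, r, cc]; y <- driver[, r, cc]
    ctl <- lapply(controls, function(a) a[, r, cc])
    ok <- !is.na(x) & !is.na(y)
    for (v in ctl) ok <- ok & !is.na(v)
    n <- sum(ok)
    ctl <- Filter(function(v) stats::sd(v[ok]) > 0, ctl)
    q <- length(ctl)
    if (n < 3L + q) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    M <- cbind(x[ok], y[ok])
    for (v in ctl) M <- cbind(M, v[ok])
    R <- stats::cor(M)
    Om <- tryCatch(solve(R), error = function(e) NULL)
    if (is.null(Om)) { n_singular <- n_singular + 1L; next }
    rv <- -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
    rm_[r, cc] <- rv
    nm[r, cc] <- n
    pm[r, cc] <- r_to_p(rv, n, q)
  }
  if (n_singular > 0L)
    warning(n_singular, " pixels had singular correlation matrices and ",
            "were masked", call. = FALSE)
  correlation_field(rm_, pm, nm, "partial", control_names)
}

#' Area summary of a correlation field
#'
#' @param field A `correlation_field`.
#' @param alpha Significance level for the significant-area fraction.
#' @return List with `mean_r`, `frac_positive`, `frac_significant` over
#'   valid pixels.
#' @export
area_summary <- function(field, alpha = 0.05) {
  ok <- !is.na(field$r)
  if (!any(ok)) stop("empty correlation field")
  list(mean_r = mean(field$r[ok]),
       frac_positive = mean(field$r[ok] > 0),
       frac_significant = mean(field$p[ok] < alpha, na.rm = TRUE))
}

#' Correlation of NPP aggregates with a matching-scale drought index
#'
#' Pairs per-pixel NPP aggregates with index values at the scale-appropriate
#' sampling month and correlates them across years. For a 3-month index the
#' season is represented by the index at the season's final month (May,
#' August, November, February - the February of the following year for
#' winter); for a 12-month index the year is represented by December; for a
#' 1-month index each requested month contributes its own pair.
#'
#' @param npp Monthly NPP [grid_cube()].
#' @param index A [drought_index_cube()] on the same calendar.
#' @param months Calendar months (1-12) defining the NPP aggregation window
#'   (e.g. `season_months("summer")`); for `scale_k = 12` use `1:12`.
#' @return A `correlation_field`.
#' @export
lagged_index_correlation <- function(npp, index, months) {
  check_same_grid(npp, index, "npp and index")
  months <- as.integer(months)
  if (!length(months) || !all(months %in% 1:12))
    stop("months must be a non-empty subset of 1..12")
  k <- index$scale_k
  if (k == 3L && length(months) != 3L)
    stop("a 3-month index expects a 3-month season window")
  if (k == 12L && length(months) != 12L)
    stop("a 12-month index expects the full-year window 1:12")
  winter <- all(sort(months) == c(1L, 2L, 12L))
  end_month <- if (winter) 2L else max(months)
  yrs <- unique(npp$times$year)
  nr <- npp$meta$n_rows; nc <- npp$meta$n_cols
  npp_agg <- list(); idx_val <- list()
  for (y in yrs) {
    # aggregation window; winter = Dec of y-1 .. Feb of y
    if (winter) {
      sel <- (npp$times$year == y - 1L & npp$times$month == 12L) |
        (npp$times$year == y & npp$times$month %in% c(1L, 2L))
      if (sum(sel) != 3L) next
    } else {
      sel <- npp$times$year == y & npp$times$month %in% months
      if (sum(sel) != length(months)) next
    }
    it <- which(index$times$year == y & index$times$month == end_month)
    if (!length(it)) next
    npp_agg[[length(npp_agg) + 1L]] <-
      colSums(npp$values[sel, , , drop = FALSE], dims = 1L)
    idx_val[[length(idx_val) + 1L]] <- index$values[it, , ]
  }
  ny <- length(npp_agg)
  if (ny < 3L) stop("fewer than 3 usable years for the correlation")
  a <- array(NA_real_, c(ny, nr, nc)); b <- a
  for (i in seq_len(ny)) { a[i, , ] <- npp_agg[[i]]; b[i, , ] <- idx_val[[i]] }
  pearson_map(a, b)
}
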