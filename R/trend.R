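#' Theil-Sen slope of a series
#'
#' The median of all pairwise slopes `(x_j - x_i)/(t_j - t_i)`, `i < j`; a
#' robust trend estimator insensitive to outliers. Returns `NA` with fewer
#' than 3 valid points.
#'
#' @param x Numeric values.
#' @param t Time coordinates (defaults to `1..n`), same length as `x`.
#' @return Slope in units of `x` per unit of `t`.
#' @export
sen_slope <- function(x, t = seq_along(x)) {
  ok <- !is.na(x) & !is.na(t)
  x <- x[ok]; t <- t[ok]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  dx <- outer(x, x, `-`)
  dt <- outer(t, t, `-`)
  sel <- upper.tri(dt) & dt != 0
  stats::median(-dx[sel] / -dt[sel])
}

#' Mann-Kendall trend test
#'
#' Rank-based monotone-trend test.
#' `S = sum_{i<j} sign(x_j - x_i)`; the variance uses the tie correction
#' `var_S = (n(n-1)(2n+5) - sum_t t(t-1)(2t+5)) / 18` over tie groups of
#' extent `t`. The normal deviate applies the continuity correction
#' `z = (S - sign(S))/sqrt(var_S)` (`z = 0` when `S = 0`), and the p-value
#' is the two-sided normal tail. An all-tied series returns
#' `z = 0, p = 1`.
#'
#' @param x Numeric series (`NA`s dropped).
#' @return List with `S`, `var_S`, `z`, `p`, `n`.
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(list(S = NA_real_, var_S = NA_real_,
                          z = NA_real_, p = NA_real_, n = n))
  sgn <- sign(outer(x, x, FUN = function(a, b) b - a))
  S <- sum(sgn[upper.tri(sgn)])
  ties <- table(x)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_S <= 0) return(list(S = S, var_S = var_S, z = 0, p = 1, n = n))
  z <- if (S > 0) (S - 1) / sqrt(var_S)
       else if (S < 0) (S + 1) / sqrt(var_S)
       else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(S = S, var_S = var_S, z = z, p = p, n = n)
}

#' Per-pixel trend field: Sen slope + Mann-Kendall significance
#'
#' Applies [sen_slope()] and [mann_kendall()] to each pixel's series (an
#' annualized cube for per-annum rates) and classifies each pixel at level
#' `alpha` into `sig_increase`, `nonsig_increase`, `nonsig_decrease`,
#' `sig_decrease`.
#'
#' @param values `[time, row, col]` array (e.g. from [annualize()]).
#' @param t Time coordinate per slice (e.g. the years).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `trend_field`: matrices `slope`, `z`, `p`,
#'   `sig_class` (integer codes 1-4 in the order above), plus
#'   `class_fractions` over valid pixels and `alpha`.
#' @export
trend_map <- function(values, t = seq_len(dim(values)[1L]), alpha = 0.05) {
  stopifnot(length(dim(values)) == 3L, dim(values)[1L] == length(t))
  nr <- dim(values)[2L]; nc <- dim(values)[3L]
  slope <- zm <- pm <- matrix(NA_real_, nr, nc)
  cls <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    v <- values[, r, cc]
    if (sum(!is.na(v)) < 3L) next
    slope[r, cc] <- sen_slope(v, t)
    mk <- mann_kendall(v)
    zm[r, cc] <- mk$z
    pm[r, cc] <- mk$p
    sig <- !is.na(mk$p) && mk$p < alpha
    up <- slope[r, cc] >= 0
    cls[r, cc] <- if (up && sig) 1L else if (up) 2L
                  else if (!sig) 3L else 4L
  }
  nvalid <- sum(!is.na(cls))
  frac <- if (nvalid) tabulate(cls, 4L) / nvalid else rep(NA_real_, 4L)
  names(frac) <- trend_class_labels()
  structure(list(slope = slope, z = zm, p = pm, sig_class = cls,
                 class_fractions = frac, alpha = alpha),
            class = "trend_field")
}

#' Trend class labels
#' @return Character vector for codes 1..4.
#' @export
trend_class_labels <- function() {
  c("sig_increase", "nonsig_increase", "nonsig_decrease", "sig_decrease")
}

#' @export
print.trend_field <- function(x, ...) {
  cat(sprintf("trend_field (alpha = %g): median slope %g\n", x$alpha,
              stats::median(x$slope, na.rm = TRUE)))
  print(round(x$class_fractions, 4))
  invisible(x)
}
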