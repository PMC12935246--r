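#' Non-drought NPP baseline per (vegetation class, calendar month)
#'
#' The baseline is the mean NPP over all pixels of a vegetated class and all
#' years where the severity cube says "no drought" in that calendar month -
#' the reference against which drought-month NPP anomalies are expressed.
#' A (class, month) cell with zero non-drought samples gets `NA` and a
#' warning; downstream anomaly rows for it are skipped.
#'
#' @param npp Monthly NPP [grid_cube()].
#' @param severity Severity cube aligned with `npp` (codes 0-4).
#' @param landcover [land_cover_map()].
#' @return Object of class `npp_baseline`: a 3 x 12 matrix (classes
#'   farmland/woodland/grassland by calendar month) plus a matching sample
#'   count matrix `n`.
#' @export
non_drought_baseline <- function(npp, severity, landcover) {
  check_same_grid(npp, severity, "npp and severity")
  check_same_grid(npp, landcover, "npp and landcover")
  cn <- landcover_class_names()[vegetated_classes()]
  base <- nmat <- matrix(NA_real_, 3L, 12L,
                         dimnames = list(cn, month.abb))
  present <- intersect(vegetated_classes(),
                       unique(as.vector(landcover$classes)))
  for (k in present) {
    sel_class <- landcover$classes == k
    for (m in 1:12) {
      tsel <- which(npp$times$month == m)
      if (!length(tsel)) next
      vals <- c()
      for (i in tsel) {
        nd <- severity$values[i, , ] == 0L
        take <- !is.na(nd) & nd & sel_class
        v <- npp$values[i, , ][take]
        vals <- c(vals, v[!is.na(v)])
      }
      nmat[k, m] <- length(vals)
      base[k, m] <- if (length(vals)) mean(vals) else NA_real_
    }
  }
  absent <- sum(is.na(base) & !is.na(nmat) & nmat == 0)
  if (absent > 0L)
    warning(absent, " (class, month) baselines have no non-drought samples ",
            "and are absent", call. = FALSE)
  structure(list(baseline = base, n = nmat), class = "npp_baseline")
}

#' Percent NPP anomaly by vegetation class and drought severity
#'
#' For every drought pixel-month (severity >= mild) of a vegetated class,
#' `dNPP = 100 (NPP - baseline(class, month)) / baseline(class, month)`,
#' aggregated as the mean per (class, severity) and, when
#' `by_month = TRUE`, per calendar month as well. Rows with no contributing
#' pixel-months are absent, not zero; pixel-months whose baseline is
#' missing or zero are excluded (counted in a warning).
#'
#' @param npp Monthly NPP [grid_cube()].
#' @param severity Aligned severity cube.
#' @param landcover [land_cover_map()].
#' @param baseline An `npp_baseline` from [non_drought_baseline()].
#' @param by_month Resolve the table by calendar month too?
#' @return Data frame (class `delta_npp_table`) with columns `class`,
#'   `severity`, optional `month`, `delta_npp_pct`, `n`.
#' @export
delta_npp <- function(npp, severity, landcover, baseline,
                      by_month = FALSE) {
  stopifnot(inherits(baseline, "npp_baseline"))
  check_same_grid(npp, severity, "npp and severity")
  cn <- landcover_class_names()[vegetated_classes()]
  labs <- severity_labels()
  acc <- list()   # running sums keyed by class|severity|month
  n_nobase <- 0L
  for (i in seq_len(n_times(npp))) {
    m <- npp$times$month[i]
    sev <- severity$values[i, , ]
    for (k in vegetated_classes()) {
      b <- baseline$baseline[k, m]
      sel_class <- landcover$classes == k
      for (code in 1:4) {
        hit <- !is.na(sev) & sev == code & sel_class
        v <- npp$values[i, , ][hit]
        v <- v[!is.na(v)]
        if (!length(v)) next
        if (is.na(b) || b == 0) { n_nobase <- n_nobase + length(v); next }
        key <- paste(k, code, if (by_month) m else 0L, sep = "|")
        d <- 100 * (v - b) / b
        if (is.null(acc[[key]])) acc[[key]] <- c(sum = 0, n = 0)
        acc[[key]] <- acc[[key]] + c(sum = sum(d), n = length(d))
      }
    }
  }
  if (n_nobase > 0L)
    warning(n_nobase, " drought pixel-months had no usable baseline and ",
            "were excluded", call. = FALSE)
  if (!length(acc)) {
    out <- data.frame(class = character(0), severity = character(0),
                      delta_npp_pct = numeric(0), n = integer(0))
    if (by_month) out$month <- integer(0)
  } else {
    parts <- do.call(rbind, strsplit(names(acc), "|", fixed = TRUE))
    out <- data.frame(
      class = cn[as.integer(parts[, 1])],
      severity = labs[as.integer(parts[, 2]) + 1L],
      month = as.integer(parts[, 3]),
      delta_npp_pct = vapply(acc, function(a) a["sum"] / a["n"], 0),
      n = vapply(acc, function(a) as.integer(a["n"]), 0L),
      row.names = NULL)
    if (!by_month) out$month <- NULL
    ord <- order(match(out$class, cn), match(out$severity, labs))
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("delta_npp_table", class(out))
  out
}

#' Early- versus peak-growing-season anomaly comparison
#'
#' Compares the mean percent NPP anomaly between March-May (early growing
#' season) and June-August (peak growing season) per vegetation class and
#' severity, reporting which window is more negative. Rows lacking either
#' window are absent.
#'
#' @param delta_table A monthly-resolved table from
#'   `delta_npp(..., by_month = TRUE)`.
#' @return Data frame with `class`, `severity`, `early_mam`, `peak_jja`
#'   (n-weighted mean anomalies) and `more_negative`
#'   (`"peak_jja"`, `"early_mam"` or `"equal"`).
#' @export
seasonal_anomaly_profile <- function(delta_table) {
  if (!"month" %in% names(delta_table))
    stop("delta table must be monthly-resolved (by_month = TRUE)")
  win_mean <- function(df, months) {
    d <- df[df$month %in% months, , drop = FALSE]
    if (!nrow(d)) return(NA_real_)
    sum(d$delta_npp_pct * d$n) / sum(d$n)
  }
  keys <- unique(delta_table[, c("class", "severity")])
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    d <- delta_table[delta_table$class == keys$class[i] &
                     delta_table$severity == keys$severity[i], ,
                     drop = FALSE]
    early <- win_mean(d, 3:5)
    peak <- win_mean(d, 6:8)
    if (is.na(early) || is.na(peak)) next
    cmp <- if (peak < early) "peak_jja"
           else if (early < peak) "early_mam" else "equal"
    out <- rbind(out, data.frame(class = keys$class[i],
                                 severity = keys$severity[i],
                                 early_mam = early, peak_jja = peak,
                                 more_negative = cmp))
  }
  if (is.null(out))
    out <- data.frame(class = character(0), severity = character(0),
                      early_mam = numeric(0), peak_jja = numeric(0),
                      more_negative = character(0))
  rownames(out) <- NULL
  out
}

#' Regional monthly drought flags from an index cube
#'
#' Reduces a drought-index cube to one boolean per month by either rule:
#' `"mean_index"` flags months whose regional mean index is at or below
#' `tau`; `"area_fraction"` flags months where the fraction of valid pixels
#' at mild-or-worse severity (index at or below the scheme's mild boundary)
#' reaches `phi`.
#'
#' @param index A [drought_index_cube()].
#' @param rule `"mean_index"` or `"area_fraction"`.
#' @param tau Threshold on the regional mean index (default -0.5).
#' @param phi Area-fraction threshold in `[0, 1]` (default 0.3).
#' @param mild_boundary Index value at or below which a pixel counts as in
#'   drought for the area rule; defaults to the scheme boundary (-0.5 for
#'   SPEI, 0 for SSMI).
#' @return Data frame with `year`, `month`, `flag` (logical).
#' @export
regional_drought_flags <- function(index,
                                   rule = c("mean_index", "area_fraction"),
                                   tau = -0.5, phi = 0.3,
                                   mild_boundary = NULL) {
  rule <- match.arg(rule)
  if (is.null(mild_boundary))
    mild_boundary <- if (identical(index$index_kind, "ssmi")) 0 else -0.5
  nt <- n_times(index)
  flag <- logical(nt)
  for (i in seq_len(nt)) {
    v <- index$values[i, , ]
    v <- v[!is.na(v)]
    if (!length(v)) { flag[i] <- NA; next }
    flag[i] <- if (rule == "mean_index") mean(v) <= tau
               else mean(v <= mild_boundary) >= phi
  }
  data.frame(year = index$times$year, month = index$times$month,
             flag = flag)
}

#' Categorical skill scores against a drought-event catalog
#'
#' Month-level contingency counting: a month inside any catalog event that
#' is flagged is a hit (H), inside an event but unflagged a miss (M), and a
#' flagged month outside all events a false alarm (F). Scores:
#' `POD = H/(H+M)`, `FAR = F/(H+F)`, `CSI = H/(H+M+F)`; a score with a zero
#' denominator is reported as `NA` (absent).
#'
#' @param flags Data frame from [regional_drought_flags()] (`year`, `month`,
#'   `flag`).
#' @param catalog Event catalog data frame (see [read_event_catalog()]);
#'   catalog months must lie within the flag range.
#' @return Object of class `skill_scores`: `hits`, `misses`, `false_alarms`,
#'   `pod`, `far`, `csi`.
#' @export
skill_scores <- function(flags, catalog) {
  stopifnot(all(c("year", "month", "flag") %in% names(flags)))
  ser <- flags$year * 12L + (flags$month - 1L)
  in_event <- rep(FALSE, nrow(flags))
  if (nrow(catalog)) {
    for (i in seq_len(nrow(catalog))) {
      s <- catalog$start_year[i] * 12L + (catalog$start_month[i] - 1L)
      e <- catalog$end_year[i] * 12L + (catalog$end_month[i] - 1L)
      if (s < min(ser) || e > max(ser))
        stop("catalog event ", i, " lies outside the flag range")
      in_event <- in_event | (ser >= s & ser <= e)
    }
  }
  ok <- !is.na(flags$flag)
  f <- flags$flag[ok]; ev <- in_event[ok]
  H <- sum(f & ev); M <- sum(!f & ev); FA <- sum(f & !ev)
  structure(list(
    hits = H, misses = M, false_alarms = FA,
    pod = if (H + M > 0) H / (H + M) else NA_real_,
    far = if (H + FA > 0) FA / (H + FA) else NA_real_,
    csi = if (H + M + FA > 0) H / (H + M + FA) else NA_real_),
    class = "skill_scores")
}

#' @export
print.skill_scores <- function(x, ...) {
  cat(sprintf("skill_scores: H=%d M=%d F=%d  POD=%s FAR=%s CSI=%s\n",
              x$hits, x$misses, x$false_alarms,
              format(x$pod, digits = 4), format(x$far, digits = 4),
              format(x$csi, digits = 4)))
  invisible(x)
}
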