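#' Run configuration for the full pipeline
#'
#' Validated container for an end-to-end run. Inputs are either the
#' synthetic scenario (`synthetic` = arguments for [synth_config()], minus
#' the seed which comes from `seed`) or directories of per-month rasters
#' (`inputs`). Unknown keys are rejected.
#'
#' @param seed Integer RNG seed for the whole run.
#' @param out_dir Output directory.
#' @param synthetic List of [synth_config()] overrides (use `list()` for all
#'   defaults), or `NULL` when `inputs` is given.
#' @param inputs `NULL`, or a named list with glob patterns for `precip`,
#'   `temp`, `sol`, `sm`, `ndvi` monthly rasters plus a `landcover` path and
#'   optionally a `catalog` CSV path.
#' @param casa List of [casa_params()] overrides.
#' @param spei_scales Integer vector of SPEI accumulation scales.
#' @param ssmi_scales Integer vector of SSMI accumulation scales.
#' @param dfi_threshold Drought threshold for the frequency map.
#' @param trend_alpha Significance level for trend classes.
#' @param skill_rule `"mean_index"` or `"area_fraction"` for the regional
#'   drought flag.
#' @param skill_tau,skill_phi Thresholds for the two flag rules.
#' @param format Raster output format, `"ascii"` or `"tiff"`.
#' @param write_inputs Also write the (synthetic) input cubes?
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, out_dir, synthetic = list(), inputs = NULL,
                       casa = list(), spei_scales = c(1L, 3L, 12L),
                       ssmi_scales = 1L, dfi_threshold = -1,
                       trend_alpha = 0.05,
                       skill_rule = c("mean_index", "area_fraction"),
                       skill_tau = -0.5, skill_phi = 0.3,
                       format = c("ascii", "tiff"), write_inputs = FALSE) {
  skill_rule <- match.arg(skill_rule)
  format <- match.arg(format)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.character(out_dir), length(out_dir) == 1L)
  if (is.null(synthetic) && is.null(inputs))
    stop("either synthetic or inputs must be given")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synthetic = synthetic, inputs = inputs, casa = casa,
                 spei_scales = as.integer(spei_scales),
                 ssmi_scales = as.integer(ssmi_scales),
                 dfi_threshold = dfi_threshold, trend_alpha = trend_alpha,
                 skill_rule = skill_rule, skill_tau = skill_tau,
                 skill_phi = skill_phi, format = format,
                 write_inputs = write_inputs),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; unknown keys are a
#' hard error.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @param out_dir Optional output directory overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(run_config, y)
}

read_pipeline_inputs <- function(cfg) {
  inp <- cfg$inputs
  need <- c("precip", "temp", "sol", "sm", "ndvi", "landcover")
  miss <- setdiff(need, names(inp))
  if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "))
  units <- c(precip = "mm", temp = "degC", sol = "MJ m-2 month-1",
             sm = "m3 m-3", ndvi = "")
  out <- list()
  for (v in setdiff(need, "landcover")) {
    paths <- sort(Sys.glob(inp[[v]]))
    if (!length(paths)) stop("no files match inputs$", v)
    out[[v]] <- read_cube(paths, units = units[[v]])
  }
  lc <- read_field(inp$landcover)
  cls <- lc$field
  storage.mode(cls) <- "integer"
  out$landcover <- land_cover_map(cls, out$precip$meta)
  out$truth <- NULL
  if (!is.null(inp$catalog)) out$catalog <- read_event_catalog(inp$catalog)
  out
}

#' Execute the full analysis pipeline
#'
#' Runs, in order: input generation/ingest, PET, SPEI/SSMI index cubes with
#' severity classification and drought-frequency maps, CASA NPP
#' (monthly + annual), per-pixel trend fields, Pearson/partial correlation
#' fields of NPP against climate drivers, seasonal index-NPP correlations,
#' the drought-severity NPP anomaly table, and catalog-based skill
#' validation. Every artifact is written under `out_dir` and listed, with
#' its MD5 checksum, in `manifest.json`; identical config and seed give
#' identical checksums.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress stage messages?
#' @return The manifest, invisibly (list with `artifacts` data frame and
#'   stage summaries).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  od <- cfg$out_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[droughtnpp] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- character(0)
  fmt <- cfg$format

  # --- inputs ---
  say("stage inputs")
  dat <- stage("inputs", {
    if (!is.null(cfg$synthetic)) {
      sc <- do.call(synth_config, c(cfg$synthetic, list(seed = cfg$seed)))
      g <- generate_synthetic(sc)
      g$catalog <- make_event_catalog(g$truth)
      g
    } else read_pipeline_inputs(cfg)
  })
  if (!is.null(dat$catalog)) {
    p <- file.path(od, "event_catalog.csv")
    write_event_catalog(dat$catalog, p); paths <- c(paths, p)
  }
  if (cfg$write_inputs) {
    for (v in c("precip", "temp", "sol", "sm", "ndvi"))
      paths <- c(paths, write_cube(dat[[v]], file.path(od, "inputs"), v, fmt))
  }

  # --- drought indices ---
  say("stage indices")
  idx <- stage("indices", {
    pet <- pet_thornthwaite(dat$temp)
    speis <- lapply(cfg$spei_scales, function(k)
      suppressWarnings(spei(dat$precip, pet, k)))
    names(speis) <- paste0("spei_", cfg$spei_scales)
    ssmis <- lapply(cfg$ssmi_scales, function(k)
      suppressWarnings(ssmi(dat$sm, k)))
    names(ssmis) <- paste0("ssmi_", cfg$ssmi_scales)
    list(pet = pet, speis = speis, ssmis = ssmis)
  })
  for (nm in names(idx$speis))
    paths <- c(paths, write_cube(idx$speis[[nm]], file.path(od, nm), nm, fmt))
  for (nm in names(idx$ssmis))
    paths <- c(paths, write_cube(idx$ssmis[[nm]], file.path(od, nm), nm, fmt))

  spei1 <- idx$speis[[1L]]
  sev <- classify_severity(spei1)
  paths <- c(paths,
             write_cube(sev, file.path(od, "severity_spei1"), "severity", fmt))
  area <- drought_area_series(sev)
  p <- file.path(od, "drought_area_spei1.csv")
  utils::write.csv(area, p, row.names = FALSE); paths <- c(paths, p)
  dfi <- drought_frequency(spei1, cfg$dfi_threshold)
  p <- file.path(od, "dfi_spei1.asc")
  write_field(dfi, dat$precip$meta, p, "ascii"); paths <- c(paths, p)

  # --- CASA NPP ---
  say("stage npp")
  casa <- stage("npp", {
    params <- do.call(casa_params, cfg$casa)
    npp <- casa_npp(dat$ndvi, dat$temp, dat$sol, dat$precip, dat$landcover,
                    pet = idx$pet, sm = dat$sm, params = params)
    list(params = params, npp = npp, annual = annualize(npp, "sum"))
  })
  paths <- c(paths,
             write_cube(casa$npp, file.path(od, "npp_monthly"), "npp", fmt))
  for (i in seq_along(casa$annual$years)) {
    p <- file.path(od, "npp_annual",
                   sprintf("npp_annual_%d.asc", casa$annual$years[i]))
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    write_field(casa$annual$values[i, , ], dat$precip$meta, p, "ascii")
    paths <- c(paths, p)
  }

  # --- trends ---
  say("stage trends")
  tr <- stage("trends", {
    trend_map(casa$annual$values, casa$annual$years, cfg$trend_alpha)
  })
  for (layer in c("slope", "z", "p")) {
    p <- file.path(od, sprintf("trend_npp_%s.asc", layer))
    write_field(tr[[layer]], dat$precip$meta, p, "ascii")
    paths <- c(paths, p)
  }
  p <- file.path(od, "trend_npp_class.asc")
  write_field(tr$sig_class + 0, dat$precip$meta, p, "ascii")
  paths <- c(paths, p)

  # --- correlations ---
  say("stage correlations")
  corr <- stage("correlations", {
    ann <- list(npp = casa$annual$values,
                precip = annualize(dat$precip, "sum")$values,
                temp = annualize(dat$temp, "mean")$values,
                sol = annualize(dat$sol, "sum")$values)
    fields <- list()
    for (drv in c("precip", "temp", "sol")) {
      fields[[paste0("pearson_", drv)]] <- pearson_map(ann$npp, ann[[drv]])
      ctl_names <- setdiff(c("precip", "temp", "sol"), drv)
      fields[[paste0("partial_", drv)]] <-
        partial_map(ann$npp, ann[[drv]], ann[ctl_names], ctl_names)
    }
    if ("spei_3" %in% names(idx$speis)) {
      for (s in c("spring", "summer", "autumn", "winter")) {
        fields[[paste0("spei3_", s)]] <- tryCatch(
          lagged_index_correlation(casa$npp, idx$speis[["spei_3"]],
                                   season_months(s)),
          error = function(e) NULL)
      }
    }
    Filter(Negate(is.null), fields)
  })
  corr_summary <- NULL
  for (nm in names(corr)) {
    for (layer in c("r", "p")) {
      p <- file.path(od, "correlations", sprintf("%s_%s.asc", nm, layer))
      dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
      write_field(corr[[nm]][[layer]], dat$precip$meta, p, "ascii")
      paths <- c(paths, p)
    }
    s <- area_summary(corr[[nm]], cfg$trend_alpha)
    corr_summary <- rbind(corr_summary,
                          data.frame(field = nm, mean_r = s$mean_r,
                                     frac_positive = s$frac_positive,
                                     frac_significant = s$frac_significant))
  }
  p <- file.path(od, "correlation_summary.csv")
  utils::write.csv(corr_summary, p, row.names = FALSE); paths <- c(paths, p)

  # --- impact ---
  say("stage impact")
  imp <- stage("impact", {
    base <- suppressWarnings(
      non_drought_baseline(casa$npp, sev, dat$landcover))
    tab <- suppressWarnings(
      delta_npp(casa$npp, sev, dat$landcover, base, by_month = TRUE))
    list(baseline = base, delta = tab,
         profile = seasonal_anomaly_profile(tab))
  })
  p <- file.path(od, "delta_npp.csv")
  utils::write.csv(imp$delta, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(od, "seasonal_profile.csv")
  utils::write.csv(imp$profile, p, row.names = FALSE); paths <- c(paths, p)

  # --- validation ---
  say("stage validation")
  val <- stage("validation", {
    if (is.null(dat$catalog)) return(NULL)
    flags <- regional_drought_flags(spei1, cfg$skill_rule,
                                    tau = cfg$skill_tau, phi = cfg$skill_phi)
    list(flags = flags, scores = skill_scores(flags, dat$catalog))
  })
  if (!is.null(val)) {
    p <- file.path(od, "drought_flags.csv")
    utils::write.csv(val$flags, p, row.names = FALSE); paths <- c(paths, p)
    p <- file.path(od, "skill_scores.json")
    jsonlite::write_json(unclass(val$scores), p, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, p)
  }

  # --- manifest ---
  say("stage manifest")
  paths <- unique(paths)
  art <- data.frame(path = sub(paste0("^", od, "/?"), "", paths),
                    md5 = unname(tools::md5sum(paths)),
                    stringsAsFactors = FALSE)
  art <- art[order(art$path), , drop = FALSE]
  manifest <- list(
    package = "droughtnpp",
    seed = cfg$seed,
    n_artifacts = nrow(art),
    artifacts = art)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("done: %d artifacts in %.1f s", nrow(art),
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(c(manifest, list(out_dir = od)))
}

#' Summarize a pipeline run from its written artifacts
#'
#' Re-derives headline numbers from the rasters and tables on disk (never
#' from in-memory state): regional mean annual NPP and its Theil-Sen slope,
#' trend-class area fractions, drought-frequency mean, correlation
#' summaries, the anomaly table and skill scores. Missing artifacts are
#' listed as absent rather than crashing.
#'
#' @param out_dir A pipeline output directory containing `manifest.json`.
#' @return Object of class `run_summary` (also printed nicely).
#' @export
summarize_run <- function(out_dir) {
  mf <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", out_dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  absent <- character(0)
  out <- list(out_dir = out_dir, seed = manifest$seed,
              n_artifacts = manifest$n_artifacts)

  ann_files <- sort(Sys.glob(file.path(out_dir, "npp_annual",
                                       "npp_annual_*.asc")))
  if (length(ann_files)) {
    yrs <- as.integer(sub(".*_(\\d{4})\\.asc$", "\\1", ann_files))
    series <- vapply(ann_files, function(f)
      mean(read_field(f)$field, na.rm = TRUE), 0)
    out$mean_annual_npp <- mean(series)
    out$npp_sen_slope <- sen_slope(series, yrs)
    out$npp_annual_series <- data.frame(year = yrs, npp = unname(series))
  } else absent <- c(absent, "npp_annual")

  cls_file <- file.path(out_dir, "trend_npp_class.asc")
  if (file.exists(cls_file)) {
    cl <- read_field(cls_file)$field
    frac <- tabulate(cl[!is.na(cl)], 4L) / sum(!is.na(cl))
    names(frac) <- trend_class_labels()
    out$trend_class_fractions <- frac
  } else absent <- c(absent, "trend_npp_class")

  dfi_file <- file.path(out_dir, "dfi_spei1.asc")
  if (file.exists(dfi_file)) {
    out$mean_dfi_pct <- mean(read_field(dfi_file)$field, na.rm = TRUE)
  } else absent <- c(absent, "dfi_spei1")

  cs <- file.path(out_dir, "correlation_summary.csv")
  if (file.exists(cs)) out$correlations <- utils::read.csv(cs)
  else absent <- c(absent, "correlation_summary")

  dn <- file.path(out_dir, "delta_npp.csv")
  if (file.exists(dn)) out$delta_npp <- utils::read.csv(dn)
  else absent <- c(absent, "delta_npp")

  sk <- file.path(out_dir, "skill_scores.json")
  if (file.exists(sk)) out$skill <- jsonlite::read_json(sk,
                                                        simplifyVector = TRUE)
  else absent <- c(absent, "skill_scores")

  out$absent <- absent
  if (length(absent)) warning("absent artifacts: ",
                              paste(absent, collapse = ", "), call. = FALSE)
  structure(out, class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("droughtnpp run summary (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$mean_annual_npp))
    cat(sprintf("  mean annual NPP: %.2f gC m-2 a-1 (Sen slope %+.3f per a)\n",
                x$mean_annual_npp, x$npp_sen_slope))
  if (!is.null(x$trend_class_fractions)) {
    cat("  NPP trend classes: ")
    cat(paste(sprintf("%s %.1f%%", names(x$trend_class_fractions),
                      100 * x$trend_class_fractions), collapse = ", "), "\n")
  }
  if (!is.null(x$mean_dfi_pct))
    cat(sprintf("  mean drought frequency (SPEI-1): %.1f%%\n", x$mean_dfi_pct))
  if (!is.null(x$skill))
    cat(sprintf("  drought detection: POD %.4f, FAR %.4f, CSI %.4f\n",
                x$skill$pod, x$skill$far, x$skill$csi))
  if (length(x$absent))
    cat("  absent artifacts:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}
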