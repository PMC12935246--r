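make_sev <- function(codes, meta, times) {
  # codes: [time, row, col] integer array
  grid_cube(codes, meta, times, "severity")
}

test_that("baseline without drought equals the climatological monthly mean", {
  set.seed(40)
  npp <- tiny_cube(24, fill = function(i, m) matrix(runif(9, 10, 50), 3, 3))
  sev <- make_sev(array(0L, c(24, 3, 3)), tiny_meta(), npp$times)
  lc <- grass_map()
  base <- non_drought_baseline(npp, sev, lc)
  for (m in 1:12) {
    want <- mean(npp$values[npp$times$month == m, , ])
    expect_equal(unname(base$baseline["grassland", m]), want)
  }
  expect_true(all(is.na(base$baseline[c("farmland", "woodland"), ])))
})

test_that("a class in permanent drought has absent baselines", {
  npp <- tiny_cube(24, fill = 20)
  sev <- make_sev(array(2L, c(24, 3, 3)), tiny_meta(), npp$times)
  expect_warning(base <- non_drought_baseline(npp, sev, grass_map()),
                 "no non-drought samples")
  expect_true(all(is.na(base$baseline["grassland", ])))
})

test_that("baseline on a hand-built two-pixel, two-year toy matches hand averages", {
  meta <- grid_meta(1, 2)
  tt <- tiny_times(24)
  v <- array(NA_real_, c(24, 1, 2))
  v[, 1, 1] <- 10 + seq_len(24)        # pixel 1
  v[, 1, 2] <- 100 + seq_len(24)       # pixel 2
  npp <- grid_cube(v, meta, tt, "gC m-2 month-1")
  codes <- array(0L, c(24, 1, 2))
  codes[13, 1, 1] <- 2L                # Jan of year 2, pixel 1 in drought
  sev <- make_sev(codes, meta, tt)
  lc <- land_cover_map(matrix(3L, 1, 2), meta)
  base <- non_drought_baseline(npp, sev, lc)
  # January baseline: pixels {11 (y1 p1), 101 (y1 p2), 113 (y2 p2)};
  # the drought month (y2 p1) is excluded
  expect_equal(unname(base$baseline["grassland", 1]), mean(c(11, 101, 113)))
  # February baseline: all four pixel-months
  expect_equal(unname(base$baseline["grassland", 2]),
               mean(c(12, 102, 24, 114)))
})

test_that("delta NPP is the percent departure from the class-month baseline", {
  npp <- tiny_cube(24, fill = function(i, m) matrix(50, 3, 3))
  codes <- array(0L, c(24, 3, 3))
  codes[7, , ] <- 1L                   # one mild-drought July
  sev <- make_sev(codes, tiny_meta(), npp$times)
  lc <- grass_map()
  base <- non_drought_baseline(npp, sev, lc)
  # NPP equal to baseline in drought months: all rows zero
  tab <- delta_npp(npp, sev, lc, base)
  expect_equal(tab$delta_npp_pct, 0)
  expect_equal(tab$severity, "mild")
  expect_equal(tab$n, 9L)

  # drought months at 1.2x the baseline: +20 percent
  v2 <- npp$values; v2[7, , ] <- 60
  npp2 <- cube_like(npp, v2)
  base2 <- non_drought_baseline(npp2, sev, lc)
  tab2 <- delta_npp(npp2, sev, lc, base2)
  expect_equal(tab2$delta_npp_pct, 20)
})

test_that("rows with no contributing pixel-months are absent, not zero", {
  npp <- tiny_cube(12, fill = 50)
  codes <- array(0L, c(12, 3, 3))
  codes[5, 1, 1] <- 3L                 # a single severe pixel-month
  sev <- make_sev(codes, tiny_meta(), npp$times)
  lc <- grass_map()
  base <- non_drought_baseline(npp, sev, lc)
  tab <- delta_npp(npp, sev, lc, base)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$severity, "severe")
  expect_equal(tab$class, "grassland")
})

test_that("an imposed 30 percent severe-drought reduction is recovered", {
  sc <- generate_synthetic(synth_config(n_rows = 8, n_cols = 8, seed = 41))
  pet <- pet_thornthwaite(sc$temp)
  sev <- classify_severity(spei(sc$precip, pet, 1))
  # baseline NPP: pure seasonal climatology + small noise, no P coupling
  set.seed(41)
  tt <- sc$precip$times
  v <- array(NA_real_, c(240, 8, 8))
  for (i in 1:240)
    v[i, , ] <- 60 + 40 * cos(2 * pi * (tt$month[i] - 7) / 12) +
      matrix(rnorm(64, 0, 2), 8, 8)
  npp0 <- grid_cube(v, sc$precip$meta, tt, "gC m-2 month-1")
  red <- c(mild = 0.05, moderate = 0.15, severe = 0.30, extreme = 0.50)
  npp <- impose_drought_response(npp0, sev, sc$landcover, red, classes = 3L)
  base <- suppressWarnings(non_drought_baseline(npp, sev, sc$landcover))
  tab <- suppressWarnings(delta_npp(npp, sev, sc$landcover, base))
  grass <- tab[tab$class == "grassland", ]
  sev_row <- grass[grass$severity == "severe", ]
  expect_gt(nrow(sev_row), 0)
  expect_gt(sev_row$delta_npp_pct, -33)
  expect_lt(sev_row$delta_npp_pct, -27)
  # severity-monotonic scenario gives a severity-monotonic table
  present <- intersect(severity_labels()[-1], grass$severity)
  means <- grass$delta_npp_pct[match(present, grass$severity)]
  expect_true(all(diff(means) < 0))
})

test_that("the n-weighted severity means pool back to the drought-month mean", {
  sc <- generate_synthetic(synth_config(n_rows = 6, n_cols = 6, seed = 42))
  pet <- pet_thornthwaite(sc$temp)
  sev <- classify_severity(spei(sc$precip, pet, 1))
  npp <- casa_npp(sc$ndvi, sc$temp, sc$sol, sc$precip, sc$landcover, pet = pet)
  base <- suppressWarnings(non_drought_baseline(npp, sev, sc$landcover))
  tab <- suppressWarnings(delta_npp(npp, sev, sc$landcover, base))
  for (k in unique(tab$class)) {
    rows <- tab[tab$class == k, ]
    pooled_from_table <- sum(rows$delta_npp_pct * rows$n) / sum(rows$n)
    # oracle: directly pool every drought pixel-month of that class
    kcode <- match(k, landcover_class_names())
    sel_class <- sc$landcover$classes == kcode
    ds <- c()
    for (i in 1:240) {
      s <- sev$values[i, , ]
      m <- npp$times$month[i]
      b <- base$baseline[kcode, m]
      hit <- !is.na(s) & s >= 1 & sel_class
      if (!any(hit) || is.na(b) || b == 0) next
      ds <- c(ds, 100 * (npp$values[i, , ][hit] - b) / b)
    }
    expect_equal(pooled_from_table, mean(ds), tolerance = 1e-10)
  }
})

test_that("seasonal anomaly profile orders windows as constructed", {
  tab <- data.frame(
    class = "grassland",
    severity = rep(c("mild", "severe"), each = 6),
    month = rep(3:8, 2),
    delta_npp_pct = c(rep(-10, 6), -10, -10, -10, -30, -30, -30),
    n = 5L)
  class(tab) <- c("delta_npp_table", class(tab))
  prof <- seasonal_anomaly_profile(tab)
  mild <- prof[prof$severity == "mild", ]
  sevr <- prof[prof$severity == "severe", ]
  expect_equal(mild$more_negative, "equal")
  expect_equal(sevr$more_negative, "peak_jja")
  expect_equal(sevr$early_mam, -10)
  expect_equal(sevr$peak_jja, -30)
  expect_error(seasonal_anomaly_profile(tab[, setdiff(names(tab), "month")]),
               "monthly-resolved")
})

test_that("regional drought flags obey both rules and a counting oracle", {
  tt <- tiny_times(3)
  mk_idx <- function(fill) drought_index_cube(
    grid_cube(array(fill, c(3, 4, 4)), grid_meta(4, 4), tt), 1, "spei")
  dry <- mk_idx(-2); wet <- mk_idx(1)
  expect_true(all(regional_drought_flags(dry, "mean_index")$flag))
  expect_true(all(regional_drought_flags(dry, "area_fraction")$flag))
  expect_false(any(regional_drought_flags(wet, "mean_index")$flag))
  expect_false(any(regional_drought_flags(wet, "area_fraction")$flag))

  set.seed(43)
  v <- array(rnorm(12 * 4 * 4), c(12, 4, 4))
  idx <- drought_index_cube(
    grid_cube(v, grid_meta(4, 4), tiny_times(12)), 1, "spei")
  got <- regional_drought_flags(idx, "area_fraction", phi = 0.3)$flag
  want <- vapply(1:12, function(i) mean(v[i, , ] <= -0.5) >= 0.3, NA)
  expect_identical(got, want)
})

test_that("skill scores satisfy the perfect-forecast identity and count formulas", {
  tt <- tiny_times(24)
  catalog <- data.frame(start_year = 2001L, start_month = 3L,
                        end_year = 2001L, end_month = 5L, label = "ev")
  flags <- data.frame(year = tt$year, month = tt$month,
                      flag = tt$year == 2001 & tt$month %in% 3:5)
  s <- skill_scores(flags, catalog)
  expect_equal(s$pod, 1); expect_equal(s$far, 0); expect_equal(s$csi, 1)

  # no flags: POD 0, FAR absent
  s0 <- skill_scores(data.frame(year = tt$year, month = tt$month,
                                flag = FALSE), catalog)
  expect_equal(s0$pod, 0)
  expect_true(is.na(s0$far))

  # H=16, M=7, F=3 evaluates to the closed-form ratios
  flags2 <- data.frame(year = rep(2001:2003, each = 12),
                       month = rep(1:12, 3), flag = FALSE)
  cat2 <- data.frame(start_year = 2001L, start_month = 1L,
                     end_year = 2002L, end_month = 11L, label = "long")
  flags2$flag[1:16] <- TRUE                       # 16 hits inside the event
  flags2$flag[24 + (1:3)] <- TRUE                 # 3 false alarms in 2003
  s2 <- skill_scores(flags2, cat2)
  expect_equal(c(s2$hits, s2$misses, s2$false_alarms), c(16, 7, 3))
  expect_equal(s2$pod, 16 / 23, tolerance = 1e-12)   # 0.6957
  expect_equal(s2$far, 3 / 19, tolerance = 1e-12)    # 0.1579
  expect_equal(s2$csi, 16 / 26, tolerance = 1e-12)
})

test_that("skill scores equal brute-force counting on random flag/catalog pairs", {
  set.seed(44)
  tt <- tiny_times(60)
  for (rep in 1:30) {
    flag <- runif(60) < 0.3
    st <- sample(1:40, 1); en <- st + sample(0:10, 1)
    catalog <- data.frame(start_year = tt$year[st], start_month = tt$month[st],
                          end_year = tt$year[en], end_month = tt$month[en],
                          label = "r")
    s <- skill_scores(data.frame(year = tt$year, month = tt$month,
                                 flag = flag), catalog)
    inside <- seq_len(60) %in% st:en
    H <- sum(flag & inside); M <- sum(!flag & inside); FA <- sum(flag & !inside)
    expect_equal(c(s$hits, s$misses, s$false_alarms), c(H, M, FA))
    if (H + M + FA > 0 && H + M > 0 && H + FA > 0)
      expect_lte(s$csi, min(s$pod, 1 - s$far) + 1e-12)
  }
  expect_error(skill_scores(
    data.frame(year = 2001, month = 1, flag = TRUE),
    data.frame(start_year = 2005L, start_month = 1L, end_year = 2005L,
               end_month = 2L, label = "x")), "outside the flag range")
})
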