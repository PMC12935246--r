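test_that("FPAR hits its bounds at the class NDVI endpoints", {
  params <- casa_params(ndvi_bounds = list(grassland = c(0.1, 0.9)),
                        fpar_bounds = c(0.001, 0.95))
  lc <- grass_map()
  at_min <- fpar(tiny_cube(fill = 0.1), lc, params)
  at_max <- fpar(tiny_cube(fill = 0.9), lc, params)
  expect_equal(unique(as.numeric(at_min$values)), 0.001)
  expect_equal(unique(as.numeric(at_max$values)), 0.95)
})

test_that("FPAR mixes the ramp and simple-ratio estimates as specified", {
  # independent scalar evaluation of both estimates at NDVI = 0.5,
  # class bounds (0.1, 0.9), FPAR bounds (0.001, 0.95), alpha = 0.5
  nb <- c(0.1, 0.9); fb <- c(0.001, 0.95)
  ramp <- (0.5 - nb[1]) / (nb[2] - nb[1]) * (fb[2] - fb[1]) + fb[1]
  sr <- (1 + 0.5) / (1 - 0.5)
  sr_min <- (1 + nb[1]) / (1 - nb[1]); sr_max <- (1 + nb[2]) / (1 - nb[2])
  srp <- (sr - sr_min) / (sr_max - sr_min) * (fb[2] - fb[1]) + fb[1]
  expected <- 0.5 * ramp + 0.5 * srp

  params <- casa_params(ndvi_bounds = list(grassland = nb), fpar_bounds = fb)
  got <- fpar(tiny_cube(fill = 0.5), grass_map(), params)
  expect_equal(unique(as.numeric(got$values)), expected, tolerance = 1e-12)
  # monotone non-decreasing in NDVI
  seqv <- seq(-0.2, 1, by = 0.05)
  vals <- vapply(seqv, function(nd)
    fpar(tiny_cube(n = 1, fill = nd), grass_map(), params)$values[1, 1, 1], 0)
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= fb[1] - 1e-12 & vals <= fb[2] + 1e-12))
})

test_that("FPAR masks non-vegetated classes and rejects NDVI outside [-1, 1]", {
  lc <- land_cover_map(matrix(rep(c(3L, 4L, 5L), each = 3), 3, 3),
                       tiny_meta())
  out <- fpar(tiny_cube(fill = 0.5), lc,
              casa_params(ndvi_bounds = list(grassland = c(0.1, 0.9))))
  expect_true(all(is.na(out$values[, , 2:3])))
  expect_true(all(!is.na(out$values[, , 1])))
  expect_error(fpar(tiny_cube(fill = 1.5), lc, casa_params()), "NDVI")
})

test_that("optimal temperature picks the NDVI-peak month, earliest on ties", {
  # NDVI peaks every July; July temperature is 20
  ndvi <- tiny_cube(24, fill = function(i, m) {
    matrix(ifelse(m == 7, 0.9, 0.3), 3, 3)
  })
  temp <- tiny_cube(24, fill = function(i, m) matrix(ifelse(m == 7, 20, 5), 3, 3))
  expect_equal(unique(as.numeric(optimal_temperature(ndvi, temp))), 20)

  # tie between March and July: earliest (March) wins
  ndvi2 <- tiny_cube(24, fill = function(i, m)
    matrix(ifelse(m %in% c(3, 7), 0.9, 0.3), 3, 3))
  temp2 <- tiny_cube(24, fill = function(i, m) matrix(m, 3, 3))
  expect_equal(unique(as.numeric(optimal_temperature(ndvi2, temp2))), 3)
})

test_that("optimal temperature recovers a forced per-pixel peak month", {
  set.seed(42)
  nr <- 4; nc <- 5
  m_star <- matrix(sample(1:12, nr * nc, replace = TRUE), nr, nc)
  tt <- tiny_times(36)
  nv <- array(NA_real_, c(36, nr, nc))
  tv <- array(NA_real_, c(36, nr, nc))
  for (i in 1:36) {
    nv[i, , ] <- 0.3 + 0.5 * (m_star == tt$month[i]) +
      matrix(runif(nr * nc, 0, 0.05), nr, nc)
    tv[i, , ] <- matrix(tt$month[i] * 2, nr, nc)
  }
  meta <- grid_meta(nr, nc)
  topt <- optimal_temperature(grid_cube(nv, meta, tt),
                              grid_cube(tv, meta, tt))
  # brute-force oracle: argmax of the 12 multi-year mean NDVI values
  for (r in 1:nr) for (cc in 1:nc) {
    means <- vapply(1:12, function(m) mean(nv[tt$month == m, r, cc]), 0)
    expect_equal(topt[r, cc], which.max(means) * 2)
  }
})

test_that("temperature stress scalars follow their closed forms", {
  temp <- tiny_cube(n = 1, fill = 20)
  topt <- matrix(20, 3, 3)
  ts <- temperature_stress(temp, topt)
  expect_equal(unique(as.numeric(ts$t1$values)), 1.0)  # 0.8 + 0.4 - 0.2
  # T = Topt: direct scalar substitution of the two logistic factors
  t2_hand <- 1.1814 / (1 + exp(0.2 * (20 - 10 - 20))) /
    (1 + exp(0.3 * (-20 - 10 + 20)))
  expect_equal(unique(as.numeric(ts$t2$values)), t2_hand, tolerance = 1e-12)
  # far below the optimum the cold logistic kills T2
  cold <- temperature_stress(tiny_cube(n = 1, fill = -40), matrix(25, 3, 3))
  expect_lt(max(cold$t2$values), 1e-4)
  expect_true(all(ts$t1$values >= 0) && all(ts$t2$values >= 0))
})

test_that("water stress spans [0.5, 1] with the documented couplings", {
  # scalar oracle for the evapotranspiration coupling at P = 50, Rn = 40
  p <- 50; rn <- 40
  eet_hand <- p * rn * (p^2 + rn^2 + p * rn) / ((p + rn) * (p^2 + rn^2))
  expect_equal(droughtnpp:::zhou_zhang_eet(p, rn), eet_hand)

  params <- casa_params()
  precip <- tiny_cube(n = 1, fill = 50, units = "mm")
  pet0 <- tiny_cube(n = 1, fill = 0, units = "mm")
  expect_equal(unique(as.numeric(
    water_stress(precip, pet0, params = params)$values)), 0.5)
  pet <- tiny_cube(n = 1, fill = 80, units = "mm")
  w <- water_stress(precip, pet, params = params)
  rn_used <- 80 * params$rn_a + params$rn_b * 50
  w_hand <- 0.5 + 0.5 * min(droughtnpp:::zhou_zhang_eet(50, rn_used) / 80, 1)
  expect_equal(unique(as.numeric(w$values)), w_hand, tolerance = 1e-12)
  expect_true(all(w$values >= 0.5 & w$values <= 1))

  # soil-moisture mode: SM at its 95th percentile gives W = 1
  smv <- tiny_cube(12, fill = function(i, m) matrix(0.1 + 0.02 * i, 3, 3))
  params_sm <- casa_params(water_stress_mode = "soil_moisture")
  wsm <- water_stress(tiny_cube(12, fill = 10), sm = smv, params = params_sm)
  expect_true(all(wsm$values >= 0.5 & wsm$values <= 1))
  expect_equal(max(wsm$values), 1, tolerance = 1e-12)
})

test_that("APAR is half of SOL times FPAR", {
  sol <- tiny_cube(fill = 100, units = "MJ m-2 month-1")
  fp <- tiny_cube(fill = 0.4)
  expect_equal(unique(as.numeric(apar(sol, fp)$values)), 20)
  expect_equal(unique(as.numeric(apar(sol, tiny_cube(fill = 0))$values)), 0)
  expect_error(apar(tiny_cube(fill = -1), fp), "negative")
  # element-wise oracle on a random cube
  set.seed(3)
  sv <- tiny_cube(fill = function(i, m) matrix(runif(9, 0, 600), 3, 3))
  fv <- tiny_cube(fill = function(i, m) matrix(runif(9), 3, 3))
  got <- apar(sv, fv)$values
  for (i in 1:12) for (r in 1:3) for (cc in 1:3)
    expect_identical(got[i, r, cc], 0.5 * sv$values[i, r, cc] * fv$values[i, r, cc])
})

test_that("monthly NPP is the product of APAR, stresses and eps_max", {
  ap <- tiny_cube(n = 1, fill = 20)
  one <- tiny_cube(n = 1, fill = 1)
  lc <- grass_map()
  params <- casa_params(eps_max = c(grassland = 0.542))
  npp <- npp_monthly(ap, one, one, one, lc, params)
  expect_equal(unique(as.numeric(npp$values)), 10.84)
  # linear in each stress factor
  half <- tiny_cube(n = 1, fill = 0.5)
  npp_half <- npp_monthly(ap, one, one, half, lc, params)
  expect_equal(npp_half$values, 0.5 * npp$values)
  # homogeneity: doubling APAR doubles NPP
  npp2 <- npp_monthly(tiny_cube(n = 1, fill = 40), one, one, one, lc, params)
  expect_equal(npp2$values, 2 * npp$values)
  # vegetated class without eps_max is a hard error
  expect_error(npp_monthly(ap, one, one, one, lc,
                           casa_params(eps_max = c(farmland = 0.542))),
               "grassland")
  # non-vegetated cells are masked
  lc_mix <- land_cover_map(matrix(rep(c(3L, 4L, 3L), each = 3), 3, 3),
                           tiny_meta())
  npp_mix <- npp_monthly(ap, one, one, one, lc_mix, params)
  expect_true(all(is.na(npp_mix$values[, , 2])))
})

test_that("the CASA chain equals its element-wise factorization", {
  sc <- small_scenario(seed = 30)
  params <- casa_params()
  pet <- pet_thornthwaite(sc$temp)
  fp <- fpar(sc$ndvi, sc$landcover, params)
  topt <- optimal_temperature(sc$ndvi, sc$temp)
  ts <- temperature_stress(sc$temp, topt)
  w <- water_stress(sc$precip, pet, params = params)
  npp <- npp_monthly(apar(sc$sol, fp), ts$t1, ts$t2, w, sc$landcover, params)

  eps <- matrix(NA_real_, 6, 6)
  for (k in 1:3)
    eps[sc$landcover$classes == k] <-
      params$eps_max[[landcover_class_names()[k]]]
  for (i in seq(1, 240, by = 37)) for (r in 1:6) for (cc in 1:6) {
    want <- 0.5 * sc$sol$values[i, r, cc] * fp$values[i, r, cc] *
      ts$t1$values[i, r, cc] * ts$t2$values[i, r, cc] *
      w$values[i, r, cc] * eps[r, cc]
    expect_equal(npp$values[i, r, cc], want, tolerance = 1e-12)
  }
})

test_that("NPP responds monotonically to its drivers", {
  lc <- grass_map()
  params <- casa_params(ndvi_bounds = list(grassland = c(0.1, 0.9)))
  base <- list(ndvi = 0.5, sol = 400, w = 0.8)
  run1 <- function(ndvi_v, sol_v, w_v) {
    fp <- fpar(tiny_cube(n = 1, fill = ndvi_v), lc, params)
    ap <- apar(tiny_cube(n = 1, fill = sol_v), fp)
    one <- tiny_cube(n = 1, fill = 1)
    npp_monthly(ap, one, one, tiny_cube(n = 1, fill = w_v), lc,
                params)$values[1, 1, 1]
  }
  ref <- run1(0.5, 400, 0.8)
  expect_gt(run1(0.7, 400, 0.8), ref)   # greener
  expect_gt(run1(0.5, 500, 0.8), ref)   # sunnier
  expect_gt(run1(0.5, 400, 0.9), ref)   # wetter
})

test_that("annual NPP sums 12 months and demands complete years", {
  npp <- tiny_cube(24, fill = 10)
  ann <- npp_annual(npp, 2001)
  expect_equal(unique(as.numeric(ann)), 120)
  expect_error(npp_annual(tiny_cube(10), 2001), "need 12")
  # one masked month masks the pixel
  v <- npp$values; v[3, 2, 2] <- NA
  npp2 <- cube_like(npp, v)
  ann2 <- npp_annual(npp2, 2001)
  expect_true(is.na(ann2[2, 2]) && !is.na(ann2[1, 1]))
  # random cube equals an explicit 12-term sum
  set.seed(4)
  rnd <- tiny_cube(12, fill = function(i, m) matrix(runif(9, 0, 50), 3, 3))
  annr <- npp_annual(rnd, 2001)
  for (r in 1:3) for (cc in 1:3)
    expect_equal(annr[r, cc], sum(rnd$values[, r, cc]))
})

test_that("benchmark agreement against an identical reference is perfect", {
  sc <- small_scenario(seed = 31)
  npp <- casa_npp(sc$ndvi, sc$temp, sc$sol, sc$precip, sc$landcover)
  res <- suppressWarnings(benchmark_agreement(npp, npp, sc$landcover))
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_lt(res$p_value, 0.01)
})
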