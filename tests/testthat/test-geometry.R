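make_traps <- function(x, y, catch, year = 1) {
  data.frame(year = year, x_km = x, y_km = y, catch = catch, treated = 0L)
}

test_that("mask_treatments: no-op, boundary-inclusive, brute force", {
  tr <- make_traps(c(0, 1, 2, 5), c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_identical(mask_treatments(tr, NULL)[, 1:5], tr[, 1:5])

  sites <- data.frame(x_km = 0, y_km = 0)
  out <- mask_treatments(tr, sites, radius = 1.5)
  expect_equal(out$x_km, c(2, 5))       # trap at exactly 1.5 km? none here
  out2 <- mask_treatments(make_traps(c(1.5, 3), c(0, 0), c(1, 2)), sites)
  expect_equal(out2$x_km, 3)            # exactly 1.5 km is removed

  set.seed(2)
  tr10 <- make_traps(runif(10, 0, 10), runif(10, 0, 10), 1:10)
  s2 <- data.frame(x_km = 5, y_km = 5)
  d <- sqrt((tr10$x_km - 5)^2 + (tr10$y_km - 5)^2)
  kept <- mask_treatments(tr10, s2, 3)
  expect_equal(nrow(kept), sum(d > 3))
  expect_equal(attr(kept, "n_removed"), sum(d <= 3))
  expect_error(mask_treatments(tr10, s2, radius = 100), "unusable")
})

test_that("indicator surface: degenerate cases and exact interpolation", {
  tr <- make_traps(0:10, rep(0, 11), rep(50, 11))
  expect_error(fit_indicator_surface(tr), "fully occupied")
  tr$catch <- 0
  expect_error(fit_indicator_surface(tr), "fully unoccupied")

  set.seed(5)
  x <- rep(0:4 * 2, 5); y <- rep(0:4 * 2, each = 5)
  catch <- ifelse(x <= 4, 20, 0) + rpois(25, 1)
  tr2 <- make_traps(x, y, catch)
  surf <- fit_indicator_surface(tr2, threshold_catch = 10, cell_km = 2)
  I <- as.numeric(catch >= 10)
  # traps sit on cell centers: kriging with no nugget reproduces the data
  ix <- match(x, surf$x); iy <- match(y, surf$y)
  expect_equal(surf$values[cbind(ix, iy)], I, tolerance = 1e-6)
})

test_that("1-D front: kriging matches full-system oracle, 0.5 level inside gap", {
  x <- c(0, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20)
  I <- as.numeric(x <= 10)
  tr <- make_traps(x, rep(0, 11), I * 20)
  surf <- fit_indicator_surface(tr, threshold_catch = 10, cell_km = 1)
  # independent oracle: solve the full kriging system at probe points
  vg <- surf$variogram
  probes <- seq(9, 13, by = 0.25)
  oracle <- oracle_krige(x, rep(0, 11), I, probes, rep(0, 11), vg)
  mine <- synchrospread:::krige_predict(x, rep(0, 11), I, probes,
                                        rep(0, 11), vg, n_nn = 16)
  expect_equal(mine, oracle, tolerance = 1e-8)
  # 0.5 level falls strictly between the last 1 (x=10) and first 0 (x=12)
  j <- which(oracle[-length(oracle)] >= 0.5 & oracle[-1] < 0.5)
  expect_true(length(j) >= 1)
  cross <- probes[j[length(j)]]
  expect_gt(cross, 10); expect_lt(cross, 12)
})

test_that("crossings on analytic surfaces", {
  # half-plane front at radius 40
  gx <- seq(-60, 60); gy <- seq(0, 60)
  rad <- sqrt(outer(gx^2, gy^2, `+`))
  surf <- raster_grid((rad < 40) * 1, gx, gy, 1)
  surf$year <- 1
  fan <- transect_fan(c(0, 0), seq(-30, 30, by = 5))
  cs <- transect_crossings(surf, fan, step_km = 0.25)
  expect_false(any(cs$missing))
  expect_true(all(abs(cs$distance_km - 40) <= 1))  # grid + sampling error

  # monotone logistic profile: crossing equals analytic level-set distance
  pr <- 1 / (1 + exp((rad - 40) / 3))
  surf2 <- raster_grid(pr, gx, gy, 1); surf2$year <- 1
  cs2 <- transect_crossings(surf2, transect_fan(c(0, 0), c(0, 10)),
                            step_km = 0.25)
  expect_true(all(abs(cs2$distance_km - 40) < 0.5))

  # occupied island beyond the front: outermost transition wins
  gx1 <- seq(-5, 5); gy1 <- seq(0, 70)
  prof <- function(d) as.numeric(d <= 30 | (d >= 50 & d <= 55))
  vals <- outer(gx1, gy1, function(x, y) prof(sqrt(x^2 + y^2)))
  surf3 <- raster_grid(vals, gx1, gy1, 1); surf3$year <- 1
  cs3 <- transect_crossings(surf3, transect_fan(c(0, 0), 0), step_km = 0.25)
  expect_false(cs3$missing)
  expect_gt(cs3$distance_km, 50)
  expect_lt(cs3$distance_km, 57)
  expect_gte(cs3$n_transitions, 2)

  # ray leaving the surface while occupied is missing, not a guess
  surf4 <- raster_grid(matrix(1, 11, 11), seq(-5, 5), seq(0, 10), 1)
  surf4$year <- 1
  cs4 <- transect_crossings(surf4, transect_fan(c(0, 0), 0))
  expect_true(cs4$missing)
})

test_that("crossings are invariant to rotating surface and fan together", {
  set.seed(8)
  x <- rep(seq(0, 20, 2), 6); y <- rep(seq(30, 40, 2), each = 11)
  catch <- rpois(66, ifelse(y <= 34 + x / 10, 30, 0.3))
  tr <- make_traps(x, y, catch)
  surf <- fit_indicator_surface(tr, cell_km = 1)
  fan <- transect_fan(c(10, 0), seq(-10, 10, 5))
  cs <- transect_crossings(surf, fan)
  # rotate everything 90 degrees clockwise: (x, y) -> (y, -x)
  tr90 <- make_traps(y, -x, catch)
  surf90 <- fit_indicator_surface(tr90, cell_km = 1)
  fan90 <- transect_fan(c(0, -10), seq(-10, 10, 5) + 90)
  cs90 <- transect_crossings(surf90, fan90)
  expect_equal(cs90$distance_km, cs$distance_km, tolerance = 1e-6)
  expect_identical(cs90$missing, cs$missing)
})

test_that("spread_rates: displacement, telescoping, missingness", {
  mk <- function(year, d, miss = rep(FALSE, length(d))) {
    structure(data.frame(bearing = seq_along(d), year = year,
                         distance_km = d, missing = miss,
                         n_transitions = 1L),
              class = c("crossing_set", "data.frame"))
  }
  cs <- list(mk(1, c(40, 41)), mk(2, c(50, 43)), mk(3, c(55, 41)))
  sp <- spread_rates(cs)
  expect_equal(unclass(sp)[1, ], c(10, 5), ignore_attr = TRUE)
  expect_equal(unclass(sp)[2, ], c(2, -2), ignore_attr = TRUE)
  # telescoping identity
  expect_equal(rowSums(unclass(sp)), c(55 - 40, 41 - 41),
               ignore_attr = TRUE)
  # static front
  sp0 <- spread_rates(list(mk(1, c(40, 41)), mk(2, c(40, 41))))
  expect_true(all(unclass(sp0) == 0))
  # missing crossing propagates
  spm <- spread_rates(list(mk(1, c(40, 41), c(FALSE, TRUE)),
                           mk(2, c(50, 43))))
  expect_true(is.na(unclass(spm)[2, 1]) && unclass(spm)[1, 1] == 10)
})

test_that("buffer_mean: uniform, gradient symmetry, explicit enumeration", {
  g <- raster_grid(matrix(7, 21, 21), -10:10, -10:10, 1)
  expect_equal(as.numeric(buffer_mean(g, c(0, 0), 8)), 7)

  grad <- raster_grid(outer(-10:10, -10:10, function(x, y) 2 * x + 3 * y),
                      -10:10, -10:10, 1)
  expect_equal(as.numeric(buffer_mean(grad, c(1, 2), 9)),
               2 * 1 + 3 * 2, tolerance = 1e-12)

  step <- raster_grid(outer(-10:10, -10:10, function(x, y) (x > 0) * 1),
                      -10:10, -10:10, 1)
  inside <- which(outer((-10:10)^2, (-10:10)^2, `+`) <= 3^2, arr.ind = TRUE)
  expected <- mean(((-10:10)[inside[, 1]] > 0) * 1)
  got <- buffer_mean(step, c(0, 0), 6)
  expect_equal(as.numeric(got), expected)
  expect_equal(attr(got, "n_cells"), nrow(inside))
  expect_error(buffer_mean(g, c(500, 500), 2), "no raster cell")
})

test_that("region_buffer_diameter: signed vs absolute, brute force", {
  f <- stfield(matrix(12, 4, 5), region = "A")
  expect_equal(region_buffer_diameter(f, "A"), 12)
  f2 <- stfield(matrix(c(10, -10), 2, 4), region = "A")
  expect_equal(region_buffer_diameter(f2, "A"), 0)
  expect_equal(region_buffer_diameter(f2, "A", "absolute"), 10)
  set.seed(3)
  m <- matrix(rnorm(12), 3, 4)
  f3 <- stfield(m, region = c("A", "A", "B"))
  expect_equal(region_buffer_diameter(f3, "A"), mean(m[1:2, ]))
})

test_that("local projection is consistent at the reference point", {
  p <- project_local(c(43.6, 43.7), c(-84.2, -84.2), c(43.6, -84.2))
  expect_equal(p$x_km, c(0, 0))
  expect_equal(p$y_km[1], 0)
  expect_equal(p$y_km[2], 0.1 * 111.32, tolerance = 1e-10)
})
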