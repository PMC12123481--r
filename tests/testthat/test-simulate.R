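test_that("driver: noise-free sinusoid, zero spec, and Nyquist guard", {
  d <- simulate_driver(driver_spec(c(5, 1, 0), ar1_sigma = 0), 30, seed = 1)
  expect_equal(d, sin(2 * pi * (1:30) / 5), tolerance = 1e-12)
  expect_equal(d[1:25], d[6:30])   # exactly periodic with period 5

  d0 <- simulate_driver(driver_spec(c(5, 0, 0), ar1_sigma = 0), 20)
  expect_identical(d0, rep(0, 20))

  expect_error(driver_spec(c(1.5, 1, 0)), "Nyquist")
})

test_that("driver AR(1) noise has the specified lag-1 autocorrelation", {
  d <- simulate_driver(driver_spec(c(5, 0, 0), ar1_phi = 0.5, ar1_sigma = 1),
                       10000, seed = 42)
  r1 <- cor(d[-1], d[-length(d)])
  expect_lt(abs(r1 - 0.5), 0.02)
})

test_that("same seed is bit-identical, different seeds differ", {
  cfg <- sim_config(seed = 7, n_transects = 6)
  a <- simulate_series_bundle(cfg, truth_pct = FALSE)
  b <- simulate_series_bundle(cfg, truth_pct = FALSE)
  expect_identical(a, b)
  c3 <- simulate_series_bundle(sim_config(seed = 8, n_transects = 6),
                               truth_pct = FALSE)
  expect_false(identical(unclass(a$spread), unclass(c3$spread)))
})

test_that("truth telescoping: spread rows sum to front displacement", {
  b <- simulate_series_bundle(sim_config(seed = 3, n_transects = 8),
                              truth_pct = FALSE)
  tr <- b$truth
  expect_equal(rowSums(tr$true_spread),
               tr$true_front_distance[, ncol(tr$true_front_distance)] -
                 tr$true_front_distance[, 1], tolerance = 1e-12)
  w <- simulate_trap_world(sim_config(seed = 4, n_years = 20,
                                      n_transects = 4))
  expect_equal(rowSums(w$truth$true_spread),
               w$truth$true_front_distance[, 20] -
                 w$truth$true_front_distance[, 1], tolerance = 1e-12)
})

test_that("b = 0 with no idiosyncratic noise gives constant true rates", {
  w <- simulate_trap_world(sim_config(seed = 5, n_years = 20,
                                      n_transects = 4, coupling_b = 0,
                                      idio_sigma_spread = 0,
                                      base_spread_mu = 7))
  expect_true(all(abs(w$truth$true_spread - 7) < 1e-12))
})

test_that("no idiosyncratic noise gives identical series and WPMF = 1", {
  b <- simulate_series_bundle(sim_config(seed = 6, n_transects = 10,
                                         idio_sigma_spread = 0,
                                         coupling_b = 1),
                              truth_pct = FALSE)
  v <- unclass(b$spread)
  expect_true(all(abs(sweep(v, 2, v[1, ])) < 1e-12))
  mf <- wpmf(morlet_cwt(clean_field(b$spread)$field))
  mags <- Mod(mf$values)[!mf$coi]
  expect_true(all(abs(mags - 1) < 1e-8))
})

test_that("front exiting the domain is an explicit error naming the year", {
  cfg <- sim_config(seed = 1, n_years = 25, n_transects = 4,
                    base_spread_mu = 100, domain_max_km = 800)
  expect_error(simulate_trap_world(cfg), "domain in year")
})

test_that("fractional climate lag shifts the deterministic driver exactly", {
  cfg <- sim_config(seed = 9, n_transects = 4, climate_lag = 1.25,
                    idio_sigma_climate = 0, idio_sigma_spread = 0,
                    coupling_b = 1, base_spread_mu = 0)
  b <- simulate_series_bundle(cfg, driver_spec(c(5, 1, 0), ar1_sigma = 0),
                              truth_pct = FALSE)
  tt <- seq_len(cfg$n_years)
  expect_equal(unclass(b$climate)[1, ], sin(2 * pi * (tt - 1.25) / 5),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("step front with Poisson-like counts: crossings hit the truth", {
  # scaled-down version of the 50-seed check: sharp front, huge K,
  # near-Poisson counts; the estimated isocline must sit within one grid
  # cell (1 km) of the true front on every bearing
  errs <- sapply(1:5, function(sd) {
    cfg <- sim_config(seed = sd, n_years = 20, n_transects = 8,
                      front_width_w = 0, nb_dispersion = Inf,
                      carrying_K = 1000, idio_sigma_spread = 0,
                      transition_zone_width = 60)
    w <- simulate_trap_world(cfg)
    tt <- w$traps[w$traps$year == 1, ]
    cs <- transect_crossings(fit_indicator_surface(tt), w$fan)
    max(abs(cs$distance_km - w$truth$true_front_distance[, 1]))
  })
  expect_true(all(errs <= 1))
})

test_that("doubling trap spacing does not improve crossing accuracy", {
  err_at <- function(spacing) {
    mean(sapply(1:6, function(sd) {
      cfg <- sim_config(seed = sd, n_years = 20, n_transects = 6,
                        front_width_w = 0, nb_dispersion = Inf,
                        carrying_K = 1000, idio_sigma_spread = 0,
                        trap_spacing = spacing,
                        transition_zone_width = 60)
      w <- simulate_trap_world(cfg)
      tt <- w$traps[w$traps$year == 1, ]
      cs <- transect_crossings(fit_indicator_surface(tt), w$fan)
      mean(abs(cs$distance_km - w$truth$true_front_distance[, 1]))
    }))
  }
  expect_gte(err_at(4), err_at(2))
})
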