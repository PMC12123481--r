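test_that("band constructor and scale lookup", {
  expect_equal(band("short")$lower, 2); expect_equal(band("short")$upper, 4)
  expect_equal(band("long")$upper, Inf)
  expect_error(band("custom"), "explicit")
  expect_error(band("custom", 5, 3), "lower < upper")
  f <- noise_field(4, 31, seed = 1)
  expect_error(band_test(f, f, band("custom", 20, 30), n_surrog = 0),
               "no usable grid timescales")
})

test_that("self- and anti-coherence under per-timescale normalisation", {
  f <- clean_field(noise_field(6, 31, seed = 2))$field
  wx <- morlet_cwt(f)
  cs <- spatial_coherence(wx, morlet_cwt(f), norm = "per_timescale")
  ok <- !is.na(cs)
  expect_equal(Mod(cs[ok]), rep(1, sum(ok)), tolerance = 1e-10)
  expect_equal(Arg(cs[ok]), rep(0, sum(ok)), tolerance = 1e-10)

  neg <- restfield(-unclass(f), f)
  cs2 <- spatial_coherence(morlet_cwt(f), morlet_cwt(neg),
                           norm = "per_timescale")
  expect_equal(Mod(cs2[ok]), rep(1, sum(ok)), tolerance = 1e-10)
  expect_true(all(abs(abs(Arg(cs2[ok])) - pi) < 1e-8))

  # |coh| <= 1 under per-timescale normalisation, arbitrary fields
  for (s in 1:5) {
    a <- clean_field(noise_field(8, 31, seed = 400 + s))$field
    b <- clean_field(noise_field(8, 31, seed = 500 + s))$field
    cc <- spatial_coherence(morlet_cwt(a), morlet_cwt(b),
                            norm = "per_timescale")
    expect_true(all(Mod(cc[!is.na(cc)]) <= 1 + 1e-10))
  }
})

test_that("quarter-cycle lag gives theta_bar +0.5 with the sign convention", {
  x <- sinusoid_field(12, 31, period = 4, lag = 0, noise_sd = 0.05, seed = 3)
  y <- sinusoid_field(12, 31, period = 4, lag = 1, noise_sd = 0.05, seed = 4)
  ct <- band_test(clean_field(x)$field, clean_field(y)$field,
                  band("short"), n_surrog = 0)
  expect_lt(abs(ct$theta_bar - 0.5), 0.05)
})

test_that("theta_bar antisymmetry under swapping response and predictor", {
  x <- clean_field(sinusoid_field(10, 31, period = 5, noise_sd = 0.3,
                                  seed = 5))$field
  y <- clean_field(sinusoid_field(10, 31, period = 5, lag = 0.7,
                                  noise_sd = 0.3, seed = 6))$field
  a <- band_test(x, y, band("long"), n_surrog = 0)
  b <- band_test(y, x, band("long"), n_surrog = 0)
  expect_equal(a$theta_bar, -b$theta_bar, tolerance = 1e-10)
})

test_that("fft surrogates preserve spectra, cross-spectra and the mean", {
  f <- clean_field(noise_field(6, 31, seed = 7))$field
  ens <- make_surrogates(f, n_surrog = 8, seed = 11)
  F0 <- t(stats::mvfft(t(unclass(f))))
  for (s in ens$surrogates) {
    Fs <- t(stats::mvfft(t(s)))
    expect_equal(Mod(Fs)^2, Mod(F0)^2, tolerance = 1e-9, ignore_attr = TRUE)
    # sync-preserving: cross-spectra between rows are exactly preserved
    expect_equal(Fs[1, ] * Conj(Fs[2, ]), F0[1, ] * Conj(F0[2, ]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(rowMeans(s), rowMeans(unclass(f)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # even length exercises the Nyquist bin
  fe <- stfield(matrix(rnorm(60), 2, 30))
  ense <- make_surrogates(fe, 4, seed = 3)
  for (s in ense$surrogates) {
    expect_equal(Mod(t(stats::mvfft(t(s))))^2,
                 Mod(t(stats::mvfft(t(unclass(fe)))))^2,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(make_surrogates(stfield(matrix(1, 2, 31))), "constant rows")
  # reproducible by seed
  e2 <- make_surrogates(f, 3, seed = 11)
  expect_identical(ens$surrogates[1:3], e2$surrogates)
})

test_that("aaft surrogates keep each row's value multiset", {
  f <- clean_field(noise_field(3, 31, seed = 8))$field
  ens <- make_surrogates(f, 3, method = "aaft", seed = 5)
  for (s in ens$surrogates) {
    for (i in 1:3) {
      expect_equal(sort(unname(s[i, ])), sort(unname(unclass(f)[i, ])))
    }
  }
})

test_that("identical response and predictor: minimal p, zero phase", {
  f <- clean_field(noise_field(8, 31, seed = 9))$field
  ct <- band_test(f, f, band("short"), n_surrog = 50, seed = 21)
  expect_equal(ct$p, 1 / 51)
  expect_equal(ct$theta_bar, 0, tolerance = 1e-12)
})

test_that("coupled simulator worlds are detected in the driver band", {
  ps <- sapply(1:10, function(s) {
    bnd <- simulate_series_bundle(sim_config(seed = s, n_transects = 15),
                                  driver_spec(c(3, 1, 0)),
                                  truth_pct = FALSE)
    band_test(clean_field(bnd$spread)$field,
              clean_field(bnd$climate)$field,
              band("short"), n_surrog = 100, seed = s + 900)$p
  })
  expect_gte(mean(ps < 0.1), 0.9)
})

test_that("index coherence: identical, delayed, and sign conventions", {
  set.seed(13)
  idx <- sin(2 * pi * (1:31) / 4) + 0.3 * rnorm(31)
  f <- stfield(matrix(idx, 8, 31, byrow = TRUE) +
                 matrix(rnorm(8 * 31, sd = 0.05), 8, 31))
  ct <- index_band_coherence(clean_field(f)$field, idx, band("short"),
                             n_surrog = 30, seed = 2)
  expect_equal(ct$p, 1 / 31, tolerance = 1e-12)
  expect_lt(abs(ct$theta_bar), 0.05)

  # field rows = index delayed by 1 year at period 4: predictor leads,
  # theta_bar ~ -0.5
  tt <- 1:31
  fld <- stfield(matrix(sin(2 * pi * (tt - 1) / 4), 8, 31, byrow = TRUE) +
                   matrix(rnorm(8 * 31, sd = 0.05), 8, 31))
  idx2 <- data.frame(year = tt, value = sin(2 * pi * tt / 4))
  ct2 <- index_band_coherence(clean_field(fld)$field, idx2, band("short"),
                              n_surrog = 0)
  expect_lt(abs(ct2$theta_bar + 0.5), 0.05)

  expect_error(index_band_coherence(f, data.frame(year = 1:10, value = 1:10),
                                    band("short"), n_surrog = 0),
               "does not cover")
})

test_that("band statistic is invariant to relabeling locations", {
  x <- clean_field(noise_field(9, 31, seed = 14))$field
  y <- clean_field(noise_field(9, 31, seed = 15))$field
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  xp <- restfield(unclass(x)[perm, ], x, rows = perm)
  yp <- restfield(unclass(y)[perm, ], y, rows = perm)
  a <- band_test(x, y, band("short"), n_surrog = 0)
  b <- band_test(xp, yp, band("short"), n_surrog = 0)
  expect_equal(a$stat, b$stat, tolerance = 1e-12)
})
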