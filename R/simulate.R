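#' Shared oscillatory driver specification
#'
#' The synthetic worlds are forced by a common "climate driver": a sum of
#' sinusoids (the teleconnection-like multi-annual oscillation) plus AR(1)
#' red noise.  Spread pulses in the system being emulated recur roughly
#' every 4-6 years, so the default is a single period-5 component.
#'
#' @param components list of numeric vectors `c(period, amplitude, phase)`;
#'   period in years (>= 2, the Nyquist limit at annual sampling),
#'   amplitude dimensionless (>= 0), phase in radians.
#' @param ar1_phi AR(1) coefficient, in (-1, 1).
#' @param ar1_sigma innovation standard deviation, >= 0.
#' @return object of class `driver_spec`.
#' @export
driver_spec <- function(components = list(c(period = 5, amplitude = 1, phase = 0)),
                        ar1_phi = 0.5, ar1_sigma = 0.5) {
  if (is.numeric(components)) components <- list(components)
  components <- lapply(components, function(cm) {
    cm <- unname(as.numeric(cm))
    if (length(cm) == 2L) cm <- c(cm, 0)
    stopifnot(length(cm) == 3L)
    if (cm[1] < 2) {
      stop("driver component period ", cm[1],
           " yr is below the Nyquist limit of 2 yr for annual sampling")
    }
    if (cm[2] < 0) stop("driver component amplitude must be >= 0")
    cm
  })
  stopifnot(ar1_phi > -1, ar1_phi < 1, ar1_sigma >= 0)
  structure(list(components = components, ar1_phi = ar1_phi,
                 ar1_sigma = ar1_sigma),
            class = "driver_spec")
}

# Deterministic (sinusoidal) part of the driver at arbitrary, possibly
# fractional, times.
driver_deterministic <- function(spec, times) {
  out <- numeric(length(times))
  for (cm in spec$components) {
    out <- out + cm[2] * sin(2 * pi * times / cm[1] + cm[3])
  }
  out
}

# AR(1) path over integer times t_min..t_max, stationary initial condition.
ar1_path <- function(phi, sigma, t_min, t_max) {
  n <- t_max - t_min + 1L
  z <- numeric(n)
  if (sigma > 0) {
    z[1] <- stats::rnorm(1L, sd = sigma / sqrt(1 - phi^2))
    eps <- stats::rnorm(n - 1L, sd = sigma)
    for (i in seq_len(n - 1L)) z[i + 1L] <- phi * z[i] + eps[i]
  }
  z
}

# Evaluate a run-sequence at fractional times by linear interpolation.
interp_path <- function(z, t_min, times) {
  idx <- seq_along(z) + t_min - 1
  stats::approx(idx, z, xout = times, rule = 2)$y
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate the shared driver series
#'
#' @param spec a [driver_spec()].
#' @param n_years number of annual steps (>= 4).
#' @param seed integer seed; same seed gives a bit-identical series.
#' @return numeric vector of length `n_years` (times 1..n_years).
#' @examples
#' d <- simulate_driver(driver_spec(ar1_sigma = 0), 20, seed = 1)
#' all.equal(d, sin(2 * pi * (1:20) / 5))
#' @export
simulate_driver <- function(spec, n_years, seed = NULL) {
  stopifnot(inherits(spec, "driver_spec"), n_years >= 4)
  with_seed(seed, {
    t <- seq_len(n_years)
    driver_deterministic(spec, t) + ar1_path(spec$ar1_phi, spec$ar1_sigma, 1L, n_years)
  })
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic invasion-front world.  Defaults
#' mirror the survey design being emulated: 31 annual steps, 36 radial
#' transects at 0.5 degree spacing, ~2 km inter-trap distances, and a
#' ~170 km wide monitored swath around the range edge.
#'
#' @param n_years annual steps (>= 20, or downstream length filters reject
#'   all series).
#' @param n_transects number of transects.
#' @param bearing_step angular spacing between transects, degrees.
#' @param bearing_start bearing of the first transect, degrees clockwise
#'   from north.
#' @param base_spread_mu mean spread rate, km/yr.
#' @param coupling_b driver-to-spread coupling, (km/yr) per driver unit.
#' @param climate_lag lag of the climate series behind the driver, years
#'   (may be fractional; the sinusoidal part is evaluated at the shifted
#'   time, the AR(1) part linearly interpolated).
#' @param idio_sigma_spread,idio_sigma_climate SD of transect-level
#'   idiosyncratic noise added to spread (km/yr) and climate.
#' @param trap_spacing trap grid spacing, km.
#' @param front_width_w logistic front width parameter, km.
#' @param carrying_K density far behind the front, moths/trap.
#' @param nb_dispersion negative-binomial size parameter (> 0); `Inf` gives
#'   Poisson counts.
#' @param transition_zone_width width of the monitored band around the
#'   front, km.
#' @param front_start_km initial front distance from the fan origin, km.
#' @param domain_max_km outer limit of the simulated domain, km.
#' @param climate_cell_km climate raster resolution, km.
#' @param treated_fraction fraction of traps flagged as treatment-adjacent.
#' @param region region label applied to all transects.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_years = 31, n_transects = 36, bearing_step = 0.5,
                       bearing_start = 0,
                       base_spread_mu = 10, coupling_b = 5, climate_lag = 0,
                       idio_sigma_spread = 2, idio_sigma_climate = 0.5,
                       trap_spacing = 2, front_width_w = 10, carrying_K = 500,
                       nb_dispersion = 1, transition_zone_width = 170,
                       front_start_km = 150, domain_max_km = 2000,
                       climate_cell_km = 4, treated_fraction = 0,
                       region = "SIM", seed = 1L) {
  stopifnot(n_years >= 20, n_transects >= 2, bearing_step > 0,
            trap_spacing > 0, idio_sigma_spread >= 0, idio_sigma_climate >= 0,
            front_width_w >= 0, carrying_K > 0, nb_dispersion > 0,
            transition_zone_width > 0, treated_fraction >= 0,
            treated_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Driver values at integer analysis times and at lagged (possibly
# fractional) times, sharing one AR(1) realisation.
driver_pair <- function(spec, n_years, lag) {
  t <- seq_len(n_years)
  t_lag <- t - lag
  t_min <- as.integer(floor(min(c(t, t_lag)))) - 1L
  z <- ar1_path(spec$ar1_phi, spec$ar1_sigma, t_min, n_years)
  list(now = driver_deterministic(spec, t) + interp_path(z, t_min, t),
       lagged = driver_deterministic(spec, t_lag) + interp_path(z, t_min, t_lag))
}

#' Simulate direct spread and climate series (no trap geometry)
#'
#' Bypasses the spatial world: each transect's spread series is
#' `mu + b * driver(t)` plus idiosyncratic Gaussian noise, and each
#' transect's climate series is the driver evaluated `climate_lag` years
#' earlier plus noise.  Ground truth, including the percentage of synchrony
#' in spread explained by climate computed on the noise-free construction,
#' is returned for recovery tests.
#'
#' @param config a [sim_config()].
#' @param spec a [driver_spec()].
#' @param truth_pct if `TRUE` (default) run the Moran decomposition on the
#'   cleaned noise-free construction to record `true_pct_explained` per
#'   standard timescale band.
#' @return list with elements `spread` ([stfield]), `climate` ([stfield])
#'   and `truth` (list: `driver_series`, `true_front_distance`,
#'   `true_spread`, `true_pct_explained`).
#' @export
simulate_series_bundle <- function(config, spec = driver_spec(),
                                   truth_pct = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "driver_spec"))
  with_seed(config$seed, {
    n <- config$n_transects
    ny <- config$n_years
    dp <- driver_pair(spec, ny, config$climate_lag)
    bearings <- config$bearing_start + (seq_len(n) - 1L) * config$bearing_step
    mu_mat <- matrix(config$base_spread_mu + config$coupling_b * dp$now,
                     nrow = n, ncol = ny, byrow = TRUE)
    clim_mat <- matrix(dp$lagged, nrow = n, ncol = ny, byrow = TRUE)
    spread <- mu_mat + matrix(stats::rnorm(n * ny, sd = config$idio_sigma_spread), n, ny)
    climate <- clim_mat + matrix(stats::rnorm(n * ny, sd = config$idio_sigma_climate), n, ny)
    spread_f <- stfield(spread, locations = bearings, region = config$region)
    climate_f <- stfield(climate, locations = bearings, region = config$region)
    front <- config$front_start_km +
      t(apply(cbind(0, mu_mat[, -ny, drop = FALSE]), 1, cumsum))
    # telescoping convention: true_spread[, t] = front[, t+1] - front[, t]
    truth <- list(
      driver_series = dp$now,
      true_front_distance = front,
      true_spread = front[, -1, drop = FALSE] - front[, -ny, drop = FALSE],
      true_pct_explained = NULL)
    if (truth_pct) {
      x0 <- clean_field(stfield(mu_mat, locations = bearings))$field
      e0 <- clean_field(stfield(clim_mat, locations = bearings))$field
      truth$true_pct_explained <- c(
        short = moran_decompose(x0, e0, band("short"))$pct_explained,
        long = moran_decompose(x0, e0, band("long"))$pct_explained)
    }
    list(spread = spread_f, climate = climate_f, truth = truth)
  })
}

#' Simulate a full trap-catch world with a moving logistic front
#'
#' The true front along bearing theta advances each year by
#' `mu + b * driver(t)` plus noise.  Expected moth density at radial
#' distance `d` is the logistic profile `K / (1 + exp((d - f) / w))`, and
#' trap catches are negative-binomial draws on a square grid of traps
#' covering a band of width `transition_zone_width` around the front.
#' Yearly climate rasters hold the lagged driver plus cell-level noise.
#'
#' @inheritParams simulate_series_bundle
#' @return list with `traps` (data.frame: year, x_km, y_km, catch, treated),
#'   `climate` (list of yearly [raster_grid] objects), `truth` (as in
#'   [simulate_series_bundle], without `true_pct_explained`), and `fan`
#'   (the matching [transect_fan]).
#' @export
simulate_trap_world <- function(config, spec = driver_spec()) {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "driver_spec"))
  with_seed(config$seed, {
    n <- config$n_transects
    ny <- config$n_years
    dp <- driver_pair(spec, ny, config$climate_lag)
    bearings <- config$bearing_start + (seq_len(n) - 1L) * config$bearing_step
    rates <- config$base_spread_mu + config$coupling_b *
      matrix(dp$now, n, ny, byrow = TRUE) +
      matrix(stats::rnorm(n * ny, sd = config$idio_sigma_spread), n, ny)
    front <- config$front_start_km +
      t(apply(cbind(0, rates[, -ny, drop = FALSE]), 1, cumsum))
    half <- config$transition_zone_width / 2
    bad <- which(apply(front, 2, max) + half > config$domain_max_km |
                 apply(front, 2, min) - half < config$trap_spacing)
    if (length(bad)) {
      stop("invasion front exits the simulated domain in year ", bad[1])
    }
    wedge <- range(bearings) + c(-1, 1) * config$bearing_step / 2
    traps_by_year <- vector("list", ny)
    climate <- vector("list", ny)
    for (t in seq_len(ny)) {
      r_lo <- min(front[, t]) - half
      r_hi <- max(front[, t]) + half
      g <- band_grid(r_lo, r_hi, wedge, config$trap_spacing)
      f_here <- stats::approx(bearings, front[, t], xout = g$bearing, rule = 2)$y
      dens <- config$carrying_K /
        (1 + exp(pmin((g$r - f_here) / max(config$front_width_w, 1e-9), 700)))
      catch <- if (is.finite(config$nb_dispersion)) {
        stats::rnbinom(length(dens), size = config$nb_dispersion, mu = dens)
      } else stats::rpois(length(dens), dens)
      treated <- stats::rbinom(length(dens), 1L, config$treated_fraction)
      traps_by_year[[t]] <- data.frame(year = t, x_km = g$x, y_km = g$y,
                                       catch = catch, treated = treated)
      cg <- band_grid(r_lo, r_hi, wedge, config$climate_cell_km, full_box = TRUE)
      vals <- dp$lagged[t] +
        stats::rnorm(length(cg$gx) * length(cg$gy), sd = config$idio_sigma_climate)
      climate[[t]] <- raster_grid(matrix(vals, length(cg$gx), length(cg$gy)),
                                  x = cg$gx, y = cg$gy,
                                  cell_km = config$climate_cell_km)
    }
    truth <- list(driver_series = dp$now,
                  true_front_distance = front,
                  true_spread = front[, -1, drop = FALSE] - front[, -ny, drop = FALSE])
    list(traps = do.call(rbind, traps_by_year),
         climate = climate, truth = truth,
         fan = transect_fan(origin = c(0, 0), bearings = bearings,
                            region = config$region))
  })
}

# Grid points of the annular wedge band. Returns trap coordinates (filtered
# to the wedge) or, with full_box = TRUE, the axis vectors of the covering
# rectangle (for rasters).
band_grid <- function(r_lo, r_hi, wedge, spacing, full_box = FALSE) {
  th <- seq(wedge[1], wedge[2], length.out = 65) * pi / 180
  xs <- c(outer(c(r_lo, r_hi), sin(th)))
  ys <- c(outer(c(r_lo, r_hi), cos(th)))
  gx <- seq(floor(min(xs) / spacing), ceiling(max(xs) / spacing)) * spacing
  gy <- seq(floor(min(ys) / spacing), ceiling(max(ys) / spacing)) * spacing
  if (full_box) return(list(gx = gx, gy = gy))
  pts <- expand.grid(x = gx, y = gy)
  r <- sqrt(pts$x^2 + pts$y^2)
  brg <- (atan2(pts$x, pts$y) * 180 / pi) %% 360
  d1 <- (brg - wedge[1]) %% 360
  keep <- r >= r_lo & r <= r_hi & d1 <= (wedge[2] - wedge[1]) %% 360
  list(x = pts$x[keep], y = pts$y[keep], r = r[keep], bearing = brg[keep])
}
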