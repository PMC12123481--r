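#' Timescale grid for the Morlet transform
#'
#' Geometric grid of timescales (years).  At annual sampling the shortest
#' resolvable timescale is 2 years; the default maximum is half the series
#' length, set when the transform is computed.  With the default center
#' frequency `omega0 = 6` the Morlet scale parameter and the Fourier
#' period agree to within 3.3%, so timescales are treated as periods in
#' years throughout.
#'
#' @param s_min shortest timescale, years (>= 2).
#' @param s_max longest timescale, years; `NULL` means `T/2` at transform
#'   time.
#' @param sigma multiplicative scale step (> 1, default 1.05).
#' @param omega0 Morlet center frequency (default 6).
#' @return object of class `scale_grid`.
#' @export
scale_grid <- function(s_min = 2, s_max = NULL, sigma = 1.05, omega0 = 6) {
  stopifnot(s_min >= 2, sigma > 1, omega0 > 0,
            is.null(s_max) || s_max >= s_min)
  structure(list(s_min = s_min, s_max = s_max, sigma = sigma,
                 omega0 = omega0),
            class = "scale_grid")
}

grid_scales <- function(grid, T_len) {
  s_max <- grid$s_max %||% (T_len / 2)
  if (s_max > T_len) {
    warning("s_max ", s_max, " exceeds series length ", T_len,
            "; trimming to T")
    s_max <- T_len
  }
  k_max <- floor(log(s_max / grid$s_min) / log(grid$sigma) + 1e-9)
  grid$s_min * grid$sigma^(0:k_max)
}

# Cells affected by the series boundaries: timescale s is unreliable within
# sqrt(2) * s years of either end. TRUE = masked.
coi_mask <- function(T_len, scales) {
  t_edge <- pmin(seq_len(T_len) - 1, T_len - seq_len(T_len))
  outer(t_edge, sqrt(2) * scales, `<`)
}

# Dense CWT operator: rows index (time, scale) pairs, columns index input
# time. W_vec = K %*% x, then dim(W) = c(T, S). Cached per (T, scales).
cwt_operator_cache <- new.env(parent = emptyenv())

cwt_operator <- function(T_len, scales, omega0) {
  key <- paste(T_len, omega0, paste(signif(scales, 12), collapse = ","),
               sep = "|")
  K <- cwt_operator_cache[[key]]
  if (!is.null(K)) return(K)
  u_minus_t <- outer(seq_len(T_len), seq_len(T_len), `-`)  # [t, u]
  blocks <- lapply(scales, function(s) {
    eta <- -u_minus_t / s   # (u - t)/s with u along columns
    s^(-0.5) * pi^(-0.25) * exp(-1i * omega0 * eta) * exp(-eta^2 / 2)
  })
  K <- do.call(rbind, blocks)  # (S*T) x T, scale-major blocks
  cwt_operator_cache[[key]] <- K
  K
}

#' Continuous Morlet wavelet transform of annual series
#'
#' Computes `W(t, s) = s^(-1/2) sum_u x(u) psi*((u - t)/s)` with the Morlet
#' mother wavelet `psi(eta) = pi^(-1/4) exp(i omega0 eta) exp(-eta^2/2)`
#' for every location of a field.  Cells within `sqrt(2) * s` of either
#' series end are flagged as inside the cone of influence and excluded
#' from all downstream averages.
#'
#' @param x numeric vector (one location) or [stfield] / matrix with
#'   locations in rows; series must be cleaned (see [clean_field]) and at
#'   least 20 years long.
#' @param grid a [scale_grid].
#' @return object of class `wavefield`: complex array
#'   `locations x times x timescales`, logical `coi` (times x timescales,
#'   `TRUE` = masked), `timescales`, `years`, `locations`, and the power
#'   normalisation applied (`"none"` here).
#' @export
morlet_cwt <- function(x, grid = scale_grid()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  v <- unclass(x)
  T_len <- ncol(v)
  stopifnot(T_len >= 20, !anyNA(v))
  scales <- grid_scales(grid, T_len)
  K <- cwt_operator(T_len, scales, grid$omega0)
  W <- K %*% t(v)                       # (S*T) x n
  coef <- array(NA_complex_, c(nrow(v), T_len, length(scales)))
  for (i in seq_len(nrow(v))) {
    coef[i, , ] <- matrix(W[, i], nrow = T_len)
  }
  structure(list(coef = coef,
                 coi = coi_mask(T_len, scales),
                 timescales = scales,
                 years = if (is_stfield(x)) attr(x, "years") else seq_len(T_len),
                 locations = if (is_stfield(x)) attr(x, "locations") else seq_len(nrow(v)),
                 omega0 = grid$omega0,
                 normalized = "none"),
            class = "wavefield")
}

#' @export
print.wavefield <- function(x, ...) {
  cat(sprintf("<wavefield> %d locations x %d times x %d timescales (%.3g..%.3g yr), normalized: %s\n",
              dim(x$coef)[1], dim(x$coef)[2], dim(x$coef)[3],
              min(x$timescales), max(x$timescales), x$normalized))
  invisible(x)
}

#' Power normalisation of a wavelet field
#'
#' `per_timescale` (used for mean fields) divides each location's
#' coefficients at each timescale by the square root of its mean squared
#' magnitude over non-cone times, so every (location, timescale) carries
#' unit mean power; this is what pins the time-averaged wavelet mean field
#' magnitude into (0, 1).  `global` (used for coherence and the Moran
#' decomposition) uses one denominator per location -- the mean over all
#' non-cone cells -- so relative power across timescales still informs the
#' statistic.  Timescales whose cells are all inside the cone are
#' normalised by their all-cell power (they never enter averages).
#'
#' @param wf a [wavefield].
#' @param mode `"per_timescale"` or `"global"`.
#' @return normalised [wavefield].
#' @export
normalize_power <- function(wf, mode = c("per_timescale", "global")) {
  mode <- match.arg(mode)
  if (wf$normalized != "none") {
    stop("wavefield is already normalized (", wf$normalized, ")")
  }
  open_cells <- !wf$coi
  n <- dim(wf$coef)[1]
  for (i in seq_len(n)) {
    Wi <- wf$coef[i, , ]
    p <- Mod(Wi)^2
    if (mode == "global") {
      denom <- sqrt(mean(p[open_cells]))
      if (denom == 0) {
        stop("zero wavelet power at location ", wf$locations[i])
      }
      wf$coef[i, , ] <- Wi / denom
    } else {
      open_per_s <- colSums(open_cells)
      ms <- ifelse(open_per_s > 0,
                   colSums(p * open_cells) / pmax(open_per_s, 1),
                   colMeans(p))
      if (any(ms == 0 & open_per_s > 0)) {
        bad <- which(ms == 0 & open_per_s > 0)[1]
        stop("zero wavelet power at location ", wf$locations[i],
             ", timescale ", signif(wf$timescales[bad], 4))
      }
      wf$coef[i, , ] <- Wi / rep(sqrt(pmax(ms, 1e-300)), each = dim(wf$coef)[2])
    }
  }
  wf$normalized <- mode
  wf
}

mean_field_struct <- function(values, wf, kind) {
  structure(list(values = values, coi = wf$coi, timescales = wf$timescales,
                 years = wf$years, kind = kind, n = dim(wf$coef)[1]),
            class = "meanfield")
}

#' @export
print.meanfield <- function(x, ...) {
  cat(sprintf("<meanfield:%s> %d times x %d timescales, n = %d locations\n",
              x$kind, nrow(x$values), ncol(x$values), x$n))
  invisible(x)
}

#' Wavelet mean field (WMF)
#'
#' The mean across locations of per-timescale power-normalised transforms.
#' Its magnitude is near 1 at times and timescales where oscillations have
#' both aligned phases and consistent magnitudes across locations, near 0
#' where they do not; the time-averaged magnitude at any timescale cannot
#' exceed 1.
#'
#' @param wf a [wavefield] over `n >= 2` locations (unnormalised or
#'   already `per_timescale`).
#' @return a `meanfield` of kind `"wmf"` (complex values; take `Mod()` for
#'   the magnitude surface).
#' @export
wmf <- function(wf) {
  stopifnot(inherits(wf, "wavefield"), dim(wf$coef)[1] >= 2)
  if (wf$normalized == "none") wf <- normalize_power(wf, "per_timescale")
  if (wf$normalized != "per_timescale") {
    stop("wmf needs per_timescale normalization, got ", wf$normalized)
  }
  mean_field_struct(apply(wf$coef, c(2, 3), mean), wf, "wmf")
}

#' Wavelet phasor mean field (WPMF)
#'
#' The mean across locations of unit-modulus wavelet phasors
#' `W / |W|`: pure phase synchrony, with magnitude between 0 (random
#' phases) and 1 (phase locking).  Cells where any location has a zero
#' coefficient are masked, not errored.
#'
#' @param wf a [wavefield] over `n >= 2` locations (raw coefficients; any
#'   prior normalisation cancels in the phasor).
#' @return a `meanfield` of kind `"wpmf"`.
#' @export
wpmf <- function(wf) {
  stopifnot(inherits(wf, "wavefield"), dim(wf$coef)[1] >= 2)
  m <- Mod(wf$coef)
  ph <- wf$coef / ifelse(m > 0, m, NA_real_)
  vals <- apply(ph, c(2, 3), mean)      # NA where any phasor undefined
  mf <- mean_field_struct(vals, wf, "wpmf")
  mf$coi <- mf$coi | is.na(vals)
  mf
}

#' Phase-synchrony significance threshold for the WPMF
#'
#' Monte-Carlo `(1 - p)` quantile of the magnitude of the mean of `n`
#' independent uniform unit phasors -- the null of unsynchronised phases.
#' Contours of the WPMF above this magnitude are significant at level `p`.
#' For large `n` the threshold approaches `sqrt(-log(p) / n)`.
#'
#' @param n number of locations (>= 2).
#' @param p significance level in (0, 1) (default 0.001).
#' @param n_draws Monte-Carlo draws (default 10000).
#' @param seed optional seed.
#' @return magnitude threshold in (0, 1).
#' @export
wpmf_threshold <- function(n, p = 0.001, n_draws = 10000, seed = NULL) {
  stopifnot(n >= 2)
  if (p <= 0 || p >= 1) stop("p must be inside (0, 1)")
  with_seed(seed, {
    th <- matrix(stats::runif(n * n_draws, 0, 2 * pi), n, n_draws)
    mags <- Mod(colMeans(exp(1i * th)))
    unname(stats::quantile(mags, 1 - p, type = 8))
  })
}

#' Time-averaged synchrony profile of a mean field
#'
#' Mean of the mean-field magnitude (or squared magnitude, the "mean
#' squared synchrony") over non-cone times at each timescale.  For a
#' wavelet mean field this time average cannot exceed 1.
#'
#' @param mf a `meanfield` (see [wmf], [wpmf]).
#' @param square average `|M|^2` instead of `|M|`.
#' @return numeric vector, one value per timescale (`NA` where a
#'   timescale lies fully inside the cone of influence).
#' @export
timescale_profile <- function(mf, square = FALSE) {
  m <- Mod(mf$values)
  if (square) m <- m^2
  m[mf$coi] <- NA
  colMeans(m, na.rm = TRUE)
}
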