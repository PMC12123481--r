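#' Rectangularize a spatio-temporal field
#'
#' Wavelet analysis needs complete, equal-length series.  Three rules are
#' applied in order: (1) drop locations with fewer than `min_years`
#' non-missing years; (2) drop years in which fewer than `min_locations`
#' of the remaining locations have data; (3) drop locations still missing
#' any retained year.  The result is asserted complete.
#'
#' @param field an [stfield], possibly with `NA` entries.
#' @param min_years minimum series length per location (default 20).
#' @param min_locations minimum locations per retained year (default 10).
#' @return complete [stfield]; attribute `drops` lists dropped locations
#'   and years per rule.
#' @export
rectangularize <- function(field, min_years = 20, min_locations = 10) {
  stopifnot(is_stfield(field), nrow(field) > 0, ncol(field) > 0)
  v <- unclass(field)
  keep_loc <- rowSums(!is.na(v)) >= min_years
  if (!any(keep_loc)) {
    stop("rectangularize: the >= ", min_years,
         "-year rule removed every location")
  }
  v1 <- v[keep_loc, , drop = FALSE]
  keep_yr <- colSums(!is.na(v1)) >= min_locations
  if (!any(keep_yr)) {
    stop("rectangularize: the >= ", min_locations,
         "-locations-per-year rule removed every year")
  }
  v2 <- v1[, keep_yr, drop = FALSE]
  keep_loc2 <- rowSums(is.na(v2)) == 0L
  if (!any(keep_loc2)) {
    stop("rectangularize: removing locations with residual gaps emptied ",
         "the field")
  }
  v3 <- v2[keep_loc2, , drop = FALSE]
  stopifnot(!anyNA(v3))
  rows <- which(keep_loc)[keep_loc2]
  out <- restfield(v3, field, rows = rows, cols = which(keep_yr))
  attr(out, "drops") <- list(
    locations_short = attr(field, "locations")[!keep_loc],
    years_sparse = attr(field, "years")[!keep_yr],
    locations_gappy = attr(field, "locations")[which(keep_loc)[!keep_loc2]])
  out
}

# Box-Cox profile log-likelihood at lambda for shifted data xs > 0.
boxcox_loglik <- function(lambda, xs, lx_sum) {
  y <- if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
  n <- length(xs)
  s2 <- stats::var(y) * (n - 1) / n
  -n / 2 * log(s2) + (lambda - 1) * lx_sum
}

#' Box-Cox normalisation of one annual series
#'
#' A shift `c = 1 - min(x)` is applied when the series has non-positive
#' values (so the shifted minimum is exactly 1); the exponent `lambda`
#' maximises the profile log-likelihood over `[-5, 5]` on a 0.01 grid with
#' local refinement; the transform is `((x + c)^lambda - 1) / lambda`
#' (`log(x + c)` at `lambda = 0`).
#'
#' @param x numeric series, length >= 20, non-constant.
#' @return list: `y` transformed series, `lambda`, `shift`.
#' @export
boxcox_transform <- function(x) {
  stopifnot(is.numeric(x), !anyNA(x))
  if (length(x) < 20) {
    stop("boxcox_transform needs a series of at least 20 years, got ",
         length(x))
  }
  if (max(x) == min(x)) stop("constant series: nothing to normalise")
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  lx <- log(xs)
  lx_sum <- sum(lx)
  n <- length(xs)
  grid <- seq(-5, 5, by = 0.01)
  # vectorised profile likelihood over the whole grid
  M <- exp(outer(lx, grid))             # xs^lambda, n x n_grid
  Y <- sweep(M - 1, 2, grid, `/`)
  zero <- abs(grid) < 1e-12
  if (any(zero)) Y[, zero] <- lx
  s2 <- colMeans(Y^2) - colMeans(Y)^2
  ll <- -n / 2 * log(s2) + (grid - 1) * lx_sum
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(boxcox_loglik, c(lo, hi), xs = xs, lx_sum = lx_sum,
                         maximum = TRUE, tol = 1e-6)
  lambda <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  y <- if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
  list(y = y, lambda = lambda, shift = shift)
}

#' Normalise a rectangular field for wavelet analysis
#'
#' Applies, per location and in this order: Box-Cox normalisation, ordinary
#' least-squares linear detrend on the year index, demeaning, and scaling
#' to unit variance (n - 1 denominator).  Output rows have mean 0 and
#' variance 1 to within 1e-8.
#'
#' @param field complete [stfield] (see [rectangularize]).
#' @return list: `field` cleaned [stfield]; `params` data.frame with one
#'   row per location (`lambda`, `shift`, `slope`, `intercept`, `scale`).
#' @export
clean_field <- function(field) {
  stopifnot(is_stfield(field), !anyNA(field))
  v <- unclass(field)
  tt <- seq_len(ncol(v))
  out <- v
  params <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    # a series that is an exact linear function of time carries no signal
    # once detrended; reject before Box-Cox bends it
    raw_fit <- stats::lm.fit(cbind(1, tt), v[i, ])
    if (stats::sd(raw_fit$residuals) < 1e-10 * max(stats::sd(v[i, ]), 1e-300)) {
      stop("location ", attr(field, "locations")[i],
           " has no variance after detrending")
    }
    bc <- boxcox_transform(v[i, ])
    fit <- stats::lm.fit(cbind(1, tt), bc$y)
    resid <- bc$y - cbind(1, tt) %*% fit$coefficients
    resid <- resid - mean(resid)
    s <- stats::sd(resid)
    if (s < 1e-12) {
      stop("location ", attr(field, "locations")[i],
           " has no variance after detrending")
    }
    out[i, ] <- resid / s
    params[[i]] <- data.frame(
      location = as.character(attr(field, "locations")[i]),
      lambda = bc$lambda, shift = bc$shift,
      intercept = fit$coefficients[1], slope = fit$coefficients[2],
      scale = s)
  }
  list(field = restfield(out, field), params = do.call(rbind, params))
}
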