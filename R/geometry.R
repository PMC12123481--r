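#' Regular planar grid container
#'
#' Values on a regular km grid; `values[i, j]` sits at `(x[i], y[j])` (cell
#' centers).  Used for climate rasters and interpolated density surfaces.
#'
#' @param values numeric matrix, `length(x)` rows by `length(y)` columns.
#' @param x,y cell-center coordinate vectors, km, evenly spaced.
#' @param cell_km cell size, km.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, x, y, cell_km) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(x), ncol(values) == length(y),
            cell_km > 0)
  structure(list(values = values, x = x, y = y, cell_km = cell_km),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells of %.3g km, x:[%.4g, %.4g] y:[%.4g, %.4g]\n",
              length(x$x), length(x$y), x$cell_km,
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Fan of radial transects
#'
#' Evenly spaced bearings radiating from a fixed origin; bearings are
#' degrees clockwise from north.  A lat/lon origin is accepted and other
#' lat/lon points can be projected with [project_local()].
#'
#' @param origin numeric `c(x_km, y_km)` planar origin (default `c(0, 0)`).
#' @param bearings strictly increasing bearings, degrees, constant step.
#' @param region region label per bearing (length 1 recycled).
#' @param origin_latlon optional `c(lat, lon)` recorded for projecting
#'   geographic inputs.
#' @return object of class `transect_fan`.
#' @export
transect_fan <- function(origin = c(0, 0), bearings, region = "ALL",
                         origin_latlon = NULL) {
  stopifnot(length(origin) == 2, length(bearings) >= 1)
  if (length(bearings) > 1) {
    st <- diff(bearings)
    if (any(st <= 0)) stop("bearings must be strictly increasing")
    if (max(abs(st - st[1])) > 1e-8) stop("bearing step must be constant")
  }
  if (length(region) == 1L) region <- rep(region, length(bearings))
  stopifnot(length(region) == length(bearings))
  structure(list(origin = as.numeric(origin), bearings = as.numeric(bearings),
                 region = region, origin_latlon = origin_latlon),
            class = "transect_fan")
}

#' Local equirectangular projection
#'
#' Projects lat/lon to planar km about a reference point: one degree of
#' latitude is 111.32 km, one degree of longitude is scaled by
#' `cos(lat_ref)`.  Adequate over the few-hundred-km extent of a transect
#' fan; it replaces GIS projection steps.
#'
#' @param lat,lon coordinates in degrees.
#' @param ref `c(lat, lon)` reference (projected to `(0, 0)`).
#' @return data.frame with `x_km` (east) and `y_km` (north).
#' @export
project_local <- function(lat, lon, ref) {
  km_deg <- 111.32
  data.frame(x_km = (lon - ref[2]) * km_deg * cos(ref[1] * pi / 180),
             y_km = (lat - ref[1]) * km_deg)
}

#' Remove traps near suppression treatments
#'
#' Drops every trap record within `radius` km (closed ball: the boundary is
#' removed too) of any treatment site.
#'
#' @param traps data.frame with `x_km`, `y_km` columns (a yearly trap
#'   table).
#' @param treatment_sites data.frame with `x_km`, `y_km` of treated
#'   locations; `NULL` or zero rows leaves `traps` untouched.
#' @param radius exclusion radius, km (default 1.5).
#' @return filtered `traps`; attribute `n_removed` records the count.
#' @export
mask_treatments <- function(traps, treatment_sites, radius = 1.5) {
  stopifnot(radius >= 0)
  if (is.null(treatment_sites) || nrow(treatment_sites) == 0L) {
    attr(traps, "n_removed") <- 0L
    return(traps)
  }
  near <- rep(FALSE, nrow(traps))
  for (k in seq_len(nrow(treatment_sites))) {
    d2 <- (traps$x_km - treatment_sites$x_km[k])^2 +
      (traps$y_km - treatment_sites$y_km[k])^2
    near <- near | d2 <= radius^2
  }
  out <- traps[!near, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("all traps fall within ", radius, " km of a treatment site; ",
         "year unusable")
  }
  attr(out, "n_removed") <- sum(near)
  out
}

#' Indicator interpolation of trap catches
#'
#' Converts catches to the indicator `I = 1{catch >= threshold}` and
#' interpolates the exceedance probability `P` on a regular grid: ordinary
#' kriging of the indicator with an exponential variogram fitted by
#' weighted least squares (default), or inverse-distance-squared weighting.
#' `P` is clipped to `[0, 1]`.  The 0.5 level of this surface is the
#' operational range-edge isocline (the density isocline at the threshold
#' catch maps to exceedance probability one half).
#'
#' @param traps data.frame with `x_km`, `y_km`, `catch` (one year, already
#'   treatment-masked).
#' @param threshold_catch isocline threshold, moths/trap (default 10).
#' @param cell_km grid resolution, km (default 1).
#' @param method `"kriging"` or `"idw"`.
#' @param n_nn search neighbourhood size (nearest traps; default 16).
#' @param pad_km margin added around the trap bounding box.
#' @return object of class `density_surface`: a [raster_grid] of `P` plus
#'   `year`, `threshold_catch`, `method` and the fitted variogram.
#' @export
fit_indicator_surface <- function(traps, threshold_catch = 10, cell_km = 1,
                                  method = c("kriging", "idw"), n_nn = 16,
                                  pad_km = 2 * cell_km) {
  method <- match.arg(method)
  stopifnot(nrow(traps) >= 10)
  I <- as.numeric(traps$catch >= threshold_catch)
  if (all(I == 1)) {
    stop("degenerate surface: every trap is at or above the threshold; ",
         "treat the area as fully occupied")
  }
  if (all(I == 0)) {
    stop("degenerate surface: no trap reaches the threshold; ",
         "treat the area as fully unoccupied")
  }
  gx <- seq(floor((min(traps$x_km) - pad_km) / cell_km),
            ceiling((max(traps$x_km) + pad_km) / cell_km)) * cell_km
  gy <- seq(floor((min(traps$y_km) - pad_km) / cell_km),
            ceiling((max(traps$y_km) + pad_km) / cell_km)) * cell_km
  pts <- expand.grid(x = gx, y = gy)
  vg <- NULL
  if (method == "kriging") {
    emp <- empirical_variogram(traps$x_km, traps$y_km, I)
    vg <- fit_variogram_exponential(emp)
    P <- krige_predict(traps$x_km, traps$y_km, I, pts$x, pts$y, vg,
                       n_nn = n_nn)
  } else {
    P <- idw_predict(traps$x_km, traps$y_km, I, pts$x, pts$y, n_nn = n_nn)
  }
  P <- pmin(pmax(P, 0), 1)
  out <- raster_grid(matrix(P, length(gx), length(gy)), gx, gy, cell_km)
  out$year <- if ("year" %in% names(traps)) traps$year[1] else NA_integer_
  out$threshold_catch <- threshold_catch
  out$method <- method
  out$variogram <- vg
  class(out) <- c("density_surface", class(out))
  out
}

# Bilinear interpolation on a raster_grid; NA outside the grid hull.
bilinear <- function(grid, px, py) {
  x <- grid$x; y <- grid$y
  ix <- findInterval(px, x)
  iy <- findInterval(py, y)
  ok <- ix >= 1 & ix < length(x) & iy >= 1 & iy < length(y)
  # points exactly on the outer max edges are still inside
  ix[px == x[length(x)]] <- length(x) - 1L
  iy[py == y[length(y)]] <- length(y) - 1L
  ok <- ok | (px == x[length(x)] & iy >= 1 & iy < length(y)) |
    (py == y[length(y)] & ix >= 1 & ix < length(x))
  out <- rep(NA_real_, length(px))
  if (!any(ok)) return(out)
  i <- ix[ok]; j <- iy[ok]
  tx <- (px[ok] - x[i]) / (x[i + 1] - x[i])
  ty <- (py[ok] - y[j]) / (y[j + 1] - y[j])
  v <- grid$values
  n <- nrow(v)
  f00 <- v[cbind(i, j)]; f10 <- v[cbind(i + 1, j)]
  f01 <- v[cbind(i, j + 1)]; f11 <- v[cbind(i + 1, j + 1)]
  out[ok] <- (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
  out
}

#' Isocline crossings along a transect fan
#'
#' Samples the interpolated exceedance surface along each bearing at
#' `step_km` and locates the outermost transition from `P >= level` to
#' `P < level`; the crossing distance is linearly interpolated between the
#' bracketing samples.  A transect is flagged missing when no transition
#' exists, or when the ray leaves the surface while still at `P >= level`
#' (the edge cannot be bracketed).  With occupied islands beyond the front,
#' the outermost transition -- the island's outer edge -- is returned and a
#' multiple-transition count is recorded.
#'
#' @param surface a `density_surface` (see [fit_indicator_surface]).
#' @param fan a [transect_fan].
#' @param level probability level of the isocline (default 0.5).
#' @param step_km ray sampling step (default 0.25).
#' @param r_max maximum ray length; defaults to the grid's far corner.
#' @return data.frame (class `crossing_set`): `bearing`, `year`,
#'   `distance_km`, `missing`, `n_transitions`.
#' @export
transect_crossings <- function(surface, fan, level = 0.5, step_km = 0.25,
                               r_max = NULL) {
  if (is.null(r_max)) {
    r_max <- sqrt(max((surface$x - fan$origin[1])^2) +
                  max((surface$y - fan$origin[2])^2))
  }
  r <- seq(step_km, r_max, by = step_km)
  out <- data.frame(bearing = fan$bearings,
                    year = surface$year %||% NA_integer_,
                    distance_km = NA_real_,
                    missing = TRUE, n_transitions = 0L)
  for (k in seq_along(fan$bearings)) {
    th <- fan$bearings[k] * pi / 180
    P <- bilinear(surface, fan$origin[1] + r * sin(th),
                  fan$origin[2] + r * cos(th))
    ok <- which(!is.na(P))
    if (!length(ok)) next
    Pv <- P[ok]; rv <- r[ok]
    if (Pv[length(Pv)] >= level) next      # leaves surface still occupied
    trans <- which(Pv[-length(Pv)] >= level & Pv[-1] < level)
    out$n_transitions[k] <- length(trans)
    if (!length(trans)) next
    i <- trans[length(trans)]
    frac <- (Pv[i] - level) / (Pv[i] - Pv[i + 1])
    out$distance_km[k] <- rv[i] + frac * (rv[i + 1] - rv[i])
    out$missing[k] <- FALSE
  }
  class(out) <- c("crossing_set", class(out))
  out
}

#' Annual spread rates from yearly isocline crossings
#'
#' Boundary displacement: the spread rate of transect `theta` over year
#' pair `t -> t+1` is the difference of consecutive crossing distances,
#' km/yr.  Negative values are range contraction.  Missing if either
#' crossing is missing.
#'
#' @param crossings either a list of yearly `crossing_set` data.frames or
#'   one data.frame stacking them.
#' @param region optional region label per bearing (length 1 recycled).
#' @return an [stfield] of spread rates, bearings x year-pairs; column
#'   `t` holds the displacement from year `t` to `t + 1`.
#' @export
spread_rates <- function(crossings, region = "ALL") {
  if (is.data.frame(crossings)) {
    crossings <- split(crossings, crossings$year)
  }
  years <- as.numeric(vapply(crossings, function(cs) cs$year[1], 0))
  o <- order(years)
  crossings <- crossings[o]; years <- years[o]
  if (length(years) < 2) stop("need crossings for at least 2 years")
  bearings <- crossings[[1]]$bearing
  D <- vapply(crossings, function(cs) {
    stopifnot(identical(cs$bearing, bearings))
    ifelse(cs$missing, NA_real_, cs$distance_km)
  }, numeric(length(bearings)))
  D <- matrix(D, nrow = length(bearings))
  rates <- D[, -1, drop = FALSE] - D[, -ncol(D), drop = FALSE]
  stfield(rates, locations = bearings, years = years[-length(years)],
          region = region)
}

#' Mean of raster cells inside a circular buffer
#'
#' Averages all cells whose centers fall within the closed disc of the
#' given diameter around `center`.
#'
#' @param raster a [raster_grid].
#' @param center `c(x_km, y_km)`.
#' @param diameter buffer diameter, km (> 0).
#' @return scalar mean; attribute `n_cells` counts contributing cells.
#' @export
buffer_mean <- function(raster, center, diameter) {
  stopifnot(diameter > 0)
  r2 <- (diameter / 2)^2
  dx2 <- (raster$x - center[1])^2
  dy2 <- (raster$y - center[2])^2
  inside <- outer(dx2, dy2, `+`) <= r2
  n <- sum(inside)
  if (n == 0L) {
    stop("buffer of diameter ", diameter, " km at (", center[1], ", ",
         center[2], ") contains no raster cell centers")
  }
  structure(mean(raster$values[inside]), n_cells = n)
}

#' Region-level buffer diameter from annual displacements
#'
#' The climate-extraction buffer diameter for a region is the mean over the
#' region's transects and years of the annual displacement of the range
#' edge.  By default the signed mean (contractions offset expansions); an
#' absolute-value variant is available.
#'
#' @param spread an [stfield] of annual displacements (km/yr).
#' @param region region label to use.
#' @param method `"signed"` (default) or `"absolute"`.
#' @return diameter, km.
#' @export
region_buffer_diameter <- function(spread, region,
                                   method = c("signed", "absolute")) {
  method <- match.arg(method)
  sub <- stfield_region(spread, region)
  v <- as.vector(unclass(sub))
  v <- v[!is.na(v)]
  if (!length(v)) stop("region ", region, " has no non-missing displacements")
  if (method == "absolute") mean(abs(v)) else mean(v)
}
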