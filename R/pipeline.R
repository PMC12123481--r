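#' Analysis configuration
#'
#' Bundles the knobs of the end-to-end workflow.  Defaults follow the
#' standard protocol: a 10 moths/trap isocline threshold, short `[2, 4)`
#' and long `[4, Inf)` year timescale bands, 2000 surrogates, coherence
#' significance at `p < 0.1` (the surrogate test is conservative) and
#' phase-synchrony significance at `p < 0.001`.
#'
#' @param regions optional data.frame (`label`, `bearing_lo`, `bearing_hi`)
#'   mapping bearings to region labels; `NULL` uses the region labels
#'   already on the input fields.
#' @param threshold_catch isocline threshold, moths/trap.
#' @param bands list of [band()] objects.
#' @param n_surrog surrogates per coherence test.
#' @param alpha_coherence coherence significance level.
#' @param alpha_wpmf phase-synchrony significance level.
#' @param min_years,min_locations rectangularisation rules.
#' @param grid a [scale_grid].
#' @param seed master seed for surrogate draws.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(regions = NULL, threshold_catch = 10,
                            bands = list(band("short"), band("long")),
                            n_surrog = 2000, alpha_coherence = 0.1,
                            alpha_wpmf = 0.001, min_years = 20,
                            min_locations = 10, grid = scale_grid(),
                            seed = 1L) {
  stopifnot(alpha_coherence > 0, alpha_coherence < 1,
            alpha_wpmf > 0, alpha_wpmf < 1)
  structure(as.list(environment()), class = "analysis_config")
}

#' Seasonal means of a monthly climate index
#'
#' Converts a monthly teleconnection index (NAO/MEI/PDO-shaped) to annual
#' seasonal means.  The winter attributed to analysis year `t` is
#' December of `t - 1` through February of `t` -- the winter preceding the
#' summer trap-catch season.  The larval-period mean averages the months
#' that overlap the supplied larval date range for each region and year
#' (any month containing at least one day of the range counts).
#'
#' @param index data.frame with columns `year`, `month`, `value`,
#'   contiguous monthly coverage.
#' @param window `"winter"` or `"larval"`.
#' @param years analysis years wanted.
#' @param larval_windows data.frame (`region`, `year`, `start_date`,
#'   `end_date`, dates as `"YYYY-MM-DD"`), required for `window =
#'   "larval"`.
#' @return for `"winter"`, a data.frame (`year`, `value`); for
#'   `"larval"`, a named list of such data.frames, one per region.
#' @export
seasonal_index_means <- function(index, window = c("winter", "larval"),
                                 years, larval_windows = NULL) {
  window <- match.arg(window)
  stopifnot(all(c("year", "month", "value") %in% names(index)))
  lookup <- function(yr, mo) {
    v <- index$value[index$year == yr & index$month == mo]
    if (length(v) != 1L) NA_real_ else v
  }
  if (window == "winter") {
    vals <- vapply(years, function(t) {
      v <- c(lookup(t - 1, 12), lookup(t, 1), lookup(t, 2))
      if (anyNA(v)) {
        miss <- c(paste0(t - 1, "-12"), paste0(t, "-01"),
                  paste0(t, "-02"))[is.na(v)]
        stop("missing index months: ", paste(miss, collapse = ", "))
      }
      mean(v)
    }, 0)
    return(data.frame(year = years, value = vals))
  }
  stopifnot(!is.null(larval_windows))
  out <- list()
  for (rg in unique(larval_windows$region)) {
    lw <- larval_windows[larval_windows$region == rg, ]
    vals <- vapply(years, function(t) {
      row <- lw[lw$year == t, ]
      if (nrow(row) != 1L) stop("no larval window for region ", rg,
                                ", year ", t)
      m1 <- as.integer(format(as.Date(row$start_date), "%m"))
      m2 <- as.integer(format(as.Date(row$end_date), "%m"))
      if (m2 < m1) stop("larval window may not wrap the year end")
      v <- vapply(m1:m2, function(mo) lookup(t, mo), 0)
      if (anyNA(v)) {
        stop("missing index months: ",
             paste(paste0(t, "-", sprintf("%02d", (m1:m2)[is.na(v)])),
                   collapse = ", "))
      }
      mean(v)
    }, 0)
    out[[rg]] <- data.frame(year = years, value = vals)
  }
  out
}

# Derive spread and per-variable climate stfields from trap-level inputs.
trap_stage <- function(inputs, config) {
  traps <- inputs$traps
  fan <- inputs$fan
  crossings <- lapply(split(traps, traps$year), function(tt) {
    tt <- mask_treatments(tt, inputs$treatment_sites)
    surf <- fit_indicator_surface(tt, threshold_catch = config$threshold_catch)
    transect_crossings(surf, fan)
  })
  spread <- spread_rates(crossings, region = fan$region)
  years_sp <- attr(spread, "years")
  climate <- list()
  for (nm in names(inputs$climate_rasters %||% list())) {
    rasters <- inputs$climate_rasters[[nm]]
    vals <- matrix(NA_real_, length(fan$bearings), length(years_sp))
    for (j in seq_along(years_sp)) {
      yr <- years_sp[j]
      cs <- crossings[[as.character(yr)]]
      ras <- rasters[[as.character(yr)]] %||% rasters[[j]]
      for (k in seq_along(fan$bearings)) {
        if (cs$missing[k]) next
        th <- fan$bearings[k] * pi / 180
        ctr <- fan$origin + cs$distance_km[k] * c(sin(th), cos(th))
        dia <- tryCatch(abs(region_buffer_diameter(spread, fan$region[k])),
                        error = function(e) NA_real_)
        if (!is.finite(dia) || dia <= 0) dia <- 2 * ras$cell_km
        vals[k, j] <- tryCatch(as.numeric(buffer_mean(ras, ctr, dia)),
                               error = function(e) NA_real_)
      }
    }
    climate[[nm]] <- stfield(vals, locations = fan$bearings,
                             years = years_sp, region = fan$region)
  }
  list(spread = spread, climate = climate, crossings = crossings)
}

#' Run the full synchrony analysis
#'
#' Orchestrates, per region: (optional) trap-level geometry into spread
#' rates and buffer-averaged climate; rectangularisation; cleaning; the
#' wavelet mean field and phasor mean field with its significance
#' threshold; band-level coherence of spread against every climate
#' variable; the Moran decomposition for pairs passing the significance
#' level; and coherence of those climate variables against teleconnection
#' index series.  Deterministic given the config seed.
#'
#' @param config an [analysis_config()].
#' @param inputs list.  Series mode: `spread` (raw [stfield]) and
#'   `climate` (named list of raw [stfield]s).  Trap mode: `traps`
#'   (data.frame `year`, `x_km`, `y_km`, `catch`, `treated`), `fan`
#'   ([transect_fan]), optional `treatment_sites`, and `climate_rasters`
#'   (named list: variable -> list of yearly [raster_grid]s).  Either
#'   mode: optional `indices`, named list of annual series data.frames
#'   (`year`, `value`).
#' @return list: `table` (tidy data.frame, one row per test:
#'   `region`, `band`, `response`, `predictor`, `p`, `theta_bar`,
#'   `pct_explained`, `pct_cross`, `significant`), `mean_fields` (per
#'   region: `wmf`, `wpmf`, `wpmf_threshold`), `cleaned` fields and
#'   `params`.
#' @export
run_analysis <- function(config, inputs) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(inputs$traps)) {
    staged <- trap_stage(inputs, config)
    spread_raw <- staged$spread
    climate_raw <- staged$climate
  } else {
    spread_raw <- inputs$spread
    climate_raw <- inputs$climate %||% list()
  }
  if (!is.null(config$regions)) {
    reg <- rep(NA_character_, nrow(spread_raw))
    b <- as.numeric(attr(spread_raw, "locations"))
    for (i in seq_len(nrow(config$regions))) {
      hit <- b >= config$regions$bearing_lo[i] &
        b < config$regions$bearing_hi[i]
      reg[hit] <- config$regions$label[i]
    }
    attr(spread_raw, "region") <- reg
    climate_raw <- lapply(climate_raw, function(f) {
      attr(f, "region") <- reg; f
    })
  }
  rows <- list()
  mean_fields <- list()
  cleaned <- list()
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    (config$seed * 1000L + seed_i) %% .Machine$integer.max
  }
  for (rg in unique(attr(spread_raw, "region"))) {
    if (is.na(rg)) next
    sp <- rectangularize(stfield_region(spread_raw, rg),
                         config$min_years, config$min_locations)
    sp_clean <- clean_field(sp)
    wf <- morlet_cwt(sp_clean$field, config$grid)
    n_loc <- nrow(sp)
    mean_fields[[rg]] <- list(
      wmf = wmf(wf), wpmf = wpmf(wf),
      wpmf_threshold = wpmf_threshold(n_loc, config$alpha_wpmf,
                                      seed = next_seed()))
    cleaned[[rg]] <- list(spread = sp_clean)
    sig_climate <- character(0)
    for (nm in names(climate_raw)) {
      cl <- tryCatch(
        rectangularize(stfield_region(climate_raw[[nm]], rg),
                       config$min_years, config$min_locations),
        error = function(e) NULL)
      if (is.null(cl)) next
      locs <- intersect(rownames(sp), rownames(cl))
      yrs <- intersect(colnames(sp), colnames(cl))
      if (length(locs) < config$min_locations ||
          length(yrs) < config$min_years) next
      spa <- clean_field(restfield(unclass(sp)[locs, yrs], sp,
                                   match(locs, rownames(sp)),
                                   match(yrs, colnames(sp))))$field
      cla <- clean_field(restfield(unclass(cl)[locs, yrs], cl,
                                   match(locs, rownames(cl)),
                                   match(yrs, colnames(cl))))$field
      cleaned[[rg]][[nm]] <- cla
      for (bd in config$bands) {
        ct <- band_test(spa, cla, bd, n_surrog = config$n_surrog,
                        seed = next_seed(), grid = config$grid)
        sig <- ct$p < config$alpha_coherence
        pct <- c(NA_real_, NA_real_)
        if (sig) {
          md <- moran_decompose(spa, cla, bd, config$grid)
          pct <- c(md$pct_explained, md$pct_cross)
          sig_climate <- union(sig_climate, nm)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, band = sprintf("%g-%g", bd$lower, bd$upper),
          response = "spread", predictor = nm, p = ct$p,
          theta_bar = ct$theta_bar, pct_explained = pct[1],
          pct_cross = pct[2], significant = sig)
      }
    }
    for (nm in sig_climate) {
      for (ix in names(inputs$indices %||% list())) {
        for (bd in config$bands) {
          ct <- tryCatch(
            index_band_coherence(cleaned[[rg]][[nm]], inputs$indices[[ix]],
                                 bd, n_surrog = config$n_surrog,
                                 seed = next_seed(), grid = config$grid),
            error = function(e) NULL)
          if (is.null(ct)) next
          sig <- ct$p < config$alpha_coherence
          rows[[length(rows) + 1L]] <- data.frame(
            region = rg, band = sprintf("%g-%g", bd$lower, bd$upper),
            response = nm, predictor = ix, p = ct$p,
            theta_bar = if (sig) ct$theta_bar else NA_real_,
            pct_explained = NA_real_, pct_cross = NA_real_,
            significant = sig)
        }
      }
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(region = character(), band = character(),
                    response = character(), predictor = character(),
                    p = numeric(), theta_bar = numeric(),
                    pct_explained = numeric(), pct_cross = numeric(),
                    significant = logical()),
       mean_fields = mean_fields, cleaned = cleaned)
}
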