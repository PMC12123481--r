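#' Timescale band
#'
#' Half-open interval of timescales `[lower, upper)`, years.  The standard
#' bands split at 4 years: `"short"` is `[2, 4)` (cycles that are
#' negatively lag-1 autocorrelated at annual sampling) and `"long"` is
#' `[4, Inf)`.
#'
#' @param label `"short"`, `"long"`, or `"custom"`.
#' @param lower,upper band limits in years (needed for `"custom"`; `upper`
#'   may be `Inf`).
#' @return object of class `band`.
#' @export
band <- function(label = c("short", "long", "custom"), lower = NULL,
                 upper = NULL) {
  label <- match.arg(label)
  if (label == "short") { lower <- lower %||% 2; upper <- upper %||% 4 }
  if (label == "long") { lower <- lower %||% 4; upper <- upper %||% Inf }
  if (is.null(lower) || is.null(upper)) {
    stop("custom band needs explicit lower and upper limits")
  }
  stopifnot(lower < upper)
  structure(list(label = label, lower = lower, upper = upper),
            class = "band")
}

band_scale_idx <- function(bd, timescales, open_count = NULL) {
  idx <- which(timescales >= bd$lower & timescales < bd$upper)
  if (!is.null(open_count)) idx <- idx[open_count[idx] > 0]
  if (!length(idx)) {
    stop(sprintf("band [%s, %s) contains no usable grid timescales",
                 bd$lower, bd$upper))
  }
  idx
}

# ---- coherence core -------------------------------------------------------

# Precomputed machinery for repeated coherence evaluations against a fixed
# predictor: the quadratic form giving each real series' global open-cell
# wavelet power, and the band-restricted CWT rows for the numerator.
coh_engine <- function(T_len, scales, omega0, coi, band_idx) {
  K <- cwt_operator(T_len, scales, omega0)
  open_vec <- as.vector(!coi)
  Ko <- K[open_vec, , drop = FALSE]
  Q <- crossprod(Re(Ko)) + crossprod(Im(Ko))   # T x T real
  cell_scale <- rep(seq_along(scales), each = T_len)
  brows <- which(open_vec & cell_scale %in% band_idx)
  aggb <- t(vapply(band_idx, function(s) {
    as.numeric(cell_scale[brows] == s)
  }, numeric(length(brows))))
  list(K = K, Q = Q, n_open = sum(open_vec), brows = brows, aggb = aggb,
       Kb = K[brows, , drop = FALSE],
       n_open_band = colSums(!coi)[band_idx])
}

# Band-restricted per-timescale coherence of C = n_loc * n_rep real series
# (columns of X, location index fastest) against fixed conjugated,
# globally-normalised predictor band cells conj_yb ((n_band_cells) x n_loc).
# Returns length(band_idx) x n_rep complex matrix.
coh_band <- function(eng, X, conj_yb, n_loc) {
  den2 <- colSums(X * (eng$Q %*% X)) / eng$n_open
  if (any(den2 == 0)) stop("zero wavelet power in a response location")
  n_rep <- ncol(X) / n_loc
  Wb <- eng$Kb %*% X
  P <- Wb * conj_yb[, rep.int(seq_len(n_loc), n_rep)]
  num <- eng$aggb %*% P                 # S_band x C
  num <- num / rep(sqrt(den2), each = nrow(num))
  dim(num) <- c(nrow(eng$aggb), n_loc, n_rep)
  colSums(aperm(num, c(2, 1, 3))) / (n_loc * eng$n_open_band)
}

#' Spatial wavelet coherence between two fields
#'
#' The per-timescale mean, over locations and non-cone times, of
#' `Wx * Conj(Wy)` with both transforms globally power-normalised.  The
#' modulus measures how consistent the two variables' oscillations are
#' across space and time at that timescale; the argument is their mean
#' phase difference (positive: the response `x` leads the predictor `y`).
#'
#' With `global` normalisation (the default, used by [band_test]) the
#' relative power across timescales informs the statistic, so the modulus
#' at a power-dominant timescale may exceed 1; with `per_timescale`
#' normalisation every timescale carries unit power, the modulus is
#' bounded by 1 and self-coherence is exactly 1 at every timescale.
#'
#' @param x,y [wavefield]s on identical locations, years and timescales
#'   (unnormalised, or both already normalised the same way).
#' @param norm normalisation applied to unnormalised inputs: `"global"`
#'   (default) or `"per_timescale"`.
#' @return complex vector of coherences, one per timescale (`NA` at
#'   timescales fully inside the cone of influence).
#' @export
spatial_coherence <- function(x, y, norm = c("global", "per_timescale")) {
  norm <- match.arg(norm)
  stopifnot(inherits(x, "wavefield"), inherits(y, "wavefield"))
  if (!isTRUE(all.equal(x$timescales, y$timescales)) ||
      dim(x$coef)[1] != dim(y$coef)[1] || dim(x$coef)[2] != dim(y$coef)[2]) {
    stop("wavefields do not share locations, years and timescale grid")
  }
  if (x$normalized == "none") x <- normalize_power(x, norm)
  if (y$normalized == "none") y <- normalize_power(y, norm)
  if (x$normalized != y$normalized) {
    stop("x and y must share one normalisation, got ", x$normalized,
         " and ", y$normalized)
  }
  n <- dim(x$coef)[1]; T_len <- dim(x$coef)[2]; S <- dim(x$coef)[3]
  open <- !x$coi
  n_open_s <- colSums(open)
  cross <- x$coef * Conj(y$coef)
  out <- complex(S)
  for (s in seq_len(S)) {
    if (n_open_s[s] == 0) { out[s] <- NA_complex_; next }
    out[s] <- mean(cross[, open[, s], s])
  }
  out
}

# ---- surrogates -----------------------------------------------------------

#' Synchrony-preserving Fourier surrogates
#'
#' Phase-randomised copies of a complete, cleaned field, forming the null
#' of "no coherence with anything external, same autocorrelation and same
#' spatial synchrony".  The `fft` method multiplies every location's
#' discrete Fourier transform by one common random unit phase per
#' frequency (conjugate-symmetric, DC and Nyquist untouched), which
#' preserves each location's periodogram exactly and every cross-location
#' cross-spectrum, hence the field's own synchrony and autocorrelation.
#' With `sync_preserving = FALSE` each location gets independent phases.
#' `aaft` additionally rank-remaps each surrogate row onto the original
#' row's values (amplitude adjustment).
#'
#' @param field complete [stfield] (or plain matrix, locations x years).
#' @param n_surrog number of surrogates (default 2000).
#' @param method `"fft"` or `"aaft"`.
#' @param sync_preserving share one phase vector across locations
#'   (default `TRUE`).
#' @param seed optional seed.
#' @return object of class `surrogate_ensemble`: list with `surrogates`
#'   (list of matrices), `method`, `sync_preserving`, `seed`.
#' @export
make_surrogates <- function(field, n_surrog = 2000, method = c("fft", "aaft"),
                            sync_preserving = TRUE, seed = NULL) {
  method <- match.arg(method)
  v <- unclass(field)
  stopifnot(!anyNA(v), n_surrog >= 1)
  if (any(apply(v, 1, function(r) max(r) == min(r)))) {
    stop("constant rows cannot be phase-randomised")
  }
  n <- nrow(v); T_len <- ncol(v)
  Fv <- t(stats::mvfft(t(v)))           # n x T, row-wise DFT
  half <- floor((T_len - 1) / 2)        # free phases at k = 2..half+1
  sym_from <- seq_len(half) + 1L
  sym_to <- T_len + 1L - seq_len(half)
  has_nyq <- T_len %% 2 == 0
  sorted_rows <- if (method == "aaft") apply(v, 1, sort) else NULL
  with_seed(seed, {
    surr <- vector("list", n_surrog)
    for (q in seq_len(n_surrog)) {
      rot_one <- function() {
        rot <- rep(1 + 0i, T_len)
        ph <- stats::runif(half, 0, 2 * pi)
        rot[sym_from] <- exp(1i * ph)
        rot[sym_to] <- exp(-1i * ph)
        if (has_nyq) rot[T_len / 2 + 1L] <- sample(c(-1, 1), 1L)
        rot
      }
      Fq <- if (sync_preserving) {
        Fv * matrix(rot_one(), n, T_len, byrow = TRUE)
      } else {
        t(vapply(seq_len(n), function(i) Fv[i, ] * rot_one(),
                 complex(T_len)))
      }
      s <- Re(t(stats::mvfft(t(Fq), inverse = TRUE))) / T_len
      if (method == "aaft") {
        for (i in seq_len(n)) s[i, ] <- sorted_rows[, i][rank(s[i, ],
                                                              ties.method = "first")]
      }
      dimnames(s) <- dimnames(v)
      surr[[q]] <- s
    }
    structure(list(surrogates = surr, method = method,
                   sync_preserving = sync_preserving, seed = seed),
              class = "surrogate_ensemble")
  })
}

# ---- band-level significance test ----------------------------------------

#' Band-aggregated spatial coherence test
#'
#' Computes spatial wavelet coherence between a response field `x` and a
#' predictor field `y`, aggregates it over a timescale band, and compares
#' the observed statistic with the same statistic on `n_surrog`
#' synchrony-preserving Fourier surrogates of the response (the predictor
#' stays fixed).  The default statistic is the band mean of `|coh(s)|`
#' (`"mean_mod"`); `"mod_mean"` uses the modulus of the band-mean complex
#' coherence instead.  The p-value uses the add-one rank estimator
#' `p = (1 + #&#123;surrogate >= observed&#125;) / (1 + n_surrog)`.  The mean phase
#' `theta_bar = Arg(band-mean coherence) / pi` lies in `[-1, 1]`; positive
#' values mean synchrony in the response precedes (leads) that of the
#' predictor.
#'
#' @param x,y cleaned, complete, aligned [stfield]s (response, predictor).
#' @param bd a [band()].
#' @param n_surrog number of surrogates (default 2000).
#' @param seed optional seed for the surrogates.
#' @param grid a [scale_grid].
#' @param stat `"mean_mod"` (default) or `"mod_mean"`.
#' @param surrogate_method passed to [make_surrogates].
#' @param chunk surrogates transformed per block (memory/speed trade-off).
#' @return object of class `coherence_result`: `coh` (complex per
#'   timescale), `timescales`, `band`, `stat`, `surrogate_stats`, `p`,
#'   `theta_bar`, `n_surrog`.
#' @export
band_test <- function(x, y, bd = band("short"), n_surrog = 2000,
                      seed = NULL, grid = scale_grid(),
                      stat = c("mean_mod", "mod_mean"),
                      surrogate_method = "fft", chunk = 100) {
  stat <- match.arg(stat)
  xv <- unclass(x); yv <- unclass(y)
  stopifnot(identical(dim(xv), dim(yv)), !anyNA(xv), !anyNA(yv))
  n <- nrow(xv); T_len <- ncol(xv)
  xwf <- normalize_power(morlet_cwt(x, grid), "global")
  ywf <- normalize_power(morlet_cwt(y, grid), "global")
  scales <- ywf$timescales
  n_open_s <- colSums(!ywf$coi)
  obs_coh <- spatial_coherence(xwf, ywf)
  idx <- band_scale_idx(bd, scales, n_open_s)
  band_stat <- function(coh_s) {
    if (stat == "mean_mod") mean(Mod(coh_s)) else Mod(mean(coh_s))
  }
  obs <- band_stat(obs_coh[idx])
  theta_bar <- Arg(mean(obs_coh[idx])) / pi
  surr_stats <- numeric(0)
  if (n_surrog > 0) {
    eng <- coh_engine(T_len, scales, grid$omega0, ywf$coi, idx)
    conj_yb <- Conj(vapply(seq_len(n), function(i) {
      as.vector(ywf$coef[i, , ])[eng$brows]
    }, complex(length(eng$brows))))
    ens <- make_surrogates(x, n_surrog, method = surrogate_method,
                           sync_preserving = TRUE, seed = seed)
    surr_stats <- numeric(n_surrog)
    starts <- seq(1, n_surrog, by = chunk)
    for (st in starts) {
      qs <- st:min(st + chunk - 1, n_surrog)
      V <- do.call(rbind, ens$surrogates[qs])   # (chunk*n) x T, loc fastest
      coh_mat <- coh_band(eng, t(V), conj_yb, n)
      surr_stats[qs] <- apply(coh_mat, 2, band_stat)
    }
  }
  p <- (1 + sum(surr_stats >= obs)) / (1 + n_surrog)
  structure(list(coh = obs_coh, timescales = scales, band = bd,
                 stat = obs, stat_method = stat,
                 surrogate_stats = surr_stats, p = p,
                 theta_bar = theta_bar, n_surrog = n_surrog),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> band [%s, %s): stat = %.4f, p = %.4g (%d surrogates), theta_bar = %.4f pi\n",
              x$band$lower, x$band$upper, x$stat, x$p, x$n_surrog,
              x$theta_bar))
  invisible(x)
}

#' Coherence between a field and a single index series
#'
#' Replicates an annual index (e.g., a seasonal-mean teleconnection index)
#' across the field's locations and runs [band_test] with the field as
#' response and the replicated index as predictor.  A positive mean phase
#' means synchrony in the response preceded that of the index.
#'
#' @param field cleaned, complete [stfield] (response).
#' @param index numeric annual series covering the field's years, or a
#'   2-column data.frame (year, value).
#' @param bd a [band()].
#' @param clean_index Box-Cox/detrend/standardise the index before use
#'   (default `TRUE`; set `FALSE` if the series is already cleaned).
#' @param ... passed to [band_test] (`n_surrog`, `seed`, `grid`, ...).
#' @return a `coherence_result`.
#' @export
index_band_coherence <- function(field, index, bd = band("short"),
                                 clean_index = TRUE, ...) {
  years <- attr(field, "years")
  if (is.data.frame(index)) {
    m <- match(years, index[[1]])
    if (anyNA(m)) {
      stop("index does not cover field years: ",
           paste(years[is.na(m)], collapse = ", "))
    }
    index <- index[[2]][m]
  }
  stopifnot(length(index) == ncol(field), !anyNA(index))
  rep_f <- stfield(matrix(index, nrow(field), ncol(field), byrow = TRUE),
                   locations = attr(field, "locations"), years = years,
                   region = attr(field, "region"))
  if (clean_index) rep_f <- clean_field(rep_f)$field
  band_test(field, rep_f, bd = bd, ...)
}
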