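# Ordinary kriging of indicator data with an exponential variogram.
# Small, self-contained engine: empirical variogram, weighted-least-squares
# model fit, and local-neighbourhood kriging prediction.

# Empirical semivariogram. For large n a deterministic thinning keeps the
# pair count manageable; indicator variograms are robust to this.
empirical_variogram <- function(x, y, z, n_bins = 15, cutoff = NULL,
                                max_points = 1500) {
  n <- length(z)
  if (n > max_points) {
    idx <- unique(round(seq(1, n, length.out = max_points)))
    x <- x[idx]; y <- y[idx]; z <- z[idx]
  }
  d <- as.vector(stats::dist(cbind(x, y)))
  g <- 0.5 * as.vector(stats::dist(z))^2
  if (is.null(cutoff)) cutoff <- max(d) / 2
  keep <- d > 0 & d <= cutoff
  d <- d[keep]; g <- g[keep]
  if (!length(d)) stop("no point pairs within the variogram cutoff")
  br <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE, labels = FALSE)
  data.frame(dist = tapply(d, bin, mean),
             gamma = tapply(g, bin, mean),
             n = as.vector(table(factor(bin, levels = seq_len(n_bins)))[
               sort(unique(bin))]),
             row.names = NULL)
}

# Exponential model gamma(h) = sill * (1 - exp(-h / range)), no nugget.
# WLS fit with Cressie weights n_j / gamma_model^2; the range starts at the
# median pair distance.
fit_variogram_exponential <- function(emp, init_range = NULL) {
  if (is.null(init_range)) init_range <- stats::median(emp$dist)
  obj <- function(par) {
    mod <- par[1] * (1 - exp(-emp$dist / par[2]))
    sum(emp$n * (emp$gamma - mod)^2 / pmax(mod, 1e-10)^2)
  }
  init <- c(sill = max(stats::weighted.mean(emp$gamma, emp$n), 1e-6),
            range = max(init_range, 1e-6))
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(1e-8, 1e-6),
                      upper = c(10 * init[1] + 1, 100 * init[2]))
  list(model = "exponential", sill = unname(fit$par[1]),
       range = unname(fit$par[2]))
}

exp_cov <- function(h, vg) vg$sill * exp(-h / vg$range)

# Ordinary kriging with a moving neighbourhood of the n_nn nearest data
# points. Exact interpolator (no nugget): predictions at data locations
# reproduce the data.
krige_predict <- function(x, y, z, px, py, vg, n_nn = 16) {
  n <- length(z)
  n_nn <- min(n_nn, n)
  m <- length(px)
  out <- numeric(m)
  xy <- cbind(x, y)
  # cache solved neighbourhood systems keyed by the neighbour index set
  cache <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_len(m)) {
    d2 <- (x - px[j])^2 + (y - py[j])^2
    if (n_nn < n) {
      kth <- sort.int(d2, partial = n_nn)[n_nn]
      nb <- which(d2 <= kth)[seq_len(n_nn)]
    } else nb <- seq_len(n)
    key <- paste(nb, collapse = ",")
    sys <- cache[[key]]
    if (is.null(sys)) {
      h <- as.matrix(stats::dist(xy[nb, , drop = FALSE]))
      A <- rbind(cbind(exp_cov(h, vg), 1), c(rep(1, length(nb)), 0))
      sys <- list(nb = nb, Ainv = solve(A))
      cache[[key]] <- sys
    }
    h0 <- sqrt(d2[sys$nb])
    b <- c(exp_cov(h0, vg), 1)
    w <- sys$Ainv %*% b
    out[j] <- sum(w[seq_along(sys$nb)] * z[sys$nb])
  }
  out
}

# Inverse-distance-squared interpolation on the same neighbourhood,
# used as the kriging fallback.
idw_predict <- function(x, y, z, px, py, n_nn = 16, power = 2) {
  n <- length(z)
  n_nn <- min(n_nn, n)
  out <- numeric(length(px))
  for (j in seq_along(px)) {
    d2 <- (x - px[j])^2 + (y - py[j])^2
    if (n_nn < n) {
      kth <- sort.int(d2, partial = n_nn)[n_nn]
      nb <- which(d2 <= kth)[seq_len(n_nn)]
    } else nb <- seq_len(n)
    dj <- sqrt(d2[nb])
    if (any(dj == 0)) {
      out[j] <- z[nb][which.min(dj)]
    } else {
      w <- 1 / dj^power
      out[j] <- sum(w * z[nb]) / sum(w)
    }
  }
  out
}
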