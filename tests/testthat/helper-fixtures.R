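# Shared fixtures and independent oracles, built in code at test time.

# iid Gaussian field, standardised rows (a valid "cleaned" input).
noise_field <- function(n = 20, T_len = 31, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * T_len), n, T_len)
  v <- t(scale(t(v)))
  stfield(v)
}

# Common sinusoid plus small independent noise, one row per location.
sinusoid_field <- function(n = 15, T_len = 31, period = 4, lag = 0,
                           noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  tt <- seq_len(T_len)
  base <- sin(2 * pi * (tt - lag) / period)
  v <- matrix(base, n, T_len, byrow = TRUE) +
    matrix(rnorm(n * T_len, sd = noise_sd), n, T_len)
  stfield(v)
}

# Direct-summation Morlet transform at one (t, s): the oracle against which
# the operator-based implementation is checked.
oracle_cwt_point <- function(x, t, s, omega0 = 6) {
  u <- seq_along(x)
  eta <- (u - t) / s
  s^(-0.5) * sum(x * pi^(-0.25) * exp(-1i * omega0 * eta) * exp(-eta^2 / 2))
}

# Full ordinary-kriging system solved with every data point (no moving
# neighbourhood): independent check of the kriging engine on tiny cases.
oracle_krige <- function(x, y, z, px, py, vg) {
  h <- as.matrix(dist(cbind(x, y)))
  C <- vg$sill * exp(-h / vg$range)
  A <- rbind(cbind(C, 1), c(rep(1, length(z)), 0))
  vapply(seq_along(px), function(j) {
    h0 <- sqrt((x - px[j])^2 + (y - py[j])^2)
    w <- solve(A, c(vg$sill * exp(-h0 / vg$range), 1))
    sum(w[seq_along(z)] * z)
  }, 0)
}

# Brute-force rectangularisation oracle: literal application of the three
# drop rules.
oracle_rectangularize <- function(v, min_years, min_locations) {
  keep_r <- which(rowSums(!is.na(v)) >= min_years)
  v1 <- v[keep_r, , drop = FALSE]
  keep_c <- which(colSums(!is.na(v1)) >= min_locations)
  v2 <- v1[, keep_c, drop = FALSE]
  keep_r2 <- keep_r[rowSums(is.na(v2)) == 0]
  list(rows = keep_r2, cols = keep_c,
       values = v[keep_r2, keep_c, drop = FALSE])
}
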