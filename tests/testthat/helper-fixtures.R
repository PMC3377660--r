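# shared helpers: small deterministic datasets and independent oracles

# default conversion factor: mmol m^-2 per uM of overlying water
POOL_PER_UM <- 3.8 / 1000 / (pi * 0.05^2)

# brute-force two-member mixing oracle: assemble a pool from x units of
# label and y units of background, return the measured atom fraction
mix_pool_f <- function(x, y, f_label, f_bg) {
  (x * f_label + y * f_bg) / (x + y)
}

# concentration series whose areal pool follows pool0 + slope * t_d exactly
conc_from_pool <- function(time_h, pool0, slope_per_d) {
  (pool0 + slope_per_d * time_h / 24) / POOL_PER_UM
}

# grouped data for mixed-model tests, generated under the model itself
sim_lme_data <- function(n_core, times_d, beta0, beta1, tau, sigma, delta) {
  core <- rep(sprintf("C%02d", seq_len(n_core)), each = length(times_d))
  t_d <- rep(times_d, n_core)
  a <- rep(stats::rnorm(n_core, 0, tau), each = length(times_d))
  eps <- stats::rnorm(length(t_d), 0, sigma * exp(delta * t_d))
  data.frame(core_id = core, time_d = t_d,
             pool = beta0 + beta1 * t_d + a + eps)
}

# dense GLS oracle: beta = (X' V^-1 X)^-1 X' V^-1 y with V built explicitly
gls_oracle <- function(X, y, grp, w, tau2) {
  n <- length(y)
  V <- diag(w, n)
  for (g in unique(grp)) {
    i <- which(grp == g)
    V[i, i] <- V[i, i] + tau2
  }
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}
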