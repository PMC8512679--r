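# Shared fixtures, memoised so expensive synthetic objects are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

fix_subject <- function(seed = 11) {
  cached(paste0("subject", seed), generate_subject(seed))
}

fix_trial <- function(seed = 11, k = 1, noise_scale = 0) {
  cached(sprintf("trial_%d_%d_%g", seed, k, noise_scale),
         generate_stance_trial(fix_subject(seed), k,
                               noise = default_noise_config(noise_scale)))
}

# a static pose: constant joint angles and hip position
static_kinematics <- function(seg, n = 7, fs = 100,
                              theta = c(hip = 0, knee = -0.1, ankle = 0)) {
  th <- tibble::tibble(hip = rep(theta[["hip"]], n),
                       knee = rep(theta[["knee"]], n),
                       ankle = rep(theta[["ankle"]], n))
  build_leg_kinematics(th, rep(0, n), rep(0.95 * seg$subject_height, n),
                       seg, fs)
}

# minimal one-joint MTU set operating at the linear, neutral point of every
# muscle curve: l_mt = slack + l0 at theta = 0, linear activation
toy_geom <- function(r0 = 0.05, label = "toy", channel = "ch1",
                     fmax = 100, dof = "knee") {
  r <- stats::setNames(r0, dof)
  mtu_geometry(label, r0 = r, base_l0 = 0.1, base_slack = 0.1,
               fmax = fmax, recorded_channel = channel)
}

toy_params <- function() {
  mtu_params(tendon_slack_scale = 1, optimal_fibre_scale = 1,
             strength_coeff = 1, c1 = -1e-4, c2 = -1e-4,
             shape_factor = -1e-8)
}

# independent pair-by-pair NCA objective (triple loop), used as the oracle
nca_bruteforce <- function(w, X, y, sigma, lambda) {
  n <- nrow(X)
  p <- ncol(X)
  dmat <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d <- 0
    for (r in 1:p) d <- d + w[r]^2 * abs(X[i, r] - X[j, r])
    dmat[i, j] <- d
  }
  l <- numeric(n)
  for (i in 1:n) {
    kern <- exp(-dmat[i, -i] / sigma)
    pij <- kern / sum(kern)
    l[i] <- sum(pij * abs(y[i] - y[-i]))
  }
  mean(l) + lambda * sum(w^2)
}

# independent two-line metrics oracle
metrics_oracle <- function(y, yhat) {
  c(r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean((y - yhat)^2)))
}

fit_sine <- function(x, fs, freq) {
  t <- seq_along(x) / fs
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- stats::lm.fit(X, x)$coefficients
  list(amplitude = sqrt(sum(cf^2)), phase = atan2(cf[2], cf[1]))
}
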