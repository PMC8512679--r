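test_that("minimum-effort excitations reproduce target torques and stay in the box", {
  tr <- fix_trial()
  sub <- fix_subject()
  E <- tr$truth$excitations
  expect_true(all(E >= 0 & E <= 1))
  tau <- emg_driven_torques(tr$truth$theta, tr$truth$omega, sub$mtus,
                            sub$params_true, E)
  rmse <- sqrt(mean((as.matrix(tau) - as.matrix(tr$truth$torques))^2))
  expect_lt(rmse, 1e-3)
  # unrecorded MTUs carry no ground-truth drive
  rec <- !is.na(vapply(sub$mtus, function(g) g$recorded_channel, character(1)))
  expect_true(all(E[, !rec] == 0))
})

test_that("zero target torques with passive forces disabled need no excitation", {
  n <- 25
  theta <- data.frame(hip = rep(0.1, n), knee = rep(-0.3, n), ankle = rep(0, n))
  omega <- theta * 0
  sub <- fix_subject()
  target <- data.frame(hip = rep(0, n), knee = rep(0, n), ankle = rep(0, n))
  E <- excitations_from_torques(theta, omega, target, sub$mtus,
                                sub$params_true, passive = FALSE)
  expect_lt(max(abs(E)), 1e-4)
})

test_that("infeasible torque targets are reported with frame and residual", {
  n <- 10
  theta <- data.frame(hip = rep(0, n), knee = rep(0, n), ankle = rep(0, n))
  sub <- fix_subject()
  target <- data.frame(hip = rep(0, n), knee = rep(1e4, n), ankle = rep(0, n))
  expect_error(
    excitations_from_torques(theta, theta * 0, target, sub$mtus,
                             sub$params_true),
    "frame")
})

test_that("hybrid tracking-dominated limit reproduces target torques per frame", {
  tr <- fix_trial()
  sub <- fix_subject()
  env <- tr$truth$envelopes
  sol <- hybrid_solve(tr$truth$theta, tr$truth$omega, tr$truth$torques,
                      sub$mtus, sub$params_true, env,
                      hybrid_weights(beta = 1e-9, gamma = 1e-9))
  expect_lt(max(sol$e_mom_frames), 1e-6)
  expect_true(all(sol$excitations >= 0 & sol$excitations <= 1))
})

test_that("hybrid EMG-dominated limit pins recorded excitations to the envelopes", {
  tr <- fix_trial()
  sub <- fix_subject()
  env <- tr$truth$envelopes
  sol <- hybrid_solve(tr$truth$theta, tr$truth$omega, tr$truth$torques,
                      sub$mtus, sub$params_true, env,
                      hybrid_weights(beta = 1e-9, gamma = 1e6))
  e_exp <- gaittorque:::excitation_matrix_from_envelopes(env, sub$mtus, tr$n)
  rec <- !is.na(vapply(sub$mtus, function(g) g$recorded_channel, character(1)))
  expect_lt(max(abs((sol$excitations - e_exp)[, rec])), 1e-3)
})

test_that("hybrid breakdown satisfies its weighted-total identity", {
  tr <- fix_trial()
  sub <- fix_subject()
  w <- hybrid_weights(beta = 0.2, gamma = 2)
  sol <- hybrid_solve(tr$truth$theta, tr$truth$omega, tr$truth$torques,
                      sub$mtus, sub$params_true, tr$truth$envelopes, w)
  bd <- sol$breakdown
  expect_equal(bd$F, bd$E_trackMOM + 0.2 * bd$E_sumEXC + 2 * bd$E_trackEMG)
  expect_true(all(c(bd$E_trackMOM, bd$E_sumEXC, bd$E_trackEMG) >= 0))
})

test_that("with all MTUs recorded and gamma large, hybrid equals the EMG-driven model", {
  n <- 40
  theta <- data.frame(hip = rep(0, n), knee = sin(seq(0, pi, length.out = n)) * -0.2,
                      ankle = rep(0, n))
  omega <- as.data.frame(lapply(theta, differentiate, fs = 100))
  g1 <- toy_geom(0.05, "ag", "ch1")
  g2 <- toy_geom(-0.04, "ant", "ch2")
  geoms <- list(g1, g2)
  params <- list(toy_params(), toy_params())
  env <- list(ch1 = 0.3 + 0.2 * sin(seq(0, 2, length.out = n)),
              ch2 = rep(0.25, n))
  tau_emg <- emg_driven_torques(theta, omega, geoms, params,
                                gaittorque:::excitation_matrix_from_envelopes(env, geoms, n))
  sol <- hybrid_solve(theta, omega, tau_emg, geoms, params, env,
                      hybrid_weights(beta = 1e-12, gamma = 1e6))
  expect_lt(max(abs(as.matrix(sol$torques) - as.matrix(tau_emg))), 1e-3)
})

test_that("calibration respects bounds and improves the objective", {
  sub <- fix_subject()
  trs <- lapply(1:2, function(k) fix_trial(11, k))
  cal <- lapply(trs, function(tr) {
    list(theta = tr$truth$theta, omega = tr$truth$omega,
         envelopes = tr$truth$envelopes, torques = tr$truth$torques)
  })
  fit <- calibrate_mtu_params(cal, sub$mtus, seed = 2, mass = sub$mass,
                              maxit = 25, n_starts = 1)
  expect_lte(fit$objective, fit$objective_initial)
  b <- mtu_param_bounds()
  for (p in fit$params) {
    for (nm in names(b)) {
      expect_gte(p[[nm]], b[[nm]][1])
      expect_lte(p[[nm]], b[[nm]][2])
    }
  }
})

test_that("calibration objective agrees with the EMG-driven torque model", {
  sub <- fix_subject()
  tr <- fix_trial()
  cal <- list(list(theta = tr$truth$theta, omega = tr$truth$omega,
                   envelopes = tr$truth$envelopes, torques = tr$truth$torques))
  fit <- calibrate_mtu_params(cal, sub$mtus, init = sub$params_true,
                              seed = 1, mass = sub$mass, maxit = 1,
                              n_starts = 1)
  E <- gaittorque:::excitation_matrix_from_envelopes(tr$truth$envelopes,
                                                     sub$mtus, tr$n)
  tau <- emg_driven_torques(tr$truth$theta, tr$truth$omega, sub$mtus,
                            sub$params_true, E)
  manual <- mean((as.matrix(tau) - as.matrix(tr$truth$torques))^2) / sub$mass^2
  expect_equal(fit$objective_initial, manual, tolerance = 1e-10)
})

test_that("beta/gamma selection: argmin contract and limit behaviour", {
  sub <- fix_subject()
  tr <- fix_trial()
  trial <- list(theta = tr$truth$theta, omega = tr$truth$omega,
                envelopes = tr$truth$envelopes, torques = tr$truth$torques)
  one <- tune_beta_gamma(list(trial), sub$mtus, sub$params_true,
                         data.frame(beta = 0.1, gamma = 1))
  expect_equal(one$weights$beta, 0.1)
  expect_equal(one$weights$gamma, 1)
  grid <- data.frame(beta = c(1e-6, 0.05, 1), gamma = c(1, 1, 1))
  out <- tune_beta_gamma(list(trial), sub$mtus, sub$params_true, grid)
  best <- which(out$grid$beta == out$weights$beta)
  expect_equal(min(out$grid$score), out$grid$score[best])
  # EMG-dominated vs effort-dominated candidates
  emg_dom <- tune_beta_gamma(list(trial), sub$mtus, sub$params_true,
                             data.frame(beta = 0, gamma = 1e6))$grid
  eff_dom <- tune_beta_gamma(list(trial), sub$mtus, sub$params_true,
                             data.frame(beta = 1e6, gamma = 0))$grid
  expect_lt(emg_dom$E_trackEMG, eff_dom$E_trackEMG)
})
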