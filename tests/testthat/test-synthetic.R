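test_that("subject generation is deterministic and respects its ranges", {
  s1 <- generate_subject(7)
  s2 <- generate_subject(7)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  rng <- default_anthropometry_ranges()
  for (seed in 1:5) {
    s <- generate_subject(seed)
    expect_gte(s$mass, rng$mass[1]); expect_lte(s$mass, rng$mass[2])
    expect_gte(s$height, rng$height[1]); expect_lte(s$height, rng$height[2])
    rec <- vapply(s$mtus, function(g) g$recorded_channel, character(1))
    expect_gte(sum(is.na(rec)), 2)
    # every DoF actuated by antagonistic MTUs
    for (dof in c("hip", "knee", "ankle")) {
      arms <- unlist(lapply(s$mtus, function(g) g$r0[dof]))
      expect_true(any(arms > 0, na.rm = TRUE) && any(arms < 0, na.rm = TRUE))
    }
    b <- mtu_param_bounds()
    for (p in s$params_true) {
      for (nm in names(b)) {
        expect_gte(p[[nm]], b[[nm]][1]); expect_lte(p[[nm]], b[[nm]][2])
      }
    }
  }
  expect_error(generate_subject(1, list(mass = c(70, 70), height = c(1.6, 1.9))),
               "degenerate")
})

test_that("noiseless trials: measured channels equal truth and dynamics closes", {
  tr <- fix_trial(11, 1, 0)
  expect_equal(tr$data$grf_ap, tr$truth$grf$grf_ap)
  expect_equal(tr$data$cop_ap, tr$truth$cop$cop_ap)
  expect_equal(tr$data$theta_hip, tr$truth$theta$hip)
  expect_equal(tr$data$cop_ap[1], tr$truth$cop$cop_ap[1])
  expect_true(all(tr$data$grf_v >= 0))
  expect_equal(tr$t, seq(0, by = 1 / tr$fs, length.out = tr$n))
  env <- tr$data[, paste0("emg_env_", emg_channels())]
  expect_true(all(env >= 0 & env <= 1))
})

test_that("different trial seeds give different ground reactions, same seed repeats", {
  tr1 <- fix_trial(11, 1)
  tr2 <- fix_trial(11, 2)
  expect_gt(max(abs(resample_stance(tr1$truth$grf$grf_v) -
                      resample_stance(tr2$truth$grf$grf_v))), 0)
  tr1b <- generate_stance_trial(fix_subject(11), 1,
                                noise = default_noise_config(0))
  expect_equal(tr1$data, tr1b$data)
})

test_that("raw EMG synthesis modulates a reproducible band-limited carrier", {
  expect_equal(synthesize_raw_emg(rep(0, 200), 1000, 3), rep(0, 200))
  e <- c(rep(0, 50), seq(0, 1, length.out = 100), rep(1, 50))
  r1 <- synthesize_raw_emg(e, 1000, 3)
  r2 <- synthesize_raw_emg(e, 1000, 3)
  expect_identical(r1, r2)
  expect_gt(max(abs(r1 - synthesize_raw_emg(e, 1000, 4))), 0)
  expect_error(synthesize_raw_emg(e, 50, 1), "60")
})

test_that("the EMG processing chain recovers a constant excitation plateau", {
  fs <- 1000
  env <- rep(0.6, 3 * fs)
  raw <- synthesize_raw_emg(env, fs, 21)
  rec <- process_emg(raw, fs)
  plateau <- mean(rec[500:2500])
  expect_lt(abs(plateau - 0.6) / 0.6, 0.15)
})

test_that("measurement noise amplitude raises expected channel error monotonically", {
  sub <- fix_subject(11)
  rmse_at <- function(scale) {
    vals <- vapply(1:10, function(k) {
      tr <- generate_stance_trial(sub, 100 + k,
                                  noise = default_noise_config(scale))
      grf <- sqrt(mean((tr$data$grf_v - tr$truth$grf$grf_v)^2))
      env <- sqrt(mean((as.matrix(tr$data[, paste0("emg_env_", emg_channels())]) -
                          as.matrix(tr$truth$envelopes))^2))
      c(grf, env)
    }, numeric(2))
    rowMeans(vals)
  }
  lo <- rmse_at(0.5)
  hi <- rmse_at(1.0)
  expect_gte(hi[1], lo[1]) # GRF
  expect_gte(hi[2], lo[2]) # envelopes
})

test_that("trial CSV round-trips the measured and truth blocks", {
  tr <- fix_trial(11, 1)
  path <- file.path(withr::local_tempdir(), "trial.csv")
  write_trial_csv(tr, path)
  back <- read_trial_csv(path)
  expect_equal(as.data.frame(back$data), as.data.frame(tr$data),
               tolerance = 1e-12)
  expect_equal(back$mass, tr$mass)
  expect_equal(back$fs, tr$fs)
  expect_equal(as.matrix(back$truth$torques), as.matrix(tr$truth$torques),
               tolerance = 1e-12)
  expect_equal(back$truth$excitations, tr$truth$excitations,
               tolerance = 1e-12, ignore_attr = TRUE)
  # rebuilt kinematics give the same inverse-dynamics torques
  tau <- inverse_dynamics(back$truth$kin, back$truth$grf$grf_ap,
                          back$truth$grf$grf_v, back$truth$cop$cop_ap / 1000,
                          segment_parameters(back$mass, back$height),
                          cop_warn = FALSE)
  expect_equal(as.matrix(tau), as.matrix(tr$truth$torques), tolerance = 1e-6)
})

test_that("cohort YAML configuration honours defaults and overrides", {
  path <- file.path(withr::local_tempdir(), "cohort.yaml")
  writeLines(c("n_subjects: 3", "seed: 9", "noise:", "  emg_sd: 0.05"), path)
  cfg <- read_cohort_config(path)
  expect_equal(cfg$n_subjects, 3)
  expect_equal(cfg$n_trials, 4)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$noise$emg_sd, 0.05)
  expect_equal(cfg$noise$cop_sd, default_noise_config()$cop_sd)
})
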