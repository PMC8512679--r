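#' Candidate features of a stance trial
#'
#' The candidate set offered to feature selection: sagittal joint angles,
#' joint angular velocities and accelerations, joint-centre linear
#' velocities and accelerations (hip, knee, ankle; AP and vertical), and
#' the eight EMG envelopes. Ground-reaction channels are deliberately
#' excluded: they are the estimation targets.
#'
#' @param trial A [generate_stance_trial()] object.
#' @return Tibble with one row per sample and 29 feature columns.
#' @export
trial_features <- function(trial) {
  d <- trial$data
  cols <- c(
    "theta_hip", "theta_knee", "theta_ankle",
    "omega_hip", "omega_knee", "omega_ankle",
    "alpha_hip", "alpha_knee", "alpha_ankle",
    "hip_vx", "hip_vy", "knee_vx", "knee_vy", "ankle_vx", "ankle_vy",
    "hip_ax", "hip_ay", "knee_ax", "knee_ay", "ankle_ax", "ankle_ay",
    paste0("emg_env_", emg_channels())
  )
  d[, cols]
}

#' Ground-reaction targets of a stance trial
#'
#' GRF channels in % of body weight, COP channels in mm relative to the
#' heel, as measured (i.e. including measurement noise).
#'
#' @param trial A [generate_stance_trial()] object.
#' @return Tibble with columns `grf_ap`, `grf_ml`, `grf_v` (%BW), `cop_ap`,
#'   `cop_ml` (mm).
#' @export
trial_targets <- function(trial) {
  d <- trial$data
  tibble::tibble(
    grf_ap = 100 * d$grf_ap / trial$bw,
    grf_ml = 100 * d$grf_ml / trial$bw,
    grf_v = 100 * d$grf_v / trial$bw,
    cop_ap = d$cop_ap,
    cop_ml = d$cop_ml
  )
}

#' All five ground-reaction target channels
#' @return Character vector of target labels.
#' @export
grf_cop_channels <- function() c("grf_ap", "grf_ml", "grf_v", "cop_ap", "cop_ml")

#' Default configuration of the ground-reaction estimator
#'
#' Controls the per-target pipeline: NCA feature selection (regularisation
#' defaults to 1/n; `sample_max` caps the rows entering the O(n^2)
#' objective), hyperparameter tuning (budget of worst-fold CV evaluations)
#' and network training (minimum-gradient threshold). The `fast` profile
#' loosens the gradient threshold and shrinks the search so a whole-cohort
#' evaluation stays desk-scale; the `standard` profile is the
#' single-subject default.
#'
#' @param profile `"standard"` or `"fast"`.
#' @return Named list of settings.
#' @export
default_estimator_config <- function(profile = c("standard", "fast")) {
  profile <- match.arg(profile)
  if (profile == "standard") {
    list(nca_maxit = 100L, nca_sample_max = 200L, nca_fraction = 0.01,
         tune_budget = 15L, cv_folds = 5L, grad_tol = 1e-4,
         tune_sample_max = Inf,
         channels = grf_cop_channels(), profile = profile)
  } else {
    list(nca_maxit = 30L, nca_sample_max = 70L, nca_fraction = 0.01,
         tune_budget = 10L, cv_folds = 5L, grad_tol = 5e-3,
         tune_sample_max = 90L,
         channels = grf_cop_channels(), profile = profile)
  }
}

#' Estimate GRF and COP of a test trial from its kinematics and EMG
#'
#' Leave-one-trial-out estimation: for every requested target channel, NCA
#' selects features on the pooled training trials, the network
#' hyperparameters are tuned by minimising the worst-fold CV objective over
#' the admissible box, a final network is trained on all pooled training
#' samples, and the test trial is predicted from its features only (its
#' force-plate channels are never read). GRF estimates are in %BW, COP
#' estimates in mm relative to the heel.
#'
#' @param test_trial The held-out trial.
#' @param train_trials List of training trials (must not contain the test
#'   trial).
#' @param cfg A [default_estimator_config()] list.
#' @param seed Integer seed.
#' @return Tibble with one row per test-trial sample: `sample`, per-channel
#'   `est_*` and `meas_*` columns. Attributes: `models` (per-target list
#'   with the NCA selection, tuning log and stop reason).
#' @export
estimate_ground_reaction <- function(test_trial, train_trials,
                                     cfg = default_estimator_config(),
                                     seed = 1L) {
  for (tr in train_trials) {
    if (identical(tr$subject_id, test_trial$subject_id) &&
        identical(tr$trial_seed, test_trial$trial_seed)) {
      stop("test trial must be excluded from the training trials")
    }
  }
  X_train <- do.call(rbind, lapply(train_trials, trial_features))
  Y_train <- do.call(rbind, lapply(train_trials, trial_targets))
  X_test <- trial_features(test_trial)
  Y_test <- trial_targets(test_trial)
  channels <- cfg$channels %||% grf_cop_channels()
  bad <- setdiff(channels, names(Y_train))
  if (length(bad) > 0) stop("unknown target channel(s): ", paste(bad, collapse = ", "))
  out <- tibble::tibble(sample = seq_len(nrow(X_test)))
  models <- list()
  for (ch in channels) {
    y <- Y_train[[ch]]
    nca <- fit_nca(X_train, y, seed = child_seed(seed, "nca", ch),
                   maxit = cfg$nca_maxit, sample_max = cfg$nca_sample_max)
    sel <- select_features(nca, cfg$nca_fraction)
    Xs <- as.matrix(X_train)[, sel, drop = FALSE]
    tune <- tune_hyperparameters(Xs, y, budget = cfg$tune_budget,
                                 seed = child_seed(seed, "tune", ch),
                                 k = cfg$cv_folds, grad_tol = cfg$grad_tol,
                                 sample_max = cfg$tune_sample_max %||% Inf)
    model <- train_ann(Xs, y, tune$hp,
                       seed = child_seed(seed, "final", ch),
                       grad_tol = cfg$grad_tol)
    est <- predict_ann(model, as.matrix(X_test)[, sel, drop = FALSE])
    out[[paste0("est_", ch)]] <- est
    out[[paste0("meas_", ch)]] <- Y_test[[ch]]
    models[[ch]] <- list(
      selection = tidy(nca, cfg$nca_fraction),
      selected = sel,
      hp = tune$hp, f_obj = tune$f_obj, tuning_log = tune$log,
      stop_reason = model$stop_reason, epochs_run = model$epochs_run
    )
  }
  attr(out, "models") <- models
  attr(out, "subject_id") <- test_trial$subject_id
  attr(out, "trial_seed") <- test_trial$trial_seed
  out
}

#' Goodness-of-fit of ground-reaction estimates
#'
#' @param est Output of [estimate_ground_reaction()].
#' @return Tibble with one row per estimated channel: `channel`, `r2`,
#'   `rmse` (in the channel's native unit, %BW or mm).
#' @export
grf_estimate_metrics <- function(est) {
  chans <- sub("^est_", "", grep("^est_", names(est), value = TRUE))
  purrr::map_dfr(chans, function(ch) {
    m <- fit_metrics(est[[paste0("meas_", ch)]], est[[paste0("est_", ch)]])
    tibble::tibble(channel = ch, r2 = m[["r2"]], rmse = m[["rmse"]])
  })
}
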