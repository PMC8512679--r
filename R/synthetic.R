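#' Default anthropometry ranges for the synthetic cohort
#'
#' Mass and stature ranges for subject generation, bracketing a typical
#' healthy adult cohort (the study population this generator emulates was
#' 71.0 +/- 13.8 kg and 1.71 +/- 0.10 m).
#'
#' @return Named list with `mass` and `height` ranges (c(min, max)).
#' @export
default_anthropometry_ranges <- function() {
  list(mass = c(55, 90), height = c(1.55, 1.90))
}

#' The reduced sagittal musculotendon set
#'
#' Eleven MTUs spanning hip, knee and ankle flexion/extension, with the
#' recorded/unrecorded structure of an 8-channel surface-EMG montage: one
#' electrode may drive several MTUs (the medial gastrocnemius channel drives
#' both gastrocnemius heads), and two deep muscles (iliopsoas, short head of
#' biceps femoris) have no recording at all, so their excitations must be
#' synthesised by the hybrid optimisation. Moment arms and fibre/tendon
#' lengths are fixed plausible constants scaled linearly with stature;
#' maximum isometric forces are constants in N.
#'
#' @param height Subject stature (m); path constants scale with
#'   `height / 1.70`.
#' @return List of [mtu_geometry()] objects.
#' @export
default_mtu_set <- function(height = 1.70) {
  s <- height / 1.70
  # fibres sit at optimal length in a mid-stance posture, not at q = 0
  q_ref <- c(hip = -0.15, knee = -0.40, ankle = 0.0)
  mk <- function(label, r0, r1, l0, slack, fmax, ch) {
    mtu_geometry(label, r0 = r0 * s, r1 = r1 * s, base_l0 = l0 * s,
                 base_slack = slack * s, fmax = fmax, recorded_channel = ch,
                 q_ref = q_ref)
  }
  list(
    mk("iliopsoas", c(hip = -0.035), c(hip = -0.004), 0.10, 0.09, 2500,
       NA_character_),
    mk("glut_max", c(hip = 0.055), c(hip = 0.005), 0.14, 0.11, 3200,
       "gluteus_maximus"),
    mk("glut_med", c(hip = 0.030), c(hip = 0.003), 0.09, 0.05, 1500,
       "gluteus_medius"),
    mk("rect_fem", c(hip = -0.045, knee = 0.045), c(hip = -0.004, knee = 0.005),
       0.11, 0.31, 2800, "rectus_femoris"),
    mk("vasti", c(knee = 0.045), c(knee = 0.005), 0.10, 0.16, 5000,
       "vastus_medialis"),
    mk("hamstrings", c(hip = 0.055, knee = -0.030),
       c(hip = 0.005, knee = -0.003), 0.11, 0.30, 3000, "semitendinosus"),
    mk("bf_short", c(knee = -0.025), c(knee = -0.003), 0.11, 0.10, 800,
       NA_character_),
    mk("tib_ant", c(ankle = -0.040), c(ankle = -0.004), 0.10, 0.22, 1800,
       "tibialis_anterior"),
    mk("soleus", c(ankle = 0.045), c(ankle = 0.004), 0.09, 0.24, 4000,
       "soleus"),
    mk("med_gas", c(ankle = 0.042, knee = -0.018),
       c(ankle = 0.004, knee = -0.002), 0.09, 0.38, 2000,
       "gastrocnemius_medialis"),
    mk("lat_gas", c(ankle = 0.040, knee = -0.018),
       c(ankle = 0.004, knee = -0.002), 0.09, 0.37, 1300,
       "gastrocnemius_medialis")
  )
}

#' EMG channel names of the synthetic montage
#' @return Character vector of the eight channel labels.
#' @export
emg_channels <- function() {
  c("soleus", "tibialis_anterior", "gastrocnemius_medialis", "rectus_femoris",
    "vastus_medialis", "semitendinosus", "gluteus_maximus", "gluteus_medius")
}

#' Generate a synthetic subject
#'
#' Draws anthropometry, derives planar segment parameters, instantiates the
#' reduced MTU set, and draws ground-truth musculotendon parameters inside
#' (a conservative interior of) the calibration box so that calibration can
#' in principle recover them. Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param anthropometry_ranges As [default_anthropometry_ranges()].
#' @return An object of class `subject_model` with fields `subject_id`,
#'   `mass` (kg), `height` (m), `seg` ([segment_parameters()]), `mtus`
#'   (geometry list), `params_true` (ground-truth [mtu_params()] list),
#'   `emg_channel_map` (channel -> MTU labels) and `seed`.
#' @export
generate_subject <- function(seed, anthropometry_ranges = default_anthropometry_ranges()) {
  rng <- anthropometry_ranges
  for (nm in c("mass", "height")) {
    if (length(rng[[nm]]) != 2 || diff(rng[[nm]]) <= 0 || any(rng[[nm]] <= 0)) {
      stop("degenerate anthropometry range for ", nm)
    }
  }
  local_rng_seed(child_seed(seed, "subject"))
  mass <- stats::runif(1, rng$mass[1], rng$mass[2])
  height <- stats::runif(1, rng$height[1], rng$height[2])
  mtus <- default_mtu_set(height)
  params_true <- lapply(seq_along(mtus), function(i) {
    mtu_params(
      tendon_slack_scale = stats::runif(1, 0.97, 1.03),
      optimal_fibre_scale = stats::runif(1, 0.98, 1.02),
      strength_coeff = stats::runif(1, 0.85, 1.5),
      c1 = stats::runif(1, -0.55, -0.2),
      c2 = stats::runif(1, -0.3, -0.05),
      shape_factor = stats::runif(1, -3, -0.5)
    )
  })
  channels <- vapply(mtus, function(g) g$recorded_channel, character(1))
  labels <- vapply(mtus, function(g) g$label, character(1))
  cmap <- split(labels[!is.na(channels)], channels[!is.na(channels)])
  sub <- structure(list(
    subject_id = sprintf("S%d", seed),
    mass = mass, height = height,
    seg = segment_parameters(mass, height),
    mtus = mtus,
    params_true = params_true,
    emg_channel_map = cmap,
    seed = as.integer(seed)
  ), class = "subject_model")
  stopifnot(sum(is.na(channels)) >= 2)
  sub
}

# stance-phase joint-angle templates (degrees, clinical convention),
# evaluated on normalised phase. Smooth natural splines through landmark
# values typical of self-paced walking.
template_angles <- function(phase) {
  hip_flex <- stats::splinefun(
    c(0, 0.25, 0.5, 0.75, 1), c(28, 15, 0, -10, -6), method = "natural")
  knee_flex <- stats::splinefun(
    c(0, 0.15, 0.45, 0.8, 1), c(6, 18, 7, 15, 38), method = "natural")
  dorsi <- stats::splinefun(
    c(0, 0.08, 0.45, 0.72, 0.9, 1), c(0, -5, 7, 11, -3, -17),
    method = "natural")
  list(hip_flex = hip_flex(phase), knee_flex = knee_flex(phase),
       dorsi = dorsi(phase))
}

# double-hump vertical loading template, normalised to unit mean
template_vload <- function(phase, hump = 0.22, edge = 0.10) {
  env <- sin(pi * pmin(pmax(phase, 0), 1))^0.6
  w <- edge + env * (1 + hump * cos(2 * pi * phase))
  w / mean(w)
}

#' Default measurement-noise configuration
#'
#' Amplitudes reflect a well-calibrated gait laboratory after the standard
#' 8 Hz low-pass preprocessing: ~0.2 deg RMS joint-angle noise, ~0.5 mm
#' residual marker noise on the hip trajectory, force-plate noise of 0.5%
#' of body weight, 1.5 mm COP noise, and envelope noise of 2% of the peak.
#' Noise is low-pass filtered (6 Hz) so it has the temporal correlation of
#' filtered measurement chains rather than white noise; note that position
#' noise is amplified twice by frame-by-frame differentiation before it
#' reaches the acceleration features.
#'
#' @param scale Multiplies every amplitude (0 = noiseless trials).
#' @return Named list of amplitudes: `angle_sd` (rad), `pos_sd` (m),
#'   `grf_sd` (N per 100 N of BW scale, see details), `cop_sd` (mm),
#'   `emg_sd` (envelope units).
#' @export
default_noise_config <- function(scale = 1) {
  stopifnot(scale >= 0)
  list(angle_sd = 0.003 * scale, pos_sd = 0.0005 * scale,
       grf_frac_sd = 0.005 * scale, cop_sd = 1.5 * scale,
       emg_sd = 0.02 * scale)
}

smooth_noise <- function(n, fs, sd) {
  if (sd <= 0) return(numeric(n))
  x <- stats::rnorm(n + 40)
  y <- butterworth_zero_lag(x, fs, filter_spec("lowpass", 2, min(6, fs / 4)))
  y <- y[21:(20 + n)]
  y * sd / stats::sd(y)
}

#' Generate one dynamically consistent synthetic stance trial
#'
#' Builds smooth seeded perturbations of template stance-phase joint-angle
#' curves, derives the hip trajectory from a prescribed vertical-load
#' profile and a heel-to-toe COP progression via whole-body planar dynamics
#' (so AP/vertical GRF and AP COP are exactly consistent with the
#' kinematics), derives ground-truth torques by inverse dynamics,
#' ground-truth muscle excitations by minimum-effort torque matching, and
#' synthesises raw EMG. ML GRF and ML COP are smooth seeded templates and
#' are deliberately *not* dynamically constrained (a planar sagittal model
#' cannot determine them). With `noise` amplitudes all zero the measured
#' channels equal the truth channels exactly.
#'
#' @param subject A [generate_subject()] object.
#' @param trial_seed Integer seed for this trial.
#' @param noise A [default_noise_config()]-shaped list.
#' @param fs Sampling frequency (Hz).
#' @param speed_scale Multiplies the nominal forward speed / cadence.
#' @return An object of class `stance_trial`; see the package vignette for
#'   the field layout. Key elements: `data` (tibble of measured per-sample
#'   channels), `kin` (measured kinematics), `truth` (noiseless block with
#'   `torques` in Nm, excitations, clean GRF/COP and kinematics), `fs`,
#'   `mass`, `bw`.
#' @export
generate_stance_trial <- function(subject, trial_seed,
                                  noise = default_noise_config(),
                                  fs = 100, speed_scale = 1) {
  stopifnot(inherits(subject, "subject_model"))
  for (nm in names(noise)) {
    if (noise[[nm]] < 0) stop("noise amplitude ", nm, " must be >= 0")
  }
  # Rarely, a drawn angle-wiggle/load combination demands torques a few
  # tenths of a Nm beyond the muscle set's reach at one frame; re-draw the
  # trial deterministically rather than fail (at most 3 retries).
  last_err <- NULL
  for (attempt in 1:4) {
    out <- tryCatch(
      generate_stance_trial_once(subject, trial_seed, noise, fs, speed_scale,
                                 attempt),
      error = function(e) e)
    if (!inherits(out, "error")) return(out)
    if (!grepl("infeasible", conditionMessage(out))) stop(out)
    last_err <- out
  }
  stop(last_err)
}

generate_stance_trial_once <- function(subject, trial_seed, noise, fs,
                                       speed_scale, attempt = 1L) {
  if (attempt == 1L) {
    local_rng_seed(child_seed(subject$seed, "trial", trial_seed))
  } else {
    local_rng_seed(child_seed(subject$seed, "trial", trial_seed,
                              "retry", attempt))
  }
  seg <- subject$seg
  duration <- stats::runif(1, 0.64, 0.72) / speed_scale
  n <- round(duration * fs) + 1L
  t <- seq(0, by = 1 / fs, length.out = n)
  phase <- seq(0, 1, length.out = n)
  tmpl <- template_angles(phase)
  wiggle <- function(amp_deg) {
    a <- stats::runif(2, -amp_deg, amp_deg)
    ph <- stats::runif(2, 0, 2 * pi)
    (a[1] * sin(2 * pi * phase + ph[1]) +
       a[2] * sin(4 * pi * phase + ph[2])) * pi / 180
  }
  deg <- pi / 180
  # package convention: positive = extension / plantarflexion
  theta <- tibble::tibble(
    hip = -(tmpl$hip_flex * deg + wiggle(1.5)),
    knee = -(tmpl$knee_flex * deg + wiggle(1.5)),
    ankle = -(tmpl$dorsi * deg + wiggle(1.0))
  )
  # vertical hip trajectory from the loading template
  w <- template_vload(phase, hump = 0.22 + stats::runif(1, -0.04, 0.04))
  g <- seg$g
  ay <- g * (w - 1)
  h <- 1 / fs
  y_rel <- numeric(n)
  y_rel[2] <- 0
  for (i in 2:(n - 1)) y_rel[i + 1] <- 2 * y_rel[i] - y_rel[i - 1] + h^2 * ay[i]
  # zero-hip-x pass to get x-offsets, heights and angular terms
  kin0 <- build_leg_kinematics(theta, rep(0, n), y_rel, seg, fs)
  # place the hip so the heel starts on the ground line y = 0
  y0 <- -kin0$points$heel$y[1]
  y_hip <- y_rel + y0
  kin0 <- build_leg_kinematics(theta, rep(0, n), y_hip, seg, fs)
  # COP progression template, m ahead of the heel
  prog <- 0.03 + (0.16 + stats::runif(1, -0.02, 0.02)) * smootherstep(phase) +
    0.01 * sin(2 * pi * phase + stats::runif(1, 0, 2 * pi))
  # Solve for the hip AP trajectory that realises this COP by whole-body
  # moment balance, using the same discrete differentiation operator that
  # the dynamics sees (so consistency is exact in floating point).
  segs <- c("foot", "shank", "thigh", "hat")
  m_s <- seg$mass[segs]
  FV <- numeric(n); C <- numeric(n); rhs <- numeric(n)
  for (i in seq_along(segs)) {
    p <- kin0$points[[paste0("com_", segs[i])]]
    FV <- FV + m_s[i] * (p$ay + g)
    C <- C + m_s[i] * p$y
    rhs <- rhs + m_s[i] * p$x * (p$ay + g) - m_s[i] * p$y * p$ax
  }
  for (s in c("foot", "shank", "thigh")) {
    rhs <- rhs + seg$inertia[[s]] * kin0$segments[[s]]$alpha
  }
  if (any(FV <= 0)) stop("internal error: loading template yields non-positive vertical force")
  rhs <- rhs - (kin0$points$heel$x + prog) * FV
  D1 <- diff_matrix(n, fs)
  D2 <- D1 %*% D1
  A <- C * D2 # moment balance: C_i * (D2 x)_i = rhs_i at every node
  # The balance operator has a two-dimensional affine nullspace; pin it with
  # position and initial-velocity rows and solve the slightly overdetermined
  # system in least squares, which distributes the two-equation deficiency
  # as a negligible COP deviation instead of concentrating it at the edges.
  v0 <- 1.15 * speed_scale * (1 + stats::runif(1, -0.05, 0.05))
  wbc <- max(abs(A)) * 100
  bc1 <- numeric(n); bc1[1] <- wbc
  bc2 <- numeric(n); bc2[1] <- -wbc; bc2[2] <- wbc
  M <- rbind(A, bc1, bc2)
  b <- c(rhs, 0, wbc * v0 * h)
  x_hip <- as.numeric(qr.solve(M, b))
  kin <- build_leg_kinematics(theta, x_hip, y_hip, seg, fs)
  fgr <- forward_ground_reaction(kin, seg)
  if (hat_moment_residual(kin, fgr$grf_ap, fgr$grf_v, fgr$cop_ap, seg) > 1e-6) {
    stop("internal error: synthetic trial is not dynamically consistent")
  }
  tau_truth <- inverse_dynamics(kin, fgr$grf_ap, fgr$grf_v, fgr$cop_ap, seg,
                                cop_warn = FALSE)
  omega <- tibble::tibble(
    hip = differentiate(theta$hip, fs),
    knee = differentiate(theta$knee, fs),
    ankle = differentiate(theta$ankle, fs)
  )
  alpha <- tibble::tibble(
    hip = differentiate(omega$hip, fs),
    knee = differentiate(omega$knee, fs),
    ankle = differentiate(omega$ankle, fs)
  )
  exc <- excitations_from_torques(theta, omega, tau_truth, subject$mtus,
                                  subject$params_true)
  env_truth <- excitations_to_envelopes(exc, subject$mtus)
  emg_raw <- purrr::imap(env_truth, function(e, ch) {
    synthesize_raw_emg(e, fs, child_seed(subject$seed, "emg", trial_seed, ch))
  })
  # ML channels: smooth seeded templates, not dynamically constrained
  bw <- subject$mass * g
  grf_ml <- bw * (0.045 * sin(pi * phase)^1.2 +
                    0.008 * sin(2 * pi * phase + stats::runif(1, 0, 2 * pi)))
  cop_ml <- 4 + 9 * sin(pi * phase) + 2 * sin(2 * pi * phase + stats::runif(1, 0, 2 * pi))
  # --- measurement noise ---
  nz <- function(sd) smooth_noise(n, fs, sd)
  theta_m <- tibble::tibble(
    hip = theta$hip + nz(noise$angle_sd),
    knee = theta$knee + nz(noise$angle_sd),
    ankle = theta$ankle + nz(noise$angle_sd)
  )
  x_hip_m <- x_hip + nz(noise$pos_sd)
  y_hip_m <- y_hip + nz(noise$pos_sd)
  kin_m <- build_leg_kinematics(theta_m, x_hip_m, y_hip_m, seg, fs)
  grf_sd <- noise$grf_frac_sd * bw
  grf_ap_m <- fgr$grf_ap + nz(grf_sd * 0.5)
  grf_v_m <- pmax(fgr$grf_v + nz(grf_sd), 0)
  grf_ml_m <- grf_ml + nz(grf_sd * 0.5)
  cop_ap_m <- fgr$cop_ap * 1000 + nz(noise$cop_sd) # stored in mm
  cop_ml_m <- cop_ml + nz(noise$cop_sd)
  env_m <- purrr::map(env_truth, function(e) {
    pmin(pmax(e + nz(noise$emg_sd), 0), 1)
  })
  omega_m <- tibble::tibble(
    hip = differentiate(theta_m$hip, fs),
    knee = differentiate(theta_m$knee, fs),
    ankle = differentiate(theta_m$ankle, fs)
  )
  alpha_m <- tibble::tibble(
    hip = differentiate(omega_m$hip, fs),
    knee = differentiate(omega_m$knee, fs),
    ankle = differentiate(omega_m$ankle, fs)
  )
  data <- tibble::tibble(
    t = t,
    theta_hip = theta_m$hip, theta_knee = theta_m$knee,
    theta_ankle = theta_m$ankle,
    omega_hip = omega_m$hip, omega_knee = omega_m$knee,
    omega_ankle = omega_m$ankle,
    alpha_hip = alpha_m$hip, alpha_knee = alpha_m$knee,
    alpha_ankle = alpha_m$ankle,
    hip_x = x_hip_m, hip_y = y_hip_m,
    knee_x = kin_m$points$knee$x, knee_y = kin_m$points$knee$y,
    ankle_x = kin_m$points$ankle$x, ankle_y = kin_m$points$ankle$y,
    heel_x = kin_m$points$heel$x, heel_y = kin_m$points$heel$y,
    hip_vx = kin_m$points$hip$vx, hip_vy = kin_m$points$hip$vy,
    knee_vx = kin_m$points$knee$vx, knee_vy = kin_m$points$knee$vy,
    ankle_vx = kin_m$points$ankle$vx, ankle_vy = kin_m$points$ankle$vy,
    hip_ax = kin_m$points$hip$ax, hip_ay = kin_m$points$hip$ay,
    knee_ax = kin_m$points$knee$ax, knee_ay = kin_m$points$knee$ay,
    ankle_ax = kin_m$points$ankle$ax, ankle_ay = kin_m$points$ankle$ay,
    grf_ap = grf_ap_m, grf_ml = grf_ml_m, grf_v = grf_v_m,
    cop_ap = cop_ap_m, cop_ml = cop_ml_m
  )
  for (ch in emg_channels()) {
    data[[paste0("emg_env_", ch)]] <- env_m[[ch]]
    data[[paste0("emg_raw_", ch)]] <- emg_raw[[ch]]
  }
  structure(list(
    subject_id = subject$subject_id,
    trial_seed = as.integer(trial_seed),
    fs = fs, t = t, n = n,
    mass = subject$mass, height = subject$height, bw = bw,
    data = data,
    theta = theta_m, omega = omega_m, alpha = alpha_m,
    kin = kin_m,
    truth = list(
      theta = theta, omega = omega, alpha = alpha, kin = kin,
      torques = tau_truth,
      grf = tibble::tibble(grf_ap = fgr$grf_ap, grf_ml = grf_ml,
                           grf_v = fgr$grf_v),
      cop = tibble::tibble(cop_ap = fgr$cop_ap * 1000, cop_ml = cop_ml),
      excitations = unclass_matrix(exc),
      envelopes = tibble::as_tibble(env_truth)
    )
  ), class = "stance_trial")
}

unclass_matrix <- function(x) {
  attr(x, "solution") <- NULL
  x
}

# per-channel envelopes from per-MTU excitations (MTUs sharing a channel
# share the excitation by construction)
excitations_to_envelopes <- function(exc, geoms) {
  out <- list()
  for (g in geoms) {
    if (!is.na(g$recorded_channel)) {
      out[[g$recorded_channel]] <- exc[, g$label]
    }
  }
  out[emg_channels()]
}

#' Synthesise raw surface EMG from an excitation envelope
#'
#' Amplitude-modulates a zero-mean band-limited Gaussian carrier
#' (30 Hz to 0.45 fs) so that the standard conditioning chain
#' ([process_emg()]) recovers the envelope up to smoothing error. The
#' carrier is scaled so its full-wave-rectified mean is 1.
#'
#' @param envelope Non-negative envelope series.
#' @param fs Sampling frequency (Hz); must exceed 60 Hz.
#' @param seed Integer seed.
#' @return Raw EMG series (arbitrary units).
#' @export
synthesize_raw_emg <- function(envelope, fs, seed) {
  if (fs <= 60) stop("fs must exceed 60 Hz for the 30 Hz high-pass chain")
  stopifnot(all(envelope >= 0))
  local_rng_seed(seed)
  n <- length(envelope)
  pad <- 50L
  white <- stats::rnorm(n + 2 * pad)
  carrier <- butterworth_zero_lag(white, fs, filter_spec("highpass", 4, 30))
  carrier <- butterworth_zero_lag(carrier, fs, filter_spec("lowpass", 4, 0.45 * fs))
  carrier <- carrier[(pad + 1):(pad + n)]
  mabs <- mean(abs(carrier))
  if (mabs > 0) carrier <- carrier / mabs
  envelope * carrier
}

#' Generate a synthetic cohort
#'
#' @param n_subjects,n_trials Cohort dimensions (the emulated study design
#'   is 5 subjects x 4 self-paced walking trials).
#' @param seed Cohort seed; subject seeds are derived from it.
#' @param noise Noise configuration, see [default_noise_config()].
#' @param fs Sampling frequency (Hz).
#' @param speed_scale Forward-speed scale shared by all trials.
#' @return A list with `subjects` (list of `subject_model`) and `trials`
#'   (nested list: `trials[[subject]][[trial]]`).
#' @export
generate_cohort <- function(n_subjects = 5, n_trials = 4, seed = 1,
                            noise = default_noise_config(), fs = 100,
                            speed_scale = 1) {
  subjects <- lapply(seq_len(n_subjects), function(i) {
    generate_subject(child_seed(seed, "cohort-subject", i))
  })
  trials <- lapply(subjects, function(sub) {
    lapply(seq_len(n_trials), function(k) {
      generate_stance_trial(sub, trial_seed = k, noise = noise, fs = fs,
                            speed_scale = speed_scale)
    })
  })
  list(subjects = subjects, trials = trials, seed = seed)
}

#' Read a cohort configuration from YAML
#'
#' Recognised keys: `n_subjects`, `n_trials`, `seed`, `fs`, `speed_scale`,
#' and a `noise` block with any of `angle_sd`, `pos_sd`, `grf_frac_sd`,
#' `cop_sd`, `emg_sd` (missing entries keep their defaults).
#'
#' @param path Path to a YAML file.
#' @return Argument list suitable for `do.call(generate_cohort, ...)`.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  noise <- default_noise_config()
  for (nm in names(cfg$noise %||% list())) noise[[nm]] <- cfg$noise[[nm]]
  list(
    n_subjects = cfg$n_subjects %||% 5,
    n_trials = cfg$n_trials %||% 4,
    seed = cfg$seed %||% 1,
    noise = noise,
    fs = cfg$fs %||% 100,
    speed_scale = cfg$speed_scale %||% 1
  )
}
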