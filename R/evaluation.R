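#' Coefficient of determination and root-mean-squared error
#'
#' R^2 is defined as `1 - SS_res / SS_tot` about the mean of the measured
#' series (not a squared correlation), so it can be negative; RMSE is in
#' the unit of the inputs.
#'
#' @param y_meas Measured series.
#' @param y_pred Predicted series, same length.
#' @return Named numeric vector `c(r2, rmse)`.
#' @export
#' @examples
#' fit_metrics(c(0, 1, 2), c(0, 1, 1))
fit_metrics <- function(y_meas, y_pred) {
  n <- length(y_meas)
  if (n < 2 || length(y_pred) != n) stop("need equal lengths >= 2")
  ss_tot <- sum((y_meas - mean(y_meas))^2)
  if (ss_tot <= 0) stop("zero variance in measured series: R^2 undefined")
  ss_res <- sum((y_meas - y_pred)^2)
  c(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((y_meas - y_pred)^2)))
}

#' Experimental condition label
#'
#' The crossed design: GRF source x COP source x torque model. The three
#' study conditions are EGEC (both estimated), EGMC (estimated GRF,
#' measured COP) and MGEC (measured GRF, estimated COP), each run through
#' model M (inverse dynamics) and model N (hybrid neuromusculoskeletal).
#' The fully measured pair is allowed only as the control configuration
#' used by oracle tests.
#'
#' @param grf_source,cop_source `"estimated"` or `"measured"`.
#' @param model `"M"` (inverse dynamics) or `"N"` (hybrid).
#' @return Object of class `condition_label` with a printable `code` such
#'   as `"EGEC-M"`.
#' @export
condition_label <- function(grf_source = c("estimated", "measured"),
                            cop_source = c("estimated", "measured"),
                            model = c("M", "N")) {
  grf_source <- match.arg(grf_source)
  cop_source <- match.arg(cop_source)
  model <- match.arg(model)
  code <- paste0(
    if (grf_source == "estimated") "EG" else "MG",
    if (cop_source == "estimated") "EC" else "MC",
    "-", model
  )
  structure(list(grf_source = grf_source, cop_source = cop_source,
                 model = model, code = code,
                 control = grf_source == "measured" && cop_source == "measured"),
            class = "condition_label")
}

#' The six study conditions
#' @return List of [condition_label()]s: EGEC/EGMC/MGEC x M/N.
#' @export
study_conditions <- function() {
  out <- list()
  for (m in c("M", "N")) {
    out[[paste0("EGEC-", m)]] <- condition_label("estimated", "estimated", m)
    out[[paste0("EGMC-", m)]] <- condition_label("estimated", "measured", m)
    out[[paste0("MGEC-", m)]] <- condition_label("measured", "estimated", m)
  }
  out
}

# measured-pipeline reference torques (Nm, native frames)
measured_torques <- function(trial, seg) {
  inverse_dynamics(trial$kin, trial$data$grf_ap, trial$data$grf_v,
                   trial$data$cop_ap / 1000, seg, cop_warn = FALSE)
}

trial_envelopes <- function(trial) {
  env <- trial$data[, paste0("emg_env_", emg_channels())]
  names(env) <- emg_channels()
  env
}

#' Run one experimental condition on one test trial
#'
#' Assembles the (GRF, COP) input pair of the condition (estimated channels
#' from [estimate_ground_reaction()] output, measured channels from the
#' trial), computes torques with model M (inverse dynamics) or model N
#' (hybrid EMG-informed optimisation tracking the condition's
#' inverse-dynamics torques), normalises to body mass, resamples to 100
#' stance samples, and scores against the fully measured pipeline's
#' torques.
#'
#' @param subject The trial's [generate_subject()] object.
#' @param test_trial The held-out trial.
#' @param condition A [condition_label()].
#' @param estimates Output of [estimate_ground_reaction()] for this trial
#'   (needed when the condition uses estimated channels).
#' @param calib_params Calibrated [mtu_params()] list (model N only;
#'   defaults to the subject's ground-truth parameters).
#' @param weights [hybrid_weights()] for model N.
#' @param hybrid_maxit Per-frame optimiser cap for model N.
#' @return Tibble with one row per joint: identifiers, `r2`, `rmse`
#'   (Nm/kg), and list-columns `torque_pred`, `torque_meas` (length-100
#'   phase-normalised series, Nm/kg).
#' @export
run_condition <- function(subject, test_trial, condition, estimates = NULL,
                          calib_params = NULL, weights = hybrid_weights(),
                          hybrid_maxit = 60L) {
  stopifnot(inherits(condition, "condition_label"))
  seg <- subject$seg
  mass <- subject$mass
  d <- test_trial$data
  need_est <- condition$grf_source == "estimated" ||
    condition$cop_source == "estimated"
  if (need_est) {
    if (is.null(estimates)) stop("condition ", condition$code,
                                 " needs ground-reaction estimates")
    for (ch in c(if (condition$grf_source == "estimated") c("grf_ap", "grf_v"),
                 if (condition$cop_source == "estimated") "cop_ap")) {
      if (!paste0("est_", ch) %in% names(estimates)) {
        stop("estimate channel ", ch, " missing for condition ", condition$code)
      }
    }
  }
  grf_ap <- if (condition$grf_source == "estimated") {
    estimates$est_grf_ap * test_trial$bw / 100
  } else d$grf_ap
  grf_v <- if (condition$grf_source == "estimated") {
    pmax(estimates$est_grf_v * test_trial$bw / 100, 0)
  } else d$grf_v
  cop_ap <- if (condition$cop_source == "estimated") {
    estimates$est_cop_ap / 1000
  } else d$cop_ap / 1000
  tau_ref <- measured_torques(test_trial, seg)
  tau_id <- inverse_dynamics(test_trial$kin, grf_ap, grf_v, cop_ap, seg,
                             cop_warn = FALSE)
  tau_pred <- if (condition$model == "M") {
    tau_id
  } else {
    params <- calib_params %||% subject$params_true
    sol <- hybrid_solve(test_trial$theta, test_trial$omega, tau_id,
                        subject$mtus, params, trial_envelopes(test_trial),
                        weights = weights, maxit = hybrid_maxit)
    sol$torques
  }
  code <- condition$code
  grf_src <- condition$grf_source
  cop_src <- condition$cop_source
  model_lbl <- condition$model
  purrr::map_dfr(c("hip", "knee", "ankle"), function(j) {
    pred <- resample_stance(tau_pred[[j]]) / mass
    meas <- resample_stance(tau_ref[[j]]) / mass
    m <- fit_metrics(meas, pred)
    tibble::tibble(
      subject = subject$subject_id,
      trial = test_trial$trial_seed,
      joint = j, condition = code,
      grf_source = grf_src, cop_source = cop_src,
      model = model_lbl,
      r2 = m[["r2"]], rmse = m[["rmse"]],
      torque_pred = list(pred), torque_meas = list(meas)
    )
  })
}

#' Evaluation pipeline configuration
#'
#' @param profile `"standard"` or `"fast"` (reduced optimisation budgets
#'   for whole-cohort runs).
#' @return Named list: estimator config, calibration settings, hybrid
#'   settings, and the condition set.
#' @export
evaluation_config <- function(profile = c("standard", "fast")) {
  profile <- match.arg(profile)
  fast <- profile == "fast"
  list(
    estimator = default_estimator_config(if (fast) "fast" else "standard"),
    calib_maxit = if (fast) 60L else 200L,
    calib_frames = if (fast) 30L else 50L,
    calib_starts = 1L,
    calibrate = TRUE,
    hybrid_maxit = if (fast) 40L else 100L,
    weights = hybrid_weights(),
    conditions = study_conditions(),
    profile = profile
  )
}

# resampled calibration view of a trial (measured channels)
calibration_trial <- function(trial, seg, n_frames) {
  rs <- function(df) as.data.frame(lapply(df, resample_stance, n = n_frames))
  tau <- measured_torques(trial, seg)
  list(theta = rs(trial$theta), omega = rs(trial$omega),
       envelopes = rs(trial_envelopes(trial)), torques = rs(tau))
}

#' Evaluate the experimental conditions over a synthetic cohort
#'
#' The full study design: for every subject and every test trial, the
#' remaining trials serve as training data; GRF/COP are estimated
#' leave-one-trial-out, the musculotendon parameters are calibrated on the
#' training trials' measured data, and every requested condition is run
#' through both torque models. All seeds derive from `seed`.
#'
#' @param cohort A [generate_cohort()] object.
#' @param cfg An [evaluation_config()].
#' @param seed Integer seed.
#' @param conditions Optional subset of [study_conditions()].
#' @return Tibble of per subject x trial x joint x condition results (see
#'   [run_condition()]).
#' @export
evaluate_cohort <- function(cohort, cfg = evaluation_config("fast"),
                            seed = 1L, conditions = NULL) {
  conditions <- conditions %||% cfg$conditions
  need_est <- any(vapply(conditions, function(cd) {
    cd$grf_source == "estimated" || cd$cop_source == "estimated"
  }, logical(1)))
  est_channels <- unique(unlist(lapply(conditions, function(cd) {
    c(if (cd$grf_source == "estimated") c("grf_ap", "grf_v"),
      if (cd$cop_source == "estimated") "cop_ap")
  })))
  need_n <- any(vapply(conditions, function(cd) cd$model == "N", logical(1)))
  res <- list()
  for (si in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[si]]
    trials <- cohort$trials[[si]]
    for (ti in seq_along(trials)) {
      test_trial <- trials[[ti]]
      train <- trials[-ti]
      est <- NULL
      if (need_est) {
        ecfg <- cfg$estimator
        ecfg$channels <- est_channels
        est <- estimate_ground_reaction(test_trial, train, ecfg,
                                        seed = child_seed(seed, "est", si, ti))
      }
      params <- NULL
      if (need_n && isTRUE(cfg$calibrate)) {
        cal <- lapply(train, calibration_trial, seg = sub$seg,
                      n_frames = cfg$calib_frames)
        fit <- calibrate_mtu_params(cal, sub$mtus,
                                    seed = child_seed(seed, "calib", si, ti),
                                    mass = sub$mass, maxit = cfg$calib_maxit,
                                    n_starts = cfg$calib_starts)
        params <- fit$params
      }
      for (cd in conditions) {
        res[[length(res) + 1]] <- run_condition(
          sub, test_trial, cd, estimates = est, calib_params = params,
          weights = cfg$weights, hybrid_maxit = cfg$hybrid_maxit)
      }
    }
  }
  dplyr::bind_rows(res)
}

#' Friedman rank test for repeated measures
#'
#' Within-block mid-ranks with the tie-corrected chi-squared statistic
#' (delegates to [stats::friedman.test()]).
#'
#' @param data Numeric matrix, blocks x treatments.
#' @return Tibble with `chi2`, `df`, `p_value`, `n_blocks`, `k`.
#' @export
#' @examples
#' friedman_test(matrix(rep(1:3, each = 3), 3, byrow = FALSE))
friedman_test <- function(data) {
  data <- as.matrix(data)
  if (ncol(data) < 2) stop("need at least 2 treatments")
  if (nrow(data) < 2) stop("need at least 2 blocks")
  ranks <- t(apply(data, 1, rank))
  if (all(apply(ranks, 2, stats::var) == 0) &&
      length(unique(colMeans(ranks))) == 1) {
    # complete ties: statistic 0 by convention
    return(tibble::tibble(chi2 = 0, df = ncol(data) - 1, p_value = 1,
                          n_blocks = nrow(data), k = ncol(data)))
  }
  ft <- stats::friedman.test(data)
  tibble::tibble(chi2 = unname(ft$statistic), df = unname(ft$parameter),
                 p_value = ft$p.value, n_blocks = nrow(data), k = ncol(data))
}

#' Dunn-Bonferroni post hoc comparisons after a Friedman test
#'
#' Pairwise z statistics from the within-block mean ranks with standard
#' error `sqrt(k (k + 1) / (6 n))`, two-sided normal p-values multiplied by
#' the number of comparisons and capped at 1.
#'
#' @param data Numeric matrix, blocks x treatments (column names label the
#'   treatments).
#' @param alpha Significance level for the flags (default 0.05).
#' @return Tibble with one row per pair: `treatment_1`, `treatment_2`, `z`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
dunn_bonferroni <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  if (ncol(data) < 2) stop("need at least 2 treatments")
  if (nrow(data) < 2) stop("need at least 2 blocks")
  k <- ncol(data); n <- nrow(data)
  labs <- colnames(data) %||% paste0("T", seq_len(k))
  rbar <- colMeans(t(apply(data, 1, rank)))
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(ix) {
    i <- pairs[1, ix]; j <- pairs[2, ix]
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(treatment_1 = labs[i], treatment_2 = labs[j],
                   z = unname(z), p_value = p,
                   p_adjusted = min(1, p * m),
                   significant = min(1, p * m) < alpha)
  })
}

#' Condition-wise summary tables
#'
#' Mean and standard deviation of R^2 and RMSE per condition x joint over
#' all trials and subjects — the study's summary layout (6 conditions x 3
#' joints).
#'
#' @param results Output of [evaluate_cohort()].
#' @return List with `r2` and `rmse` tibbles (condition rows, one column
#'   pair per joint) and `long`, the long-format per-trial table.
#' @export
summarize_conditions <- function(results) {
  stopifnot(nrow(results) >= 1)
  long <- dplyr::select(results, -dplyr::any_of(c("torque_pred", "torque_meas")))
  cells <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$joint),
    r2_mean = mean(.data$r2), r2_sd = stats::sd(.data$r2),
    rmse_mean = mean(.data$rmse), rmse_sd = stats::sd(.data$rmse),
    n = dplyr::n(), .groups = "drop"
  )
  cells$r2_sd[is.na(cells$r2_sd)] <- 0
  cells$rmse_sd[is.na(cells$rmse_sd)] <- 0
  wide <- function(stat) {
    fmt <- tidyr::pivot_wider(
      dplyr::transmute(cells, .data$condition, .data$joint,
                       value = sprintf("%.3g ± %.2g",
                                       .data[[paste0(stat, "_mean")]],
                                       .data[[paste0(stat, "_sd")]])),
      names_from = "joint", values_from = "value")
    fmt[, c("condition", intersect(c("hip", "knee", "ankle"), names(fmt)))]
  }
  list(r2 = wide("r2"), rmse = wide("rmse"), cells = cells, long = long)
}

#' Friedman/Dunn statistics over the cohort results
#'
#' Within-subject tests use trials as blocks and conditions as treatments
#' (one test per subject x joint x metric); the between-subject variant
#' blocks on subjects using per-subject trial means. Conditions are
#' compared at significance level 0.05.
#'
#' @param results Output of [evaluate_cohort()].
#' @param metric `"rmse"` or `"r2"`.
#' @return List with `within` (per subject x joint Friedman results),
#'   `between` (per joint), and `posthoc` (Dunn-Bonferroni on the
#'   between-subject matrices).
#' @export
condition_statistics <- function(results, metric = c("rmse", "r2")) {
  metric <- match.arg(metric)
  long <- dplyr::select(results, dplyr::all_of(
    c("subject", "trial", "joint", "condition", metric)))
  mat_for <- function(df, blocks) {
    w <- tidyr::pivot_wider(df, id_cols = dplyr::all_of(blocks),
                            names_from = "condition",
                            values_from = dplyr::all_of(metric))
    as.matrix(w[, setdiff(names(w), blocks)])
  }
  within <- purrr::map_dfr(
    split(long, interaction(long$subject, long$joint, drop = TRUE)),
    function(df) {
      m <- mat_for(df, "trial")
      if (nrow(m) < 2 || any(is.na(m))) return(NULL)
      cbind(tibble::tibble(subject = df$subject[1], joint = df$joint[1]),
            friedman_test(m))
    })
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$subject, .data$joint, .data$condition),
    value = mean(.data[[metric]]), .groups = "drop")
  names(means)[names(means) == "value"] <- metric
  between <- purrr::map_dfr(split(means, means$joint), function(df) {
    m <- mat_for(df, "subject")
    if (nrow(m) < 2 || any(is.na(m))) return(NULL)
    cbind(tibble::tibble(joint = df$joint[1]), friedman_test(m))
  })
  posthoc <- purrr::map(split(means, means$joint), function(df) {
    dunn_bonferroni(mat_for(df, "subject"))
  })
  list(within = within, between = between, posthoc = posthoc,
       metric = metric)
}
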