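#' Write a stance trial to CSV with a JSON sidecar
#'
#' The flat dialect: one row per sample, one column per measured channel
#' (the trial's `data` tibble), plus `truth_*` columns for the noiseless
#' block (torques in Nm, clean GRF in N, clean COP in mm, per-MTU
#' excitations). Scalar metadata (sampling rate, anthropometry, seeds) goes
#' to a `<path>.json` sidecar so the trial can be reconstructed exactly.
#'
#' @param trial A [generate_stance_trial()] object.
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param truth Include the ground-truth columns? (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, truth = TRUE) {
  d <- trial$data
  if (truth && !is.null(trial$truth)) {
    tt <- trial$truth
    d$truth_tau_hip <- tt$torques$hip
    d$truth_tau_knee <- tt$torques$knee
    d$truth_tau_ankle <- tt$torques$ankle
    d$truth_grf_ap <- tt$grf$grf_ap
    d$truth_grf_ml <- tt$grf$grf_ml
    d$truth_grf_v <- tt$grf$grf_v
    d$truth_cop_ap <- tt$cop$cop_ap
    d$truth_cop_ml <- tt$cop$cop_ml
    d$truth_theta_hip <- tt$theta$hip
    d$truth_theta_knee <- tt$theta$knee
    d$truth_theta_ankle <- tt$theta$ankle
    d$truth_hip_x <- tt$kin$points$hip$x
    d$truth_hip_y <- tt$kin$points$hip$y
    for (lbl in colnames(tt$excitations)) {
      d[[paste0("truth_exc_", lbl)]] <- tt$excitations[, lbl]
    }
  }
  dd <- as.data.frame(lapply(d, function(x) format(x, digits = 17)))
  names(dd) <- names(d)
  utils::write.csv(dd, path, row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = trial$subject_id, trial_seed = trial$trial_seed,
               fs = trial$fs, n = trial$n, mass = trial$mass, bw = trial$bw,
               height = trial$height %||% NA,
               truth_included = truth && !is.null(trial$truth))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stance trial written by [write_trial_csv()]
#'
#' Reconstructs the measured channels, the derived kinematic chain (from
#' the stored subject anthropometry) and, when present, the ground-truth
#' block.
#'
#' @param path CSV path (sidecar expected at `<path>.json`).
#' @param height Subject stature in m, needed to rebuild segment
#'   parameters when absent from the sidecar.
#' @return A `stance_trial`-shaped list (without solver attributes).
#' @export
read_trial_csv <- function(path, height = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- tibble::as_tibble(utils::read.csv(path))
  height <- height %||% meta$height
  if (is.null(height) || !is.finite(height)) {
    stop("subject height unavailable; pass `height` to rebuild kinematics")
  }
  seg <- segment_parameters(meta$mass, height)
  theta <- tibble::tibble(hip = d$theta_hip, knee = d$theta_knee,
                          ankle = d$theta_ankle)
  omega <- tibble::tibble(hip = d$omega_hip, knee = d$omega_knee,
                          ankle = d$omega_ankle)
  alpha <- tibble::tibble(hip = d$alpha_hip, knee = d$alpha_knee,
                          ankle = d$alpha_ankle)
  kin <- build_leg_kinematics(theta, d$hip_x, d$hip_y, seg, meta$fs)
  truth <- NULL
  if (isTRUE(meta$truth_included) && "truth_tau_hip" %in% names(d)) {
    tth <- tibble::tibble(hip = d$truth_theta_hip, knee = d$truth_theta_knee,
                          ankle = d$truth_theta_ankle)
    exc_cols <- grep("^truth_exc_", names(d), value = TRUE)
    exc <- as.matrix(d[, exc_cols])
    colnames(exc) <- sub("^truth_exc_", "", exc_cols)
    truth <- list(
      theta = tth,
      kin = build_leg_kinematics(tth, d$truth_hip_x, d$truth_hip_y, seg, meta$fs),
      torques = tibble::tibble(hip = d$truth_tau_hip, knee = d$truth_tau_knee,
                               ankle = d$truth_tau_ankle),
      grf = tibble::tibble(grf_ap = d$truth_grf_ap, grf_ml = d$truth_grf_ml,
                           grf_v = d$truth_grf_v),
      cop = tibble::tibble(cop_ap = d$truth_cop_ap, cop_ml = d$truth_cop_ml),
      excitations = exc
    )
  }
  keep <- setdiff(names(d), grep("^truth_", names(d), value = TRUE))
  structure(list(
    subject_id = meta$subject_id, trial_seed = meta$trial_seed,
    fs = meta$fs, t = d$t, n = nrow(d), mass = meta$mass,
    height = height, bw = meta$bw,
    data = d[, keep], theta = theta, omega = omega, alpha = alpha,
    kin = kin, truth = truth
  ), class = "stance_trial")
}

#' Write long-format condition results to CSV
#'
#' @param results Output of [evaluate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  long <- dplyr::select(results,
                        -dplyr::any_of(c("torque_pred", "torque_meas")))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write an NCA selection table to CSV
#'
#' One row per (target, feature) with the weight and selection flag — the
#' serialisable record of which inputs each estimator network received.
#'
#' @param models The `models` attribute of [estimate_ground_reaction()]
#'   output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(models, path) {
  tab <- purrr::map_dfr(names(models), function(ch) {
    sel <- models[[ch]]$selection
    sel$target <- ch
    sel[, c("target", "feature", "weight", "weight_sq", "selected")]
  })
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a Markdown report of cohort condition results
#'
#' Emits the condition-by-joint mean +/- SD tables for both metrics and the
#' between-subject nonparametric test results.
#'
#' @param results Output of [evaluate_cohort()].
#' @param path Output path (Markdown).
#' @return `path`, invisibly.
#' @export
write_report_md <- function(results, path) {
  s <- summarize_conditions(results)
  md_table <- function(df) {
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, rows)
  }
  lines <- c(
    "# Joint torque prediction from statistical ground-reaction estimates",
    "", sprintf("Synthetic cohort: %d results (%d subjects).",
                nrow(s$long), length(unique(s$long$subject))),
    "", "## R^2 of joint torques (mean ± SD)", "", md_table(s$r2),
    "", "## RMSE of joint torques, Nm/kg (mean ± SD)", "", md_table(s$rmse),
    "",
    "Subject-level significance statements on synthetic subjects are",
    "illustrative of the workflow only; they do not characterise any real",
    "population.", ""
  )
  if (length(unique(s$long$subject)) >= 2 &&
      length(unique(s$long$condition)) >= 2) {
    st <- condition_statistics(results, "rmse")
    if (nrow(st$between) > 0) {
      lines <- c(lines, "## Between-subject Friedman tests (RMSE)", "",
                 md_table(data.frame(
                   joint = st$between$joint,
                   chi2 = sprintf("%.3g", st$between$chi2),
                   df = st$between$df,
                   p = sprintf("%.3g", st$between$p_value))), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
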