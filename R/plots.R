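#' Plot the measured channels of a stance trial
#'
#' Faceted overview: sagittal joint angles, GRF components (%BW), AP/ML COP
#' (mm) and the EMG envelopes, against percent of stance.
#'
#' @param object A [generate_stance_trial()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stance_trial
#' @export
autoplot.stance_trial <- function(object, ...) {
  d <- object$data
  phase <- seq(0, 100, length.out = nrow(d))
  long <- dplyr::bind_rows(
    tibble::tibble(phase = rep(phase, 3), panel = "joint angle (deg)",
                   channel = rep(c("hip", "knee", "ankle"), each = nrow(d)),
                   value = c(d$theta_hip, d$theta_knee, d$theta_ankle) * 180 / pi),
    tibble::tibble(phase = rep(phase, 3), panel = "GRF (%BW)",
                   channel = rep(c("AP", "ML", "V"), each = nrow(d)),
                   value = 100 * c(d$grf_ap, d$grf_ml, d$grf_v) / object$bw),
    tibble::tibble(phase = rep(phase, 2), panel = "COP (mm)",
                   channel = rep(c("AP", "ML"), each = nrow(d)),
                   value = c(d$cop_ap, d$cop_ml)),
    purrr::map_dfr(emg_channels(), function(ch) {
      tibble::tibble(phase = phase, panel = "EMG envelope",
                     channel = ch, value = d[[paste0("emg_env_", ch)]])
    })
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "stance phase (%)", y = NULL,
                  title = sprintf("%s / trial %d", object$subject_id,
                                  object$trial_seed)) +
    ggplot2::theme_minimal()
}

#' Plot measured vs estimated ground-reaction channels
#'
#' @param est Output of [estimate_ground_reaction()].
#' @return A ggplot object (one facet per channel).
#' @export
plot_grf_estimate <- function(est) {
  chans <- sub("^est_", "", grep("^est_", names(est), value = TRUE))
  long <- purrr::map_dfr(chans, function(ch) {
    tibble::tibble(
      sample = rep(est$sample, 2), channel = ch,
      source = rep(c("measured", "estimated"), each = nrow(est)),
      value = c(est[[paste0("meas_", ch)]], est[[paste0("est_", ch)]])
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value,
                                     colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "sample", y = "%BW (GRF) / mm (COP)") +
    ggplot2::theme_minimal()
}

#' Plot condition-wise torque metrics over a cohort
#'
#' Boxplots of R^2 or RMSE per condition, faceted by joint — the study's
#' summary figure layout.
#'
#' @param results Output of [evaluate_cohort()].
#' @param metric `"rmse"` or `"r2"`.
#' @return A ggplot object.
#' @export
plot_condition_metrics <- function(results, metric = c("rmse", "r2")) {
  metric <- match.arg(metric)
  results$joint <- factor(results$joint, c("hip", "knee", "ankle"))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$condition,
                                        y = .data[[metric]],
                                        fill = .data$model)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = if (metric == "rmse") "RMSE (Nm/kg)" else
                    expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot predicted vs measured torque trajectories
#'
#' Mean (and per-trial) phase-normalised torque curves per joint for one
#' condition.
#'
#' @param results Output of [evaluate_cohort()] (or [run_condition()]).
#' @param condition Condition code to display, e.g. `"EGEC-M"`.
#' @return A ggplot object.
#' @export
plot_condition_torques <- function(results, condition = "EGEC-M") {
  res <- results[results$condition == condition, ]
  if (nrow(res) == 0) stop("no results for condition ", condition)
  long <- purrr::map_dfr(seq_len(nrow(res)), function(i) {
    tibble::tibble(
      phase = rep(seq(0, 100, length.out = 100), 2),
      joint = res$joint[i],
      trial = paste(res$subject[i], res$trial[i]),
      source = rep(c("predicted", "measured"), each = 100),
      value = c(res$torque_pred[[i]], res$torque_meas[[i]])
    )
  })
  long$joint <- factor(long$joint, c("hip", "knee", "ankle"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$value,
                                     colour = .data$source,
                                     group = interaction(.data$trial,
                                                         .data$source))) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = "stance phase (%)", y = "torque (Nm/kg)",
                  title = condition) +
    ggplot2::theme_minimal()
}
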