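#' Calibration bounds for musculotendon parameters
#'
#' The five per-MTU parameters adjusted during calibration, with their
#' admissible ranges: tendon slack length and optimal fibre length enter as
#' dimensionless multiplicative scales on the subject's base geometry
#' (0.95-1.05 and 0.975-1.025), the muscle strength coefficient scales
#' maximum isometric force (0.5-2), the two activation filtering
#' coefficients live in (-1, 1) (filter stability), and the shape factor of
#' the activation nonlinearisation lies in \[-5, 0\].
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
mtu_param_bounds <- function() {
  list(
    tendon_slack_scale = c(0.95, 1.05),
    optimal_fibre_scale = c(0.975, 1.025),
    strength_coeff = c(0.5, 2),
    c1 = c(-1, 1),
    c2 = c(-1, 1),
    shape_factor = c(-5, 0)
  )
}

#' Per-MTU calibration parameters
#'
#' @param tendon_slack_scale,optimal_fibre_scale,strength_coeff,c1,c2,shape_factor
#'   See [mtu_param_bounds()] for meanings and admissible ranges.
#' @return An object of class `mtu_params`.
#' @export
mtu_params <- function(tendon_slack_scale = 1, optimal_fibre_scale = 1,
                       strength_coeff = 1, c1 = -0.5, c2 = -0.5,
                       shape_factor = -2) {
  b <- mtu_param_bounds()
  p <- list(tendon_slack_scale = tendon_slack_scale,
            optimal_fibre_scale = optimal_fibre_scale,
            strength_coeff = strength_coeff, c1 = c1, c2 = c2,
            shape_factor = shape_factor)
  for (nm in names(p)) {
    lo <- b[[nm]][1]; hi <- b[[nm]][2]
    strict <- nm %in% c("c1", "c2")
    ok <- if (strict) p[[nm]] > lo && p[[nm]] < hi else
      p[[nm]] >= lo && p[[nm]] <= hi
    if (!ok) stop(sprintf("%s = %.4g outside its admissible range [%g, %g]",
                          nm, p[[nm]], lo, hi))
  }
  structure(p, class = "mtu_params")
}

#' Musculotendon path geometry
#'
#' Angle-dependent path of one musculotendon unit over the sagittal degrees
#' of freedom it spans. The musculotendon length is a per-DoF quadratic,
#' `l_mt(q) = l0_const - sum_j (r0_j q_j + r1_j q_j^2 / 2)`, so the moment
#' arm about DoF j is the analytic derivative `r_j(q) = -dl_mt/dq_j = r0_j +
#' r1_j q_j`. Angles follow the package convention (positive = extension /
#' plantarflexion), so extensors and plantarflexors have positive moment
#' arms, flexors and dorsiflexors negative ones.
#'
#' @param label MTU name.
#' @param r0 Named numeric: constant moment-arm component (m) per spanned
#'   DoF (names among `hip`, `knee`, `ankle`).
#' @param r1 Named numeric, same names: linear angle dependence of the
#'   moment arm (m/rad); defaults to 0.
#' @param base_l0 Base optimal fibre length (m).
#' @param base_slack Base tendon slack length (m).
#' @param fmax Maximum isometric force (N).
#' @param recorded_channel EMG channel label driving this MTU, or `NA` if
#'   the muscle has no surface recording and its excitation must be
#'   synthesised.
#' @param q_ref Named reference posture (rad) at which the fibre sits at its
#'   optimal length (`l_mt(q_ref) = base_slack + base_l0`); defaults to the
#'   zero posture. Referencing to a mid-stance posture keeps normalised
#'   fibre lengths near 1 over the stance-phase motion range.
#' @return An object of class `mtu_geometry`.
#' @export
mtu_geometry <- function(label, r0, r1 = NULL, base_l0, base_slack, fmax,
                         recorded_channel = NA_character_, q_ref = NULL) {
  stopifnot(length(r0) >= 1, !is.null(names(r0)),
            all(names(r0) %in% c("hip", "knee", "ankle")),
            base_l0 > 0, base_slack >= 0, fmax > 0)
  if (is.null(r1)) r1 <- stats::setNames(rep(0, length(r0)), names(r0))
  stopifnot(identical(sort(names(r1)), sort(names(r0))))
  qr <- stats::setNames(rep(0, length(r0)), names(r0))
  if (!is.null(q_ref)) {
    qr[intersect(names(qr), names(q_ref))] <-
      q_ref[intersect(names(qr), names(q_ref))]
  }
  l0_const <- base_slack + base_l0 +
    sum(r0 * qr + r1 * qr^2 / 2)
  structure(list(label = label, r0 = r0, r1 = r1[names(r0)],
                 base_l0 = base_l0, base_slack = base_slack, fmax = fmax,
                 l0_const = l0_const, q_ref = qr,
                 recorded_channel = recorded_channel),
            class = "mtu_geometry")
}

#' Musculotendon length, velocity and moment arms from joint kinematics
#'
#' @param theta Matrix or data frame of joint angles (rad), columns `hip`,
#'   `knee`, `ankle`.
#' @param omega Matching angular velocities (rad/s).
#' @param g An [mtu_geometry()].
#' @return List with `l_mt` (m), `v_mt` (m/s, lengthening positive) and `r`,
#'   a matrix of per-DoF moment arms (m) with one column per spanned DoF.
#'   By construction `v_mt = -sum_j r_j omega_j` (power balance).
#' @export
mtu_state <- function(theta, omega, g) {
  stopifnot(inherits(g, "mtu_geometry"))
  theta <- as.matrix(as.data.frame(theta))
  omega <- as.matrix(as.data.frame(omega))
  dofs <- names(g$r0)
  q <- theta[, dofs, drop = FALSE]
  w <- omega[, dofs, drop = FALSE]
  r <- sweep(q, 2, g$r1, "*")
  r <- sweep(r, 2, g$r0, "+") # r_j = r0_j + r1_j q_j
  l_mt <- g$l0_const -
    as.numeric(q %*% g$r0 + (q^2 / 2) %*% g$r1)
  v_mt <- -rowSums(r * w)
  list(l_mt = l_mt, v_mt = v_mt, r = r)
}

#' Activation dynamics: recursive filter plus nonlinearisation
#'
#' Neural excitation is mapped to muscle activation by a critically damped
#' second-order recursive filter `u(t) = a_g e(t) - b1 u(t-1) - b2 u(t-2)`
#' with `b1 = c1 + c2`, `b2 = c1 c2` and unit steady-state gain
#' `a_g = 1 + b1 + b2`, followed by the exponential nonlinearisation
#' `a = (exp(A u) - 1) / (exp(A) - 1)` (with the continuous limit `a = u`
#' as the shape factor `A -> 0`). Output is clamped to \[0, 1\].
#'
#' @param excitation Excitation series in \[0, 1\].
#' @param p An [mtu_params()] (uses `c1`, `c2`, `shape_factor`).
#' @return Activation series in \[0, 1\].
#' @export
activation_dynamics <- function(excitation, p) {
  if (abs(p$c1) >= 1 || abs(p$c2) >= 1) {
    stop("activation filter unstable: |c1| and |c2| must be < 1")
  }
  stopifnot(all(excitation >= -1e-12), all(excitation <= 1 + 1e-12))
  u <- activation_filter(matrix(excitation, ncol = 1), p$c1, p$c2)[, 1]
  pmin(pmax(activation_nonlin(u, p$shape_factor), 0), 1)
}

# vectorised over columns: E is T x M, c1/c2 length-M (recycled).
# The filter history is initialised at the steady state of the first sample
# (muscles pre-activate before heel strike), so the first frame has full
# excitation authority; with unit DC gain the steady state for constant
# input e is u = e.
activation_filter <- function(E, c1, c2) {
  b1 <- c1 + c2
  b2 <- c1 * c2
  ag <- 1 + b1 + b2
  U <- E
  n <- nrow(E)
  u1 <- u2 <- as.numeric(E[1, ])
  for (t in seq_len(n)) {
    u <- ag * E[t, ] - b1 * u1 - b2 * u2
    U[t, ] <- u
    u2 <- u1
    u1 <- u
  }
  U
}

activation_nonlin <- function(u, A) {
  if (abs(A) < 1e-6) return(u)
  (exp(A * u) - 1) / (exp(A) - 1)
}

activation_nonlin_deriv <- function(u, A) {
  if (abs(A) < 1e-6) return(rep(1, length(u)))
  A * exp(A * u) / (exp(A) - 1)
}

# normalised Hill curves ------------------------------------------------

# active force-length: Gaussian centred at optimal length, width 0.45
fl_curve <- function(lnorm) exp(-((lnorm - 1) / 0.45)^2)

# force-velocity: logistic saturating curve, f_v(0) = 1 exactly,
# -> 0 at fast shortening (vnorm -> -1), -> 1.6 at fast lengthening
fv_curve <- function(vnorm) 1.6 / (1 + 0.6 * exp(-4 * vnorm))

# passive force-length: exponential, zero at and below optimal length,
# reaching 1 at 60% fibre strain
fp_curve <- function(lnorm) {
  out <- numeric(length(lnorm))
  ix <- lnorm > 1
  out[ix] <- (exp(4 * (lnorm[ix] - 1)) - 1) / (exp(4 * 0.6) - 1)
  out
}

#' Rigid-tendon Hill-type musculotendon force
#'
#' Fibre length is `l_m = l_mt - tendon_slack_scale * base_slack` (rigid
#' tendon, zero pennation); normalised by the scaled optimal fibre length it
#' feeds the active force-length (Gaussian), force-velocity (saturating
#' logistic, normalising velocity 10 optimal lengths/s) and passive
#' (exponential) curves:
#' `F = strength_coeff * Fmax * (a * f_l * f_v + f_p)`.
#'
#' @param a Activation in \[0, 1\].
#' @param l_mt,v_mt Musculotendon length (m) and velocity (m/s).
#' @param g An [mtu_geometry()].
#' @param p An [mtu_params()].
#' @param passive Include the passive elastic term? (default `TRUE`).
#' @return Force in N (non-negative).
#' @export
mtu_force <- function(a, l_mt, v_mt, g, p, passive = TRUE) {
  lts <- p$tendon_slack_scale * g$base_slack
  l0 <- p$optimal_fibre_scale * g$base_l0
  l_m <- l_mt - lts
  if (any(l_m <= 0)) {
    stop(sprintf("non-physical fibre length (<= 0) for MTU '%s'", g$label))
  }
  lnorm <- l_m / l0
  vnorm <- v_mt / (10 * l0)
  fp <- if (passive) fp_curve(lnorm) else 0
  pmax(p$strength_coeff * g$fmax * (a * fl_curve(lnorm) * fv_curve(vnorm) + fp), 0)
}

# Precompute everything angle-dependent for a whole trial: per MTU the
# length/velocity/moment arms, and the force gains so that
# F_i(t) = gain_i(t) * a_i(t) + passive_i(t).
mtu_trial_gains <- function(theta, omega, geoms, params, passive = TRUE) {
  n <- nrow(as.data.frame(theta))
  m <- length(geoms)
  gain <- pas <- matrix(0, n, m)
  arms <- array(0, c(n, 3, m), dimnames = list(NULL, c("hip", "knee", "ankle"), NULL))
  for (i in seq_len(m)) {
    g <- geoms[[i]]; p <- params[[i]]
    st <- mtu_state(theta, omega, g)
    lts <- p$tendon_slack_scale * g$base_slack
    l0 <- p$optimal_fibre_scale * g$base_l0
    l_m <- st$l_mt - lts
    if (any(l_m <= 0)) {
      stop(sprintf("non-physical fibre length (<= 0) for MTU '%s'", g$label))
    }
    lnorm <- l_m / l0
    vnorm <- st$v_mt / (10 * l0)
    gain[, i] <- p$strength_coeff * g$fmax * fl_curve(lnorm) * fv_curve(vnorm)
    if (passive) pas[, i] <- p$strength_coeff * g$fmax * fp_curve(lnorm)
    arms[, names(g$r0), i] <- st$r
  }
  list(gain = gain, passive = pas, arms = arms,
       labels = vapply(geoms, function(g) g$label, character(1)))
}

#' Joint torques of the EMG-driven musculotendon model
#'
#' Runs every MTU through activation dynamics and the Hill model and maps
#' forces to sagittal joint torques through the moment arms:
#' `tau_j(t) = sum_i r_ij(theta(t)) F_i(t)`. Excitations may come from
#' recorded EMG envelopes (one envelope can drive several MTUs, as with the
#' two gastrocnemius heads sharing one electrode) or be supplied directly
#' (e.g. synthesised by the hybrid optimisation).
#'
#' @param theta,omega Joint angle/velocity matrices (columns `hip`, `knee`,
#'   `ankle`).
#' @param geoms List of [mtu_geometry()] objects.
#' @param params List of [mtu_params()] objects, same order.
#' @param excitations Matrix (time x MTU) of excitations in \[0, 1\],
#'   columns named by MTU label, or a named list of per-channel envelope
#'   series to be expanded through the geometries' `recorded_channel`
#'   mapping.
#' @param passive Include passive forces?
#' @return Tibble with columns `hip`, `knee`, `ankle` (Nm).
#' @export
emg_driven_torques <- function(theta, omega, geoms, params, excitations,
                               passive = TRUE) {
  labels <- vapply(geoms, function(g) g$label, character(1))
  E <- expand_excitations(excitations, geoms)
  gains <- mtu_trial_gains(theta, omega, geoms, params, passive = passive)
  c1 <- vapply(params, `[[`, numeric(1), "c1")
  c2 <- vapply(params, `[[`, numeric(1), "c2")
  A <- vapply(params, `[[`, numeric(1), "shape_factor")
  U <- activation_filter(E, c1, c2)
  Act <- vapply(seq_along(geoms), function(i) {
    pmin(pmax(activation_nonlin(U[, i], A[i]), 0), 1)
  }, numeric(nrow(E)))
  Act <- matrix(Act, nrow = nrow(E))
  Force <- gains$gain * Act + gains$passive
  tau <- sapply(c("hip", "knee", "ankle"), function(j) {
    rowSums(gains$arms[, j, , drop = FALSE][, 1, ] * Force)
  })
  tibble::tibble(hip = tau[, "hip"], knee = tau[, "knee"], ankle = tau[, "ankle"])
}

# Accepts a T x M excitation matrix (columns = MTU labels) or a named list /
# data frame of per-channel envelopes that is expanded via recorded_channel.
expand_excitations <- function(excitations, geoms) {
  labels <- vapply(geoms, function(g) g$label, character(1))
  if (is.matrix(excitations)) {
    missing <- setdiff(labels, colnames(excitations))
    if (length(missing) > 0) {
      stop("no excitation series for MTU(s): ", paste(missing, collapse = ", "))
    }
    return(excitations[, labels, drop = FALSE])
  }
  env <- as.data.frame(excitations)
  n <- nrow(env)
  E <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  for (i in seq_along(geoms)) {
    ch <- geoms[[i]]$recorded_channel
    if (is.na(ch)) {
      stop(sprintf("MTU '%s' has no recorded channel and no supplied excitation",
                   labels[i]))
    }
    if (!ch %in% names(env)) {
      stop(sprintf("EMG channel '%s' (for MTU '%s') missing from envelopes",
                   ch, labels[i]))
    }
    E[, i] <- env[[ch]]
  }
  E
}
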