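#' Objective weights for the hybrid EMG-informed optimisation
#'
#' The hybrid objective is `F = alpha * E_trackMOM + beta * E_sumEXC +
#' gamma * E_trackEMG`, where `E_trackMOM` is the sum of squared differences
#' between model and target joint torques, `E_sumEXC` the sum of squared
#' excitations over all MTUs, and `E_trackEMG` the sum of absolute
#' deviations between adjusted and experimental excitations (recorded
#' channels only). `alpha` is fixed at 1; `beta` and `gamma` trade off
#' effort minimisation against EMG fidelity.
#'
#' @param beta,gamma Non-negative weights.
#' @return An object of class `hybrid_weights` (`alpha` fixed at 1).
#' @export
hybrid_weights <- function(beta = 0.1, gamma = 1) {
  stopifnot(beta >= 0, gamma >= 0)
  structure(list(alpha = 1, beta = beta, gamma = gamma),
            class = "hybrid_weights")
}

smooth_abs <- function(x, eps = 1e-8) sqrt(x^2 + eps^2) - eps
smooth_abs_deriv <- function(x, eps = 1e-8) x / sqrt(x^2 + eps^2)

# Frame-sequential bounded minimisation over MTU excitations with
# activation-dynamics history propagation. Shared engine behind
# excitations_from_torques() and hybrid_solve().
#
# groups: integer vector (length = #MTUs) assigning each MTU to a decision
# variable, NA = pinned at `pinned`. MTUs sharing a group share one
# excitation (an EMG channel driving several MTUs). `free` is a convenience
# logical mask expanded to one group per free MTU.
solve_excitations <- function(theta, omega, target, geoms, params,
                              w_mom = 1, beta = 0.1, gamma = 0,
                              e_exp = NULL, free = NULL, groups = NULL,
                              pinned = 0, passive = TRUE, polish = NULL,
                              maxit = 200L) {
  theta <- as.matrix(as.data.frame(theta))
  omega <- as.matrix(as.data.frame(omega))
  target <- as.matrix(as.data.frame(target))[, c("hip", "knee", "ankle"), drop = FALSE]
  n <- nrow(theta)
  m <- length(geoms)
  labels <- vapply(geoms, function(g) g$label, character(1))
  if (is.null(groups)) {
    if (is.null(free)) free <- rep(TRUE, m)
    groups <- rep(NA_integer_, m)
    groups[free] <- seq_len(sum(free))
  }
  stopifnot(length(groups) == m)
  ng <- max(groups, na.rm = TRUE)
  act_ix <- which(!is.na(groups))
  gidx <- groups[act_ix]
  expand_e <- function(z) {
    e_all <- rep(pinned, m)
    e_all[act_ix] <- z[gidx]
    e_all
  }
  gains <- mtu_trial_gains(theta, omega, geoms, params, passive = passive)
  c1 <- vapply(params, `[[`, numeric(1), "c1")
  c2 <- vapply(params, `[[`, numeric(1), "c2")
  A <- vapply(params, `[[`, numeric(1), "shape_factor")
  b1 <- c1 + c2; b2 <- c1 * c2; ag <- 1 + b1 + b2
  rec <- !is.na(vapply(geoms, function(g) g$recorded_channel, character(1)))
  if (is.null(e_exp)) e_exp <- matrix(0, n, m)
  if (is.null(polish)) polish <- (beta + gamma) <= 1e-4 * w_mom
  E <- matrix(0, n, m, dimnames = list(NULL, labels))
  tau_out <- matrix(0, n, 3, dimnames = list(NULL, c("hip", "knee", "ankle")))
  e_mom_frames <- numeric(n)
  u1 <- u2 <- rep(0, m)
  z <- rep(0.1, ng)
  # vectorised nonlinearisation with the A -> 0 limit folded in once
  lin <- abs(A) < 1e-6
  A_s <- ifelse(lin, -1, A)
  den <- expm1(A_s)
  nl <- function(u) {
    v <- expm1(A_s * u) / den
    v[lin] <- u[lin]
    v
  }
  nld <- function(u) {
    v <- A_s * exp(A_s * u) / den
    v[lin] <- 1
    v
  }
  act_mask <- seq_len(m) %in% act_ix
  collapse_g <- function(g_all) {
    as.numeric(rowsum(g_all[act_ix], gidx, reorder = TRUE))
  }
  for (t in seq_len(n)) {
    # frame 1: filter history at the steady state of the frame-1 excitation
    # (pre-activation before heel strike), i.e. u = e; matches
    # activation_filter()'s initialisation exactly
    if (t == 1L) {
      ag_t <- rep(1, m)
      h <- rep(0, m)
    } else {
      ag_t <- ag
      h <- -b1 * u1 - b2 * u2
    }
    gt <- gains$gain[t, ]
    Rt <- t(gains$arms[t, , ]) # m x 3
    tau_pas <- colSums(Rt * gains$passive[t, ])
    tstar <- target[t, ]
    gmask <- rec & !is.na(groups)
    obj <- function(zz) {
      e_all <- expand_e(zz)
      a <- nl(ag_t * e_all + h)
      tau <- as.numeric(colSums(Rt * (gt * a))) + tau_pas
      d <- tau - tstar
      val <- w_mom * sum(d^2) + beta * sum(e_all[act_ix]^2)
      if (gamma > 0) {
        val <- val + gamma * sum(smooth_abs((e_all - e_exp[t, ])[gmask]))
      }
      val
    }
    grad <- function(zz) {
      e_all <- expand_e(zz)
      u <- ag_t * e_all + h
      a <- nl(u)
      tau <- as.numeric(colSums(Rt * (gt * a))) + tau_pas
      d <- tau - tstar
      # dtau_j/de_i = R[i, j] * gt_i * nl'(u_i) * ag_i
      dtde <- Rt * (gt * nld(u) * ag_t) # m x 3
      g_all <- 2 * w_mom * as.numeric(dtde %*% d) + 2 * beta * e_all
      g_all[!act_mask] <- 0
      if (gamma > 0) {
        gg <- numeric(m)
        gg[gmask] <- gamma * smooth_abs_deriv((e_all - e_exp[t, ])[gmask])
        g_all <- g_all + gg
      }
      collapse_g(g_all)
    }
    start <- pmin(pmax(z, 1e-6), 1 - 1e-6)
    fit <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                        lower = 0, upper = 1,
                        control = list(maxit = maxit,
                                       factr = if (polish) 1e4 else 10))
    z <- fit$par
    if (polish) {
      # Sequential linearised refinement, candidate-based so a failed
      # refinement can never degrade the L-BFGS-B solution: (a) Gauss-Newton
      # projection onto the torque-tracking manifold; (b) in effort mode
      # (beta > 0, no EMG term) additionally a damped move towards the
      # minimum-weighted-norm excitation achieving the target under the
      # local linearisation (weights = group sizes, matching beta * sum
      # e^2), re-projected afterwards. The candidate with the lower full
      # objective wins.
      n_g <- as.numeric(table(factor(gidx, levels = seq_len(ng))))
      lin_step <- function(zz, effort) {
        e_all <- expand_e(zz)
        u <- ag_t * e_all + h
        tau <- as.numeric(colSums(Rt * (gt * nl(u)))) + tau_pas
        d <- tstar - tau
        Jm <- Rt * (gt * nld(u) * ag_t) # m x 3
        Jz <- rowsum(Jm[act_ix, , drop = FALSE], gidx, reorder = TRUE)
        out <- try({
          if (effort) {
            JDJ <- crossprod(Jz / n_g, Jz)
            rhs <- as.numeric(crossprod(Jz, zz)) + d
            z_new <- as.numeric((Jz / n_g) %*% solve(JDJ + diag(1e-12, 3), rhs))
            zz + 0.7 * (z_new - zz)
          } else {
            zz + as.numeric(Jz %*% solve(crossprod(Jz) + diag(1e-12, 3), d))
          }
        }, silent = TRUE)
        if (inherits(out, "try-error")) return(list(z = zz, d2 = sum(d^2), fail = TRUE))
        list(z = pmin(pmax(out, 0), 1), d2 = sum(d^2), fail = FALSE)
      }
      track_polish <- function(zz) {
        for (it in 1:10) {
          st_ <- lin_step(zz, FALSE)
          if (st_$fail || st_$d2 < 1e-22) break
          zz <- st_$z
        }
        zz
      }
      zA <- track_polish(z)
      z <- zA
      if (beta > 0 && gamma == 0) {
        zB <- zA
        for (it in 1:12) {
          st_ <- lin_step(zB, TRUE)
          if (st_$fail) break
          zB <- st_$z
        }
        zB <- track_polish(zB)
        if (obj(zB) < obj(zA)) z <- zB
      }
    }
    e_all <- expand_e(z)
    u <- ag_t * e_all + h
    tau <- as.numeric(colSums(Rt * (gt * nl(u)))) + tau_pas
    E[t, ] <- e_all
    tau_out[t, ] <- tau
    e_mom_frames[t] <- sum((tau - tstar)^2)
    if (t == 1L) {
      u2 <- u1 <- u # steady-state pre-stance history
    } else {
      u2 <- u1
      u1 <- u
    }
  }
  e_sum <- sum(E^2)
  e_emg <- sum(abs((E - e_exp)[, rec, drop = FALSE]))
  list(
    excitations = E,
    torques = tibble::tibble(hip = tau_out[, 1], knee = tau_out[, 2],
                             ankle = tau_out[, 3]),
    e_mom_frames = e_mom_frames,
    breakdown = list(E_trackMOM = sum(e_mom_frames), E_sumEXC = e_sum,
                     E_trackEMG = e_emg),
    recorded = rec
  )
}

#' Minimum-effort excitations reproducing target joint torques
#'
#' Frame-by-frame minimisation of the sum of squared excitations subject to
#' the MTU-model torques matching the targets (enforced as a heavily
#' weighted tracking term plus a Gauss-Newton projection), with activation
#' dynamics propagated across frames. Used by the synthetic-trial generator
#' to derive ground-truth neural drive from inverse-dynamics torques.
#'
#' @param theta,omega Joint angle/velocity matrices.
#' @param target Target torque series (columns `hip`, `knee`, `ankle`, Nm).
#' @param geoms,params MTU geometry and parameter lists.
#' @param groups Integer vector assigning each MTU to a shared excitation
#'   variable (`NA` = held at zero). Defaults to one variable per recorded
#'   EMG channel, so muscles sharing an electrode share one excitation and
#'   unrecorded MTUs stay silent.
#' @param passive Include passive forces?
#' @param tol Maximum admissible per-frame torque residual (Nm); an
#'   infeasible frame raises an error naming the frame and residual.
#' @return Matrix (time x MTU) of excitations in \[0, 1\], with the solver
#'   output attached as attribute `"solution"`.
#' @export
excitations_from_torques <- function(theta, omega, target, geoms, params,
                                     groups = NULL, passive = TRUE,
                                     tol = 1e-3) {
  if (is.null(groups)) {
    # MTUs sharing a recorded EMG channel share one excitation variable,
    # so each channel envelope is well defined; unrecorded MTUs stay silent
    ch <- vapply(geoms, function(g) g$recorded_channel, character(1))
    groups <- match(ch, unique(stats::na.omit(ch)))
  }
  sol <- solve_excitations(theta, omega, target, geoms, params,
                           w_mom = 1e6, beta = 1, gamma = 0,
                           groups = groups, passive = passive, polish = TRUE)
  resid <- sqrt(sol$e_mom_frames)
  if (any(resid > tol)) {
    worst <- which.max(resid)
    stop(sprintf(
      "target torques infeasible within [0,1] excitations at frame %d (residual %.3g Nm)",
      worst, resid[worst]))
  }
  structure(sol$excitations, solution = sol)
}

#' Hybrid EMG-informed static optimisation of muscle excitations
#'
#' Per-frame bounded minimisation of the hybrid objective over all MTU
#' excitations: torque tracking (`alpha = 1`), excitation effort (`beta`)
#' and fidelity to the experimental envelopes for recorded MTUs (`gamma`),
#' with activation-dynamics history propagated using the adjusted
#' excitations of previous frames. Recorded MTUs are pulled towards their
#' experimental envelopes; unrecorded MTUs are synthesised, appearing only
#' in the effort term.
#'
#' @param theta,omega Joint angle/velocity matrices.
#' @param target_torques Inverse-dynamics torque series to track (Nm).
#' @param geoms,params MTU geometry and calibrated parameter lists.
#' @param envelopes Named list/data frame of recorded per-channel EMG
#'   envelopes (experimental excitations).
#' @param weights A [hybrid_weights()].
#' @param passive Include passive forces?
#' @param maxit Per-frame optimiser iteration cap.
#' @return List with `excitations` (adjusted + synthesised, time x MTU),
#'   `torques` (tibble), `breakdown` (`E_trackMOM`, `E_sumEXC`,
#'   `E_trackEMG`, and their weighted total `F`), and `e_mom_frames`.
#' @export
hybrid_solve <- function(theta, omega, target_torques, geoms, params,
                         envelopes, weights = hybrid_weights(),
                         passive = TRUE, maxit = 200L) {
  stopifnot(inherits(weights, "hybrid_weights"))
  n <- nrow(as.data.frame(theta))
  stopifnot(nrow(as.data.frame(target_torques)) == n)
  e_exp <- excitation_matrix_from_envelopes(envelopes, geoms, n)
  sol <- solve_excitations(theta, omega, target_torques, geoms, params,
                           w_mom = weights$alpha, beta = weights$beta,
                           gamma = weights$gamma, e_exp = e_exp,
                           free = rep(TRUE, length(geoms)),
                           passive = passive, maxit = maxit)
  bd <- sol$breakdown
  bd$F <- weights$alpha * bd$E_trackMOM + weights$beta * bd$E_sumEXC +
    weights$gamma * bd$E_trackEMG
  sol$breakdown <- bd
  sol$weights <- weights
  sol
}

# Expand per-channel envelopes to a time x MTU matrix; unrecorded MTUs 0.
excitation_matrix_from_envelopes <- function(envelopes, geoms, n) {
  env <- as.data.frame(envelopes)
  labels <- vapply(geoms, function(g) g$label, character(1))
  E <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  for (i in seq_along(geoms)) {
    ch <- geoms[[i]]$recorded_channel
    if (!is.na(ch)) {
      if (!ch %in% names(env)) {
        stop(sprintf("EMG channel '%s' missing from envelopes", ch))
      }
      E[, i] <- env[[ch]]
    }
  }
  E
}

pack_params <- function(params) {
  unlist(lapply(params, function(p) unlist(p[names(mtu_param_bounds())])))
}

unpack_params <- function(x, m) {
  nms <- names(mtu_param_bounds())
  k <- length(nms)
  lapply(seq_len(m), function(i) {
    v <- x[((i - 1) * k + 1):(i * k)]
    names(v) <- nms
    structure(as.list(v), class = "mtu_params")
  })
}

#' Calibrate musculotendon parameters against measured torques
#'
#' Bounded minimisation (L-BFGS-B over the admissible parameter box, see
#' [mtu_param_bounds()]) of the squared difference between the EMG-driven
#' model torques and the measured (inverse-dynamics) torques, pooled over
#' the calibration trials. Deterministic for a fixed seed; the seed controls
#' the randomised second start point used to guard against local minima.
#'
#' @param trials List of calibration trials; each a list with `theta`,
#'   `omega` (matrices), `envelopes` (per-channel EMG envelopes) and
#'   `torques` (measured joint torques, Nm).
#' @param geoms MTU geometry list.
#' @param init Initial [mtu_params()] list (defaults to box midpoints).
#' @param seed Integer seed.
#' @param mass Subject mass (kg), used to express the objective in
#'   (Nm/kg)^2 for conditioning.
#' @param maxit Iteration cap per start.
#' @param n_starts Number of optimiser starts (first = `init`, the others
#'   seeded random points in the box).
#' @param passive Include passive forces?
#' @return List with `params` (calibrated [mtu_params()] list), `objective`
#'   (final value), `objective_initial`, `trace` (per-start results) and
#'   `convergence`.
#' @export
calibrate_mtu_params <- function(trials, geoms, init = NULL, seed = 1L,
                                 mass = 75, maxit = 150L, n_starts = 2L,
                                 passive = TRUE) {
  m <- length(geoms)
  b <- mtu_param_bounds()
  eps <- 1e-3
  lower <- rep(vapply(b, `[`, numeric(1), 1), m)
  upper <- rep(vapply(b, `[`, numeric(1), 2), m)
  # strict bounds for the filter coefficients
  ix_c <- rep(names(b) %in% c("c1", "c2"), m)
  lower[ix_c] <- lower[ix_c] + eps
  upper[ix_c] <- upper[ix_c] - eps
  if (is.null(init)) {
    init <- unpack_params((lower + upper) / 2, m)
  }
  # shape-factor upper bound kept strictly negative so the nonlinearisation
  # stays differentiable in its closed form
  ix_a <- rep(names(b) == "shape_factor", m)
  upper[ix_a] <- upper[ix_a] - eps
  pre <- lapply(trials, function(tr) {
    theta <- as.matrix(as.data.frame(tr$theta))
    omega <- as.matrix(as.data.frame(tr$omega))
    sts <- lapply(geoms, function(g) mtu_state(theta, omega, g))
    arms <- array(0, c(nrow(theta), 3, m),
                  dimnames = list(NULL, c("hip", "knee", "ankle"), NULL))
    for (i in seq_len(m)) arms[, names(geoms[[i]]$r0), i] <- sts[[i]]$r
    list(
      l_mt = vapply(sts, `[[`, numeric(nrow(theta)), "l_mt"),
      v_mt = vapply(sts, `[[`, numeric(nrow(theta)), "v_mt"),
      arms = arms,
      E = excitation_matrix_from_envelopes(
        tr$envelopes, geoms, nrow(theta)),
      tau = as.matrix(as.data.frame(tr$torques))[, c("hip", "knee", "ankle")]
    )
  })
  base_slack <- vapply(geoms, `[[`, numeric(1), "base_slack")
  base_l0 <- vapply(geoms, `[[`, numeric(1), "base_l0")
  fmax <- vapply(geoms, `[[`, numeric(1), "fmax")
  nms <- names(b)
  k_par <- length(nms)
  # fast objective: same model as emg_driven_torques(), evaluated with
  # precomputed geometry and pure matrix operations
  objective <- function(x) {
    P <- matrix(x, nrow = k_par)
    ts <- P[1, ] * base_slack
    l0 <- P[2, ] * base_l0
    s <- P[3, ] * fmax
    c1 <- P[4, ]; c2 <- P[5, ]; A <- P[6, ]
    val <- 0
    for (tr in pre) {
      U <- activation_filter(tr$E, c1, c2)
      a <- sweep(expm1(sweep(U, 2, A, "*")), 2, expm1(A), "/")
      a <- pmin(pmax(a, 0), 1)
      l_m <- sweep(tr$l_mt, 2, ts, "-")
      if (any(l_m <= 0)) return(1e6)
      lnorm <- sweep(l_m, 2, l0, "/")
      vnorm <- sweep(tr$v_mt, 2, 10 * l0, "/")
      fl <- exp(-((lnorm - 1) / 0.45)^2)
      fv <- 1.6 / (1 + 0.6 * exp(-4 * vnorm))
      fp <- if (passive) fp_curve(lnorm) else 0
      if (passive) dim(fp) <- dim(lnorm)
      Force <- sweep(a * fl * fv + fp, 2, s, "*")
      Force <- pmax(Force, 0)
      for (j in 1:3) {
        tau_j <- rowSums(tr$arms[, j, ] * Force)
        val <- val + mean((tau_j - tr$tau[, j])^2)
      }
    }
    val / (3 * mass^2)
  }
  x0 <- pmin(pmax(pack_params(init), lower), upper)
  f0 <- objective(x0)
  rng <- local_rng_seed(seed)
  starts <- list(x0)
  if (n_starts > 1L) {
    for (k in 2:n_starts) {
      starts[[k]] <- lower + stats::runif(length(lower)) * (upper - lower)
    }
  }
  fits <- lapply(starts, function(s) {
    stats::optim(s, objective, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = maxit,
                                parscale = (upper - lower),
                                ndeps = 1e-4 * (upper - lower)))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (any(best$par < lower - 1e-9) || any(best$par > upper + 1e-9)) {
    stop("internal error: calibrated parameters violate their bounds")
  }
  list(
    params = unpack_params(best$par, m),
    objective = best$value,
    objective_initial = f0,
    trace = tibble::tibble(
      start = seq_along(fits),
      value = vapply(fits, `[[`, numeric(1), "value"),
      convergence = vapply(fits, `[[`, numeric(1), "convergence")
    ),
    convergence = best$convergence
  )
}

#' Select hybrid objective weights on calibration trials
#'
#' Evaluates [hybrid_solve()] on the calibration trials for every candidate
#' `(beta, gamma)` pair and selects the candidate minimising the sum of
#' min-max-normalised torque-tracking (`E_trackMOM`) and EMG-tracking
#' (`E_trackEMG`) terms, i.e. the pair under which both reach jointly low
#' values. The full grid table is returned for inspection.
#'
#' @param trials Calibration trials as in [calibrate_mtu_params()], each
#'   additionally providing its tracking `torques`.
#' @param geoms,params MTU geometry and calibrated parameters.
#' @param grid Data frame with columns `beta`, `gamma`.
#' @param passive Include passive forces?
#' @return List with `weights` (a [hybrid_weights()]) and `grid` (tibble of
#'   all candidates with their objective terms and the normalised score).
#' @export
tune_beta_gamma <- function(trials, geoms, params, grid, passive = TRUE) {
  grid <- as.data.frame(grid)
  stopifnot(nrow(grid) >= 1, all(c("beta", "gamma") %in% names(grid)))
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    mom <- emg <- 0
    for (tr in trials) {
      sol <- hybrid_solve(tr$theta, tr$omega, tr$torques, geoms, params,
                          tr$envelopes,
                          hybrid_weights(grid$beta[i], grid$gamma[i]),
                          passive = passive)
      mom <- mom + sol$breakdown$E_trackMOM
      emg <- emg + sol$breakdown$E_trackEMG
    }
    tibble::tibble(beta = grid$beta[i], gamma = grid$gamma[i],
                   E_trackMOM = mom, E_trackEMG = emg)
  })
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) < 1e-300) return(rep(0, length(x)))
    (x - rng[1]) / diff(rng)
  }
  res$score <- norm01(res$E_trackMOM) + norm01(res$E_trackEMG)
  best <- which.min(res$score)
  list(weights = hybrid_weights(res$beta[best], res$gamma[best]), grid = res)
}
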