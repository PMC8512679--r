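#' Anthropometric segment parameters for the planar stance-leg model
#'
#' Returns masses, lengths, centre-of-mass fractions and moments of inertia
#' for the four bodies of the planar sagittal model: foot, shank, thigh and a
#' HAT lump (head-arms-trunk plus the swing leg) attached at the hip. The
#' default table uses the classical cadaver-based body-segment fractions of
#' Winter's *Biomechanics and Motor Control of Human Movement* (4th ed.,
#' Table 4.1): foot 1.45% of body mass, shank 4.65%, thigh 10.0%; segment
#' lengths 15.2%, 24.6% and 24.5% of stature; COM at 50%, 43.3% and 43.3% of
#' segment length from the proximal end; radii of gyration about the COM of
#' 47.5%, 30.2% and 32.3% of segment length. The HAT lump absorbs the
#' remaining 83.9% of body mass so segment masses always sum to the subject
#' mass exactly; it is modelled as a point mass offset vertically above the
#' hip (no angular dynamics, since the trunk is assumed upright).
#'
#' @param mass Subject mass in kg (> 0).
#' @param height Subject stature in m (> 0).
#' @param table_id Anthropometric table identifier; only `"winter"` is
#'   available.
#'
#' @return An object of class `segment_params`: a list with per-segment
#'   `mass` (kg), `length` (m), `com_frac`, `inertia` (kg m^2), the foot
#'   geometry (ankle height, heel/toe offsets), the HAT offset, and `g`.
#' @export
#' @examples
#' segment_parameters(70, 1.75)
segment_parameters <- function(mass, height, table_id = "winter") {
  stopifnot(mass > 0, height > 0)
  if (!identical(table_id, "winter")) {
    stop("unknown anthropometric table: ", table_id)
  }
  frac_m <- c(foot = 0.0145, shank = 0.0465, thigh = 0.100)
  frac_l <- c(foot = 0.152, shank = 0.246, thigh = 0.245)
  com_frac <- c(foot = 0.50, shank = 0.433, thigh = 0.433)
  rog <- c(foot = 0.475, shank = 0.302, thigh = 0.323)
  m <- frac_m * mass
  len <- frac_l * height
  inertia <- m * (rog * len)^2
  structure(list(
    mass = c(m, hat = mass - sum(m)),
    length = len,
    com_frac = com_frac,
    inertia = c(inertia, hat = 0), # HAT point mass, upright: no I*alpha term
    ankle_height = 0.039 * height,
    # foot-frame offsets relative to the ankle (x along the sole, y up)
    heel_offset = c(-0.25 * len[["foot"]], -0.039 * height),
    toe_offset = c(0.75 * len[["foot"]], -0.039 * height),
    foot_com_offset = c(0.25 * len[["foot"]], -0.5 * 0.039 * height),
    hat_offset = 0.30 * height, # HAT COM this far above the hip
    g = 9.81,
    table_id = table_id,
    subject_mass = mass,
    subject_height = height
  ), class = "segment_params")
}

rot2 <- function(px, py, ang) {
  list(x = cos(ang) * px - sin(ang) * py,
       y = sin(ang) * px + cos(ang) * py)
}

# z-component of the planar cross product r x F
cross_z <- function(rx, ry, fx, fy) rx * fy - ry * fx

#' Build the planar stance-leg kinematic chain from joint angles
#'
#' Joint angles use the torque-conjugate sign convention of the whole
#' package: positive hip/knee angle = extension, positive ankle angle =
#' plantarflexion (so clinical flexion/dorsiflexion are the negatives).
#' Given the hip trajectory and the three joint-angle series, all joint
#' centres (hip, knee, ankle), heel and toe landmarks, segment COM positions
#' and segment orientation angles are computed, and velocities/accelerations
#' are obtained with [differentiate()] so that forward and inverse dynamics
#' see numerically identical derivatives.
#'
#' @param theta Data frame or list with series `hip`, `knee`, `ankle` (rad).
#' @param hip_x,hip_y Hip joint-centre trajectory (m).
#' @param seg A [segment_parameters()] object.
#' @param fs Sampling frequency in Hz.
#'
#' @return An object of class `stance_kinematics`: per-point position /
#'   velocity / acceleration series and per-segment orientation angle,
#'   angular velocity and acceleration series.
#' @export
build_leg_kinematics <- function(theta, hip_x, hip_y, seg, fs) {
  n <- length(hip_x)
  stopifnot(length(theta$hip) == n, length(theta$knee) == n,
            length(theta$ankle) == n, length(hip_y) == n)
  d_th <- -theta$hip                    # thigh angle from straight-down
  d_sh <- -theta$hip + theta$knee       # shank angle from straight-down
  eta <- d_sh - theta$ankle             # foot sole angle from horizontal
  l_th <- seg$length[["thigh"]]; l_sh <- seg$length[["shank"]]
  knee_x <- hip_x + l_th * sin(d_th); knee_y <- hip_y - l_th * cos(d_th)
  ank_x <- knee_x + l_sh * sin(d_sh); ank_y <- knee_y - l_sh * cos(d_sh)
  heel <- rot2(seg$heel_offset[1], seg$heel_offset[2], eta)
  toe <- rot2(seg$toe_offset[1], seg$toe_offset[2], eta)
  fcom <- rot2(seg$foot_com_offset[1], seg$foot_com_offset[2], eta)
  pts <- list(
    hip = list(x = hip_x, y = hip_y),
    knee = list(x = knee_x, y = knee_y),
    ankle = list(x = ank_x, y = ank_y),
    heel = list(x = ank_x + heel$x, y = ank_y + heel$y),
    toe = list(x = ank_x + toe$x, y = ank_y + toe$y),
    com_foot = list(x = ank_x + fcom$x, y = ank_y + fcom$y),
    com_shank = list(x = knee_x + seg$com_frac[["shank"]] * (ank_x - knee_x),
                     y = knee_y + seg$com_frac[["shank"]] * (ank_y - knee_y)),
    com_thigh = list(x = hip_x + seg$com_frac[["thigh"]] * (knee_x - hip_x),
                     y = hip_y + seg$com_frac[["thigh"]] * (knee_y - hip_y)),
    com_hat = list(x = hip_x, y = hip_y + seg$hat_offset)
  )
  pts <- lapply(pts, function(p) {
    p$vx <- differentiate(p$x, fs); p$vy <- differentiate(p$y, fs)
    p$ax <- differentiate(p$vx, fs); p$ay <- differentiate(p$vy, fs)
    p
  })
  angs <- list(foot = eta, shank = d_sh, thigh = d_th)
  angs <- lapply(angs, function(a) {
    w <- differentiate(a, fs)
    list(ang = a, omega = w, alpha = differentiate(w, fs))
  })
  structure(list(points = pts, segments = angs, theta = theta,
                 fs = fs, n = n), class = "stance_kinematics")
}

#' Forward synthesis of dynamically consistent ground reactions
#'
#' Computes the anterio-posterior and vertical ground reaction force and the
#' AP centre of pressure implied by whole-body planar dynamics:
#' \eqn{F = \sum_s m_s (a_s - g)} summed over foot, shank, thigh and HAT
#' lump, and the COP from the moment balance of all segment weights,
#' inertial forces and rotational inertia terms about the ground line.
#' Inverse dynamics run on the resulting (kinematics, GRF, COP) triple
#' reproduces any torque series computed from them, which is the package's
#' central consistency oracle.
#'
#' @param kin A [build_leg_kinematics()] object.
#' @param seg A [segment_parameters()] object.
#' @param clamp_tol Vertical forces more negative than `-clamp_tol` N raise
#'   an error (the single-stance assumption is violated); tiny negatives are
#'   clamped to zero with a warning.
#'
#' @return A tibble with `grf_ap`, `grf_v` (N), `cop_x` (lab frame, m) and
#'   `cop_ap` (m, relative to the heel).
#' @export
forward_ground_reaction <- function(kin, seg, clamp_tol = 1e-6) {
  segs <- c("foot", "shank", "thigh", "hat")
  coms <- paste0("com_", segs)
  m <- seg$mass[segs]
  g <- seg$g
  grf_ap <- grf_v <- mom <- numeric(kin$n)
  for (i in seq_along(segs)) {
    p <- kin$points[[coms[i]]]
    grf_ap <- grf_ap + m[i] * p$ax
    grf_v <- grf_v + m[i] * (p$ay + g)
    mom <- mom + p$x * m[i] * (p$ay + g) - p$y * m[i] * p$ax
  }
  for (s in c("foot", "shank", "thigh")) {
    mom <- mom + seg$inertia[[s]] * kin$segments[[s]]$alpha
  }
  if (any(grf_v < -clamp_tol)) {
    stop(sprintf(
      "net vertical ground reaction is negative (min %.3g N): stance assumption violated",
      min(grf_v)))
  }
  if (any(grf_v < 0)) {
    warning("clamping tiny negative vertical GRF samples to zero")
    grf_v <- pmax(grf_v, 0)
  }
  cop_x <- mom / grf_v
  tibble::tibble(grf_ap = grf_ap, grf_v = grf_v, cop_x = cop_x,
                 cop_ap = cop_x - kin$points$heel$x)
}

#' Newton-Euler inverse dynamics of the planar stance leg
#'
#' Distal-to-proximal recursion (foot, then shank, then thigh) propagating
#' joint reaction forces and moments. The GRF acts at the COP on the ground
#' line (y = 0); the COP is supplied heel-referenced and converted to the
#' lab frame internally. Output torques use the convention positive =
#' extension (hip, knee) / plantarflexion (ankle), i.e. they are conjugate
#' to the package's joint-angle convention so that muscle-model torques and
#' inverse-dynamics torques are directly comparable.
#'
#' @param kin A [build_leg_kinematics()] object.
#' @param grf_ap,grf_v GRF series in N.
#' @param cop_ap COP series in m, relative to the heel marker.
#' @param seg A [segment_parameters()] object.
#' @param mass_normalise Divide torques by subject mass (Nm/kg)?
#' @param cop_warn Warn if the COP leaves the heel-toe band by more than
#'   2 cm (plausibility check; late-stance COP near the toe is expected).
#'
#' @return A tibble with columns `hip`, `knee`, `ankle` (Nm, or Nm/kg when
#'   `mass_normalise = TRUE`).
#' @export
inverse_dynamics <- function(kin, grf_ap, grf_v, cop_ap, seg,
                             mass_normalise = FALSE, cop_warn = TRUE) {
  n <- kin$n
  stopifnot(length(grf_ap) == n, length(grf_v) == n, length(cop_ap) == n)
  for (nm in c("grf_ap", "grf_v", "cop_ap")) {
    if (!all(is.finite(get(nm)))) stop("non-finite values in ", nm)
  }
  pts <- kin$points
  cop_x <- pts$heel$x + cop_ap
  if (cop_warn) {
    lo <- pts$heel$x - 0.02
    hi <- pts$toe$x + 0.02
    if (any(cop_x < lo | cop_x > hi)) {
      warning(sprintf(
        "COP outside the heel-toe band on %d of %d samples", sum(cop_x < lo | cop_x > hi), n))
    }
  }
  g <- seg$g
  mz <- function(rx, ry, fx, fy) rx * fy - ry * fx
  # --- foot ---
  mf <- seg$mass[["foot"]]
  fc <- pts$com_foot
  # reaction of shank on foot at the ankle
  ra_x <- mf * fc$ax - grf_ap
  ra_y <- mf * fc$ay + mf * g - grf_v
  tau_a <- seg$inertia[["foot"]] * kin$segments$foot$alpha -
    mz(cop_x - fc$x, 0 - fc$y, grf_ap, grf_v) -
    mz(pts$ankle$x - fc$x, pts$ankle$y - fc$y, ra_x, ra_y)
  # --- shank ---
  ms <- seg$mass[["shank"]]
  sc <- pts$com_shank
  rk_x <- ms * sc$ax + ra_x
  rk_y <- ms * sc$ay + ms * g + ra_y
  tau_k <- seg$inertia[["shank"]] * kin$segments$shank$alpha + tau_a -
    mz(pts$knee$x - sc$x, pts$knee$y - sc$y, rk_x, rk_y) -
    mz(pts$ankle$x - sc$x, pts$ankle$y - sc$y, -ra_x, -ra_y)
  # --- thigh ---
  mt <- seg$mass[["thigh"]]
  tc <- pts$com_thigh
  rh_x <- mt * tc$ax + rk_x
  rh_y <- mt * tc$ay + mt * g + rk_y
  tau_h <- seg$inertia[["thigh"]] * kin$segments$thigh$alpha + tau_k -
    mz(pts$hip$x - tc$x, pts$hip$y - tc$y, rh_x, rh_y) -
    mz(pts$knee$x - tc$x, pts$knee$y - tc$y, -rk_x, -rk_y)
  scale <- if (mass_normalise) 1 / seg$subject_mass else 1
  tibble::tibble(hip = -tau_h * scale, knee = tau_k * scale,
                 ankle = -tau_a * scale)
}

#' Residual of the HAT-lump balance after the inverse-dynamics recursion
#'
#' For a dynamically consistent trial the hip reaction and torque delivered
#' by the recursion must exactly balance the HAT lump's own Newton-Euler
#' equations; the returned moment residual is therefore a machine-precision
#' zero for generator output and a diagnostic for inconsistent inputs.
#'
#' @inheritParams inverse_dynamics
#' @return Maximum absolute HAT moment residual (Nm).
#' @keywords internal
hat_moment_residual <- function(kin, grf_ap, grf_v, cop_ap, seg) {
  pts <- kin$points
  cop_x <- pts$heel$x + cop_ap
  g <- seg$g
  # reconstruct hip reaction by force balance over the leg
  rh_x <- rh_y <- numeric(kin$n)
  for (s in c("foot", "shank", "thigh")) {
    p <- pts[[paste0("com_", s)]]
    rh_x <- rh_x + seg$mass[[s]] * p$ax
    rh_y <- rh_y + seg$mass[[s]] * (p$ay + g)
  }
  rh_x <- rh_x - grf_ap
  rh_y <- rh_y - grf_v
  tau <- inverse_dynamics(kin, grf_ap, grf_v, cop_ap, seg, cop_warn = FALSE)
  hc <- pts$com_hat
  mh <- seg$mass[["hat"]]
  # Moment about the HAT COM: 0 = tau_h_z + (r_hip - r_com) x (-R_h); the
  # recursion reports hip = -tau_h_z. Point mass: no I*alpha term; gravity
  # and inertial forces act through the COM.
  mres <- tau$hip + cross_z(pts$hip$x - hc$x, pts$hip$y - hc$y, -rh_x, -rh_y)
  # Force balance: m_h a = -R_h - m_h g * yhat
  fres_x <- mh * hc$ax + rh_x
  fres_y <- mh * (hc$ay + g) + rh_y
  max(abs(mres), abs(fres_x), abs(fres_y))
}
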