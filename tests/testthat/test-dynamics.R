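test_that("segment parameters close the mass balance and scale linearly", {
  seg <- segment_parameters(70, 1.75)
  expect_equal(sum(seg$mass), 70)
  expect_equal(seg$mass[["foot"]], 70 * 0.0145) # Winter table constant
  seg2 <- segment_parameters(140, 1.75)
  expect_equal(seg2$mass, seg$mass * 2)
  expect_equal(seg2$inertia[c("foot", "shank", "thigh")],
               seg$inertia[c("foot", "shank", "thigh")] * 2)
  expect_error(segment_parameters(70, 1.75, "dempster"), "unknown")
})

test_that("static standing: vertical force equals weight, COP sits under the COM", {
  seg <- segment_parameters(80, 1.80)
  kin <- static_kinematics(seg)
  fgr <- forward_ground_reaction(kin, seg)
  expect_equal(fgr$grf_v, rep(80 * 9.81, kin$n), tolerance = 1e-9)
  expect_equal(fgr$grf_ap, rep(0, kin$n), tolerance = 1e-9)
  com_x <- Reduce(`+`, lapply(c("foot", "shank", "thigh", "hat"), function(s) {
    seg$mass[[s]] * kin$points[[paste0("com_", s)]]$x
  })) / sum(seg$mass)
  # static moment balance: COP is the ground projection of the COM,
  # heel-referenced COP = COM offset ahead of the heel
  expect_equal(fgr$cop_ap, com_x - kin$points$heel$x, tolerance = 1e-9)
})

test_that("static ankle torque: massless foot, 700 N at 5 cm gives 35 Nm", {
  seg <- segment_parameters(70, 1.72)
  seg$mass[["foot"]] <- 0
  seg$inertia[["foot"]] <- 0
  kin <- static_kinematics(seg)
  n <- kin$n
  cop_ap <- (kin$points$ankle$x + 0.05) - kin$points$heel$x
  tau <- inverse_dynamics(kin, rep(0, n), rep(700, n), cop_ap, seg,
                          cop_warn = FALSE)
  expect_equal(tau$ankle, rep(35, n), tolerance = 1e-9)
  # anterior COP shift changes the ankle torque by exactly GRF_V * delta
  tau2 <- inverse_dynamics(kin, rep(0, n), rep(700, n), cop_ap + 0.01, seg,
                           cop_warn = FALSE)
  expect_equal(tau2$ankle - tau$ankle, rep(700 * 0.01, n), tolerance = 1e-9)
})

test_that("round-trip: inverse dynamics recovers generator torques exactly", {
  tr <- fix_trial()
  sub <- fix_subject()
  tau <- inverse_dynamics(tr$truth$kin, tr$truth$grf$grf_ap,
                          tr$truth$grf$grf_v, tr$truth$cop$cop_ap / 1000,
                          sub$seg, cop_warn = FALSE)
  expect_lt(max(abs(as.matrix(tau) - as.matrix(tr$truth$torques))), 1e-8)
})

test_that("COP perturbations and GRF perturbations propagate differently", {
  tr <- fix_trial()
  sub <- fix_subject()
  kin <- tr$truth$kin
  grf_ap <- tr$truth$grf$grf_ap
  grf_v <- tr$truth$grf$grf_v
  cop <- tr$truth$cop$cop_ap / 1000
  base <- inverse_dynamics(kin, grf_ap, grf_v, cop, sub$seg, cop_warn = FALSE)
  # COP perturbation enters through the foot's GRF moment term only:
  # every joint torque shifts by exactly GRF_V * delta
  dcop <- inverse_dynamics(kin, grf_ap, grf_v, cop + 0.01, sub$seg,
                           cop_warn = FALSE)
  expect_equal(dcop$ankle - base$ankle, grf_v * 0.01, tolerance = 1e-9)
  expect_equal(abs(dcop$knee - base$knee), abs(grf_v * 0.01), tolerance = 1e-9)
  # a GRF error grows along the distal-to-proximal recursion: the hip,
  # solved last, moves more than the ankle, solved first
  dgrf <- inverse_dynamics(kin, grf_ap + 10, grf_v, cop, sub$seg,
                           cop_warn = FALSE)
  expect_gt(mean(abs(dgrf$hip - base$hip)), mean(abs(dgrf$ankle - base$ankle)))
})

test_that("doubling GRF with massless segments doubles all torques", {
  seg <- segment_parameters(75, 1.75)
  for (s in c("foot", "shank", "thigh")) {
    seg$mass[[s]] <- 0
    seg$inertia[[s]] <- 0
  }
  kin <- static_kinematics(seg)
  n <- kin$n
  cop_ap <- (kin$points$ankle$x + 0.03) - kin$points$heel$x
  t1 <- inverse_dynamics(kin, rep(20, n), rep(400, n), cop_ap, seg,
                         cop_warn = FALSE)
  t2 <- inverse_dynamics(kin, rep(40, n), rep(800, n), cop_ap, seg,
                         cop_warn = FALSE)
  expect_equal(as.matrix(t2), 2 * as.matrix(t1), tolerance = 1e-9)
})

test_that("non-finite force inputs are rejected by channel name", {
  tr <- fix_trial()
  sub <- fix_subject()
  bad <- tr$truth$grf$grf_v
  bad[3] <- NA
  expect_error(
    inverse_dynamics(tr$truth$kin, tr$truth$grf$grf_ap, bad,
                     tr$truth$cop$cop_ap / 1000, sub$seg, cop_warn = FALSE),
    "grf_v")
})
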