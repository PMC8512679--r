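---
title: "Models and methods behind gaittorque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gaittorque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaittorque` predicts sagittal hip, knee and ankle torques over the stance
phase of gait from statistically estimated ground reactions, and measures
how estimation errors propagate through two torque models. This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions taken where the problem was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The planar stance-leg model

Torques are computed on a planar sagittal model of the stance leg: foot,
shank and thigh segments plus a head–arms–trunk (HAT) lump — which also
absorbs the swing leg — attached at the hip as a point mass with fixed
(upright) orientation. Segment masses, lengths, centre-of-mass fractions
and radii of gyration come from Winter's classical anthropometric table;
the HAT mass is defined as the remainder so segment masses always sum to
the subject mass exactly. Gravity is 9.81 m/s².

Sign conventions: x anterior, y up; joint angles and torques are positive
in extension (hip, knee) and plantarflexion (ankle), i.e. torque-conjugate
to the angles, so inverse-dynamics torques and musculotendon-model torques
are directly comparable without sign juggling. COP is stored relative to
the heel marker (and in mm at package boundaries; metres internally;
forces in N internally, %BW at the estimation boundary).

**Inverse dynamics (model M)** is the standard distal-to-proximal
Newton–Euler recursion: the foot balance consumes the GRF applied at the
COP on the ground line and yields the ankle reaction and torque; shank and
thigh follow. A planar model was chosen deliberately over a full 3-D
musculoskeletal pipeline: it admits an *exact* forward/inverse consistency
oracle (below), at the cost of not constraining the medio-lateral
channels. ML GRF is accepted and ignored by the recursion; frontal- and
transverse-plane torques are out of scope.

**Forward consistency.** The synthetic generator derives the AP and
vertical GRF as `F = Σ_s m_s (a_s − g)` over the four bodies and the COP
from the whole-body moment balance about the ground line. Because
inverse dynamics later consumes exactly these series with exactly the same
discrete derivatives (central differences inside, one-sided at the ends),
the ground-truth torques are recovered to floating-point precision — the
package's central oracle, asserted at 1e-8 Nm in the tests. A residual
check on the HAT lump's own balance guards the construction.

## 2. The synthetic gait generator

The generator emulates the statistical structure the analysis assumes: a
cohort of subjects (default 5, mass 55–90 kg, stature 1.55–1.90 m),
each with four self-paced stance-phase trials at 100 Hz (~0.64–0.72 s per
stance). Per trial:

* Joint angles are smooth seeded perturbations (two sinusoidal wiggle
  terms, ~1.5° amplitude) of natural-spline templates of typical walking
  curves.
* The vertical hip trajectory integrates a double-hump vertical-load
  template normalised to unit mean (so momentum closes over the stance).
* The AP hip trajectory is *solved* from the whole-body moment balance
  given a heel-to-toe COP progression template (3–21 cm ahead of the
  heel). The balance operator, written with the same discrete
  differentiation matrix the dynamics uses, has a two-dimensional affine
  nullspace; it is pinned by initial position and forward speed
  (~1.15 m/s) and solved in weighted least squares, which spreads the
  two-equation deficiency as a negligible COP deviation instead of
  concentrating it at the trial edges.
* ML GRF and ML COP are smooth seeded templates and are deliberately *not*
  dynamically constrained — a planar model cannot determine them. They
  exist so the estimator has all five channels to learn; their torque
  influence is nil.
* Ground-truth muscle excitations come from minimum-effort torque matching
  (Section 4) restricted to muscles with a recorded EMG channel, so the
  EMG-driven calibration target is self-consistent. Muscles sharing an
  electrode (both gastrocnemius heads) share one excitation variable, so
  each channel envelope is well defined.
* Raw EMG amplitude-modulates a zero-mean band-limited (30 Hz–0.45 fs)
  Gaussian carrier scaled to unit rectified mean, so the standard
  conditioning chain recovers the envelope up to smoothing error. The
  simplest carrier whose rectified low-passed magnitude tracks the
  envelope.

**Measurement noise** (the study conditions; defaults chosen once as
laboratory-realistic): 0.2° RMS joint-angle noise and 0.5 mm hip-marker
noise (residuals after 8 Hz low-pass preprocessing), 0.5 %BW force-plate
noise, 1.5 mm COP noise, 2% envelope noise; all noise is 6 Hz low-pass
filtered so it has the temporal correlation of filtered measurement
chains. Position noise is amplified twice by frame-by-frame
differentiation before it reaches the acceleration features, which is the
dominant error source for the estimator — as in real gait laboratories.
With all amplitudes at zero the measured channels equal the truth
channels exactly.

What the generator does **not** emulate: marker clouds and inverse
kinematics, double support and force-sharing between plates, EMG
cross-talk and movement artifacts, trial-to-trial fatigue, and any
frontal-plane dynamics. Passing tests therefore demonstrate correctness of
the pipeline's machinery and the direction of error propagation, not
performance on any real population. Walking-speed variability is exposed
as a `speed_scale` parameter with no claim that its distribution matches
any particular study.

## 3. Signal processing

Zero-lag filtering applies the one-pass Butterworth design forward and
backward ("zero-lag second-order" is read as a 2nd-order design applied
twice, matching common gait-lab usage). Endpoint transients are suppressed
by odd (point-reflected) edge padding of 3·(order + 1) samples combined
with steady-state initial conditions, so constants pass exactly. The EMG
envelope chain is 30 Hz high-pass, full-wave rectification, 6 Hz low-pass
(both 4th order, zero-lag), then per-subject peak normalisation across all
trials. Differentiation is frame-by-frame: central differences with
first-order one-sided ends. Stance-phase normalisation resamples to 100
samples by linear interpolation (length-preserving endpoints, no
overshoot), 0% = heel strike, 100% = toe-off.

## 4. Musculotendon model and the hybrid optimisation

Eleven MTUs span the three sagittal DoFs with the recorded/unrecorded
structure of an 8-electrode montage: nine muscles have a surface channel
(one channel drives both gastrocnemius heads) and two deep muscles
(iliopsoas, short head of biceps femoris) have none, so their excitations
must be synthesised. Musculotendon length is a per-DoF quadratic in the
joint angles, so moment arms `r_j = −∂l_mt/∂q_j` are analytic and
`v_mt = −Σ r_j ω_j` holds by construction (power balance). Optimal fibre
lengths are referenced to a mid-stance posture so normalised fibre lengths
stay near 1 over the stance motion range.

Activation dynamics is a second-order recursive filter
`u(t) = a_g e(t) − b1 u(t−1) − b2 u(t−2)` with `b1 = c1 + c2`,
`b2 = c1 c2` and unit DC gain, followed by the exponential
nonlinearisation `a = (e^{Au} − 1)/(e^{A} − 1)` with shape factor
`A ∈ [−5, 0]` (`a = u` in the `A → 0` limit). The filter history is
initialised at the steady state of the first frame's excitation — muscles
pre-activate before heel strike — because zero history would leave the
model with almost no torque authority at the first frames. The
electromechanical delay is zero frames by default.

Force is a rigid-tendon, zero-pennation Hill model:
`F = s · F_max (a f_l(l̃) f_v(ṽ) + f_p(l̃))` with a Gaussian active
force-length curve (width 0.45), a saturating logistic force-velocity
curve (`f_v(0) = 1`, → 0 in fast shortening, → 1.6 in fast lengthening,
normalising velocity 10 optimal lengths/s) and an exponential passive
curve that is zero at or below optimal length and reaches 1 at 60% fibre
strain. These curve constants are fixed and documented, not calibrated;
the five calibrated parameters per MTU are the tendon-slack and
optimal-fibre multiplicative scales (0.95–1.05, 0.975–1.025 — the bounds
are dimensionless, hence the multiplicative reading), the strength
coefficient (0.5–2), the two filter coefficients (−1, 1) and the shape
factor [−5, 0].

**Calibration** minimises the pooled squared difference between EMG-driven
and measured torques over the calibration trials (L-BFGS-B over the
bounded box, objective in (Nm/kg)² for conditioning, parameters scaled by
their box widths). Trials are resampled to 30–50 frames for the
objective — the fit is over smooth curves, so this loses nothing — and a
seeded random second start can be requested to guard against local minima.

**The hybrid (EMG-assisted) optimisation** minimises, frame by frame with
activation history propagated,
`F = α E_trackMOM + β E_sumEXC + γ E_trackEMG` over all excitations in
[0, 1]: squared torque-tracking error (α = 1), squared excitation effort,
and absolute deviation from the recorded envelopes (recorded MTUs only;
smoothed with a pseudo-absolute value, ε = 1e-8, for differentiability).
Per-frame static optimisation (not whole-trial) matches the static-
optimisation framing at desk scale. The solver is L-BFGS-B with analytic
gradients plus a sequential linearised refinement: Gauss–Newton
projections drive the tracking residual to machine level, and in the
effort-dominated mode a damped move toward the minimum-weighted-norm
excitation removes residual co-contraction; refinement is candidate-based
so it can never degrade the optimiser's solution.

`tune_beta_gamma()` selects (β, γ) as the candidate minimising the sum of
min–max-normalised tracking and EMG terms over a grid — one concrete
reading of "both terms jointly minimal"; the full grid table is returned
so other readings can be applied. The evaluation pipeline defaults to
fixed documented weights (β = 0.1, γ = 1) rather than re-tuning per
subject: with a redundant muscle set the tracking term dominates whenever
the targets are feasible, so condition-wise comparisons are insensitive to
the exact weights, and the tuning grid remains available.

## 5. Feature selection and the estimator networks

Regression NCA is implemented from its defining quantities: exponential
kernel `k(z) = e^{−z/σ}` on the weighted L1 distance with squared weights,
leave-one-out expected absolute loss, and an L2 penalty `λ Σ w_r²`.
Features are standardised internally. Defaults: `λ = 1/n`; `σ` equals the
mean pairwise weighted distance at the all-ones initial weights. The
self-scaling σ matters: distances grow linearly with the feature count, so
a fixed small width collapses the neighbour distribution onto the single
nearest point and washes out the weight gradient; scaling σ to the actual
distance magnitude makes the 1%-of-maximum rule (applied to `w_r²`, the
quantity that enters the distance and the penalty) cleanly separate
informative features from decoys at the default λ. The O(n²p) objective
caps its row count by seeded subsampling (`sample_max`) in whole-cohort
runs. NCA runs once per (subject, target, test-trial) combination; the
candidate set is the 29 per-sample features: 3 joint angles, 3+3 angular
velocities/accelerations, 6+6 joint-centre linear velocities/
accelerations, 8 EMG envelopes.

The estimator is one network per target channel: single hidden layer,
tanh/linear, full-batch Levenberg–Marquardt with adaptive damping (step
accepted only if the residual sum decreases; damping ×10 on rejection,
÷10 on acceptance; singular normal equations simply raise damping). When
parameters outnumber samples the damped normal equations are solved in
their dual n×n form (push-through identity) — algebraically identical,
much cheaper. LM has no classical learning rate; the tuned "learning rate"
maps to the inverse initial damping, `μ0 = 1/learning_rate`. Stopping is
by minimum gradient (default threshold 1e-7 on the standardised scale;
relaxed in the fast profile), epoch cap, or damping saturation, with the
stop reason recorded. Hyperparameter search minimises the worst of five
seeded random sample-level folds (three trials cannot form five
trial-level folds; the sample-level split is the documented choice, with
near-equal seeded fold sizes). The search itself is a space-filling
initial design (Latin hypercube when available, seeded uniform fallback)
for 60% of the budget, then a Gaussian-kernel radial-basis surrogate with
a distance-based exploration bonus proposing the rest; every evaluation is
logged and the box-feasible argmin is returned.

## 6. Evaluation design

For each subject and each held-out trial, the other three trials provide
estimator training data and calibration data ("measured" everywhere).
Conditions cross the GRF source and COP source (EGEC, EGMC, MGEC) with
model M (inverse dynamics) and model N (hybrid). Model N tracks the
inverse-dynamics torques computed *from that condition's inputs* — that is
the propagation pathway under study. The reference is always the fully
measured pipeline; torques are body-mass-normalised and phase-normalised
to 100 samples before `R² = 1 − SS_res/SS_tot` (not squared correlation —
it can be negative) and RMSE. The fully measured control configuration is
not a study condition but must reproduce the reference exactly (R² = 1,
RMSE = 0); any deviation indicates wiring, not noise.

Statistics follow the nonparametric branch only: within-subject Friedman
tests (blocks = trials, treatments = conditions), a between-subject
variant on per-subject trial means, and Dunn–Bonferroni post hoc pairwise
comparisons at p = 0.05. The parametric branch (mixed ANOVA and its
assumption tests) is deliberately not implemented. On synthetic subjects
the subject-level significance statements are illustrative of the workflow
only.

## 7. Problem sizes, budgets and numerical choices

The package exposes two budget profiles. `"standard"` is the
single-subject default; `"fast"` is the whole-cohort profile used by the
evaluation pipeline and the test suite: NCA capped at 80 rows / 40 BFGS
iterations, tuning budget 10 worst-fold evaluations on at most 100 pooled
rows, LM gradient threshold 3e-3, calibration at 30 frames / 60
iterations, hybrid per-frame cap 40. These sizes were chosen so a full
5×4 cohort evaluation completes in about a minute on one CPU while leaving
every qualitative result (estimator fits, condition orderings) intact;
they are knobs, not science. The cohort-level sensitivity suite runs model
N with the generator's ground-truth musculotendon parameters: the
hip-vs-ankle error-propagation ordering under estimated inputs does not
depend on calibration residuals, and calibration accuracy has its own
dedicated suite.

Degenerate inputs are failed loudly: cutoffs at or above Nyquist, all-zero
EMG channels, fewer than 3 samples to differentiate, non-finite force
inputs (named), infeasible torque targets (frame index and residual
reported), unmapped MTUs (named), zero-variance references for R². COP
positions outside the heel–toe band warn rather than clamp — late-stance
COP near or past the toe is expected and application points are the
user's data, not the model's to repair.

## 8. Known limitations

* Planar sagittal dynamics: no frontal/transverse torques; ML channels are
  estimated but never enter the dynamics.
* The HAT lump has no angular dynamics (upright-trunk assumption).
* Rigid tendons and zero pennation; no elastic-tendon ODEs.
* The synthetic EMG carrier is Gaussian and stationary within a trial; no
  cross-talk, artifacts, or electrode lift-off.
* Intrasubject only — no cross-subject generalisation of the estimator.
* Calibration identifiability is limited (many parameter combinations fit
  three trials almost equally well); held-out torque error, not parameter
  error, is the meaningful recovery metric.
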