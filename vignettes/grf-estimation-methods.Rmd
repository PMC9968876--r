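---
title: "Methods: estimating vertical GRF waveforms from three IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating vertical GRF waveforms from three IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During overground running, the vertical ground reaction force (GRF) is
the primary mechanical load on the body, but measuring it outside the
laboratory requires force sensing insoles, which are fragile and
calibration-sensitive. Inertial measurement units (IMUs) are cheap and
robust. `imugrf` implements a pipeline that maps the signals of three
IMUs — one on the dorsum of each foot and one at the sacrum — onto the
summed bilateral vertical GRF waveform, normalized to body weight (BW),
using a sequence-to-sequence LSTM. The package covers the whole
measurement chain: signal conditioning, inter-device synchronization,
model training and leave-one-subject-out cross-validation (LOOCV),
gait-event and kinetic-variable extraction, and agreement statistics.

## Signal conditioning

IMU channels (200 Hz nominal) are down-sampled to the insole rate of
100 Hz (anti-alias low-pass, then linear interpolation onto the target
grid, which also absorbs phase offsets between device grids) and
low-pass filtered with a 4th-order zero-lag Butterworth at 35 Hz. Force
channels are filtered with a 2nd-order zero-lag Butterworth at 20 Hz.
"Zero-lag" means the filter is applied forward and backward; we
interpret the stated order as the per-pass design order (the dominant
convention in biomechanics reporting) and expose
`filter_order_is_per_pass = FALSE` in `pipeline_config()` for the
alternative reading. The digital design uses the bilinear transform
with prewarping, matching the MATLAB/scipy `butter`/`filtfilt`
convention to machine precision (verified against `scipy.signal` during
development); edge effects are controlled by odd reflective padding of
`3 * order` samples and steady-state initial conditions. Note that a
bilinear digital filter has zeros at Nyquist, so its attenuation near
Nyquist is much stronger than the analog closed form
$|H(f)|^2 = 1/(1 + (f/f_c)^{2n})$; the closed form is therefore only
used as an oracle at sampling rates where the probe frequencies sit far
below Nyquist.

Measured force below 5% BW is set to 0 BW. This threshold is applied
right after filtering — the filter's flight-phase ripple would
otherwise leave no exact zeros for the drift-correction edits below.

## Synchronization and clock drift

The two sensor systems are synchronized at a pre-trial foot stomp,
located as the acceleration-magnitude peak (IMU) and the first rise of
summed force above 5% BW (insoles); the clock offset is their
difference. Residual *drift* between the internal clocks is corrected
iteratively: initial contacts (ICs) are detected independently from the
foot IMUs (minimum of the sagittal-plane angular velocity in the 0.12 s
before each resultant-acceleration impact peak — a standard foot-IMU
heuristic used *only* for alignment, never for reported kinetics) and
from the force waveform (5% BW threshold). ICs are paired greedily by
nearest time within 0.1 s, and whenever a pair's residual exceeds
0.02 s, zero-valued samples are inserted into or removed from the
zero-force swing interval preceding that IC, at its midpoint. Edits
never touch a stance sample, so per-step impulses are bit-invariant,
and a no-edit pass follows a corrected pass, making the sweep
idempotent. Only the force stream is edited. The correction works in
the recording's own timebase (median timestep): re-stamping at the
nominal rate would silently erase the very drift being corrected.

## Windowing and the model

Synchronized trials are cut into non-overlapping 4 s windows of 400
samples. The 24 input channels are the 18 raw channels (3 sites × 6)
plus a per-site acceleration magnitude and angular-velocity magnitude
(3 × 2) — the only reading of "raw channels plus resultant magnitudes"
consistent with a 24-wide input. Inputs are z-scored per channel with
training-set statistics stored in the model (mixed physical units would
otherwise dominate gradients); targets stay in BW. Windows span stance
*and* swing, so the model learns full waveforms with several stances
per window.

The regressor is a single-layer unidirectional LSTM (default 42 hidden
units, searchable over 10–50) with a linear per-timestep readout,
trained by Adam (learning rate 0.001, decay 0.9/0.999, L2 1e-4 by
default) on mean squared error over all 400 output steps. Training is
bit-deterministic given the seed: initialization uses R's RNG and
minibatch shuffling uses an explicit Fisher–Yates sweep on a fixed
Mersenne Twister. Hyperparameter search evaluates a seeded grid on a
70/15/15 split grouped *by participant* (window-level splitting would
leak) and selects by test-set waveform RMSE; a surrogate model is not
required by anything downstream, since in this design only the
hidden-unit count matters. LOOCV trains one model per held-out
participant on all other participants' windows.

Estimated windows are concatenated per trial, then post-processed
exactly like measured data: 20 Hz low-pass, 5% BW zeroing, and removal
of supra-threshold contacts shorter than 0.050 s (too brief to be
running foot contacts).

## Events and kinetics

IC is the first sample with force above 5% BW of a contiguous
supra-threshold run, toe-off (TO) the last; both thresholds are strict.
Stances touching the first or last sample of a trial are excluded from
summaries. Per stance we compute contact time, stance average force,
trapezoidal impulse, peak force, and the average vertical loading rate.
The loading rate defaults to the secant slope over the middle 60% of
the IC-to-impact-peak interval (on a uniform grid the mean of pointwise
slopes telescopes to exactly this secant); when no impact peak exists
the slope is taken between 10% and 40% of contact time instead
(`strategy = "fixed_window"`). The impact peak is the first local
maximum in the first 35% of stance with prominence of at least 0.05 BW
— a declared stand-in criterion, since no printed rule exists for the
transient-peak detector this field commonly cites; 35% bounds the
passive-peak region and the prominence floor guards against noise.

## Agreement statistics

Waveform RMSE covers every sample; stance RMSE is computed per measured
stance and averaged. Gait-event differences are signed measured minus
estimated (positive IC difference = estimate early). Trial-level means
of each kinetic variable enter ordinary least squares regression (with
t-based 95% CIs), squared Pearson correlation with strength bands
(strong ≥ 0.8, moderate [0.5, 0.8), weak [0.3, 0.5), negligible below),
and Bland–Altman bias with limits of agreement bias ± 1.96 SD (n−1
denominator). Per-velocity tables report mean ± SD, with SD 0 for
single-trial velocities.

## The synthetic runner

Because no public recordings exist for this protocol, the package ships
a forward simulator whose defaults state the world the tests run in:

* Per step, the active force is a half-sine $A\sin(\pi t/T_c)$ with an
  optional Gaussian impact bump (center 13% of stance, SD 4% of contact
  time, amplitude 0.25 BW by default). $A$ is set so the
  stride-averaged summed force is exactly 1 BW — the impulse–momentum
  constraint for level running — with the bump integral subtracted.
* Contact time follows $T_c(v) = 0.38 - 0.03 v$ s and step frequency
  $f(v) = 2.5 + 0.12 v$ Hz, monotone trends typical of recreational
  runners (about 0.28 s and 2.9 Hz at 3.35 m s⁻¹), with small seeded
  per-participant variation (SD 0.008 s and 0.05 Hz) and masses drawn
  from 54–82 kg. The profile constructor rejects configurations without
  a flight phase: walking is not modeled.
* The sacrum vertical channel is the exact affine image
  $a_z = (F_{BW} - 1)\,g$ of the summed force before noise, so the
  IMU-to-GRF mapping is learnable by construction and model-level tests
  are meaningful rather than vacuous. Foot sensors carry a decaying
  12 Hz impact transient after each ipsilateral IC and a sagittal gyro
  dip centered exactly at IC (the cue the alignment detector uses).
  Sensor noise is white Gaussian (0.4 m s⁻², 0.08 rad s⁻¹, 0.01 BW on
  active force samples); acceleration clips at ±16 g.
* Clock drift is injected by scaling timestamps (`inject_drift`) or via
  the per-participant `drift_ppm` drawn from ±50 ppm in cohorts; trials
  open with 4 s of quiet standing containing the sync stomp.

What the simulator does **not** emulate: soft-tissue and mounting
artifacts, insole calibration drift and slippage, curve running,
surface gradients, fatigue, or genuinely nonlinear IMU-to-force
relationships. A green end-to-end test therefore establishes that the
pipeline's plumbing, alignment, learning machinery and statistics are
correct — not that the model reaches any particular accuracy on human
data, whose headline agreement numbers are far harder.

## Numerical choices and known limitations

* Events are quantized to the 100 Hz grid, so IC/TO are recovered only
  to ±1 sample; contact time can differ from the continuous truth by up
  to 2 samples (~7%), and the fixed-window loading rate inherits that
  (observed ≲12% deviation from the 2000 Hz analytic truth on noiseless
  data). The event-level acceptance check is therefore stated in
  samples, not percent.
* Velocities printed for the 7:30 and 6:30 mile paces in the source
  pace ladder are inconsistent with `1609.34 / pace_seconds` at two
  decimals; the package implements the exact formula.
* The trial warmup trim (`warmup_s`, default 4.1 s) must cover the
  quiet/stomp period of the recording protocol; it matches the
  simulator's default 4 s quiet phase.
* Degenerate inputs fail loudly: stances under 3 samples, loading-rate
  intervals under one sample, unpairable ICs, sync transients absent,
  walking profiles, upsampling requests.
* `estimate_grf()` is pure inference; all cleaning lives in
  `postprocess_estimate()`, so the two stages can be validated
  independently.
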