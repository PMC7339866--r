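---
title: "Modeling beta oscillations and self-tuning DBS in the STN-GPe loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling beta oscillations and self-tuning DBS in the STN-GPe loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadbs)
```

## The model

`betadbs` simulates a two-population firing-rate model of the reciprocally
coupled subthalamic nucleus (STN, excitatory) and external globus pallidus
(GPe, inhibitory), the subcircuit of the basal ganglia most strongly
implicated in the exaggerated beta-band (13–30 Hz) oscillations of
Parkinson's disease:

$$\tau_1 \dot x_1(t) = -x_1(t) + S_1\big(c_{11}x_1(t-\delta_{11})
  - c_{12}x_2(t-\delta_{12}) + b_1 u_1(t) + \mu(t)\big)$$
$$\tau_2 \dot x_2(t) = -x_2(t) + S_2\big(c_{21}x_1(t-\delta_{21})
  - c_{22}x_2(t-\delta_{22}) - b_2 u_2(t)\big)$$

Here $x_1, x_2$ are population firing rates (pulses/s), $u_1, u_2$ the
cortical and striatal inputs, $\mu$ the stimulation term, and the
$\delta_{ij}$ axonal/synaptic transmission delays, which make the system a
delay differential equation (DDE): its state is a *history function* over
the maximal delay, not a point. The activations are unit-max-slope logistic
sigmoids

$$S_i(x) = \frac{M_i B_i}{B_i + e^{-4x/M_i}(M_i - B_i)},$$

so $S_i(0) = B_i$ (baseline rate), $S_i$ saturates at $M_i$, and the maximum
slope is exactly 1 (or the output scale $a$ when an identified activation is
rescaled). Standard constants: $M = (300, 400)$, $B = (17, 75)$ pulses/s,
$\tau = (6, 14)$ ms, $\delta_{12} = \delta_{21} = 6$ ms, $\delta_{22} = 4$
ms, and no STN self-coupling ($c_{11} = 0$) in any standard configuration.

Two oscillation regimes are bundled as `loopPreset()`:

* **endogenous** ($c_{12}=3, c_{21}=10, c_{22}=0.9, b_1=5, b_2=139.4$):
  strong reciprocal coupling pushes the loop through a Hopf bifurcation; it
  self-oscillates at ~20 Hz under constant input.
* **exogenous** ($c_{12}=1.12, c_{21}=19, c_{22}=0.9, b_1=2.42, b_2=15.1$):
  the loop is stable and *entrainable* — any periodic cortical input
  produces a periodic steady state at the same frequency — which is what
  makes a nonlinear Bode characterization meaningful.

The striatal level $\bar u_2$ is not fixed by the standard parameter tables;
the package default is the constant 2 pulses/s conventionally used with this
model family. It is exposed everywhere as an argument, and absolute
oscillation amplitudes (though not frequencies or qualitative behavior)
depend on it.

## Numerical integration

`integrateDDE()` is a fixed-step explicit RK4 scheme with delayed terms
resolved from the stored solution history. Choices that matter:

* **Delay commensurability is enforced, not rounded.** Every delay must be
  an integer multiple of `dt`; full-step stage lookups then hit stored grid
  samples exactly, and only the two half-step RK stages interpolate
  (linearly) between adjacent samples. This removes any ambiguity at the
  exact delay lag at the cost of rejecting ill-posed configurations loudly.
* **Effective order.** Linear interpolation of delayed stage values limits
  the scheme to second order on delayed dynamics (RK4's fourth order is
  recovered for delay-free systems). The convergence test asserts the
  error-ratio ~4 per step halving accordingly. At the default `dt = 0.1` ms
  (≥ 40 steps per delay, ~500 steps per beta period) the absolute error is
  far below anything the analyses resolve.
* **History defaults to the constant equilibrium.** Simulations start at
  rest; unstable configurations therefore stay on the (exactly preserved)
  fixed point unless perturbed. Analyses that look for limit cycles start
  from a 5% STN offset, which is also what the sweep engine does per cell.
* **Degenerate inputs.** Non-finite right-hand sides abort with the failure
  time; delayed lookups outside the buffer are hard errors, never silent
  extrapolation.

## Controllers

Stimulation is feedback on the STN deviation from its operating point,
$\mu(t) = -\theta(t)\,(x_1(t) - \bar x_1)$, where $\bar x_1$ comes from the
equilibrium at the inputs' initial mean levels and stays fixed for the run —
the controller has a fixed setpoint, as a practical device would. The gain
laws:

* **proportional**: fixed $\theta$;
* **self-tuning** (σ-modification): $\tau_\theta \dot\theta = d(t) -
  \sigma\theta$, with drive $d$ either the rectified deviation $|x_1 - \bar
  x_1|$ (`adaptive_abs`) or a beta-selective biomarker (`adaptive_beta`):
  the peak-to-peak amplitude of the causally band-passed (Butterworth,
  order 5, 15–30 Hz) STN deviation over the trailing 500 ms. The gain grows
  while pathological activity persists, settles near the minimal effective
  value, and leaks away at rate $\sigma/\tau_\theta$ when the band is quiet.

The gain is integrated by explicit Euler at the simulation step and clamped
at zero (the continuous law preserves nonnegativity; clamping removes
discretization undershoot). Its closed forms — decay $e^{-\sigma
t/\tau_\theta}$ at zero drive, fixed point $d/\sigma$ at constant drive —
are verified to 1e-6 against the exact linear-ODE solution.

**Biomarker sampling rate.** The biomarker stream runs at 1 kHz, the
standard rate for LFP band-power work: a 15–30 Hz order-5 IIR bandpass is
well conditioned there, whereas the same design collapses numerically at the
10 kHz integration rate (normalized band 0.003–0.006). The filter state is
carried across steps, so the controller is strictly causal; the drive is
zero until the 500 ms window first fills.

For stimulation plants where *increasing* amplitude suppresses the
biomarker, the plant-facing law uses positive feedback $\mu = +\theta \cdot
\mathrm{ARV}$ with drive the half-wave-rectified, target-normalized error
$\max(\mathrm{ARV} - r, 0)/r$. Normalizing makes the mean-squared tracking
error scale-free and — with the leak $\sigma\theta$ balancing a
dimensionless residual — keeps residual tracking errors proportional rather
than absolute across target levels. `errorDrive()` exposes both forms.

The analytic bound `thetaStarBound()` gives the conservative estimate
$\theta^* \le 8\big(c_{11}^2 + 4c_{21}^2c_{12}^2/(1-c_{22})^2\big)$ on the
minimal stabilizing proportional gain (undefined at $c_{22} = 1$); its
practical value is qualitative — the self-tuner exists precisely because
$\theta^*$ is unknown and this estimate is orders of magnitude conservative.

## Characterization analyses

**Oscillation maps** (`oscillationMap()`) sweep $(c_{12}, c_{21})$ with
$c_{22}=4$, $b_1=8$, $b_2=139.4$, simulate 5 s per cell, and measure the
peak-to-peak of the zero-phase 16–24 Hz filtered rate over the last 2 s,
normalized to $[0,1]$ per population panel. Amplitude extraction runs on a
1 kHz resample (see above). Cells that fail to integrate are flagged, never
silently zeroed.

**Bode profiles** (`bodeProfile()`) drive the entrainable preset with
sinusoids and report steady-state half-peak-to-peak over input amplitude per
population. The loop near its Hopf point rings down slowly (~3 s for small
signals), so the default settle is 2 s, each frequency warm-starts from the
previous one's final state, and the linear-limit validation uses a 3.5 s
settle. Non-entrained cells (dominant output frequency off the input by more
than one FFT bin) are flagged. Small-amplitude profiles match the closed
form `linearizedGain()` — the transfer function of the linearization about
the equilibrium with delays as $e^{-i\omega\delta}$ phase factors — within
10%, and its $\omega \to 0$ limit equals the equilibrium continuation slope.

**Controller timing in comparisons.** The robustness-contrast experiment
(self-tuner vs. fixed gain matched to the "pre-step effective adaptive
gain") places the mid-run input step at 2.5 s: the adaptive gain peaks
during its transient (values ~25) before settling near ~1.2, and matching a
fixed gain to the transient value would trivially suppress everything,
voiding the comparison. Matching the *settled* gain is the meaningful
reading, so the step comes after settling.

## Identification

The GPe activation and self-coupling are estimated from steady-state
(STN rate, GPe rate) pairs in two stages, mirroring how such data are
produced by disconnection experiments:

1. With the self-coupling absent, `fitActivation()` estimates the output
   scale $a$ as the least-squares line through the central 50% of the drive
   range, fits the unit-slope sigmoid to the rescaled data, and rescales by
   $a$. Because a chord slope systematically underestimates the maximum
   slope, a joint $(a, M, B)$ nonlinear refinement (initialized at the
   two-stage estimate) is applied by default; noiseless synthetic data are
   then recovered to machine precision, and 5% multiplicative noise at
   $n = 50$ keeps parameters within 10%.
2. With the coupling present, `estimateC22()` scans a candidate grid
   (default `seq(0, 0.9 / l2, 0.01)`, inside the contraction region
   $c_{22}\ell_2 < 1$), predicting each drive's steady state as the solution
   of $x = S_2(u + c_{22}x)$ — damped fixed-point iteration, $\lambda =
   0.5$ — and minimizing the normalized square error
   $\sum_i(f_{c_{22}}(u_i) - x_{2,i})^2 / \sum_i x_{2,i}^2$. Ties break
   toward the smaller coupling. Note the self-term enters with a positive
   sign in this disconnected-GPe setup, where $u$ aggregates the signed
   inputs.

`stabilizabilityCheck()` then reports whether $c_{22}\ell_2 < 1$, the
condition under which STN-only stimulation can stabilize the loop (a GPe
that paces itself cannot be quieted from the STN).

## The surrogate plant and what it does not show

`runScenario()` exercises the plant-facing controller in three scenarios
(target change, background-beta fluctuation, impedance drift — 130 s each)
against a *synthetic* plant: background beta ARV times a Hill-type
suppression curve of effective current, with impedance entering as
$Z_E(0)/Z_E(t)$ on a current-controlled stimulus, a first-order 100 ms
response lag, and seeded 5% Gaussian epoch noise. Defaults (background
0.5/0.08 µV, $I_{50} = 0.5$ mA, Hill exponent 2, floor 5%) were chosen once
as a plausible rendering of graded beta suppression under increasing
stimulation.

The plant reproduces the *shape* of the closed-loop problem — monotone
saturating dose response, impedance-driven loss of efficacy, epoch-rate
measurement — and therefore supports qualitative claims only: error/power
orderings between self-tuning and fixed-gain control, gain growth along the
impedance ramp, stimulation shutdown at unattainable targets, and tracking
within 25% of reachable targets. It does not model spiking dynamics, LFP
biophysics, stimulation pulse shape, or antidromic effects, so absolute MSE
percentages and microwatt figures are properties of the surrogate, not
predictions, and are not compared against any reference values.

Controller constants for scenario runs default to $\tau_\theta = 100$ ms,
$\sigma = 0.00875$ at a 100 ms update cadence (one update per completed
biomarker epoch).

## Problem sizes and reproducibility

Default analysis sizes — 5 s simulations at `dt = 0.1` ms for spectra, 4 s
for controller ladders, 2–4.5 s per Bode frequency, 130 s at the 100 ms
epoch scale for scenarios, grids of tens of cells for maps — were chosen so
every documented analysis reruns from scratch in seconds to a few minutes
on a laptop while leaving its conclusions insensitive to further refinement
(halving `dt` or doubling spans moves reported frequencies by less than an
FFT bin and amplitudes by well under the tolerances tested).

Every stochastic element (plant noise, synthetic identification data) takes
an explicit seed; identical seeds give bit-identical results, and
`runCommand()` writes a manifest (resolved config, seed, config MD5) beside
every artifact so deterministic commands can be reproduced exactly.

## Known limitations

* The firing-rate abstraction has no spatial structure, no spiking, and no
  field model; stimulation enters as an additive term in the STN activation
  argument rather than as an electric field.
* Absolute amplitudes in the endogenous/exogenous demonstrations depend on
  the unprinted striatal level $\bar u_2$ and on initial histories; only
  frequencies, orderings and suppression ratios are treated as conclusions.
* The integrator is deliberately fixed-step and explicit; stiff or
  state-dependent-delay problems are out of scope.
* The adaptive laws here tune a single gain; tuning $\tau_\theta$ or
  $\sigma$ themselves is not attempted.
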