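---
title: "Closed-loop baroreflex-regulated cardiovascular models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop baroreflex-regulated cardiovascular models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baroloop)
```

## The models

`baroloop` implements two pulsatile lumped-parameter (0D) circulation
models, each available with and without closed-loop baroreflex control:

* **One-chamber (1CH)**: a left ventricle with a time-varying elastance,
  mitral and aortic diode valves, and a systemic
  compliance–resistance–compliance (CRC) Windkessel. Three states:
  ventricular, arterial, and venous pressure.
* **Four-chamber (4CH)**: left and right ventricles and atria, systemic
  and pulmonary CRC loops, four diode valves. The atria are merged with
  the adjacent venous compliances (right atrial pressure equals systemic
  venous pressure, left atrial pressure equals pulmonary venous
  pressure), giving six pressure states.

Chamber contraction uses the double-cosine activation
$e(t;\tau_{es},\tau_{ep})$: a rising half-cosine to the systolic peak
$\tau_{es}$, a falling half-cosine to the end of systole $\tau_{ep}$,
zero otherwise; the chamber elastance is
$E(t) = (E_{max}-E_{min})\,e(t) + E_{min}$. Timing parameters are stored
as *fractions* of the heart period (ventricles 0.30 and 0.45; atria
0.92, 0.96, 1.0, wrapping across the cycle boundary), so timing scales
consistently when the period is regulated. All chamber unstressed
volumes are zero, which lets every chamber volume be eliminated in
favour of its pressure ($V = P/E$) and reduces the closed loop to a pure
ODE/DDE system with no algebraic constraints.

Valves are Ohmic diodes: resistance $r_{val}$ under forward bias,
$1000\,r_{val}$ under reverse bias — continuous at zero gradient, but
with a kink that matters numerically (see below).

## Baroreflex

Arterial pressure is the carotid-sinus surrogate. The afferent pathway
filters it through a real-pole/real-zero element
($\tau_p \dot{\tilde P} = P_{art} + \tau_z \dot P_{art} - \tilde P$; the
$\dot P_{art}$ it needs is taken from the assembled right-hand side, not
from numerical differencing) and transduces $\tilde P$ into an afferent
spiking frequency through a sigmoid centred on the set-point
$P_n = 92$ mmHg. Two efferent arcs follow: sympathetic (exponential,
decreasing) and vagal (sigmoid, increasing). Each effector reads its arc
at a pathway-specific delay $D$ (0.2 s vagal, 2 s sympathetic, 5 s
unstressed volume), applies a static characteristic (logarithmic with a
cutoff for sympathetic targets, linear for the vagal heart-period arc),
and relaxes toward it with a first-order time constant. The heart-period
deviation is the *sum* of a sympathetic and a vagal contribution, each
integrated as its own state.

Regulated quantities: heart period, maximal left-ventricular elastance,
systemic resistance (1CH and 4CH), plus maximal right-ventricular
elastance and venous unstressed volume (4CH only). Systemic resistance
and unstressed volume update continuously; heart period and
contractilities update beat-to-beat.

### Beat-to-beat promotion

Beat-held effectors are represented as smooth states: the held value
relaxes toward $\theta_0 + \Delta\theta(t)$ under a narrow Gaussian bump
centred on beat onsets. Two choices here are deliberate:

* A *unit-mass* Gaussian would move the held state only $1-e^{-1}$ of
  the way to its target across a beat, and only the post-onset half of a
  bump keyed to a detected onset can act (the onset time is not known in
  advance while the period itself is being regulated). The integrator
  therefore applies a one-sided post-onset half-Gaussian with doubled
  amplitude — total mass `promotion_gain` (default 12) — so the full
  promotion happens just after each detected onset and the post-beat
  residual is $e^{-\mathrm{gain}} \approx 6\times 10^{-6}$ relative.
  (An earlier design predicted a second bump centre at the next onset;
  it smears the promotion whenever the period is still changing, so it
  was dropped.)
* The bump width `promotion_sigma` (default $10^{-3}$ s) is far below
  the shortest transport delay (0.2 s), so the promotion is effectively
  instantaneous on circulatory time scales while keeping the system a
  smooth DDE.

A beat ends when the cycle time reaches the *current* held heart period;
the elastance timing fractions are evaluated against the live held
period with the full chain rule (see below).

### Unstressed volume

The venous unstressed-volume effector $\Delta\theta_{V_{un}}$ (negative
gain: sympathetic activation *reduces* unstressed volume) couples into
the merged right-atrial/venous node as a volume source: a decrease in
unstressed volume injects stressed volume, i.e. the inflow term is
$-\mathrm{d}\Delta\theta_{V_{un}}/\mathrm{d}t$. With this sign the sum
of stressed volume and the unstressed-volume deviation is exactly
conserved, and a pressure drop is counteracted — the physiologically and
algebraically consistent reading. Only the systemic venous node is
regulated; the pulmonary venous node is passive.

## Initial conditions and total blood volume

The closed loop conserves total stressed volume (plus the
unstressed-volume deviation in the regulated 4CH), so the initial state
*is* a model constant: it fixes the operating point. Every compartment
pressure starts at a uniform initial filling pressure `P_init`;
ventricular volumes follow from $V = P/E$.

* **4CH**: `P_init` equals the mean circulatory filling pressure
  (6 mmHg). The regulated 4CH operating point is insensitive to this
  choice because unstressed-volume regulation autonomously shifts volume
  into the stressed circulation until the loop settles near the
  set-point; the settled effector values reproduce the published
  comparison-protocol values to ~1% untouched.
* **1CH**: there is no volume regulation, so the settled effector values
  depend directly on the conserved volume. The published steady-state
  values pin it down: `P_init` = 9.0 mmHg (a total stressed volume of
  ≈259 ml) reproduces the published regulated steady state
  ($\tau_{HR}=0.906$ s, $E_{LV,max}=2.48$, $R_{sys}=2.386$) to a few
  tenths of a percent. This is the package's resolution of an initial
  state the reference parameter tables leave unspecified; it was
  calibrated once against
  the steady-state protocol values and then frozen. Redistributing the
  same total volume across compartments leaves the settled state
  unchanged (tested), so only the conserved total matters.

## Integration

The coupled system is integrated with a fixed-step classical
Runge–Kutta (RK4) scheme in compiled code, with a ring-buffer history of
the filtered pressure and cubic Hermite interpolation at the lagged
evaluation times. History before $t=0$ is the constant initial state.
Design points:

* **Fixed step, not adaptive.** The promotion bump forces small steps
  near beat onsets regardless of error control, and a fixed step makes
  every run bit-reproducible and embarrassingly parallel for
  sensitivity sweeps. Accuracy is verified by step halving (outputs move
  by far less than 0.1%); the `abs_tol`/`rel_tol` config fields document
  the target that the default steps comfortably meet. Default outer
  steps: 2.5×10⁻⁴ s (regulated 1CH), 2×10⁻⁴ s (4CH), 10⁻³ s
  (unregulated 1CH).
* **Event-aware substepping.** Steps near a bump centre, steps in which
  a valve switches bias, and steps containing an activation branch joint
  are re-taken as 16 substeps, so no kink or stiff bump sits inside a
  full-length step.
* **Exact elastance chain rule.** Because the timing fractions ride on
  the *promoted* heart period, the elastance time-derivative includes
  the $\partial E/\partial\tau\,\dot\tau$ and
  $\partial E/\partial E_{max}\,\dot E_{max}$ terms. Omitting them
  violates volume conservation through the beat transition (the atria
  are in systole exactly when the period is promoted).
* **Conservative projection.** Residual truncation at the diode kinks
  would still let the conserved volume wander by ~10⁻³ over a long
  transient, *path-dependently in the parameters* — a common noise mode
  that corrupts finite-difference sensitivities and inflates Sobol
  indices of inert parameters. After every step the volume defect
  (typically ~10⁻⁸ relative) is distributed uniformly over the pressure
  states, pinning the invariant to machine precision. The largest
  per-step correction is tracked and reported with each run.
* **Beat bookkeeping** happens promptly after every (sub)step, so the
  cycle coordinate never overruns the held period by more than a
  substep.

Simulation horizons: 150 s (regulated 1CH) and 300 s (regulated 4CH)
model time, with a periodicity warning if the final two cycles' arterial
maxima differ by more than 0.1%; unregulated runs settle within a few
seconds and use 20–40 s. The "final 200 time points" of the comparison
protocol are read as 200 trailing output samples at the default 0.01 s
sampling — a 2 s window, more than one full beat; the window length is
configurable and doubling the horizon moves the trailing means by well
under 0.2%.

## Sensitivity analysis

### Local

Scaled local sensitivities
$\hat S_{ij} = (\theta_i/y_j)\,\partial y_j/\partial\theta_i$ use
central differences with a relative step (default 10⁻⁴), verified by a
Richardson step-halving check (entries where the two step sizes disagree
by more than 1% are flagged, with the disagreement judged against a
floor of 5% of the output's dominant derivative so negligible entries do
not flag on noise). Outputs that vanish at the base point make the
scaling undefined; such entries are flagged, never dropped silently.
For regulated variants a longer horizon and a larger step (10⁻² works
well) are advisable: the sensitivity signal must clear the residual
settling transient.

### Global (Sobol)

The variance-based pipeline perturbs every free parameter uniformly
within ±10% of its base value (intervals around negative gains are
ordered numerically), draws the A/B base matrices from a seeded
randomised Latin hypercube over 2n dimensions (a stratified
space-filling design; plain Monte Carlo is also available), forms the
radial matrices AB$_i$, and evaluates the model at all $K(n+2)$ rows.
First-order indices use the Saltelli (2010) estimator with centred
outputs; total-order indices use the Jansen (1999) estimator;
higher-order structure is read from ST − S1. Confidence intervals come
from bootstrap resampling of the (A, B, AB$_i$) rows *jointly*
(preserving the estimator pairing), 95% percentile intervals. Negative
Monte-Carlo estimates are retained in stored results and clipped only
for heatmap display, where each output column is normalised by its
maximum absolute entry onto [0, 1].

Failed runs (non-finite outputs, or timing orderings broken by a joint
perturbation — possible for the atrial fractions in the unregulated 4CH
set, whose ±10% ranges overlap) are imputed with the base-point output
and logged; a failure rate above 1% aborts. Runs that both fail and
matter are thus visible, never silent.

The convergence machinery follows the reference sampling schedule
(K = 100–2000 by
100 with B = 100; 2500–10000 by 500 and 15000–150000 by 5000 with
B = 1000) and records selected (parameter, output) entries with their
CIs; the half-widths shrink like $K^{-1/2}$, which the tests verify on
closed-form oracles. Full-size (K = 150000) sweeps of the regulated
models are cluster-scale and are not run here; the package's analyses
use K = 2048 for the unregulated 1CH (≈22500 runs, ~1 minute) and
reduced K with bootstrap CIs for the regulated variants. The CLI guard
refuses K > 8192 without an explicit override.

### Perturbable parameter sets

The reference analysis reports only the parameter-space dimensions
(36 and 9 for the
regulated/unregulated 1CH; 51 and 22 for the 4CH). The package publishes
its reconciled lists via `free_parameter_order()`, built from one rule:

* structural constants (mean circulatory filling pressure, initial
  venous unstressed volume, initial filling pressure) are never
  perturbed;
* pinned timings ($\tau_{initV}=0$, whose relative interval is
  degenerate, and $\tau_{S2A}=1.0\,\tau_{HR}$, pinned at the cycle
  boundary) are never perturbed;
* all cardiac timing fractions are excluded from the regulated 4CH set
  (they destabilise the regulated four-chamber analysis — note the
  ±10% intervals of the two free atrial fractions overlap, so joint
  perturbation can invert their ordering);
* the base heart period is excluded from both *unregulated* sets, where
  heart period is excluded from the analysis altogether because it is
  constant.

This reproduces 36/9/51/22 exactly.

## What the tests do and do not show

The test suite verifies the building blocks against independent oracles
(plain-R activation/valve formulas, an explicit-volume
differential-algebraic formulation of both circulations, a deSolve
delay-equation solution of the regulated 1CH with the same beat schedule
injected, closed-form Sobol indices of additive and Ishigami test
functions), the conservation and reduction properties (zero-gain
regulated ≡ unregulated; stressed+unstressed volume constant;
redistribution-invariance of the steady state), and the reproduction of
the published steady-state effector values and the scaled-down global
sensitivity entries. They do not validate the models against
physiological recordings; all claims are about the stated equations at
the stated parameter values, at rest, within the ±10% box.

One published value resisted reproduction: the total-order index of
systemic resistance against cardiac output in the *regulated* 1CH is
reported as damped below 0.005, while this implementation yields ≈0.1
(with direct ±10% perturbations of the resistance base value moving
steady cardiac output by ∓4%, versus ∓6% unregulated). With
proportional (non-integral) effector dynamics the loop pins arterial
pressure rather than total resistance, so cardiac output — arterial
minus venous pressure over total resistance — necessarily retains a
few-percent response; full compensation would require integral action
absent from the effector equations. The corresponding acceptance test
states the published value and fails honestly; all other reproductions
(steady-state effector values of both models, the unregulated and
regulated first-order contractility indices) pass within tolerance.

## Known limitations

* No inertial elements, valve dynamics, or nonlinear compliances; the
  diode valves make the vector field non-smooth, which is handled
  numerically but remains a modelling simplification.
* Rest state only: no exercise, tilt, or pathological scenario library.
* The afferent filter's zero ($\tau_z = 6.37$ s) amplifies the pulsatile
  component of the filtered pressure about three-fold, so the efferent
  sigmoids operate well into saturation over each beat; static loop-gain
  reasoning therefore underestimates rectification effects, which the
  simulations capture.
* The regulated 4CH admits a mild dependence of its transient (not its
  settled state) on the promotion width; widths far above the default
  would blur beat-to-beat regulation into quasi-continuous regulation.
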