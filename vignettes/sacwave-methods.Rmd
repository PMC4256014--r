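---
title: "Modelling cholinergic retinal waves with sacwave: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cholinergic retinal waves with sacwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`sacwave` simulates stage II (cholinergic) retinal waves: spontaneous,
slowly spreading bursts of depolarisation in the developing retina,
initiated by rare intrinsic depolarisations of starburst amacrine cells
(SACs) and propagated laterally through the volume release and diffusion
of acetylcholine (ACh). Each lattice point carries one SAC with state
$(v, r, s, a)$: membrane potential (mV), a potassium/refractory gate, a
slow after-hyperpolarisation (sAHP) level, and the local extracellular
ACh concentration (nM). Only $a$ diffuses; all lateral coupling is
through it.

$$C \dot v = -g_L (v - E_L) - g_K\, r\, (v - E_K)
  - g_{Ca}\, m_\infty(v)\, (v - E_{Ca})
  - \big(g_{ACh}\, \alpha(a) + g_\chi \chi\big)(v - E_{ACh})$$
$$\dot r = \frac{w_\infty(v) + \kappa s - r}{\tau_w(v)}, \qquad
  \dot s = \frac{s_\infty(v) - s}{\tau_s(v)}, \qquad
  \dot a = D \nabla^2 a + \beta\, \rho(v) - a/\tau_a$$

with the standard Morris–Lecar auxiliary functions
$m_\infty, w_\infty$ (tanh sigmoids) and $\tau_w$ (cosh form), a Hill
conductance $\alpha(a) = a^2/(a^2 + K^2)$ with $K = 800$ nM, a sigmoidal
release function $\rho(v)$ half-maximal at the ACh release threshold
(about $-55$ mV), and a Bernoulli channel $\chi$ redrawn every 10 ms
(open with probability rate $\times$ 10 ms) that injects the excitatory
noise conductance driving spontaneous depolarisations.

Three design choices deserve emphasis, because they decide whether the
model can support travelling fronts at all:

1. **The calcium conductance is the dominant one** ($g_{Ca} = 30$ nS
   against $g_K = 10$ nS). With the opposite ordering the depolarised
   state cannot persist for any gate level and the fast subsystem loses
   its excited fixed point — no travelling front exists, contradicting
   the front construction the analysis relies on.
2. **The sAHP enters the gate equation as an uncapped additive target**,
   $r \to w_\infty(v) + \kappa s$. The variable $r$ is therefore the
   voltage-gated K$^+$ activation *plus* sAHP-recruited K$^+$
   conductance, in units of $g_K$; it lies in $[0,1]$ at rest but exceeds
   1 transiently when the sAHP is loaded. This is what terminates bursts:
   the fast $(v, r, a)$ subsystem with $s$ frozen is bistable, and only
   the slow growth of $s$ (activation time $\tau_R = 5$ s) shuts the
   burst down after roughly half a second — matching the sub-second mean
   wave duration — after which $s$ decays on $\tau_S = 60$ s and holds
   the cell hyperpolarised (the deep after-hyperpolarisation).
3. **The sAHP time constant is state dependent**:
   $\tau_s(v) = \tau_S + (\tau_R - \tau_S)\, s_\infty(v)$, i.e. ~5 s
   while depolarised and ~60 s at rest. A single 60 s constant cannot
   both load the sAHP gradedly during a burst (larger/longer
   depolarisations load more, hence longer refractory periods) and decay
   on the minute scale.

## Parameters

Defaults live in `modelParams()` and can be serialised to a flat
key/value registry (`writeParamRegistry()` / `readParamRegistry()`,
bit-exact round trip). Voltages are mV, conductances nS, times s,
concentrations nM, $D$ mm$^2$/s. The headline geometry is a 2 mm square
of retina on a $64\times 64$ lattice — one SAC per ~31 µm, the SAC
density in the inner plexiform layer.

Two parameters are calibrated rather than taken as fixed constants:

* **The noise rate** (default 0.12/s). As in the experimental
  literature this rate is set so that an *isolated* cell crosses the
  $-50$ mV event threshold about once per 15 minutes. At that rate a
  single 10 ms channel opening depolarises a resting cell to just below
  the $-60$ mV analysis threshold; bursts require (roughly) two
  consecutive openings, which is what makes intrinsic events rare while
  leaving the cell one opening away from recruitment by neighbouring
  ACh. `calibrateNoiseRate()` re-runs this calibration for modified
  parameter sets.
* **The ACh release scale** $\beta$ (default $2\times 10^4$ nM/s) and
  clearance $\tau_a$ (0.2 s). Together they set the ACh a bursting cell
  presents to its neighbours (high hundreds of nM against the 800 nM
  half-saturation, over a diffusion length
  $\sqrt{D \tau_a} \approx 45$ µm — the scale of a SAC arbor). They are
  fixed by two network-level anchors: a single bursting cell must be
  able to recruit neighbours (waves are nucleated by single-cell
  events), and the resulting front speed must lie at the 0.1 mm/s scale
  of recorded waves.

## Nondimensionalization

`nondimensionalize()` rescales by 50 mV, $g_{Ca}$, the 5 s sAHP
activation time, $\sqrt{D\,\times\,5\ \mathrm{s}}$ and 1 nM. The scaled
reversals are $(-1.8, 1, -1.4)$ for K/Ca/leak, the conductance ratios
$(1/3, 1/15, 1/10)$ for K/leak/ACh, and the three timescale ratios of
the membrane time $C/g_{Ca} = 5.33$ ms to the 0.2 s gate, the 5 s sAHP
activation and the 60 s sAHP decay are $2.67\times10^{-2}$,
$1.07\times10^{-3}$ (the singular parameter $\varepsilon$) and
$8.89\times10^{-5}$. Because space is scaled by $\sqrt{D t_0}$, $D$
drops out of the scaled equations entirely: it sets the speed of waves
but not whether they exist. The test suite verifies that dimensioned
and dimensionless trajectories map onto each other under these scalings
to $10^{-6}$.

# Numerics

Time stepping is Strang-split: a half step of ACh diffusion, a full
Heun (two-stage Runge–Kutta) step of the reaction terms, and a second
diffusion half step. Diffusion uses the locally one-dimensional
Crank–Nicolson scheme — one implicit tridiagonal solve along x then y in
the first half step, y then x in the second, which cancels the
directional bias of the sweep ordering. Boundaries are zero-flux
(Neumann), so total ACh is conserved under pure diffusion to solver
precision; the conservative stencil makes a uniform field an exact
steady state. The default step is 1 ms with the stochastic conductance
redrawn every 10 ms and snapshots every 10 ms.

The compiled integrator evaluates the five voltage sigmoids through
piecewise-linear lookup tables on a 0.005 mV grid (interpolation error
~$10^{-9}$, far below the $10^{-6}$ agreement verified against an
independent ODE solver in the decoupled limit); the exposed single-step
functions (`stepReaction()`, `stepDiffusion()`) evaluate the exact
expressions. All randomness is drawn from R's RNG, so a seed fixes a
run bit-exactly.

Degenerate inputs are rejected at construction (negative conductances,
non-positive time constants, Hill coefficient below 1, inverted
reversal ordering) or fail loudly at run time (numerical blow-up stops
with a time stamp; an opening probability outside $[0,1]$ is an error).

# Wave detection and statistics

The analysis follows the standard imaging pipeline: lattice points with
$v > -60$ mV are active (a $-55$ mV variant selects the ACh-release
threshold, better matched to calcium imaging); a 5-cell boundary margin
is excluded; active points adjacent within a snapshot (4-neighbourhood
by default, 8 available) or across consecutive snapshots (same cell or
spatial neighbour) share a wave label. A wave's size is its number of
distinct member cells, its duration the time from first to last active
snapshot. Waves with more than one onset cluster — active points with
no active predecessor — are collisions. Front speeds are measured by
backward tracing: from the active point most distal to the initiation
centroid at the wave's last snapshot, step back in 0.5 s increments to
the nearest active point; the path length over the duration gives the
mean speed, the largest segment the maximum front speed. Waves smaller
than 50 cells or shorter than 1 s, and collisions, are excluded from
speed estimates only. Per-cell inter-wave intervals (IWIs) pool the
times between successive threshold crossings, imposing a 2 s minimum
interval. Smoothing of the voltage field is not applied; at the $-60$
mV threshold it makes no material difference to labelling.

Every stage is calibrated against synthetic fixtures with closed-form
ground truth (`makeDiskWave()`, `samplePowerLaw()`): programmed disk
speeds of 0.05–0.2 mm/s are recovered within 10%, merging disks are
flagged as one collision wave with two onset points, and the log-binned
power-law fit recovers a programmed exponent of 1.5 within $\pm0.1$ on
$10^4$ draws while flagging exponential samples through the curvature
diagnostic.

# Front analysis

With $s$ frozen, `fastFixedPoints()` locates the uniform states of the
fast $(v, r, a)$ subsystem by slaving $r$ and $a$ to $v$ and scanning
the voltage axis; stability comes from the analytic Jacobian. Front
speeds are computed two independent ways:

* **Relaxation** (`frontSpeedRelaxation()`): integrate the frozen-$s$
  subsystem on a long strip from a sigmoid joining the excited and rest
  states and fit the drift of the mid-level voltage contour over the
  second half of the run. The sign is positive when the excited region
  grows. On the lattice, bistable interfaces *pin* over a band of $s$
  — the front stalls without receding; this is reported as status
  `"pinned"` and treated as non-propagating.
* **Moving-frame boundary-value solve** (`frontProfileBVP()`): Newton
  iteration on the collocated stationary equations in the co-moving
  frame ($c v' + f_v = 0$, $c r' + f_r = 0$, $D a'' + c a' + f_a = 0$)
  with Dirichlet fixed-point boundary values, the speed $c$ as an
  unknown, and a phase condition pinning the mid-level crossing at the
  interval centre. The truncation interval is 2.4 mm (about 50
  diffusion lengths); the analytic sparse Jacobian drives the scaled
  residual below $10^{-8}$. Solutions are translation invariant and
  agree with relaxation speeds to within 5%.

`speedVsRefractory()` maps $c(s)$ — monotone decreasing — and bisects
for the propagation threshold $s^*$ where the front stops advancing.
`absoluteRefractoryPeriod()` then simulates a standard
(noise-kick-evoked) burst and reports how long $s(t)$ stays above
$s^*$: with the 60 s decay this follows the closed form
$\tau_S \ln(s_0/s^*)$, on the order of half a minute. Because the
threshold involves only the fast subsystem, it is insensitive to the
sAHP timescales and the noise rate, and — after nondimensionalization —
to $D$; `excitabilityThresholdCurve()` exposes the ACh/K conductance
threshold curve and `excitabilityBySimulation()` cross-checks it in the
full model, with strip and point initial data giving the same verdict.

# Forest-fire mapping

`ffmRun()` implements the Drossel–Schwabl forest-fire model with both
per-step spread (finite front speed, fires merging into one avalanche —
the variant matching the retinal analogy) and instantaneous cluster
burn (the classical event statistics). `mapToFFM()` rescales wave-model
observables onto $(p, f)$: one time unit is the burst duration
$\tau_b$, one lattice point is the elementary excited patch of linear
size (wave speed $\times\ \tau_b$), regrowth is
$p = \tau_b / T_{refractory}$ and lightning is
$f = \lambda\, \tau_b\, n_{cells}$ for per-cell spontaneous rate
$\lambda$. `socRegion()` encodes the double separation of timescales
under which the DS-FFM shows scale-free avalanches — lightning much
rarer than regrowth ($f \le p/5$), cluster burning much faster than
regrowth ($p\sqrt{p/f} \le 1/5$), and a mean cluster size small against
the lattice ($p/f \le \mathrm{side}^2/50$). The separation factor 5 and
size margin 50 are the package's operationalisation of "much"; the
boundaries are soft in the underlying physics. The reference slope for
comparisons is the ~1.14 size exponent reported for the 2D DS-FFM
scaling regime (`ffmReferenceExponent()`).

# Problem sizes and what the tests show

The test suite and the acceptance script use scaled-down runs: 400–600
s of 64$\times$64 simulation (after a warm-up of several hundred
seconds to desynchronise the refractory mosaic from the uniform initial
state), isolated-cell ensembles of 64–128 cells over a few thousand
seconds, and DS-FFM lattices of 64$^2$ with $10^4$–$10^5$ fires. These
reproduce the reported wave statistics at stochastic accuracy; they are
not the multi-thousand-second, 128$^2$ runs needed to resolve deep
power-law tails. The synthetic generator emulates the geometry of
spreading activity (programmed fronts, collisions, heavy-tailed size
samples) and deliberately does not emulate imaging noise, indicator
kinetics, or electrode subsampling, so passing fixture tests calibrates
the estimators, not the comparison to raw recordings.

# Known limitations

* The equations of motion were reconstructed from parameter tables and
  qualitative behaviour (see README); individual sigmoid assignments
  carry uncertainty even where the collective behaviour is tightly
  constrained.
* At the default parameters the network's self-organised state is the
  *synchronised, domain-covering* wave regime — one of the three regimes
  of spatially extended activity this class of models exhibits — rather
  than the asynchronous mosaic of bounded waves seen in recordings. The
  root cause is a margin mismatch in the reconstruction: a resting cell
  can only be ignited by the noise channel while its sAHP level is below
  ~0.03, whereas a travelling front invades any tissue below ~0.12, so
  whenever spontaneous ignition becomes possible the whole domain is
  already passable and each wave spans it. Statistics that average over
  this regime (mean wave speed, per-cell inter-wave interval, global wave
  frequency) therefore deviate from recorded retinal values even though
  the single-cell physiology, the front analysis and the isolated-cell
  statistics are reproduced; the acceptance script reports the measured
  values as they are.
* Lattice pinning makes the propagation threshold $s^*$ an interval in
  the strict continuum sense; the package reports the advancing/
  non-advancing transition of the discrete system, which is what
  governs the simulated waves on the same lattice.
* Directional bias of propagation, a ganglion-cell read-out layer,
  stage III (glutamatergic) waves, and electrode-subsampling artefacts
  are out of scope.
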