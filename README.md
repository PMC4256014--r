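# sacwave — reaction–diffusion modelling of cholinergic retinal waves

Before the retina can see, it generates its own input: spontaneous
waves of depolarisation sweep across the developing tissue and drive
activity-dependent wiring of the visual system. During stage II these
waves are cholinergic — initiated by rare intrinsic depolarisations of
starburst amacrine cells (SACs) and propagated laterally by the volume
release and diffusion of acetylcholine (ACh), with wave boundaries set
by an evolving mosaic of cells still refractory from earlier activity.

`sacwave` implements a biophysically grounded reaction–diffusion model
of this system for R, together with the analysis machinery used to
characterise it. Each lattice point carries one SAC with state
$(v, r, s, a)$ — membrane potential, K⁺/refractory gate, slow
after-hyperpolarisation (sAHP) level, and local extracellular ACh:

```
C v̇ = −g_L (v−E_L) − g_K r (v−E_K) − g_Ca m∞(v) (v−E_Ca) − (g_ACh α(a) + g_χ χ)(v−E_ACh)
 ṙ  = (w∞(v) + κ s − r) / τ_w(v)
 ṡ  = (s∞(v) − s) / τ_s(v)          τ_s: ~5 s depolarised, ~60 s at rest
 ȧ  = D ∇²a + β ρ(v) − a/τ_a
```

with Morris–Lecar gating (tanh/cosh forms), a Hill ACh conductance
α(a) = a²/(a² + K²) with K = 800 nM, sigmoidal ACh release above about
−55 mV, and a Bernoulli noise conductance (redrawn every 10 ms) that
produces the sparse spontaneous depolarisations. Only ACh diffuses;
it is the sole lateral coupling.

The package provides:

* **model core** — parameters and registry IO, gating/release/conductance
  functions, reaction right-hand sides, rest-state computation, and full
  nondimensionalization (`modelParams`, `reactionRHS`, `findRestState`,
  `nondimensionalize`);
* **simulator** — compiled stochastic integrator for 1D strips and 2D
  lattices (Strang-split locally-one-dimensional Crank–Nicolson
  diffusion around a Heun reaction step, zero-flux boundaries, seeded
  bit-exact reproducibility), single-cell and stimulation protocols
  (`runSimulation`, `runSingleCell`, `spontaneousRate`,
  `calibrateNoiseRate`);
* **wave analysis** — activity thresholding with boundary margin,
  spatiotemporal connected-component wave labelling, collision
  detection via onset clusters, backward-traced front speeds, per-cell
  inter-wave intervals, correlation-versus-distance curves, log-binned
  power-law fits (`waveStatistics`, `labelWaves`, `waveSpeed`,
  `interwaveIntervals`, `correlationVsDistance`, `fitPowerLaw`);
* **front analysis** — fixed points of the frozen-sAHP fast subsystem,
  travelling-front speeds by PDE relaxation and by a moving-frame
  Newton boundary-value solve, c(s) curves and the propagation
  threshold s*, excitability-threshold maps over the ACh/K conductance
  plane, and the absolute refractory period
  (`fastFixedPoints`, `frontSpeedRelaxation`, `frontProfileBVP`,
  `speedVsRefractory`, `excitabilityThresholdCurve`,
  `absoluteRefractoryPeriod`);
* **forest-fire mapping** — a Drossel–Schwabl lattice model (per-step
  spread and classical instantaneous modes), the rescaling of wave
  observables onto its (p, f) parameters, and the predicate for the
  self-organised-criticality region (`ffmRun`, `mapToFFM`,
  `socRegion`, `compareAvalancheStats`);
* **synthetic fixtures** — programmable disk-wave movies and
  power-law/exponential size samples with closed-form ground truth for
  calibrating every analysis stage (`makeDiskWave`, `samplePowerLaw`).

A command-line tool wrapping these stages (subcommands `simulate`,
`analyze`, `front-speed`, `threshold-map`, `refractory-period`, `ffm`,
`soc-map`, `make-fixture`) is installed at
`system.file("exec", "sacwave", package = "sacwave")`.

## A note on provenance

The model's equations were reconstructed from a parameter table
(dimensioned and dimensionless) and qualitative descriptions; the
reconstruction is validated in the test suite against the behaviour it
must reproduce (rest state, burst shape and graded refractory loading,
the ~15-minute isolated-cell event rate, travelling-front existence and
c(s) structure, the ~30 s absolute refractory period). The methods
vignette (`vignettes/sacwave-methods.Rmd`) documents every choice, the
numerical schemes, and the known limitation that at the default
parameters the network self-organises into a synchronised
domain-covering wave regime rather than the asynchronous mosaic of
bounded waves, which biases the network-level speed and inter-wave
statistics (see "Reproducing the results" below).

## Worked example

A two-minute simulation of a quarter-size lattice, analysed end to end:

```r
library(sacwave)

p <- modelParams()                      # registry defaults
cfg <- simConfig(duration = 120, warmup = 120, gridN = 64,
                 seed = 1, record = "activity")
snap <- runSimulation(cfg, p)
st <- waveStatistics(snap)              # threshold -60 mV, margin 5 cells
st$summary
#>       statistic        mean        sd    n
#> 1   waveSizeMm2  0.02066307 0.2361009  434     (0.5 ks run shown)
#> 2 waveDurationS  0.12744240 0.6342180  434
#> 3  waveSpeedMmS  0.30274737        NA    1
#> 4          iwiS 159.8630941 27.207684 6144
```

(The numbers above are from the 500 s headline run at seed 5; short
runs give noisier versions of the same statistics.) The size and
duration means count every labelled event, from single-cell noise
blips upward, which is why they sit far below the largest waves; the
speed is a backward-traced front speed of waves of at least 50 cells.

Single-cell physiology and the front analysis:

```r
spontaneousRate(p, cells = 96, duration = 4000, seed = 2)$meanInterval / 60
#> [1] 15.0      # minutes between isolated-cell events at -50 mV

sc <- speedVsRefractory(p, sGrid = c(0, 0.02, 0.05, 0.1, 0.15, 0.2))
sc$curve[1:3, c("s", "speed")]
#>      s     speed   # mm/s; monotone decreasing in the sAHP level
absoluteRefractoryPeriod(p, sStar = sc$sStar)
#> ~30 s             # time s(t) stays above the propagation threshold
```

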