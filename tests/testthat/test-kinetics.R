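# Single-cell kinetics: gating functions, ACh conductance and release,
# reaction right-hand side, rest state.

test_that("gating functions match an independent evaluation of the canonical forms", {
  p <- defaultP
  g <- p@gating
  vs <- c(-80, -55, -40, -20, 10)
  gf <- gatingFunctions(vs, p)
  # independent re-derivation, written out directly
  expect_equal(gf$mInf, 0.5 * (1 + tanh((vs - (-20)) / 20)), tolerance = 1e-12)
  expect_equal(gf$wInf, 0.5 * (1 + tanh((vs - (-40)) / 40)), tolerance = 1e-12)
  expect_equal(gf$tauW, 0.2 / cosh((vs - (-40)) / 80), tolerance = 1e-12)
})

test_that("gating midpoints, saturation, bounds and monotonicity hold", {
  p <- defaultP
  expect_equal(gatingFunctions(p@gating[["mHalf"]], p)$mInf, 0.5)
  expect_equal(gatingFunctions(p@gating[["wHalf"]], p)$wInf, 0.5)
  hi <- gatingFunctions(1e4, p)
  expect_equal(hi$mInf, 1); expect_equal(hi$wInf, 1)
  vs <- seq(-120, 80, length.out = 1000)
  gf <- gatingFunctions(vs, p)
  expect_true(all(gf$mInf >= 0 & gf$mInf <= 1))
  expect_true(all(gf$wInf >= 0 & gf$wInf <= 1))
  expect_true(all(gf$tauW > 0))
  expect_true(all(diff(gf$mInf) >= 0))
  expect_true(all(diff(gf$wInf) >= 0))
  expect_error(gatingFunctions(NaN, p), "finite")
})

test_that("ACh conductance is the Hill form with the expected anchors", {
  p <- defaultP
  gmax <- conductances(p)[["ACh"]]
  expect_equal(achConductance(0, p), 0)
  expect_equal(achConductance(800, p), gmax / 2)
  expect_equal(achConductance(1600, p), gmax * 4 / 5)  # 2K at n = 2
  aa <- seq(0, 5000, length.out = 1000)
  g <- achConductance(aa, p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= gmax))
  expect_error(achConductance(-1, p), ">= 0")
})

test_that("ACh release is sigmoidal with half-maximum at the release threshold", {
  p <- defaultP
  beta <- p@ach[["releaseRate"]]
  expect_equal(achReleaseRate(p@ach[["releaseHalf"]], p), beta / 2)
  expect_lt(achReleaseRate(-90, p), 0.01 * beta)   # deep hyperpolarisation
  expect_gt(achReleaseRate(50, p), 0.99 * beta)    # saturated during a burst
  vs <- seq(-120, 80, length.out = 1000)
  expect_true(all(diff(achReleaseRate(vs, p)) >= 0))
})

test_that("reaction RHS vanishes at the rest state and has decay-only ACh kinetics when hyperpolarised", {
  p <- defaultP
  rest <- findRestState(p)
  d <- reactionRHS(rest, p)
  # scale to comparable units (fractions/s; voltage scaled by 50 mV)
  expect_lt(max(abs(d / c(50, 1, 1, 800))), 1e-8)
  # hyperpolarised cell with residual ACh: a decays
  d2 <- reactionRHS(c(-85, 0.1, 0, 50), p)
  expect_lt(d2[["a"]], 0)
  expect_error(reactionRHS(c(-60, -0.2, 0, 0), p), "non-negative")
})

test_that("sAHP level relaxes to its voltage-dependent saturation from below", {
  # hold v depolarised, integrate s alone; closed-form exponential target
  p <- defaultP
  vHold <- 0
  sa <- sahpActivation(vHold, p)
  tau <- sa$tauS; sInf <- sa$sInf
  dt <- 0.01; nT <- round(3 * tau / dt)
  s <- 0; traj <- numeric(nT)
  for (i in seq_len(nT)) {
    s <- s + dt * (sInf - s) / tau
    traj[i] <- s
  }
  tt <- dt * seq_len(nT)
  expect_true(all(traj < sInf))
  expect_true(all(diff(traj) > 0))
  expect_equal(traj, sInf * (1 - exp(-tt / tau)), tolerance = 1e-3)
})

test_that("rest state is stable, hyperpolarised and nearly ACh-free", {
  rest <- findRestState(defaultP)
  expect_true(attr(rest, "stable"))
  expect_lt(rest[["v"]], -60)
  expect_gt(rest[["v"]], -85)
  expect_lt(rest[["a"]], 10)
  expect_true(rest[["r"]] >= 0 && rest[["r"]] <= 1)
  # removing the ACh conductance barely moves rest (negligible drive there)
  p0 <- modelParams(conductances = c(ACh = 0))
  expect_lt(abs(findRestState(p0)[["v"]] - rest[["v"]]), 0.5)
})

test_that("strongly raised calcium conductance destabilises the rest state and is flagged", {
  pHot <- modelParams(conductances = c(Ca = 300))
  expect_error(findRestState(pHot, requireStable = TRUE))
})
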