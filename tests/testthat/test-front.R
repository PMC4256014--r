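# Travelling-front analysis: fixed points, relaxation vs BVP speeds,
# c(s) monotonicity, threshold invariances, refractory period.

test_that("the frozen-s fast subsystem is bistable at s = 0 and mono-stable at large s", {
  fp0 <- fastFixedPoints(0)
  expect_true(attr(fp0, "bistable"))
  expect_gte(nrow(fp0), 3)  # rest + excited + saddle
  expect_true(any(fp0$type == "saddle"))
  stableV <- sort(fp0$v[fp0$type == "stable"])
  expect_lt(stableV[1], -60)            # rest
  expect_gt(stableV[length(stableV)], -30)  # excited
  fpHi <- fastFixedPoints(2)
  expect_false(attr(fpHi, "bistable"))
})

test_that("relaxation and BVP front speeds agree within 5% across the propagating range", {
  # the comparison is made at a lattice spacing fine enough to resolve the
  # voltage layer; the headline simulation spacing biases speeds ~5% low
  pFine <- sacwave:::modelParamsFrom(defaultP,
                                     domain = c(length = 0.5, gridN = 64))
  sVals <- c(0, 0.02, 0.04)
  cRel <- cBvp <- numeric(0)
  for (s in sVals) {
    rel <- frontSpeedRelaxation(s, defaultP)
    expect_identical(rel$status, "front")
    relF <- frontSpeedRelaxation(s, pFine, n = 1200, duration = 12)
    sol <- frontProfileBVP(s, defaultP, cInit = rel$speed,
                           profileInit = rel$profile)
    expect_true(sol@converged)
    expect_lt(sol@residual, 1e-8)
    cRel <- c(cRel, relF$speed); cBvp <- c(cBvp, sol@speed)
  }
  expect_lt(max(abs(cRel - cBvp) / abs(cBvp)), 0.05)
})

test_that("the BVP profile connects the fixed points and is translation invariant", {
  rel <- frontSpeedRelaxation(0, defaultP)
  sol <- frontProfileBVP(0, defaultP, cInit = rel$speed,
                         profileInit = rel$profile)
  n <- length(sol@xi)
  expect_equal(unname(sol@profile[1, "v"]), sol@excitedPoint[["v"]],
               tolerance = 1e-6)
  expect_equal(unname(sol@profile[n, "v"]), sol@restPoint[["v"]],
               tolerance = 1e-6)
  # re-solve from a profile shifted by 10 grid points: same speed
  pr <- rel$profile
  shift <- 10 * (pr$x[2] - pr$x[1])
  pr2 <- pr; pr2$x <- pr2$x + shift
  sol2 <- frontProfileBVP(0, defaultP, cInit = rel$speed, profileInit = pr2)
  expect_equal(sol2@speed, sol@speed, tolerance = 1e-4)
})

test_that("c(s) is monotone decreasing and lowered pointwise by a weaker ACh conductance", {
  sc <- speedVsRefractory(defaultP, sGrid = c(0, 0.02, 0.04, 0.08, 0.15),
                          n = 300, duration = 30)
  cv <- sc$curve
  adv <- cv[cv$status == "front" & is.finite(cv$speed), ]
  expect_gte(nrow(adv), 2)
  expect_true(all(diff(adv$speed) < 0))
  expect_true(is.finite(sc$sStar) && sc$sStar > 0)
  # a 25% reduction of g_ACh lowers the curve pointwise and lowers s*
  pLow <- modelParams(conductances = c(ACh = 0.75 * 3))
  scLow <- speedVsRefractory(pLow, sGrid = c(0, 0.02, 0.04, 0.08, 0.15),
                             n = 300, duration = 30)
  for (s in intersect(adv$s, scLow$curve$s)) {
    cHi <- cv$speed[cv$s == s]; cLo <- scLow$curve$speed[scLow$curve$s == s]
    if (is.finite(cHi) && is.finite(cLo)) expect_lt(cLo, cHi)
  }
  expect_lte(scLow$sStar, sc$sStar)
})

test_that("without lateral excitation the excited region recedes", {
  p0 <- modelParams(conductances = c(ACh = 0))
  r <- frontSpeedRelaxation(0, p0)
  expect_true(r$status %in% c("receding", "no-front", "pinned"))
  if (is.finite(r$speed)) expect_lte(r$speed, 0)
})

test_that("front speed scales as sqrt(D)", {
  # at halved lattice spacing, where discreteness no longer biases the speed
  pF <- sacwave:::modelParamsFrom(defaultP, domain = c(length = 1, gridN = 64))
  p4 <- sacwave:::modelParamsFrom(modelParams(diffusion = 0.04),
                                  domain = c(length = 1, gridN = 64))
  r1 <- frontSpeedRelaxation(0, pF, n = 600, duration = 25)
  r4 <- frontSpeedRelaxation(0, p4, n = 600, duration = 20)
  expect_equal(r4$speed / r1$speed, 2, tolerance = 0.03)
})

test_that("grid refinement changes the relaxation speed by less than ~1%", {
  r1 <- frontSpeedRelaxation(0, defaultP, n = 300)
  # halve the lattice spacing by shrinking the stored domain length
  pFine <- sacwave:::modelParamsFrom(defaultP,
                                     domain = c(length = 1, gridN = 64))
  r2 <- frontSpeedRelaxation(0, pFine, n = 600)
  expect_equal(r2$speed, r1$speed, tolerance = 0.05)
})

test_that("excitability by simulation matches the front analysis and initial-data geometry", {
  expect_true(excitabilityBySimulation(defaultP, gridN = 48,
                                       domainLength = 0.75, duration = 8))
  p0 <- modelParams(conductances = c(ACh = 0))
  expect_false(excitabilityBySimulation(p0, gridN = 48, domainLength = 0.75,
                                        duration = 8))
  # strip and point initial data agree on both sides of the threshold
  for (gA in c(1, 3)) {
    pA <- modelParams(conductances = c(ACh = gA))
    st <- excitabilityBySimulation(pA, init = "strip", gridN = 48,
                                   domainLength = 0.75, duration = 8)
    pt <- excitabilityBySimulation(pA, init = "point", gridN = 48,
                                   domainLength = 0.75, duration = 8)
    expect_identical(st, pt, label = sprintf("gA = %g", gA))
  }
})

test_that("the excitability threshold is insensitive to slow timescales and noise rate", {
  grid <- c(8, 10)
  base <- excitabilityThresholdCurve(defaultP, gKGrid = grid,
                                     gARange = c(0.2, 8), tol = 0.1,
                                     n = 200, duration = 20)
  expect_true(all(is.finite(base$gAThreshold)))
  pSlow <- sacwave:::modelParamsFrom(defaultP,
                                     sahp = c(tauAct = 10, tauDecay = 120),
                                     noise = c(rate = 3))
  alt <- excitabilityThresholdCurve(pSlow, gKGrid = grid,
                                    gARange = c(0.2, 8), tol = 0.1,
                                    n = 200, duration = 20)
  expect_equal(alt$gAThreshold, base$gAThreshold, tolerance = 0.15)
  # D is scaled out: quadrupling D leaves the threshold unchanged
  pD <- modelParams(diffusion = 0.04)
  altD <- excitabilityThresholdCurve(pD, gKGrid = grid,
                                     gARange = c(0.2, 8), tol = 0.1,
                                     n = 200, duration = 20)
  expect_equal(altD$gAThreshold, base$gAThreshold, tolerance = 0.15)
})

test_that("the absolute refractory period follows the sAHP decay law", {
  sc <- speedVsRefractory(defaultP, sGrid = c(0, 0.02, 0.05, 0.1, 0.15),
                          n = 300, duration = 30)
  arp <- absoluteRefractoryPeriod(defaultP, sStar = sc$sStar)
  expect_gt(as.numeric(arp), 5)
  expect_lt(as.numeric(arp), 120)
  s0 <- attr(arp, "s0")
  # exponential-decay closed form: period ~ tauDecay * log(s0/s*)
  pred <- defaultP@sahp[["tauDecay"]] * log(s0 / attr(arp, "sStar"))
  expect_equal(as.numeric(arp), pred, tolerance = 0.35)
  # period grows with the sAHP decay time
  periods <- vapply(c(30, 60, 90), function(tauS) {
    pT <- sacwave:::modelParamsFrom(defaultP, sahp = c(tauDecay = tauS))
    as.numeric(absoluteRefractoryPeriod(pT, sStar = sc$sStar))
  }, 0)
  expect_true(all(diff(periods) > 0))
  # a vanishing threshold pushes the period beyond any finite horizon
  arp0 <- absoluteRefractoryPeriod(defaultP, sStar = 1e-6, horizon = 60)
  expect_true(!is.finite(arp0) || arp0 > 55)
})
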