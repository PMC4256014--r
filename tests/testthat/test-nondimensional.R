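# Nondimensionalization: reference values, degenerate scaling, and
# dimensional consistency of trajectories.

test_that("dimensionless parameters reproduce the reference table to 4 significant digits", {
  dp <- nondimensionalize(defaultP)
  ref <- dimensionlessReference()
  for (i in seq_len(nrow(ref))) {
    expect_equal(unname(dp@values[[ref$name[i]]]), ref$value[i],
                 tolerance = 5e-4, label = ref$name[i])
  }
  # space scale = sqrt(D * time scale)
  expect_equal(dp@scales[["space"]],
               sqrt(defaultP@diffusion * dp@scales[["time"]]))
  expect_lt(dp@values[["epsilon"]], 0.01)  # strong timescale separation
})

test_that("zero diffusion gives a degenerate (flagged) space scale", {
  p0 <- modelParams(diffusion = 0)
  expect_warning(dp <- nondimensionalize(p0), "degenerate")
  expect_equal(dp@scales[["space"]], 0)
})

test_that("dimensioned and dimensionless trajectories map onto each other", {
  p <- defaultP
  dp <- nondimensionalize(p)
  V0 <- dp@scales[["voltage"]]; T0 <- dp@scales[["time"]]
  A0 <- dp@scales[["concentration"]]
  y <- c(v = -50, r = 0.2, s = 0.05, a = 400)     # off-rest initial state
  z <- c(y[["v"]] / V0, y[["r"]], y[["s"]], y[["a"]] / A0)
  dtD <- 1e-4                                      # s
  dtS <- dtD / T0
  nSteps <- 20000                                  # 2 s of model time
  for (i in seq_len(nSteps)) {
    # midpoint steps of both systems
    k1 <- reactionRHS(y, p)
    k2 <- reactionRHS(y + 0.5 * dtD * k1, p)
    y <- y + dtD * k2
    q1 <- scaledReactionRHS(z, dp)
    q2 <- scaledReactionRHS(z + 0.5 * dtS * q1, dp)
    z <- z + dtS * q2
  }
  mapped <- c(y[["v"]] / V0, y[["r"]], y[["s"]], y[["a"]] / A0)
  expect_equal(unname(mapped), unname(z), tolerance = 1e-6)
})

test_that("fixed points of the scaled and dimensioned fast kinetics correspond", {
  fp <- fastFixedPoints(0, defaultP)
  expect_true(attr(fp, "bistable"))
  dp <- nondimensionalize(defaultP)
  # scaled voltages of the fixed points stay fixed points of the scaled RHS
  for (i in seq_len(nrow(fp))) {
    z <- c(fp$v[i] / 50, fp$r[i], 0, fp$a[i])
    dz <- scaledReactionRHS(z, dp)
    expect_lt(max(abs(dz[c(1, 2, 4)] / c(1 / dp@values[["epsilon"]], 1, dp@values[["betaScaled"]]))), 1e-6)
  }
})
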