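# Simulator numerics: symmetry, convergence order, diffusion solver,
# noise statistics, determinism, decoupled limit.

test_that("a uniform lattice stays exactly uniform under the reaction step", {
  n <- 64
  st <- list(v = rep(-50, n), r = rep(0.3, n), s = rep(0.02, n),
             a = rep(100, n))
  out <- stepReaction(st, defaultP, dt = 0.001)
  for (f in c("v", "r", "s", "a"))
    expect_true(all(out[[f]] == out[[f]][1]))
})

test_that("the Heun reaction step is second order (Richardson ratio ~4)", {
  y0 <- list(v = -55, r = 0.15, s = 0.01, a = 300)
  stepTo <- function(dt, nStep) {
    st <- y0
    for (i in seq_len(nStep)) st <- stepReaction(st, defaultP, dt)
    unlist(st)
  }
  # high-accuracy reference: many tiny steps
  ref <- stepTo(1e-6, 4000)
  eBig <- max(abs(stepTo(4e-3, 1) - ref) / c(50, 1, 1, 800))
  eSmall <- max(abs(stepTo(2e-3, 2) - ref) / c(50, 1, 1, 800))
  expect_gt(eBig / eSmall, 3)
  expect_lt(eBig / eSmall, 5.5)
})

test_that("pure diffusion preserves a uniform field and conserves total ACh", {
  n <- 32
  a0 <- matrix(7.5, n, n)
  a1 <- stepDiffusion(a0, D = 0.01, dt = 0.01, dx = 0.03125)
  expect_equal(a1, a0, tolerance = 1e-13)
  set.seed(3)
  a0 <- matrix(runif(n * n, 0, 500), n, n)
  a1 <- a0
  for (i in 1:200) a1 <- stepDiffusion(a1, D = 0.01, dt = 0.01, dx = 0.03125)
  expect_equal(sum(a1), sum(a0), tolerance = 1e-10)
  expect_true(all(a1 >= 0))
  expect_lt(max(a1) - min(a1), max(a0) - min(a0))  # smoothing
})

test_that("diffusion of a Gaussian bump matches the analytic heat kernel", {
  # wide domain so boundaries are irrelevant over the horizon
  n <- 96; dx <- 0.02; D <- 0.01; sigma0 <- 0.08; tEnd <- 0.5; dt <- 0.001
  a <- gaussianBump(n, dx, sigma0)
  for (i in seq_len(round(tEnd / dt))) a <- stepDiffusion(a, D, dt, dx)
  sigmaT2 <- sigma0^2 + 2 * D * tEnd
  exact <- gaussianBump(n, dx, sqrt(sigmaT2)) * sigma0^2 / sigmaT2
  l2err <- sqrt(sum((a - exact)^2) / sum(exact^2))
  expect_lt(l2err, 0.01)
})

test_that("noise mask statistics are Bernoulli with the configured rate", {
  p <- defaultP
  pOpen <- p@noise[["rate"]] * p@noise[["updateInterval"]]
  set.seed(99)
  n <- 1e6
  mask <- updateNoiseMask(logical(n), p)
  k <- sum(mask)
  expect_lt(abs(k - n * pOpen), 3 * sqrt(n * pOpen * (1 - pOpen)))
  # inter-opening intervals of a single cell are geometric with mean 1/p
  set.seed(7)
  draws <- runif(2e5) < pOpen
  gaps <- diff(which(draws))
  expect_equal(mean(gaps), 1 / pOpen, tolerance = 0.05)
  pBad <- modelParams(noise = c(rate = 200))  # rate*interval = 2 > 1
  expect_error(updateNoiseMask(logical(2), pBad), "probability")
})

test_that("rate zero keeps every channel closed", {
  p0 <- modelParams(noise = c(rate = 0))
  set.seed(1)
  expect_false(any(updateNoiseMask(logical(1e4), p0)))
})

test_that("identical seeds give bit-identical snapshot series, different seeds differ", {
  cfg <- tinyConfig(duration = 1, seed = 42, noise = TRUE, record = "full")
  s1 <- runSimulation(cfg)
  s2 <- runSimulation(cfg)
  expect_identical(s1@fields, s2@fields)
  expect_identical(s1@times, s2@times)
  cfg2 <- tinyConfig(duration = 1, seed = 43, noise = TRUE, record = "full")
  s3 <- runSimulation(cfg2)
  expect_false(identical(s1@fields$v, s3@fields$v))
  # provenance metadata (parameters) identical across seeds
  expect_identical(sacwave:::asParamVector(s1@metadata$params),
                   sacwave:::asParamVector(s3@metadata$params))
})

test_that("with D = 0 and no noise every lattice cell follows the single-cell trajectory", {
  p0 <- modelParams(diffusion = 0)
  init <- list(v = -55, r = 0.1, s = 0.01, a = 200)
  cfg <- tinyConfig(duration = 5, n = 8, record = "full")
  snap <- runSimulation(cfg, p0, init = init)
  tr <- runSingleCell(p0, duration = 5, init = init,
                      recordInterval = cfg@snapshotInterval)
  nt <- length(snap@times)
  vGrid <- matrix(snap@fields$v, 64, nt)
  for (cell in c(1, 30, 64))
    expect_equal(vGrid[cell, ], tr$v, tolerance = 1e-8)
})

test_that("the decoupled limit agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p0 <- modelParams(diffusion = 0)
  init <- c(v = -65, r = 0.25, s = 0.05, a = 150)  # smooth relaxation to rest
  tr <- runSingleCell(p0, duration = 100, init = init, recordInterval = 0.5)
  rhs <- function(t, y, parms) list(unname(reactionRHS(y, p0)))
  ref <- deSolve::lsoda(init, seq(0, 100, by = 0.5), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(tr$v - ref[, "v"])) / 50, 1e-6)
  expect_lt(max(abs(tr$s - ref[, "s"])), 1e-6)
  expect_lt(max(abs(tr$a - ref[, "a"])) / 800, 1e-6)
})

test_that("a suprathreshold current injection evokes a burst with graded refractory loading", {
  p <- defaultP
  prot <- data.frame(start = 2, end = 3.5, amplitude = 100)
  tr <- runSingleCell(p, duration = 60, protocol = prot)
  expect_gt(max(tr$v), -20)                      # burst
  expect_lt(min(tr$v[tr$time > 6]), restDefault[["v"]] - 3)  # after-hyperpolarisation
  sPeak1 <- max(tr$s)
  prot2 <- data.frame(start = 2, end = 3.5, amplitude = 200)
  tr2 <- runSingleCell(p, duration = 60, protocol = prot2)
  expect_gte(max(tr2$s), sPeak1)                 # larger injection, larger load
  # second response shortly after the burst is suppressed while s is elevated
  prot3 <- data.frame(start = c(2, 12), end = c(3.5, 13.5),
                      amplitude = c(100, 100))
  tr3 <- runSingleCell(p, duration = 30, protocol = prot3)
  resp1 <- max(tr3$v[tr3$time >= 2 & tr3$time < 6])
  resp2 <- max(tr3$v[tr3$time >= 12 & tr3$time < 16])
  expect_lt(resp2, resp1 - 10)
})

test_that("a centred point stimulus under zero noise spreads with radial symmetry", {
  p <- defaultP
  n <- 32
  cfg <- simConfig(duration = 2, warmup = 0, gridN = n, domainLength = 1,
                   seed = 1, noise = FALSE, record = "full",
                   snapshotInterval = 0.05)
  centre <- c(n / 2, n / 2)
  cells <- as.vector(outer((centre[1] - 1):(centre[1] + 1),
                           ((centre[2] - 1):(centre[2] + 1) - 1) * n, "+"))
  prot <- data.frame(start = 0.1, end = 0.6, amplitude = 300, cell = cells)
  snap <- runSimulation(cfg, p, protocol = prot)
  nt <- length(snap@times)
  v <- array(snap@fields$v, c(n, n, nt))
  fr <- which.min(abs(snap@times - 1.5))  # front mid-domain, pre-boundary
  act <- which(v[, , fr] > -40, arr.ind = TRUE)
  expect_gt(nrow(act), 100)  # a wave is spreading
  r <- sqrt((act[, 1] - centre[1])^2 + (act[, 2] - centre[2])^2)
  ang <- atan2(act[, 2] - centre[2], act[, 1] - centre[1])
  bins <- cut(ang, breaks = seq(-pi, pi, length.out = 9))
  rmax <- tapply(r, bins, max)
  rmax <- rmax[is.finite(rmax)]
  expect_lt(diff(range(rmax)), 1.5)  # radius varies by < a cell over angle
})

test_that("snapshot bookkeeping matches the configured cadence", {
  cfg <- tinyConfig(duration = 0.2, record = "activity")
  snap <- runSimulation(cfg)
  expect_equal(length(snap@times), 21)         # 0..0.2 every 0.01
  expect_equal(diff(snap@times)[1], cfg@snapshotInterval)
  expect_s4_class(snap, "SnapshotSeries")
  expect_error(simConfig(duration = 1, snapshotInterval = 0.0015),
               "integer multiple")
})
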