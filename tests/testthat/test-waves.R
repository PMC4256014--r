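# Wave-analysis pipeline against fixtures with closed-form ground truth.

test_that("thresholding respects the margin and the threshold", {
  snap <- makeDiskWave(data.frame(x = 16, y = 16), onsets = 0, speed = 0.1,
                       duration = 1, gridN = 32, domainLength = 1)
  # all-rest series -> empty mask
  snapRest <- makeDiskWave(data.frame(x = 16, y = 16), onsets = 10,
                           speed = 0.1, duration = 1, gridN = 32,
                           domainLength = 1)
  m0 <- thresholdActivity(snapRest, -60, margin = 5)
  expect_equal(sum(as.integer(m0$mask)), 0)
  # a single interior active cell -> exactly one active entry
  one <- snapRest
  one@fields$v[16, 16, 3] <- -20
  m1 <- thresholdActivity(one, -60, margin = 5)
  expect_equal(sum(as.integer(m1$mask)), 1)
  # margin cells never active even when suprathreshold
  edge <- snapRest
  edge@fields$v[2, 16, 3] <- -20
  m2 <- thresholdActivity(edge, -60, margin = 5)
  expect_equal(sum(as.integer(m2$mask)), 0)
  expect_error(thresholdActivity(snapRest, -60, margin = 16), "margin")
})

test_that("disjoint blobs get distinct labels; merging disks are one collision wave", {
  two <- makeDiskWave(data.frame(x = c(12, 52), y = c(12, 52)),
                      onsets = c(0.2, 0.2), speed = 0.1, duration = 2)
  w2 <- labelWaves(thresholdActivity(two, -60))
  expect_equal(nrow(w2), 2)
  expect_false(any(w2$collision))
  # two nearby disks timed to merge -> one wave, collision flagged
  mer <- makeDiskWave(data.frame(x = c(28, 38), y = c(32, 32)),
                      onsets = c(0.2, 0.6), speed = 0.1, duration = 4,
                      burstDuration = 2)
  wm <- labelWaves(thresholdActivity(mer, -60))
  expect_equal(nrow(wm), 1)
  expect_true(wm$collision[1])
  expect_equal(wm$nOnsets[1], 2)
})

test_that("a single expanding disk has the programmed size and duration", {
  snap <- makeDiskWave(data.frame(x = 32, y = 32), onsets = 0.5, speed = 0.1,
                       duration = 5, burstDuration = 0.5)
  mask <- thresholdActivity(snap, -60, margin = 5)
  w <- labelWaves(mask)
  expect_equal(nrow(w), 1)
  expect_false(w$collision[1])
  # ground truth: cells within the final outer radius
  dx <- 2 / 64
  rOut <- 0.1 * (5 - 0.5)
  xs <- ((1:64) - 0.5) * dx
  cx <- (32 - 0.5) * dx
  inDisk <- outer(xs, xs, function(a, b) sqrt((a - cx)^2 + (b - cx)^2) <= rOut)
  inDisk[c(1:5, 60:64), ] <- FALSE; inDisk[, c(1:5, 60:64)] <- FALSE
  expect_equal(w$sizeCells[1], sum(inDisk), tolerance = 0.06)
  expect_equal(w$durationS[1], 4.5, tolerance = 0.02)
})

test_that("the speed estimator recovers programmed disk speeds within 10%", {
  for (sp in c(0.05, 0.10, 0.20)) {
    snap <- makeDiskWave(data.frame(x = 32, y = 32), onsets = 0.3, speed = sp,
                         duration = min(6, 0.3 + 0.85 / sp),
                         burstDuration = max(0.4, 1.5 * (2 / 64) / sp))
    w <- waveSpeed(labelWaves(thresholdActivity(snap, -60)))
    est <- w$meanSpeed[!is.na(w$meanSpeed)]
    expect_length(est, 1)
    expect_equal(est, sp, tolerance = 0.1, label = sprintf("speed %g", sp))
  }
})

test_that("a stationary blinking blob has near-zero speed and collisions are excluded", {
  snap <- makeDiskWave(data.frame(x = 32, y = 32), onsets = 0.2,
                       speed = 1e-6, duration = 4, burstDuration = 10,
                       maxRadius = 0.12)
  # force the blob to cover >= 50 cells instantly: use a faster growth then cap
  snap2 <- makeDiskWave(data.frame(x = 32, y = 32), onsets = 0.2, speed = 0.4,
                        duration = 4, burstDuration = 10, maxRadius = 0.15)
  w <- waveSpeed(labelWaves(thresholdActivity(snap2, -60)))
  est <- w$meanSpeed[!is.na(w$meanSpeed)]
  expect_length(est, 1)
  expect_lt(est, 0.07)  # front only moves during the brief growth phase
  mer <- makeDiskWave(data.frame(x = c(28, 38), y = c(32, 32)),
                      onsets = c(0.2, 0.6), speed = 0.1, duration = 6,
                      burstDuration = 3)
  wm <- waveSpeed(labelWaves(thresholdActivity(mer, -60)))
  expect_true(all(is.na(wm$meanSpeed)))
  expect_equal(wm$excludedReason, "collision")
})

test_that("interwave intervals implement the minimum-interval merge rule", {
  # crossings at 10, 11 and 60 s with a 2 s minimum -> one interval of 50 s
  nx <- 12; nt <- 700
  m <- array(0L, c(nx, nx, nt))
  tt <- seq(0.1, 70, by = 0.1)
  cell <- c(7, 7)
  for (t0 in c(10, 11, 60)) m[cell[1], cell[2], which.min(abs(tt - t0))] <- 1L
  mask <- structure(list(mask = as.raw(m), times = tt, gridN = c(nx, nx),
                         domainLength = 1, threshold = -60, margin = 0),
                    class = "activityMask")
  iwi <- interwaveIntervals(mask, minIwi = 2)
  expect_equal(nrow(iwi), 1)
  expect_equal(iwi$interval, 50)
  # a cell active only once contributes no interval
  m2 <- array(0L, c(nx, nx, nt)); m2[3, 3, 5] <- 1L
  mask2 <- structure(list(mask = as.raw(m2), times = tt, gridN = c(nx, nx),
                          domainLength = 1, threshold = -60, margin = 0),
                     class = "activityMask")
  expect_equal(nrow(interwaveIntervals(mask2)), 0)
})

test_that("every active entry belongs to exactly one wave (partition property)", {
  set.seed(21)
  for (rep in 1:3) {
    nx <- 20; nt <- 40
    m <- array(as.integer(runif(nx * nx * nt) < 0.12), c(nx, nx, nt))
    mask <- structure(list(mask = as.raw(m), times = (1:nt) * 0.01,
                           gridN = c(nx, nx), domainLength = 1,
                           threshold = -60, margin = 0),
                      class = "activityMask")
    w <- labelWaves(mask)
    vox <- attr(w, "voxels")
    expect_equal(nrow(vox), sum(m))                 # no orphan entries
    expect_equal(sum(w$activeEntries), sum(m))      # sizes partition the mask
    expect_equal(sort(unique(vox$wave)), w$wave)    # ids consistent
  }
})

test_that("raising the threshold never increases any wave's size", {
  cfg <- tinyConfig(duration = 3, n = 24, seed = 9, noise = TRUE,
                    record = "full")
  p <- modelParams(noise = c(rate = 3))  # dense blips on the tiny lattice
  snap <- runSimulation(cfg, p)
  mLow <- thresholdActivity(snap, -62, margin = 2)
  mHigh <- thresholdActivity(snap, -55, margin = 2)
  expect_lte(sum(as.integer(mHigh$mask)), sum(as.integer(mLow$mask)))
  totLow <- sum(labelWaves(mLow)$sizeCells)
  totHigh <- sum(labelWaves(mHigh)$sizeCells)
  expect_lte(totHigh, totLow)
})

test_that("labels are deterministic for a fixed mask", {
  set.seed(4)
  nx <- 16; nt <- 20
  m <- array(as.integer(runif(nx * nx * nt) < 0.1), c(nx, nx, nt))
  mask <- structure(list(mask = as.raw(m), times = (1:nt) * 0.01,
                         gridN = c(nx, nx), domainLength = 1,
                         threshold = -60, margin = 0),
                    class = "activityMask")
  expect_identical(labelWaves(mask)$sizeCells, labelWaves(mask)$sizeCells)
})

test_that("correlation is 1 at zero distance and ~0 for white-noise fields", {
  set.seed(8)
  nx <- 24; nt <- 400
  noise <- array(rnorm(nx * nx * nt), c(nx, nx, nt))
  snap <- new("SnapshotSeries", times = (1:nt) * 0.1,
              fields = list(v = noise), activity = raw(0),
              coarseTimes = (1:nt) * 0.1, gridN = c(nx, nx),
              domainLength = 1, metadata = list())
  cc <- correlationVsDistance(snap, "v", margin = 2)
  expect_true(all(abs(cc$correlation) <= 1))
  ref <- (nx %/% 2) * nx + nx %/% 2 + 1
  expect_equal(cc$correlation[which(cc$distance == 0)], 1)
  far <- cc$curve$mean[cc$curve$distance > 0.2]
  expect_lt(max(abs(far), na.rm = TRUE), 3 / sqrt(nt))
})

test_that("the power-law fit recovers a programmed exponent and flags exponential samples", {
  s <- samplePowerLaw(1.5, n = 1e4, seed = 2)
  fit <- fitPowerLaw(s)
  expect_equal(fit$slope, -1.5, tolerance = 0.1)
  expect_false(fit$curved)
  expect_equal(fit$mleExponent, 1.5, tolerance = 0.1)
  e <- sampleExponentialSizes(20, n = 1e4, seed = 3)
  fitE <- fitPowerLaw(e)
  expect_true(fitE$curved)
  expect_error(fitPowerLaw(rep(5, 100)), "degenerate")
  expect_error(fitPowerLaw(samplePowerLaw(1.5, n = 10, seed = 1)), "at least 50")
})
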