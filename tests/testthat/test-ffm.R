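# Forest-fire model: rules, determinism, avalanche statistics, the
# (p, f) mapping and the SOC-region predicate.

# independent reference implementation of the instantaneous-burn DS-FFM,
# written in plain R over full-lattice draws (no shared code with the
# compiled simulator beyond R's RNG stream semantics)
refFFM <- function(side, p, f, steps, seed, burnin = steps / 5) {
  set.seed(seed)
  st <- matrix(0L, side, side)
  sizes <- integer(0)
  nb <- function(i, j) {
    cbind(c(i - 1, i + 1, i, i), c(j, j, j - 1, j + 1))
  }
  for (step in seq_len(steps)) {
    grow <- st == 0L & matrix(runif(side * side) < p, side, side)
    st[grow] <- 1L
    strike <- which(st == 1L & matrix(runif(side * side) < f, side, side),
                    arr.ind = TRUE)
    if (nrow(strike)) for (k in seq_len(nrow(strike))) {
      i <- strike[k, 1]; j <- strike[k, 2]
      if (st[i, j] != 1L) next
      queue <- matrix(c(i, j), 1)
      st[i, j] <- 0L
      sz <- 1L
      while (nrow(queue)) {
        cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
        for (q in 1:4) {
          nn <- nb(cur[1], cur[2])[q, ]
          if (nn[1] >= 1 && nn[1] <= side && nn[2] >= 1 && nn[2] <= side &&
              st[nn[1], nn[2]] == 1L) {
            st[nn[1], nn[2]] <- 0L
            sz <- sz + 1L
            queue <- rbind(queue, nn)
          }
        }
      }
      if (step > burnin) sizes <- c(sizes, sz)
    }
  }
  sizes
}

test_that("no lightning means no fires; full lattice burns as one cluster", {
  rec <- ffmRun(16, p = 0.1, f = 0, steps = 500, seed = 1)
  expect_equal(nrow(rec$fires), 0)
  # p = 1 fills the lattice; f = 1 then burns the whole connected cluster
  rec2 <- ffmRun(16, p = 1, f = 0, steps = 3, seed = 1,
                 mode = "instantaneous", burnin = 0)
  expect_true(all(rec2$finalState == 1))
  rec3 <- ffmRun(16, p = 1, f = 1, steps = 2, seed = 1,
                 mode = "instantaneous", burnin = 0)
  expect_equal(max(rec3$fires$size), 16 * 16)
})

test_that("each site is in exactly one of the three states; runs are seed-deterministic", {
  rec <- ffmRun(24, p = 0.05, f = 0.002, steps = 2000, seed = 5)
  expect_true(all(rec$finalState %in% 0:2))
  rec2 <- ffmRun(24, p = 0.05, f = 0.002, steps = 2000, seed = 5)
  expect_identical(rec$fires, rec2$fires)
  expect_identical(rec$finalState, rec2$finalState)
  rec3 <- ffmRun(24, p = 0.05, f = 0.002, steps = 2000, seed = 6)
  expect_false(identical(rec$fires, rec3$fires))
})

test_that("tree density is stationary after burn-in", {
  rec <- ffmRun(48, p = 0.05, f = 0.005, steps = 6000, seed = 2,
                trackDensity = TRUE, burnin = 3000)
  d <- rec$treeDensity
  half1 <- mean(d[seq_len(length(d) / 2)])
  half2 <- mean(d[-seq_len(length(d) / 2)])
  expect_lt(abs(half1 - half2), 0.05)
  expect_gt(half1, 0.1); expect_lt(half1, 0.9)
})

test_that("mean fire size grows monotonically with p/f", {
  ratios <- c(10, 30, 100, 300, 1000)
  means <- vapply(ratios, function(rr) {
    rec <- ffmRun(64, p = 0.05, f = 0.05 / rr, steps = 12000, seed = 3,
                  mode = "instantaneous", burnin = 4000)
    mean(rec$fires$size)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("avalanche-size slope matches an independent implementation within 0.2", {
  side <- 64; p <- 0.05; f <- p / 200
  rec <- ffmRun(side, p, f, steps = 60000, seed = 11,
                mode = "instantaneous", burnin = 10000)
  expect_gt(nrow(rec$fires), 500)
  fit <- fitPowerLaw(rec$fires$size, xmin = 1)
  ref <- refFFM(side, p, f, steps = 6000, seed = 12, burnin = 1500)
  expect_gt(length(ref), 100)
  fitRef <- fitPowerLaw(ref, xmin = 1)
  expect_equal(fit$slope, fitRef$slope, tolerance = 0.2,
               label = "compiled vs reference slope")
})

test_that("the (p, f) mapping has the expected functional form", {
  base <- mapToFFM(waveSpeed = 0.11, spontRate = 1 / 900,
                   burstDuration = 0.6, refractoryPeriod = 30)
  doubledRefr <- mapToFFM(0.11, 1 / 900, 0.6, 60)
  expect_equal(doubledRefr$p, base$p / 2)
  expect_equal(doubledRefr$f, base$f)
  doubledRate <- mapToFFM(0.11, 2 / 900, 0.6, 30)
  expect_equal(doubledRate$f, 2 * base$f)
  expect_equal(doubledRate$p, base$p)
  expect_error(mapToFFM(0.11, 1 / 900, 30, 10), "degenerate")
})

test_that("the SOC predicate excludes both no-separation and domain-spanning limits", {
  expect_false(as.logical(socRegion(0.05, 0.05, 128)))       # f = p
  expect_false(as.logical(socRegion(0.05, 1e-9, 128)))       # p/f -> infinity
  expect_true(as.logical(socRegion(0.01, 0.01 / 200, 128)))  # scaling regime
  # for fixed p the predicate is true on one interval of f and false outside
  fGrid <- 10^seq(-8, -1, length.out = 60)
  inside <- vapply(fGrid, function(f) as.logical(socRegion(0.01, f, 128)), NA)
  runs <- rle(inside)
  expect_equal(sum(runs$values), 1)
})

test_that("avalanche comparison flags only the exponential sample as curved", {
  s1 <- samplePowerLaw(1.3, n = 5000, seed = 4)
  s2 <- samplePowerLaw(1.3, n = 5000, seed = 5)
  cmpOk <- compareAvalancheStats(s1, s2)
  expect_true(cmpOk$agree)
  expect_false(cmpOk$waveCurved); expect_false(cmpOk$ffmCurved)
  e <- sampleExponentialSizes(15, n = 5000, seed = 6)
  cmpBad <- compareAvalancheStats(e, s2)
  expect_true(cmpBad$waveCurved)
  expect_false(cmpBad$ffmCurved)
  expect_warning(compareAvalancheStats(s1[1:50], s2), "under-powered")
})
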