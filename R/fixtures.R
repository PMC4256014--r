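# Synthetic fixtures with closed-form ground truth: programmable
# expanding/colliding disk waves and power-law samples, for calibrating
# the analysis pipeline without running the simulator.

#' Generate a synthetic disk-wave snapshot series
#'
#' Builds a \code{\link{SnapshotSeries}} in which the voltage field is
#' suprathreshold inside expanding annuli of programmed radial speed and
#' per-cell burst duration, and at rest elsewhere. The active member set
#' is computable in closed form, so the series carries exact ground truth
#' for the wave detector, the speed estimator and the collision flag.
#'
#' @param centres matrix/data.frame with columns \code{x}, \code{y}
#'   (cell coordinates, 1-based) — one row per initiation point.
#' @param onsets onset time of each wave, s.
#' @param speed radial front speed, mm/s (recycled per wave).
#' @param burstDuration time each cell stays active after the front passes,
#'   s (default 0.5).
#' @param duration total series duration, s (a zero or negative duration
#'   gives an empty series).
#' @param gridN lattice side (default 64).
#' @param domainLength mm (default 2).
#' @param snapshotInterval s (default 0.01).
#' @param maxRadius stop radius, mm (default: grows for the whole series).
#' @param vRest,vActive voltages used for inactive/active cells, mV.
#' @return a \code{\link{SnapshotSeries}} with a \code{v} field; ground
#'   truth in \code{metadata$groundTruth}.
#' @examples
#' snap <- makeDiskWave(data.frame(x = 32, y = 32), onsets = 0.5,
#'                      speed = 0.1, duration = 5)
#' @export
makeDiskWave <- function(centres, onsets, speed = 0.1, burstDuration = 0.5,
                         duration, gridN = 64, domainLength = 2,
                         snapshotInterval = 0.01, maxRadius = NULL,
                         vRest = -74, vActive = 0) {
  centres <- as.data.frame(centres)
  if (!all(c("x", "y") %in% names(centres))) stop("centres needs columns x, y")
  nW <- nrow(centres)
  onsets <- rep_len(onsets, nW)
  speed <- rep_len(speed, nW)
  if (any(speed <= 0)) stop("speeds must be positive")
  if (any(centres$x < 1 | centres$x > gridN | centres$y < 1 | centres$y > gridN))
    stop("initiation points must lie inside the domain")
  dx <- domainLength / gridN
  if (duration <= 0) {
    times <- numeric(0)
    fields <- list(v = array(numeric(0), c(gridN, gridN, 0)))
  } else {
    times <- seq(0, duration, by = snapshotInterval)
    nt <- length(times)
    xs <- (seq_len(gridN) - 0.5) * dx
    grid <- expand.grid(x = xs, y = xs)
    v <- array(vRest, c(gridN, gridN, nt))
    for (w in seq_len(nW)) {
      cx <- (centres$x[w] - 0.5) * dx
      cy <- (centres$y[w] - 0.5) * dx
      dd <- sqrt((grid$x - cx)^2 + (grid$y - cy)^2)
      for (ti in seq_len(nt)) {
        tEl <- times[ti] - onsets[w]
        if (tEl < 0) next
        rOut <- speed[w] * tEl
        if (!is.null(maxRadius)) rOut <- min(rOut, maxRadius)
        rIn <- max(0, speed[w] * (tEl - burstDuration))
        act <- dd <= rOut & dd >= rIn
        if (any(act)) {
          sl <- v[, , ti]
          sl[act] <- vActive
          v[, , ti] <- sl
        }
      }
    }
    fields <- list(v = v)
  }
  cfg <- simConfig(duration = max(duration, 1e-6), warmup = 0, gridN = gridN,
                   domainLength = domainLength,
                   snapshotInterval = snapshotInterval, seed = 0,
                   noise = FALSE, record = "full")
  new("SnapshotSeries", times = times, fields = fields, activity = raw(0),
      coarseTimes = times, gridN = c(gridN, gridN),
      domainLength = domainLength,
      metadata = list(config = cfg, fixture = "diskWave",
                      groundTruth = list(centres = centres, onsets = onsets,
                                         speed = speed,
                                         burstDuration = burstDuration)))
}

#' Sample from a discrete power law
#'
#' Inverse-CDF draws from a Pareto tail, rounded up to integers (sizes
#' >= xmin), with density ~ x^-exponent.
#'
#' @param exponent tail exponent (> 1).
#' @param xmin minimum size (default 1).
#' @param n sample size (>= 1).
#' @param seed RNG seed.
#' @return integer vector of length n.
#' @examples
#' s <- samplePowerLaw(1.5, n = 1000, seed = 1)
#' @export
samplePowerLaw <- function(exponent, xmin = 1, n, seed = 1L) {
  if (exponent <= 1) stop("exponent must exceed 1")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  u <- runif(n)
  x <- xmin * (1 - u)^(-1 / (exponent - 1))
  x <- pmin(x, 2^31 - 10)  # keep within integer range on heavy tails
  as.integer(ceiling(x - 0.5 + 1e-12))
}

#' Sample exponentially distributed sizes
#'
#' Complementary fixture for the curvature diagnostic: integer sizes with
#' an exponential tail.
#'
#' @param meanSize mean of the exponential, in size units.
#' @param n sample size.
#' @param seed RNG seed.
#' @return integer vector (>= 1).
#' @export
sampleExponentialSizes <- function(meanSize = 20, n, seed = 1L) {
  set.seed(seed)
  pmax(1L, as.integer(round(rexp(n, 1 / meanSize))))
}
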