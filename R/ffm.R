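# Drossel-Schwabl forest-fire model: lattice simulator, the retina->(p,f)
# rescaling map, the self-organised-criticality region predicate, and
# avalanche-statistics comparison.

#' Run the forest-fire lattice model
#'
#' Simulates the Drossel-Schwabl forest-fire model (DS-FFM): per step,
#' occupied sites ignite spontaneously with probability f, burning trees
#' ignite their occupied 4-neighbours, burning trees become empty, and
#' empty sites regrow with probability p. Two spread modes: per-step
#' spread (one neighbour ring per step — finite front speed, matching the
#' retinal-wave analogy; merging fires are pooled into one avalanche) and
#' instantaneous cluster burn (classical DS-FFM event statistics).
#'
#' @param side lattice side (>= 16).
#' @param p regrowth probability per step.
#' @param f lightning probability per occupied site per step.
#' @param steps number of steps.
#' @param seed RNG seed.
#' @param mode \code{"spread"} (default) or \code{"instantaneous"}.
#' @param burnin steps discarded before recording fires (default
#'   \code{steps/5}).
#' @param trackDensity record the tree density per step after burn-in.
#' @return list of class \code{ffmRecord}: \code{fires} (data.frame
#'   \code{size}, \code{lifetime}), \code{treeDensity}, \code{finalState}
#'   (side x side matrix of 0 empty / 1 tree / 2 burning), and the call
#'   parameters.
#' @examples
#' rec <- ffmRun(32, p = 0.05, f = 0.001, steps = 2000, seed = 1)
#' @export
ffmRun <- function(side, p, f, steps, seed = 1L,
                   mode = c("spread", "instantaneous"),
                   burnin = NULL, trackDensity = FALSE) {
  mode <- match.arg(mode)
  if (side < 16) stop("lattice side must be >= 16")
  if (p < 0 || p > 1 || f < 0 || f > 1) stop("p and f must lie in [0, 1]")
  if (is.null(burnin)) burnin <- as.integer(steps / 5)
  set.seed(seed)
  res <- cpp_ffm_run(as.integer(side), p, f, as.integer(steps),
                     mode == "instantaneous", as.integer(burnin),
                     trackDensity)
  structure(list(
    fires = data.frame(size = res$size, lifetime = res$lifetime),
    treeDensity = res$treeDensity,
    finalState = matrix(res$finalState, side, side),
    side = side, p = p, f = f, steps = steps, mode = mode, seed = seed),
    class = "ffmRecord")
}

#' Map wave-model observables onto forest-fire parameters
#'
#' Rescales time and space so that one time unit is the duration of a
#' burst during wave activity and one lattice point covers the elementary
#' excited area (the patch a bursting cell recruits, of linear size wave
#' speed x burst duration). Under this rescaling the wave dynamics
#' approximate the DS-FFM rules with
#' \deqn{p = \tau_{burst} / T_{refractory}, \qquad
#'       f = \lambda\, \tau_{burst}\, n_{cells},}
#' where \eqn{\lambda} is the per-cell spontaneous firing rate and
#' \eqn{n_{cells}} the number of cells per lattice point.
#'
#' @param waveSpeed mm/s.
#' @param spontRate per-cell spontaneous firing rate, 1/s.
#' @param burstDuration s.
#' @param refractoryPeriod s (must exceed the burst duration).
#' @param domainLength mm.
#' @param cellSpacing mm.
#' @return list: \code{p}, \code{f}, \code{latticeScale} (mm per lattice
#'   point), \code{latticeSide}, \code{cellsPerPoint}, \code{timeUnit}.
#' @export
mapToFFM <- function(waveSpeed, spontRate, burstDuration, refractoryPeriod,
                     domainLength = 2, cellSpacing = 2 / 64) {
  if (any(c(waveSpeed, spontRate, burstDuration, refractoryPeriod,
            domainLength, cellSpacing) <= 0))
    stop("all inputs must be positive")
  if (refractoryPeriod <= burstDuration)
    stop("degenerate mapping: refractory period must exceed the burst duration")
  latticeScale <- max(waveSpeed * burstDuration, cellSpacing)
  cellsPerPoint <- (latticeScale / cellSpacing)^2
  list(p = min(1, burstDuration / refractoryPeriod),
       f = min(1, spontRate * burstDuration * cellsPerPoint),
       latticeScale = latticeScale,
       latticeSide = max(16L, as.integer(round(domainLength / latticeScale))),
       cellsPerPoint = cellsPerPoint,
       timeUnit = burstDuration)
}

#' Self-organised-criticality region predicate
#'
#' The DS-FFM exhibits scale-free (power-law) avalanches under a double
#' separation of timescales: lightning must be much rarer than regrowth
#' (f << p), burning the largest cluster must be much faster than
#' regrowth (p sqrt(p/f) << 1), and the characteristic cluster scale must
#' stay small compared to the lattice so fires do not span the domain.
#' The predicate operationalises each "<<" as a factor
#' \code{1/separation} and the finite-size bound as mean cluster size
#' p/f <= side^2/\code{sizeMargin}.
#'
#' @param p,f DS-FFM probabilities.
#' @param latticeSide lattice side.
#' @param separation timescale separation factor (default 5).
#' @param sizeMargin finite-size margin (default 50).
#' @return logical; attribute \code{checks} details the three conditions.
#' @export
socRegion <- function(p, f, latticeSide, separation = 5, sizeMargin = 50) {
  if (p < 0 || p > 1 || f < 0 || f > 1) stop("p and f must lie in [0, 1]")
  checks <- c(
    rareLightning = f > 0 && f <= p / separation,
    fastBurns = p * sqrt(p / max(f, .Machine$double.xmin)) <= 1 / separation,
    finiteSize = f > 0 && p / f <= latticeSide^2 / sizeMargin)
  structure(all(checks), checks = checks)
}

#' Compare avalanche statistics of waves and forest fires
#'
#' Fits matched log-binned power laws to a wave-size sample and an FFM
#' avalanche-size sample, reports both slopes with standard errors,
#' whether the slopes agree within their joint confidence interval, and a
#' curvature diagnostic flagging sub-critical (exponentially decaying)
#' distributions.
#'
#' @param waveSizes numeric vector of wave sizes (cells).
#' @param ffmRecord an \code{ffmRecord} from \code{\link{ffmRun}} (or a
#'   numeric vector of fire sizes).
#' @param xmin fitting-range lower end (default 1).
#' @param level confidence level for slope agreement (default 0.95).
#' @return list of class \code{avalancheComparison}: \code{waveFit},
#'   \code{ffmFit} (\code{\link{fitPowerLaw}} results),
#'   \code{slopeDifference}, \code{agree}, \code{waveCurved},
#'   \code{ffmCurved}, \code{underpowered}.
#' @export
compareAvalancheStats <- function(waveSizes, ffmRecord, xmin = 1,
                                  level = 0.95) {
  ffmSizes <- if (inherits(ffmRecord, "ffmRecord")) ffmRecord$fires$size
              else as.numeric(ffmRecord)
  under <- length(waveSizes) < 100 || length(ffmSizes) < 100
  if (under)
    warning("fewer than 100 events in a sample; comparison is under-powered")
  wf <- fitPowerLaw(waveSizes, xmin = xmin)
  ff <- fitPowerLaw(ffmSizes, xmin = xmin)
  z <- qnorm(1 - (1 - level) / 2)
  dslope <- wf$slope - ff$slope
  se <- sqrt(wf$slopeSE^2 + ff$slopeSE^2)
  structure(list(waveFit = wf, ffmFit = ff,
                 slopeDifference = dslope,
                 agree = abs(dslope) <= z * se,
                 waveCurved = wf$curved, ffmCurved = ff$curved,
                 underpowered = under),
            class = "avalancheComparison")
}

#' Reference DS-FFM avalanche exponent
#'
#' The approximate size-distribution exponent of the two-dimensional
#' DS-FFM in its scaling regime, stored as configuration for comparisons
#' (density ~ size^-tau).
#'
#' @return tau (positive number).
#' @export
ffmReferenceExponent <- function() 1.14
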