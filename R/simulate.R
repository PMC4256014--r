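# Lattice simulator front-end: configuration, full runs, single-cell runs,
# 1D front runs, and the exposed single-step operations.

#' Simulation configuration constructor
#'
#' @param duration recorded simulation time, s.
#' @param dt integration step, s (default 0.001, i.e. the 1 ms step used
#'   for all headline runs).
#' @param warmup discarded warm-up, s (default 500).
#' @param gridN lattice side (default 64).
#' @param domainLength domain side, mm (default 2).
#' @param snapshotInterval snapshot cadence, s (default 0.01 = every 10
#'   steps).
#' @param coarseInterval full-field cadence in activity mode, s (default
#'   0.1, the cadence used for correlation analysis).
#' @param seed RNG seed (integer).
#' @param noise logical; stochastic excitatory channel on (default TRUE).
#' @param dims 1 or 2 (default 2).
#' @param record \code{"full"}, \code{"activity"} or \code{"final"}.
#'   Default "full"; use "activity" for long runs (stores the thresholded
#'   activity mask at full cadence and the fields at \code{coarseInterval}).
#' @param activityThreshold mV (default -60, the analysis threshold).
#' @return a validated \code{\link{SimConfig}}.
#' @export
simConfig <- function(duration, dt = 0.001, warmup = 500, gridN = 64,
                      domainLength = 2, snapshotInterval = 0.01,
                      coarseInterval = 0.1, seed = 1L, noise = TRUE,
                      dims = 2, record = c("full", "activity", "final"),
                      activityThreshold = -60) {
  record <- match.arg(record)
  obj <- new("SimConfig", dt = dt, duration = duration, warmup = warmup,
             gridN = gridN, domainLength = domainLength,
             snapshotInterval = snapshotInterval, coarseInterval = coarseInterval,
             seed = as.numeric(seed), noise = noise, dims = dims,
             record = record, activityThreshold = activityThreshold)
  validObject(obj)
  obj
}

recordModeCode <- function(record) {
  match(record, c("full", "activity", "final")) - 1L
}

#' Run a full lattice simulation
#'
#' Integrates the stochastic reaction-diffusion system on a 1D strip or a
#' 2D square lattice with the operator-splitting scheme (Strang splitting
#' of a locally one-dimensional Crank-Nicolson diffusion solve around a
#' Heun reaction step; zero-flux boundaries). The warm-up period is
#' integrated and discarded; snapshots are collected at the configured
#' cadence. Identical (config, params, seed) triples give bit-identical
#' output.
#'
#' @param config a \code{\link{SimConfig}}. Its \code{gridN} and
#'   \code{domainLength} override the entries in \code{params}.
#' @param params a \code{\link{ModelParams}} (default \code{modelParams()}).
#' @param protocol optional stimulation protocol: data.frame/matrix with
#'   columns \code{start}, \code{end} (s), \code{amplitude} (pA) and
#'   \code{cell} (1-based lattice index), or NULL.
#' @param init optional named list of initial fields (\code{v}, \code{r},
#'   \code{s}, \code{a}), each scalar or a full lattice. The default
#'   (\code{NULL}) uses the rest state with, for noisy 2D runs, per-cell
#'   sAHP levels drawn from a broad stationary-like distribution: starting
#'   from a desynchronised refractory mosaic removes the long transient of
#'   system-wide synchronised waves that a uniform rest start induces (the
#'   warm-up then relaxes the mosaic to its self-organised state).
#' @param freezeS freeze the sAHP level at its initial value (used for
#'   fast-subsystem runs).
#' @param collectEvents also record upward crossings of
#'   \code{eventThreshold} per cell (returned in metadata).
#' @param eventThreshold mV (default -50, the burst-detection threshold).
#' @return a \code{\link{SnapshotSeries}}.
#' @examples
#' cfg <- simConfig(duration = 2, warmup = 0, gridN = 16, seed = 7,
#'                  domainLength = 0.5)
#' snap <- runSimulation(cfg)
#' @export
runSimulation <- function(config, params = modelParams(), protocol = NULL,
                          init = NULL, freezeS = FALSE, collectEvents = FALSE,
                          eventThreshold = -50) {
  stopifnot(is(config, "SimConfig"), is(params, "ModelParams"))
  n <- as.integer(config@gridN)
  nx <- n
  ny <- if (config@dims == 2) n else 1L
  ncell <- nx * ny
  pv <- asParamVector(params)
  pv[30] <- config@domainLength  # lattice spacing derives from length/nx

  if (is.null(init)) {
    rest <- findRestState(params)
    init <- list(v = rest[["v"]], r = rest[["r"]], s = rest[["s"]],
                 a = rest[["a"]])
    if (config@noise && config@dims == 2) {
      # desynchronised refractory mosaic (seeded; see @param init)
      set.seed(config@seed)
      u <- runif(ncell)
      s0 <- 0.22 * u
      init$s <- s0
      init$r <- gatingFunctions(rest[["v"]], params)$wInf +
        params@sahp[["strength"]] * s0
    }
  }
  expand <- function(x) {
    if (length(x) == 1) rep(as.numeric(x), ncell)
    else if (length(x) == ncell) as.numeric(x)
    else stop("initial field has wrong length")
  }
  v0 <- expand(init$v); r0 <- expand(init$r)
  s0 <- expand(init$s); a0 <- expand(init$a)

  stim <- protocolMatrix(protocol)
  set.seed(config@seed)
  res <- cpp_run_grid(pv, nx, ny, config@dt, config@duration, config@warmup,
                      config@snapshotInterval, config@noise,
                      config@activityThreshold, recordModeCode(config@record),
                      config@coarseInterval, v0, r0, s0, a0, stim, freezeS,
                      collectEvents, eventThreshold)
  buildSnapshotSeries(res, config, params, collectEvents)
}

protocolMatrix <- function(protocol) {
  if (is.null(protocol) || NROW(protocol) == 0)
    return(matrix(numeric(0), 0, 4))
  m <- as.matrix(as.data.frame(protocol)[, c("start", "end", "amplitude", "cell")])
  if (any(m[, 2] <= m[, 1])) stop("protocol entries must have end > start")
  m[, 4] <- m[, 4] - 1  # to 0-based
  storage.mode(m) <- "double"
  m
}

buildSnapshotSeries <- function(res, config, params, collectEvents = FALSE) {
  n <- as.integer(config@gridN)
  nx <- n; ny <- if (config@dims == 2) n else 1L
  meta <- list(config = config, params = params, seed = config@seed,
               activityThreshold = config@activityThreshold,
               package = as.character(utils::packageVersion("sacwave")),
               finalState = list(v = res$finalV, r = res$finalR,
                                 s = res$finalS, a = res$finalA))
  if (collectEvents)
    meta$events <- data.frame(time = res$eventTimes, cell = res$eventCells)
  fields <- list()
  activity <- raw(0)
  times <- numeric(0)
  coarseTimes <- numeric(0)
  if (config@record == "full") {
    times <- res$times
    nt <- length(times)
    fields <- lapply(res[c("v", "r", "s", "a")], function(x)
      array(x, dim = c(nx, ny, nt)))
    coarseTimes <- times
  } else if (config@record == "activity") {
    times <- res$times
    coarseTimes <- res$coarseTimes
    ntc <- length(coarseTimes)
    fields <- lapply(res[c("v", "r", "s", "a")], function(x)
      array(x, dim = c(nx, ny, ntc)))
    activity <- res$activity
  }
  new("SnapshotSeries", times = times, fields = fields, activity = activity,
      coarseTimes = coarseTimes, gridN = c(nx, ny),
      domainLength = config@domainLength, metadata = meta)
}

#' Run a single cell
#'
#' Integration of the local kinetics for one isolated cell. The spatial
#' coupling reduces to a diffusive self-drain of the cell's own ACh cloud
#' (rate 2 D / dx^2 for the lattice spacing dx), so an isolated cell keeps
#' only part of what it releases — with D = 0 this is the exact decoupled
#' limit of the lattice. Optional stochastic channel and current-injection
#' protocol; depolarisation events are detected as upward crossings of
#' \code{eventThreshold} (default -50 mV).
#'
#' @param params a \code{\link{ModelParams}}.
#' @param duration simulated time, s.
#' @param protocol optional data.frame with \code{start}, \code{end},
#'   \code{amplitude} (pA); applied to the single cell.
#' @param noise logical (default FALSE).
#' @param dt step, s.
#' @param recordInterval trace cadence, s.
#' @param seed RNG seed (used when \code{noise}).
#' @param init optional initial state c(v, r, s, a); defaults to rest.
#' @param eventThreshold mV.
#' @param warmup discarded time, s (default 0).
#' @return data.frame with columns \code{time}, \code{v}, \code{r},
#'   \code{s}, \code{a}; event times in \code{attr(, "events")}.
#' @export
runSingleCell <- function(params = modelParams(), duration, protocol = NULL,
                          noise = FALSE, dt = 0.001, recordInterval = 0.01,
                          seed = 1L, init = NULL, eventThreshold = -50,
                          warmup = 0) {
  stopifnot(is(params, "ModelParams"), duration > 0)
  if (is.null(init)) init <- findRestState(params)
  pv <- asParamVector(params)
  drain <- isolatedSelfDrain(params)
  pv[27] <- 0  # spatial coupling replaced by the isolated-cell ACh drain
  stim <- if (is.null(protocol)) matrix(numeric(0), 0, 4) else {
    pr <- as.data.frame(protocol)
    pr$cell <- 1
    protocolMatrix(pr)
  }
  set.seed(seed)
  res <- cpp_run_grid(pv, 1L, 1L, dt, duration, warmup, recordInterval, noise,
                      -60, 0L, recordInterval, init[[1]], init[[2]], init[[3]],
                      init[[4]], stim, FALSE, TRUE, eventThreshold, drain)
  out <- data.frame(time = res$times, v = res$v, r = res$r, s = res$s, a = res$a)
  attr(out, "events") <- res$eventTimes
  out
}

#' Estimate the spontaneous event rate of isolated cells
#'
#' Simulates an ensemble of independent noisy cells (a diffusionless strip)
#' and returns the mean inter-event interval at the -50 mV threshold, the
#' statistic used to calibrate the stochastic channel against recorded
#' spontaneous SAC depolarisation rates.
#'
#' @param params a \code{\link{ModelParams}}.
#' @param cells ensemble size (default 64).
#' @param duration per-cell simulated time, s.
#' @param seed RNG seed.
#' @param eventThreshold mV (default -50).
#' @param dt step, s.
#' @return list: \code{meanInterval} (s), \code{nEvents}, \code{ratePerCell}
#'   (events per cell-second), \code{events} (data.frame time, cell).
#' @export
spontaneousRate <- function(params = modelParams(), cells = 64,
                            duration = 2000, seed = 1L, eventThreshold = -50,
                            dt = 0.001) {
  rest <- isolatedRestState(params)
  pv <- asParamVector(params)
  drain <- isolatedSelfDrain(params)
  pv[27] <- 0
  set.seed(seed)
  res <- cpp_run_grid(pv, as.integer(cells), 1L, dt, duration, 20, duration,
                      TRUE, -60, 2L, duration, rep(rest[["v"]], cells),
                      rep(rest[["r"]], cells), rep(rest[["s"]], cells),
                      rep(rest[["a"]], cells), matrix(numeric(0), 0, 4),
                      FALSE, TRUE, eventThreshold, drain)
  nEv <- length(res$eventTimes)
  rate <- nEv / (cells * duration)
  list(meanInterval = if (nEv > 0) 1 / rate else Inf,
       nEvents = nEv, ratePerCell = rate,
       events = data.frame(time = res$eventTimes, cell = res$eventCells))
}

#' Calibrate the noise rate to a target spontaneous interval
#'
#' Adjusts the channel opening rate so the simulated mean inter-event
#' interval of an isolated cell matches a target (e.g. the ~15 minute
#' interval recorded in mouse retina), by bisection on log-rate.
#'
#' @param params starting \code{\link{ModelParams}}.
#' @param targetInterval target mean inter-event interval, s (default 900).
#' @param tol relative tolerance on the achieved interval (default 0.2).
#' @param cells,duration ensemble size and per-cell time for each probe.
#' @param maxIter bisection iterations.
#' @param seed RNG seed.
#' @return a \code{ModelParams} with calibrated noise rate; the achieved
#'   interval is in \code{attr(, "achievedInterval")}.
#' @export
calibrateNoiseRate <- function(params = modelParams(), targetInterval = 900,
                               tol = 0.2, cells = 64, duration = 3000,
                               maxIter = 8, seed = 1L) {
  probe <- function(rate) {
    p2 <- modelParamsFrom(params, noise = c(rate = rate))
    spontaneousRate(p2, cells = cells, duration = duration, seed = seed)$meanInterval
  }
  r0 <- params@noise[["rate"]]
  iv <- probe(r0)
  if (is.finite(iv) && abs(iv - targetInterval) / targetInterval <= tol) {
    out <- params
    attr(out, "achievedInterval") <- iv
    return(out)
  }
  lo <- r0; hi <- r0
  # interval decreases with rate
  for (i in 1:12) {
    if (is.finite(iv) && iv < targetInterval) { lo <- r0 / 2^i; iv2 <- probe(lo)
      if (!is.finite(iv2) || iv2 > targetInterval) break } else {
      hi <- r0 * 2^i; iv2 <- probe(hi)
      if (is.finite(iv2) && iv2 < targetInterval) break }
  }
  lo <- min(lo, hi); hi <- max(lo, hi)
  best <- params; bestIv <- iv
  for (i in seq_len(maxIter)) {
    mid <- sqrt(lo * hi)
    ivm <- probe(mid)
    if (is.finite(ivm) && abs(ivm - targetInterval) / targetInterval <= tol) {
      best <- modelParamsFrom(params, noise = c(rate = mid))
      bestIv <- ivm
      break
    }
    if (!is.finite(ivm) || ivm > targetInterval) lo <- mid else hi <- mid
    best <- modelParamsFrom(params, noise = c(rate = mid))
    bestIv <- ivm
  }
  attr(best, "achievedInterval") <- bestIv
  best
}

# rebuild a ModelParams with component overrides (keeps everything else)
modelParamsFrom <- function(p, ...) {
  base <- list(capacitance = p@capacitance, reversals = p@reversals,
               conductances = p@conductances, gating = p@gating,
               sahp = p@sahp, ach = p@ach, noise = p@noise,
               diffusion = p@diffusion, domain = p@domain)
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("capacitance", "diffusion")) base[[nm]] <- ov[[nm]]
    else base[[nm]][names(ov[[nm]])] <- ov[[nm]]
  }
  do.call(modelParams, base)
}

#' One reaction (Heun) step
#'
#' Applies a single explicit two-stage Runge-Kutta (Heun) step of the local
#' kinetics to every cell; no spatial coupling. Exposed for verification.
#'
#' @param state named list of equal-length numeric fields \code{v},
#'   \code{r}, \code{s}, \code{a}.
#' @param params a \code{\link{ModelParams}}.
#' @param dt step, s.
#' @param iExt per-cell external current, pA (recycled).
#' @param gNoise per-cell noise conductance, nS (recycled).
#' @param freezeS logical.
#' @return named list of updated fields.
#' @export
stepReaction <- function(state, params, dt, iExt = 0, gNoise = 0,
                         freezeS = FALSE) {
  stopifnot(dt > 0)
  n <- length(state$v)
  res <- cpp_step_reaction(asParamVector(params), state$v, state$r, state$s,
                           state$a, dt, rep_len(gNoise, n), rep_len(iExt, n),
                           freezeS)
  if (any(!is.finite(res$v))) stop("numerical blow-up in reaction step")
  res
}

#' One diffusion step (LOD Crank-Nicolson)
#'
#' Advances the ACh field by \code{dt} of pure diffusion using two half
#' steps of the locally one-dimensional Crank-Nicolson scheme (x-then-y,
#' then y-then-x) with zero-flux boundaries. Total ACh is conserved to
#' solver precision and a uniform field is an exact steady state.
#'
#' @param aField numeric matrix (nx x ny) or vector (1D strip).
#' @param D diffusion coefficient, mm^2/s.
#' @param dt step, s.
#' @param dx lattice spacing, mm.
#' @return updated field, same shape.
#' @export
stepDiffusion <- function(aField, D, dt, dx) {
  stopifnot(dt > 0, dx > 0, D >= 0)
  d <- dim(aField)
  nx <- if (is.null(d)) length(aField) else d[1]
  ny <- if (is.null(d)) 1L else d[2]
  out <- cpp_step_diffusion(as.numeric(aField), nx, ny, D, dt, dx)
  if (!is.null(d)) dim(out) <- d
  out
}

#' Update the stochastic channel mask
#'
#' Redraws every cell's excitatory noise channel independently: open with
#' probability \code{rate * updateInterval}. An open channel contributes
#' the noise conductance until the next update.
#'
#' @param mask logical vector/matrix (current mask; shape is preserved).
#' @param params a \code{\link{ModelParams}}.
#' @return updated logical mask.
#' @export
updateNoiseMask <- function(mask, params) {
  p <- params@noise[["rate"]] * params@noise[["updateInterval"]]
  if (p < 0 || p > 1) stop("open probability per update outside [0, 1]")
  out <- runif(length(mask)) < p
  attributes(out) <- attributes(mask)
  out
}

#' Run a 1D front and measure its speed
#'
#' Integrates the model on a long 1D strip from a sigmoidal profile
#' connecting the excited state (left) to the rest state (right), with
#' noise off and optionally the sAHP level frozen, then measures the
#' asymptotic front speed as the slope of a linear fit to the position of
#' the mid-level voltage contour over the second half of the run.
#'
#' @param params a \code{\link{ModelParams}}.
#' @param frozenS frozen sAHP level (NULL integrates s as usual; a number
#'   freezes s at that level; default 0).
#' @param n strip length, cells. Lattice spacing is kept at
#'   \code{domainLength/gridN} of \code{params}.
#' @param duration integration time, s.
#' @param dt step, s.
#' @param level contour level, mV; default midway between rest and excited
#'   voltages.
#' @param restState,excitedState optional precomputed fixed points.
#' @return list: \code{speed} (mm/s, positive when the excited region
#'   grows), \code{status} ("front", "receding" or "none"), \code{times},
#'   \code{positions} (mm), \code{profile} (final v/r/s/a), \code{level}.
#' @export
runFront1D <- function(params = modelParams(), frozenS = 0, n = 300,
                       duration = 40, dt = 0.001, level = NULL,
                       restState = NULL, excitedState = NULL) {
  dx <- params@domain[["length"]] / params@domain[["gridN"]]
  fp <- fastFixedPointsDimensioned(params, s = if (is.null(frozenS)) 0 else frozenS)
  if (is.null(restState)) restState <- fp$rest
  if (is.null(excitedState)) excitedState <- fp$excited
  if (is.null(excitedState))
    return(list(speed = NA_real_, status = "none", times = numeric(0),
                positions = numeric(0), profile = NULL, level = NA_real_))
  if (is.null(level)) level <- (restState[["v"]] + excitedState[["v"]]) / 2

  x <- seq_len(n)
  x0 <- n / 4
  w <- 2
  blend <- 1 / (1 + exp((x - x0) / w))   # 1 at left (excited), 0 at right
  sFr <- if (is.null(frozenS)) 0 else frozenS
  init <- list(v = blend * excitedState[["v"]] + (1 - blend) * restState[["v"]],
               r = blend * excitedState[["r"]] + (1 - blend) * restState[["r"]],
               s = rep(sFr, n),
               a = blend * excitedState[["a"]] + (1 - blend) * restState[["a"]])
  pv <- asParamVector(params)
  pv[30] <- dx * n  # strip length
  snapdt <- max(dt, duration / 400)
  set.seed(1)
  res <- cpp_run_grid(pv, as.integer(n), 1L, dt, duration, 0, snapdt, FALSE,
                      -60, 0L, snapdt, init$v, init$r, init$s, init$a,
                      matrix(numeric(0), 0, 4), !is.null(frozenS), FALSE, -50)
  nt <- length(res$times)
  vmat <- matrix(res$v, n, nt)
  pos <- apply(vmat, 2, function(vv) {
    above <- vv > level
    if (!any(above)) return(NA_real_)
    if (all(above)) return(n)
    k <- max(which(above))
    if (k >= n) return(n)
    # linear interpolation of the crossing
    k + (level - vv[k]) / (vv[k + 1] - vv[k])
  })
  posMm <- pos * dx
  tt <- res$times
  ok <- !is.na(posMm)
  if (sum(ok) < 5 || all(is.na(posMm[tt > duration / 2])))
    return(list(speed = NA_real_, status = "none", times = tt,
                positions = posMm, profile = NULL, level = level))
  use <- ok & tt > duration / 2 & pos > 3 & pos < n - 3
  status <- "front"
  if (sum(use) < 5) {
    # front collapsed or hit the boundary; fall back to all valid points
    use <- ok & pos > 3 & pos < n - 3
    if (sum(use) < 5)
      return(list(speed = NA_real_,
                  status = if (mean(pos[ok]) < x0) "receding" else "none",
                  times = tt, positions = posMm, profile = NULL, level = level))
  }
  fit <- lm(posMm[use] ~ tt[use])
  speed <- unname(coef(fit)[2])
  if (speed < 0) status <- "receding"
  # profile from the latest frame in which the interface is mid-strip
  good <- which(ok & pos > 0.25 * n & pos < 0.75 * n)
  pframe <- if (length(good)) max(good) else nt
  prof <- data.frame(x = x * dx, v = vmat[, pframe],
                     r = matrix(res$r, n, nt)[, pframe],
                     s = matrix(res$s, n, nt)[, pframe],
                     a = matrix(res$a, n, nt)[, pframe])
  list(speed = speed, status = status, times = tt, positions = posMm,
       profile = prof, level = level)
}


# diffusive loss rate of an isolated cell's own ACh cloud: half the
# 4-neighbour lattice conductance (the other half returns from the cloud)
isolatedSelfDrain <- function(params) {
  dx <- params@domain[["length"]] / params@domain[["gridN"]]
  2 * params@diffusion / dx^2
}

# rest state of the isolated cell (drained ACh pool)
isolatedRestState <- function(params) {
  rest <- findRestState(params)
  drain <- isolatedSelfDrain(params)
  aRest <- achReleaseRate(rest[["v"]], params) /
    (1 / params@ach[["clearanceTime"]] + drain)
  rest[["a"]] <- aRest
  rest
}
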