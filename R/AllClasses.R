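#' Biophysical parameter set for the SAC wave model
#'
#' Dimensioned parameters of the starburst-amacrine-cell (SAC) reaction-
#' diffusion model. Membrane potential obeys Morris-Lecar dynamics with an
#' additional ACh-gated excitatory conductance, a stochastic excitatory
#' noise conductance, and a slow after-hyperpolarisation (sAHP) cascade that
#' raises the potassium-gate target. Construct with \code{\link{modelParams}}.
#'
#' @slot capacitance membrane capacitance, nF.
#' @slot reversals named numeric, reversal potentials in mV:
#'   \code{K}, \code{Ca}, \code{leak}, \code{ACh}.
#' @slot conductances named numeric, maximal conductances in nS:
#'   \code{leak}, \code{K}, \code{Ca}, \code{ACh}, \code{noise}.
#' @slot gating named numeric: \code{mHalf}, \code{mSlope}, \code{wHalf},
#'   \code{wSlope} (mV) and \code{tauW} (s), the Morris-Lecar auxiliary
#'   function constants.
#' @slot sahp named numeric: \code{half}, \code{slope} (mV) of the sAHP
#'   activation sigmoid, \code{tauAct} and \code{tauDecay} (s) of the
#'   two-stage cascade, and the dimensionless coupling \code{strength} of
#'   the sAHP level into the refractory-gate target.
#' @slot ach named numeric: \code{releaseHalf}, \code{releaseSlope} (mV),
#'   \code{releaseRate} (nM/s), \code{clearanceTime} (s),
#'   \code{halfSaturation} (nM) and Hill coefficient \code{hill} of the
#'   ACh conductance.
#' @slot noise named numeric: \code{rate} (1/s), the channel opening rate of
#'   the excitatory noise conductance, and \code{updateInterval} (s).
#' @slot diffusion effective ACh diffusion coefficient, mm^2/s.
#' @slot domain named numeric: \code{length} (mm) and \code{gridN}.
#' @export
setClass("ModelParams", representation(
  capacitance = "numeric",
  reversals = "numeric",
  conductances = "numeric",
  gating = "numeric",
  sahp = "numeric",
  ach = "numeric",
  noise = "numeric",
  diffusion = "numeric",
  domain = "numeric"
))

setValidity("ModelParams", function(object) {
  msg <- character()
  need <- function(x, nms, what) {
    if (!all(nms %in% names(x))) paste0(what, " must contain: ", paste(nms, collapse = ", "))
    else NA_character_
  }
  msg <- c(msg,
    need(object@reversals, c("K", "Ca", "leak", "ACh"), "reversals"),
    need(object@conductances, c("leak", "K", "Ca", "ACh", "noise"), "conductances"),
    need(object@gating, c("mHalf", "mSlope", "wHalf", "wSlope", "tauW"), "gating"),
    need(object@sahp, c("half", "slope", "tauAct", "tauDecay", "strength"), "sahp"),
    need(object@ach, c("releaseHalf", "releaseSlope", "releaseRate",
                       "clearanceTime", "halfSaturation", "hill"), "ach"),
    need(object@noise, c("rate", "updateInterval"), "noise"),
    need(object@domain, c("length", "gridN"), "domain"))
  msg <- msg[!is.na(msg)]
  if (length(msg)) return(msg)
  if (object@capacitance <= 0) msg <- c(msg, "capacitance must be positive")
  if (any(object@conductances < 0)) msg <- c(msg, "conductances must be non-negative")
  if (object@diffusion < 0) msg <- c(msg, "diffusion coefficient must be non-negative")
  tc <- c(object@gating["tauW"], object@sahp[c("tauAct", "tauDecay")],
          object@ach["clearanceTime"], object@noise["updateInterval"])
  if (any(tc <= 0)) msg <- c(msg, "all time constants must be positive")
  if (object@ach["hill"] < 1) msg <- c(msg, "hill coefficient must be >= 1")
  rv <- object@reversals
  if (!(rv["K"] < rv["leak"] && rv["leak"] < rv["ACh"]))
    msg <- c(msg, "reversals must satisfy E_K < E_leak < E_ACh")
  if (object@domain["gridN"] < 2) msg <- c(msg, "gridN must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Dimensionless parameter set
#'
#' Nondimensionalised parameters of the SAC wave model together with the
#' voltage, time, space, conductance and concentration scales used to
#' produce them. Construct with \code{\link{nondimensionalize}}.
#'
#' @slot values named numeric of dimensionless parameters (scaled reversals,
#'   conductance ratios, timescale ratios including the singular parameter
#'   \code{epsilon}, scaled gating constants and scaled ACh constants).
#' @slot scales named numeric: \code{voltage} (mV), \code{time} (s),
#'   \code{space} (mm), \code{conductance} (nS), \code{concentration} (nM),
#'   \code{membraneTime} (s).
#' @slot params the originating \code{ModelParams}.
#' @export
setClass("DimensionlessParams", representation(
  values = "numeric",
  scales = "numeric",
  params = "ModelParams"
))

#' Simulation configuration
#'
#' Grid, duration and integration settings for \code{\link{runSimulation}}.
#' Construct with \code{\link{simConfig}}.
#'
#' @slot dt integration step, s.
#' @slot duration recorded simulation time after warm-up, s.
#' @slot warmup discarded warm-up time, s.
#' @slot gridN lattice side (number of cells per side).
#' @slot domainLength physical domain side, mm.
#' @slot snapshotInterval snapshot cadence, s (integer multiple of dt).
#' @slot coarseInterval cadence for full-field snapshots when
#'   \code{record = "activity"}, s.
#' @slot seed integer RNG seed.
#' @slot noise logical, whether the stochastic channel is active.
#' @slot dims 1 (strip) or 2 (square lattice).
#' @slot record \code{"full"} (all four fields at each snapshot),
#'   \code{"activity"} (activity mask at each snapshot plus full fields at
#'   the coarse cadence) or \code{"final"}.
#' @slot activityThreshold mV, mask threshold used when
#'   \code{record = "activity"}.
#' @export
setClass("SimConfig", representation(
  dt = "numeric", duration = "numeric", warmup = "numeric",
  gridN = "numeric", domainLength = "numeric",
  snapshotInterval = "numeric", coarseInterval = "numeric",
  seed = "numeric", noise = "logical", dims = "numeric",
  record = "character", activityThreshold = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@warmup < 0) msg <- c(msg, "warmup must be non-negative")
  ratio <- object@snapshotInterval / object@dt
  if (abs(ratio - round(ratio)) > 1e-8)
    msg <- c(msg, "snapshotInterval must be an integer multiple of dt")
  if (!object@dims %in% c(1, 2)) msg <- c(msg, "dims must be 1 or 2")
  if (!object@record %in% c("full", "activity", "final"))
    msg <- c(msg, "record must be 'full', 'activity' or 'final'")
  if (length(msg)) msg else TRUE
})

#' Snapshot series produced by the simulator or the fixture generator
#'
#' Time-stamped stacks of the lattice fields. Depending on the recording
#' mode, holds full fields (v, r, s, a) at the snapshot cadence, or an
#' activity mask at the snapshot cadence plus full fields at a coarser
#' cadence. Field arrays have dimensions nx x ny x length(times).
#'
#' @slot times snapshot times, s (relative to the end of warm-up).
#' @slot fields named list of 3D arrays (any of \code{v}, \code{r},
#'   \code{s}, \code{a}), mV / fractions / nM.
#' @slot activity optional raw 3D array of 0/1 activity at \code{times}
#'   (present when recorded in activity mode; otherwise 0-length).
#' @slot coarseTimes times of the entries of \code{fields} when recorded in
#'   activity mode (otherwise identical to \code{times}).
#' @slot gridN lattice side(s), c(nx, ny).
#' @slot domainLength physical domain side, mm.
#' @slot metadata list: config, parameter values, seed, package version.
#' @export
setClass("SnapshotSeries", representation(
  times = "numeric",
  fields = "list",
  activity = "raw",
  coarseTimes = "numeric",
  gridN = "numeric",
  domainLength = "numeric",
  metadata = "list"
))

setValidity("SnapshotSeries", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE) && length(object@times) > 1)
    msg <- c(msg, "times must be strictly increasing")
  nc <- prod(object@gridN)
  for (f in names(object@fields)) {
    d <- dim(object@fields[[f]])
    if (length(d) != 3 || d[1] * d[2] != nc)
      msg <- c(msg, sprintf("field '%s' has inconsistent dimensions", f))
  }
  if (length(object@activity) > 0 &&
      length(object@activity) != nc * length(object@times))
    msg <- c(msg, "activity array inconsistent with grid and times")
  if (length(msg)) msg else TRUE
})

#' Travelling-front solution of the fast subsystem
#'
#' A front profile of the fast subsystem (v, r, a with the sAHP level s
#' frozen) in the frame moving with speed c, together with the endpoint
#' fixed points. Produced by \code{\link{frontProfileBVP}}.
#'
#' @slot xi moving-frame coordinate grid, mm.
#' @slot profile matrix with columns v, r, a (and da, the ACh spatial
#'   derivative).
#' @slot speed front speed, mm/s (positive = excited state invades rest).
#' @slot speedDimensionless speed in units of space scale per time scale.
#' @slot sFrozen the frozen sAHP level.
#' @slot restPoint,excitedPoint named numeric fixed points (v, r, a).
#' @slot residual maximum absolute residual of the moving-frame equations.
#' @slot converged logical.
#' @export
setClass("FrontSolution", representation(
  xi = "numeric", profile = "matrix", speed = "numeric",
  speedDimensionless = "numeric", sFrozen = "numeric",
  restPoint = "numeric", excitedPoint = "numeric",
  residual = "numeric", converged = "logical"
))

#' @describeIn ModelParams compact display
#' @param object a \code{ModelParams}
#' @export
setMethod("show", "ModelParams", function(object) {
  cat("ModelParams (SAC reaction-diffusion model)\n")
  cat(sprintf("  C = %.3g nF;  D = %.3g mm^2/s;  domain %g mm, %d cells/side\n",
              object@capacitance, object@diffusion,
              object@domain[["length"]], as.integer(object@domain[["gridN"]])))
  cat("  reversals (mV):   ",
      paste(sprintf("%s=%g", names(object@reversals), object@reversals), collapse = "  "), "\n")
  cat("  conductances (nS):",
      paste(sprintf("%s=%g", names(object@conductances), object@conductances), collapse = "  "), "\n")
  cat(sprintf("  sAHP: tauAct=%g s tauDecay=%g s strength=%g\n",
              object@sahp[["tauAct"]], object@sahp[["tauDecay"]], object@sahp[["strength"]]))
  cat(sprintf("  ACh: release %g nM/s, clearance %g s, K=%g nM (Hill %g)\n",
              object@ach[["releaseRate"]], object@ach[["clearanceTime"]],
              object@ach[["halfSaturation"]], object@ach[["hill"]]))
  cat(sprintf("  noise: rate %g /s every %g s\n",
              object@noise[["rate"]], object@noise[["updateInterval"]]))
})

#' @describeIn SnapshotSeries compact display
#' @param object a \code{SnapshotSeries}
#' @export
setMethod("show", "SnapshotSeries", function(object) {
  cat(sprintf("SnapshotSeries: %d x %d lattice (%g mm), %d snapshots",
              object@gridN[1], object@gridN[2], object@domainLength,
              length(object@times)))
  if (length(object@times))
    cat(sprintf(" spanning %.6g..%.6g s", min(object@times), max(object@times)))
  cat("\n  fields:", if (length(object@fields)) paste(names(object@fields), collapse = ", ")
      else "(none)",
      if (length(object@activity)) sprintf("+ activity mask (threshold %g mV)",
        object@metadata$activityThreshold %||% NA) else "", "\n")
})

#' @describeIn FrontSolution compact display
#' @param object a \code{FrontSolution}
#' @export
setMethod("show", "FrontSolution", function(object) {
  cat(sprintf(
    "FrontSolution: c = %.5g mm/s (s = %g), residual %.2e, %s\n",
    object@speed, object@sFrozen, object@residual,
    if (object@converged) "converged" else "NOT converged"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
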