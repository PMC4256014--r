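# Parameter construction, registry IO and the canonical numeric layout
# shared with the compiled core.

# order must match the enum in src/core.cpp
.paramOrder <- c(
  "capacitance", "E_K", "E_Ca", "E_leak", "E_ACh",
  "g_leak", "g_K", "g_Ca", "g_ACh", "g_noise",
  "m_half", "m_slope", "w_half", "w_slope", "tau_w",
  "sahp_half", "sahp_slope", "sahp_tau_act", "sahp_tau_decay", "sahp_strength",
  "release_half", "release_slope", "release_rate", "clearance_time",
  "half_saturation", "hill", "D", "noise_rate", "noise_interval", "domain_length")

#' Construct the biophysical parameter set
#'
#' Returns a \code{\link{ModelParams}} object populated with the default
#' dimensioned parameters of the SAC wave model; any component can be
#' overridden. Voltages are in mV, conductances in nS, times in s,
#' concentrations in nM, the ACh diffusion coefficient in mm^2/s and the
#' capacitance in nF.
#'
#' The defaults describe a 2 mm square patch of developing retina sampled
#' at one SAC per 31.25 um (a 64 x 64 lattice): Morris-Lecar kinetics with
#' E_K = -90, E_Ca = 50, E_leak = -70, E_ACh = 50 mV and maximal
#' conductances g_Ca = 30, g_K = 10, g_leak = 2, g_ACh = 3, g_noise = 2 nS;
#' a potassium gate with half-activation -40 mV (slope 40 mV) relaxing on
#' 0.2 s; an sAHP cascade activated above about -25 mV that loads in ~5 s
#' and decays in ~60 s, coupled into the gate target with strength 5; ACh
#' released above about -55 mV at up to 20000 nM/s, cleared in 0.2 s and
#' sensed through a Hill conductance (K = 800 nM, n = 2); and a stochastic
#' excitatory conductance that opens with rate 0.12/s, re-drawn every 10 ms.
#'
#' @param ... named overrides. Scalar slots (\code{capacitance},
#'   \code{diffusion}) are replaced; named-vector slots (\code{reversals},
#'   \code{conductances}, \code{gating}, \code{sahp}, \code{ach},
#'   \code{noise}, \code{domain}) are updated element-wise, e.g.
#'   \code{modelParams(conductances = c(ACh = 2.25))}.
#' @return a validated \code{\link{ModelParams}} object.
#' @examples
#' p <- modelParams()
#' pLow <- modelParams(conductances = c(ACh = 0.75 * conductances(p)[["ACh"]]))
#' @export
modelParams <- function(...) {
  def <- list(
    capacitance = 0.160,
    reversals = c(K = -90, Ca = 50, leak = -70, ACh = 50),
    conductances = c(leak = 2, K = 10, Ca = 30, ACh = 3, noise = 2),
    gating = c(mHalf = -20, mSlope = 20, wHalf = -40, wSlope = 40, tauW = 0.2),
    sahp = c(half = -25, slope = 5, tauAct = 5, tauDecay = 60, strength = 5),
    ach = c(releaseHalf = -55, releaseSlope = 5, releaseRate = 20000,
            clearanceTime = 0.2, halfSaturation = 800, hill = 2),
    noise = c(rate = 0.12, updateInterval = 0.01),
    diffusion = 0.01,
    domain = c(length = 2, gridN = 64))
  ov <- list(...)
  bad <- setdiff(names(ov), names(def))
  if (length(bad)) stop("unknown parameter group(s): ", paste(bad, collapse = ", "))
  for (nm in names(ov)) {
    if (nm %in% c("capacitance", "diffusion")) {
      def[[nm]] <- as.numeric(ov[[nm]])
    } else {
      val <- ov[[nm]]
      if (is.null(names(val)) && length(val) == length(def[[nm]])) {
        names(val) <- names(def[[nm]])
      }
      unknown <- setdiff(names(val), names(def[[nm]]))
      if (length(unknown))
        stop(sprintf("unknown entries in '%s': %s", nm, paste(unknown, collapse = ", ")))
      def[[nm]][names(val)] <- val
    }
  }
  obj <- new("ModelParams",
             capacitance = def$capacitance, reversals = def$reversals,
             conductances = def$conductances, gating = def$gating,
             sahp = def$sahp, ach = def$ach, noise = def$noise,
             diffusion = def$diffusion, domain = def$domain)
  validObject(obj)
  obj
}

#' @rdname accessors
#' @export
setGeneric("conductances", function(object) standardGeneric("conductances"))
#' @rdname accessors
#' @export
setGeneric("reversals", function(object) standardGeneric("reversals"))
#' @rdname accessors
#' @export
setGeneric("domainGeometry", function(object) standardGeneric("domainGeometry"))

#' Accessors for ModelParams components
#'
#' @param object a \code{\link{ModelParams}} object.
#' @return the named numeric vector of the requested component.
#' @name accessors
#' @aliases conductances,ModelParams-method reversals,ModelParams-method
#'   domainGeometry,ModelParams-method
NULL

#' @rdname accessors
#' @export
setMethod("conductances", "ModelParams", function(object) object@conductances)
#' @rdname accessors
#' @export
setMethod("reversals", "ModelParams", function(object) object@reversals)
#' @rdname accessors
#' @export
setMethod("domainGeometry", "ModelParams", function(object) object@domain)

# flatten to the canonical vector handed to the compiled core
asParamVector <- function(p) {
  stopifnot(is(p, "ModelParams"))
  v <- c(p@capacitance,
         p@reversals[c("K", "Ca", "leak", "ACh")],
         p@conductances[c("leak", "K", "Ca", "ACh", "noise")],
         p@gating[c("mHalf", "mSlope", "wHalf", "wSlope", "tauW")],
         p@sahp[c("half", "slope", "tauAct", "tauDecay", "strength")],
         p@ach[c("releaseHalf", "releaseSlope", "releaseRate", "clearanceTime",
                 "halfSaturation", "hill")],
         p@diffusion, p@noise[c("rate", "updateInterval")],
         p@domain[["length"]])
  names(v) <- .paramOrder
  unname(v)
}

paramVectorToList <- function(v) {
  names(v) <- .paramOrder
  v
}

#' Write the parameter registry file
#'
#' Serialises a \code{\link{ModelParams}} object to a flat YAML key/value
#' registry with unit comments. Values are written with 17 significant
#' digits so that \code{\link{readParamRegistry}} restores them bit-exactly.
#'
#' @param params a \code{\link{ModelParams}} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeParamRegistry <- function(params, path) {
  stopifnot(is(params, "ModelParams"))
  num <- function(x) sprintf("%.17g", x)
  ln <- c(
    "# sacwave parameter registry",
    "# units: voltages mV, conductances nS, times s, concentrations nM,",
    "#        capacitance nF, diffusion mm^2/s, rates 1/s, lengths mm",
    paste0("membrane_capacitance: ", num(params@capacitance)),
    "# reversal potentials (mV)",
    paste0("reversal_potentials.E_", c("K", "Ca", "leak", "ACh"), ": ",
           num(params@reversals[c("K", "Ca", "leak", "ACh")])),
    "# maximal conductances (nS)",
    paste0("max_conductances.g_", c("leak", "K", "Ca", "ACh", "noise"), ": ",
           num(params@conductances[c("leak", "K", "Ca", "ACh", "noise")])),
    "# Morris-Lecar gating constants (mV; tau_w s)",
    paste0("gating_params.", c("m_half", "m_slope", "w_half", "w_slope", "tau_w"), ": ",
           num(params@gating[c("mHalf", "mSlope", "wHalf", "wSlope", "tauW")])),
    "# sAHP cascade (mV; s; strength dimensionless)",
    paste0("sahp_params.", c("half", "slope"), ": ",
           num(params@sahp[c("half", "slope")])),
    paste0("sahp_times.tau_R: ", num(params@sahp[["tauAct"]])),
    paste0("sahp_times.tau_S: ", num(params@sahp[["tauDecay"]])),
    paste0("sahp_strength: ", num(params@sahp[["strength"]])),
    "# ACh release, clearance and receptor (mV; nM/s; s; nM)",
    paste0("ach_params.", c("release_half", "release_slope", "release_rate",
                            "clearance_time", "half_saturation", "hill_coefficient"), ": ",
           num(params@ach[c("releaseHalf", "releaseSlope", "releaseRate",
                            "clearanceTime", "halfSaturation", "hill")])),
    "# effective ACh diffusion (mm^2/s)",
    paste0("diffusion_coefficient: ", num(params@diffusion)),
    "# stochastic excitatory channel",
    paste0("noise.open_probability_rate: ", num(params@noise[["rate"]])),
    paste0("noise.update_interval: ", num(params@noise[["updateInterval"]])),
    "# domain",
    paste0("domain.length: ", num(params@domain[["length"]])),
    paste0("domain.grid_n: ", num(params@domain[["gridN"]])))
  writeLines(ln, path)
  invisible(path)
}

#' Read a parameter registry file
#'
#' Parses a registry written by \code{\link{writeParamRegistry}} (or edited
#' by hand), validates units/ranges through the \code{ModelParams} validity
#' checks, and returns the parameter object.
#'
#' @param path registry file path.
#' @return a \code{\link{ModelParams}} object.
#' @export
readParamRegistry <- function(path) {
  y <- yaml::read_yaml(path)
  getv <- function(key) {
    if (is.null(y[[key]])) stop("registry is missing key: ", key)
    as.numeric(y[[key]])
  }
  modelParams(
    capacitance = getv("membrane_capacitance"),
    reversals = c(K = getv("reversal_potentials.E_K"),
                  Ca = getv("reversal_potentials.E_Ca"),
                  leak = getv("reversal_potentials.E_leak"),
                  ACh = getv("reversal_potentials.E_ACh")),
    conductances = c(leak = getv("max_conductances.g_leak"),
                     K = getv("max_conductances.g_K"),
                     Ca = getv("max_conductances.g_Ca"),
                     ACh = getv("max_conductances.g_ACh"),
                     noise = getv("max_conductances.g_noise")),
    gating = c(mHalf = getv("gating_params.m_half"),
               mSlope = getv("gating_params.m_slope"),
               wHalf = getv("gating_params.w_half"),
               wSlope = getv("gating_params.w_slope"),
               tauW = getv("gating_params.tau_w")),
    sahp = c(half = getv("sahp_params.half"), slope = getv("sahp_params.slope"),
             tauAct = getv("sahp_times.tau_R"), tauDecay = getv("sahp_times.tau_S"),
             strength = getv("sahp_strength")),
    ach = c(releaseHalf = getv("ach_params.release_half"),
            releaseSlope = getv("ach_params.release_slope"),
            releaseRate = getv("ach_params.release_rate"),
            clearanceTime = getv("ach_params.clearance_time"),
            halfSaturation = getv("ach_params.half_saturation"),
            hill = getv("ach_params.hill_coefficient")),
    noise = c(rate = getv("noise.open_probability_rate"),
              updateInterval = getv("noise.update_interval")),
    diffusion = getv("diffusion_coefficient"),
    domain = c(length = getv("domain.length"), gridN = getv("domain.grid_n")))
}
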