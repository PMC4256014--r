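# Nondimensionalization: scales, dimensionless parameter table, and the
# scaled reaction system used to verify dimensional consistency.

#' Nondimensionalize the model parameters
#'
#' Rescales the dimensioned parameter set with the natural scales of the
#' model: voltage by 50 mV, conductances by the calcium maximal
#' conductance, time by the sAHP activation time, space by
#' \code{sqrt(D * timeScale)} (so the diffusion coefficient is scaled out
#' of the equations) and ACh concentration by 1 nM. The singular parameter
#' \code{epsilon} is the ratio of the membrane time \code{C/g0} to the
#' time scale; the companion ratios \code{epsilonW} (to the K-gate time)
#' and \code{epsilonS} (to the sAHP decay time) order the remaining
#' timescales.
#'
#' @param params a \code{\link{ModelParams}}.
#' @param voltageScale mV (default 50).
#' @param concentrationScale nM (default 1).
#' @return a \code{\link{DimensionlessParams}}.
#' @examples
#' dp <- nondimensionalize(modelParams())
#' dp@values[["eK"]]       # -1.8
#' dp@values[["epsilon"]]  # ~1.067e-3
#' @export
nondimensionalize <- function(params, voltageScale = 50,
                              concentrationScale = 1) {
  stopifnot(is(params, "ModelParams"))
  V0 <- voltageScale
  g0 <- params@conductances[["Ca"]]
  if (g0 <= 0) stop("zero conductance scale")
  tauM <- params@capacitance / g0
  tau0 <- params@sahp[["tauAct"]]
  if (tau0 <= 0) stop("zero time scale")
  space <- sqrt(params@diffusion * tau0)
  degenerate <- params@diffusion == 0
  if (degenerate)
    warning("D = 0: degenerate space scale (0 mm); spatial terms undefined")
  A0 <- concentrationScale
  rv <- params@reversals; cc <- params@conductances
  g <- params@gating; sa <- params@sahp; ac <- params@ach
  vals <- c(
    eK = rv[["K"]] / V0, eCa = rv[["Ca"]] / V0,
    eL = rv[["leak"]] / V0, eA = rv[["ACh"]] / V0,
    gL = cc[["leak"]] / g0, gK = cc[["K"]] / g0,
    gACh = cc[["ACh"]] / g0, gNoise = cc[["noise"]] / g0,
    v1 = g[["mHalf"]] / V0, v2 = g[["mSlope"]] / V0,
    v3 = g[["wHalf"]] / V0, v4 = g[["wSlope"]] / V0,
    sHalf = sa[["half"]] / V0, sSlope = sa[["slope"]] / V0,
    relHalf = ac[["releaseHalf"]] / V0, relSlope = ac[["releaseSlope"]] / V0,
    epsilon = tauM / tau0,
    epsilonW = tauM / g[["tauW"]],
    epsilonS = tauM / sa[["tauDecay"]],
    tauWScaled = g[["tauW"]] / tau0,
    tauDecayScaled = sa[["tauDecay"]] / tau0,
    tauAScaled = ac[["clearanceTime"]] / tau0,
    kappa = sa[["strength"]],
    hill = ac[["hill"]],
    aHalf = ac[["halfSaturation"]] / A0,
    betaScaled = ac[["releaseRate"]] * tau0 / A0,
    noiseRateScaled = params@noise[["rate"]] * tau0,
    domainScaled = if (degenerate) Inf else params@domain[["length"]] / space)
  scales <- c(voltage = V0, time = tau0, space = space, conductance = g0,
              concentration = A0, membraneTime = tauM)
  new("DimensionlessParams", values = vals, scales = scales, params = params)
}

#' @describeIn nondimensionalize compact display
#' @param object a \code{DimensionlessParams}
#' @export
setMethod("show", "DimensionlessParams", function(object) {
  s <- object@scales
  cat("DimensionlessParams\n")
  cat(sprintf("  scales: %g mV, %g s, %g mm, %g nS, %g nM (membrane time %g s)\n",
              s[["voltage"]], s[["time"]], s[["space"]], s[["conductance"]],
              s[["concentration"]], s[["membraneTime"]]))
  v <- object@values
  cat(sprintf("  epsilon = %.4g (fast/slow ratio); epsilonW = %.4g; epsilonS = %.4g\n",
              v[["epsilon"]], v[["epsilonW"]], v[["epsilonS"]]))
  cat("  ", paste(sprintf("%s=%.4g", names(v)[1:8], v[1:8]), collapse = " "), "\n")
})

#' Scaled reaction right-hand side
#'
#' Local kinetics of the nondimensionalized system (time in units of the
#' time scale, voltage in units of the voltage scale, ACh in units of the
#' concentration scale; diffusion excluded). Written independently from
#' the scaled parameters so that trajectories of the dimensioned and
#' dimensionless systems can be checked to map onto each other under the
#' scalings.
#'
#' @param state numeric \code{c(v, r, s, a)} in scaled units.
#' @param dp a \code{\link{DimensionlessParams}}.
#' @return scaled derivatives \code{c(v, r, s, a)}.
#' @export
scaledReactionRHS <- function(state, dp) {
  p <- dp@values
  v <- state[1]; r <- state[2]; s <- state[3]; a <- state[4]
  minf <- 0.5 * (1 + tanh((v - p[["v1"]]) / p[["v2"]]))
  winf <- 0.5 * (1 + tanh((v - p[["v3"]]) / p[["v4"]]))
  lamw <- cosh((v - p[["v3"]]) / (2 * p[["v4"]])) / p[["tauWScaled"]]
  sinf <- 0.5 * (1 + tanh((v - p[["sHalf"]]) / p[["sSlope"]]))
  tauS <- p[["tauDecayScaled"]] + (1 - p[["tauDecayScaled"]]) * sinf
  rel <- 0.5 * (1 + tanh((v - p[["relHalf"]]) / p[["relSlope"]]))
  alpha <- if (a <= 0) 0 else a^p[["hill"]] / (a^p[["hill"]] + p[["aHalf"]]^p[["hill"]])
  iion <- -p[["gL"]] * (v - p[["eL"]]) - p[["gK"]] * r * (v - p[["eK"]]) -
    minf * (v - p[["eCa"]]) - p[["gACh"]] * alpha * (v - p[["eA"]])
  c(v = iion / p[["epsilon"]],
    r = lamw * (winf + p[["kappa"]] * s - r),
    s = (sinf - s) / tauS,
    a = p[["betaScaled"]] * rel - a / p[["tauAScaled"]])
}

#' Reference values of the dimensionless parameters
#'
#' The dimensionless constants implied by the default parameter registry,
#' as fixed reference values for regression checks (relation and value for
#' each entry).
#'
#' @return data.frame: \code{name}, \code{relation}, \code{value}.
#' @export
dimensionlessReference <- function() {
  data.frame(
    name = c("eK", "eCa", "eL", "gK", "gL", "gACh",
             "v1", "v2", "v3", "v4", "sHalf",
             "epsilon", "epsilonW", "epsilonS", "aHalf"),
    relation = c("E_K/V0", "E_Ca/V0", "E_leak/V0", "g_K/g0", "g_leak/g0",
                 "g_ACh/g0", "m_half/V0", "m_slope/V0", "w_half/V0",
                 "w_slope/V0", "sahp_half/V0", "(C/g0)/tau_R",
                 "(C/g0)/tau_w", "(C/g0)/tau_S", "K/A0"),
    value = c(-1.8, 1, -1.4, 1 / 3, 1 / 15, 1 / 10,
              -0.4, 0.4, -0.8, 0.8, -0.5,
              0.0010667, 0.026667, 8.889e-05, 800))
}
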