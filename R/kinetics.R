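# Single-cell reaction kinetics: auxiliary functions, right-hand sides and
# the rest state. These are the reference (pure R) implementations; the
# compiled integrator in src/core.cpp evaluates the same expressions.

#' Morris-Lecar auxiliary gating functions
#'
#' Evaluates the steady-state calcium activation \code{mInf}, the
#' steady-state potassium-gate activation \code{wInf} and the voltage-
#' dependent gate time constant \code{tauW} at membrane potential \code{v}.
#' The standard forms are used:
#' \deqn{m_\infty(v) = \tfrac12 (1 + \tanh((v - v_1)/v_2)),}
#' \deqn{w_\infty(v) = \tfrac12 (1 + \tanh((v - v_3)/v_4)),}
#' \deqn{\tau_w(v) = \bar\tau_w / \cosh((v - v_3)/(2 v_4)).}
#'
#' @param v membrane potential(s), mV. Must be finite.
#' @param params a \code{\link{ModelParams}} object.
#' @return list with numeric components \code{mInf}, \code{wInf} (both in
#'   \eqn{[0,1]}) and \code{tauW} (s, positive).
#' @examples
#' gatingFunctions(-20, modelParams())$mInf  # 0.5 at the half-activation
#' @export
gatingFunctions <- function(v, params) {
  stopifnot(is(params, "ModelParams"))
  if (!all(is.finite(v))) stop("membrane potential must be finite")
  g <- params@gating
  list(
    mInf = 0.5 * (1 + tanh((v - g[["mHalf"]]) / g[["mSlope"]])),
    wInf = 0.5 * (1 + tanh((v - g[["wHalf"]]) / g[["wSlope"]])),
    tauW = g[["tauW"]] / cosh((v - g[["wHalf"]]) / (2 * g[["wSlope"]])))
}

#' ACh-gated excitatory conductance
#'
#' Hill-form dependence of the nicotinic conductance on the local
#' extracellular ACh concentration:
#' \deqn{g(a) = \bar g_{ACh} \, a^n / (a^n + K^n).}
#'
#' @param a ACh concentration(s), nM; must be non-negative.
#' @param params a \code{\link{ModelParams}} object.
#' @return conductance(s) in nS, in \eqn{[0, \bar g_{ACh}]}, nondecreasing
#'   in \code{a}, equal to \eqn{\bar g_{ACh}/2} at the half-saturation K.
#' @examples
#' achConductance(800, modelParams())  # half of g_ACh
#' @export
achConductance <- function(a, params) {
  stopifnot(is(params, "ModelParams"))
  if (any(!is.finite(a)) || any(a < 0)) stop("ACh concentration must be finite and >= 0")
  K <- params@ach[["halfSaturation"]]
  n <- params@ach[["hill"]]
  params@conductances[["ACh"]] * a^n / (a^n + K^n)
}

#' Voltage-dependent ACh release rate
#'
#' Sigmoidal release of ACh into the extracellular space, half-maximal at
#' the release threshold:
#' \deqn{\rho(v) = \beta \tfrac12 (1 + \tanh((v - v_{rel})/k_{rel})).}
#'
#' @param v membrane potential(s), mV; must be finite.
#' @param params a \code{\link{ModelParams}} object.
#' @return release rate(s) in nM/s, non-negative and nondecreasing in v.
#' @export
achReleaseRate <- function(v, params) {
  stopifnot(is(params, "ModelParams"))
  if (!all(is.finite(v))) stop("membrane potential must be finite")
  a <- params@ach
  a[["releaseRate"]] * 0.5 * (1 + tanh((v - a[["releaseHalf"]]) / a[["releaseSlope"]]))
}

#' sAHP activation sigmoid and state-dependent time constant
#'
#' The sAHP level s relaxes towards \code{sInf(v)} with a time constant that
#' interpolates between the activation time (depolarised) and the decay time
#' (at rest): \code{tauS(v) = tauDecay + (tauAct - tauDecay) sInf(v)}.
#'
#' @param v membrane potential(s), mV.
#' @param params a \code{\link{ModelParams}} object.
#' @return list with components \code{sInf} and \code{tauS} (s).
#' @export
sahpActivation <- function(v, params) {
  stopifnot(is(params, "ModelParams"))
  s <- params@sahp
  si <- 0.5 * (1 + tanh((v - s[["half"]]) / s[["slope"]]))
  list(sInf = si, tauS = s[["tauDecay"]] + (s[["tauAct"]] - s[["tauDecay"]]) * si)
}

#' Local reaction right-hand side
#'
#' Time derivatives of the state (v, r, s, a) of a single cell (or,
#' vectorised, of every lattice cell), excluding the ACh diffusion term:
#' \deqn{C \dot v = -g_L (v-E_L) - g_K r (v-E_K) - g_{Ca} m_\infty(v)(v-E_{Ca})
#'   - (g_{ACh}\alpha(a) + g_\chi)(v - E_{ACh}) + I_{ext},}
#' \deqn{\dot r = (\min(w_\infty(v) + \kappa s, 1) - r)/\tau_w(v), \quad
#'   \dot s = (s_\infty(v) - s)/\tau_s(v), \quad
#'   \dot a = \rho(v) - a/\tau_a.}
#' The sAHP level enters through the refractory-gate target, saturating at
#' full gate activation.
#'
#' @param state numeric vector \code{c(v, r, s, a)} or a 4-column matrix of
#'   states (columns v, r, s, a).
#' @param params a \code{\link{ModelParams}} object.
#' @param iExt external current, pA (recycled).
#' @param gNoise additional excitatory conductance (noise channel), nS.
#' @return derivative(s) in the same shape as \code{state}; units mV/s,
#'   1/s, 1/s, nM/s.
#' @examples
#' p <- modelParams()
#' rest <- findRestState(p)
#' max(abs(reactionRHS(rest, p)))  # ~0 at the rest state
#' @export
reactionRHS <- function(state, params, iExt = 0, gNoise = 0) {
  stopifnot(is(params, "ModelParams"))
  vec <- is.null(dim(state))
  m <- if (vec) matrix(state, 1) else state
  if (ncol(m) != 4) stop("state must have four components (v, r, s, a)")
  if (any(!is.finite(m))) stop("state must be finite")
  if (any(m[, 2] < -1e-9))
    stop("refractory gate r must be non-negative")
  if (any(m[, 4] < -1e-9)) stop("ACh concentration must be non-negative")
  v <- m[, 1]; r <- m[, 2]; s <- m[, 3]; a <- pmax(m[, 4], 0)
  gg <- gatingFunctions(v, params)
  sa <- sahpActivation(v, params)
  cc <- params@conductances
  rv <- params@reversals
  iIon <- -cc[["leak"]] * (v - rv[["leak"]]) -
    cc[["K"]] * r * (v - rv[["K"]]) -
    cc[["Ca"]] * gg$mInf * (v - rv[["Ca"]]) -
    (achConductance(a, params) + gNoise) * (v - rv[["ACh"]]) + iExt
  out <- cbind(
    v = iIon / params@capacitance,
    r = (gg$wInf + params@sahp[["strength"]] * s - r) / gg$tauW,
    s = (sa$sInf - s) / sa$tauS,
    a = achReleaseRate(v, params) - a / params@ach[["clearanceTime"]])
  if (vec) drop(out) else out
}

#' Find the stable rest state
#'
#' Locates the hyperpolarised fixed point of the local kinetics by damped
#' Newton iteration from a hyperpolarised seed, polishing a settled forward
#' integration, and verifies linear stability (all eigenvalues of the
#' Jacobian have negative real part).
#'
#' @param params a \code{\link{ModelParams}} object.
#' @param vInit starting potential for the search, mV.
#' @param requireStable error if the located fixed point is unstable
#'   (default TRUE; with FALSE the state is returned with a warning and
#'   attribute \code{stable = FALSE}).
#' @return named numeric \code{c(v, r, s, a)} with attribute \code{stable}.
#' @export
findRestState <- function(params, vInit = -70, requireStable = TRUE) {
  stopifnot(is(params, "ModelParams"))
  key <- paste(sprintf("%.17g", c(asParamVector(params), vInit)), collapse = ",")
  hit <- .restCache[[key]]
  if (!is.null(hit)) return(hit)
  f <- function(y) reactionRHS(clampState(y), params)
  # settle by integration first (robust bracketing of the attractor)
  y <- c(v = vInit, r = gatingFunctions(vInit, params)$wInf,
         s = sahpActivation(vInit, params)$sInf, a = 0)
  y[["a"]] <- achReleaseRate(vInit, params) * params@ach[["clearanceTime"]]
  h <- 0.01
  for (i in 1:4000) {
    d <- f(y)
    y <- clampState(y + h * d)
    if (i %% 200 == 0 && max(abs(d)) < 1e-8) break
  }
  # damped Newton polish (residuals scaled per component: 50 mV, 1, 1, 800 nM)
  dscale <- c(50, 1, 1, 800)
  for (i in 1:100) {
    d <- f(y)
    if (max(abs(d / dscale)) < 1e-11) break
    J <- numJacobian(f, y)
    step <- tryCatch(solve(J, -d), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      yn <- clampState(y + lam * step)
      if (max(abs(f(yn) / dscale)) < max(abs(d / dscale)) || lam < 1e-4) break
      lam <- lam / 2
    }
    y <- yn
  }
  res <- max(abs(f(y) / dscale))
  if (res > 1e-8)
    stop(sprintf("rest-state search did not converge (residual %.3g)", res))
  if (y[["v"]] > -50)
    stop(sprintf(
      "no hyperpolarised rest state: kinetics settle at v = %.1f mV", y[["v"]]))
  J <- numJacobian(f, y)
  stable <- all(Re(eigen(J, only.values = TRUE)$values) < 0)
  if (!stable) {
    if (requireStable) stop("located fixed point is linearly unstable")
    warning("located fixed point is linearly unstable")
  }
  names(y) <- c("v", "r", "s", "a")
  attr(y, "stable") <- stable
  .restCache[[key]] <- y
  y
}

.restCache <- new.env(parent = emptyenv())

clampState <- function(y) {
  y[2] <- max(y[2], 0)
  y[3] <- max(y[3], 0)
  y[4] <- max(y[4], 0)
  y
}

numJacobian <- function(f, y, eps = 1e-6) {
  n <- length(y)
  f0 <- f(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}
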