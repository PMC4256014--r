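# Travelling-front analysis of the fast subsystem: fixed points, front
# speeds by relaxation and by a moving-frame boundary-value solve, c(s)
# curves, excitability thresholds, and the absolute refractory period.
#
# The fast subsystem holds the slow sAHP level s frozen as a parameter and
# retains the three fast variables (v, r, a); only a diffuses. A front is a
# heteroclinic connection between the rest and excited spatially uniform
# fixed points in the frame moving with speed c.

# analytic partial derivatives of the local kinetics (s frozen)
kineticsPartials <- function(v, r, a, s, params) {
  g <- params@gating; cc <- params@conductances; rv <- params@reversals
  sa <- params@sahp; ac <- params@ach
  C <- params@capacitance
  mi <- 0.5 * (1 + tanh((v - g[["mHalf"]]) / g[["mSlope"]]))
  dmi <- 0.5 / g[["mSlope"]] / cosh((v - g[["mHalf"]]) / g[["mSlope"]])^2
  wi <- 0.5 * (1 + tanh((v - g[["wHalf"]]) / g[["wSlope"]]))
  dwi <- 0.5 / g[["wSlope"]] / cosh((v - g[["wHalf"]]) / g[["wSlope"]])^2
  lam <- cosh((v - g[["wHalf"]]) / (2 * g[["wSlope"]])) / g[["tauW"]]
  dlam <- sinh((v - g[["wHalf"]]) / (2 * g[["wSlope"]])) /
    (2 * g[["wSlope"]] * g[["tauW"]])
  K <- ac[["halfSaturation"]]; n <- ac[["hill"]]
  an <- pmax(a, 1e-12)^n
  alpha <- an / (an + K^n)
  dalpha <- n * pmax(a, 1e-12)^(n - 1) * K^n / (an + K^n)^2
  rel <- 0.5 * (1 + tanh((v - ac[["releaseHalf"]]) / ac[["releaseSlope"]]))
  drel <- 0.5 / ac[["releaseSlope"]] /
    cosh((v - ac[["releaseHalf"]]) / ac[["releaseSlope"]])^2
  gtot <- cc[["leak"]] + cc[["K"]] * r + cc[["Ca"]] * mi + cc[["ACh"]] * alpha
  fv <- (-cc[["leak"]] * (v - rv[["leak"]]) - cc[["K"]] * r * (v - rv[["K"]]) -
           cc[["Ca"]] * mi * (v - rv[["Ca"]]) -
           cc[["ACh"]] * alpha * (v - rv[["ACh"]])) / C
  fr <- lam * (wi + sa[["strength"]] * s - r)
  fa <- ac[["releaseRate"]] * rel - a / ac[["clearanceTime"]]
  list(
    fv = fv, fr = fr, fa = fa,
    dfv_dv = (-gtot - cc[["Ca"]] * dmi * (v - rv[["Ca"]])) / C,
    dfv_dr = -cc[["K"]] * (v - rv[["K"]]) / C,
    dfv_da = -cc[["ACh"]] * dalpha * (v - rv[["ACh"]]) / C,
    dfr_dv = dlam * (wi + sa[["strength"]] * s - r) + lam * dwi,
    dfr_dr = -lam,
    dfa_dv = ac[["releaseRate"]] * drel,
    dfa_da = rep(-1 / ac[["clearanceTime"]], length(v)))
}

# fixed points of the frozen-s fast subsystem, dimensioned units
fastFixedPointsDimensioned <- function(params, s = 0, vRange = c(-110, 49),
                                       nScan = 1200) {
  wOf <- function(v) gatingFunctions(v, params)$wInf + params@sahp[["strength"]] * s
  aOf <- function(v) achReleaseRate(v, params) * params@ach[["clearanceTime"]]
  Fv <- function(v) {
    reactionRHS(cbind(v, pmax(wOf(v), 0), s, aOf(v)), params)[, "v"]
  }
  vs <- seq(vRange[1], vRange[2], length.out = nScan)
  fs <- Fv(vs)
  roots <- c()
  for (i in seq_len(nScan - 1)) {
    if (is.finite(fs[i]) && is.finite(fs[i + 1]) && fs[i] * fs[i + 1] < 0) {
      roots <- c(roots, uniroot(Fv, c(vs[i], vs[i + 1]), tol = 1e-12)$root)
    }
  }
  pts <- lapply(roots, function(v) {
    y <- c(v = v, r = max(wOf(v), 0), s = s, a = aOf(v))
    kp <- kineticsPartials(v, y[["r"]], y[["a"]], s, params)
    J <- matrix(c(kp$dfv_dv, kp$dfv_dr, kp$dfv_da,
                  kp$dfr_dv, kp$dfr_dr, 0,
                  kp$dfa_dv, 0, kp$dfa_da), 3, 3, byrow = TRUE)
    ev <- eigen(J, only.values = TRUE)$values
    list(state = y, eigenvalues = ev,
         stable = all(Re(ev) < 0),
         type = if (all(Re(ev) < 0)) "stable" else
           if (all(Re(ev) > 0)) "unstable" else "saddle")
  })
  stablePts <- Filter(function(p) p$stable, pts)
  vsStable <- vapply(stablePts, function(p) p$state[["v"]], 0)
  rest <- if (length(stablePts)) stablePts[[which.min(vsStable)]]$state else NULL
  excited <- if (length(stablePts) >= 2) stablePts[[which.max(vsStable)]]$state else NULL
  list(points = pts, rest = rest, excited = excited,
       bistable = length(stablePts) >= 2)
}

#' Fixed points of the frozen-s fast subsystem
#'
#' Finds all spatially uniform fixed points of the fast subsystem (v, r, a)
#' with the sAHP level frozen at \code{s}, and classifies their linear
#' stability. For small s and default parameters the system is bistable
#' (hyperpolarised rest state and depolarised excited state separated by a
#' saddle); for s above the propagation threshold only the rest state
#' remains relevant to fronts.
#'
#' @param s frozen sAHP level (dimensionless, >= 0).
#' @param params a \code{\link{ModelParams}}.
#' @return data.frame with one row per fixed point: \code{v}, \code{r},
#'   \code{a}, \code{type} ("stable", "saddle", "unstable"),
#'   \code{maxRealEigen}; attribute \code{bistable}.
#' @export
fastFixedPoints <- function(s, params = modelParams()) {
  fp <- fastFixedPointsDimensioned(params, s)
  if (!length(fp$points)) {
    out <- data.frame(v = numeric(0), r = numeric(0), a = numeric(0),
                      type = character(0), maxRealEigen = numeric(0))
  } else {
    out <- do.call(rbind, lapply(fp$points, function(p)
      data.frame(v = p$state[["v"]], r = p$state[["r"]], a = p$state[["a"]],
                 type = p$type, maxRealEigen = max(Re(p$eigenvalues)))))
  }
  attr(out, "bistable") <- fp$bistable
  out
}

#' Front speed of the fast subsystem by PDE relaxation
#'
#' Integrates the frozen-s fast subsystem on a long 1D strip from a
#' sigmoidal profile joining the excited and rest states, and measures the
#' asymptotic signed front velocity (positive when the excited region
#' invades rest, negative when it recedes).
#'
#' @param s frozen sAHP level.
#' @param params a \code{\link{ModelParams}}.
#' @param n strip length in cells (default 400).
#' @param duration integration time, s (default 40).
#' @param dt step, s.
#' @return list: \code{speed} (mm/s; 0 for a pinned/stationary interface),
#'   \code{status} ("front", "receding", "pinned", "no-front"),
#'   \code{fixedPoints}, \code{profile} (final profiles; NULL if the
#'   interface disappeared), \code{confidence} ("ok" or "low").
#' @export
frontSpeedRelaxation <- function(s, params = modelParams(), n = 400,
                                 duration = 40, dt = 0.001) {
  fp <- fastFixedPointsDimensioned(params, s)
  if (!fp$bistable)
    return(list(speed = NA_real_, status = "no-front", fixedPoints = fp,
                profile = NULL, confidence = "ok"))
  res <- runFront1D(params, frozenS = s, n = n, duration = duration, dt = dt,
                    restState = fp$rest, excitedState = fp$excited)
  speed <- res$speed
  status <- res$status
  conf <- "ok"
  if (status == "none") {
    # interface collapsed: measure the shrink rate over the frames it lived
    pos <- res$positions; tt <- res$times
    ok <- is.finite(pos)
    if (sum(ok) >= 5) {
      fit <- lm(pos[ok] ~ tt[ok])
      speed <- unname(coef(fit)[2])
      status <- "receding"
      conf <- "low"
    } else {
      speed <- NA_real_
      status <- "receding"
      conf <- "low"
    }
  } else if (is.finite(speed) && abs(speed) < 2e-4) {
    speed <- 0
    status <- "pinned"
  } else if (is.finite(speed) && speed < 0) {
    status <- "receding"
  }
  list(speed = speed, status = status, fixedPoints = fp,
       profile = res$profile, confidence = conf)
}

#' Travelling-front profile by a moving-frame boundary-value solve
#'
#' Refines a relaxation front into a stationary solution of the moving-
#' frame equations
#' \deqn{c v' + f_v(v,r,a) = 0,\; c r' + f_r(v,r;s) = 0,\;
#'       D a'' + c a' + f_a(v,a) = 0}
#' on a truncated interval with the fixed points as Dirichlet boundary
#' values and a phase condition pinning the mid-level voltage crossing at
#' the interval centre. Newton iteration with an analytic sparse Jacobian;
#' the unknowns are the three profiles and the speed c.
#'
#' @param s frozen sAHP level.
#' @param params a \code{\link{ModelParams}}.
#' @param cInit initial speed guess, mm/s (e.g. from
#'   \code{\link{frontSpeedRelaxation}}); required.
#' @param profileInit optional data.frame with columns \code{x}, \code{v},
#'   \code{r}, \code{a} (e.g. the relaxation profile); a tanh seed is used
#'   otherwise.
#' @param n collocation points (default 4000; the voltage transition layer
#'   is ~2 um wide and must be resolved).
#' @param halfWidth half interval length, mm (default 0.8).
#' @param tol Newton tolerance on the scaled residual (default 1e-10).
#' @param maxIter Newton iterations.
#' @return a \code{\link{FrontSolution}}.
#' @export
frontProfileBVP <- function(s, params = modelParams(), cInit,
                            profileInit = NULL, n = 4000, halfWidth = 0.8,
                            tol = 1e-10, maxIter = 40) {
  fp <- fastFixedPointsDimensioned(params, s)
  if (!fp$bistable) stop("fast subsystem is not bistable at s = ", s)
  rest <- fp$rest; exc <- fp$excited
  D <- params@diffusion
  xi <- seq(-halfWidth, halfWidth, length.out = n)
  h <- xi[2] - xi[1]
  mid <- (n + 1) %/% 2
  level <- (rest[["v"]] + exc[["v"]]) / 2

  gapV <- exc[["v"]] - rest[["v"]]
  if (!is.null(profileInit) &&
      (diff(range(profileInit$v)) < 0.5 * gapV || anyNA(profileInit$v)))
    profileInit <- NULL   # degenerate relaxation profile; use the tanh seed
  if (is.null(profileInit)) {
    w <- 0.05
    blend <- 0.5 * (1 - tanh(xi / w))  # 1 at left (excited), 0 at right
    v <- blend * exc[["v"]] + (1 - blend) * rest[["v"]]
    r <- blend * exc[["r"]] + (1 - blend) * rest[["r"]]
    a <- blend * exc[["a"]] + (1 - blend) * rest[["a"]]
  } else {
    # centre the supplied profile on its mid-level crossing
    pr <- profileInit
    below <- which(pr$v <= level)
    cross <- if (length(below) && min(below) > 1) {
      i <- min(below)
      approx(pr$v[c(i - 1, i)], pr$x[c(i - 1, i)], xout = level)$y
    } else NA_real_
    if (is.na(cross)) cross <- mean(range(pr$x))
    v <- approx(pr$x - cross, pr$v, xout = xi, rule = 2)$y
    r <- approx(pr$x - cross, pr$r, xout = xi, rule = 2)$y
    a <- approx(pr$x - cross, pr$a, xout = xi, rule = 2)$y
    if (v[1] < v[n]) { v <- rev(v); r <- rev(r); a <- rev(a) }
  }
  cc <- cInit
  # smooth the interpolated guess by integrating the frozen-s subsystem
  # briefly on the collocation grid, then re-centre on the level crossing
  pv <- asParamVector(params)
  pv[30] <- h * n
  sm <- cpp_run_grid(pv, as.integer(n), 1L, 5e-4, 0.2, 0, 0.2, FALSE, -60,
                     0L, 0.2, v, r, rep(s, n), a,
                     matrix(numeric(0), 0, 4), TRUE, FALSE, -50, 0)
  nt <- length(sm$times)
  v <- matrix(sm$v, n, nt)[, nt]
  r <- matrix(sm$r, n, nt)[, nt]
  a <- matrix(sm$a, n, nt)[, nt]
  below <- which(v <= level)
  if (length(below) && min(below) > 0.15 * n && min(below) < 0.85 * n) {
    mid <- min(below)   # pin the phase at the profile's own crossing
  } else if (length(below) && min(below) > 1) {
    shift <- min(below) - mid
    idx <- pmin(pmax(seq_len(n) + shift, 1), n)
    v <- v[idx]; r <- r[idx]; a <- a[idx]
  }
  v[1] <- exc[["v"]]; r[1] <- exc[["r"]]; a[1] <- exc[["a"]]
  v[n] <- rest[["v"]]; r[n] <- rest[["r"]]; a[n] <- rest[["a"]]

  # residual scaling to O(1) (fast-subsystem time units)
  g0 <- params@conductances[["Ca"]]
  sv <- params@capacitance / (g0 * 50)       # v-equation -> per membrane time
  sr <- params@gating[["tauW"]]
  sa <- params@ach[["clearanceTime"]] / max(params@ach[["halfSaturation"]], 1)

  idxV <- seq_len(n); idxR <- n + seq_len(n); idxA <- 2 * n + seq_len(n)
  idxC <- 3 * n + 1

  # The v and r equations are first-order transport; pure central
  # differencing admits odd-even modes and pure upwinding amplifies the
  # stable-manifold mode along the plateaus. Use central differences with
  # streamline (artificial) diffusion eps = |c| h / 2 -- the standard
  # stabilisation, first-order consistent in h.
  ctr <- function(y) c(0, (y[3:n] - y[1:(n - 2)]) / (2 * h), 0)
  lap <- function(y) c(0, (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / h^2, 0)
  residual <- function(v, r, a, cc) {
    kp <- kineticsPartials(v, r, a, s, params)
    eps <- abs(cc) * h / 2
    Rv <- (cc * ctr(v) + eps * lap(v) + kp$fv) * sv
    Rr <- (cc * ctr(r) + eps * lap(r) + kp$fr) * sr
    Ra <- (D * lap(a) + cc * ctr(a) + kp$fa) * sa
    Rv[1] <- (v[1] - exc[["v"]]) / 50
    Rv[n] <- (v[n] - rest[["v"]]) / 50
    Rr[1] <- r[1] - exc[["r"]]
    Rr[n] <- r[n] - rest[["r"]]
    Ra[1] <- (a[1] - exc[["a"]]) / max(exc[["a"]], 1)
    Ra[n] <- (a[n] - rest[["a"]]) / max(exc[["a"]], 1)
    phase <- (v[mid] - level) / 50
    c(Rv, Rr, Ra, phase)
  }

  mu <- 0
  for (iter in seq_len(maxIter)) {
    R <- residual(v, r, a, cc)
    if (any(!is.finite(R)))
      stop("non-finite residual at Newton iteration ", iter,
           " (c = ", signif(cc, 4), ")")
    if (max(abs(R)) < tol) break
    kp <- kineticsPartials(v, r, a, s, params)
    eps <- abs(cc) * h / 2
    dvdx <- ctr(v); drdx <- ctr(r); dadx <- ctr(a)
    dvdxL <- lap(v); drdxL <- lap(r)
    cm <- -cc / (2 * h) + eps / h^2   # coefficient of y_{i-1}
    cp2 <- cc / (2 * h) + eps / h^2   # coefficient of y_{i+1}
    cd <- -2 * eps / h^2              # added diagonal
    ii <- jj <- integer(0); vv <- numeric(0)
    add <- function(i, j, x) {
      keep <- x != 0
      ii <<- c(ii, i[keep]); jj <<- c(jj, j[keep]); vv <<- c(vv, x[keep])
    }
    int <- 2:(n - 1)
    sgn <- sign(cc + (cc == 0))
    # v equations (d eps/d c = sgn * h/2 enters the c-column)
    add(idxV[int], idxV[int], (kp$dfv_dv[int] + cd) * sv)
    add(idxV[int], idxV[int - 1], rep(cm, n - 2) * sv)
    add(idxV[int], idxV[int + 1], rep(cp2, n - 2) * sv)
    add(idxV[int], idxR[int], kp$dfv_dr[int] * sv)
    add(idxV[int], idxA[int], kp$dfv_da[int] * sv)
    add(idxV[int], rep(idxC, n - 2),
        (dvdx[int] + sgn * h / 2 * dvdxL[int]) * sv)
    add(idxV[c(1, n)], idxV[c(1, n)], c(1 / 50, 1 / 50))
    # r equations
    add(idxR[int], idxR[int], (kp$dfr_dr[int] + cd) * sr)
    add(idxR[int], idxR[int - 1], rep(cm, n - 2) * sr)
    add(idxR[int], idxR[int + 1], rep(cp2, n - 2) * sr)
    add(idxR[int], idxV[int], kp$dfr_dv[int] * sr)
    add(idxR[int], rep(idxC, n - 2),
        (drdx[int] + sgn * h / 2 * drdxL[int]) * sr)
    add(idxR[c(1, n)], idxR[c(1, n)], c(1, 1))
    # a equations
    add(idxA[int], idxA[int], (kp$dfa_da[int] - 2 * D / h^2) * sa)
    add(idxA[int], idxA[int - 1], rep(D / h^2 - cc / (2 * h), n - 2) * sa)
    add(idxA[int], idxA[int + 1], rep(D / h^2 + cc / (2 * h), n - 2) * sa)
    add(idxA[int], idxV[int], kp$dfa_dv[int] * sa)
    add(idxA[int], rep(idxC, n - 2), dadx[int] * sa)
    aden <- max(exc[["a"]], 1)
    add(idxA[c(1, n)], idxA[c(1, n)], c(1 / aden, 1 / aden))
    # phase condition
    add(idxC, idxV[mid], 1 / 50)
    J <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                              dims = c(3 * n + 1, 3 * n + 1))
    # damped (Levenberg-style) Newton: on a stalled line search, retry the
    # linear solve with a diagonal shift and keep it until steps improve
    improved <- FALSE
    repeat {
      Jm <- if (mu > 0) J + Matrix::Diagonal(3 * n + 1, mu) else J
      step <- tryCatch(as.numeric(Matrix::solve(Jm, -R)),
                       error = function(e) NULL)
      if (!is.null(step)) {
        lam <- 1
        while (lam >= 1 / 256) {
          v2 <- v + lam * step[idxV]; r2 <- r + lam * step[idxR]
          a2 <- pmax(a + lam * step[idxA], 0); c2 <- cc + lam * step[idxC]
          R2 <- residual(v2, r2, a2, c2)
          if (all(is.finite(R2)) && max(abs(R2)) < max(abs(R))) {
            improved <- TRUE
            break
          }
          lam <- lam / 2
        }
      }
      if (improved || mu > 1) break
      mu <- if (mu == 0) 1e-4 else mu * 10
    }
    if (!improved)
      stop(sprintf(
        "Newton iteration stalled at residual %.3g (iteration %d)",
        max(abs(R)), iter))
    v <- v2; r <- r2; a <- a2; cc <- c2
    mu <- mu / 4
  }
  R <- residual(v, r, a, cc)
  resid <- max(abs(R))
  converged <- resid < 1e-8
  if (!converged)
    warning(sprintf("front BVP did not reach tolerance (residual %.3g)", resid))
  dp <- nondimensionalize(params)
  prof <- cbind(v = v, r = r, a = a,
                da = c(NA, (a[3:n] - a[1:(n - 2)]) / (2 * h), NA))
  new("FrontSolution", xi = xi, profile = prof, speed = cc,
      speedDimensionless = cc * dp@scales[["time"]] / dp@scales[["space"]],
      sFrozen = s,
      restPoint = c(v = rest[["v"]], r = rest[["r"]], a = rest[["a"]]),
      excitedPoint = c(v = exc[["v"]], r = exc[["r"]], a = exc[["a"]]),
      residual = resid, converged = converged)
}

#' Front speed as a function of the frozen refractory level
#'
#' Computes the c(s) curve by PDE relaxation over a grid of frozen sAHP
#' levels and locates the propagation threshold s* (the level at which the
#' front stops advancing) by bisection. c(s) is monotone decreasing; s*
#' defines the absolute refractory criterion c(s*) = 0.
#'
#' @param params a \code{\link{ModelParams}}.
#' @param sGrid sAHP levels (default \code{seq(0, 0.25, by = 0.025)}).
#' @param bvpRefine also refine each propagating point with
#'   \code{\link{frontProfileBVP}} (slower; default FALSE).
#' @param n,duration passed to \code{\link{frontSpeedRelaxation}}.
#' @return list of class \code{speedCurve}: \code{curve} (data.frame s,
#'   speed, status, and bvpSpeed if requested), \code{sStar}.
#' @export
speedVsRefractory <- function(params = modelParams(),
                              sGrid = seq(0, 0.25, by = 0.025),
                              bvpRefine = FALSE, n = 400, duration = 40) {
  rows <- lapply(sGrid, function(s) {
    r <- frontSpeedRelaxation(s, params, n = n, duration = duration)
    data.frame(s = s, speed = r$speed, status = r$status)
  })
  curve <- do.call(rbind, rows)
  if (bvpRefine) {
    curve$bvpSpeed <- NA_real_
    for (i in seq_len(nrow(curve))) {
      if (identical(curve$status[i], "front") && is.finite(curve$speed[i]) &&
          curve$speed[i] > 0) {
        rel <- frontSpeedRelaxation(curve$s[i], params, n = n,
                                    duration = duration)
        sol <- tryCatch(
          frontProfileBVP(curve$s[i], params, cInit = curve$speed[i],
                          profileInit = rel$profile),
          error = function(e) NULL)
        if (!is.null(sol)) curve$bvpSpeed[i] <- sol@speed
      }
    }
  }
  # bisect the advancing/non-advancing transition
  adv <- curve$s[curve$status == "front" & curve$speed > 0]
  non <- curve$s[curve$status %in% c("pinned", "receding", "no-front")]
  sStar <- NA_real_
  if (length(adv) && length(non) && max(adv) < min(non)) {
    lo <- max(adv); hi <- min(non)
    for (i in 1:7) {
      mids <- (lo + hi) / 2
      r <- frontSpeedRelaxation(mids, params, n = n, duration = duration)
      if (identical(r$status, "front") && is.finite(r$speed) && r$speed > 0)
        lo <- mids else hi <- mids
    }
    sStar <- (lo + hi) / 2
  } else if (length(non) && !length(adv)) {
    sStar <- 0
  }
  structure(list(curve = curve, sStar = sStar), class = "speedCurve")
}

#' Excitability threshold curve over two conductances
#'
#' Maps the boundary between propagating and non-propagating media at
#' s = 0 over the plane of the ACh and K maximal conductances: for each K
#' conductance on the grid, bisects on the ACh conductance to locate the
#' front transition. Points above the curve are excitable. The threshold
#' depends only on the fast subsystem, hence not on the sAHP timescales or
#' the noise rate, and (after nondimensionalisation) not on D.
#'
#' @param params base \code{\link{ModelParams}}.
#' @param gKGrid K-conductance values, nS.
#' @param gARange search interval for the ACh conductance, nS.
#' @param tol bisection tolerance on g_ACh, nS.
#' @param n,duration relaxation-run settings.
#' @return data.frame: \code{gK}, \code{gAThreshold} (NA marks an open
#'   boundary, i.e. no transition inside \code{gARange}).
#' @export
excitabilityThresholdCurve <- function(params = modelParams(),
                                       gKGrid = seq(6, 14, by = 2),
                                       gARange = c(0.2, 12), tol = 0.05,
                                       n = 250, duration = 25) {
  propagates <- function(gA, gK) {
    p <- modelParamsFrom(params, conductances = c(ACh = gA, K = gK))
    r <- tryCatch(frontSpeedRelaxation(0, p, n = n, duration = duration),
                  error = function(e) list(status = "no-front", speed = NA))
    identical(r$status, "front") && is.finite(r$speed) && r$speed > 0
  }
  out <- lapply(gKGrid, function(gK) {
    lo <- gARange[1]; hi <- gARange[2]
    pLo <- propagates(lo, gK); pHi <- propagates(hi, gK)
    if (pLo == pHi) return(data.frame(gK = gK, gAThreshold = NA_real_))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (propagates(mid, gK) == pHi) hi <- mid else lo <- mid
    }
    data.frame(gK = gK, gAThreshold = (lo + hi) / 2)
  })
  do.call(rbind, out)
}

#' Excitability by direct simulation
#'
#' Simulates the full model (noise disabled) from an initial condition in
#' which a strip or a small point cluster on one side of the domain is
#' excited, and reports whether activity above the excited threshold
#' reaches the far side of the domain within the horizon.
#'
#' @param params a \code{\link{ModelParams}}.
#' @param epsilonScale multiplies the separation between the fast and slow
#'   timescales: the sAHP times are divided by \code{epsilonScale}, so
#'   values < 1 slow the sAHP further (larger separation) and approach the
#'   frozen-s analysis.
#' @param init \code{"strip"} (excited column, 1D-like front) or
#'   \code{"point"} (small cluster, radially symmetric wave).
#' @param duration horizon, s (default 10).
#' @param gridN,domainLength lattice geometry (defaults 64, 1 mm for a
#'   10 s horizon at the default wave speeds).
#' @param excitedThreshold mV (default -20).
#' @return logical: TRUE if the far 10% of the domain is excited.
#' @export
excitabilityBySimulation <- function(params = modelParams(),
                                     epsilonScale = 1,
                                     init = c("strip", "point"),
                                     duration = 10, gridN = 64,
                                     domainLength = 1,
                                     excitedThreshold = -20) {
  init <- match.arg(init)
  p <- modelParamsFrom(params,
                       sahp = c(tauAct = params@sahp[["tauAct"]] / epsilonScale,
                                tauDecay = params@sahp[["tauDecay"]] / epsilonScale))
  rest <- findRestState(p)
  fp <- fastFixedPointsDimensioned(p, 0)
  exc <- if (!is.null(fp$excited)) fp$excited else
    c(v = 0, r = 1, s = 0, a = p@ach[["releaseRate"]] * p@ach[["clearanceTime"]])
  n <- gridN
  vm <- matrix(rest[["v"]], n, n); rm <- matrix(rest[["r"]], n, n)
  sm <- matrix(0, n, n); am <- matrix(rest[["a"]], n, n)
  seedCols <- 1:3
  if (init == "strip") {
    vm[seedCols, ] <- exc[["v"]]; rm[seedCols, ] <- exc[["r"]]
    am[seedCols, ] <- exc[["a"]]
  } else {
    cy <- n %/% 2
    pts <- expand.grid(x = 1:3, y = (cy - 1):(cy + 1))
    for (k in seq_len(nrow(pts))) {
      vm[pts$x[k], pts$y[k]] <- exc[["v"]]
      rm[pts$x[k], pts$y[k]] <- exc[["r"]]
      am[pts$x[k], pts$y[k]] <- exc[["a"]]
    }
  }
  cfg <- simConfig(duration = duration, warmup = 0, gridN = n,
                   domainLength = domainLength, snapshotInterval = 0.05,
                   seed = 1, noise = FALSE, record = "activity",
                   activityThreshold = excitedThreshold)
  snap <- runSimulation(cfg, p, init = list(v = as.numeric(vm),
                                            r = as.numeric(rm),
                                            s = as.numeric(sm),
                                            a = as.numeric(am)))
  act <- array(as.integer(snap@activity), c(n, n, length(snap@times)))
  far <- (n - max(1, round(0.1 * n)) + 1):n
  any(act[far, , ] > 0)
}

#' Absolute refractory period
#'
#' Time after a standard spontaneous burst during which a cell cannot
#' support wave propagation: the sAHP level s(t) is simulated for a single
#' cell following a burst and compared against the propagation threshold
#' s* from \code{\link{speedVsRefractory}}; the period is the time from
#' the burst until s first falls below s*.
#'
#' @param params a \code{\link{ModelParams}}.
#' @param sStar optional precomputed propagation threshold; computed by
#'   bisection otherwise.
#' @param horizon simulated time, s (default 240).
#' @return the refractory period in seconds, with attributes \code{sStar},
#'   \code{s0} (post-burst peak level) and \code{curve} (s(t) samples).
#'   Zero (with a warning) if s never exceeds s*.
#' @export
absoluteRefractoryPeriod <- function(params = modelParams(), sStar = NULL,
                                     horizon = 240) {
  if (is.null(sStar)) {
    sc <- speedVsRefractory(params, sGrid = seq(0, 0.3, by = 0.05))
    sStar <- sc$sStar
  }
  if (!is.finite(sStar)) stop("no propagation threshold s* available")
  rest <- findRestState(params)
  kick <- data.frame(start = 1, end = 1.03,
                     amplitude = params@conductances[["noise"]] *
                       (params@reversals[["ACh"]] - rest[["v"]]))
  tr <- runSingleCell(params, duration = horizon, protocol = kick,
                      recordInterval = 0.05)
  burstEnd <- tr$time[max(which(tr$v > -50))]
  s0 <- max(tr$s)
  if (s0 <= sStar) {
    warning("sAHP level never exceeds s*; refractory period is zero")
    period <- 0
  } else {
    after <- tr$time > burstEnd
    below <- after & tr$s < sStar
    period <- if (any(below)) min(tr$time[below]) - burstEnd else Inf
  }
  structure(period, sStar = sStar, s0 = s0,
            curve = tr[seq(1, nrow(tr), by = 4), c("time", "s")])
}
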