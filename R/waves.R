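# Wave-statistics pipeline: thresholding, spatiotemporal labelling,
# size/duration/speed/IWI statistics, correlation curves, power-law fits.

#' Threshold a snapshot series into an activity mask
#'
#' Marks a lattice point active when its potential exceeds the threshold,
#' excluding a margin near the boundary (margin cells are never active).
#' If the series was recorded in activity mode its stored mask is reused
#' (it must have been recorded at the same threshold).
#'
#' @param snap a \code{\link{SnapshotSeries}}.
#' @param threshold mV (default -60, the analysis threshold; -55 selects
#'   the ACh-release threshold used for comparison with calcium imaging).
#' @param margin boundary margin in cells (default 5).
#' @return an \code{activityMask}: list with \code{mask} (raw array
#'   nx x ny x nt), \code{times}, \code{gridN}, \code{domainLength},
#'   \code{threshold}, \code{margin}.
#' @export
thresholdActivity <- function(snap, threshold = -60, margin = 5) {
  stopifnot(is(snap, "SnapshotSeries"))
  nx <- snap@gridN[1]; ny <- snap@gridN[2]
  if (margin >= min(nx, ny) / 2)
    stop("margin must be smaller than half the grid")
  if (length(snap@activity)) {
    thr <- snap@metadata$activityThreshold
    if (!is.null(thr) && abs(thr - threshold) > 1e-9)
      stop(sprintf(
        "series was recorded with activity threshold %g mV, not %g mV", thr,
        threshold))
    m <- array(as.integer(snap@activity), c(nx, ny, length(snap@times)))
    times <- snap@times
  } else {
    if (is.null(snap@fields$v)) stop("series has no voltage field")
    m <- array(0L, dim(snap@fields$v))
    m[snap@fields$v > threshold] <- 1L
    times <- snap@coarseTimes
  }
  if (margin > 0) {
    m[seq_len(margin), , ] <- 0L
    m[(nx - margin + 1):nx, , ] <- 0L
    if (ny > 1) {
      m[, seq_len(margin), ] <- 0L
      m[, (ny - margin + 1):ny, ] <- 0L
    }
  }
  structure(list(mask = as.raw(m), times = times, gridN = c(nx, ny),
                 domainLength = snap@domainLength,
                 threshold = threshold, margin = margin),
            class = "activityMask")
}

#' Label spatiotemporal waves
#'
#' Assigns a common wave id to all active points connected through spatial
#' adjacency within a snapshot (4-neighbourhood by default) or through
#' same-cell/adjacent-cell overlap between consecutive snapshots. Every
#' active entry belongs to exactly one wave. Waves with more than one
#' onset cluster (sets of active points with no active predecessor) are
#' flagged as collisions.
#'
#' @param mask an \code{activityMask} from \code{\link{thresholdActivity}}.
#' @param neighbourhood 4 (default) or 8.
#' @return a data.frame (one row per wave): \code{wave}, \code{t0},
#'   \code{t1}, \code{durationS}, \code{sizeCells} (distinct cells),
#'   \code{sizeMm2}, \code{activeEntries}, \code{nOnsets},
#'   \code{collision}, plus attributes \code{voxels} (active-entry table)
#'   and \code{mask} parameters for downstream estimators.
#' @export
labelWaves <- function(mask, neighbourhood = 4) {
  stopifnot(inherits(mask, "activityMask"), neighbourhood %in% c(4, 8))
  nx <- mask$gridN[1]; ny <- mask$gridN[2]
  nt <- length(mask$times)
  lab <- cpp_label_waves(mask$mask, nx, ny, nt, neighbourhood == 8)
  if (lab$nWaves == 0) {
    out <- data.frame(wave = integer(0), t0 = numeric(0), t1 = numeric(0),
                      durationS = numeric(0), sizeCells = integer(0),
                      sizeMm2 = numeric(0), activeEntries = integer(0),
                      nOnsets = integer(0), collision = logical(0))
    attr(out, "voxels") <- data.frame(cell = integer(0), frame = integer(0),
                                      wave = integer(0), onset = integer(0))
    attr(out, "geometry") <- mask[c("gridN", "domainLength", "times", "margin")]
    return(out)
  }
  vox <- data.frame(cell = lab$cell, frame = lab$frame, wave = lab$wave,
                    onset = lab$onset)
  dxArea <- (mask$domainLength / nx)^2
  f <- split(seq_len(nrow(vox)), vox$wave)
  t0 <- t1 <- sizeC <- entries <- nOn <- numeric(length(f))
  for (i in seq_along(f)) {
    idx <- f[[i]]
    fr <- vox$frame[idx]
    t0[i] <- mask$times[min(fr)]
    t1[i] <- mask$times[max(fr)]
    sizeC[i] <- length(unique(vox$cell[idx]))
    entries[i] <- length(idx)
    nOn[i] <- countOnsetClusters(vox$cell[idx][vox$onset[idx] == 1],
                                 vox$frame[idx][vox$onset[idx] == 1], nx)
  }
  out <- data.frame(wave = as.integer(names(f)), t0 = t0, t1 = t1,
                    durationS = t1 - t0, sizeCells = as.integer(sizeC),
                    sizeMm2 = sizeC * dxArea,
                    activeEntries = as.integer(entries),
                    nOnsets = as.integer(nOn), collision = nOn > 1)
  attr(out, "voxels") <- vox
  attr(out, "geometry") <- mask[c("gridN", "domainLength", "times", "margin")]
  out
}

# cluster onset voxels of one wave: spatial 4-adjacency, frames within 1
countOnsetClusters <- function(cells, frames, nx) {
  n <- length(cells)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  x <- (cells - 1) %% nx
  y <- (cells - 1) %/% nx
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(frames[i] - frames[j]) <= 1 &&
        abs(x[i] - x[j]) + abs(y[i] - y[j]) <= 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

#' Wave-front speed by backward tracing
#'
#' Reconstructs the wave-front trajectory of a non-collision wave: starting
#' from the active point most distal from the initiation centroid at the
#' last active snapshot, repeatedly steps backward in time by \code{step}
#' seconds to the nearest active point of the same wave, producing a
#' polyline from termination back to initiation. The mean speed is the
#' path length divided by the wave duration; the maximum front speed is the
#' largest single-segment speed. Waves smaller than \code{minCells}, shorter
#' than \code{minDuration}, or flagged as collisions are excluded.
#'
#' @param waves the wave table from \code{\link{labelWaves}}.
#' @param step backward step, s (default 0.5).
#' @param minCells,minDuration exclusion filters (defaults 50 cells, 1 s).
#' @param collisionPolicy \code{"exclude"} (default) omits collision waves
#'   from speed estimates, as their initiation point is ambiguous;
#'   \code{"primaryOnset"} traces them anyway from the earliest onset
#'   cluster (useful when nearly every large wave has absorbed a secondary
#'   onset).
#' @return the wave table with added columns \code{meanSpeed},
#'   \code{maxFrontSpeed} (mm/s; NA for excluded waves) and
#'   \code{excludedReason} (\code{""}, \code{"collision"}, \code{"small"},
#'   \code{"short"}).
#' @export
waveSpeed <- function(waves, step = 0.5, minCells = 50, minDuration = 1,
                      collisionPolicy = c("exclude", "primaryOnset")) {
  collisionPolicy <- match.arg(collisionPolicy)
  vox <- attr(waves, "voxels")
  geo <- attr(waves, "geometry")
  if (is.null(vox) || is.null(geo))
    stop("wave table lacks voxel attributes; use the output of labelWaves()")
  nx <- geo$gridN[1]
  dx <- geo$domainLength / nx
  waves$meanSpeed <- NA_real_
  waves$maxFrontSpeed <- NA_real_
  waves$excludedReason <- ""
  if (collisionPolicy == "exclude")
    waves$excludedReason[waves$collision] <- "collision"
  free <- waves$excludedReason == ""
  waves$excludedReason[free & waves$sizeCells < minCells] <- "small"
  waves$excludedReason[free & waves$sizeCells >= minCells &
                         waves$durationS < minDuration] <- "short"
  todo <- which(waves$excludedReason == "")
  if (!length(todo)) return(waves)
  bywave <- split(seq_len(nrow(vox)), vox$wave)
  for (i in todo) {
    idx <- bywave[[as.character(waves$wave[i])]]
    cells <- vox$cell[idx]; frames <- vox$frame[idx]
    x <- ((cells - 1) %% nx) * dx
    y <- ((cells - 1) %/% nx) * dx
    tt <- geo$times[frames]
    onset <- vox$onset[idx] == 1 & frames == min(frames)
    cx <- mean(x[onset]); cy <- mean(y[onset])
    # most distal active point at the last active time
    lastT <- max(tt)
    atEnd <- which(tt == lastT)
    d2 <- (x[atEnd] - cx)^2 + (y[atEnd] - cy)^2
    cur <- atEnd[which.max(d2)]
    path <- c(x[cur], y[cur])
    curT <- lastT
    totalLen <- 0
    maxSeg <- 0
    while (curT - step >= min(tt) - 1e-9) {
      tPrev <- curT - step
      # active points at the snapshot nearest to tPrev
      dts <- abs(tt - tPrev)
      sel <- which(dts == min(dts))
      if (!length(sel)) break
      dd <- sqrt((x[sel] - path[1])^2 + (y[sel] - path[2])^2)
      j <- sel[which.min(dd)]
      seg <- dd[which.min(dd)]
      totalLen <- totalLen + seg
      maxSeg <- max(maxSeg, seg / step)
      path <- c(x[j], y[j])
      curT <- tPrev
    }
    dur <- waves$durationS[i]
    if (dur > 0) {
      waves$meanSpeed[i] <- totalLen / dur
      waves$maxFrontSpeed[i] <- maxSeg
    }
  }
  waves
}

#' Per-cell inter-wave intervals
#'
#' For every interior lattice cell, records upward crossings of the
#' activity threshold and pools the intervals between successive
#' crossings. Crossings closer than \code{minIwi} to the previous accepted
#' crossing are merged (a minimum inter-wave interval is imposed).
#'
#' @param mask an \code{activityMask}.
#' @param minIwi minimum interval, s (default 2).
#' @return data.frame with \code{interval} (s) and \code{cell}.
#' @export
interwaveIntervals <- function(mask, minIwi = 2) {
  stopifnot(inherits(mask, "activityMask"))
  res <- cpp_interwave_intervals(mask$mask, prod(mask$gridN),
                                 length(mask$times), mask$times, minIwi)
  data.frame(interval = res$interval, cell = res$cell)
}

#' Correlation of activity versus distance
#'
#' Pearson correlation between the time series of a reference cell (the
#' domain centre by default) and every other interior cell, as a function
#' of the Euclidean distance between the cells, with a local-regression
#' (loess) mean curve and a +/-1 SD dispersion band.
#'
#' @param snap a \code{\link{SnapshotSeries}} (full fields; for activity-
#'   mode series the coarse fields are used).
#' @param variable one of \code{"v"}, \code{"r"}, \code{"s"}, \code{"a"}.
#' @param reference cell index (1-based) or NULL for the domain centre.
#' @param span loess span (default 0.3).
#' @param margin boundary margin excluded from the correlation, cells.
#' @return list of class \code{correlationCurve}: \code{distance} (mm),
#'   \code{correlation}, \code{curve} (data.frame distance, mean, sd),
#'   \code{variable}.
#' @export
correlationVsDistance <- function(snap, variable = c("v", "r", "s", "a"),
                                  reference = NULL, span = 0.3, margin = 5) {
  stopifnot(is(snap, "SnapshotSeries"))
  variable <- match.arg(variable)
  f <- snap@fields[[variable]]
  if (is.null(f)) stop("field not recorded: ", variable)
  d <- dim(f)
  nx <- d[1]; ny <- d[2]; nt <- d[3]
  if (nt < 100)
    warning("fewer than 100 snapshots; correlation estimates will be noisy")
  dx <- snap@domainLength / nx
  if (is.null(reference)) reference <- (ny %/% 2) * nx + nx %/% 2 + 1
  m <- matrix(f, nx * ny, nt)
  keep <- interiorCells(nx, ny, margin)
  ref <- m[reference, ]
  if (sd(ref) == 0) stop("reference cell has zero variance")
  sds <- apply(m[keep, , drop = FALSE], 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance series dropped")
    keep <- keep[sds > 0]
  }
  cc <- suppressWarnings(as.vector(cor(t(m[keep, , drop = FALSE]), ref)))
  rx <- (reference - 1) %% nx; ry <- (reference - 1) %/% nx
  kx <- (keep - 1) %% nx; ky <- (keep - 1) %/% nx
  dist <- sqrt((kx - rx)^2 + (ky - ry)^2) * dx
  ok <- is.finite(cc)
  dist <- dist[ok]; cc <- cc[ok]
  o <- order(dist)
  lo <- loess(cc[o] ~ dist[o], span = span, degree = 1)
  grid <- seq(0, max(dist), length.out = 80)
  mu <- predict(lo, newdata = grid)
  resid <- cc[o] - predict(lo)
  sdBand <- sapply(grid, function(g) {
    w <- abs(dist[o] - g) <= max(dist) * span / 2
    if (sum(w) > 2) sd(resid[w]) else NA_real_
  })
  structure(list(distance = dist, correlation = cc,
                 curve = data.frame(distance = grid, mean = mu, sd = sdBand),
                 variable = variable),
            class = "correlationCurve")
}

interiorCells <- function(nx, ny, margin) {
  x <- (seq_len(nx * ny) - 1) %% nx
  y <- (seq_len(nx * ny) - 1) %/% nx
  which(x >= margin & x < nx - margin &
          (ny == 1 | (y >= margin & y < ny - margin)))
}

#' Exponential decay length of a correlation curve
#'
#' Fits log(correlation) ~ distance over the positive part of the loess
#' mean curve; the negative reciprocal slope is the decay length.
#'
#' @param curve a \code{correlationCurve}.
#' @return decay length, mm.
#' @export
correlationDecayLength <- function(curve) {
  cv <- curve$curve
  ok <- is.finite(cv$mean) & cv$mean > 0.02 & cv$distance > 0
  if (sum(ok) < 4) return(NA_real_)
  fit <- lm(log(cv$mean[ok]) ~ cv$distance[ok])
  -1 / coef(fit)[[2]]
}

#' Fit a power law to wave sizes
#'
#' Logarithmically bins the size sample, fits a least-squares line to
#' log-density versus log-size over the fitting range, and cross-checks
#' with the continuous maximum-likelihood (Hill) exponent estimate. A
#' curvature diagnostic (quadratic term of a second fit) flags samples
#' whose log-log density is convex, as for exponentially distributed
#' (sub-critical) sizes.
#'
#' @param sizes numeric vector of event sizes (>= 1); at least 50 values.
#' @param xmin lower end of the fitting range (default 1).
#' @param xmax upper end (default the 99.5 percentile).
#' @param nbins number of logarithmic bins (default 16).
#' @return list of class \code{powerlawFit}: \code{slope} (log-log density
#'   slope; a pure power law x^-tau gives slope -tau), \code{intercept},
#'   \code{slopeSE}, \code{mleExponent}, \code{curvature},
#'   \code{curvatureSE}, \code{curved} (logical diagnostic), \code{bins}.
#' @export
fitPowerLaw <- function(sizes, xmin = 1, xmax = NULL, nbins = 16) {
  sizes <- sizes[is.finite(sizes) & sizes >= 1]
  if (length(sizes) < 50) stop("need at least 50 sizes for a power-law fit")
  if (length(unique(sizes)) < 3) stop("degenerate size sample")
  if (is.null(xmax)) xmax <- quantile(sizes, 0.995)
  if (xmax <= xmin * 2) xmax <- max(sizes)
  binned <- function(hi, nb) {
    br <- exp(seq(log(xmin), log(hi * 1.0001), length.out = nb + 1))
    h <- hist(sizes[sizes >= xmin & sizes <= hi], breaks = br, plot = FALSE)
    dens <- h$counts / diff(br) / length(sizes)
    mid <- sqrt(br[-1] * br[-length(br)])
    ok <- dens > 0
    list(lx = log(mid[ok]), ly = log(dens[ok]), mid = mid, dens = dens)
  }
  b <- binned(xmax, nbins)
  if (length(b$lx) < 4) stop("degenerate size sample: too few occupied bins")
  fit <- lm(b$ly ~ b$lx)
  # curvature diagnostic over the full range, where an exponential cutoff
  # (sub-critical decay) bends the log-log density downward
  bFull <- binned(max(sizes), nbins)
  quad <- lm(bFull$ly ~ bFull$lx + I(bFull$lx^2))
  curv <- coef(summary(quad))[3, ]
  lx <- b$lx; ly <- b$ly; mid <- b$mid; dens <- b$dens; ok <- dens > 0
  mle <- 1 + length(sizes[sizes >= xmin]) /
    sum(log(sizes[sizes >= xmin] / (xmin - 0.5 + 1e-9)))
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    slopeSE = coef(summary(fit))[2, 2],
    mleExponent = mle,
    curvature = unname(curv[1]),
    curvatureSE = unname(curv[2]),
    curved = is.finite(curv[1]) && curv[1] < 0 &&
      abs(curv[1]) > 3 * curv[2] && abs(curv[1]) > 0.15,
    bins = data.frame(size = mid, density = dens)),
    class = "powerlawFit")
}

#' Summary statistics of a simulation in the style of the headline figures
#'
#' Runs the full analysis pipeline on a snapshot series: thresholding,
#' labelling, speed estimation, and inter-wave intervals, returning the
#' summary means and the per-wave table.
#'
#' @param snap a \code{\link{SnapshotSeries}} recorded in activity mode (or
#'   full mode).
#' @param threshold,margin see \code{\link{thresholdActivity}}.
#' @param minIwi minimum IWI, s.
#' @param speedStep backward-tracing step, s.
#' @return list: \code{waves} (table with speeds), \code{iwi},
#'   \code{summary} (data.frame of mean/sd for size mm2, duration s, speed
#'   mm/s, IWI s), \code{globalInitiationInterval} (s; mean interval
#'   between onsets of distinct non-blip waves, sizes >= 2 cells),
#'   \code{waveInitiationInterval} (s; waves >= 50 cells).
#' @export
waveStatistics <- function(snap, threshold = -60, margin = 5, minIwi = 2,
                           speedStep = 0.5) {
  mask <- thresholdActivity(snap, threshold, margin)
  waves <- labelWaves(mask)
  waves <- waveSpeed(waves, step = speedStep)
  if (!any(is.finite(waves$meanSpeed)) &&
      any(waves$collision & waves$sizeCells >= 50)) {
    # every large wave absorbed a secondary onset; trace from the primary
    waves <- waveSpeed(waves, step = speedStep,
                       collisionPolicy = "primaryOnset")
    attr(waves, "speedPolicy") <- "primaryOnset"
  }
  iwi <- interwaveIntervals(mask, minIwi)
  span <- diff(range(mask$times))
  sp <- waves$meanSpeed[!is.na(waves$meanSpeed)]
  multi <- waves$sizeCells >= 2
  big <- waves$sizeCells >= 50
  summary <- data.frame(
    statistic = c("waveSizeMm2", "waveDurationS", "waveSpeedMmS", "iwiS"),
    mean = c(mean(waves$sizeMm2), mean(waves$durationS),
             if (length(sp)) mean(sp) else NA_real_,
             if (nrow(iwi)) mean(iwi$interval) else NA_real_),
    sd = c(sd(waves$sizeMm2), sd(waves$durationS),
           if (length(sp) > 1) sd(sp) else NA_real_,
           if (nrow(iwi) > 1) sd(iwi$interval) else NA_real_),
    n = c(nrow(waves), nrow(waves), length(sp), nrow(iwi)))
  list(waves = waves, iwi = iwi, summary = summary,
       globalInitiationInterval = if (sum(multi)) span / sum(multi) else NA_real_,
       waveInitiationInterval = if (sum(big)) span / sum(big) else NA_real_)
}

#' Export a wave table to CSV
#'
#' @param waves wave table from \code{\link{waveSpeed}} (or
#'   \code{\link{labelWaves}}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeWaveTable <- function(waves, path) {
  cols <- intersect(c("wave", "t0", "t1", "sizeCells", "sizeMm2", "durationS",
                      "meanSpeed", "maxFrontSpeed", "nOnsets", "collision",
                      "excludedReason"), names(waves))
  write.csv(waves[, cols], path, row.names = FALSE)
  invisible(path)
}
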