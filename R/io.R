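# Snapshot-container IO and run manifests.
#
# Containers are written as versioned RDS files with an explicit schema
# (named fields, times, geometry, metadata incl. the full parameter
# registry and seed), so a write -> read round trip is lossless.

.containerSchema <- "sacwave-snapshots-v1"

#' Write a snapshot series container
#'
#' Serialises a \code{\link{SnapshotSeries}} plus a run manifest (schema
#' version, parameter registry values, configuration, seed, package
#' version, timestamp) to a single container file.
#'
#' @param snap a \code{\link{SnapshotSeries}}.
#' @param path output path (conventionally \code{.rds}).
#' @return \code{path}, invisibly.
#' @export
writeSnapshotSeries <- function(snap, path) {
  stopifnot(is(snap, "SnapshotSeries"))
  payload <- list(
    schema = .containerSchema,
    times = snap@times,
    fields = snap@fields,
    activity = snap@activity,
    coarseTimes = snap@coarseTimes,
    gridN = snap@gridN,
    domainLength = snap@domainLength,
    metadata = snap@metadata,
    manifest = runManifest(snap))
  saveRDS(payload, path)
  invisible(path)
}

#' Read a snapshot series container
#'
#' @param path container path written by \code{\link{writeSnapshotSeries}}.
#' @return a \code{\link{SnapshotSeries}}.
#' @export
readSnapshotSeries <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable container: ", path, " (", conditionMessage(e), ")"))
  if (!identical(payload$schema, .containerSchema))
    stop("unsupported container schema: ",
         if (is.null(payload$schema)) "<missing>" else payload$schema,
         " (expected ", .containerSchema, ")")
  new("SnapshotSeries", times = payload$times, fields = payload$fields,
      activity = payload$activity, coarseTimes = payload$coarseTimes,
      gridN = payload$gridN, domainLength = payload$domainLength,
      metadata = payload$metadata)
}

#' Run manifest of a snapshot series
#'
#' Reproducibility metadata attached to every container: a digest of the
#' parameter registry, the configuration, the seed, the package version
#' and a timestamp. Identical parameter/config/seed triples produce
#' identical simulation output.
#'
#' @param snap a \code{\link{SnapshotSeries}}.
#' @return named list.
#' @export
runManifest <- function(snap) {
  md <- snap@metadata
  pv <- if (!is.null(md$params)) asParamVector(md$params) else numeric(0)
  list(schema = .containerSchema,
       paramDigest = paste(sprintf("%.17g", pv), collapse = ","),
       seed = md$seed,
       package = md$package,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
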