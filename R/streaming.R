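# Acquisition-to-reconstruction bridge. A polling watcher emits one event
# per new projection file whose size is stable across two polls (a
# write-completion guard). The live pipeline appends projections to a
# running reconstruction without restarting it, and publishes consistent
# intermediate snapshots under a triple-buffer contract: one working copy on
# the solver, one published copy for consumers, and a transient staging copy
# during the handoff - never more than three full-volume copies.

#' Create a polling directory watcher
#'
#' @param dir directory to watch (must exist)
#' @param pattern filename glob for projection images (default "*.tif*")
#' @return a watcher object for \code{\link{pollEvents}}
#' @export
directoryWatcher <- function(dir, pattern = "*.tif*") {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  w <- new.env(parent = emptyenv())
  w$dir <- dir
  w$regex <- utils::glob2rx(pattern)
  w$prevSizes <- numeric(0)
  w$emitted <- character(0)
  w$seq <- 0L
  class(w) <- "directoryWatcher"
  w
}

.sidecarAngles <- function(dir) {
  tlt <- sort(list.files(dir, pattern = "\\.(tlt|rawtlt)$",
                         full.names = TRUE))
  if (!length(tlt)) return(NULL)
  tryCatch(readAngleFile(tlt[1L]), error = function(e) NULL)
}

.eventAngle <- function(fname, sidecar) {
  if (!is.null(sidecar)) {
    # sequence prefix (first integer token) indexes into the sidecar list
    m <- regmatches(basename(fname), regexpr("[0-9]+", basename(fname)))
    if (length(m)) {
      idx <- as.integer(m)
      if (!is.na(idx) && idx >= 1L && idx <= length(sidecar))
        return(sidecar[idx])
    }
  }
  .parseAngleToken(fname)
}

#' Poll a watcher once
#'
#' Emits one event per new file matching the pattern whose size is unchanged
#' since the previous poll (so partially written files are never ingested).
#' Each file is emitted exactly once. The tilt angle comes from a sidecar
#' angle list (indexed by the filename's sequence prefix) if one is present,
#' else from the last signed decimal token in the filename; files with
#' unparseable angles are skipped with a warning.
#'
#' @param w a watcher from \code{\link{directoryWatcher}}
#' @return list of events, each a list(path, angleDeg, sequenceIndex,
#'   observedAt)
#' @export
pollEvents <- function(w) {
  files <- list.files(w$dir, pattern = w$regex, full.names = TRUE)
  files <- files[!grepl("\\.json$", files)] # never ingest metadata sidecars
  sizes <- file.size(files)
  names(sizes) <- files
  sidecar <- .sidecarAngles(w$dir)
  events <- list()
  for (f in setdiff(files, w$emitted)) {
    if (!is.na(w$prevSizes[f]) && w$prevSizes[f] == sizes[[f]]) {
      ang <- .eventAngle(f, sidecar)
      w$emitted <- c(w$emitted, f)
      if (is.na(ang) || abs(ang) > 90) {
        warning("skipping ", basename(f), ": unparseable tilt angle")
        next
      }
      w$seq <- w$seq + 1L
      events[[length(events) + 1L]] <- list(
        path = f, angleDeg = ang, sequenceIndex = w$seq,
        observedAt = Sys.time())
    }
  }
  w$prevSizes <- sizes
  events
}

#' Watch a directory until a stop condition, collecting events
#'
#' Polls every \code{pollIntervalS} seconds until either \code{nFiles}
#' events have been emitted or \code{quietPolls} consecutive polls produce
#' none (with no unstable files pending).
#'
#' @param dir directory to watch
#' @param pattern filename glob
#' @param pollIntervalS poll interval in seconds
#' @param nFiles stop once this many events were emitted (NULL: quiet-stop)
#' @param quietPolls consecutive empty polls that end a quiet-stop watch
#' @param maxPolls hard poll limit
#' @return ordered list of acquisition events
#' @export
watchDirectory <- function(dir, pattern = "*.tif*", pollIntervalS = 1,
                           nFiles = NULL, quietPolls = 3L, maxPolls = 10000L) {
  w <- directoryWatcher(dir, pattern)
  events <- list()
  quiet <- 0L
  for (p in seq_len(maxPolls)) {
    ev <- pollEvents(w)
    events <- c(events, ev)
    quiet <- if (length(ev)) 0L else quiet + 1L
    if (!is.null(nFiles) && length(events) >= nFiles) break
    if (is.null(nFiles) && quiet >= quietPolls && p > 1L) break
    if (pollIntervalS > 0) Sys.sleep(pollIntervalS)
  }
  events
}

# ------------------------------------------------------------- LivePipeline

LivePipeline <- setRefClass("LivePipeline",
  fields = list(
    dir = "character",
    pattern = "character",
    config = "SolverConfig",
    sliceShape = "integer",
    watcher = "ANY",
    series = "ANY",      # TiltSeries or NULL
    state = "ANY",       # ReconState or NULL
    published = "ANY",   # array copy or NULL
    publishedIter = "integer",
    publishedResidual = "numeric",
    publishedNproj = "integer",
    copyCount = "integer",
    peakCopies = "integer",
    snapshotLog = "data.frame",
    snapshotAngles = "list",
    dirty = "logical"
  )
)

#' Create a live reconstruction pipeline over a watched directory
#'
#' @param dir directory acquisition writes into
#' @param config a \linkS4class{SolverConfig}
#' @param pattern filename glob for projection images
#' @param sliceShape integer (n_x, n_z) of the reconstruction slice; NULL
#'   defaults to (n_x, n_x) of the first ingested projection
#' @return a LivePipeline reference object
#' @export
livePipeline <- function(dir, config, pattern = "*.tif*",
                         sliceShape = NULL) {
  LivePipeline$new(
    dir = dir, pattern = pattern, config = config,
    sliceShape = if (is.null(sliceShape)) integer(0)
                 else as.integer(sliceShape),
    watcher = directoryWatcher(dir, pattern),
    series = NULL, state = NULL, published = NULL,
    publishedIter = 0L, publishedResidual = NA_real_, publishedNproj = 0L,
    copyCount = 1L, peakCopies = 1L,
    snapshotLog = data.frame(iteration = integer(0),
                             n_projections = integer(0),
                             normalized_residual = numeric(0)),
    snapshotAngles = list(), dirty = FALSE)
}

.readProjection <- function(path) {
  r <- .readScaledTiff(path)
  list(img = r$pages[[1L]],
       pixelSizeNm = if (!is.null(r$meta$pixel_size_nm))
         r$meta$pixel_size_nm else 1)
}

#' Ingest one acquisition event into a live pipeline
#'
#' The projection is inserted into the growing series in angle order. An
#' angle already present is replaced (re-acquisition semantics, latest
#' wins). For iterative algorithms the reconstruction state is extended -
#' warm start retained, Lipschitz constant re-estimated, step rescaled - so
#' the solver resumes without resetting its iterate.
#'
#' @param pipeline a \code{\link{livePipeline}}
#' @param event an event from \code{\link{pollEvents}}
#' @return the pipeline, invisibly
#' @export
ingest <- function(pipeline, event) {
  pr <- .readProjection(event$path)
  img <- pr$img
  if (is.null(pipeline$series)) {
    dat <- array(img, c(1L, dim(img)))
    pipeline$series <- tiltSeries(dat, event$angleDeg,
                                  pixelSizeNm = pr$pixelSizeNm)
    if (!length(pipeline$sliceShape))
      pipeline$sliceShape <- c(dim(img)[2L], dim(img)[2L])
  } else {
    d <- dim(pipeline$series@data)
    if (!identical(dim(img), d[2:3]))
      stop("ingest error: projection shape ", paste(dim(img), collapse = "x"),
           " does not match series ", paste(d[2:3], collapse = "x"))
    angles <- pipeline$series@anglesDeg
    hit <- which(abs(angles - event$angleDeg) <= .ANGLE_TOL)
    if (length(hit)) {
      message("replacing projection at ", event$angleDeg,
              " deg (re-acquisition)")
      dat <- pipeline$series@data
      dat[hit[1L], , ] <- img
      pipeline$series <- tiltSeries(dat, angles,
                                    pixelSizeNm = pipeline$series@pixelSizeNm)
    } else {
      dat <- array(0, c(d[1L] + 1L, d[2:3]))
      dat[seq_len(d[1L]), , ] <- pipeline$series@data
      dat[d[1L] + 1L, , ] <- img
      pipeline$series <- tiltSeries(dat, c(angles, event$angleDeg),
                                    pixelSizeNm = pipeline$series@pixelSizeNm)
      if (!is.null(pipeline$state))
        pipeline$state <- extendState(pipeline$state, pipeline$series)
    }
  }
  pipeline$dirty <- TRUE
  invisible(pipeline)
}

# Run n solver iterations on the pipeline's current series.
.pipelineIterate <- function(pipeline, n) {
  if (is.null(pipeline$series)) return(invisible(pipeline))
  cfg <- pipeline$config
  if (cfg@algorithm == "wbp") {
    vol <- wbp(pipeline$series, cfg, sliceShape = pipeline$sliceShape)
    if (is.null(pipeline$state)) {
      pipeline$state <- new("ReconState", x = vol, iteration = 0L,
        nProjectionsUsed = nAngles(pipeline$series),
        anglesDeg = pipeline$series@anglesDeg, lipschitzL = 1,
        stepSize = 1, stepSafety = 1, residualHistory = numeric(0),
        tvHistory = numeric(0), nprojHistory = integer(0),
        powerVec = numeric(0), config = cfg)
    } else {
      pipeline$state@x <- vol
      pipeline$state@anglesDeg <- pipeline$series@anglesDeg
      pipeline$state@nProjectionsUsed <- nAngles(pipeline$series)
    }
    pipeline$dirty <- FALSE
    return(invisible(pipeline))
  }
  stepCfg <- cfg
  stepCfg@maxIters <- as.integer(n)
  run <- if (cfg@algorithm == "tvmin") tvminRun else sirtRun
  pipeline$state <- run(pipeline$series, stepCfg, pipeline$state,
                        sliceShape = pipeline$sliceShape)
  pipeline$dirty <- FALSE
  invisible(pipeline)
}

# Publish the working volume: make a staging copy at an iteration boundary
# (transiently the third full-volume copy, alongside the working copy and
# the previously published one), then swap it in as the published copy.
.pipelinePublish <- function(pipeline) {
  if (is.null(pipeline$state)) return(invisible(pipeline))
  staging <- pipeline$state@x@data + 0 # deep copy
  pipeline$copyCount <- 1L + (!is.null(pipeline$published)) + 1L
  pipeline$peakCopies <- max(pipeline$peakCopies, pipeline$copyCount)
  pipeline$published <- staging
  pipeline$copyCount <- 2L
  it <- pipeline$state@iteration
  res <- if (it > 0L) pipeline$state@residualHistory[it]
         else normalizedResidual(pipeline$state@x, pipeline$series)
  pipeline$publishedIter <- it
  pipeline$publishedResidual <- res
  pipeline$publishedNproj <- pipeline$state@nProjectionsUsed
  pipeline$snapshotLog <- rbind(pipeline$snapshotLog,
    data.frame(iteration = it,
               n_projections = pipeline$state@nProjectionsUsed,
               normalized_residual = res))
  pipeline$snapshotAngles[[nrow(pipeline$snapshotLog)]] <-
    pipeline$state@anglesDeg
  invisible(pipeline)
}

#' Advance a live pipeline by n solver iterations and publish a snapshot
#'
#' Runs \code{n} iterations of the configured algorithm on the projections
#' ingested so far (for WBP: one full slice-ordered recomputation), then
#' publishes the result through the staging copy. No-op before any
#' projection has arrived.
#'
#' @param pipeline a \code{\link{livePipeline}}
#' @param n iterations to run (default: the config's updateEvery)
#' @return the pipeline, invisibly
#' @export
advancePipeline <- function(pipeline, n = pipeline$config@updateEvery) {
  if (is.null(pipeline$series)) return(invisible(pipeline))
  .pipelineIterate(pipeline, n)
  .pipelinePublish(pipeline)
  invisible(pipeline)
}

#' Take a consistent snapshot of the live reconstruction
#'
#' Returns the most recently published volume - always a complete iteration
#' boundary, never a partially updated iterate - together with its iteration
#' number and recorded normalized residual. Before the first publication the
#' zero initial volume at iteration 0 is returned. Taking a snapshot copies
#' nothing (the published buffer is already a copy), so it never blocks the
#' solver beyond the one staging copy made at publication.
#'
#' @param pipeline a \code{\link{livePipeline}}
#' @return list(volume = \linkS4class{Tomogram}, iteration, residual)
#' @export
snapshot <- function(pipeline) {
  if (is.null(pipeline$published)) {
    shape <- if (length(pipeline$sliceShape) && !is.null(pipeline$series))
      c(dim(pipeline$series@data)[2L], pipeline$sliceShape)
    else c(1L, 1L, 1L)
    return(list(volume = tomogram(array(0, shape), provenance = "initial"),
                iteration = 0L, residual = NA_real_))
  }
  ps <- if (!is.null(pipeline$series)) pipeline$series@pixelSizeNm else 1
  list(volume = tomogram(pipeline$published, voxelSizeNm = ps,
         provenance = sprintf("%s snapshot iter %d",
                              pipeline$config@algorithm,
                              pipeline$publishedIter)),
       iteration = pipeline$publishedIter,
       residual = pipeline$publishedResidual)
}

#' Run a live reconstruction over a watched directory
#'
#' Orchestrates watch, ingest and iterate: every poll, new stable files are
#' ingested (extending the running state), then \code{updateEvery}
#' iterations run and a snapshot is published. Once \code{nFilesExpected}
#' events have been seen, \code{extraIters} further iterations run (in
#' \code{updateEvery} chunks, each published). For WBP the final
#' recomputation publishes slice by slice in increasing y.
#'
#' @param dir watched directory
#' @param config a \linkS4class{SolverConfig}
#' @param nFilesExpected total projection files the acquisition will write
#' @param extraIters iterations to run after the last arrival (iterative
#'   algorithms)
#' @param pollIntervalS poll interval in seconds
#' @param pattern filename glob
#' @param sliceShape optional (n_x, n_z)
#' @param maxPolls hard poll limit (watcher error if exceeded)
#' @return the final \linkS4class{ReconState} with the pipeline attached as
#'   attribute "pipeline"
#' @export
runLive <- function(dir, config, nFilesExpected, extraIters = 50L,
                    pollIntervalS = 0.05, pattern = "*.tif*",
                    sliceShape = NULL, maxPolls = 10000L) {
  pipeline <- livePipeline(dir, config, pattern, sliceShape)
  seen <- 0L
  for (p in seq_len(maxPolls)) {
    evs <- pollEvents(pipeline$watcher)
    for (e in evs) ingest(pipeline, e)
    seen <- seen + length(evs)
    if (pipeline$dirty) {
      .pipelineIterate(pipeline, config@updateEvery)
      .pipelinePublish(pipeline)
    }
    if (seen >= nFilesExpected) break
    if (pollIntervalS > 0) Sys.sleep(pollIntervalS)
  }
  if (seen < nFilesExpected)
    stop("watcher error: saw only ", seen, " of ", nFilesExpected,
         " expected files within the poll limit")
  if (config@algorithm == "wbp") {
    # final pass, published slice by slice along y
    vol <- wbp(pipeline$series, config, sliceShape = pipeline$sliceShape,
               sliceCallback = function(y, sl) {
                 if (!is.null(pipeline$state)) {
                   pipeline$state@x@data[y, , ] <- sl
                   .pipelinePublish(pipeline)
                 }
               })
    .pipelineIterate(pipeline, 1L)
    .pipelinePublish(pipeline)
  } else {
    left <- as.integer(extraIters)
    while (left > 0L) {
      n <- min(config@updateEvery, left)
      .pipelineIterate(pipeline, n)
      .pipelinePublish(pipeline)
      left <- left - n
    }
  }
  st <- pipeline$state
  if (is.null(st)) { # degenerate run: nothing arrived, nothing expected
    st <- new("ReconState", x = tomogram(array(0, c(1L, 1L, 1L)),
                provenance = "initial"),
              iteration = 0L, nProjectionsUsed = 0L, anglesDeg = numeric(0),
              lipschitzL = 1, stepSize = 1, stepSafety = 1,
              residualHistory = numeric(0), tvHistory = numeric(0),
              nprojHistory = integer(0), powerVec = numeric(0),
              config = config)
  }
  attr(st, "pipeline") <- pipeline
  st
}
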