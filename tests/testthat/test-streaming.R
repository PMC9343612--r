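emitSmallSeries <- function(dir, size = 16, angles = seq(-40, 40, by = 10)) {
  ph <- makePhantom("spheres", size)
  ser <- simulateSeries(ph, angles)$series
  emitToDirectory(ser, dir)
  ser
}

test_that("the watcher emits one stable event per matching file", {
  d <- freshDir()
  emitSmallSeries(d, angles = c(-10, 0, 10))
  writeLines("notes", file.path(d, "notes.txt"))
  evs <- watchDirectory(d, pollIntervalS = 0, nFiles = 3)
  expect_length(evs, 3)
  expect_equal(sort(vapply(evs, `[[`, numeric(1), "angleDeg")),
               c(-10, 0, 10))
  # sequence indices are unique and ordered
  expect_equal(vapply(evs, `[[`, numeric(1), "sequenceIndex"), 1:3)
})

test_that("files created after watching starts are seen within two polls", {
  d <- freshDir()
  ser <- emitSmallSeries(d, angles = c(-10, 0))
  w <- directoryWatcher(d)
  pollEvents(w) # registers sizes
  expect_length(pollEvents(w), 2)
  # now a new file arrives
  .tomoEnv <- asNamespace("tomostream")
  .tomoEnv$.writeScaledTiff(list(seriesData(ser)[1, , ]),
                            file.path(d, "proj_003_10.00.tif"))
  expect_length(pollEvents(w), 0) # first poll only registers it
  expect_length(pollEvents(w), 1) # stable on the second: emitted
})

test_that("unparseable angles are skipped with a warning, not a crash", {
  d <- freshDir()
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(d, "mystery.tif"))
  w <- directoryWatcher(d)
  pollEvents(w)
  expect_warning(evs <- pollEvents(w), "unparseable")
  expect_length(evs, 0)
})

test_that("no event loss or duplication for a full staggered acquisition", {
  d <- freshDir()
  ph <- makePhantom("spheres", 16)
  ser <- simulateSeries(ph, defaultAngles())$series
  w <- directoryWatcher(d)
  set.seed(8)
  # write the 136 files in random-size chunks between polls
  order <- sample(nAngles(ser))
  written <- 0L
  events <- list()
  while (written < 136L || length(events) < 136L) {
    if (written < 136L) {
      k <- min(sample(1:20, 1), 136L - written)
      idx <- order[(written + 1):(written + k)]
      for (i in idx) {
        sub <- tiltSeries(seriesData(ser)[i, , , drop = FALSE],
                          tiltAngles(ser)[i])
        fn <- sprintf("proj_%03d_%s.tif", i,
                      formatC(tiltAngles(ser)[i], format = "f", digits = 2))
        asNamespace("tomostream")$.writeScaledTiff(
          list(seriesData(ser)[i, , ]), file.path(d, fn))
      }
      written <- written + k
    }
    events <- c(events, pollEvents(w))
  }
  expect_length(events, 136)
  angs <- sort(vapply(events, `[[`, numeric(1), "angleDeg"))
  expect_equal(angs, defaultAngles())
  expect_false(any(duplicated(vapply(events, `[[`, character(1), "path"))))
})

test_that("ingest keeps projections sorted and replaces re-acquired angles", {
  d <- freshDir()
  ser <- emitSmallSeries(d, angles = c(-20, -10, 0, 10, 20))
  pl <- livePipeline(d, solverConfig("sirt", maxIters = 2))
  w <- pl$watcher
  pollEvents(w)
  evs <- pollEvents(w)
  for (e in evs) ingest(pl, e)
  expect_equal(nAngles(pl$series), 5)
  expect_equal(tiltAngles(pl$series), c(-20, -10, 0, 10, 20))
  # re-acquisition: same angle replaces, count unchanged
  e2 <- evs[[2]]
  expect_message(ingest(pl, e2), "re-acquisition")
  expect_equal(nAngles(pl$series), 5)
  # shape mismatch is an ingest error
  bad <- file.path(d, "odd_5.00.tif")
  asNamespace("tomostream")$.writeScaledTiff(list(matrix(0.1, 4, 4)), bad)
  expect_error(ingest(pl, list(path = bad, angleDeg = 5, sequenceIndex = 99,
                               observedAt = Sys.time())),
               "ingest error")
})

test_that("dynamic ingestion matches batch reconstruction at equal totals", {
  ph <- makePhantom("spheres", 16)
  ang <- seq(-60, 60, by = 10)
  ser <- simulateSeries(ph, ang)$series
  total <- 120L
  batch <- sirtRun(ser, solverConfig("sirt", maxIters = total))
  # three arrival batches with 10 iterations after each of the first two
  parts <- list(1:5, 6:9, 10:13)
  state <- NULL
  done <- 0L
  for (p in seq_along(parts)) {
    use <- sort(unlist(parts[1:p]))
    sub <- tiltSeries(seriesData(ser)[use, , , drop = FALSE],
                      tiltAngles(ser)[use])
    if (!is.null(state)) state <- extendState(state, sub)
    n <- if (p < length(parts)) 10L else total - done
    state <- sirtRun(sub, solverConfig("sirt", maxIters = n), state)
    done <- done + n
  }
  expect_equal(state@iteration, total)
  rb <- tail(residualHistory(batch), 1)
  rl <- tail(residualHistory(state), 1)
  expect_lt(abs(rl - rb) / rb, 0.05)
})

test_that("snapshots are iteration-consistent and respect the triple-buffer
           contract", {
  d <- freshDir()
  emitSmallSeries(d)
  st <- suppressMessages(runLive(d,
    solverConfig("sirt", maxIters = 5, updateEvery = 5),
    nFilesExpected = 9, extraIters = 15, pollIntervalS = 0))
  pl <- attr(st, "pipeline")
  # every published snapshot recomputes to its recorded residual
  sn <- snapshot(pl)
  expect_equal(normalizedResidual(sn$volume, pl$series), sn$residual,
               tolerance = 1e-6)
  expect_equal(sn$iteration, st@iteration)
  # no intervening iteration: snapshots are bitwise identical
  sn2 <- snapshot(pl)
  expect_identical(tomoData(sn$volume), tomoData(sn2$volume))
  # peak full-volume copies: working + published + staging = 3
  expect_equal(pl$peakCopies, 3L)
  expect_lte(max(pl$copyCount), 3L)
  # snapshot cadence
  expect_gte(nrow(pl$snapshotLog), floor(st@iteration / 5))
  # a pipeline that never published returns the zero initial volume
  pl0 <- livePipeline(freshDir(), solverConfig("sirt"))
  s0 <- snapshot(pl0)
  expect_equal(s0$iteration, 0L)
  expect_equal(max(abs(tomoData(s0$volume))), 0)
})

test_that("a live run over a replayed acquisition matches direct ingestion", {
  d <- freshDir()
  ang <- seq(-40, 40, by = 10)
  ser <- emitSmallSeries(d, angles = ang)
  st <- suppressMessages(runLive(d,
    solverConfig("sirt", maxIters = 10, updateEvery = 10),
    nFilesExpected = 9, extraIters = 40, pollIntervalS = 0))
  # all projections arrived in one stable batch here, so the live result
  # must equal a batch run with the same iteration count
  batch <- sirtRun(ser, solverConfig("sirt", maxIters = st@iteration))
  # agreement is limited only by the TIFF storage quantization of the
  # replayed projections
  expect_equal(tail(residualHistory(st), 1), tail(residualHistory(batch), 1),
               tolerance = 1e-6)
  # empty directory with a zero-events stop rule: iteration-0 state
  st0 <- runLive(freshDir(), solverConfig("sirt"), nFilesExpected = 0,
                 extraIters = 0, pollIntervalS = 0)
  expect_equal(st0@iteration, 0L)
})
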