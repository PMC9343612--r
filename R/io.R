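# Readers/writers. Two interchange formats are supported for arrays:
#  * TIFF (single or multipage): samples are stored min-max scaled, with the
#    affine scaling (offset, scale) and all metadata recorded in a JSON
#    sidecar "<file>.json"; round trips are exact to ~2^-32 of the range.
#  * raw binary + JSON sidecar: little-endian IEEE floats (float32 on write,
#    per the package-wide 32-bit storage convention; float64 selectable),
#    column-major in the array's native index order. This is the lossless
#    container for volumes and series.
# Text angle lists hold one angle in degrees per non-empty line.

.sidecarPath <- function(path) paste0(path, ".json")

.writeScaledTiff <- function(pages, path, meta = list()) {
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  scale <- hi - lo
  if (scale == 0) scale <- 1
  scaled <- lapply(pages, function(p) (p - lo) / scale)
  tiff::writeTIFF(if (length(scaled) == 1L) scaled[[1L]] else scaled,
                  path, bits.per.sample = 32L)
  meta$offset <- lo
  meta$scale <- scale
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.readScaledTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- .sidecarPath(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
          else list(offset = 0, scale = 1)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L] # tolerate RGB-expanded pages
    p * meta$scale + meta$offset
  })
  list(pages = pages, meta = meta)
}

.float32 <- function(x) {
  # round-trip through IEEE float32 (the on-disk precision of raw writes)
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}

.writeRaw <- function(arr, path, meta, dtype = "float32") {
  size <- switch(dtype, float32 = 4L, float64 = 8L,
                 stop("validation error: unknown dtype ", dtype))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = size, endian = "little")
  meta$shape <- dim(arr)
  meta$dtype <- dtype
  meta$order <- "column-major"
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.readRaw <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("format error: raw binary requires the JSON sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  size <- switch(meta$dtype, float32 = 4L, float64 = 8L,
                 stop("format error: unknown dtype ", meta$dtype))
  n <- prod(meta$shape)
  v <- readBin(path, "double", n = n, size = size, endian = "little")
  if (length(v) != n)
    stop("format error: ", path, " holds ", length(v),
         " values, sidecar shape expects ", n)
  list(data = array(v, meta$shape), meta = meta)
}

.parseAngleToken <- function(fname) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(fname))
  m <- regmatches(base, gregexpr("[-+]?[0-9]+(\\.[0-9]+)?", base))[[1L]]
  if (!length(m)) return(NA_real_)
  as.numeric(m[length(m)])
}

#' Read a text angle list
#'
#' One tilt angle in degrees per non-empty line; order preserved. Trailing
#' blank lines are ignored; an empty file yields an empty list with a
#' warning.
#'
#' @param path text file path
#' @return numeric vector of angles
#' @export
readAngleFile <- function(path) {
  lines <- trimws(readLines(path))
  keep <- which(nzchar(lines))
  if (!length(keep)) {
    warning("empty angle file: ", path)
    return(numeric(0))
  }
  vals <- suppressWarnings(as.numeric(lines[keep]))
  if (anyNA(vals))
    stop("parse error: non-numeric angle at line ", keep[which(is.na(vals))[1L]],
         " of ", path)
  vals
}

#' Write a tilt series to disk
#'
#' \code{tiff}: one multipage TIFF (pages in angle order, min-max scaled)
#' plus a JSON sidecar holding angles, pixel size and the scaling.
#' \code{raw}: little-endian floats in native (n_angles, n_y, n_x)
#' column-major order plus a JSON sidecar.
#'
#' @param series a \linkS4class{TiltSeries}
#' @param path output file path
#' @param format "tiff" or "raw"
#' @param dtype raw storage type, "float32" (default) or "float64"
#' @return the path, invisibly
#' @export
writeSeries <- function(series, path, format = c("tiff", "raw"),
                        dtype = "float32") {
  stopifnot(is(series, "TiltSeries"))
  format <- match.arg(format)
  meta <- list(kind = "tilt_series", angles_deg = series@anglesDeg,
               pixel_size_nm = series@pixelSizeNm,
               is_aligned = series@isAligned)
  if (format == "tiff") {
    n <- nAngles(series)
    pages <- lapply(seq_len(n), function(a) series@data[a, , ])
    .writeScaledTiff(pages, path, meta)
  } else {
    .writeRaw(series@data, path, meta, dtype)
  }
  invisible(path)
}

.seriesFromPages <- function(pages, angles, pixelSizeNm, isAligned, files) {
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("format error: inconsistent image shape in ",
         files[which(shapes != shapes[1L])[1L]])
  d <- dim(pages[[1L]])
  dat <- array(0, c(length(pages), d))
  for (i in seq_along(pages)) dat[i, , ] <- pages[[i]]
  tiltSeries(dat, angles, pixelSizeNm = pixelSizeNm, isAligned = isAligned)
}

.readSeriesDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("format error: no TIFF files in ", dir)
  pages <- list()
  angles <- numeric(0)
  px <- NA_real_
  for (f in files) {
    r <- .readScaledTiff(f)
    ang <- if (!is.null(r$meta$angle_deg)) r$meta$angle_deg
           else .parseAngleToken(f)
    if (is.na(ang)) ang <- NA_real_
    angles <- c(angles, rep(ang, length(r$pages)))
    pages <- c(pages, r$pages)
    if (is.na(px) && !is.null(r$meta$pixel_size_nm))
      px <- r$meta$pixel_size_nm
  }
  if (anyNA(angles)) {
    tlt <- list.files(dir, pattern = "\\.(tlt|rawtlt)$", full.names = TRUE)
    if (length(tlt) == 1L && length(readAngleFile(tlt)) == length(pages))
      angles <- readAngleFile(tlt)
    else
      stop("missing angles: provide angle-encoded filenames or a sidecar ",
           "angle list (.tlt) with one line per image")
  }
  .seriesFromPages(pages, angles, if (is.na(px)) 1 else px, FALSE, files)
}

#' Read a tilt series
#'
#' Accepts a directory of single-image TIFFs (angles from per-file JSON
#' sidecars, filename tokens, or a .tlt angle list), a multipage TIFF with a
#' JSON sidecar, or a raw binary with a JSON sidecar.
#'
#' @param path file or directory path
#' @return a validated \linkS4class{TiltSeries}
#' @export
readSeries <- function(path) {
  if (dir.exists(path)) return(.readSeriesDir(path))
  if (!file.exists(path)) stop("format error: no such path ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    r <- .readScaledTiff(path)
    meta <- r$meta
    if (is.null(meta$angles_deg))
      stop("missing angles: multipage TIFF requires a JSON sidecar with ",
           "an angles_deg list (or load a directory with a .tlt file)")
    return(.seriesFromPages(r$pages, meta$angles_deg,
                            if (is.null(meta$pixel_size_nm)) 1
                            else meta$pixel_size_nm,
                            isTRUE(meta$is_aligned), path))
  }
  r <- .readRaw(path)
  if (!identical(r$meta$kind, "tilt_series"))
    stop("type error: ", path, " holds '", r$meta$kind,
         "', not a tilt series")
  tiltSeries(r$data, r$meta$angles_deg, pixelSizeNm = r$meta$pixel_size_nm,
             isAligned = isTRUE(r$meta$is_aligned))
}

#' Write / read a tomogram (raw binary + JSON sidecar)
#'
#' Volume, voxel size and the provenance string round-trip through a
#' little-endian float binary with a JSON sidecar; bitwise at the stored
#' precision.
#'
#' @param t a \linkS4class{Tomogram}
#' @param path data file path (sidecar is \code{<path>.json})
#' @param dtype "float32" (default) or "float64"
#' @return \code{writeTomogram}: the path invisibly; \code{readTomogram}:
#'   a \linkS4class{Tomogram}
#' @export
writeTomogram <- function(t, path, dtype = "float32") {
  stopifnot(is(t, "Tomogram"))
  .writeRaw(t@data, path,
            list(kind = "tomogram", voxel_size_nm = t@voxelSizeNm,
                 provenance = t@provenance), dtype)
  invisible(path)
}

#' @rdname writeTomogram
#' @export
readTomogram <- function(path) {
  r <- .readRaw(path)
  if (!identical(r$meta$kind, "tomogram"))
    stop("type error: ", path, " holds '", r$meta$kind, "', not a tomogram")
  tomogram(r$data, voxelSizeNm = r$meta$voxel_size_nm,
           provenance = r$meta$provenance)
}

#' Export central orthoslices of a volume as PNGs
#'
#' Writes the central xy, xz and yz slices as 8-bit min-max scaled PNGs
#' (slice_xy.png, slice_xz.png, slice_yz.png) with the scaling recorded in
#' orthoslices.json. A constant volume is written mid-gray with a warning.
#'
#' @param t a \linkS4class{Tomogram}
#' @param dir output directory (created if missing)
#' @return character vector of the three PNG paths
#' @export
exportOrthoslices <- function(t, dir) {
  stopifnot(is(t, "Tomogram"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(t@data)
  mids <- as.integer(ceiling(d / 2))
  slices <- list(xy = t@data[, , mids[3L]],
                 xz = t@data[mids[1L], , ],
                 yz = t@data[, mids[2L], ])
  lo <- min(t@data); hi <- max(t@data)
  if (hi == lo) {
    warning("constant volume: orthoslices written mid-gray")
    slices <- lapply(slices, function(s) array(0.5, dim(s)))
    lo <- 0; hi <- 1
  } else {
    slices <- lapply(slices, function(s) (s - lo) / (hi - lo))
  }
  paths <- character(3)
  for (i in seq_along(slices)) {
    paths[i] <- file.path(dir, sprintf("slice_%s.png", names(slices)[i]))
    png::writePNG(slices[[i]], paths[i])
  }
  jsonlite::write_json(list(offset = lo, scale = hi - lo, shape = d,
                            voxel_size_nm = t@voxelSizeNm),
                       file.path(dir, "orthoslices.json"),
                       auto_unbox = TRUE, digits = NA)
  paths
}
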