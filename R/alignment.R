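# Tilt-series pre-processing: background subtraction, center-of-mass and
# cross-correlation shift estimation, rotation-axis offset location. CoM
# alignment relies on the rigid-body property that the projected center of
# mass of an isolated object traces a circle about the tilt axis, so the
# x-CoM belongs at the detector center and the y-CoM is angle-invariant.

#' Subtract the border-frame background from a projection image
#'
#' Estimates the constant background (e.g., a thin support film) as the mean
#' of the outermost border frame of the image and subtracts it everywhere,
#' clipping negatives to zero. CoM estimation is sensitive to background, so
#' this runs before alignment.
#'
#' @param image numeric matrix (n_y, n_x)
#' @param borderFrac fraction of rows/columns forming the border frame,
#'   in (0, 0.4]
#' @return background-subtracted matrix, minimum >= 0
#' @export
backgroundSubtract <- function(image, borderFrac = 0.05) {
  image <- as.matrix(image)
  if (borderFrac <= 0 || borderFrac > 0.4)
    stop("validation error: borderFrac must lie in (0, 0.4]")
  ny <- nrow(image); nx <- ncol(image)
  by <- max(1L, floor(ny * borderFrac))
  bx <- max(1L, floor(nx * borderFrac))
  if (2L * by >= ny || 2L * bx >= nx)
    stop("validation error: border frame covers the whole image")
  mask <- matrix(FALSE, ny, nx)
  mask[c(seq_len(by), ny - seq_len(by) + 1L), ] <- TRUE
  mask[, c(seq_len(bx), nx - seq_len(bx) + 1L)] <- TRUE
  out <- image - mean(image[mask])
  out[out < 0] <- 0
  out
}

#' Center of mass of a 1D intensity profile
#'
#' \eqn{x_{CM} = \sum_i x_i \rho(x_i) / \sum_i \rho(x_i)} in 0-based pixel
#' units.
#'
#' @param profile nonnegative weights, at least one strictly positive
#' @return scalar coordinate (0-based)
#' @export
centerOfMass1d <- function(profile) {
  profile <- as.numeric(profile)
  if (any(profile < 0)) stop("validation error: negative weights")
  s <- sum(profile)
  if (s <= 0) stop("degenerate-profile error: all-zero profile")
  sum((seq_along(profile) - 1) * profile) / s
}

# Shift a single image by (dy, dx) pixels: output(y, x) = input(y-dy, x-dx)
# with bilinear interpolation and zero padding, so a feature moves by +shift.
.shiftImage <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  iy <- floor(dy); fy <- dy - iy
  ix <- floor(dx); fx <- dx - ix
  pick <- function(sy, sx) {
    out <- matrix(0, ny, nx)
    ys <- seq_len(ny) - sy # source rows
    xs <- seq_len(nx) - sx
    okY <- ys >= 1L & ys <= ny
    okX <- xs >= 1L & xs <= nx
    if (any(okY) && any(okX))
      out[okY, okX] <- img[ys[okY], xs[okX], drop = FALSE]
    out
  }
  if (fy == 0 && fx == 0) return(pick(iy, ix))
  (1 - fy) * (1 - fx) * pick(iy, ix) +
    fy * (1 - fx) * pick(iy + 1, ix) +
    (1 - fy) * fx * pick(iy, ix + 1) +
    fy * fx * pick(iy + 1, ix + 1)
}

.comOne <- function(img, borderFrac, label) {
  bs <- backgroundSubtract(img, borderFrac)
  if (sum(bs) <= 0)
    stop("alignment error: degenerate (all-zero) profile in projection ",
         label)
  c(y = centerOfMass1d(rowSums(bs)), x = centerOfMass1d(colSums(bs)))
}

#' Center-of-mass alignment of an isolated object
#'
#' After background subtraction, each projection is collapsed onto the axis
#' perpendicular to the tilt axis (x) and onto the tilt axis (y). The x
#' correction moves the x-CoM to the detector center; the y correction moves
#' the y-CoM to its mean across angles (the y mass center of a rigid object
#' is invariant under tilting). Valid for an isolated object whose projected
#' mass is fixed across the series.
#'
#' @param series a \linkS4class{TiltSeries}
#' @param borderFrac border fraction for \code{\link{backgroundSubtract}}
#' @return an \linkS4class{AlignmentTransform} (method "com")
#' @export
comAlign <- function(series, borderFrac = 0.05) {
  stopifnot(is(series, "TiltSeries"))
  d <- dim(series@data)
  cx <- (d[3L] - 1) / 2
  cm <- t(vapply(seq_len(d[1L]), function(a)
    .comOne(series@data[a, , ], borderFrac,
            sprintf("%d (%.2f deg)", a, series@anglesDeg[a])),
    numeric(2)))
  dy <- mean(cm[, "y"]) - cm[, "y"]
  dx <- cx - cm[, "x"]
  alignmentTransform(cbind(dy, dx), series@anglesDeg,
                     axisOffsetPx = 0, method = "com")
}

# Integer-precision circular cross-correlation peak: the displacement d such
# that a(p) ~= b(p - d), i.e. a is b shifted by +d.
.xcorrPeak <- function(a, b) {
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  cc <- Re(stats::fft(Fa * Conj(Fb), inverse = TRUE))
  w <- which.max(cc)
  ny <- nrow(a); nx <- ncol(a)
  dy <- (w - 1) %% ny
  dx <- (w - 1) %/% ny
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dy = dy, dx = dx)
}

#' Cross-correlation alignment for non-isolated objects
#'
#' Sequential pairwise registration: each projection is registered to its
#' predecessor via the frequency-domain correlation peak (integer
#' precision), and the relative shifts are accumulated with the
#' lowest-|angle| projection (closest to untilted) as the fixed reference.
#'
#' @param series a \linkS4class{TiltSeries} with at least two projections
#' @return an \linkS4class{AlignmentTransform} (method "xcorr")
#' @export
xcorrAlign <- function(series) {
  stopifnot(is(series, "TiltSeries"))
  n <- nAngles(series)
  if (n < 2L) stop("validation error: need at least 2 projections")
  rel <- matrix(0, n, 2) # displacement of k relative to k-1
  for (k in 2:n)
    rel[k, ] <- .xcorrPeak(series@data[k, , ], series@data[k - 1L, , ])
  ref <- which.min(abs(series@anglesDeg))
  disp <- matrix(0, n, 2) # displacement of k relative to the reference
  if (ref < n)
    for (k in (ref + 1L):n) disp[k, ] <- disp[k - 1L, ] + rel[k, ]
  if (ref > 1L)
    for (k in (ref - 1L):1L) disp[k, ] <- disp[k + 1L, ] - rel[k + 1L, ]
  alignmentTransform(-disp, series@anglesDeg, axisOffsetPx = 0,
                     method = "xcorr")
}

#' Estimate the rotation-axis offset from the detector center
#'
#' For an isolated object the projected center of mass traces a circle
#' centered on the rotation axis, so the mean over angles of
#' (x-CoM - detector center) estimates the axis offset along x.
#'
#' @param series a \linkS4class{TiltSeries}
#' @param borderFrac border fraction for \code{\link{backgroundSubtract}}
#' @return scalar offset estimate in pixels
#' @export
findAxisOffset <- function(series, borderFrac = 0.05) {
  stopifnot(is(series, "TiltSeries"))
  d <- dim(series@data)
  cx <- (d[3L] - 1) / 2
  xs <- vapply(seq_len(d[1L]), function(a)
    .comOne(series@data[a, , ], borderFrac, a)[["x"]], numeric(1))
  mean(xs - cx)
}

#' Apply an alignment transform to a tilt series
#'
#' Shifts each projection by its (dy, dx) correction with bilinear
#' interpolation (zero padding at edges); x is additionally corrected by
#' -axisOffsetPx. Marks the series aligned.
#'
#' @param series a \linkS4class{TiltSeries}
#' @param t an \linkS4class{AlignmentTransform} with one shift per projection
#' @return the corrected \linkS4class{TiltSeries}
#' @export
applyTransform <- function(series, t) {
  stopifnot(is(series, "TiltSeries"), is(t, "AlignmentTransform"))
  d <- dim(series@data)
  if (nrow(t@shifts) != d[1L])
    stop("validation error: shift count does not match the series")
  out <- series@data
  for (a in seq_len(d[1L])) {
    dy <- t@shifts[a, 1L]
    dx <- t@shifts[a, 2L] - t@axisOffsetPx
    if (dy != 0 || dx != 0)
      out[a, , ] <- .shiftImage(series@data[a, , ], dy, dx)
  }
  tiltSeries(out, series@anglesDeg, pixelSizeNm = series@pixelSizeNm,
             isAligned = TRUE)
}

#' Write an alignment transform to a plain-text table
#'
#' Tab-separated columns angle, dy, dx with the axis offset and method in
#' header comment lines; full \code{\%.17g} precision so the round trip via
#' \code{\link{readTransform}} is bit-exact.
#'
#' @param t an \linkS4class{AlignmentTransform}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeTransform <- function(t, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# axis_offset_px: %.17g", t@axisOffsetPx),
               sprintf("# method: %s", t@method),
               "angle\tdy\tdx"), con)
  for (i in seq_len(nrow(t@shifts)))
    writeLines(sprintf("%.17g\t%.17g\t%.17g", t@anglesDeg[i],
                       t@shifts[i, 1L], t@shifts[i, 2L]), con)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  lines <- readLines(path)
  off <- as.numeric(sub("^# axis_offset_px: ", "", lines[1L]))
  method <- sub("^# method: ", "", lines[2L])
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  alignmentTransform(m[, 2:3, drop = FALSE], m[, 1L], axisOffsetPx = off,
                     method = method)
}
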