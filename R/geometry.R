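# Single-axis parallel-beam geometry. Convention (fixed across the package):
# volume indexed (y, x, z); tilt axis y; beam along +z at 0 deg; angles in
# degrees, CCW about +y; 0-based pixel-center coordinates with rotation about
# the slice center ((n_x-1)/2, (n_z-1)/2); detector bins equal n_x.

.interpCode <- function(interpolation) {
  match(interpolation, c("linear", "nearest")) - 1L
}

.checkAngles <- function(anglesDeg) {
  if (any(!is.finite(anglesDeg)))
    stop("geometry error: non-finite projection angle")
  if (any(abs(anglesDeg) > 90))
    stop("geometry error: projection angles must lie within [-90, 90] degrees")
  invisible(anglesDeg)
}

# Raw operator application in voxel units (no pixel-size scaling).
# vol: array (ny, nx, nz) -> array (na, ny, nx)
.opForward <- function(vol, anglesDeg, interpolation = "linear") {
  d <- dim(vol)
  out <- cppForwardProject(as.numeric(vol), as.integer(d),
                           as.numeric(anglesDeg), .interpCode(interpolation))
  dim(out) <- c(length(anglesDeg), d[1L], d[2L])
  out
}

# sino: array (na, ny, nx) -> array (ny, nx, nz)
.opAdjoint <- function(sino, dims, anglesDeg, interpolation = "linear") {
  out <- cppBackProject(as.numeric(sino), as.integer(dims),
                        as.numeric(anglesDeg), .interpCode(interpolation))
  dim(out) <- as.integer(dims)
  out
}

# 2D slice versions used by the power method and WBP: slice (nx, nz) matrix.
.opForwardSlice <- function(op, slice) {
  dim(slice) <- c(1L, dim(slice))
  s <- .opForward(slice, op@anglesDeg, op@interpolation)
  matrix(s, nrow = length(op@anglesDeg))
}

.opAdjointSlice <- function(op, sino) {
  dim(sino) <- c(dim(sino)[1L], 1L, dim(sino)[2L])
  v <- .opAdjoint(sino, c(1L, op@sliceShape), op@anglesDeg, op@interpolation)
  matrix(v, nrow = op@sliceShape[1L])
}

#' Forward-project a tomogram into a tilt series
#'
#' Applies the measurement operator \eqn{A}: each y-slice of the volume is
#' projected by parallel-beam line integrals through its (x, z) plane,
#' rotation about the y axis. Output values are in units of density times
#' length (line integrals scaled by the voxel size).
#'
#' @param tomogram a \linkS4class{Tomogram}
#' @param anglesDeg projection angles in degrees, within [-90, 90]
#' @param interpolation "linear" (default) or "nearest" ray weighting
#' @return a \linkS4class{TiltSeries} of shape (n_angles, n_y, n_x)
#' @export
forwardProject <- function(tomogram, anglesDeg,
                           interpolation = c("linear", "nearest")) {
  stopifnot(is(tomogram, "Tomogram"))
  interpolation <- match.arg(interpolation)
  .checkAngles(anglesDeg)
  if (!all(is.finite(tomogram@data)))
    stop("validation error: non-finite tomogram values")
  raw <- .opForward(tomogram@data, anglesDeg, interpolation)
  tiltSeries(raw * tomogram@voxelSizeNm, anglesDeg,
             pixelSizeNm = tomogram@voxelSizeNm, isAligned = TRUE)
}

#' Back-project a tilt series (adjoint of the forward operator)
#'
#' Returns the adjoint action \eqn{A^T b}: each projection smeared back along
#' its ray direction with the exact transpose of the forward interpolation
#' weights. This is the unfiltered backprojection used by the gradient
#' \eqn{\nabla\|Ax-b\|^2 = 2A^T(Ax-b)}, not a reconstruction by itself.
#'
#' @param series a \linkS4class{TiltSeries}
#' @param sliceShape integer pair (n_x, n_z) of the target slice; n_x must
#'   match the detector width of the series
#' @param interpolation "linear" (default) or "nearest"
#' @return a \linkS4class{Tomogram} of shape (n_y, n_x, n_z)
#' @export
backProject <- function(series, sliceShape,
                        interpolation = c("linear", "nearest")) {
  stopifnot(is(series, "TiltSeries"))
  interpolation <- match.arg(interpolation)
  d <- dim(series@data)
  sliceShape <- as.integer(sliceShape)
  if (sliceShape[1L] != d[3L])
    stop("geometry error: sliceShape n_x must match the detector width")
  dims <- c(d[2L], sliceShape)
  vol <- .opAdjoint(series@data, dims, series@anglesDeg, interpolation)
  tomogram(vol * series@pixelSizeNm, voxelSizeNm = series@pixelSizeNm,
           provenance = "backProject (adjoint)")
}

#' Extract the sinogram of one y-slice
#'
#' For single-axis geometry the reconstruction decouples along the tilt axis:
#' the fixed-y plane across all angles is an independent 2D problem. Slices
#' are indexed 1..n_y.
#'
#' @param series a \linkS4class{TiltSeries}
#' @param y slice index along the tilt axis (1-based)
#' @return matrix (n_angles, n_x)
#' @export
sliceSinogram <- function(series, y) {
  stopifnot(is(series, "TiltSeries"))
  d <- dim(series@data)
  y <- as.integer(y)
  if (length(y) != 1L || is.na(y) || y < 1L || y > d[2L])
    stop(sprintf("index error: y must lie in 1..%d", d[2L]))
  matrix(series@data[, y, ], nrow = d[1L])
}
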