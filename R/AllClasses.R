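#' @useDynLib tomostream, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.ANGLE_TOL <- 1e-6

# ---------------------------------------------------------------- TiltSeries

#' TiltSeries: a stack of 2D projections with per-projection tilt angles
#'
#' Container for the experimental projections \eqn{b}: a real-valued array of
#' shape (n_angles, n_y, n_x) in detector counts, with one tilt angle (degrees)
#' per projection. The tilt (rotation) axis is y, the first image axis. Angles
#' must lie in [-90, 90] and be unique; projections are stored sorted by angle.
#'
#' @slot data numeric array (n_angles, n_y, n_x)
#' @slot anglesDeg numeric, tilt angles in degrees, strictly increasing
#' @slot pixelSizeNm positive scalar, detector pixel size in nm
#' @slot isAligned logical flag set once alignment corrections are applied
#' @exportClass TiltSeries
setClass("TiltSeries",
  representation(
    data = "array",
    anglesDeg = "numeric",
    pixelSizeNm = "numeric",
    isAligned = "logical"
  )
)

setValidity("TiltSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array (n_angles, n_y, n_x)")
  if (length(object@anglesDeg) != d[1L])
    return("length(anglesDeg) must equal the first dimension of data")
  if (!all(is.finite(object@data))) return("data contains non-finite values")
  if (!all(is.finite(object@anglesDeg))) return("angles contain non-finite values")
  if (any(abs(object@anglesDeg) > 90))
    return("tilt angles must lie within [-90, 90] degrees")
  if (length(object@anglesDeg) > 1L &&
      any(diff(object@anglesDeg) <= .ANGLE_TOL))
    return("tilt angles must be strictly increasing with no duplicates")
  if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
      object@pixelSizeNm <= 0)
    return("pixelSizeNm must be a positive scalar")
  TRUE
})

#' Construct a TiltSeries
#'
#' Projections are re-ordered so angles are strictly increasing.
#'
#' @param data numeric array (n_angles, n_y, n_x)
#' @param anglesDeg tilt angles in degrees, one per projection
#' @param pixelSizeNm detector pixel size in nm (default 1)
#' @param isAligned whether the series carries alignment corrections
#' @return a \linkS4class{TiltSeries}
#' @export
tiltSeries <- function(data, anglesDeg, pixelSizeNm = 1, isAligned = FALSE) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(1L, dim(data))
  if (length(anglesDeg) != dim(data)[1L])
    stop("length(anglesDeg) must equal the first dimension of data")
  ord <- order(anglesDeg)
  new("TiltSeries",
    data = data[ord, , , drop = FALSE],
    anglesDeg = as.numeric(anglesDeg[ord]),
    pixelSizeNm = as.numeric(pixelSizeNm),
    isAligned = isTRUE(isAligned)
  )
}

#' @describeIn tiltSeries projection data array (n_angles, n_y, n_x)
#' @param x a TiltSeries
#' @export
seriesData <- function(x) x@data

#' @describeIn tiltSeries tilt angles in degrees
#' @export
tiltAngles <- function(x) x@anglesDeg

#' @describeIn tiltSeries number of projections
#' @export
nAngles <- function(x) length(x@anglesDeg)

#' @describeIn tiltSeries detector pixel size in nm
#' @export
pixelSize <- function(x) x@pixelSizeNm

#' @describeIn tiltSeries has the series been aligned?
#' @export
isAligned <- function(x) x@isAligned

setMethod("show", "TiltSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("TiltSeries: %d projections of %d x %d px (%.3g nm/px)%s\n",
    d[1], d[2], d[3], object@pixelSizeNm,
    if (object@isAligned) ", aligned" else ""))
  cat(sprintf("  angles: %.2f .. %.2f deg\n",
    min(object@anglesDeg), max(object@anglesDeg)))
})

# ------------------------------------------------------------------ Tomogram

#' Tomogram: a reconstructed 3D volume
#'
#' The reconstruction target \eqn{x}: a real-valued volume of shape
#' (n_y, n_x, n_z) where y is the tilt axis and z the beam direction at zero
#' tilt.
#'
#' @slot data numeric array (n_y, n_x, n_z)
#' @slot voxelSizeNm positive scalar
#' @slot provenance free-text record of algorithm and iteration
#' @exportClass Tomogram
setClass("Tomogram",
  representation(
    data = "array",
    voxelSizeNm = "numeric",
    provenance = "character"
  )
)

setValidity("Tomogram", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array (n_y, n_x, n_z)")
  if (!all(is.finite(object@data))) return("data contains non-finite values")
  if (length(object@voxelSizeNm) != 1L || !is.finite(object@voxelSizeNm) ||
      object@voxelSizeNm <= 0)
    return("voxelSizeNm must be a positive scalar")
  TRUE
})

#' Construct a Tomogram
#'
#' @param data numeric array (n_y, n_x, n_z)
#' @param voxelSizeNm voxel edge length in nm (default 1)
#' @param provenance free-text provenance record
#' @return a \linkS4class{Tomogram}
#' @export
tomogram <- function(data, voxelSizeNm = 1, provenance = "constructed") {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(1L, dim(data))
  new("Tomogram", data = data, voxelSizeNm = as.numeric(voxelSizeNm),
      provenance = as.character(provenance))
}

#' @describeIn tomogram volume data array (n_y, n_x, n_z)
#' @param x a Tomogram
#' @export
tomoData <- function(x) x@data

#' @describeIn tomogram voxel edge length in nm
#' @export
voxelSize <- function(x) x@voxelSizeNm

#' @describeIn tomogram provenance record
#' @export
provenance <- function(x) x@provenance

setMethod("show", "Tomogram", function(object) {
  d <- dim(object@data)
  cat(sprintf("Tomogram: %d x %d x %d voxels (%.3g nm), %s\n",
    d[1], d[2], d[3], object@voxelSizeNm, object@provenance))
})

# ------------------------------------------------------- ProjectionOperator

#' ProjectionOperator: parallel-beam forward/adjoint pair
#'
#' The measurement matrix \eqn{A} acting per y-slice: line integrals through
#' the (x, z) plane with rotation about y. The forward and adjoint share one
#' set of interpolation weights (a matched pair), so the adjoint identity
#' \eqn{\langle Au, v\rangle = \langle u, A^T v\rangle} holds to rounding.
#'
#' @slot anglesDeg projection angles in degrees, within [-90, 90]
#' @slot sliceShape integer (n_x, n_z) of the reconstruction slice
#' @slot detectorBins number of detector bins (equals n_x)
#' @slot interpolation "linear" (bilinear) or "nearest"
#' @exportClass ProjectionOperator
setClass("ProjectionOperator",
  representation(
    anglesDeg = "numeric",
    sliceShape = "integer",
    detectorBins = "integer",
    interpolation = "character"
  )
)

setValidity("ProjectionOperator", function(object) {
  if (length(object@sliceShape) != 2L || any(object@sliceShape < 1L))
    return("sliceShape must be two positive integers (n_x, n_z)")
  if (any(!is.finite(object@anglesDeg)) || any(abs(object@anglesDeg) > 90))
    return("angles must be finite and within [-90, 90] degrees")
  if (!object@interpolation %in% c("linear", "nearest"))
    return("interpolation must be 'linear' or 'nearest'")
  if (object@detectorBins != object@sliceShape[1L])
    return("detectorBins must equal n_x of the slice")
  TRUE
})

#' Construct a ProjectionOperator
#'
#' @param anglesDeg projection angles in degrees
#' @param sliceShape integer pair (n_x, n_z)
#' @param interpolation "linear" or "nearest"
#' @return a \linkS4class{ProjectionOperator}
#' @export
projectionOperator <- function(anglesDeg, sliceShape,
                               interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  sliceShape <- as.integer(sliceShape)
  new("ProjectionOperator", anglesDeg = as.numeric(anglesDeg),
      sliceShape = sliceShape, detectorBins = sliceShape[1L],
      interpolation = interpolation)
}

setMethod("show", "ProjectionOperator", function(object) {
  cat(sprintf(
    "ProjectionOperator: %d angles, slice %d x %d, %s interpolation\n",
    length(object@anglesDeg), object@sliceShape[1], object@sliceShape[2],
    object@interpolation))
})

# --------------------------------------------------------------- SolverConfig

#' SolverConfig: reconstruction algorithm settings
#'
#' @slot algorithm one of "wbp", "sirt", "tvmin"
#' @slot maxIters outer iterations (ignored by wbp)
#' @slot stepSafety fraction of the 1/L safe step actually taken, in (0, 1]
#' @slot wbpWindow "ramp" or "hamming-ramp" weighting filter
#' @slot tvStepAlpha0 initial TV step fraction (of the data-step magnitude)
#' @slot tvStepAlphaMin terminal TV step fraction of the linear envelope
#' @slot tvDescentSteps TV-gradient descent steps per outer iteration
#' @slot tvEpsilon smoothing constant in the isotropic TV norm
#' @slot updateEvery iterations between published snapshots
#' @slot nonneg clip the iterate at zero after each data step
#' @slot seed RNG seed used for the power-method start vector
#' @exportClass SolverConfig
setClass("SolverConfig",
  representation(
    algorithm = "character",
    maxIters = "integer",
    stepSafety = "numeric",
    wbpWindow = "character",
    tvStepAlpha0 = "numeric",
    tvStepAlphaMin = "numeric",
    tvDescentSteps = "integer",
    tvEpsilon = "numeric",
    updateEvery = "integer",
    nonneg = "logical",
    seed = "integer"
  )
)

setValidity("SolverConfig", function(object) {
  if (!object@algorithm %in% c("wbp", "sirt", "tvmin"))
    return("algorithm must be one of 'wbp', 'sirt', 'tvmin'")
  if (object@maxIters < 1L) return("maxIters must be >= 1")
  if (object@stepSafety <= 0 || object@stepSafety > 1)
    return("stepSafety must lie in (0, 1]")
  if (!object@wbpWindow %in% c("ramp", "hamming-ramp"))
    return("wbpWindow must be 'ramp' or 'hamming-ramp'")
  if (object@tvStepAlpha0 < 0 || object@tvStepAlphaMin < 0)
    return("TV step fractions must be nonnegative")
  if (object@tvStepAlphaMin > object@tvStepAlpha0)
    return("tvStepAlphaMin must be <= tvStepAlpha0")
  if (object@tvDescentSteps < 1L) return("tvDescentSteps must be >= 1")
  if (object@tvEpsilon < 0) return("tvEpsilon must be >= 0")
  if (object@updateEvery < 1L) return("updateEvery must be >= 1")
  TRUE
})

#' Construct a SolverConfig
#'
#' Defaults follow common ADF-STEM tomography practice: a 0.95 safety factor
#' on the 1/L gradient step, ten TV descent steps per outer iteration with the
#' TV step decaying linearly from \code{tvStepAlpha0} to \code{tvStepAlphaMin}
#' over \code{maxIters}, and a nonnegativity clip for the TV solver (physical
#' densities). The plain least-squares solver leaves the iterate unclipped by
#' default so it converges to the minimum-norm solution.
#'
#' @param algorithm "wbp", "sirt" or "tvmin"
#' @param maxIters outer iteration count
#' @param stepSafety step-size safety factor in (0, 1]
#' @param wbpWindow WBP weighting filter, "ramp" or "hamming-ramp"
#' @param tvStepAlpha0,tvStepAlphaMin linear dampening-envelope endpoints
#' @param tvDescentSteps TV descent steps per outer iteration
#' @param tvEpsilon TV smoothing constant
#' @param updateEvery iterations between published snapshots
#' @param nonneg clip negatives after data steps (default TRUE for tvmin)
#' @param seed RNG seed for the power method
#' @return a \linkS4class{SolverConfig}
#' @export
solverConfig <- function(algorithm = c("sirt", "tvmin", "wbp"),
                         maxIters = 100L, stepSafety = 0.95,
                         wbpWindow = c("ramp", "hamming-ramp"),
                         tvStepAlpha0 = 0.2, tvStepAlphaMin = 0,
                         tvDescentSteps = 10L, tvEpsilon = 1e-8,
                         updateEvery = 1L,
                         nonneg = identical(algorithm[1L], "tvmin"),
                         seed = 42L) {
  algorithm <- match.arg(algorithm)
  wbpWindow <- match.arg(wbpWindow)
  new("SolverConfig", algorithm = algorithm, maxIters = as.integer(maxIters),
      stepSafety = as.numeric(stepSafety), wbpWindow = wbpWindow,
      tvStepAlpha0 = as.numeric(tvStepAlpha0),
      tvStepAlphaMin = as.numeric(tvStepAlphaMin),
      tvDescentSteps = as.integer(tvDescentSteps),
      tvEpsilon = as.numeric(tvEpsilon),
      updateEvery = as.integer(updateEvery),
      nonneg = isTRUE(nonneg), seed = as.integer(seed))
}

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf("SolverConfig: %s, %d iterations, step safety %.2f\n",
    object@algorithm, object@maxIters, object@stepSafety))
})

# ----------------------------------------------------------------- ReconState

#' ReconState: resumable state of an iterative reconstruction
#'
#' Carries the current estimate, iteration counter, Lipschitz estimate
#' \eqn{L = \|A^T A\|_2}, the step size in use, and the per-iteration
#' normalized-residual (and TV) histories plotted to monitor convergence.
#' The power-method eigenvector is retained so the Lipschitz constant can be
#' warm-started when projections are appended mid-acquisition.
#'
#' @slot x the current \linkS4class{Tomogram} estimate
#' @slot iteration completed outer iterations
#' @slot nProjectionsUsed projections in the data last run against
#' @slot anglesDeg angles of those projections
#' @slot lipschitzL power-method estimate of the largest eigenvalue of AtA
#' @slot stepSize data-fidelity gradient step in use
#' @slot stepSafety safety factor the step was derived with
#' @slot residualHistory normalized residual after each iteration
#' @slot tvHistory TV value after each iteration (tvmin only, else empty)
#' @slot nprojHistory projections in use at each iteration
#' @slot powerVec last power-method iterate (warm start for extensions)
#' @slot config the \linkS4class{SolverConfig} the state was created under
#' @exportClass ReconState
setClass("ReconState",
  representation(
    x = "Tomogram",
    iteration = "integer",
    nProjectionsUsed = "integer",
    anglesDeg = "numeric",
    lipschitzL = "numeric",
    stepSize = "numeric",
    stepSafety = "numeric",
    residualHistory = "numeric",
    tvHistory = "numeric",
    nprojHistory = "integer",
    powerVec = "numeric",
    config = "SolverConfig"
  )
)

setValidity("ReconState", function(object) {
  if (object@iteration < 0L) return("iteration must be >= 0")
  if (length(object@residualHistory) != object@iteration)
    return("residualHistory length must equal iteration")
  if (object@lipschitzL <= 0 && object@config@algorithm != "wbp")
    return("lipschitzL must be positive")
  TRUE
})

#' @describeIn reconHistory current Tomogram estimate
#' @export
reconVolume <- function(state) state@x

#' @describeIn reconHistory normalized residual per iteration
#' @export
residualHistory <- function(state) state@residualHistory

#' @describeIn reconHistory TV value per iteration (tvmin only)
#' @export
tvHistory <- function(state) state@tvHistory

#' Convergence history of a reconstruction state
#'
#' @param state a \linkS4class{ReconState}
#' @return \code{reconHistory}: data.frame with columns iteration,
#'   n_projections, normalized_residual and (for tvmin) tv
#' @export
reconHistory <- function(state) {
  df <- data.frame(
    iteration = seq_len(state@iteration),
    n_projections = state@nprojHistory,
    normalized_residual = state@residualHistory
  )
  if (length(state@tvHistory) == state@iteration) df$tv <- state@tvHistory
  df
}

setMethod("show", "ReconState", function(object) {
  cat(sprintf(
    "ReconState: %s, iteration %d, %d projections, L = %.4g, step = %.4g\n",
    object@config@algorithm, object@iteration, object@nProjectionsUsed,
    object@lipschitzL, object@stepSize))
  if (object@iteration > 0L)
    cat(sprintf("  normalized residual: %.4g\n",
      object@residualHistory[object@iteration]))
})

# -------------------------------------------------------- AlignmentTransform

#' AlignmentTransform: per-projection shift corrections plus axis offset
#'
#' @slot shifts n_angles x 2 matrix of (dy, dx) corrections in pixels
#' @slot anglesDeg the angles the rows correspond to
#' @slot axisOffsetPx rotation-axis offset from the detector center along x
#' @slot method identifier of the estimator that produced it
#' @exportClass AlignmentTransform
setClass("AlignmentTransform",
  representation(
    shifts = "matrix",
    anglesDeg = "numeric",
    axisOffsetPx = "numeric",
    method = "character"
  )
)

setValidity("AlignmentTransform", function(object) {
  if (ncol(object@shifts) != 2L) return("shifts must have two columns (dy, dx)")
  if (nrow(object@shifts) != length(object@anglesDeg))
    return("one shift pair per projection required")
  if (!all(is.finite(object@shifts)) || !is.finite(object@axisOffsetPx))
    return("all entries must be finite")
  TRUE
})

#' Construct an AlignmentTransform
#'
#' @param shifts n x 2 matrix of (dy, dx) pixel corrections
#' @param anglesDeg corresponding tilt angles
#' @param axisOffsetPx rotation-axis offset in pixels (default 0)
#' @param method estimator identifier
#' @return an \linkS4class{AlignmentTransform}
#' @export
alignmentTransform <- function(shifts, anglesDeg, axisOffsetPx = 0,
                               method = "manual") {
  shifts <- matrix(as.numeric(shifts), ncol = 2L,
                   dimnames = list(NULL, c("dy", "dx")))
  new("AlignmentTransform", shifts = shifts, anglesDeg = as.numeric(anglesDeg),
      axisOffsetPx = as.numeric(axisOffsetPx), method = as.character(method))
}

#' @describeIn alignmentTransform the (dy, dx) correction matrix
#' @param t an AlignmentTransform
#' @export
shiftTable <- function(t) t@shifts

#' @describeIn alignmentTransform rotation-axis offset in pixels
#' @export
axisOffset <- function(t) t@axisOffsetPx

setMethod("show", "AlignmentTransform", function(object) {
  cat(sprintf(
    "AlignmentTransform (%s): %d projections, axis offset %.3f px\n",
    object@method, nrow(object@shifts), object@axisOffsetPx))
  cat(sprintf("  max |shift|: %.3f px\n",
    if (nrow(object@shifts)) max(abs(object@shifts)) else 0))
})
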