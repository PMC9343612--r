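# Reconstruction engines. SIRT is plain gradient descent on ||Ax - b||^2 with
# a global step step_safety / L, L = ||AtA||_2 estimated by the power method.
# TVmin alternates one data-fidelity step with normalized TV-gradient descent
# whose step length is tied to the data-step magnitude and scaled by a
# linearly decaying dampening envelope. WBP ramp-filters each y-slice
# sinogram and backprojects, emitting slices in increasing y.

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Power method on M = AtA for one reconstruction slice, in voxel units.
.powerMethod <- function(op, nIters = 50L, tol = 1e-6, seed = 0L, v0 = NULL) {
  n <- prod(op@sliceShape)
  v <- if (!is.null(v0) && length(v0) == n) v0 else
    .withSeed(seed, stats::rnorm(n))
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate start vector")
  v <- v / nv
  rq <- NA_real_
  for (k in seq_len(max(1L, as.integer(nIters)))) {
    sl <- matrix(v, op@sliceShape[1L], op@sliceShape[2L])
    w <- as.numeric(.opAdjointSlice(op, .opForwardSlice(op, sl)))
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("degenerate-operator error: AtA annihilates the iterate")
    rqNew <- sum(v * w) # v is unit norm
    if (!is.na(rq) && abs(rqNew - rq) <= tol * abs(rqNew)) {
      rq <- rqNew
      v <- w / nw
      break
    }
    rq <- rqNew
    v <- w / nw
  }
  list(L = rq, vec = v)
}

#' Estimate the Lipschitz constant L = ||AtA||_2 by the power method
#'
#' The safe gradient step for SIRT/TVmin is bounded by 1/L where L is the
#' largest eigenvalue of \eqn{A^T A}. Iterates \eqn{v \gets A^TAv/\|A^TAv\|}
#' from a seeded random start until the Rayleigh quotient changes by less
#' than \code{tol} (relative) or \code{nIters} is reached.
#'
#' @param op a \linkS4class{ProjectionOperator}
#' @param nIters maximum power iterations (default 50)
#' @param tol relative Rayleigh-quotient convergence tolerance
#' @param seed seed for the random start vector
#' @param v0 optional warm-start vector (length n_x * n_z)
#' @return positive scalar estimate of \eqn{\|A^T A\|_2} (voxel units)
#' @export
estimateLipschitz <- function(op, nIters = 50L, tol = 1e-6, seed = 0L,
                              v0 = NULL) {
  stopifnot(is(op, "ProjectionOperator"), nIters >= 1L)
  .powerMethod(op, nIters, tol, seed, v0)$L
}

#' Linearly decaying dampening envelope for the TV step
#'
#' Returns \code{alpha0 + (alphaMin - alpha0) * min(k, kMax) / kMax}: linear
#' decay from \code{alpha0} at iteration 0 to \code{alphaMin} at and beyond
#' \code{kMax}.
#'
#' @param k iteration index (>= 0)
#' @param alpha0 envelope value at k = 0
#' @param kMax iteration at which the floor is reached (>= 1)
#' @param alphaMin terminal envelope value (<= alpha0)
#' @return scalar envelope value
#' @export
dampeningEnvelope <- function(k, alpha0, kMax, alphaMin = 0) {
  if (any(k < 0)) stop("validation error: k must be >= 0")
  stopifnot(kMax >= 1, alphaMin <= alpha0)
  w <- pmin(k, kMax) / kMax
  alpha0 * (1 - w) + alphaMin * w # exact at both endpoints
}

#' Ramp-filter a sinogram along the detector axis
#'
#' Each angle's detector row is filtered in the frequency domain by the ramp
#' |f| (normalized to 1 at Nyquist), optionally apodized by a Hamming window.
#' The zero-frequency component is exactly nulled. Rows are padded with
#' edge replication to the next power of two of at least twice the detector
#' width, so the circular convolution neither wraps nor sees artificial
#' edge steps; a constant row maps exactly to zero.
#'
#' @param sinogram matrix (n_angles, n_x)
#' @param window "ramp" (Ram-Lak) or "hamming-ramp"
#' @return filtered matrix of the same shape
#' @export
rampFilter <- function(sinogram, window = c("ramp", "hamming-ramp")) {
  window <- match.arg(window)
  if (!all(is.finite(sinogram)))
    stop("validation error: non-finite sinogram values")
  sinogram <- as.matrix(sinogram)
  nx <- ncol(sinogram)
  m <- 2^ceiling(log2(max(64, 2 * nx)))
  f <- c(0:(m / 2), -(m / 2 - 1):-1) / m
  H <- 2 * abs(f)
  if (window == "hamming-ramp")
    H <- H * (0.54 + 0.46 * cos(pi * f / 0.5))
  # edge-replicated padding: a constant row stays constant on the whole
  # circle (so the nulled DC bin removes it exactly), while compactly
  # supported rows behave as zero-padded
  gap <- m - nx
  g1 <- ceiling(gap / 2)
  P <- matrix(0, m, nrow(sinogram))
  P[seq_len(nx), ] <- t(sinogram)
  P[nx + seq_len(g1), ] <- matrix(sinogram[, nx], g1, nrow(sinogram),
                                  byrow = TRUE)
  P[nx + g1 + seq_len(gap - g1), ] <- matrix(sinogram[, 1L], gap - g1,
                                             nrow(sinogram), byrow = TRUE)
  Fp <- stats::mvfft(P) * H
  out <- Re(stats::mvfft(Fp, inverse = TRUE)) / m
  t(out[seq_len(nx), , drop = FALSE])
}

.relres <- function(Ax, b, normb) {
  r <- sqrt(sum((Ax - b)^2))
  if (normb == 0) {
    if (r == 0) return(0)
    return(Inf)
  }
  r / normb
}

.seriesGeom <- function(series, sliceShape = NULL) {
  d <- dim(series@data)
  if (is.null(sliceShape)) sliceShape <- c(d[3L], d[3L])
  list(na = d[1L], ny = d[2L], nx = d[3L],
       sliceShape = as.integer(sliceShape))
}

#' Normalized projection residual
#'
#' Returns \eqn{\|Ax - b\|_2 / \|b\|_2}, the convergence monitor recorded per
#' iteration; defined as 0 when both b and x are zero.
#'
#' @param x a \linkS4class{Tomogram}
#' @param series a \linkS4class{TiltSeries} providing b and the angles
#' @return nonnegative scalar
#' @export
normalizedResidual <- function(x, series) {
  stopifnot(is(x, "Tomogram"), is(series, "TiltSeries"))
  d <- dim(series@data)
  dx <- dim(x@data)
  if (dx[1L] != d[2L] || dx[2L] != d[3L])
    stop("geometry error: tomogram (n_y, n_x) does not match the series")
  Ax <- .opForward(x@data, series@anglesDeg) * series@pixelSizeNm
  .relres(Ax, series@data, sqrt(sum(series@data^2)))
}

.freshState <- function(series, config, sliceShape) {
  g <- .seriesGeom(series, sliceShape)
  ps <- series@pixelSizeNm
  op <- projectionOperator(series@anglesDeg, g$sliceShape)
  pm <- .powerMethod(op, 50L, 1e-6, config@seed)
  L <- pm$L * ps^2
  x0 <- tomogram(array(0, c(g$ny, g$sliceShape)), voxelSizeNm = ps,
                 provenance = sprintf("%s iter 0", config@algorithm))
  new("ReconState", x = x0, iteration = 0L, nProjectionsUsed = g$na,
      anglesDeg = series@anglesDeg, lipschitzL = L,
      stepSize = config@stepSafety / L, stepSafety = config@stepSafety,
      residualHistory = numeric(0), tvHistory = numeric(0),
      nprojHistory = integer(0), powerVec = pm$vec, config = config)
}

.checkResume <- function(state, series) {
  if (length(state@anglesDeg) != length(series@anglesDeg) ||
      any(abs(state@anglesDeg - series@anglesDeg) > .ANGLE_TOL))
    stop("state error: resumed state does not match the series angles; ",
         "use extendState() after appending projections")
  dx <- dim(state@x@data)
  d <- dim(series@data)
  if (dx[1L] != d[2L] || dx[2L] != d[3L])
    stop("state error: resumed state geometry does not match the series")
}

#' Run SIRT (Lipschitz-stepped gradient descent on the projection residual)
#'
#' Iterates \eqn{x_{k+1} = x_k - \mathrm{step}\, A^T(Ax_k - b)} with
#' step = stepSafety / L. Fresh runs start from \eqn{x_0 = 0}; passing a
#' \code{state} resumes from its iterate (warm start). One normalized
#' residual is appended per iteration; non-convergence never raises - the
#' histories tell the story.
#'
#' @param series an aligned \linkS4class{TiltSeries}
#' @param config a \linkS4class{SolverConfig}; \code{maxIters} iterations run
#' @param state optional \linkS4class{ReconState} to resume
#' @param sliceShape integer (n_x, n_z) of the reconstruction slice; default
#'   (n_x, n_x)
#' @return an updated \linkS4class{ReconState}
#' @export
sirtRun <- function(series, config = solverConfig("sirt"), state = NULL,
                    sliceShape = NULL) {
  stopifnot(is(series, "TiltSeries"), is(config, "SolverConfig"))
  if (is.null(state)) state <- .freshState(series, config, sliceShape)
  else .checkResume(state, series)
  .descend(series, config, state, tv = FALSE)
}

#' Run dynamic TV-minimization (data step + dampened TV descent)
#'
#' Per outer iteration: (i) one SIRT data-fidelity step (step = stepSafety/L)
#' followed by a nonnegativity clip; (ii) \code{tvDescentSteps} steps of
#' normalized TV-gradient descent with step length
#' \code{dampeningEnvelope(k, alpha0, maxIters, alphaMin)} times the
#' data-step magnitude. The normalized residual is recorded after the data
#' step (before the TV steps) and the TV value after the TV steps. With
#' \code{tvStepAlpha0 = 0} the trajectory is identical to \code{sirtRun}
#' under the same config.
#'
#' @inheritParams sirtRun
#' @return an updated \linkS4class{ReconState}
#' @export
tvminRun <- function(series, config = solverConfig("tvmin"), state = NULL,
                     sliceShape = NULL) {
  stopifnot(is(series, "TiltSeries"), is(config, "SolverConfig"))
  if (is.null(state)) state <- .freshState(series, config, sliceShape)
  else .checkResume(state, series)
  .descend(series, config, state, tv = TRUE)
}

# Shared descent loop. tv = FALSE: pure gradient descent, residual of the
# new iterate recorded lazily (reusing the next iteration's forward pass).
# tv = TRUE: residual recorded after the data step, before the TV steps.
.descend <- function(series, config, state, tv) {
  b <- series@data
  ps <- series@pixelSizeNm
  angles <- series@anglesDeg
  normb <- sqrt(sum(b^2))
  x <- state@x@data
  dims <- dim(x)
  step <- state@stepSize
  n <- config@maxIters
  na <- length(angles)
  res <- numeric(n)
  tvh <- numeric(n)
  fw <- function(v) .opForward(v, angles) * ps
  bk <- function(s) .opAdjoint(s, dims, angles) * ps
  if (!tv) {
    for (k in seq_len(n)) {
      Ax <- fw(x)
      if (k > 1L) res[k - 1L] <- .relres(Ax, b, normb)
      x <- x - step * bk(Ax - b)
      if (config@nonneg) x[x < 0] <- 0
    }
    res[n] <- .relres(fw(x), b, normb)
  } else {
    eps <- config@tvEpsilon
    for (k in seq_len(n)) {
      kGlobal <- state@iteration + k - 1L
      Ax <- fw(x)
      xd <- x - step * bk(Ax - b)
      if (config@nonneg) xd[xd < 0] <- 0
      res[k] <- .relres(fw(xd), b, normb)
      dt <- sqrt(sum((xd - x)^2))
      x <- xd
      alpha <- dampeningEnvelope(kGlobal, config@tvStepAlpha0,
                                 config@maxIters, config@tvStepAlphaMin)
      if (alpha * dt > 0) {
        for (s in seq_len(config@tvDescentSteps)) {
          g <- .tvGradient(x, eps)
          ng <- sqrt(sum(g^2))
          if (ng > 0) x <- x - (alpha * dt / ng) * g
        }
      }
      tvh[k] <- .tvNormArray(x, eps)
    }
  }
  iter <- state@iteration + n
  state@x <- tomogram(x, voxelSizeNm = ps,
    provenance = sprintf("%s iter %d", config@algorithm, iter))
  state@iteration <- iter
  state@residualHistory <- c(state@residualHistory, res)
  state@tvHistory <- c(state@tvHistory, if (tv) tvh else numeric(0))
  state@nprojHistory <- c(state@nprojHistory, rep(na, n))
  state@nProjectionsUsed <- na
  state@config <- config
  validObject(state)
  state
}

# forward difference along dim, zero beyond the far boundary
.fdiff <- function(a, dm) {
  d <- dim(a)
  n <- d[dm]
  out <- array(0, d)
  if (n < 2L) return(out)
  idxHi <- lapply(d, seq_len)
  idxLo <- idxHi
  idxHi[[dm]] <- 2:n
  idxLo[[dm]] <- 1:(n - 1L)
  asn <- idxLo
  out[asn[[1]], asn[[2]], asn[[3]]] <-
    a[idxHi[[1]], idxHi[[2]], idxHi[[3]]] - a[idxLo[[1]], idxLo[[2]], idxLo[[3]]]
  out
}

# adjoint of .fdiff applied to the normalized gradient field:
# (Dt p)_i = p_{i-1} - p_i
.fdiffT <- function(p, dm) {
  d <- dim(p)
  n <- d[dm]
  out <- -p
  if (n < 2L) return(out)
  idx <- lapply(d, seq_len)
  src <- idx
  idx[[dm]] <- 2:n
  src[[dm]] <- 1:(n - 1L)
  out[idx[[1]], idx[[2]], idx[[3]]] <- out[idx[[1]], idx[[2]], idx[[3]]] +
    p[src[[1]], src[[2]], src[[3]]]
  out
}

.tvNormArray <- function(a, eps) {
  g2 <- .fdiff(a, 1L)^2 + .fdiff(a, 2L)^2 + .fdiff(a, 3L)^2
  sum(sqrt(g2 + eps^2) - eps)
}

.tvGradient <- function(a, eps) {
  d1 <- .fdiff(a, 1L)
  d2 <- .fdiff(a, 2L)
  d3 <- .fdiff(a, 3L)
  den <- sqrt(d1^2 + d2^2 + d3^2 + eps^2)
  den[den < 1e-12] <- 1e-12
  .fdiffT(d1 / den, 1L) + .fdiffT(d2 / den, 2L) + .fdiffT(d3 / den, 3L)
}

#' Isotropic total variation of a volume
#'
#' \eqn{\sum_v \sqrt{\Delta_x^2 + \Delta_y^2 + \Delta_z^2 + \epsilon^2} -
#' \epsilon} with forward differences, one-sided (zero) at the far
#' boundaries. At \code{epsilon = 0} this is the exact isotropic TV norm.
#'
#' @param tomogram a \linkS4class{Tomogram}
#' @param epsilon smoothing constant (default 0)
#' @return nonnegative scalar
#' @export
tvNorm <- function(tomogram, epsilon = 0) {
  stopifnot(is(tomogram, "Tomogram"))
  if (!all(is.finite(tomogram@data)))
    stop("validation error: non-finite volume")
  .tvNormArray(tomogram@data, epsilon)
}

#' Weighted back projection, emitted slice by slice along the tilt axis
#'
#' Per y-slice: the sinogram is ramp-filtered along the detector axis,
#' backprojected with the adjoint operator, and scaled by
#' \eqn{\pi/(2 n_{angles})}. Slices are computed (and optionally published
#' through \code{sliceCallback}) in increasing y, so a live consumer sees the
#' volume grow in one direction.
#'
#' @param series an aligned \linkS4class{TiltSeries}
#' @param config a \linkS4class{SolverConfig} (only \code{wbpWindow} is used)
#' @param sliceShape integer (n_x, n_z); default (n_x, n_x)
#' @param sliceCallback optional \code{function(y, slice)} called after each
#'   slice is reconstructed
#' @return a \linkS4class{Tomogram}
#' @export
wbp <- function(series, config = solverConfig("wbp"), sliceShape = NULL,
                sliceCallback = NULL) {
  stopifnot(is(series, "TiltSeries"))
  g <- .seriesGeom(series, sliceShape)
  if (g$na < 1L) stop("validation error: empty series")
  ps <- series@pixelSizeNm
  op <- projectionOperator(series@anglesDeg, g$sliceShape)
  vol <- array(0, c(g$ny, g$sliceShape))
  scale <- pi / (2 * g$na)
  for (y in seq_len(g$ny)) {
    sino <- sliceSinogram(series, y) / ps
    filt <- rampFilter(sino, config@wbpWindow)
    sl <- .opAdjointSlice(op, filt) * scale
    vol[y, , ] <- sl
    if (!is.null(sliceCallback)) sliceCallback(y, sl)
  }
  tomogram(vol, voxelSizeNm = ps,
           provenance = sprintf("wbp (%s), %d angles", config@wbpWindow, g$na))
}

#' Extend a reconstruction state with newly arrived projections
#'
#' Appending projections enlarges the operator, so the descent parameter must
#' be rescaled: the Lipschitz constant is re-estimated on the enlarged
#' operator (power method warm-started from the stored eigenvector, which
#' guarantees the new estimate is at least the old one) and the step reset to
#' stepSafety / L. The current iterate is kept as a warm start. For WBP the
#' contract is instead full recomputation against all projections.
#'
#' @param state a \linkS4class{ReconState}
#' @param seriesNew a \linkS4class{TiltSeries} whose angles are a superset of
#'   the state's
#' @return the updated \linkS4class{ReconState}
#' @export
extendState <- function(state, seriesNew) {
  stopifnot(is(state, "ReconState"), is(seriesNew, "TiltSeries"))
  newAngles <- seriesNew@anglesDeg
  for (a in state@anglesDeg)
    if (min(abs(newAngles - a)) > .ANGLE_TOL)
      stop("consistency error: previously used projection at ", a,
           " deg is missing from the extended series")
  cfg <- state@config
  if (cfg@algorithm == "wbp") {
    vol <- wbp(seriesNew, cfg, sliceShape = dim(state@x@data)[2:3])
    state@x <- vol
    state@anglesDeg <- newAngles
    state@nProjectionsUsed <- length(newAngles)
    return(state)
  }
  ps <- seriesNew@pixelSizeNm
  op <- projectionOperator(newAngles, dim(state@x@data)[2:3])
  pm <- .powerMethod(op, 50L, 1e-6, cfg@seed, v0 = state@powerVec)
  state@lipschitzL <- pm$L * ps^2
  state@stepSize <- state@stepSafety / state@lipschitzL
  state@powerVec <- pm$vec
  state@anglesDeg <- newAngles
  state@nProjectionsUsed <- length(newAngles)
  validObject(state)
  state
}

#' Write the convergence history of a state to CSV
#'
#' Columns: iteration, n_projections, normalized_residual and (tvmin) tv.
#'
#' @param state a \linkS4class{ReconState}
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeHistoryCsv <- function(state, path) {
  utils::write.csv(reconHistory(state), path, row.names = FALSE)
  invisible(path)
}
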