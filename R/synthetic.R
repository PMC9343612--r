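# Phantoms and simulated acquisition. These are desk-scale surrogates for
# typical specimens: random non-overlapping spheres (piecewise-constant
# density), a chiral helical tube (handedness only resolvable in 3D), a
# periodic lattice of Gaussian blobs (periodicity visible in the FFT), plus
# an impulse and a disc for point-spread and filter checks. Acquisition is
# simulated with a missing wedge, per-projection shift jitter, rotation-axis
# offset and a scaled-Poisson dose model.

#' Default acquisition angles
#'
#' The single-axis acquisition grid used throughout: -64 to +71 degrees
#' inclusive at a 1 degree increment (136 projections, an asymmetric missing
#' wedge).
#'
#' @return numeric vector of 136 angles in degrees
#' @export
defaultAngles <- function() seq(-64, 71, by = 1)

.sphereInto <- function(vol, cy, cx, cz, r, value) {
  d <- dim(vol)
  y2 <- (seq_len(d[1L]) - 1 - cy)^2
  x2 <- (seq_len(d[2L]) - 1 - cx)^2
  z2 <- (seq_len(d[3L]) - 1 - cz)^2
  m <- outer(outer(y2, x2, `+`), z2, `+`) <= r^2
  vol[m] <- value
  vol
}

#' Generate a deterministic phantom volume
#'
#' Kinds: \code{spheres} (random non-overlapping spheres of varying
#' density), \code{helix} (a tube of spheres sweeping a helical path of the
#' requested handedness; mirroring along x flips handedness bitwise),
#' \code{lattice} (periodic Gaussian blobs at \code{periodPx}),
#' \code{impulse} (single center voxel) and \code{disc} (a single-slice
#' centered disc for 2D filter tests). Densities lie in [0, 1].
#'
#' @param kind phantom kind
#' @param size cube edge length in voxels (>= 8); disc gives (1, size, size)
#' @param handedness "right" or "left" (helix only)
#' @param periodPx lattice period in voxels (lattice only)
#' @param seed RNG seed (spheres only)
#' @return a \linkS4class{Tomogram}
#' @export
makePhantom <- function(kind = c("spheres", "helix", "lattice", "impulse",
                                 "disc"),
                        size = 64L, handedness = c("right", "left"),
                        periodPx = 8L, seed = 1L) {
  kind <- match.arg(kind)
  handedness <- match.arg(handedness)
  size <- as.integer(size)
  if (size < 8L) stop("validation error: size must be >= 8")
  c0 <- (size - 1) / 2
  vol <- switch(kind,
    impulse = {
      v <- array(0, c(size, size, size))
      mid <- as.integer(ceiling(size / 2))
      v[mid, mid, mid] <- 1
      v
    },
    disc = {
      v <- array(0, c(1L, size, size))
      x2 <- (seq_len(size) - 1 - c0)^2
      v[1L, , ][outer(x2, x2, `+`) <= (0.35 * size)^2] <- 1
      v
    },
    spheres = .withSeed(seed, {
      v <- array(0, c(size, size, size))
      centers <- NULL
      tries <- 0L
      while ((is.null(centers) || nrow(centers) < 5L) && tries < 200L) {
        tries <- tries + 1L
        r <- stats::runif(1, 0.08, 0.16) * size
        p <- stats::runif(3, 0.25 * size, 0.75 * size)
        ok <- TRUE
        if (!is.null(centers))
          ok <- all(sqrt(colSums((t(centers[, 1:3, drop = FALSE]) - p)^2)) >
                    centers[, 4L] + r + 1)
        if (ok) centers <- rbind(centers, c(p, r))
      }
      dens <- stats::runif(nrow(centers), 0.5, 1)
      for (i in seq_len(nrow(centers)))
        v <- .sphereInto(v, centers[i, 1L], centers[i, 2L], centers[i, 3L],
                         centers[i, 4L], dens[i])
      v
    }),
    helix = {
      v <- array(0, c(size, size, size))
      sgn <- if (handedness == "right") 1 else -1
      R <- 0.28 * size
      rTube <- 0.07 * size
      turns <- 2
      nstep <- 6L * size
      for (i in seq_len(nstep)) {
        t <- (i - 1) / (nstep - 1)
        phi <- 2 * pi * turns * t
        cy <- 0.1 * size + 0.8 * size * t
        cxp <- c0 + sgn * R * cos(phi)
        czp <- c0 + R * sin(phi)
        v <- .sphereInto(v, cy, cxp, czp, rTube, 1)
      }
      v
    },
    lattice = {
      p <- as.integer(periodPx)
      if (p < 2L) stop("validation error: periodPx must be >= 2")
      sigma <- p / 10
      g1 <- function(n) {
        u <- (seq_len(n) - 1) %% p
        dmin <- pmin(abs(u - p / 2), p - abs(u - p / 2))
        # distance to the blob center at p/2 within each period (periodic)
        exp(-(dmin^2) / (2 * sigma^2))
      }
      gy <- g1(size)
      v <- outer(outer(gy, gy), gy)
      v[v < 1e-4] <- 0
      array(v, c(size, size, size))
    })
  tomogram(vol, voxelSizeNm = 1,
           provenance = sprintf("phantom:%s size %d", kind, size))
}

#' Simulate a tilt-series acquisition from a phantom
#'
#' Forward-projects the phantom at the given angles, shifts the rotation
#' axis by \code{axisOffsetPx} (all projections displaced along x), applies
#' per-projection random shifts drawn from Normal(0, shiftSigmaPx), then
#' applies Poisson counting noise with per-pixel expectation
#' \code{dose * I / max(I)} scaled back to the original intensity scale.
#' \code{dose = Inf} means noiseless. Fully seeded and reproducible.
#'
#' @param phantom a \linkS4class{Tomogram}
#' @param anglesDeg projection angles in degrees
#' @param dose expected peak counts per pixel, or Inf for noiseless
#' @param shiftSigmaPx standard deviation of the (dy, dx) jitter in pixels
#' @param axisOffsetPx rotation-axis offset in pixels
#' @param seed RNG seed
#' @return list with elements \code{series} (a \linkS4class{TiltSeries}) and
#'   \code{truth} (list: trueShifts n x 2 matrix of applied (dy, dx),
#'   trueAxisOffsetPx, dose, anglesDeg)
#' @export
simulateSeries <- function(phantom, anglesDeg = defaultAngles(), dose = Inf,
                           shiftSigmaPx = 0, axisOffsetPx = 0, seed = 1L) {
  stopifnot(is(phantom, "Tomogram"))
  if (!(is.infinite(dose) || dose > 0))
    stop("validation error: dose must be positive or infinite")
  if (shiftSigmaPx < 0) stop("validation error: shiftSigmaPx must be >= 0")
  series <- forwardProject(phantom, anglesDeg)
  dat <- series@data
  n <- dim(dat)[1L]
  shifts <- .withSeed(seed, matrix(stats::rnorm(2L * n, 0, shiftSigmaPx), n, 2L,
                                   dimnames = list(NULL, c("dy", "dx"))))
  if (shiftSigmaPx == 0) shifts[] <- 0
  for (a in seq_len(n)) {
    dy <- shifts[a, 1L]
    dx <- shifts[a, 2L] + axisOffsetPx
    if (dy != 0 || dx != 0) dat[a, , ] <- .shiftImage(dat[a, , ], dy, dx)
  }
  if (is.finite(dose)) {
    peak <- max(dat)
    if (peak > 0) {
      scale <- peak / dose
      lam <- pmax(dat, 0) / scale
      counts <- .withSeed(seed + 1L, stats::rpois(length(lam), lam))
      dat <- array(counts * scale, dim(dat))
    }
  }
  out <- tiltSeries(dat, anglesDeg, pixelSizeNm = phantom@voxelSizeNm,
                    isAligned = FALSE)
  list(series = out,
       truth = list(trueShifts = shifts, trueAxisOffsetPx = axisOffsetPx,
                    dose = dose, anglesDeg = sort(as.numeric(anglesDeg))))
}

#' Replay a tilt series into a directory as acquisition would
#'
#' Writes one single-page TIFF per projection (angle-encoded filename
#' \code{proj_NNN_<angle>.tif} with a per-file JSON scale sidecar) plus a
#' sidecar angle list \code{angles.tlt}, pausing \code{intervalS} seconds
#' between files. The dialect is exactly what \code{\link{directoryWatcher}}
#' and \code{\link{readSeries}} consume.
#'
#' @param series a \linkS4class{TiltSeries}
#' @param dir writable output directory (created if missing)
#' @param intervalS pause between files in seconds (0 = all at once)
#' @param shuffle write in random order instead of angle order
#' @param seed RNG seed for the shuffle
#' @return character vector of written TIFF paths (write order)
#' @export
emitToDirectory <- function(series, dir, intervalS = 0, shuffle = FALSE,
                            seed = 1L) {
  stopifnot(is(series, "TiltSeries"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nAngles(series)
  writeLines(sprintf("%.6f", series@anglesDeg), file.path(dir, "angles.tlt"))
  ord <- seq_len(n)
  if (shuffle) ord <- .withSeed(seed, sample(n))
  paths <- character(n)
  for (k in seq_along(ord)) {
    i <- ord[k]
    fname <- sprintf("proj_%03d_%s.tif", i,
                     formatC(series@anglesDeg[i], format = "f", digits = 2))
    path <- file.path(dir, fname)
    .writeScaledTiff(list(series@data[i, , ]), path,
                     meta = list(kind = "projection",
                                 angle_deg = series@anglesDeg[i],
                                 pixel_size_nm = series@pixelSizeNm))
    paths[k] <- path
    if (intervalS > 0 && k < length(ord)) Sys.sleep(intervalS)
  }
  paths
}
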