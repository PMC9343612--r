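# Shared fixtures, all generated in code.

# centered sphere of radius r in a size^3 volume (density 1)
centeredSphere <- function(size, r) {
  c0 <- (size - 1) / 2
  q <- (seq_len(size) - 1 - c0)^2
  v <- array(0, c(size, size, size))
  v[outer(outer(q, q, `+`), q, `+`) <= r^2] <- 1
  tomogram(v)
}

# densely assemble the operator matrix of a slice geometry by probing with
# unit basis vectors (rows: angle-major detector bins; cols: voxels)
denseOperator <- function(op) {
  n <- prod(op@sliceShape)
  A <- matrix(0, length(op@anglesDeg) * op@sliceShape[1L], n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- 1
    A[, j] <- as.numeric(tomostream:::.opForwardSlice(
      op, matrix(e, op@sliceShape[1L], op@sliceShape[2L])))
  }
  A
}

# single-slice (n_y = 1) tilt series from a 2D slice image
sliceSeries <- function(op, slice) {
  s <- tomostream:::.opForwardSlice(op, slice)
  tiltSeries(array(s, c(length(op@anglesDeg), 1L, op@sliceShape[1L])),
             op@anglesDeg)
}

# half-maximum extent of a 1D profile with linear-interpolated crossings
fwhmOf <- function(p) {
  h <- max(p) / 2
  idx <- which(p >= h)
  lo <- min(idx); hi <- max(idx)
  a <- if (lo > 1) lo - (p[lo] - h) / (p[lo] - p[lo - 1]) else lo
  b <- if (hi < length(p)) hi + (p[hi] - h) / (p[hi] - p[hi + 1]) else hi
  b - a
}

# central profile of a volume along x or z, averaged over the 2x2 center
centralProfile <- function(vol, along = c("x", "z")) {
  along <- match.arg(along)
  n <- dim(vol)[1L]
  i <- n / 2; j <- i + 1L
  if (along == "x")
    (vol[i, , i] + vol[j, , j] + vol[i, , j] + vol[j, , i]) / 4
  else
    (vol[i, i, ] + vol[j, j, ] + vol[i, j, ] + vol[j, i, ]) / 4
}

freshDir <- function() {
  d <- tempfile("fix")
  dir.create(d)
  d
}

quantF32 <- function(x) {
  q <- tomostream:::.float32(x)
  if (!is.null(dim(x))) dim(q) <- dim(x)
  q
}
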