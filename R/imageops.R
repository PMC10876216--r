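## Small image-processing primitives shared by the salience channels and
## the Canny edge detector. Frames are numeric matrices [y, x] in [0, 1];
## convolutions use reflective boundary handling.

.reflectPad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(pmin(k:1, nr), seq_len(nr), nr + 1 - pmin(seq_len(k), nr))
  ci <- c(pmin(k:1, nc), seq_len(nc), nc + 1 - pmin(seq_len(k), nc))
  m[ri, ci, drop = FALSE]
}

## separable 1-D convolution along rows then columns
.convSep <- function(m, kRow, kCol = kRow) {
  kr <- (length(kRow) - 1L) %/% 2L
  kc <- (length(kCol) - 1L) %/% 2L
  k <- max(kr, kc)
  p <- .reflectPad(m, k)
  nr <- nrow(m); nc <- ncol(m)
  ## vertical pass (kernel runs over rows = y)
  acc <- matrix(0, nr, nc + 2L * k)
  for (j in seq_along(kCol)) {
    off <- j - 1L - kc
    acc <- acc + kCol[j] * p[(k + 1L + off):(k + nr + off), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(kRow)) {
    off <- j - 1L - kr
    out <- out + kRow[j] * acc[, (k + 1L + off):(k + nc + off), drop = FALSE]
  }
  out
}

.gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

.gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  .convSep(m, .gaussKernel1d(sigma))
}

## full 2-D convolution with a small kernel (used for Gabor filters)
.conv2 <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  k <- max(kr, kc)
  p <- .reflectPad(m, k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * p[(k + i - kr):(k + i - kr + nr - 1L),
                         (k + j - kc):(k + j - kc + nc - 1L), drop = FALSE]
    }
  }
  out
}

## shift an image by (dy, dx) pixels, zero-filling the vacated border
.shiftImage <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  sr <- max(1L, 1L - dy):min(nr, nr - dy)
  sc <- max(1L, 1L - dx):min(nc, nc - dx)
  if (!length(sr) || !length(sc)) return(out)
  out[sr + dy, sc + dx] <- m[sr, sc]
  out
}

## per-frame min-max normalization to [0, 1]; flat maps collapse to 0
.minMax <- function(m, eps = 1e-12) {
  r <- range(m)
  if (r[2L] - r[1L] < eps) return(matrix(0, nrow(m), ncol(m)))
  (m - r[1L]) / (r[2L] - r[1L])
}

## intensity of a frame given either a matrix or an [y, x, 3] RGB array
.intensity <- function(frame) {
  if (length(dim(frame)) == 3L)
    (frame[, , 1L] + frame[, , 2L] + frame[, , 3L]) / 3
  else frame
}

## odd-symmetric + even Gabor energy at one orientation (radians)
.gaborEnergy <- function(m, theta, wavelength = 6, sigma = 2.5, halfSize = 6) {
  g <- seq(-halfSize, halfSize)
  xx <- outer(rep(1, length(g)), g)   # column offsets (x)
  yy <- outer(g, rep(1, length(g)))   # row offsets (y)
  xr <- xx * cos(theta) + yy * sin(theta)
  yr <- -xx * sin(theta) + yy * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / wavelength)
  odd <- env * sin(2 * pi * xr / wavelength)
  even <- even - mean(even)  # zero DC response
  sqrt(.conv2(m, even)^2 + .conv2(m, odd)^2)
}
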