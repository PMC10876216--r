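#' Grid specification over the screen
#'
#' The screen is tiled with square cells (default 4 x 4 px, i.e. a
#' 480 x 300 cell grid for a 1920 x 1200 px screen); densities are stored
#' at cell centers. Sub-fixation spatial precision is dominated by the
#' 100-level quantization of the Proximity Index, so a coarser-than-pixel
#' grid loses nothing.
#'
#' @param geometry a [ScreenGeometry-class]
#' @param cellSizePx cell side length in pixels
#' @return list with \code{xCenters}, \code{yCenters}, \code{cellSizePx}
#' @export
gridSpec <- function(geometry, cellSizePx = 4) {
  nx <- ceiling(geometry@widthPx / cellSizePx)
  ny <- ceiling(geometry@heightPx / cellSizePx)
  list(xCenters = -0.5 + (seq_len(nx) - 0.5) * cellSizePx,
       yCenters = -0.5 + (seq_len(ny) - 0.5) * cellSizePx,
       cellSizePx = cellSizePx)
}

#' Construct a density surface directly from a grid of values
#'
#' Mainly useful for constructing reference surfaces with known analytic
#' structure; [adaptiveKDE()] is the estimation route. The grid is
#' renormalized to integrate to 1 unless \code{normalize = FALSE}.
#'
#' @param grid numeric matrix \code{[y, x]} of nonnegative values
#' @param cellSizePx cell side length in pixels
#' @param xCenters,yCenters cell center coordinates; defaults to a grid
#'   anchored at the screen origin
#' @param nPoints number of points the surface notionally represents; 0
#'   (the default for unnormalized surfaces) waives the unit-integral
#'   invariant
#' @param normalize renormalize to unit discrete integral
#' @return a [DensitySurface-class]
#' @export
densitySurface <- function(grid, cellSizePx = 4, xCenters = NULL,
                           yCenters = NULL,
                           nPoints = if (normalize) 1L else 0L,
                           normalize = TRUE) {
  if (is.null(xCenters))
    xCenters <- -0.5 + (seq_len(ncol(grid)) - 0.5) * cellSizePx
  if (is.null(yCenters))
    yCenters <- -0.5 + (seq_len(nrow(grid)) - 0.5) * cellSizePx
  if (normalize) {
    tot <- sum(grid) * cellSizePx^2
    if (tot <= 0) stop("cannot normalize an all-zero surface")
    grid <- grid / tot
  }
  new("DensitySurface", grid = grid, xCenters = xCenters,
      yCenters = yCenters, cellSizePx = cellSizePx,
      nPoints = as.integer(nPoints))
}

setMethod("show", "DensitySurface", function(object) {
  cat(sprintf(
    "DensitySurface: %d x %d cells (%g px), %d points, max density %.3g\n",
    nrow(object@grid), ncol(object@grid), object@cellSizePx,
    object@nPoints, max(object@grid)))
})

#' Maximum density of a surface
#' @param density a [DensitySurface-class]
#' @return the maximum grid density
#' @export
maxDensity <- function(density) max(density@grid)

#' Adaptive-bandwidth kernel density estimate of gaze on the screen
#'
#' Estimates the gaze probability density on the screen grid from a set of
#' gaze points with Gaussian kernels of per-point adaptive bandwidth.
#' A fixed-bandwidth pilot estimate (Silverman's rule per axis) is evaluated
#' at the data points, and Abramson factors
#' \eqn{\lambda_i = (f_{pilot}(x_i) / g)^{-1/2}} (g the geometric mean of
#' the pilot densities) then widen kernels in sparse regions and sharpen
#' them at tightly packed peaks, so multimodal frames are neither
#' over-smoothed at the modes nor under-smoothed in the tails. Kernels are
#' truncated at the screen bounds and the surface renormalized globally to
#' unit discrete integral.
#'
#' @param points numeric matrix with columns x, y (pixels)
#' @param grid a grid specification from [gridSpec()]
#' @param adaptive use Abramson factors; \code{FALSE} forces all adaptive
#'   factors to 1 (plain fixed-bandwidth KDE)
#' @param bandwidth optional fixed per-axis bandwidth \code{c(hx, hy)}
#'   overriding Silverman's rule
#' @return a [DensitySurface-class]
#' @export
adaptiveKDE <- function(points, grid, adaptive = TRUE, bandwidth = NULL) {
  points <- .asPointMatrix(points)
  n <- nrow(points)
  if (n < 1) stop("density surface undefined: no gaze points")
  h <- if (is.null(bandwidth)) .silvermanBandwidth(points, grid$cellSizePx)
       else rep_len(bandwidth, 2L)
  lambda <- rep(1, n)
  if (adaptive && n > 1) {
    fp <- .kdeAtPoints(points, h)
    fp <- pmax(fp, .Machine$double.xmin)
    g <- exp(mean(log(fp)))
    lambda <- (fp / g)^(-1 / 2)
  }
  ## separable evaluation: grid[y, x] = sum_i Gy[y, i] * Gx[x, i]
  hx <- h[1L] * lambda
  hy <- h[2L] * lambda
  Gx <- stats::dnorm(outer(grid$xCenters, points[, 1L], "-"),
                     sd = rep(hx, each = length(grid$xCenters)))
  Gy <- stats::dnorm(outer(grid$yCenters, points[, 2L], "-"),
                     sd = rep(hy, each = length(grid$yCenters)))
  g <- (Gy %*% t(Gx)) / n
  tot <- sum(g) * grid$cellSizePx^2
  if (tot <= 0) stop("degenerate density: all mass off the grid")
  new("DensitySurface", grid = g / tot, xCenters = grid$xCenters,
      yCenters = grid$yCenters, cellSizePx = grid$cellSizePx,
      nPoints = as.integer(n))
}

.asPointMatrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  storage.mode(points) <- "double"
  points
}

## Silverman's rule of thumb per axis for a 2-D Gaussian kernel:
## h_j = sigma_j * n^(-1/6), floored at one grid cell so the surface stays
## resolvable at the grid spacing even for degenerate tight point sets
.silvermanBandwidth <- function(points, cellSizePx) {
  n <- nrow(points)
  s <- apply(points, 2L, stats::sd)
  s[!is.finite(s) | s <= 0] <- cellSizePx
  pmax(s * n^(-1 / 6), cellSizePx)
}

## fixed-bandwidth pilot KDE evaluated at the data points themselves
.kdeAtPoints <- function(points, h) {
  dx <- outer(points[, 1L], points[, 1L], "-") / h[1L]
  dy <- outer(points[, 2L], points[, 2L], "-") / h[2L]
  rowMeans(exp(-0.5 * (dx^2 + dy^2))) / (2 * pi * h[1L] * h[2L])
}

#' Extract 100 linearly spaced isoline levels from a density surface
#'
#' Levels are \eqn{l_k = k \cdot f_{max} / n_{levels}} for k = 1..100, i.e.
#' each frame's surface is contoured against its own maximum, which is what
#' makes the Proximity Index a per-frame score scaled from 0 to 1.
#'
#' @param density a [DensitySurface-class]
#' @param nLevels number of isolines (the Proximity Index definition uses
#'   100)
#' @return a [ContourLevels-class]
#' @export
levelSets <- function(density, nLevels = 100) {
  m <- max(density@grid)
  if (m <= 0) stop("flat zero surface has no level sets")
  new("ContourLevels", levels = seq_len(nLevels) * m / nLevels, sourceMax = m)
}

setMethod("show", "ContourLevels", function(object) {
  cat(sprintf("ContourLevels: %d levels, %.3g to %.3g\n",
              length(object@levels), object@levels[1L],
              object@levels[length(object@levels)]))
})

#' Bilinear interpolation of a density surface at arbitrary points
#'
#' Coordinates beyond the outermost cell centers are clamped to the edge.
#'
#' @param density a [DensitySurface-class]
#' @param x,y pixel coordinates
#' @return interpolated density values
#' @export
densityAt <- function(density, x, y) {
  .bilinear(density@grid, density@xCenters, density@yCenters, x, y)
}

.bilinear <- function(grid, xc, yc, x, y) {
  nx <- length(xc); ny <- length(yc)
  x <- pmin(pmax(x, xc[1L]), xc[nx])
  y <- pmin(pmax(y, yc[1L]), yc[ny])
  ix <- pmin(pmax(findInterval(x, xc), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(y, yc), 1L), ny - 1L)
  if (nx == 1L) { ix <- 1L; tx <- 0 } else {
    tx <- (x - xc[ix]) / (xc[ix + 1L] - xc[ix])
  }
  if (ny == 1L) { iy <- 1L; ty <- 0 } else {
    ty <- (y - yc[iy]) / (yc[iy + 1L] - yc[iy])
  }
  ix1 <- pmin(ix + 1L, nx); iy1 <- pmin(iy + 1L, ny)
  (1 - ty) * ((1 - tx) * grid[cbind(iy, ix)] + tx * grid[cbind(iy, ix1)]) +
    ty * ((1 - tx) * grid[cbind(iy1, ix)] + tx * grid[cbind(iy1, ix1)])
}
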