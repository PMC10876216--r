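#' Construct a screen geometry
#'
#' Defaults describe a 1920 x 1200 px display subtending 45 deg 53 min
#' horizontally and 29 deg 38 min vertically at a 60 cm viewing distance,
#' refreshing at 60 Hz.
#'
#' @param widthPx,heightPx screen extent in pixels
#' @param widthDeg,heightDeg screen extent in degrees of visual angle
#' @param viewingDistanceCm viewing distance in centimetres
#' @param refreshHz display refresh rate in Hz
#' @return a [ScreenGeometry-class]
#' @examples
#' geom <- screenGeometry()
#' pixelsToDegrees(1200, geom, axis = "y")  # full vertical extent
#' @export
screenGeometry <- function(widthPx = 1920, heightPx = 1200,
                           widthDeg = 45 + 53 / 60, heightDeg = 29 + 38 / 60,
                           viewingDistanceCm = 60, refreshHz = 60) {
  new("ScreenGeometry",
      widthPx = widthPx, heightPx = heightPx,
      widthDeg = widthDeg, heightDeg = heightDeg,
      viewingDistanceCm = viewingDistanceCm, refreshHz = refreshHz)
}

setMethod("show", "ScreenGeometry", function(object) {
  cat(sprintf("ScreenGeometry: %g x %g px (%.2f x %.2f deg) at %g cm, %g Hz\n",
              object@widthPx, object@heightPx, object@widthDeg,
              object@heightDeg, object@viewingDistanceCm, object@refreshHz))
})

## physical centimetres per pixel, derived from the angular extent and
## viewing distance (planar screen model)
.cmPerPx <- function(geometry) {
  d <- geometry@viewingDistanceCm
  c(x = 2 * d * tan(geometry@widthDeg * pi / 360) / geometry@widthPx,
    y = 2 * d * tan(geometry@heightDeg * pi / 360) / geometry@heightPx)
}

#' Convert pixel displacements to degrees of visual angle
#'
#' Uses the planar screen model: a displacement is mapped to physical
#' centimetres on the screen and the subtended angle computed by
#' trigonometry at the configured viewing distance, so the full screen
#' extent maps exactly back to the configured angular extent. The result is
#' odd in its argument (symmetric magnitude in sign).
#'
#' @param dx displacement along x in pixels (or the single-axis displacement
#'   when \code{dy} is omitted)
#' @param geometry a [ScreenGeometry-class]
#' @param dy optional displacement along y in pixels; when given, the
#'   magnitude of the 2-D displacement angle is returned
#' @param axis which axis \code{dx} refers to when \code{dy} is missing
#' @return visual angle in degrees
#' @export
pixelsToDegrees <- function(dx, geometry, dy = NULL, axis = c("x", "y")) {
  if (geometry@viewingDistanceCm <= 0) stop("viewing distance must be positive")
  cpp <- .cmPerPx(geometry)
  d <- geometry@viewingDistanceCm
  if (is.null(dy)) {
    axis <- match.arg(axis)
    cm <- dx * cpp[[axis]]
    sign(cm) * 2 * atan(abs(cm) / (2 * d)) * 180 / pi
  } else {
    cm <- sqrt((dx * cpp[["x"]])^2 + (dy * cpp[["y"]])^2)
    2 * atan(cm / (2 * d)) * 180 / pi
  }
}

#' Convert a visual angle to a pixel displacement along one axis
#'
#' Inverse of [pixelsToDegrees()] for single-axis displacements.
#'
#' @param deg visual angle in degrees
#' @param geometry a [ScreenGeometry-class]
#' @param axis screen axis
#' @return displacement in pixels
#' @export
degreesToPixels <- function(deg, geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  cpp <- .cmPerPx(geometry)
  d <- geometry@viewingDistanceCm
  sign(deg) * 2 * d * tan(abs(deg) * pi / 360) / cpp[[axis]]
}

#' Construct a frame timeline
#'
#' By default a 25 fps video of 173 s (4325 frames), the configuration used
#' for a roughly three-minute animated stimulus; both parameters are free.
#'
#' @param fps frames per second
#' @param nFrames number of frames; computed from \code{duration} if missing
#' @param duration video duration in seconds (ignored when \code{nFrames}
#'   is given)
#' @return a [FrameTimeline-class]
#' @export
frameTimeline <- function(fps = 25, nFrames = NULL, duration = 173) {
  if (is.null(nFrames)) nFrames <- as.integer(round(fps * duration))
  new("FrameTimeline", fps = fps, nFrames = as.integer(nFrames))
}

setMethod("show", "FrameTimeline", function(object) {
  cat(sprintf("FrameTimeline: %d frames at %g fps (%.2f s)\n",
              object@nFrames, object@fps, object@nFrames / object@fps))
})

#' Temporal midpoints of video frames
#'
#' @param timeline a [FrameTimeline-class]
#' @return numeric vector of frame midpoint times in seconds
#' @export
frameMidpoints <- function(timeline) {
  (seq_len(timeline@nFrames) - 0.5) / timeline@fps
}

#' Frame index containing each time point
#'
#' @param t times in seconds
#' @param timeline a [FrameTimeline-class]
#' @return integer frame indices; NA outside the video
#' @export
frameOfTime <- function(t, timeline) {
  f <- floor(t * timeline@fps) + 1L
  f[t < 0 | f > timeline@nFrames] <- NA_integer_
  as.integer(f)
}

#' Number of frames
#' @param timeline a [FrameTimeline-class]
#' @return integer frame count
#' @export
nFrames <- function(timeline) timeline@nFrames
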