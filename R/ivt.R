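#' I-VT velocity-threshold fixation filter
#'
#' Extracts fixations from a gaze recording by the velocity-threshold
#' (I-VT) algorithm: angular gaze velocity is estimated by a centred
#' difference over a short window on the binocular midpoint trace, samples
#' slower than the threshold are grouped into fixations, and adjacent
#' fixations are merged when separated by at most \code{mergeMaxGap} and at
#' most \code{mergeMaxAngle}. Gaps in the trace no longer than
#' \code{mergeMaxGap} are bridged by linear interpolation; longer gaps break
#' the trace into independent segments. Defaults follow the standard
#' parameterisation: 30 deg/s threshold, 20 ms velocity window, 75 ms /
#' 0.5 deg merging.
#'
#' @param recording a [GazeRecording-class]
#' @param velocityThreshold angular velocity threshold in deg/s
#' @param velocityWindow velocity estimation window in seconds
#' @param mergeMaxGap maximum time between merged fixations, seconds
#' @param mergeMaxAngle maximum angular separation of merged fixations,
#'   degrees
#' @param minDuration discard fixations shorter than this many seconds
#'   (0 = keep all, the default)
#' @return data.frame with one row per fixation: \code{onset}, \code{offset},
#'   \code{duration} (s), \code{x}, \code{y} (centroid pixels) and
#'   \code{saccadeAmplitude} (degrees; NA for the first fixation, which has
#'   no preceding saccade)
#' @examples
#' geom <- screenGeometry()
#' t <- seq(0, 1, by = 1 / 300)
#' s <- data.frame(t = t, lx = 960, ly = 600, rx = 960, ry = 600,
#'                 lValid = TRUE, rValid = TRUE)
#' fix <- ivtFixationFilter(gazeRecording(s, geom))
#' nrow(fix)  # 1
#' @export
ivtFixationFilter <- function(recording, velocityThreshold = 30,
                              velocityWindow = 0.020, mergeMaxGap = 0.075,
                              mergeMaxAngle = 0.5, minDuration = 0) {
  geom <- recording@geometry
  tr <- .gazeTrace(recording)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), x = numeric(0), y = numeric(0),
                      saccadeAmplitude = numeric(0))
  if (sum(tr$valid) < 2) {
    warning("fewer than 2 valid samples; no fixations extracted")
    return(empty)
  }
  segs <- .fillGaps(tr, mergeMaxGap)
  fixs <- list()
  for (seg in segs) {
    if (nrow(seg) < 2) next
    v <- .angularVelocity(seg, geom, velocityWindow)
    slow <- v < velocityThreshold
    r <- rle(slow)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      idx <- starts[k]:ends[k]
      fixs[[length(fixs) + 1L]] <- list(
        onset = seg$t[idx[1L]], offset = seg$t[idx[length(idx)]],
        x = mean(seg$x[idx]), y = mean(seg$y[idx]))
    }
  }
  if (!length(fixs)) return(empty)
  fixs <- fixs[order(vapply(fixs, `[[`, numeric(1), "onset"))]
  fixs <- .mergeFixations(fixs, geom, mergeMaxGap, mergeMaxAngle)
  out <- data.frame(
    onset = vapply(fixs, `[[`, numeric(1), "onset"),
    offset = vapply(fixs, `[[`, numeric(1), "offset"),
    x = vapply(fixs, `[[`, numeric(1), "x"),
    y = vapply(fixs, `[[`, numeric(1), "y"))
  out$duration <- out$offset - out$onset
  if (minDuration > 0) out <- out[out$duration >= minDuration, , drop = FALSE]
  n <- nrow(out)
  amp <- rep(NA_real_, n)
  if (n > 1) {
    amp[-1L] <- pixelsToDegrees(diff(out$x), geom, dy = diff(out$y))
  }
  out$saccadeAmplitude <- amp
  rownames(out) <- NULL
  out[, c("onset", "offset", "duration", "x", "y", "saccadeAmplitude")]
}

## Split the trace at gaps longer than maxGap; linearly interpolate
## shorter gaps. Returns a list of gap-free data.frames (t, x, y).
.fillGaps <- function(tr, maxGap) {
  ok <- which(tr$valid)
  if (!length(ok)) return(list())
  tr <- tr[ok[1L]:ok[length(ok)], , drop = FALSE]
  valid <- tr$valid
  breaks <- integer(0)
  vidx <- which(valid)
  if (length(vidx) > 1) {
    gaps <- which(diff(vidx) > 1L)
    for (g in gaps) {
      t0 <- tr$t[vidx[g]]; t1 <- tr$t[vidx[g + 1L]]
      if (t1 - t0 > maxGap) breaks <- c(breaks, vidx[g])
    }
  }
  segBounds <- cbind(c(1L, breaks + 1L), c(breaks, nrow(tr)))
  segs <- list()
  for (i in seq_len(nrow(segBounds))) {
    seg <- tr[segBounds[i, 1L]:segBounds[i, 2L], , drop = FALSE]
    sok <- which(seg$valid)
    if (length(sok) < 2) next
    seg <- seg[sok[1L]:sok[length(sok)], , drop = FALSE]
    if (any(!seg$valid)) {
      seg$x <- stats::approx(seg$t[seg$valid], seg$x[seg$valid],
                             xout = seg$t)$y
      seg$y <- stats::approx(seg$t[seg$valid], seg$y[seg$valid],
                             xout = seg$t)$y
    }
    segs[[length(segs) + 1L]] <- seg[, c("t", "x", "y")]
  }
  segs
}

## Angular velocity per sample: angular distance between the samples half a
## window back and forward, over their time separation. Truncated
## (one-sided) at segment edges.
.angularVelocity <- function(seg, geom, window) {
  n <- nrow(seg)
  half <- window / 2
  i1 <- findInterval(seg$t - half, seg$t, left.open = TRUE) + 1L
  i2 <- findInterval(seg$t + half, seg$t)
  ## guarantee at least adjacent-sample differences when the sampling
  ## interval exceeds the half-window (e.g. 60 Hz trackers)
  idx <- seq_len(n)
  i1 <- pmin(i1, pmax(idx - 1L, 1L))
  i2 <- pmax(i2, pmin(idx + 1L, n))
  same <- i2 <= i1
  dx <- seg$x[i2] - seg$x[i1]
  dy <- seg$y[i2] - seg$y[i1]
  dt <- seg$t[i2] - seg$t[i1]
  v <- ifelse(same | dt <= 0, 0,
              pixelsToDegrees(dx, geom, dy = dy) / dt)
  v
}

.mergeFixations <- function(fixs, geom, maxGap, maxAngle) {
  if (length(fixs) < 2) return(fixs)
  out <- list(fixs[[1L]])
  for (f in fixs[-1L]) {
    last <- out[[length(out)]]
    gap <- f$onset - last$offset
    sep <- pixelsToDegrees(f$x - last$x, geom, dy = f$y - last$y)
    if (gap <= maxGap && sep <= maxAngle) {
      w1 <- last$offset - last$onset
      w2 <- f$offset - f$onset
      w <- if (w1 + w2 > 0) c(w1, w2) / (w1 + w2) else c(0.5, 0.5)
      out[[length(out)]] <- list(
        onset = last$onset, offset = f$offset,
        x = w[1L] * last$x + w[2L] * f$x, y = w[1L] * last$y + w[2L] * f$y)
    } else {
      out[[length(out) + 1L]] <- f
    }
  }
  out
}

#' Screen attendance of a recording
#'
#' Fraction of video frames with at least one binocular-valid sample
#' (both eyes valid and on screen). Recordings below the exclusion
#' threshold (default 65 per cent) are flagged for exclusion.
#'
#' @param recording a [GazeRecording-class]
#' @param timeline a [FrameTimeline-class]
#' @param threshold exclusion threshold on the attendance fraction
#' @return list with \code{fraction} in \code{[0, 1]} and logical
#'   \code{included}
#' @export
screenAttendance <- function(recording, timeline, threshold = 0.65) {
  s <- recording@samples
  bin <- s$lValid & s$rValid
  fr <- frameOfTime(s$t[bin], timeline)
  covered <- unique(fr[!is.na(fr)])
  fraction <- length(covered) / timeline@nFrames
  list(fraction = fraction, included = fraction >= threshold)
}

#' Map fixations onto video frames
#'
#' Each frame receives the centroid of the fixation active at the frame's
#' temporal midpoint; frames overlapped by no fixation (saccades, blinks,
#' off-screen intervals) are missing. Non-fixation data are thereby omitted
#' from all downstream calculations.
#'
#' @param fixations data.frame from [ivtFixationFilter()]
#' @param timeline a [FrameTimeline-class]
#' @return matrix with \code{nFrames} rows and columns \code{x}, \code{y};
#'   NA rows where no fixation covers the frame midpoint
#' @export
mapFixationsToFrames <- function(fixations, timeline) {
  mids <- frameMidpoints(timeline)
  out <- matrix(NA_real_, nrow = timeline@nFrames, ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  if (!nrow(fixations)) return(out)
  idx <- findInterval(mids, fixations$onset)
  hit <- idx >= 1L & mids <= fixations$offset[pmax(idx, 1L)]
  out[hit, "x"] <- fixations$x[idx[hit]]
  out[hit, "y"] <- fixations$y[idx[hit]]
  out
}
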