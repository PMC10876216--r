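#' Proximity Index of one gaze coordinate on one frame
#'
#' The Proximity Index is k/100 where k is the highest of the 100 isoline
#' levels whose threshold the reference density at the gaze coordinate
#' still reaches (ties count as inside), and 0 when the local density falls
#' below the lowest level. A coordinate at the surface's global maximum
#' scores 1; one whose density is half the frame maximum sits on isoline 50
#' and scores 0.50; one outside the level-1 isoline scores 0. With several
#' density peaks the highest containing contour of any peak counts, so
#' equally tall peaks score equally.
#'
#' @param gazeXY numeric length-2 vector (x, y) in pixels
#' @param density a [DensitySurface-class]
#' @param levels a [ContourLevels-class] for that surface
#' @return Proximity Index in \code{{0, 0.01, ..., 1}}
#' @examples
#' g <- matrix(0, 5, 5); g[3, 3] <- 1; g[3, 4] <- 0.5
#' surf <- densitySurface(g, cellSizePx = 1, normalize = FALSE)
#' lv <- levelSets(surf)
#' proximityIndexFrame(c(surf@xCenters[3], surf@yCenters[3]), surf, lv)  # 1
#' @export
proximityIndexFrame <- function(gazeXY, density, levels) {
  f <- densityAt(density, gazeXY[1L], gazeXY[2L])
  sum(f >= levels@levels) / length(levels@levels)
}

#' Score a recording against a reference model
#'
#' Runs the I-VT filter, maps fixations to frames, and computes the
#' Proximity Index on every frame that has both fixated gaze and a usable
#' reference surface. Frames without fixated gaze (saccades, blinks,
#' off-screen moments) and unusable reference frames are excluded from the
#' mean rather than imputed.
#'
#' @param recording a [GazeRecording-class]
#' @param reference a [ReferenceModel-class]
#' @param qcOverride score even when screen attendance is below the
#'   exclusion threshold
#' @param attendanceThreshold attendance exclusion threshold
#' @param frameGaze optional precomputed frame-gaze matrix (skips the
#'   fixation filter)
#' @param ... passed to [ivtFixationFilter()]
#' @return a [PIResult-class]
#' @export
proximityIndexSubject <- function(recording, reference, qcOverride = FALSE,
                                  attendanceThreshold = 0.65,
                                  frameGaze = NULL, ...) {
  timeline <- reference@timeline
  if (!qcOverride) {
    att <- screenAttendance(recording, timeline, attendanceThreshold)
    if (!att$included)
      stop(sprintf(
        "recording '%s' fails attendance QC (%.1f%% < %.0f%%); %s",
        recording@subjectId, 100 * att$fraction, 100 * attendanceThreshold,
        "use qcOverride = TRUE to score anyway"))
  }
  if (is.null(frameGaze))
    frameGaze <- mapFixationsToFrames(ivtFixationFilter(recording, ...),
                                      timeline)
  pi <- rep(NA_real_, timeline@nFrames)
  scoreable <- which(reference@usable & !is.na(frameGaze[, "x"]))
  for (f in scoreable) {
    pi[f] <- proximityIndexFrame(frameGaze[f, ], reference@surfaces[[f]],
                                 reference@levels[[f]])
  }
  if (!length(scoreable))
    stop("no scoreable frames: recording and usable reference never overlap")
  new("PIResult", subjectId = recording@subjectId, perFramePI = pi,
      meanPI = mean(pi[scoreable]), nFramesScored = length(scoreable))
}

setMethod("show", "PIResult", function(object) {
  cat(sprintf("PIResult '%s': mean PI %.3f over %d frames\n",
              object@subjectId, object@meanPI, object@nFramesScored))
})

#' Accessors for Proximity Index results
#'
#' @param result a [PIResult-class]
#' @return \code{meanPI}: the subject's mean Proximity Index;
#'   \code{perFramePI}: the per-frame vector (NA where not scored).
#' @export
meanPI <- function(result) result@meanPI

#' @rdname meanPI
#' @export
perFramePI <- function(result) result@perFramePI

#' Leave-one-out Proximity Index for reference members
#'
#' Each member of the reference group is scored against a reference rebuilt
#' from the remaining members, so reference subjects receive Proximity
#' Index values uncontaminated by their own gaze.
#'
#' @param group list of [GazeRecording-class] objects
#' @param timeline a [FrameTimeline-class]
#' @param minPointsPerFrame,cellSizePx,adaptive passed to [buildReference()]
#' @param ... passed to [ivtFixationFilter()]
#' @return list of [PIResult-class], one per member
#' @export
looProximity <- function(group, timeline, minPointsPerFrame = 10,
                         cellSizePx = 4, adaptive = TRUE, ...) {
  if (length(group) < 3) stop("leave-one-out needs a group of at least 3")
  frameGaze <- lapply(group, function(r)
    mapFixationsToFrames(ivtFixationFilter(r, ...), timeline))
  lapply(seq_along(group), function(i) {
    ref <- buildReference(group[-i], timeline,
                          minPointsPerFrame = minPointsPerFrame,
                          cellSizePx = cellSizePx, adaptive = adaptive,
                          frameGaze = frameGaze[-i])
    proximityIndexSubject(group[[i]], ref, qcOverride = TRUE,
                          frameGaze = frameGaze[[i]])
  })
}

#' Tabulate Proximity Index results
#'
#' @param results list of [PIResult-class]
#' @return data.frame with subjectId, meanPI, nFramesScored
#' @export
piTable <- function(results) {
  data.frame(
    subjectId = vapply(results, function(r) r@subjectId, character(1)),
    meanPI = vapply(results, function(r) r@meanPI, numeric(1)),
    nFramesScored = vapply(results, function(r) r@nFramesScored, integer(1)))
}
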