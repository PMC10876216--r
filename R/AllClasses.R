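#' @import methods
NULL

#' Screen geometry of the eye-tracking display
#'
#' Holds the pixel and angular extent of the stimulus screen together with
#' the viewing distance, and drives all pixel/visual-angle conversions.
#' Defaults correspond to a 1920 x 1200 px display subtending
#' 45 deg 53' x 29 deg 38' at 60 cm.
#'
#' @slot widthPx,heightPx screen extent in pixels
#' @slot widthDeg,heightDeg screen extent in degrees of visual angle
#' @slot viewingDistanceCm viewing distance in centimetres
#' @slot refreshHz display refresh rate in Hz
#' @export
setClass("ScreenGeometry",
  representation(
    widthPx = "numeric", heightPx = "numeric",
    widthDeg = "numeric", heightDeg = "numeric",
    viewingDistanceCm = "numeric", refreshHz = "numeric"
  )
)

setValidity("ScreenGeometry", function(object) {
  v <- c(object@widthPx, object@heightPx, object@widthDeg, object@heightDeg,
         object@viewingDistanceCm, object@refreshHz)
  if (length(v) != 6L || any(!is.finite(v)) || any(v <= 0))
    return("all geometry fields must be single positive finite numbers")
  TRUE
})

#' Frame timeline of the stimulus video
#'
#' @slot fps frames per second
#' @slot nFrames number of frames
#' @export
setClass("FrameTimeline", representation(fps = "numeric", nFrames = "integer"))

setValidity("FrameTimeline", function(object) {
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  if (length(object@nFrames) != 1L || object@nFrames < 1L)
    return("nFrames must be a single positive integer")
  TRUE
})

#' A single subject/visit gaze recording
#'
#' Stores the raw binocular sample stream together with subject metadata and
#' the screen geometry. Samples are one row per sample with columns
#' \code{t} (seconds from stimulus onset), \code{lx, ly, rx, ry} (pixel
#' coordinates per eye, 0-based, origin top-left, y down) and logical
#' validity flags \code{lValid, rValid}. Off-screen coordinates are retained
#' but flagged invalid.
#'
#' @slot subjectId character subject identifier
#' @slot group group label, typically \code{"reference"} or \code{"test"}
#' @slot ageYears age at recording in years
#' @slot samplingHz nominal sampling rate in Hz
#' @slot samples data.frame of samples (see Description)
#' @slot geometry a [ScreenGeometry-class]
#' @export
setClass("GazeRecording",
  representation(
    subjectId = "character", group = "character", ageYears = "numeric",
    samplingHz = "numeric", samples = "data.frame", geometry = "ScreenGeometry"
  )
)

setValidity("GazeRecording", function(object) {
  s <- object@samples
  need <- c("t", "lx", "ly", "rx", "ry", "lValid", "rValid")
  if (!all(need %in% names(s)))
    return(paste("samples must contain columns:", paste(need, collapse = ", ")))
  if (nrow(s) && any(s$t < 0)) return("sample times must be nonnegative")
  if (nrow(s) > 1 && any(diff(s$t) < 0))
    return("sample times must be monotone nondecreasing")
  if (length(object@samplingHz) != 1L || object@samplingHz <= 0)
    return("samplingHz must be a single positive number")
  TRUE
})

#' Gaze density surface over the screen grid
#'
#' A discretized probability density of gaze over the screen, stored as a
#' matrix with rows indexing y cells (top to bottom) and columns indexing x
#' cells. The discrete integral \code{sum(grid) * cellSizePx^2} equals 1
#' (within 1e-3) whenever the surface was estimated from at least one point.
#'
#' @slot grid numeric matrix of density values, \code{[y, x]}
#' @slot xCenters,yCenters pixel coordinates of cell centers
#' @slot cellSizePx side length of one grid cell in pixels
#' @slot nPoints number of gaze points the surface was estimated from
#' @export
setClass("DensitySurface",
  representation(
    grid = "matrix", xCenters = "numeric", yCenters = "numeric",
    cellSizePx = "numeric", nPoints = "integer"
  )
)

setValidity("DensitySurface", function(object) {
  g <- object@grid
  if (nrow(g) != length(object@yCenters) || ncol(g) != length(object@xCenters))
    return("grid dimensions must match yCenters (rows) and xCenters (columns)")
  if (any(g < 0)) return("density values must be nonnegative")
  if (object@nPoints >= 1L) {
    tot <- sum(g) * object@cellSizePx^2
    if (abs(tot - 1) > 1e-3)
      return(sprintf("discrete integral is %.6f, must be 1 within 1e-3", tot))
  }
  TRUE
})

#' Isoline levels of a density surface
#'
#' Exactly 100 strictly increasing density thresholds, linearly spaced from
#' \code{sourceMax/100} up to \code{sourceMax}, the frame's own density
#' maximum. Level k is the threshold of isoline k; the Proximity Index of a
#' gaze coordinate is k/100 for the highest k whose threshold the local
#' density still reaches.
#'
#' @slot levels ascending numeric vector of length 100
#' @slot sourceMax the density maximum the levels were derived from
#' @export
setClass("ContourLevels",
  representation(levels = "numeric", sourceMax = "numeric")
)

setValidity("ContourLevels", function(object) {
  if (length(object@levels) != 100L) return("exactly 100 levels are required")
  if (any(diff(object@levels) <= 0)) return("levels must be strictly increasing")
  if (object@levels[100L] > object@sourceMax * (1 + 1e-12))
    return("highest level must not exceed sourceMax")
  TRUE
})

#' Frame-wise referent gaze distribution
#'
#' Per-frame density surfaces with their 100-level isoline structure, built
#' from a reference group of recordings. Frames whose pooled reference point
#' count falls below a minimum are flagged unusable and yield missing
#' Proximity Index values.
#'
#' @slot surfaces list of [DensitySurface-class] (or NULL where unusable)
#' @slot levels list of [ContourLevels-class] (or NULL where unusable)
#' @slot pointCounts integer vector, pooled reference points per frame
#' @slot usable logical vector, one per frame
#' @slot members character vector of reference subject ids
#' @slot timeline a [FrameTimeline-class]
#' @export
setClass("ReferenceModel",
  representation(
    surfaces = "list", levels = "list", pointCounts = "integer",
    usable = "logical", members = "character", timeline = "FrameTimeline"
  )
)

setValidity("ReferenceModel", function(object) {
  n <- object@timeline@nFrames
  if (length(object@surfaces) != n || length(object@levels) != n ||
      length(object@pointCounts) != n || length(object@usable) != n)
    return("per-frame slots must all have timeline length")
  TRUE
})

#' Proximity Index result for one recording
#'
#' @slot subjectId subject identifier
#' @slot perFramePI numeric vector over frames; values on the 0.01 grid in
#'   \code{[0, 1]}, NA where the frame had no fixated gaze or no usable
#'   reference
#' @slot meanPI mean over non-missing frames
#' @slot nFramesScored number of non-missing frames
#' @export
setClass("PIResult",
  representation(
    subjectId = "character", perFramePI = "numeric",
    meanPI = "numeric", nFramesScored = "integer"
  )
)

setValidity("PIResult", function(object) {
  p <- object@perFramePI[!is.na(object@perFramePI)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    return("Proximity Index values must lie in [0, 1]")
  if (length(p) && any(abs(p * 100 - round(p * 100)) > 1e-9))
    return("Proximity Index values must lie on the 0.01 grid")
  TRUE
})

#' Partial least squares correlation result
#'
#' Result of decomposing the cross-correlation matrix R = t(B) A of two
#' z-scored data blocks by SVD, with permutation p-values per component and
#' bootstrap percentile intervals per salience loading.
#'
#' @slot u behavioural (B-side) saliences, columns are components
#' @slot v A-side saliences
#' @slot singularValues singular values of R
#' @slot latentCorrelations correlation of the paired latent scores per
#'   component
#' @slot scoresA,scoresB latent scores La = A v and Lb = B u
#' @slot permP permutation p-value per component
#' @slot bootLowerU,bootUpperU,bootLowerV,bootUpperV 5th/95th bootstrap
#'   percentiles per loading
#' @slot stableU,stableV logical; TRUE where the bootstrap interval excludes 0
#' @slot nPerm,nBoot resampling sizes used
#' @export
setClass("PLSCResult",
  representation(
    u = "matrix", v = "matrix", singularValues = "numeric",
    latentCorrelations = "numeric", scoresA = "matrix", scoresB = "matrix",
    permP = "numeric", bootLowerU = "matrix", bootUpperU = "matrix",
    bootLowerV = "matrix", bootUpperV = "matrix",
    stableU = "matrix", stableV = "matrix",
    nPerm = "integer", nBoot = "integer"
  )
)

#' Age-ordered sliding windows over a cohort
#'
#' @slot windows list of integer vectors indexing rows of \code{meta}
#' @slot meta age-sorted data.frame of recording metadata
#'   (recordingId, subjectId, ageYears, ...)
#' @slot sourceOrder integer vector mapping rows of \code{meta} back to the
#'   rows of the data.frame the windows were built from
#' @slot meanAge mean age per retained window
#' @slot skipped data.frame logging windows dropped by the
#'   subject-uniqueness rule
#' @slot width,step window construction parameters
#' @export
setClass("WindowSet",
  representation(
    windows = "list", meta = "data.frame", sourceOrder = "integer",
    meanAge = "numeric", skipped = "data.frame", width = "integer",
    step = "integer"
  )
)

#' Per-frame salience channel maps
#'
#' @slot channels named list; each element a list of per-frame matrices in
#'   \code{[0, 1]} for one channel (intensity, color, orientation, flicker,
#'   motion)
#' @slot full per-frame full-model maps (weighted mean of channels)
#' @slot nFrames number of frames
#' @export
setClass("SalienceStack",
  representation(channels = "list", full = "list", nFrames = "integer")
)

#' Scripted scene ground truth for the synthetic generator
#'
#' @slot nFrames,fps timeline of the scripted video
#' @slot foci list of per-frame matrices with columns x, y, weight
#'   (weights sum to 1 per frame)
#' @slot cutFrames frames that open a new shot (hard cuts)
#' @slot characterCount animate characters visible per frame (0-3)
#' @slot speech data.frame(label, onset, offset) of vocalisation intervals
#' @slot movingBackground logical per frame
#' @slot geometry screen geometry gaze is scripted in
#' @export
setClass("SceneScript",
  representation(
    nFrames = "integer", fps = "numeric", foci = "list",
    cutFrames = "integer", characterCount = "integer",
    speech = "data.frame", movingBackground = "logical",
    geometry = "ScreenGeometry"
  )
)

#' Cohort specification for the synthetic gaze generator
#'
#' @slot nSubjects subjects in the group
#' @slot group group label attached to the recordings
#' @slot ageRange range (years) base ages are drawn from
#' @slot visitsPerSubject longitudinal visits, spaced one year apart
#' @slot onScriptProb probability a dwell targets a scripted focus
#' @slot noiseSdPx gaze noise sd around the focus, pixels, at \code{ageRef}
#' @slot noiseAgeSlope change of noise sd per year of age (px/year)
#' @slot ageRef age (years) at which noiseSdPx applies
#' @slot idiosyncraticProb unused dwell mass goes to a subject-persistent
#'   idiosyncratic focus with this probability (complement of onScriptProb
#'   by default)
#' @slot dropoutRate fraction of recording time lost to blink gaps
#' @slot samplingHz tracker sampling rate
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer", group = "character", ageRange = "numeric",
    visitsPerSubject = "integer", onScriptProb = "numeric",
    noiseSdPx = "numeric", noiseAgeSlope = "numeric", ageRef = "numeric",
    idiosyncraticProb = "numeric", dropoutRate = "numeric",
    samplingHz = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  pr <- c(object@onScriptProb, object@idiosyncraticProb, object@dropoutRate)
  if (any(pr < 0) || any(pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@noiseSdPx <= 0) return("noiseSdPx must be positive")
  if (object@nSubjects < 1L) return("nSubjects must be at least 1")
  TRUE
})
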