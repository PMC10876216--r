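#' Age-ordered sliding windows over a cohort of recordings
#'
#' Sorts recordings by age, then slides a window of \code{width}
#' recordings forward by \code{step}; windows containing more than one
#' recording from the same subject are skipped (and logged), so each
#' retained window holds \code{width} distinct subjects. Build one
#' WindowSet per group and pair windows by index for group comparisons;
#' the per-window mean ages let users verify age matching.
#'
#' @param meta data.frame with at least \code{subjectId} and
#'   \code{ageYears}; one row per recording
#' @param width window size in recordings
#' @param step advance between consecutive windows
#' @return a [WindowSet-class]
#' @export
slidingWindows <- function(meta, width = 20, step = 1) {
  if (nrow(meta) < width)
    stop("window width exceeds the number of recordings")
  ord <- order(meta$ageYears)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  starts <- seq(1L, nrow(meta) - width + 1L, by = step)
  wins <- list()
  skipped <- list()
  for (s in starts) {
    idx <- s:(s + width - 1L)
    dup <- duplicated(meta$subjectId[idx])
    if (any(dup)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        start = s,
        repeatedSubject = meta$subjectId[idx][dup][1L])
    } else {
      wins[[length(wins) + 1L]] <- idx
    }
  }
  new("WindowSet",
      windows = wins, meta = meta, sourceOrder = as.integer(ord),
      meanAge = vapply(wins, function(i) mean(meta$ageYears[i]), numeric(1)),
      skipped = if (length(skipped)) do.call(rbind, skipped)
                else data.frame(start = integer(0),
                                repeatedSubject = character(0)),
      width = as.integer(width), step = as.integer(step))
}

setMethod("show", "WindowSet", function(object) {
  cat(sprintf(
    "WindowSet: %d windows of %d recordings (step %d), %d skipped; mean ages %.2f-%.2f y\n",
    length(object@windows), object@width, object@step, nrow(object@skipped),
    if (length(object@meanAge)) min(object@meanAge) else NA,
    if (length(object@meanAge)) max(object@meanAge) else NA))
})

#' @describeIn slidingWindows number of retained windows
#' @param x a [WindowSet-class]
#' @export
setMethod("length", "WindowSet", function(x) length(x@windows))

#' Gaze dispersion: mean pairwise distance per frame
#'
#' Dispersion of a pooled group of recordings on one frame is the mean
#' pairwise Euclidean distance between all gaze coordinates present on
#' that frame; the group-level value is the mean over frames contributing
#' at least two points. Dispersion is translation- and rotation-invariant
#' and scales linearly with the coordinates.
#'
#' @param frameGazeList list of per-recording frame-gaze matrices (rows =
#'   frames, columns x, y, as from [mapFixationsToFrames()])
#' @return list with \code{perFrame} (numeric vector, NA where fewer than
#'   2 points) and \code{mean}
#' @export
dispersion <- function(frameGazeList) {
  X <- vapply(frameGazeList, function(m) m[, "x"],
              numeric(nrow(frameGazeList[[1L]])))
  Y <- vapply(frameGazeList, function(m) m[, "y"],
              numeric(nrow(frameGazeList[[1L]])))
  if (is.null(dim(X))) { X <- matrix(X, 1L); Y <- matrix(Y, 1L) }
  perFrame <- .dispersionPerFrame(X, Y)
  if (all(is.na(perFrame)))
    stop("no frame carries at least 2 gaze points")
  list(perFrame = perFrame, mean = mean(perFrame, na.rm = TRUE))
}

## X, Y: frames x recordings coordinate matrices
.dispersionPerFrame <- function(X, Y) {
  vapply(seq_len(nrow(X)), function(f) {
    ok <- !is.na(X[f, ]) & !is.na(Y[f, ])
    if (sum(ok) < 2) return(NA_real_)
    mean(stats::dist(cbind(X[f, ok], Y[f, ok])))
  }, numeric(1))
}

.windowDispersion <- function(X, Y, cols) {
  mean(.dispersionPerFrame(X[, cols, drop = FALSE],
                           Y[, cols, drop = FALSE]), na.rm = TRUE)
}

#' Permutation test of a group dispersion difference in one window
#'
#' Tests H0: disp(A) - disp(B) = 0 for two age-matched windows by randomly
#' reassigning the windows' individuals to two groups of the original
#' sizes and recomputing the statistic; the two-sided p-value uses the +1
#' correction, so it is never exactly zero.
#'
#' @param frameGazeA,frameGazeB lists of per-recording frame-gaze matrices
#'   for the two windows (same frame count)
#' @param nPerm number of permutations
#' @param seed integer seed
#' @param alpha significance level for the flag
#' @return list with \code{dispA}, \code{dispB}, \code{statistic}
#'   (dispA - dispB), \code{p} and logical \code{significant}
#' @export
dispersionPermutationTest <- function(frameGazeA, frameGazeB, nPerm = 100,
                                      seed = 1, alpha = 0.05) {
  set.seed(seed)
  nA <- length(frameGazeA); nB <- length(frameGazeB)
  if (nA < 2 || nB < 2) stop("each window needs at least 2 recordings")
  all <- c(frameGazeA, frameGazeB)
  nf <- nrow(all[[1L]])
  X <- vapply(all, function(m) m[, "x"], numeric(nf))
  Y <- vapply(all, function(m) m[, "y"], numeric(nf))
  obs <- .windowDispersion(X, Y, seq_len(nA)) -
    .windowDispersion(X, Y, nA + seq_len(nB))
  null <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    perm <- sample(nA + nB)
    null[i] <- .windowDispersion(X, Y, perm[seq_len(nA)]) -
      .windowDispersion(X, Y, perm[nA + seq_len(nB)])
  }
  p <- (1 + sum(abs(null) >= abs(obs))) / (nPerm + 1)
  list(dispA = .windowDispersion(X, Y, seq_len(nA)),
       dispB = .windowDispersion(X, Y, nA + seq_len(nB)),
       statistic = obs, p = p, significant = p <= alpha)
}

#' Sliding-window dispersion trajectories for two groups
#'
#' Runs [dispersionPermutationTest()] on index-paired windows of two
#' WindowSets, given each recording's frame-gaze matrix.
#'
#' @param windowsA,windowsB [WindowSet-class] objects (one per group)
#' @param frameGazeA,frameGazeB lists of frame-gaze matrices indexed like
#'   the rows of the metadata each WindowSet was built from
#' @param nPerm permutations per window
#' @param seed integer seed
#' @param alpha significance level
#' @return data.frame with one row per paired window: window, meanAgeA,
#'   meanAgeB, dispA, dispB, statistic, p, significant
#' @export
dispersionTrajectory <- function(windowsA, windowsB, frameGazeA, frameGazeB,
                                 nPerm = 100, seed = 1, alpha = 0.05) {
  nW <- min(length(windowsA@windows), length(windowsB@windows))
  out <- vector("list", nW)
  for (w in seq_len(nW)) {
    res <- dispersionPermutationTest(
      frameGazeA[windowsA@sourceOrder[windowsA@windows[[w]]]],
      frameGazeB[windowsB@sourceOrder[windowsB@windows[[w]]]],
      nPerm = nPerm, seed = seed + w, alpha = alpha)
    out[[w]] <- data.frame(
      window = w,
      meanAgeA = windowsA@meanAge[w], meanAgeB = windowsB@meanAge[w],
      dispA = res$dispA, dispB = res$dispB,
      statistic = res$statistic, p = res$p, significant = res$significant)
  }
  do.call(rbind, out)
}
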