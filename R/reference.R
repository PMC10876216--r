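#' Build the frame-wise referent gaze distribution
#'
#' Pools, per video frame, the fixation-mapped gaze points of all reference
#' recordings and fits an adaptive-bandwidth KDE plus its 100-level isoline
#' structure on each frame. Frames with fewer pooled points than
#' \code{minPointsPerFrame} are flagged unusable and yield missing Proximity
#' Index values downstream.
#'
#' @param group list of [GazeRecording-class] objects (the reference group)
#' @param timeline a [FrameTimeline-class]
#' @param minPointsPerFrame minimum pooled reference points per frame
#' @param cellSizePx density grid cell size in pixels
#' @param adaptive use adaptive (Abramson) bandwidths
#' @param nLevels number of isolines per frame
#' @param frameGaze optional precomputed list of per-recording frame-gaze
#'   matrices (as from [mapFixationsToFrames()]); skips fixation filtering
#' @param ... further arguments to [ivtFixationFilter()]
#' @return a [ReferenceModel-class]
#' @export
buildReference <- function(group, timeline, minPointsPerFrame = 10,
                           cellSizePx = 4, adaptive = TRUE, nLevels = 100,
                           frameGaze = NULL, ...) {
  if (!length(group)) stop("reference group is empty")
  if (length(group) < 2) stop("at least 2 reference recordings are required")
  if (is.null(frameGaze))
    frameGaze <- lapply(group, function(r)
      mapFixationsToFrames(ivtFixationFilter(r, ...), timeline))
  grid <- gridSpec(group[[1L]]@geometry, cellSizePx)
  nf <- timeline@nFrames
  xs <- vapply(frameGaze, function(m) m[, "x"], numeric(nf))
  ys <- vapply(frameGaze, function(m) m[, "y"], numeric(nf))
  if (nf == 1L) { xs <- matrix(xs, 1L); ys <- matrix(ys, 1L) }
  surfaces <- vector("list", nf)
  levels <- vector("list", nf)
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    ok <- !is.na(xs[f, ]) & !is.na(ys[f, ])
    counts[f] <- sum(ok)
    if (counts[f] >= minPointsPerFrame) {
      surf <- adaptiveKDE(cbind(xs[f, ok], ys[f, ok]), grid,
                          adaptive = adaptive)
      surfaces[[f]] <- surf
      levels[[f]] <- levelSets(surf, nLevels)
    }
  }
  new("ReferenceModel", surfaces = surfaces, levels = levels,
      pointCounts = counts, usable = counts >= minPointsPerFrame,
      members = vapply(group, subjectId, character(1)),
      timeline = timeline)
}

setMethod("show", "ReferenceModel", function(object) {
  cat(sprintf(
    "ReferenceModel: %d members, %d/%d usable frames (median %d points)\n",
    length(object@members), sum(object@usable), length(object@usable),
    as.integer(stats::median(object@pointCounts))))
})

#' Accessors for reference models
#'
#' @param reference a [ReferenceModel-class]
#' @return \code{usableFrames}: logical vector over frames;
#'   \code{referenceMembers}: character vector of member subject ids.
#' @export
usableFrames <- function(reference) reference@usable

#' @rdname usableFrames
#' @export
referenceMembers <- function(reference) reference@members

#' Serialize a reference model to a directory
#'
#' Writes one CSV of density values per usable frame plus a JSON manifest
#' (grid geometry, membership, per-frame counts and flags).
#'
#' @param reference a [ReferenceModel-class]
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeReference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  first <- which(reference@usable)[1L]
  manifest <- list(
    members = reference@members,
    nFrames = reference@timeline@nFrames,
    fps = reference@timeline@fps,
    pointCounts = reference@pointCounts,
    usable = reference@usable,
    cellSizePx = if (!is.na(first)) reference@surfaces[[first]]@cellSizePx
                 else NA
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in which(reference@usable)) {
    utils::write.csv(reference@surfaces[[f]]@grid,
                     file.path(dir, sprintf("frame_%05d.csv", f)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a serialized reference model
#'
#' @param dir directory written by [writeReference()]
#' @return a [ReferenceModel-class]
#' @export
readReference <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  nf <- manifest$nFrames
  surfaces <- vector("list", nf)
  levels <- vector("list", nf)
  for (f in which(manifest$usable)) {
    g <- as.matrix(utils::read.csv(file.path(dir,
                                             sprintf("frame_%05d.csv", f))))
    dimnames(g) <- NULL
    surf <- densitySurface(g, cellSizePx = manifest$cellSizePx,
                           nPoints = manifest$pointCounts[f],
                           normalize = FALSE)
    surfaces[[f]] <- surf
    levels[[f]] <- levelSets(surf)
  }
  new("ReferenceModel", surfaces = surfaces, levels = levels,
      pointCounts = as.integer(manifest$pointCounts),
      usable = manifest$usable, members = manifest$members,
      timeline = frameTimeline(fps = manifest$fps, nFrames = nf))
}

#' Stability of the reference under subsampling
#'
#' For each candidate reference size, bootstrap subsamples of the reference
#' group define sub-references; a held-out probe set is scored against each
#' sub-reference and against the full reference, and agreement is the
#' Pearson correlation of the two mean-PI vectors. The curve is summarized
#' by the smallest size whose mean agreement reaches \code{threshold}.
#'
#' @param group list of reference [GazeRecording-class] objects
#' @param probe list of held-out probe recordings (scored, never pooled)
#' @param timeline a [FrameTimeline-class]
#' @param sizes integer vector of subsample sizes (each < length(group))
#' @param nBoot bootstrap subsamples per size
#' @param threshold agreement level defining stability
#' @param seed integer seed for reproducible subsampling
#' @param ... passed to [buildReference()]
#' @return list with \code{curve} (data.frame size, meanAgreement) and
#'   \code{smallestStableSize} (NA when no size reaches the threshold)
#' @export
referenceStability <- function(group, probe, timeline, sizes,
                               nBoot = 20, threshold = 0.95, seed = 1, ...) {
  if (any(sizes < 2)) stop("subsample sizes must be at least 2")
  if (any(sizes > length(group))) stop("sizes must not exceed group size")
  set.seed(seed)
  probeGaze <- lapply(probe, function(r)
    mapFixationsToFrames(ivtFixationFilter(r), timeline))
  groupGaze <- lapply(group, function(r)
    mapFixationsToFrames(ivtFixationFilter(r), timeline))
  full <- buildReference(group, timeline, frameGaze = groupGaze, ...)
  fullPI <- vapply(seq_along(probe), function(i)
    proximityIndexSubject(probe[[i]], full, frameGaze = probeGaze[[i]],
                          qcOverride = TRUE)@meanPI, numeric(1))
  curve <- data.frame(size = sizes, meanAgreement = NA_real_)
  for (si in seq_along(sizes)) {
    agr <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample(length(group), sizes[si])
      sub <- buildReference(group[idx], timeline,
                            frameGaze = groupGaze[idx], ...)
      subPI <- vapply(seq_along(probe), function(i)
        proximityIndexSubject(probe[[i]], sub, frameGaze = probeGaze[[i]],
                              qcOverride = TRUE)@meanPI, numeric(1))
      agr[b] <- if (stats::sd(subPI) > 0 && stats::sd(fullPI) > 0)
        stats::cor(subPI, fullPI) else NA_real_
    }
    curve$meanAgreement[si] <- mean(agr, na.rm = TRUE)
  }
  ok <- which(curve$meanAgreement >= threshold)
  list(curve = curve,
       smallestStableSize = if (length(ok)) min(curve$size[ok]) else NA)
}
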