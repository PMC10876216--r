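#' Compute bottom-up salience channel maps for a frame stack
#'
#' A simplified multi-channel conspicuity pipeline in the classic
#' center-surround style: intensity and color-opponency (red/green and
#' blue/yellow) contrast from differences of Gaussian-blurred images at two
#' scale pairs, orientation energy from Gabor filters at 0, 45, 90 and 135
#' degrees, flicker as the absolute intensity difference between successive
#' frames, and directional motion energy (up, down, left, right) from
#' shifted-frame correlation. Each channel map is summed across scales and
#' min-max normalized per frame; the full map is the (weighted) mean of the
#' requested channels. Graph-based activation/normalization schemes are not
#' reimplemented; externally computed map stacks can be evaluated directly
#' with [salienceAUC()].
#'
#' @param frames list of frames, each a numeric matrix \code{[y, x]} in
#'   \code{[0, 1]} or an \code{[y, x, 3]} RGB array
#' @param channels character subset of
#'   \code{c("intensity", "color", "orientation", "flicker", "motion")}
#' @param weights optional named channel weights for the full map
#'   (default equal)
#' @param centerSigma,surroundSigma Gaussian scales of the two
#'   center-surround pairs
#' @param motionShiftPx pixel shift probed by the motion detectors
#' @return a [SalienceStack-class]
#' @export
computeChannels <- function(frames,
                            channels = c("intensity", "color", "orientation",
                                         "flicker", "motion"),
                            weights = NULL,
                            centerSigma = c(1, 2), surroundSigma = c(4, 8),
                            motionShiftPx = 8) {
  channels <- match.arg(channels, several.ok = TRUE)
  nf <- length(frames)
  if (nf < 1) stop("no frames supplied")
  if (any(c("flicker", "motion") %in% channels) && nf < 2)
    stop("flicker and motion channels require at least 2 frames")
  ints <- lapply(frames, .intensity)
  maps <- list()
  for (ch in channels) {
    maps[[ch]] <- switch(ch,
      intensity = lapply(ints, function(I)
        .minMax(.centerSurround(I, centerSigma, surroundSigma))),
      color = lapply(frames, function(fr)
        .minMax(.colorChannel(fr, centerSigma, surroundSigma))),
      orientation = lapply(ints, function(I)
        .minMax(Reduce(`+`, lapply(c(0, 45, 90, 135) * pi / 180,
                                   function(th) .gaborEnergy(I, th))))),
      flicker = c(list(matrix(0, nrow(ints[[1L]]), ncol(ints[[1L]]))),
                  lapply(seq_len(nf - 1L), function(f)
                    .minMax(abs(ints[[f + 1L]] - ints[[f]])))),
      motion = c(list(matrix(0, nrow(ints[[1L]]), ncol(ints[[1L]]))),
                 lapply(seq_len(nf - 1L), function(f)
                   .minMax(Reduce(`+`, .motionEnergies(
                     ints[[f + 1L]], ints[[f]], motionShiftPx)))))
    )
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(channels)),
                                                   channels)
  w <- weights[channels] / sum(weights[channels])
  full <- lapply(seq_len(nf), function(f)
    Reduce(`+`, Map(function(ch, wi) wi * maps[[ch]][[f]], channels, w)))
  new("SalienceStack", channels = maps, full = full, nFrames = as.integer(nf))
}

.centerSurround <- function(I, centerSigma, surroundSigma) {
  Reduce(`+`, Map(function(sc, ss)
    abs(.gaussianBlur(I, sc) - .gaussianBlur(I, ss)),
    centerSigma, surroundSigma))
}

.colorChannel <- function(frame, centerSigma, surroundSigma) {
  if (length(dim(frame)) != 3L)
    return(matrix(0, nrow(frame), ncol(frame)))
  R <- frame[, , 1L]; G <- frame[, , 2L]; B <- frame[, , 3L]
  rg <- R - G
  by <- B - (R + G) / 2
  .centerSurround(rg, centerSigma, surroundSigma) +
    .centerSurround(by, centerSigma, surroundSigma)
}

## directional motion energy: current-frame content that aligns with the
## previous frame shifted along the direction, in excess of the static
## alignment (Reichardt-style correlation)
.motionEnergies <- function(cur, prev, shift) {
  static <- cur * prev
  dirs <- list(right = c(0L, shift), left = c(0L, -shift),
               down = c(shift, 0L), up = c(-shift, 0L))
  lapply(dirs, function(d)
    pmax(cur * .shiftImage(prev, d[1L], d[2L]) - static, 0))
}

#' Directional motion energy maps between two frames
#'
#' @param current,previous intensity matrices
#' @param shift probe shift in pixels
#' @return named list of maps (right, left, down, up)
#' @export
motionEnergy <- function(current, previous, shift = 8) {
  .motionEnergies(.intensity(current), .intensity(previous), shift)
}

setMethod("show", "SalienceStack", function(object) {
  cat(sprintf("SalienceStack: %d frames, channels: %s\n", object@nFrames,
              paste(names(object@channels), collapse = ", ")))
})

#' Accessors for salience stacks
#'
#' @param stack a [SalienceStack-class]
#' @param channel channel name, or \code{"full"}
#' @return list of per-frame maps
#' @export
salienceMaps <- function(stack, channel = "full") {
  if (channel == "full") stack@full else stack@channels[[channel]]
}

#' ROC AUC of a salience map against fixated locations
#'
#' Positives are the map values at the fixated pixels; negatives default to
#' all pixels of the frame grid (a uniform non-fixated baseline), or to an
#' explicitly supplied set of negative locations (e.g. fixations shuffled
#' across frames). The AUC is computed by the rank (Mann-Whitney)
#' formulation with mid-ranks, so a constant map scores 0.5 by convention
#' and the result is invariant under strictly monotone transforms of the
#' map.
#'
#' @param map numeric matrix \code{[y, x]}
#' @param fixations matrix with columns x, y in map pixel coordinates
#'   (0-based)
#' @param negatives \code{"grid"} for all pixels, or a matrix of negative
#'   x, y locations
#' @return AUC in \code{[0, 1]}; NA when no fixation falls on the frame
#' @export
salienceAUC <- function(map, fixations, negatives = "grid") {
  fixations <- .asPointMatrix(fixations)
  if (!nrow(fixations)) return(NA_real_)
  pos <- .mapValues(map, fixations)
  neg <- if (identical(negatives, "grid")) as.vector(map)
         else .mapValues(map, .asPointMatrix(negatives))
  nPos <- length(pos); nNeg <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(nPos)]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

## nearest-pixel map lookup; 0-based point coords, clamped to the frame
.mapValues <- function(map, pts) {
  ix <- pmin(pmax(round(pts[, 1L]) + 1L, 1L), ncol(map))
  iy <- pmin(pmax(round(pts[, 2L]) + 1L, 1L), nrow(map))
  map[cbind(iy, ix)]
}

#' Per-frame AUC series of a salience stack for a set of fixations
#'
#' @param stack a [SalienceStack-class] (or a plain list of per-frame maps)
#' @param fixationsPerFrame list (one element per frame) of fixation
#'   point matrices
#' @param channel channel to evaluate
#' @param negatives see [salienceAUC()]
#' @return numeric vector of per-frame AUC values (NA on frames without
#'   fixations)
#' @export
aucSeries <- function(stack, fixationsPerFrame, channel = "full",
                      negatives = "grid") {
  maps <- if (is(stack, "SalienceStack")) salienceMaps(stack, channel)
          else stack
  vapply(seq_along(maps), function(f) {
    fx <- fixationsPerFrame[[f]]
    if (is.null(fx) || !nrow(.asPointMatrix(fx))) return(NA_real_)
    salienceAUC(maps[[f]], fx, negatives)
  }, numeric(1))
}

#' Compare two groups' frame-wise AUC series
#'
#' Pairs the two groups' per-frame mean AUC values over the common frames
#' and applies the Wilcoxon signed-rank test (normal approximation). The
#' effect size is reported both as printed in some applied work (r = Z/N)
#' and in the conventional form (r = Z/sqrt(N)); N is the number of
#' non-tied frame pairs.
#'
#' @param seriesA,seriesB numeric per-frame AUC vectors over the same
#'   frames
#' @return list with \code{statistic} (signed-rank V), \code{p}, \code{z},
#'   \code{n}, \code{effectSizePrinted} (Z/N) and
#'   \code{effectSizeConventional} (Z/sqrt(N))
#' @export
compareGroupsAUC <- function(seriesA, seriesB) {
  if (length(seriesA) != length(seriesB))
    stop("AUC series must cover the same frames")
  ok <- !is.na(seriesA) & !is.na(seriesB)
  d <- seriesA[ok] - seriesB[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p = 1, z = 0, n = 0L,
                effectSizePrinted = 0, effectSizeConventional = 0))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                sum(tie^3 - tie) / 48)
  z <- (V - mu) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = V, p = p, z = z, n = as.integer(n),
       effectSizePrinted = z / n, effectSizeConventional = z / sqrt(n))
}
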