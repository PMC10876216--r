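#' Canny edge detection
#'
#' Gradient from a derivative-of-Gaussian filter, non-maximum suppression
#' along the quantized gradient direction, double thresholding and
#' hysteresis: weak edge pixels survive only when connected (8-neighbour)
#' to a strong one. Thresholds default to a median-based automatic rule on
#' the positive gradient magnitudes.
#'
#' @param frame numeric matrix \code{[y, x]} or RGB array
#' @param sigma Gaussian derivative scale in pixels
#' @param low,high thresholds on gradient magnitude; when NULL,
#'   \code{high = 1.33 * median(positive magnitudes)} and
#'   \code{low = 0.4 * high}
#' @return logical matrix of edge pixels
#' @export
cannyEdges <- function(frame, sigma = 1.4, low = NULL, high = NULL) {
  I <- .intensity(frame)
  if (!length(I) || all(!is.finite(I))) stop("empty image")
  S <- .gaussianBlur(I, sigma)
  gx <- .convSep(S, kRow = c(-0.5, 0, 0.5), kCol = c(0, 1, 0))
  gy <- .convSep(S, kRow = c(0, 1, 0), kCol = c(-0.5, 0, 0.5))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(I), ncol(I)))
  if (is.null(high)) {
    m <- stats::median(mag[mag > 1e-12 * max(mag)])
    high <- 1.33 * m
  }
  if (is.null(low)) low <- 0.4 * high
  crest <- .nonMaxSuppress(mag, gx, gy)
  strong <- crest & mag >= high
  weak <- crest & mag >= low
  .hysteresis(strong, weak)
}

## keep only pixels whose magnitude is a local maximum along the gradient
## direction, quantized to 4 sectors
.nonMaxSuppress <- function(mag, gx, gy) {
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (floor((ang + pi / 8) / (pi / 4)) %% 4L)
  n1 <- matrix(0, nrow(mag), ncol(mag))
  n2 <- n1
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0L, 1L),    # horizontal gradient -> compare x
                "1" = c(1L, 1L),
                "2" = c(1L, 0L),    # vertical gradient -> compare y
                "3" = c(1L, -1L))
    sel <- sector == s
    if (!any(sel)) next
    a <- .shiftImage(mag, d[1L], d[2L])
    b <- .shiftImage(mag, -d[1L], -d[2L])
    n1[sel] <- a[sel]
    n2[sel] <- b[sel]
  }
  ## strict on one side so a symmetric two-pixel ridge keeps a single crest
  mag > n1 & mag >= n2
}

## grow strong edges into connected weak ones until a fixed point
.hysteresis <- function(strong, weak) {
  cur <- strong
  repeat {
    grown <- cur
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      grown <- grown | .shiftImage(cur * 1, dy, dx) > 0
    }
    nxt <- weak & grown
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

#' Visual complexity of a frame as Canny edge length
#'
#' Counts edge pixels, i.e. the total length (in pixels) of edges
#' delimiting image elements, a standard clutter proxy.
#'
#' @param frame image matrix or RGB array
#' @param ... passed to [cannyEdges()]
#' @return integer edge-pixel count
#' @export
edgeComplexity <- function(frame, ...) {
  sum(cannyEdges(frame, ...))
}

#' Rasterize an annotation file onto the frame timeline
#'
#' Reads a behavioural-observation style CSV with columns
#' \code{label, onset, offset} (seconds; point events have onset == offset)
#' and rasterizes each channel onto the frame grid: a frame carries a code
#' when its temporal midpoint falls inside the event interval. Recognized
#' labels: \code{social_complexity_0} .. \code{social_complexity_3},
#' \code{monologue}, \code{directed_speech}, \code{moving_background} and
#' the point event \code{frame_switch}, whose first following frame is
#' coded 1. Overlapping contradictory codes on an exclusive channel
#' (social complexity; monologue vs directed speech) raise a validation
#' error.
#'
#' @param path CSV path
#' @param timeline a [FrameTimeline-class]
#' @return data.frame with one row per frame: frame, socialComplexity,
#'   monologue, directedSpeech, frameSwitch, movingBackground
#' @export
loadAnnotations <- function(path, timeline) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "onset", "offset")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  nf <- timeline@nFrames
  mids <- frameMidpoints(timeline)
  out <- data.frame(frame = seq_len(nf), socialComplexity = 0L,
                    monologue = 0L, directedSpeech = 0L, frameSwitch = 0L,
                    movingBackground = 0L)
  socialSet <- rep(FALSE, nf)
  for (i in seq_len(nrow(ann))) {
    lab <- ann$label[i]
    on <- ann$onset[i]; off <- ann$offset[i]
    if (lab == "frame_switch") {
      f <- which(mids >= on)[1L]
      if (!is.na(f)) out$frameSwitch[f] <- 1L
      next
    }
    covered <- which(mids >= on & mids < off)
    if (grepl("^social_complexity_[0-3]$", lab)) {
      val <- as.integer(sub("social_complexity_", "", lab))
      clash <- covered[socialSet[covered] &
                         out$socialComplexity[covered] != val]
      if (length(clash))
        stop("contradictory social_complexity codes on frame ", clash[1L])
      out$socialComplexity[covered] <- val
      socialSet[covered] <- TRUE
    } else if (lab == "monologue") {
      if (any(out$directedSpeech[covered] == 1L))
        stop("monologue overlaps directed_speech: speech codes are exclusive")
      out$monologue[covered] <- 1L
    } else if (lab == "directed_speech") {
      if (any(out$monologue[covered] == 1L))
        stop("directed_speech overlaps monologue: speech codes are exclusive")
      out$directedSpeech[covered] <- 1L
    } else if (lab == "moving_background") {
      out$movingBackground[covered] <- 1L
    } else {
      warning("ignoring unknown annotation label: ", lab)
    }
  }
  out
}

#' Automatic hard-cut detection from frame dissimilarity
#'
#' Flags frames whose intensity-histogram L1 distance to the previous frame
#' exceeds a threshold. Manual annotations remain authoritative; this
#' detector is a convenience for unannotated footage.
#'
#' @param frames list of image matrices/arrays
#' @param threshold histogram L1 distance threshold (range 0-2)
#' @param nBins histogram bins
#' @return integer 0/1 vector, one per frame (first frame always 0)
#' @export
detectFrameSwitch <- function(frames, threshold = 0.5, nBins = 32) {
  if (length(frames) < 2) stop("at least 2 frames required")
  brk <- seq(0, 1, length.out = nBins + 1L)
  hists <- lapply(frames, function(fr) {
    I <- pmin(pmax(.intensity(fr), 0), 1)
    h <- graphics::hist(I, breaks = brk, plot = FALSE)$counts
    h / sum(h)
  })
  d <- c(0, vapply(seq_len(length(frames) - 1L), function(f)
    sum(abs(hists[[f + 1L]] - hists[[f]])), numeric(1)))
  as.integer(d > threshold)
}

#' Assemble a per-frame scene-feature timeline
#'
#' Combines annotation channels with a per-frame visual-complexity vector
#' into a single table. Frames with no characters (social complexity 0)
#' can be excluded from content analyses downstream.
#'
#' @param annotations data.frame from [loadAnnotations()]
#' @param visualComplexity optional per-frame edge-pixel counts
#' @return data.frame with all feature columns
#' @export
featureTimeline <- function(annotations, visualComplexity = NULL) {
  out <- annotations
  if (!is.null(visualComplexity)) {
    if (length(visualComplexity) != nrow(out))
      stop("visualComplexity length must equal the frame count")
    out$visualComplexity <- visualComplexity
  }
  out
}
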