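#' Classify fixations as focal, ambient or unclassified
#'
#' A fixation is focal when longer than 180 ms and preceded by a saccade of
#' amplitude smaller than 5 degrees of visual angle; it is ambient when
#' shorter than 180 ms and preceded by a saccade larger than 5 degrees.
#' Both inequalities are strict, so boundary cases (exactly 180 ms or
#' exactly 5 degrees), mixed cases (long fixation after a long saccade,
#' short after a short one) and fixations without a preceding saccade
#' (the first of a recording) are unclassified. Focal fixations index
#' detailed foveal analysis; ambient fixations index rapid gist-level
#' scanning.
#'
#' @param fixations data.frame from [ivtFixationFilter()]
#' @param durationThreshold duration boundary in seconds (default 0.180)
#' @param amplitudeThreshold saccade-amplitude boundary in degrees
#'   (default 5)
#' @return factor with levels focal, ambient, unclassified
#' @export
classifyFixations <- function(fixations, durationThreshold = 0.180,
                              amplitudeThreshold = 5) {
  dur <- fixations$duration
  amp <- fixations$saccadeAmplitude
  lab <- rep("unclassified", length(dur))
  lab[!is.na(amp) & dur > durationThreshold & amp < amplitudeThreshold] <-
    "focal"
  lab[!is.na(amp) & dur < durationThreshold & amp > amplitudeThreshold] <-
    "ambient"
  factor(lab, levels = c("focal", "ambient", "unclassified"))
}

#' Fixation-mode profile of a recording
#'
#' Counts and proportions of focal and ambient fixations, normalized by the
#' overall fixation number, plus median fixation duration and median
#' saccade amplitude.
#'
#' @param fixations data.frame from [ivtFixationFilter()]
#' @param ... passed to [classifyFixations()]
#' @return data.frame row with nFixations, nFocal, nAmbient, nUnclassified,
#'   propFocal, propAmbient, medianFixationDurationMs,
#'   medianSaccadeAmplitudeDeg
#' @export
modeProfile <- function(fixations, ...) {
  if (!nrow(fixations)) stop("mode profile of an empty fixation list")
  lab <- classifyFixations(fixations, ...)
  n <- nrow(fixations)
  nFocal <- sum(lab == "focal")
  nAmbient <- sum(lab == "ambient")
  data.frame(
    nFixations = n, nFocal = nFocal, nAmbient = nAmbient,
    nUnclassified = n - nFocal - nAmbient,
    propFocal = nFocal / n, propAmbient = nAmbient / n,
    medianFixationDurationMs = stats::median(fixations$duration) * 1000,
    medianSaccadeAmplitudeDeg =
      stats::median(fixations$saccadeAmplitude, na.rm = TRUE))
}
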