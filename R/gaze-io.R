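#' Construct a gaze recording from a sample table
#'
#' Validates sample ordering and flags off-screen coordinates invalid.
#' Valid screen coordinates are 0-based pixels in
#' \code{[0, widthPx) x [0, heightPx)}, origin top-left, y pointing down.
#'
#' @param samples data.frame with columns t, lx, ly, rx, ry, lValid, rValid
#' @param geometry a [ScreenGeometry-class]
#' @param subjectId,group,ageYears,samplingHz recording metadata
#' @return a [GazeRecording-class]
#' @export
gazeRecording <- function(samples, geometry, subjectId = "subject",
                          group = "test", ageYears = NA_real_,
                          samplingHz = 300) {
  if (!samplingHz %in% c(300, 60))
    warning("samplingHz ", samplingHz, " outside the usual {300, 60} set")
  samples <- .flagOffscreen(samples, geometry)
  new("GazeRecording",
      subjectId = subjectId, group = group, ageYears = ageYears,
      samplingHz = samplingHz, samples = samples, geometry = geometry)
}

.flagOffscreen <- function(samples, geometry) {
  onL <- !is.na(samples$lx) & !is.na(samples$ly) &
    samples$lx >= 0 & samples$lx < geometry@widthPx &
    samples$ly >= 0 & samples$ly < geometry@heightPx
  onR <- !is.na(samples$rx) & !is.na(samples$ry) &
    samples$rx >= 0 & samples$rx < geometry@widthPx &
    samples$ry >= 0 & samples$ry < geometry@heightPx
  samples$lValid <- samples$lValid & onL
  samples$rValid <- samples$rValid & onR
  samples
}

#' Canonical column mapping for delimited gaze exports
#'
#' Names are the internal sample fields, values the column names expected in
#' the file. This is the dialect written by [writeGazeRecording()].
#'
#' @return named character vector
#' @export
gazeColumnMapping <- function() {
  c(t = "time", lx = "left_x", ly = "left_y", rx = "right_x", ry = "right_y",
    lValid = "left_valid", rValid = "right_valid")
}

#' Read a gaze recording from a delimited text file
#'
#' Accepts tab- or comma-delimited exports (auto-detected from the header
#' line) with one sample per row. Off-screen coordinates are retained but
#' their validity flags are cleared; non-monotone timestamps are a data
#' error.
#'
#' @param path file path
#' @param geometry a [ScreenGeometry-class]
#' @param subjectId,group,ageYears,samplingHz recording metadata
#' @param mapping named character vector mapping internal fields to file
#'   columns, see [gazeColumnMapping()]
#' @return a [GazeRecording-class]
#' @export
loadGazeRecording <- function(path, geometry, subjectId = "subject",
                              group = "test", ageYears = NA_real_,
                              samplingHz = 300,
                              mapping = gazeColumnMapping()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(mapping), names(raw))
  if (length(missing))
    stop("gaze file is missing required columns: ",
         paste(missing, collapse = ", "))
  samples <- data.frame(
    t = as.numeric(raw[[mapping[["t"]]]]),
    lx = as.numeric(raw[[mapping[["lx"]]]]),
    ly = as.numeric(raw[[mapping[["ly"]]]]),
    rx = as.numeric(raw[[mapping[["rx"]]]]),
    ry = as.numeric(raw[[mapping[["ry"]]]]),
    lValid = as.logical(raw[[mapping[["lValid"]]]]),
    rValid = as.logical(raw[[mapping[["rValid"]]]])
  )
  if (nrow(samples) > 1 && any(diff(samples$t) < 0))
    stop("non-monotone timestamps in ", path)
  gazeRecording(samples, geometry, subjectId = subjectId, group = group,
                ageYears = ageYears, samplingHz = samplingHz)
}

#' Write a gaze recording in the canonical delimited dialect
#'
#' @param recording a [GazeRecording-class]
#' @param path output file path
#' @param sep field separator
#' @return \code{path}, invisibly
#' @export
writeGazeRecording <- function(recording, path, sep = "\t") {
  s <- recording@samples
  out <- data.frame(time = s$t, left_x = s$lx, left_y = s$ly,
                    right_x = s$rx, right_y = s$ry,
                    left_valid = s$lValid, right_valid = s$rValid)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn gazeSamples number of samples in the recording
#' @export
setMethod("length", "GazeRecording", function(x) nrow(x@samples))

#' Accessors for gaze recordings
#'
#' @param recording a [GazeRecording-class]
#' @return \code{gazeSamples}: the sample data.frame; \code{subjectId}: the
#'   subject identifier; \code{geometry}: the [ScreenGeometry-class].
#' @export
gazeSamples <- function(recording) recording@samples

#' @rdname gazeSamples
#' @export
subjectId <- function(recording) recording@subjectId

#' @rdname gazeSamples
#' @export
geometry <- function(recording) recording@geometry

setMethod("show", "GazeRecording", function(object) {
  cat(sprintf(
    "GazeRecording '%s' (%s): %d samples at %g Hz, age %s y\n",
    object@subjectId, object@group, nrow(object@samples), object@samplingHz,
    format(object@ageYears)))
})

## Binocular gaze trace: midpoint when both eyes valid, the single valid eye
## otherwise, NA when neither. Also reports binocular validity, which is
## what screen attendance counts.
.gazeTrace <- function(recording) {
  s <- recording@samples
  both <- s$lValid & s$rValid
  x <- ifelse(both, (s$lx + s$rx) / 2, ifelse(s$lValid, s$lx,
              ifelse(s$rValid, s$rx, NA_real_)))
  y <- ifelse(both, (s$ly + s$ry) / 2, ifelse(s$lValid, s$ly,
              ifelse(s$rValid, s$ry, NA_real_)))
  data.frame(t = s$t, x = x, y = y, binocular = both,
             valid = s$lValid | s$rValid)
}

#' Write extracted fixations as delimited text
#'
#' Columns: onset, offset, duration_ms, x, y, preceding_saccade_deg.
#'
#' @param fixations data.frame as returned by [ivtFixationFilter()]
#' @param path output file path
#' @param sep field separator
#' @return \code{path}, invisibly
#' @export
writeFixations <- function(fixations, path, sep = "\t") {
  out <- data.frame(onset = fixations$onset, offset = fixations$offset,
                    duration_ms = fixations$duration * 1000,
                    x = fixations$x, y = fixations$y,
                    preceding_saccade_deg = fixations$saccadeAmplitude)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
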