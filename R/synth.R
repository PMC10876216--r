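#' Script a synthetic animated scene
#'
#' Produces the ground truth that every synthetic dataset shares: smoothly
#' moving attention foci with per-frame weights, hard-cut frames, a
#' per-frame character count tied to the number of active foci,
#' monologue / directed-speech intervals and moving-background segments.
#' All randomness is governed by \code{seed}; the same seed reproduces the
#' script exactly.
#'
#' @param nFrames number of frames
#' @param fps frames per second
#' @param geometry a [ScreenGeometry-class] the foci live in
#' @param nFoci number of concurrently scripted foci
#' @param nCuts number of hard cuts
#' @param focusSpeed multiplier on the foci's path frequency; 0 freezes
#'   every focus at a fixed position
#' @param seed integer seed
#' @return a [SceneScript-class]
#' @export
sceneScript <- function(nFrames = 500, fps = 25, geometry = screenGeometry(),
                        nFoci = 2, nCuts = 3, focusSpeed = 1, seed = 1) {
  set.seed(seed)
  nFrames <- as.integer(nFrames)
  W <- geometry@widthPx; H <- geometry@heightPx
  tt <- seq_len(nFrames) / fps
  foci <- vector("list", nFrames)
  ## each focus follows a slow Lissajous-like path with random phase
  paths <- lapply(seq_len(nFoci), function(k) {
    fx <- focusSpeed * stats::runif(1, 0.02, 0.06)
    fy <- focusSpeed * stats::runif(1, 0.02, 0.06)
    px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
    cbind(x = W * (0.5 + 0.3 * sin(2 * pi * fx * tt + px)),
          y = H * (0.5 + 0.3 * sin(2 * pi * fy * tt + py)))
  })
  ## per-frame weights drift smoothly and renormalize
  wRaw <- vapply(seq_len(nFoci), function(k)
    0.2 + (sin(2 * pi * stats::runif(1, 0.01, 0.04) * tt +
               stats::runif(1, 0, 2 * pi)) + 1) / 2, numeric(nFrames))
  if (nFrames == 1L) wRaw <- matrix(wRaw, 1L)
  for (f in seq_len(nFrames)) {
    w <- wRaw[f, ] / sum(wRaw[f, ])
    foci[[f]] <- cbind(x = vapply(paths, function(p) p[f, 1L], numeric(1)),
                       y = vapply(paths, function(p) p[f, 2L], numeric(1)),
                       weight = w)
  }
  cutFrames <- if (nCuts > 0)
    sort(sample(seq(5L, max(5L, nFrames - 5L)), min(nCuts, nFrames - 9L)))
  else integer(0)
  ## characters visible: number of foci, dipping to fewer in some shots
  shots <- findInterval(seq_len(nFrames), cutFrames)
  charCount <- as.integer(pmin(3, pmax(0, nFoci - shots %% 2)))
  ## alternating speech intervals over the video
  dur <- nFrames / fps
  bounds <- seq(0, dur, length.out = 7L)
  speech <- data.frame(
    label = rep(c("monologue", "directed_speech"), 3L),
    onset = bounds[1:6], offset = bounds[2:7])
  moving <- rep(FALSE, nFrames)
  if (nFrames >= 20L) {
    s <- sample(seq_len(nFrames - 10L), 1L)
    moving[s:(s + 9L)] <- TRUE
  }
  new("SceneScript", nFrames = nFrames, fps = fps, foci = foci,
      cutFrames = as.integer(cutFrames), characterCount = charCount,
      speech = speech, movingBackground = moving, geometry = geometry)
}

setMethod("show", "SceneScript", function(object) {
  cat(sprintf(
    "SceneScript: %d frames at %g fps, %d foci, %d cuts\n",
    object@nFrames, object@fps, nrow(object@foci[[1L]]),
    length(object@cutFrames)))
})

#' Render a scripted scene as a synthetic video
#'
#' Draws one bright disc per scripted focus over a textured background;
#' hard cuts change the background pattern and moving-background segments
#' slide it. Frames are grayscale matrices in \code{[0, 1]} at a reduced
#' resolution; focus coordinates are scaled from screen pixels
#' accordingly.
#'
#' @param script a [SceneScript-class]
#' @param size \code{c(height, width)} of the rendered frames in pixels
#' @param seed integer seed (texture noise)
#' @param discRadius disc radius in rendered pixels
#' @return list of frame matrices
#' @export
generateVideo <- function(script, size = c(120, 192), seed = 1,
                          discRadius = 5) {
  set.seed(seed)
  h <- size[1L]; w <- size[2L]
  sx <- w / script@geometry@widthPx
  sy <- h / script@geometry@heightPx
  nShots <- length(script@cutFrames) + 1L
  textures <- lapply(seq_len(nShots), function(s)
    .gaussianBlur(matrix(stats::runif(h * w, 0, 0.25 + 0.15 * (s %% 3)),
                         h, w), 2))
  shot <- findInterval(seq_len(script@nFrames), script@cutFrames) + 1L
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  offset <- 0L
  frames <- vector("list", script@nFrames)
  for (f in seq_len(script@nFrames)) {
    if (script@movingBackground[f]) offset <- offset + 2L
    bg <- textures[[shot[f]]]
    if (offset %% w != 0L) {
      k <- offset %% w
      bg <- bg[, c((k + 1L):w, 1L:k), drop = FALSE]
    }
    fr <- bg
    fc <- script@foci[[f]]
    for (i in seq_len(nrow(fc))) {
      cx <- fc[i, "x"] * sx; cy <- fc[i, "y"] * sy
      disc <- (xx - cx)^2 + (yy - cy)^2 <= discRadius^2
      fr[disc] <- 0.95
    }
    frames[[f]] <- pmin(pmax(fr, 0), 1)
  }
  frames
}

#' Construct a cohort specification
#'
#' Describes one group of a synthetic cohort: its size, age structure with
#' yearly repeat visits, and its gaze model (probability of following the
#' scripted foci, gaze noise around the chosen focus with an optional
#' linear age trend, subject-persistent idiosyncratic foci, blink dropout,
#' sampling rate).
#'
#' @param nSubjects subjects in the group
#' @param group group label
#' @param ageRange years, base ages drawn uniformly from this range
#' @param visitsPerSubject visits per subject, spaced one year apart
#' @param onScriptProb probability a dwell targets a scripted focus
#' @param noiseSdPx gaze noise sd (pixels) at \code{ageRef}
#' @param noiseAgeSlope px of noise sd per year of age
#' @param ageRef reference age for \code{noiseSdPx}
#' @param idiosyncraticProb probability an off-script dwell goes to the
#'   subject's idiosyncratic focus (vs. a uniformly random location)
#' @param dropoutRate fraction of time lost to blink gaps
#' @param samplingHz tracker sampling rate
#' @return a [CohortSpec-class]
#' @export
cohortSpec <- function(nSubjects = 20, group = "reference",
                       ageRange = c(2, 4), visitsPerSubject = 1,
                       onScriptProb = 0.9, noiseSdPx = 60,
                       noiseAgeSlope = 0, ageRef = 3,
                       idiosyncraticProb = 1, dropoutRate = 0.05,
                       samplingHz = 300) {
  new("CohortSpec", nSubjects = as.integer(nSubjects), group = group,
      ageRange = ageRange, visitsPerSubject = as.integer(visitsPerSubject),
      onScriptProb = onScriptProb, noiseSdPx = noiseSdPx,
      noiseAgeSlope = noiseAgeSlope, ageRef = ageRef,
      idiosyncraticProb = idiosyncraticProb, dropoutRate = dropoutRate,
      samplingHz = samplingHz)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec '%s': %d subjects x %d visit(s), ages %.1f-%.1f y, on-script %.2f, noise %g px\n",
    object@group, object@nSubjects, object@visitsPerSubject,
    object@ageRange[1L], object@ageRange[2L], object@onScriptProb,
    object@noiseSdPx))
})

#' Generate a cohort of synthetic gaze recordings
#'
#' Each recording is a plausible tracker sample stream: the subject dwells
#' on a target for 250-700 ms, then saccades to the next. Each dwell
#' targets a scripted focus (drawn by the frame's focus weights) with
#' probability \code{onScriptProb}; otherwise, with probability
#' \code{idiosyncraticProb}, the subject's own idiosyncratic focus (fixed
#' per subject across frames and visits), else a uniformly random
#' location. The landed position adds isotropic Gaussian noise (sd
#' \code{noiseSdPx + noiseAgeSlope * (age - ageRef)}, truncated at the
#' screen), plus sub-threshold within-dwell jitter so the I-VT filter
#' recovers the intended fixations. Blink gaps (120-400 ms, both eyes
#' invalid) cover about \code{dropoutRate} of the recording.
#'
#' @param script a [SceneScript-class]
#' @param spec a [CohortSpec-class]
#' @param seed integer seed
#' @return list with \code{recordings} (list of [GazeRecording-class]) and
#'   \code{truth} (data.frame per recording: recordingId, subjectId, visit,
#'   ageYears, noiseSd, idioX, idioY)
#' @export
generateCohortGaze <- function(script, spec, seed = 1) {
  set.seed(seed)
  geom <- script@geometry
  W <- geom@widthPx; H <- geom@heightPx
  duration <- script@nFrames / script@fps
  hz <- spec@samplingHz
  ts <- seq(0, duration - 1 / hz, by = 1 / hz)
  recs <- list()
  truth <- list()
  for (s in seq_len(spec@nSubjects)) {
    sid <- sprintf("%s_%02d", spec@group, s)
    baseAge <- stats::runif(1, spec@ageRange[1L], spec@ageRange[2L])
    idio <- c(stats::runif(1, 0.1 * W, 0.9 * W),
              stats::runif(1, 0.1 * H, 0.9 * H))
    for (v in seq_len(spec@visitsPerSubject)) {
      age <- baseAge + (v - 1)
      noiseSd <- max(0.5, spec@noiseSdPx + spec@noiseAgeSlope *
                       (age - spec@ageRef))
      pos <- .simulateScanpath(ts, script, spec, noiseSd, idio, W, H)
      eyeOff <- stats::rnorm(2, 0, 2)
      valid <- .blinkMask(ts, spec@dropoutRate)
      samples <- data.frame(
        t = ts,
        lx = pos[, 1L] - eyeOff[1L], ly = pos[, 2L] - eyeOff[2L],
        rx = pos[, 1L] + eyeOff[1L], ry = pos[, 2L] + eyeOff[2L],
        lValid = valid, rValid = valid)
      recs[[length(recs) + 1L]] <- gazeRecording(
        samples, geom, subjectId = sid, group = spec@group,
        ageYears = age, samplingHz = hz)
      truth[[length(truth) + 1L]] <- data.frame(
        recordingId = sprintf("%s_v%d", sid, v), subjectId = sid,
        visit = v, ageYears = age, noiseSd = noiseSd,
        idioX = idio[1L], idioY = idio[2L])
    }
  }
  list(recordings = recs, truth = do.call(rbind, truth))
}

## dwell/saccade scanpath: piecewise-constant targets with tiny jitter
.simulateScanpath <- function(ts, script, spec, noiseSd, idio, W, H) {
  n <- length(ts)
  pos <- matrix(NA_real_, n, 2L)
  t0 <- 0
  while (t0 < ts[n] + 1e-9) {
    dwell <- stats::runif(1, 0.25, 0.7)
    idx <- which(ts >= t0 & ts < t0 + dwell)
    t0 <- t0 + dwell
    if (!length(idx)) next
    f <- min(max(1L, floor(ts[idx[1L]] * script@fps) + 1L), script@nFrames)
    fc <- script@foci[[f]]
    if (stats::runif(1) < spec@onScriptProb) {
      k <- sample.int(nrow(fc), 1L, prob = fc[, "weight"])
      target <- fc[k, c("x", "y")]
    } else if (stats::runif(1) < spec@idiosyncraticProb) {
      target <- idio
    } else {
      target <- c(stats::runif(1, 0, W - 1), stats::runif(1, 0, H - 1))
    }
    land <- target + stats::rnorm(2, 0, noiseSd)
    ## truncate at the screen with a small margin so per-eye offsets
    ## cannot push an otherwise-valid sample off screen
    mx <- min(8, W / 4); my <- min(8, H / 4)
    land <- c(min(max(land[1L], mx), W - 1 - mx),
              min(max(land[2L], my), H - 1 - my))
    pos[idx, 1L] <- land[1L] + stats::rnorm(length(idx), 0, 0.3)
    pos[idx, 2L] <- land[2L] + stats::rnorm(length(idx), 0, 0.3)
  }
  pos[is.na(pos[, 1L]), ] <- c(W / 2, H / 2)
  pos
}

## blink gaps of 120-400 ms covering about `rate` of the recording; the
## last gap is trimmed to the remaining budget so coverage does not
## overshoot the requested rate
.blinkMask <- function(ts, rate) {
  n <- length(ts)
  valid <- rep(TRUE, n)
  span <- ts[n] - ts[1L]
  if (rate <= 0 || span <= 0) return(valid)
  total <- span * rate
  dt <- span / n
  lost <- 0
  guard <- 0L
  while (lost < total - dt && guard < 10000L) {
    guard <- guard + 1L
    len <- min(stats::runif(1, 0.12, 0.4), total - lost, span * 0.8)
    start <- stats::runif(1, 0, max(1e-9, span - len))
    sel <- ts >= start & ts < start + len
    newly <- sum(valid[sel])
    valid[sel] <- FALSE
    lost <- lost + newly * dt
  }
  valid
}

#' Generate a phenotype table with a planted latent factor
#'
#' Builds a behavioural matrix whose columns load with given signs on a
#' latent factor correlated with each subject's mean Proximity Index at
#' \code{latentCorr}, plus Gaussian noise, an optional age confound and
#' missing-completely-at-random entries -- the ground truth needed to
#' validate the PLS correlation pipeline.
#'
#' @param meanPi numeric vector of mean PI values (one per observation)
#' @param loadingPattern signed loadings, one per behavioural variable
#'   (default: 12 variables, half positive, half negative)
#' @param latentCorr correlation between the latent factor and mean PI
#' @param noiseSd sd of the additive noise per variable
#' @param missingRate MCAR missingness fraction
#' @param ages optional age vector for the confound
#' @param ageConfound loading of age on every variable
#' @param seed integer seed
#' @return list with \code{B} (matrix, observations x variables),
#'   \code{latent} (the factor) and \code{loadings}
#' @export
generatePhenotype <- function(meanPi,
                              loadingPattern = rep(c(1, -1), each = 6),
                              latentCorr = 0.5, noiseSd = 1,
                              missingRate = 0, ages = NULL,
                              ageConfound = 0, seed = 1) {
  set.seed(seed)
  n <- length(meanPi)
  z <- if (stats::sd(meanPi) > 0) as.vector(scale(meanPi)) else rep(0, n)
  latent <- latentCorr * z + sqrt(max(0, 1 - latentCorr^2)) * stats::rnorm(n)
  q <- length(loadingPattern)
  B <- outer(latent, loadingPattern) +
    matrix(stats::rnorm(n * q, 0, noiseSd), n, q)
  if (!is.null(ages) && ageConfound != 0)
    B <- B + outer(as.vector(scale(ages)), rep(ageConfound, q))
  if (missingRate > 0) {
    mask <- matrix(stats::runif(n * q) < missingRate, n, q)
    ## keep at least one observed value per column
    for (j in seq_len(q)) if (all(mask[, j])) mask[1L, j] <- FALSE
    B[mask] <- NA
  }
  colnames(B) <- sprintf("behav%02d", seq_len(q))
  list(B = B, latent = latent, loadings = loadingPattern)
}

#' Write a ready-to-run synthetic dataset directory
#'
#' Produces gaze files in the canonical dialect, an annotation CSV, a
#' phenotype table and a ground-truth JSON for a scripted scene and two
#' cohorts.
#'
#' @param dir output directory
#' @param script a [SceneScript-class]
#' @param specs list of [CohortSpec-class] (one per group)
#' @param seed integer seed
#' @return \code{dir}, invisibly
#' @export
writeSyntheticDataset <- function(dir, script, specs, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "gaze"), showWarnings = FALSE)
  truths <- list()
  for (i in seq_along(specs)) {
    cohort <- generateCohortGaze(script, specs[[i]], seed = seed + i)
    for (j in seq_along(cohort$recordings)) {
      writeGazeRecording(cohort$recordings[[j]], file.path(
        dir, "gaze", paste0(cohort$truth$recordingId[j], ".tsv")))
    }
    truths[[i]] <- cohort$truth
  }
  truth <- do.call(rbind, truths)
  utils::write.csv(truth, file.path(dir, "recordings.csv"),
                   row.names = FALSE)
  ann <- script@speech
  if (length(script@cutFrames)) {
    cutT <- (script@cutFrames - 1) / script@fps
    ann <- rbind(ann, data.frame(label = "frame_switch", onset = cutT,
                                 offset = cutT))
  }
  if (any(script@movingBackground)) {
    r <- rle(script@movingBackground)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    on <- which(r$values)
    ann <- rbind(ann, data.frame(
      label = "moving_background",
      onset = (starts[on] - 1) / script@fps,
      offset = ends[on] / script@fps))
  }
  utils::write.csv(ann, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(nFrames = script@nFrames, fps = script@fps,
         cutFrames = script@cutFrames, seed = seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
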