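geomS <- smallGeometry()

test_that("worked Proximity Index values follow the isoline definition", {
  ## estimated surface: score the global maximum and a remote point
  set.seed(10)
  grd <- gridSpec(geomS, 4)
  pts <- cbind(rnorm(100, 160, 12), rnorm(100, 100, 10))
  surf <- adaptiveKDE(pts, grd)
  lv <- levelSets(surf)
  am <- which(surf@grid == max(surf@grid), arr.ind = TRUE)[1, ]
  expect_equal(proximityIndexFrame(c(surf@xCenters[am[2]],
                                     surf@yCenters[am[1]]), surf, lv), 1)
  expect_equal(proximityIndexFrame(c(2, 2), surf, lv), 0)
  ## constructed surface with an exact half-maximum location -> isoline 50
  g <- matrix(0, 7, 7); g[4, 4] <- 2; g[4, 5] <- 1.5; g[4, 6] <- 0.5
  s2 <- densitySurface(g, cellSizePx = 1, normalize = FALSE)
  l2 <- levelSets(s2)
  half <- c(mean(s2@xCenters[5:6]), s2@yCenters[4])
  expect_equal(proximityIndexFrame(half, s2, l2), 0.50)
})

test_that("PI equals the exhaustive level-scan oracle on random surfaces", {
  set.seed(11)
  for (rep in 1:10) {
    g <- matrix(runif(20 * 30), 20, 30)
    surf <- densitySurface(g, cellSizePx = 2)
    lv <- levelSets(surf)
    for (q in 1:10) {
      xy <- c(runif(1, 0, 60), runif(1, 0, 40))
      expect_identical(proximityIndexFrame(xy, surf, lv),
                       oraclePI(xy, surf, lv))
    }
  }
})

test_that("PI is invariant to monotone rescaling of the surface", {
  set.seed(12)
  g <- matrix(runif(200), 10, 20)
  s1 <- densitySurface(g, cellSizePx = 2, normalize = FALSE)
  s2 <- densitySurface(g * 37.5, cellSizePx = 2, normalize = FALSE)
  for (q in 1:20) {
    xy <- c(runif(1, 0, 40), runif(1, 0, 20))
    expect_equal(proximityIndexFrame(xy, s1, levelSets(s1)),
                 proximityIndexFrame(xy, s2, levelSets(s2)))
  }
})

test_that("PI never increases along a path of decreasing density", {
  ## radial Gaussian: walking outward from the peak can only lower PI
  grd <- gridSpec(geomS, 4)
  surf <- adaptiveKDE(cbind(rnorm(150, 160, 20), rnorm(150, 100, 20)), grd)
  lv <- levelSets(surf)
  am <- which(surf@grid == max(surf@grid), arr.ind = TRUE)[1, ]
  start <- c(surf@xCenters[am[2]], surf@yCenters[am[1]])
  path <- seq(0, 120, by = 4)
  pis <- vapply(path, function(d)
    proximityIndexFrame(start + c(d, 0), surf, lv), numeric(1))
  dens <- vapply(path, function(d)
    densityAt(surf, start[1] + d, start[2]), numeric(1))
  dec <- which(diff(dens) <= 0)
  expect_true(all(diff(pis)[dec] <= 0))
})

test_that("subject scoring excludes missing frames and honours QC", {
  tl <- frameTimeline(fps = 25, nFrames = 40)
  script <- sceneScript(nFrames = 40, fps = 25, geometry = geomS, seed = 13)
  coh <- generateCohortGaze(script,
                            cohortSpec(nSubjects = 8, onScriptProb = 1,
                                       noiseSdPx = 15, dropoutRate = 0,
                                       samplingHz = 60), seed = 14)
  ref <- buildReference(coh$recordings, tl, minPointsPerFrame = 4)
  probe <- generateCohortGaze(script,
                              cohortSpec(nSubjects = 1, group = "probe",
                                         onScriptProb = 1, noiseSdPx = 15,
                                         dropoutRate = 0, samplingHz = 60),
                              seed = 15)$recordings[[1]]
  res <- proximityIndexSubject(probe, ref)
  expect_s4_class(res, "PIResult")
  expect_true(meanPI(res) > 0 && meanPI(res) <= 1)
  ## 50% frame dropout halves the scored frame count
  fg <- mapFixationsToFrames(ivtFixationFilter(probe), tl)
  full <- proximityIndexSubject(probe, ref, frameGaze = fg,
                                qcOverride = TRUE)
  fg2 <- fg; fg2[seq(1, 40, by = 2), ] <- NA
  halfres <- proximityIndexSubject(probe, ref, frameGaze = fg2,
                                   qcOverride = TRUE)
  scoreable <- sum(usableFrames(ref) & !is.na(fg[, "x"]))
  expect_equal(halfres@nFramesScored,
               sum(usableFrames(ref) & !is.na(fg2[, "x"])))
  expect_lt(halfres@nFramesScored, full@nFramesScored)
  ## attendance gate
  s <- gazeSamples(probe); s$lValid[s$t > 0.3] <- FALSE
  poor <- gazeRecording(s, geomS, samplingHz = 60)
  expect_error(proximityIndexSubject(poor, ref), "attendance")
  expect_s4_class(proximityIndexSubject(poor, ref, qcOverride = TRUE),
                  "PIResult")
})

test_that("on-script subjects outscore random gaze against the reference", {
  tl <- frameTimeline(fps = 25, nFrames = 40)
  script <- sceneScript(nFrames = 40, fps = 25, geometry = geomS, seed = 16)
  refCoh <- generateCohortGaze(script,
                               cohortSpec(nSubjects = 10, onScriptProb = 1,
                                          noiseSdPx = 15, dropoutRate = 0,
                                          samplingHz = 60), seed = 17)
  ref <- buildReference(refCoh$recordings, tl, minPointsPerFrame = 5)
  onScript <- generateCohortGaze(script,
                                 cohortSpec(nSubjects = 3, group = "on",
                                            onScriptProb = 1, noiseSdPx = 15,
                                            dropoutRate = 0,
                                            samplingHz = 60),
                                 seed = 18)$recordings
  randomG <- generateCohortGaze(script,
                                cohortSpec(nSubjects = 3, group = "rand",
                                           onScriptProb = 0,
                                           idiosyncraticProb = 0,
                                           noiseSdPx = 80, dropoutRate = 0,
                                           samplingHz = 60),
                                seed = 19)$recordings
  piOn <- vapply(onScript, function(r)
    meanPI(proximityIndexSubject(r, ref, qcOverride = TRUE)), numeric(1))
  piRand <- vapply(randomG, function(r)
    meanPI(proximityIndexSubject(r, ref, qcOverride = TRUE)), numeric(1))
  expect_gt(mean(piOn), 0.3)
  expect_gt(mean(piOn), mean(piRand) + 0.1)
})

test_that("leave-one-out scores each member against the others", {
  tl <- frameTimeline(fps = 25, nFrames = 30)
  script <- sceneScript(nFrames = 30, fps = 25, geometry = geomS, seed = 20)
  coh <- generateCohortGaze(script,
                            cohortSpec(nSubjects = 3, onScriptProb = 1,
                                       noiseSdPx = 12, dropoutRate = 0,
                                       samplingHz = 60), seed = 21)
  loo <- looProximity(coh$recordings, tl, minPointsPerFrame = 2)
  expect_length(loo, 3L)
  tab <- piTable(loo)
  expect_true(all(tab$meanPI >= 0 & tab$meanPI <= 1))
  expect_error(looProximity(coh$recordings[1:2], tl), "at least 3")
  ## vanishing noise on a single static focus drives LOO PI toward 1
  ## (bounded below 1 only by the grid discretization of the peak)
  staticScript <- sceneScript(nFrames = 30, fps = 25, geometry = geomS,
                              nFoci = 1, focusSpeed = 0, seed = 20)
  coh2 <- generateCohortGaze(staticScript,
                             cohortSpec(nSubjects = 8, onScriptProb = 1,
                                        noiseSdPx = 0.5, dropoutRate = 0,
                                        samplingHz = 60), seed = 22)
  loo2 <- looProximity(coh2$recordings, tl, minPointsPerFrame = 3)
  mp2 <- vapply(loo2, meanPI, numeric(1))
  expect_gt(mean(mp2), 0.85)
  expect_true(all(mp2 > 0.75))
})

test_that("a cloned member receives its twin's leave-one-out score", {
  tl <- frameTimeline(fps = 25, nFrames = 30)
  script <- sceneScript(nFrames = 30, fps = 25, geometry = geomS, seed = 23)
  coh <- generateCohortGaze(script,
                            cohortSpec(nSubjects = 6, onScriptProb = 0.9,
                                       noiseSdPx = 20, dropoutRate = 0,
                                       samplingHz = 60), seed = 24)
  recs <- coh$recordings
  clone <- recs[[1]]
  clone@subjectId <- "clone"
  group <- c(recs, clone)
  loo <- looProximity(group, tl, minPointsPerFrame = 3)
  mp <- vapply(loo, meanPI, numeric(1))
  expect_equal(mp[7], mp[1], tolerance = 0.12)
})
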