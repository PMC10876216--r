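geomS <- smallGeometry()
gridS <- gridSpec(geomS, 4)

test_that("adaptive KDE normalizes, peaks at data and matches the oracle", {
  ## single point: unimodal with argmax at that point
  s1 <- adaptiveKDE(cbind(160, 100), gridS)
  am <- which(s1@grid == max(s1@grid), arr.ind = TRUE)
  expect_lt(abs(s1@xCenters[am[1, 2]] - 160), gridS$cellSizePx)
  expect_lt(abs(s1@yCenters[am[1, 1]] - 100), gridS$cellSizePx)
  set.seed(5)
  ## two well-separated clusters: local maxima near both centroids and
  ## pointwise agreement with direct kernel summation
  pts <- rbind(cbind(rnorm(200, 80, 6), rnorm(200, 60, 6)),
               cbind(rnorm(200, 250, 6), rnorm(200, 150, 6)))
  surf <- adaptiveKDE(pts, gridS)
  expect_equal(sum(surf@grid) * gridS$cellSizePx^2, 1, tolerance = 1e-3)
  expect_equal(max(abs(surf@grid - oracleKDE(pts, gridS))), 0,
               tolerance = 1e-10)
  c1 <- colMeans(pts[1:200, ]); c2 <- colMeans(pts[201:400, ])
  for (cc in list(c1, c2)) {
    near <- surf@grid[abs(surf@yCenters - cc[2]) <= 4,
                      abs(surf@xCenters - cc[1]) <= 4]
    ## density at each cluster centroid is within a cell of a local max
    expect_gt(max(near), 0.9 * max(surf@grid[
      abs(surf@yCenters - cc[2]) <= 20, abs(surf@xCenters - cc[1]) <= 20]))
  }
})

test_that("KDE is permutation-invariant and reduces to fixed bandwidth", {
  set.seed(6)
  pts <- cbind(runif(50, 20, 300), runif(50, 20, 180))
  a <- adaptiveKDE(pts, gridS)
  b <- adaptiveKDE(pts[sample(50), ], gridS)
  expect_equal(a@grid, b@grid, tolerance = 1e-12)
  fixed <- adaptiveKDE(pts, gridS, adaptive = FALSE)
  expect_equal(max(abs(fixed@grid -
                         oracleKDE(pts, gridS, adaptive = FALSE))), 0,
               tolerance = 1e-10)
  ## duplicating every point leaves the surface unchanged at fixed bandwidth
  dup <- adaptiveKDE(rbind(pts, pts), gridS, bandwidth = 10)
  one <- adaptiveKDE(pts, gridS, bandwidth = 10)
  expect_equal(dup@grid, one@grid, tolerance = 1e-9)
  expect_error(adaptiveKDE(matrix(numeric(0), 0, 2), gridS), "no gaze")
})

test_that("level sets are 100 linear thresholds of the frame maximum", {
  g <- matrix(runif(300, 0.1, 1), 15, 20)
  surf <- densitySurface(g, cellSizePx = 1)
  lv <- levelSets(surf)
  m <- max(surf@grid)
  expect_length(lv@levels, 100L)
  expect_equal(lv@levels, (1:100) * m / 100)
  expect_equal(lv@levels[50], m / 2)
  ## every cell's highest containing level is floor(100 f / fmax)
  k <- vapply(as.vector(surf@grid), function(f) sum(f >= lv@levels),
              numeric(1))
  expect_equal(k, pmin(floor(100 * as.vector(surf@grid) / m + 1e-9), 100))
  expect_error(levelSets(densitySurface(matrix(0, 3, 3), normalize = FALSE)),
               "flat zero")
})

test_that("buildReference pools frame gaze and flags sparse frames", {
  tl <- frameTimeline(fps = 25, nFrames = 40)
  script <- sceneScript(nFrames = 40, fps = 25, geometry = geomS, seed = 2)
  coh <- generateCohortGaze(script,
                            cohortSpec(nSubjects = 6, onScriptProb = 1,
                                       noiseSdPx = 15, dropoutRate = 0,
                                       samplingHz = 60), seed = 3)
  ref <- buildReference(coh$recordings, tl, minPointsPerFrame = 3)
  expect_true(any(usableFrames(ref)))
  expect_length(referenceMembers(ref), 6L)
  ## frames where everyone blinks are unusable
  blind <- lapply(coh$recordings, function(r) {
    m <- mapFixationsToFrames(ivtFixationFilter(r), tl)
    m[10, ] <- NA
    m
  })
  ref2 <- buildReference(coh$recordings, tl, minPointsPerFrame = 3,
                         frameGaze = blind)
  expect_false(usableFrames(ref2)[10])
  expect_error(buildReference(list(), tl), "empty")
  ## per-frame argmax tracks the scripted focus when everyone is on script
  f <- which(usableFrames(ref))[5]
  surf <- ref@surfaces[[f]]
  am <- which(surf@grid == max(surf@grid), arr.ind = TRUE)[1, ]
  peak <- c(surf@xCenters[am[2]], surf@yCenters[am[1]])
  foci <- script@foci[[f]]
  dmin <- min(sqrt((foci[, "x"] - peak[1])^2 + (foci[, "y"] - peak[2])^2))
  expect_lt(dmin, 60)
})

test_that("reference round-trips through its serialized directory form", {
  tl <- frameTimeline(fps = 25, nFrames = 10)
  script <- sceneScript(nFrames = 10, fps = 25, geometry = geomS, seed = 4)
  coh <- generateCohortGaze(script,
                            cohortSpec(nSubjects = 5, onScriptProb = 1,
                                       noiseSdPx = 12, dropoutRate = 0,
                                       samplingHz = 60), seed = 5)
  ref <- buildReference(coh$recordings, tl, minPointsPerFrame = 3)
  dir <- withr::local_tempdir()
  writeReference(ref, dir)
  back <- readReference(dir)
  expect_equal(usableFrames(back), usableFrames(ref))
  f <- which(usableFrames(ref))[1]
  expect_equal(back@surfaces[[f]]@grid, ref@surfaces[[f]]@grid,
               tolerance = 1e-6)
})

test_that("reference stability rises with subsample size", {
  tl <- frameTimeline(fps = 25, nFrames = 30)
  script <- sceneScript(nFrames = 30, fps = 25, geometry = geomS, seed = 6)
  spec <- cohortSpec(nSubjects = 16, onScriptProb = 0.85, noiseSdPx = 25,
                     dropoutRate = 0, samplingHz = 60)
  coh <- generateCohortGaze(script, spec, seed = 7)
  probe <- generateCohortGaze(script,
                              cohortSpec(nSubjects = 6, group = "probe",
                                         onScriptProb = 0.6, noiseSdPx = 60,
                                         dropoutRate = 0, samplingHz = 60),
                              seed = 8)
  st <- referenceStability(coh$recordings, probe$recordings, tl,
                           sizes = c(4, 12), nBoot = 4, seed = 9,
                           minPointsPerFrame = 3)
  expect_equal(nrow(st$curve), 2L)
  expect_true(all(st$curve$meanAgreement <= 1 + 1e-9))
  expect_gte(st$curve$meanAgreement[2], st$curve$meanAgreement[1] - 0.05)
  expect_error(referenceStability(coh$recordings, probe$recordings, tl,
                                  sizes = 1, nBoot = 2), "at least 2")
})
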