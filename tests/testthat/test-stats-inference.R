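test_that("regressOut removes a covariate exactly", {
  set.seed(41)
  cov <- rnorm(50)
  ## already orthogonal columns are unchanged
  Xo <- matrix(rnorm(100), 50, 2)
  Xo <- Xo - cbind(1, cov) %*% solve(crossprod(cbind(1, cov)),
                                     crossprod(cbind(1, cov), Xo))
  expect_equal(regressOut(Xo, cov), Xo, tolerance = 1e-10)
  ## a pure multiple of the covariate residualizes to zero
  expect_equal(max(abs(regressOut(matrix(2 * cov, ncol = 1), cov))), 0,
               tolerance = 1e-10)
  ## random X: residuals decorrelated from the covariate
  X <- matrix(rnorm(300), 50, 6)
  R <- regressOut(X, cov)
  expect_true(all(abs(cor(R, cov)) < 1e-10))
  expect_warning(regressOut(X, rep(1, 50)), "constant")
})

test_that("imputation fills with column medians and reports its mask", {
  X <- matrix(c(1, 2, 3, 4, NA, 6), 3, 2)
  res <- imputeMatrix(X)
  expect_equal(res$data[2, 2], median(c(4, 6)))
  expect_equal(which(res$mask), 5L)
  ## complete matrices pass through untouched
  Xc <- matrix(rnorm(20), 5, 4)
  expect_equal(imputeMatrix(Xc)$data, Xc)
  expect_false(any(imputeMatrix(Xc)$mask))
  expect_error(imputeMatrix(matrix(NA_real_, 3, 1)), "no observed")
  ## known missingness pattern is recovered exactly
  set.seed(42)
  M <- matrix(rnorm(60), 12, 5)
  mask <- matrix(runif(60) < 0.2, 12, 5)
  mask[1, ] <- FALSE
  M[mask] <- NA
  expect_equal(imputeMatrix(M)$mask, mask)
})

test_that("a noiseless shared variable gives a perfect first component", {
  set.seed(43)
  x <- rnorm(100)
  ## B an affine transform of the single A variable: z-scoring makes the
  ## latent scores identical, so the latent correlation is exactly 1
  res <- plsc(matrix(x, ncol = 1), matrix(2 * x - 3, ncol = 1),
              nPerm = 199, nBoot = 50, seed = 44)
  expect_equal(latentCorrelations(res)[1], 1, tolerance = 1e-12)
  expect_lte(permutationP(res)[1], 2 / 200)
  ## with distractor noise columns alongside, the first component still
  ## carries the shared variable almost perfectly
  A <- matrix(rnorm(300), 100, 3)
  B <- cbind(A[, 2], matrix(rnorm(200), 100, 2))
  res2 <- plsc(A, B, nPerm = 199, nBoot = 0, seed = 45)
  expect_gt(latentCorrelations(res2)[1], 0.95)
  expect_lte(permutationP(res2)[1], 2 / 200)
})

test_that("plsc is invariant to affine rescaling of input columns", {
  set.seed(45)
  A <- matrix(rnorm(80), 40, 2)
  B <- matrix(rnorm(160), 40, 4)
  r1 <- plsc(A, B, nPerm = 49, nBoot = 0, seed = 7)
  A2 <- sweep(sweep(A, 2, c(3, 0.1), "*"), 2, c(-5, 2), "+")
  r2 <- plsc(A2, B, nPerm = 49, nBoot = 0, seed = 7)
  expect_equal(latentCorrelations(r1), latentCorrelations(r2),
               tolerance = 1e-10)
  expect_equal(r1@singularValues, r2@singularValues, tolerance = 1e-10)
  ## energy conservation: sum of squared singular values = ||R||_F^2
  Az <- scale(A); Bz <- scale(B)
  R <- crossprod(Bz, Az) / (nrow(A) - 1)
  expect_equal(sum(r1@singularValues^2), sum(R^2), tolerance = 1e-10)
})

test_that("bootstrap stability flags strong loadings, not noise", {
  set.seed(46)
  n <- 150
  latent <- rnorm(n)
  B <- cbind(outer(latent, c(1, 1, -1)) + matrix(rnorm(3 * n, 0, 0.4), n, 3),
             matrix(rnorm(2 * n, 0, 1), n, 2))
  A <- matrix(latent + rnorm(n, 0, 0.4), ncol = 1)
  res <- plsc(A, B, nPerm = 99, nBoot = 200, seed = 47)
  st <- stableLoadings(res)[, 1]
  expect_true(all(st[1:3]))
  expect_false(any(st[4:5]))
})

test_that("sliding windows honour the subject-uniqueness skip rule", {
  meta <- data.frame(
    recordingId = sprintf("r%02d", 1:24),
    subjectId = sprintf("s%02d", 1:24),
    ageYears = seq(2, 4, length.out = 24))
  ## all unique: every start position yields a window
  ws <- slidingWindows(meta, width = 20)
  expect_equal(length(ws), 5L)
  expect_equal(ws@meanAge[1], mean(sort(meta$ageYears)[1:20]))
  ## a repeated subject inside positions 3 and 9 kills windows covering both
  meta2 <- meta
  meta2$subjectId[9] <- meta2$subjectId[3]
  ws2 <- slidingWindows(meta2, width = 20)
  expect_equal(length(ws2), 5L - sum(sapply(1:5, function(s)
    3 >= s && 9 <= s + 19)))
  expect_gt(nrow(ws2@skipped), 0)
  expect_error(slidingWindows(meta[1:5, ], width = 20), "width exceeds")
  ## exhaustive enumeration oracle on a random repeat structure
  set.seed(48)
  meta3 <- data.frame(
    recordingId = sprintf("r%03d", 1:60),
    subjectId = sprintf("s%02d", sample(1:45, 60, replace = TRUE)),
    ageYears = runif(60, 1.5, 4.5))
  ws3 <- slidingWindows(meta3, width = 20)
  sorted <- meta3[order(meta3$ageYears), ]
  wanted <- sum(sapply(1:41, function(s)
    !any(duplicated(sorted$subjectId[s:(s + 19)]))))
  expect_equal(length(ws3), wanted)
  expect_true(all(sapply(ws3@windows, function(i)
    !any(duplicated(ws3@meta$subjectId[i])))))
})

test_that("dispersion reduces to known analytic values", {
  mk <- function(pts) lapply(seq_len(nrow(pts)), function(i) {
    m <- matrix(pts[i, ], 1, 2); colnames(m) <- c("x", "y"); m
  })
  ## two points at distance d
  expect_equal(dispersion(mk(rbind(c(0, 0), c(3, 4))))$mean, 5)
  ## coincident points
  expect_equal(dispersion(mk(rbind(c(7, 7), c(7, 7), c(7, 7))))$mean, 0)
  ## unit equilateral triangle
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(dispersion(mk(tri))$mean, 1)
  ## translation/rotation invariance and linear scaling
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(dispersion(mk(tri %*% rot + 5))$mean, 1)
  expect_equal(dispersion(mk(3 * tri))$mean, 3)
  expect_error(dispersion(mk(rbind(c(1, 1)))), "at least 2")
})

test_that("the dispersion permutation test behaves at its edges", {
  set.seed(49)
  a <- randomFrameGaze(6, 10, 40)
  ## identical membership on both sides: statistic 0, p = 1
  res <- dispersionPermutationTest(a, a, nPerm = 49, seed = 50)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(dispersionPermutationTest(a[1], a, nPerm = 9), "at least 2")
  ## a genuinely wider group is detected
  b <- randomFrameGaze(6, 10, 160)
  res2 <- dispersionPermutationTest(a, b, nPerm = 99, seed = 51)
  expect_lt(res2$statistic, 0)
  expect_lte(res2$p, 0.05)
})

test_that("group comparison wrappers reproduce the standard tests", {
  set.seed(52)
  x <- rnorm(30); y <- rnorm(30, 1.2)
  gt <- groupCompare(x, y, "t")
  expect_equal(gt$p, t.test(x, y)$p.value)
  gm <- groupCompare(x, y, "mann-whitney")
  expect_equal(gm$p, wilcox.test(x, y, exact = FALSE)$p.value)
  expect_lt(gm$p, 0.01)
  gw <- groupCompare(x, y, "wilcoxon-paired")
  expect_equal(gw$p, wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value)
  ## equal samples are unremarkable
  expect_gt(groupCompare(x, x + rnorm(30, 0, 1e-3), "t")$p, 0.5)
})
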