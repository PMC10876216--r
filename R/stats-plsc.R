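#' Residualize a data matrix on a covariate
#'
#' Replaces each column by the residuals of its least-squares fit on an
#' intercept plus the covariate (e.g. removing age before a PLS
#' correlation). A constant covariate triggers intercept-only
#' residualization with a warning.
#'
#' @param X numeric matrix, observations x variables
#' @param covariate numeric vector, one value per row of X
#' @return residual matrix of the same shape
#' @export
regressOut <- function(X, covariate) {
  X <- as.matrix(X)
  if (length(covariate) != nrow(X))
    stop("covariate length must equal the number of rows")
  if (stats::sd(covariate) == 0) {
    warning("constant covariate; residualizing on the intercept only")
    return(sweep(X, 2L, colMeans(X)))
  }
  Q <- qr.Q(qr(cbind(1, covariate)))
  X - Q %*% crossprod(Q, X)
}

#' Impute missing entries of a data matrix
#'
#' @param X numeric matrix with possible NAs
#' @param method \code{"median"} (column median) or \code{"mean"}
#' @return list with \code{data} (complete matrix) and \code{mask}
#'   (logical matrix of imputed positions)
#' @export
imputeMatrix <- function(X, method = c("median", "mean")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  mask <- is.na(X)
  if (any(colSums(!mask) == 0)) stop("column with no observed values")
  fill <- apply(X, 2L, if (method == "median") function(v)
    stats::median(v, na.rm = TRUE) else function(v) mean(v, na.rm = TRUE))
  for (j in which(colSums(mask) > 0)) X[mask[, j], j] <- fill[j]
  list(data = X, mask = mask)
}

.zscore <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 2L, stats::sd)
  if (any(s == 0)) stop("constant column cannot be z-scored")
  scale(X)[, , drop = FALSE]
}

#' Partial least squares correlation with permutation and bootstrap
#'
#' Z-scores both blocks, forms the cross-correlation matrix
#' \eqn{R = B^T A / (n - 1)} and decomposes it by SVD, \eqn{R = U \Delta
#' V^T}. U holds the B-side (behavioural) saliences, V the A-side
#' saliences, and the latent scores are \eqn{L_a = A V}, \eqn{L_b = B U}.
#' Component significance comes from permuting the rows of B
#' (\code{nPerm} times, p with the +1 correction, compared per component
#' without re-sorting); loading stability comes from bootstrap resampling
#' rows with replacement, Procrustes-aligning each resample's saliences to
#' the original, and taking 5th-95th percentile intervals -- a loading is
#' stable when its interval excludes zero.
#'
#' @param A,B numeric matrices with the same number of rows (observations)
#' @param nPerm permutations for component significance
#' @param nBoot bootstrap resamples for loading stability
#' @param seed integer seed
#' @return a [PLSCResult-class]
#' @export
plsc <- function(A, B, nPerm = 1000, nBoot = 1000, seed = 1) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must have the same number of rows")
  if (nrow(A) < 5) stop("at least 5 observations are required")
  set.seed(seed)
  n <- nrow(A)
  Az <- .zscore(A); Bz <- .zscore(B)
  k <- min(ncol(A), ncol(B))
  dec <- .plscSVD(Az, Bz, k)
  if (max(dec$d) == 0) warning("rank-0 cross-correlation matrix")
  La <- Az %*% dec$v
  Lb <- Bz %*% dec$u
  latentCor <- vapply(seq_len(k), function(j) {
    if (stats::sd(La[, j]) == 0 || stats::sd(Lb[, j]) == 0) 0
    else stats::cor(La[, j], Lb[, j])
  }, numeric(1))

  exceed <- integer(k)
  for (p in seq_len(nPerm)) {
    Bp <- Bz[sample(n), , drop = FALSE]
    dp <- .plscSVD(Az, .zscore(Bp), k)$d
    exceed <- exceed + (dp >= dec$d)
  }
  permP <- (1 + exceed) / (nPerm + 1)

  if (nBoot < 1) {
    nas <- matrix(NA_real_, ncol(B), k)
    nasV <- matrix(NA_real_, ncol(A), k)
    return(new("PLSCResult",
               u = dec$u, v = dec$v, singularValues = dec$d,
               latentCorrelations = latentCor, scoresA = La, scoresB = Lb,
               permP = permP,
               bootLowerU = nas, bootUpperU = nas,
               bootLowerV = nasV, bootUpperV = nasV,
               stableU = matrix(FALSE, ncol(B), k),
               stableV = matrix(FALSE, ncol(A), k),
               nPerm = as.integer(nPerm), nBoot = 0L))
  }
  bootU <- array(NA_real_, c(ncol(B), k, nBoot))
  bootV <- array(NA_real_, c(ncol(A), k, nBoot))
  b <- 0L
  tries <- 0L
  while (b < nBoot && tries < 20L * nBoot) {
    tries <- tries + 1L
    idx <- sample(n, replace = TRUE)
    Ab <- A[idx, , drop = FALSE]; Bb <- B[idx, , drop = FALSE]
    if (any(apply(Ab, 2L, stats::sd) == 0) ||
        any(apply(Bb, 2L, stats::sd) == 0)) next
    db <- .plscSVD(.zscore(Ab), .zscore(Bb), k)
    rot <- .procrustesRotation(db$u, dec$u)
    b <- b + 1L
    bootU[, , b] <- db$u %*% rot
    bootV[, , b] <- db$v %*% rot
  }
  if (b < nBoot) {
    bootU <- bootU[, , seq_len(b), drop = FALSE]
    bootV <- bootV[, , seq_len(b), drop = FALSE]
    warning("only ", b, " usable bootstrap resamples")
  }
  qU <- apply(bootU, c(1L, 2L), stats::quantile, probs = c(0.05, 0.95))
  qV <- apply(bootV, c(1L, 2L), stats::quantile, probs = c(0.05, 0.95))
  lowU <- matrix(qU[1L, , ], ncol(B), k); uppU <- matrix(qU[2L, , ], ncol(B), k)
  lowV <- matrix(qV[1L, , ], ncol(A), k); uppV <- matrix(qV[2L, , ], ncol(A), k)
  new("PLSCResult",
      u = dec$u, v = dec$v, singularValues = dec$d,
      latentCorrelations = latentCor, scoresA = La, scoresB = Lb,
      permP = permP,
      bootLowerU = lowU, bootUpperU = uppU,
      bootLowerV = lowV, bootUpperV = uppV,
      stableU = lowU * uppU > 0, stableV = lowV * uppV > 0,
      nPerm = as.integer(nPerm), nBoot = as.integer(b))
}

## SVD of the cross-correlation matrix, truncated to k components with a
## deterministic sign convention (largest-|.| element of each u positive)
.plscSVD <- function(Az, Bz, k) {
  R <- crossprod(Bz, Az) / (nrow(Az) - 1)
  s <- svd(R, nu = k, nv = k)
  u <- s$u[, seq_len(k), drop = FALSE]
  v <- s$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    sgn <- sign(u[which.max(abs(u[, j])), j])
    if (sgn < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  list(u = u, v = v, d = s$d[seq_len(k)])
}

## orthogonal Procrustes rotation aligning M onto target
.procrustesRotation <- function(M, target) {
  s <- svd(crossprod(M, target))
  s$u %*% t(s$v)
}

setMethod("show", "PLSCResult", function(object) {
  k <- length(object@singularValues)
  cat(sprintf("PLSCResult: %d component%s\n", k, if (k > 1) "s" else ""))
  for (j in seq_len(k)) {
    cat(sprintf(
      "  LC%d: singular value %.4f, latent r = %.3f, perm p = %.4g, %d/%d stable B-loadings\n",
      j, object@singularValues[j], object@latentCorrelations[j],
      object@permP[j], sum(object@stableU[, j]), nrow(object@stableU)))
  }
})

#' Accessors for PLS correlation results
#'
#' @param result a [PLSCResult-class]
#' @return \code{latentCorrelations}: per-component latent correlation;
#'   \code{permutationP}: per-component permutation p-values;
#'   \code{stableLoadings}: logical matrix of bootstrap-stable B-side
#'   loadings.
#' @export
latentCorrelations <- function(result) result@latentCorrelations

#' @rdname latentCorrelations
#' @export
permutationP <- function(result) result@permP

#' @rdname latentCorrelations
#' @export
stableLoadings <- function(result) result@stableU

#' Two-group comparison wrappers
#'
#' Thin wrappers over the standard two-sample tests used around the main
#' analyses.
#'
#' @param valuesA,valuesB numeric vectors
#' @param test \code{"t"} (Welch), \code{"mann-whitney"} or
#'   \code{"wilcoxon-paired"}
#' @return list with \code{statistic} and \code{p}
#' @export
groupCompare <- function(valuesA, valuesB,
                         test = c("t", "mann-whitney", "wilcoxon-paired")) {
  test <- match.arg(test)
  res <- switch(test,
    "t" = stats::t.test(valuesA, valuesB),
    "mann-whitney" = stats::wilcox.test(valuesA, valuesB, exact = FALSE),
    "wilcoxon-paired" = stats::wilcox.test(valuesA, valuesB, paired = TRUE,
                                           exact = FALSE))
  list(statistic = unname(res$statistic), p = res$p.value)
}
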