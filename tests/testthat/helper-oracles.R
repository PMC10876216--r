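## Independent brute-force oracles and small fixture builders used across
## the suite. Oracles are deliberately naive (loops, direct summation) and
## share no code with the package internals.

## small screen keeps KDE grids quick in unit tests
smallGeometry <- function() {
  screenGeometry(widthPx = 320, heightPx = 200, widthDeg = 20,
                 heightDeg = 12.7, viewingDistanceCm = 60)
}

## build an all-valid recording from a trace of (t, x, y)
traceRecording <- function(t, x, y, geom = screenGeometry(), hz = 300,
                           valid = TRUE) {
  s <- data.frame(t = t, lx = x, ly = y, rx = x, ry = y,
                  lValid = valid, rValid = valid)
  gazeRecording(s, geom, samplingHz = hz)
}

## direct kernel-summation adaptive KDE (pilot + Abramson), looped per point
oracleKDE <- function(pts, grid, adaptive = TRUE, bandwidth = NULL) {
  n <- nrow(pts)
  if (is.null(bandwidth)) {
    s <- apply(pts, 2, sd)
    s[!is.finite(s) | s <= 0] <- grid$cellSizePx
    h <- pmax(s * n^(-1 / 6), grid$cellSizePx)
  } else h <- rep(bandwidth, 2)
  lambda <- rep(1, n)
  if (adaptive && n > 1) {
    fp <- sapply(seq_len(n), function(i)
      mean(dnorm(pts[i, 1] - pts[, 1], sd = h[1]) *
           dnorm(pts[i, 2] - pts[, 2], sd = h[2])))
    g <- exp(mean(log(fp)))
    lambda <- (fp / g)^(-1 / 2)
  }
  M <- matrix(0, length(grid$yCenters), length(grid$xCenters))
  for (i in seq_len(n)) {
    M <- M + outer(dnorm(grid$yCenters - pts[i, 2], sd = h[2] * lambda[i]),
                   dnorm(grid$xCenters - pts[i, 1], sd = h[1] * lambda[i]))
  }
  M <- M / n
  M / (sum(M) * grid$cellSizePx^2)
}

## independent bilinear interpolation, scalar, plain arithmetic
oracleBilinear <- function(grid, xc, yc, x, y) {
  x <- min(max(x, xc[1]), xc[length(xc)])
  y <- min(max(y, yc[1]), yc[length(yc)])
  ix <- max(which(xc <= x)); iy <- max(which(yc <= y))
  ix <- min(ix, length(xc) - 1); iy <- min(iy, length(yc) - 1)
  tx <- (x - xc[ix]) / (xc[ix + 1] - xc[ix])
  ty <- (y - yc[iy]) / (yc[iy + 1] - yc[iy])
  (1 - ty) * ((1 - tx) * grid[iy, ix] + tx * grid[iy, ix + 1]) +
    ty * ((1 - tx) * grid[iy + 1, ix] + tx * grid[iy + 1, ix + 1])
}

## exhaustive level scan: count levels at or below the local density
oraclePI <- function(gazeXY, surf, lev) {
  f <- oracleBilinear(surf@grid, surf@xCenters, surf@yCenters,
                      gazeXY[1], gazeXY[2])
  k <- 0
  for (l in lev@levels) if (f >= l) k <- k + 1
  k / length(lev@levels)
}

## brute-force I-VT: label every sample by thresholded velocity (scanning
## the raw window bounds), collect runs, then merge pairwise
oracleIVT <- function(rec, vt = 30, vw = 0.020, gap = 0.075, ang = 0.5) {
  s <- gazeSamples(rec)
  geom <- geometry(rec)
  ang2d <- function(dx, dy) pixelsToDegrees(dx, geom, dy = dy)
  x <- ifelse(s$lValid & s$rValid, (s$lx + s$rx) / 2,
              ifelse(s$lValid, s$lx, ifelse(s$rValid, s$rx, NA)))
  y <- ifelse(s$lValid & s$rValid, (s$ly + s$ry) / 2,
              ifelse(s$lValid, s$ly, ifelse(s$rValid, s$ry, NA)))
  t <- s$t
  keep <- !is.na(x)
  ## split into segments at invalid gaps > gap; interpolate shorter gaps
  segs <- list(); cur <- integer(0); lastValid <- NA
  for (i in seq_along(t)) {
    if (keep[i]) {
      if (!is.na(lastValid) && t[i] - t[lastValid] > gap) {
        if (length(cur)) segs[[length(segs) + 1]] <- cur
        cur <- integer(0)
      }
      cur <- c(cur, i)
      lastValid <- i
    }
  }
  if (length(cur)) segs[[length(segs) + 1]] <- cur
  fixs <- list()
  for (seg in segs) {
    idx <- seg[1]:seg[length(seg)]
    xs <- approx(t[seg], x[seg], xout = t[idx])$y
    ys <- approx(t[seg], y[seg], xout = t[idx])$y
    tt <- t[idx]
    n <- length(idx)
    if (n < 2) next
    slow <- logical(n)
    for (i in seq_len(n)) {
      lo <- i; hi <- i
      while (lo > 1 && tt[lo - 1] >= tt[i] - vw / 2) lo <- lo - 1
      while (hi < n && tt[hi + 1] <= tt[i] + vw / 2) hi <- hi + 1
      if (hi == lo) { lo <- max(1, i - 1); hi <- min(n, i + 1) }
      v <- if (hi == lo || tt[hi] == tt[lo]) 0 else
        ang2d(xs[hi] - xs[lo], ys[hi] - ys[lo]) / (tt[hi] - tt[lo])
      slow[i] <- v < vt
    }
    i <- 1
    while (i <= n) {
      if (slow[i]) {
        j <- i
        while (j < n && slow[j + 1]) j <- j + 1
        if (j > i) fixs[[length(fixs) + 1]] <-
          list(onset = tt[i], offset = tt[j],
               x = mean(xs[i:j]), y = mean(ys[i:j]))
        i <- j + 1
      } else i <- i + 1
    }
  }
  if (!length(fixs)) return(data.frame())
  fixs <- fixs[order(sapply(fixs, `[[`, "onset"))]
  merged <- list(fixs[[1]])
  for (f in fixs[-1]) {
    m <- merged[[length(merged)]]
    if (f$onset - m$offset <= gap &&
        ang2d(f$x - m$x, f$y - m$y) <= ang) {
      w1 <- m$offset - m$onset; w2 <- f$offset - f$onset
      merged[[length(merged)]] <- list(
        onset = m$onset, offset = f$offset,
        x = (w1 * m$x + w2 * f$x) / (w1 + w2),
        y = (w1 * m$y + w2 * f$y) / (w1 + w2))
    } else merged[[length(merged) + 1]] <- f
  }
  out <- do.call(rbind, lapply(merged, as.data.frame))
  out$duration <- out$offset - out$onset
  out$saccadeAmplitude <- c(NA, sapply(seq_len(nrow(out))[-1], function(i)
    ang2d(out$x[i] - out$x[i - 1], out$y[i] - out$y[i - 1])))
  out
}

## all-pairs AUC with half credit for ties
oracleAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

## frame-gaze matrices drawn around a common center, for dispersion tests
randomFrameGaze <- function(nRec, nFrames, sd, center = c(500, 400)) {
  lapply(seq_len(nRec), function(i) {
    m <- cbind(x = rnorm(nFrames, center[1], sd),
               y = rnorm(nFrames, center[2], sd))
    m
  })
}
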