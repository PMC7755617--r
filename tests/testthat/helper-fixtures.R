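## Compact phantom geometry for fast tests: same banana shape, scaled down.
testCenterline <- function(side) {
  right <- cbind(x = c(13, 14, 12.5, 10.5, 8.5),
                 y = c(-12, -6, 0, 5, 9),
                 z = c(-4, -2, 0, 2, 5))
  if (side == "right") right else {
    left <- right; left[, 1] <- -left[, 1]; left
  }
}

testSpec <- function(side, baseRadius = 4, ...) {
  HippocampusSpec(side, centerline = testCenterline(side),
                  baseRadius = baseRadius, ...)
}

testAcq <- function(noiseSigma = 0, seed = NA_real_, ...) {
  AcquisitionSpec(gridShape = c(48L, 36L, 22L), noiseSigma = noiseSigma,
                  seed = seed, ...)
}

testSubject <- function(leftArgs = list(), rightArgs = list(),
                        noiseSigma = 0, seed = NA_real_) {
  makePhantomSubject(do.call(testSpec, c(list("left"), leftArgs)),
                     do.call(testSpec, c(list("right"), rightArgs)),
                     testAcq(noiseSigma, seed))
}

## Straight axis-aligned tube (circular cross-section) for analytic oracles.
straightSpec <- function(side = "left", length = 30, radius = 4,
                         taper = 0.35, ellipticity = 1, ...) {
  ctrl <- cbind(0, seq(-length / 2, length / 2, length.out = 5), 0)
  HippocampusSpec(side, centerline = ctrl, baseRadius = radius,
                  taper = taper, ellipticity = ellipticity, ...)
}

straightGrid <- function() phantomGrid(c(30L, 48L, 30L), 1)

## Analytic volume of the tapered elliptical tube (independent of the
## voxeliser): pi * a * b * L * integral of taper(s)^2.
analyticTubeVolume <- function(radius, ellipticity, length, taper,
                               atrophy = 1) {
  tf <- taper^2 + 2 * taper * (1 - taper) * (2 / pi) + (1 - taper)^2 / 2
  pi * radius^2 * atrophy * ellipticity * length * tf
}

## Metric-level healthy GlobalMetrics draw (Gaussian, independent sides).
drawHealthyMetrics <- function(n, volMean = 2100, volSD = 95,
                               qt2Mean = 100, qt2SD = 1.9) {
  lapply(seq_len(n), function(i) {
    vL <- stats::rnorm(1, volMean, volSD); vR <- stats::rnorm(1, volMean, volSD)
    qL <- stats::rnorm(1, qt2Mean, qt2SD); qR <- stats::rnorm(1, qt2Mean, qt2SD)
    list(metrics = new("GlobalMetrics", volLeft = vL, volRight = vR,
                       qt2Left = qL, qt2Right = qR,
                       lrVolRatioPct = 100 * vL / vR,
                       lrQt2RatioPct = 100 * qL / qR,
                       asymVolRatioPct = 100 * min(vL, vR) / max(vL, vR),
                       asymQt2RatioPct = 100 * max(qL, qR) / min(qL, qR)))
  })
}

## Brute-force balanced ANOVA sums of squares: per-row effect estimates by
## inclusion-exclusion over cell means (independent of any model fitter).
bruteForceSS <- function(data, dv, factors) {
  grand <- mean(data[[dv]])
  rowEff <- list()
  ss <- list(total = sum((data[[dv]] - grand)^2))
  for (k in seq_along(factors)) {
    for (fs in utils::combn(factors, k, simplify = FALSE)) {
      idx <- interaction(data[fs], drop = TRUE)
      e <- stats::ave(data[[dv]], idx) - grand
      for (sub in names(rowEff)) {
        if (all(strsplit(sub, ":")[[1]] %in% fs)) e <- e - rowEff[[sub]]
      }
      key <- paste(fs, collapse = ":")
      rowEff[[key]] <- e
      ss[[key]] <- sum(e^2)
    }
  }
  ss
}
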