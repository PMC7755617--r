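#' Global mask volume in mm^3
#'
#' Voxel count times voxel volume; exact.
#'
#' @param mask A non-empty \linkS4class{LabelMask}.
#' @return Volume in mm^3.
#' @export
maskVolumeMm3 <- function(mask) {
  n <- sum(mask@data == 1)
  if (n == 0L) hqStop("hippoquant_empty_mask", "mask contains no voxels")
  n * prod(mask@spacing)
}

#' Global qT2 of one hippocampus
#'
#' Summary (mean by default, median by configuration) of T2 over in-mask
#' voxels with a valid fit.
#'
#' @param mask A \linkS4class{LabelMask}.
#' @param t2map A \linkS4class{T2Map} on the same grid.
#' @param stat \code{"mean"} or \code{"median"}.
#' @return qT2 in ms.
#' @export
globalQt2 <- function(mask, t2map, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  assertSameGrid(mask, t2map@t2)
  sel <- mask@data == 1 & t2map@valid == 1
  if (!any(sel))
    hqStop("hippoquant_no_valid_fits", "no valid T2 fits inside the mask")
  vals <- t2map@t2@data[sel]
  if (stat == "mean") mean(vals) else stats::median(vals)
}

#' Left:right ratio in percent
#'
#' \code{100 * left / right}. Satisfies the anti-symmetry identity
#' \code{lrRatioPct(a, b) * lrRatioPct(b, a) == 1e4}.
#'
#' @param leftValue,rightValue Positive values.
#' @return Percent.
#' @export
lrRatioPct <- function(leftValue, rightValue) {
  if (rightValue <= 0)
    hqStop("hippoquant_bad_denominator", "right value must be positive")
  100 * leftValue / rightValue
}

#' Long-axis frame of a hippocampus
#'
#' The long axis is the leading principal axis of the in-mask voxel world
#' coordinates (a deterministic, self-contained stand-in for group-template
#' alignment), sign-fixed so its anterior (world +A) component is positive;
#' with no anterior component, the larger remaining world component decides.
#' Arc bounds are the [2.5, 97.5] percentile interval of the projections,
#' padded outwards to cover every voxel so that binning partitions the mask.
#'
#' @param mask A \linkS4class{LabelMask} with >= 10 voxels and a dominant
#'   axis (leading principal SD exceeding the second by >= 5 percent).
#' @return A \linkS4class{LongAxisFrame}.
#' @export
longAxisFrame <- function(mask) {
  W <- maskWorldCoords(mask)
  if (nrow(W) < 10L)
    hqStop("hippoquant_too_few_voxels",
           "need >= 10 mask voxels, got ", nrow(W))
  pc <- stats::prcomp(W, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] < 1.05 * pc$sdev[2])
    hqStop("hippoquant_degenerate_axis",
           "no dominant long axis (principal SDs ",
           format(pc$sdev[1]), " vs ", format(pc$sdev[2]), ")")
  dirv <- pc$rotation[, 1]
  if (abs(dirv[2]) > 1e-9) {
    if (dirv[2] < 0) dirv <- -dirv           # anterior = world +y (RAS)
  } else if (dirv[which.max(abs(dirv))] < 0) dirv <- -dirv
  dirv <- dirv / sqrt(sum(dirv^2))
  proj <- as.vector(W %*% dirv)
  q <- stats::quantile(proj, c(0.025, 0.975), names = FALSE)
  lo <- min(q[1], min(proj)); hi <- max(q[2], max(proj))
  new("LongAxisFrame", origin = colMeans(W), direction = as.numeric(dirv),
      arcBounds = c(lo, hi))
}

#' Posterior-anterior profile along the long axis
#'
#' Partitions the mask voxels by projection onto the frame direction into
#' \code{nBins} equal-width bins spanning the arc bounds. Per bin:
#' volume (exact), cross-sectional area = volume / bin width, and mean qT2
#' over valid fits (NaN where none). Positions run posterior (0) to
#' anterior (1).
#'
#' @param mask A \linkS4class{LabelMask}.
#' @param t2map A \linkS4class{T2Map} on the same grid (or NULL: qt2 all
#'   NaN).
#' @param frame A \linkS4class{LongAxisFrame}; computed from the mask when
#'   NULL.
#' @param nBins Number of bins, >= 2 (default 20).
#' @return A \linkS4class{HippocampusProfile}.
#' @export
hippocampusProfile <- function(mask, t2map = NULL, frame = NULL,
                               nBins = 20L) {
  if (nBins < 2L) hqStop("hippoquant_bad_bins", "nBins must be >= 2")
  if (is.null(frame)) frame <- longAxisFrame(mask)
  W <- maskWorldCoords(mask)
  proj <- as.vector(W %*% frame@direction)
  lo <- frame@arcBounds[1]; hi <- frame@arcBounds[2]
  width <- (hi - lo) / nBins
  bin <- pmin(pmax(floor((proj - lo) / width), 0), nBins - 1) + 1L
  voxVol <- prod(mask@spacing)
  binVolume <- tabulate(bin, nbins = nBins) * voxVol
  qt2 <- rep(NaN, nBins)
  if (!is.null(t2map)) {
    assertSameGrid(mask, t2map@t2)
    sel <- mask@data == 1
    t2v <- t2map@t2@data[sel]
    okv <- t2map@valid[sel] == 1
    for (b in seq_len(nBins)) {
      inb <- bin == b & okv
      if (any(inb)) qt2[b] <- mean(t2v[inb])
    }
  }
  new("HippocampusProfile", side = mask@side,
      positions = (seq_len(nBins) - 0.5) / nBins,
      area = binVolume / width, qt2 = qt2, binVolume = binVolume)
}

#' Global metrics for one subject
#'
#' Volumes and global qT2 per side, plain left:right ratios, and
#' orientation-free asymmetry ratios (min:max volume, max:min qT2).
#'
#' @param left,right \linkS4class{LabelMask} per side.
#' @param t2map A \linkS4class{T2Map} covering both masks.
#' @param stat Summary statistic for global qT2.
#' @return A \linkS4class{GlobalMetrics}.
#' @export
computeGlobalMetrics <- function(left, right, t2map,
                                 stat = c("mean", "median")) {
  stat <- match.arg(stat)
  vL <- maskVolumeMm3(left); vR <- maskVolumeMm3(right)
  qL <- globalQt2(left, t2map, stat); qR <- globalQt2(right, t2map, stat)
  new("GlobalMetrics", volLeft = vL, volRight = vR, qt2Left = qL,
      qt2Right = qR,
      lrVolRatioPct = lrRatioPct(vL, vR),
      lrQt2RatioPct = lrRatioPct(qL, qR),
      asymVolRatioPct = 100 * min(vL, vR) / max(vL, vR),
      asymQt2RatioPct = 100 * max(qL, qR) / min(qL, qR))
}
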