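#' Two-point monoexponential T2 fit
#'
#' Closed-form voxel fit from two effective echoes under
#' \eqn{S(TE) = S_0 \exp(-TE/T_2)}:
#' \deqn{T_2 = (TE_2 - TE_1) / \ln(S_1/S_2), \quad S_0 = S_1 e^{TE_1/T_2}.}
#' A fit is valid only when the signal decays (\eqn{S_1 > S_2 >} noise
#' floor) and the resulting T2 falls inside the clamp range; otherwise T2
#' and S0 are the \code{NaN} sentinel and the validity flag is 0, so
#' downstream code must mask explicitly.
#'
#' @param s1,s2 Signals at te1 and te2 (vectorised).
#' @param te1,te2 Echo times in ms, te1 < te2.
#' @param eps Noise floor in signal units.
#' @param clamp Admissible T2 range in ms.
#' @return A list with numeric \code{t2}, \code{s0} and 0/1 \code{valid},
#'   plus \code{clamped}: 0/1, fits rejected only because T2 fell outside
#'   the clamp range.
#' @examples
#' fitTwoPointT2(1000, 1000 / exp(1), 30, 119)$t2  # 89 ms exactly
#' @export
fitTwoPointT2 <- function(s1, s2, te1, te2, eps = 1e-6, clamp = c(1, 2000)) {
  if (te1 >= te2)
    hqStop("hippoquant_te_order", "echo times must satisfy te1 < te2 (got ",
           te1, " >= ", te2, ")")
  decaying <- is.finite(s1) & is.finite(s2) & (s2 > eps) & (s1 > s2)
  t2 <- rep(NaN, length(s1))
  t2[decaying] <- (te2 - te1) / log(s1[decaying] / s2[decaying])
  inClamp <- decaying & t2 >= clamp[1] & t2 <= clamp[2]
  clamped <- as.numeric(decaying & !inClamp)
  t2[!inClamp] <- NaN
  s0 <- rep(NaN, length(s1))
  s0[inClamp] <- s1[inClamp] * exp(te1 / t2[inClamp])
  list(t2 = t2, s0 = s0, valid = as.numeric(inClamp), clamped = clamped)
}

#' Compute a voxel-wise qT2 map from two effective-echo images
#'
#' Applies \code{\link{fitTwoPointT2}} at every voxel (or only inside
#' \code{roi} when given). Echo times are taken from the volumes'
#' \code{meta$te} unless passed explicitly.
#'
#' @param echo1,echo2 \linkS4class{Volume3D} on one grid, echo1 the shorter
#'   TE.
#' @param roi Optional \linkS4class{LabelMask} (or plain 0/1 array)
#'   restricting the fit; voxels outside are the sentinel with valid = 0.
#' @param te1,te2 Echo times in ms; default from metadata.
#' @param eps,clamp Passed to \code{\link{fitTwoPointT2}}.
#' @return A \linkS4class{T2Map}.
#' @export
computeT2Map <- function(echo1, echo2, roi = NULL, te1 = NULL, te2 = NULL,
                         eps = 1e-6, clamp = c(1, 2000)) {
  assertSameGrid(echo1, echo2)
  if (is.null(te1)) te1 <- echo1@meta$te
  if (is.null(te2)) te2 <- echo2@meta$te
  if (is.null(te1) || is.null(te2))
    hqStop("hippoquant_missing_te",
           "echo times not found in metadata; pass te1/te2 explicitly")
  s1 <- as.vector(echo1@data)
  s2 <- as.vector(echo2@data)
  sel <- if (is.null(roi)) rep(TRUE, length(s1)) else {
    r <- if (is(roi, "Volume3D")) {
      assertSameGrid(echo1, roi)
      roi@data
    } else roi
    as.vector(r) == 1
  }
  shape <- dim(echo1@data)
  t2 <- array(NaN, shape); s0 <- array(NaN, shape)
  valid <- array(0, shape); clamped <- array(0, shape)
  fit <- fitTwoPointT2(s1[sel], s2[sel], te1, te2, eps = eps, clamp = clamp)
  t2[sel] <- fit$t2; s0[sel] <- fit$s0
  valid[sel] <- fit$valid; clamped[sel] <- fit$clamped
  mk <- function(a, units) Volume3D(a, echo1@spacing, echo1@affine,
                                    list(units = units, te1 = te1, te2 = te2))
  m <- new("T2Map", t2 = mk(t2, "ms"), s0 = mk(s0, "signal"),
           valid = valid, clampRange = clamp)
  m@t2@meta$clamped <- clamped
  m
}

#' Quality control of a T2 fit within an ROI
#'
#' @param map A \linkS4class{T2Map}.
#' @param roi A \linkS4class{LabelMask} or 0/1 array; must be non-empty.
#' @return A \linkS4class{FitQC}: \code{fracNonphysical} is the share of ROI
#'   voxels with no valid fit (including clamp rejections);
#'   \code{fracClamped} the share rejected specifically at the clamp bounds.
#' @export
qcFit <- function(map, roi) {
  r <- if (is(roi, "Volume3D")) {
    assertSameGrid(map@t2, roi)
    roi@data
  } else roi
  sel <- as.vector(r) == 1
  n <- sum(sel)
  if (n == 0L) hqStop("hippoquant_empty_roi", "ROI contains no voxels")
  bad <- sum(as.vector(map@valid)[sel] == 0)
  cl <- sum(as.vector(map@t2@meta$clamped)[sel] == 1)
  new("FitQC", nVoxelsFit = as.integer(n), fracNonphysical = bad / n,
      fracClamped = cl / n,
      note = sprintf("%d ROI voxels, %d invalid (%d clamped)", n, bad, cl))
}
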