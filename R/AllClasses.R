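#' @import methods
NULL

## Error helper: every contract violation raises a classed condition so
## callers (and tests) can distinguish failure modes by name.
hqStop <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "hippoquant_error")))
}

#' Volume3D: a 3D scalar image on a regular grid
#'
#' The carrier type for all imaging data in the package: structural volumes,
#' the two effective-echo images, T2/S0 maps. Voxel indices are 0-based and a
#' voxel's world position (mm, RAS+) is the affine image of its integer index
#' (voxel-centre convention).
#'
#' @slot data 3D numeric array (arbitrary signal units).
#' @slot spacing Per-axis voxel size in mm, length 3, all positive.
#' @slot affine 4x4 voxel-index-to-world map (RAS+ world convention).
#' @slot meta Free-form named list (e.g. echo time \code{te} in ms).
#' @export
setClass("Volume3D",
  representation(data = "array", spacing = "numeric", affine = "matrix",
                 meta = "list"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3D array")
    if (any(d < 1L)) return("data dimensions must be >= 1 on every axis")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be three positive values (mm)")
    if (!all(dim(object@affine) == c(4L, 4L)))
      return("affine must be a 4x4 matrix")
    if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
    TRUE
  })

#' LabelMask: a binary hippocampal mask
#'
#' A \linkS4class{Volume3D} whose lattice contains only 0/1, tagged with the
#' side (left/right) of the hippocampus it delineates.
#'
#' @slot side \code{"left"} or \code{"right"}.
#' @export
setClass("LabelMask", contains = "Volume3D",
  representation(side = "character"),
  validity = function(object) {
    if (!object@side %in% c("left", "right"))
      return("side must be 'left' or 'right'")
    v <- unique(as.vector(object@data))
    if (!all(v %in% c(0, 1))) return("mask values must be exactly 0 or 1")
    TRUE
  })

#' T2Map: voxel-wise quantitative T2 with fit validity
#'
#' Result of the two-point monoexponential fit. Wherever \code{valid == 0}
#' the t2 and s0 lattices hold \code{NaN}; wherever \code{valid == 1} the
#' fit is physically interpretable (t2 inside the clamp range, s0 > 0).
#'
#' @slot t2 \linkS4class{Volume3D}, T2 in ms.
#' @slot s0 \linkS4class{Volume3D}, extrapolated TE=0 signal.
#' @slot valid 3D 0/1 array flagging interpretable fits.
#' @slot clampRange Admissible T2 interval in ms.
#' @export
setClass("T2Map",
  representation(t2 = "Volume3D", s0 = "Volume3D", valid = "array",
                 clampRange = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@t2@data), dim(object@valid)))
      return("valid lattice must match t2 grid")
    if (length(object@clampRange) != 2L ||
        object@clampRange[1] >= object@clampRange[2])
      return("clampRange must be an increasing length-2 interval")
    ok <- object@valid == 1
    if (any(is.na(object@t2@data[ok])))
      return("valid voxels must carry finite t2")
    if (any(!is.na(object@t2@data[!ok])))
      return("invalid voxels must carry the NaN sentinel")
    TRUE
  })

#' FitQC: quality-control summary of a T2 fit
#' @slot nVoxelsFit Number of ROI voxels attempted.
#' @slot fracNonphysical Share of ROI voxels with no interpretable fit.
#' @slot fracClamped Share of attempted fits rejected at the clamp bounds.
#' @slot note Free-text summary.
#' @export
setClass("FitQC",
  representation(nVoxelsFit = "integer", fracNonphysical = "numeric",
                 fracClamped = "numeric", note = "character"),
  validity = function(object) {
    f <- c(object@fracNonphysical, object@fracClamped)
    if (any(f < 0 | f > 1)) return("fractions must lie in [0,1]")
    TRUE
  })

#' LongAxisFrame: the long-axis coordinate frame of one hippocampus
#'
#' Direction is the leading principal axis of the in-mask voxel world
#' coordinates, sign-fixed to point anterior (positive world +A component).
#'
#' @slot origin World-mm centroid of the mask.
#' @slot direction Unit vector, posterior to anterior.
#' @slot arcBounds Projection interval [lo, hi] (mm) used for binning.
#' @export
setClass("LongAxisFrame",
  representation(origin = "numeric", direction = "numeric",
                 arcBounds = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
      return("direction must have unit norm")
    if (object@arcBounds[2] <= object@arcBounds[1])
      return("arcBounds must be increasing")
    TRUE
  })

#' HippocampusProfile: posterior-anterior long-axis profile
#'
#' Cross-sectional area (mm^2) and qT2 (ms) per bin along the hippocampal
#' long axis; position 0 is posterior, 1 anterior.
#'
#' @slot side \code{"left"} or \code{"right"}.
#' @slot positions Bin centres as arc fractions in [0,1], strictly increasing.
#' @slot area Per-bin cross-sectional area, mm^2.
#' @slot qt2 Per-bin mean qT2 over valid fits, ms (NaN where none).
#' @slot binVolume Per-bin volume, mm^3; sums exactly to the mask volume.
#' @export
setClass("HippocampusProfile",
  representation(side = "character", positions = "numeric", area = "numeric",
                 qt2 = "numeric", binVolume = "numeric"),
  validity = function(object) {
    n <- length(object@positions)
    if (n < 2L) return("a profile needs at least 2 bins")
    if (any(diff(object@positions) <= 0))
      return("positions must be strictly increasing")
    if (length(object@area) != n || length(object@qt2) != n ||
        length(object@binVolume) != n)
      return("area, qt2 and binVolume must have one value per bin")
    TRUE
  })

#' GlobalMetrics: global hippocampal measurements and L:R ratios
#'
#' Volumes (mm^3) and mean qT2 (ms) per side, the plain left:right ratios
#' (100 x left/right), and the orientation-free asymmetry ratios
#' (100 x min/max for volume, 100 x max/min for qT2) which quantify the
#' magnitude of asymmetry irrespective of side.
#' @export
setClass("GlobalMetrics",
  representation(volLeft = "numeric", volRight = "numeric",
                 qt2Left = "numeric", qt2Right = "numeric",
                 lrVolRatioPct = "numeric", lrQt2RatioPct = "numeric",
                 asymVolRatioPct = "numeric", asymQt2RatioPct = "numeric"),
  validity = function(object) {
    if (object@volLeft <= 0 || object@volRight <= 0)
      return("volumes must be positive")
    if (object@lrVolRatioPct <= 0 || object@lrQt2RatioPct <= 0)
      return("ratios must be positive")
    TRUE
  })

#' NormativeModel: reference ranges from a healthy cohort
#'
#' Per-metric (and optionally per-bin) means and SDs with mean +/- 1.96 SD
#' bands, plus provenance (cohort size, seed, build date).
#'
#' @slot global data.frame with columns metric, mean, sd, n, lo, hi.
#' @slot profiles data.frame with columns side, position, metric, mean, sd,
#'   lo, hi (zero rows when the model carries no profile bands).
#' @slot provenance Named list: n, seed, date, source.
#' @export
setClass("NormativeModel",
  representation(global = "data.frame", profiles = "data.frame",
                 provenance = "list"),
  validity = function(object) {
    need <- c("metric", "mean", "sd", "n", "lo", "hi")
    if (!all(need %in% names(object@global)))
      return("global table must have metric, mean, sd, n, lo, hi")
    if (any(object@global$sd < 0)) return("sd must be >= 0")
    if (max(abs(object@global$lo - (object@global$mean - 1.96 * object@global$sd)),
            abs(object@global$hi - (object@global$mean + 1.96 * object@global$sd))) > 1e-9)
      return("bands must equal mean +/- 1.96 sd exactly")
    if (length(unique(object@global$n)) > 1L)
      return("all entries must share one cohort n")
    TRUE
  })

#' FlagSet: normative flags for one subject
#' @slot flags Named character vector, each \code{"normal"}, \code{"low"} or
#'   \code{"high"}; names are metric names.
#' @slot overall One of \code{"normal"}, \code{"right_abnormal"},
#'   \code{"left_abnormal"}, \code{"bilateral_abnormal"}.
#' @export
setClass("FlagSet",
  representation(flags = "character", overall = "character"),
  validity = function(object) {
    if (!all(object@flags %in% c("normal", "low", "high")))
      return("flags must be normal/low/high")
    if (!object@overall %in% c("normal", "right_abnormal", "left_abnormal",
                               "bilateral_abnormal"))
      return("invalid overall impression")
    TRUE
  })

#' HippocampusSpec: generating parameters for one synthetic hippocampus
#'
#' A curved tube ("banana") around a cubic-spline centerline with elliptical
#' cross-section and sinusoidal end taper. Pathology is emulated by a volume
#' scale factor (atrophy) and a multiplicative T2 elevation, applied globally
#' or as a Gaussian bump in arc-position (focal lesion).
#'
#' @slot side \code{"left"} or \code{"right"}.
#' @slot centerline n x 3 matrix of control points in world mm.
#' @slot baseRadius Mid-tube in-plane radius, mm.
#' @slot taper End radius as a fraction of baseRadius, in (0, 1].
#' @slot ellipticity Ratio of the second cross-section semi-axis to the
#'   first, in (0, 1].
#' @slot t2 Baseline tissue T2, ms.
#' @slot s0 Baseline TE=0 signal.
#' @slot atrophyFactor Volume scale in (0, 1].
#' @slot t2Elevation Multiplicative T2 factor >= 1.
#' @slot focalCenter Arc position in [0,1] of a focal lesion, or NA (global).
#' @slot focalWidth Gaussian SD of the focal lesion in arc fraction.
#' @export
setClass("HippocampusSpec",
  representation(side = "character", centerline = "matrix",
                 baseRadius = "numeric", taper = "numeric",
                 ellipticity = "numeric", t2 = "numeric", s0 = "numeric",
                 atrophyFactor = "numeric", t2Elevation = "numeric",
                 focalCenter = "numeric", focalWidth = "numeric"),
  validity = function(object) {
    if (!object@side %in% c("left", "right"))
      return("side must be 'left' or 'right'")
    if (ncol(object@centerline) != 3L || nrow(object@centerline) < 2L)
      return("centerline must be an n x 3 matrix (n >= 2)")
    if (object@baseRadius <= 0) return("baseRadius must be > 0")
    if (object@taper <= 0 || object@taper > 1) return("taper must lie in (0,1]")
    if (object@ellipticity <= 0 || object@ellipticity > 1)
      return("ellipticity must lie in (0,1]")
    if (object@t2 <= 0) return("t2 must be > 0")
    if (object@s0 <= 0) return("s0 must be > 0")
    if (object@atrophyFactor <= 0 || object@atrophyFactor > 1)
      return("atrophyFactor must lie in (0,1]")
    if (object@t2Elevation < 1) return("t2Elevation must be >= 1")
    if (!is.na(object@focalCenter) &&
        (object@focalCenter < 0 || object@focalCenter > 1))
      return("focalCenter must lie in [0,1]")
    TRUE
  })

#' AcquisitionSpec: dual-echo acquisition parameters for the phantom
#' @slot te1,te2 Effective echo times, ms, with te1 < te2.
#' @slot tr Repetition time, ms (metadata only).
#' @slot gridShape Integer grid dimensions.
#' @slot spacing Voxel size, mm.
#' @slot noiseSigma Additive Gaussian noise SD, signal units.
#' @slot seed RNG seed (NA for no reseeding).
#' @export
setClass("AcquisitionSpec",
  representation(te1 = "numeric", te2 = "numeric", tr = "numeric",
                 gridShape = "integer", spacing = "numeric",
                 noiseSigma = "numeric", seed = "numeric"),
  validity = function(object) {
    if (!(object@te1 > 0 && object@te1 < object@te2))
      return("echo times must satisfy 0 < te1 < te2")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    TRUE
  })

#' PhantomSubject: one synthetic subject with ground truth
#' @slot t1Like Structural contrast volume.
#' @slot echo1,echo2 The two effective-echo images.
#' @slot leftMask,rightMask Hippocampal masks.
#' @slot truth Named list of generating values: per-side volume (mm^3), mean
#'   T2 (ms), and the true long-axis T2 profile.
#' @export
setClass("PhantomSubject",
  representation(t1Like = "Volume3D", echo1 = "Volume3D", echo2 = "Volume3D",
                 leftMask = "LabelMask", rightMask = "LabelMask",
                 truth = "list"))

#' QReportDoc: a structured per-subject quantitative report
#'
#' JSON-first document: demographics, QC, global metrics with reference
#' bands, both long-axis profiles with normative bands, normative flags and
#' provenance. HTML rendering is a pure view of this document.
#' @slot doc Named list (the document tree).
#' @export
setClass("QReportDoc", representation(doc = "list"),
  validity = function(object) {
    need <- c("meta", "qc", "global", "profiles", "flags", "provenance")
    miss <- setdiff(need, names(object@doc))
    if (length(miss)) return(paste("missing report sections:",
                                   paste(miss, collapse = ", ")))
    TRUE
  })

#' StudyResult: the full reader-study statistical battery
#' @slot perRater Per-(rater, condition) accuracy table.
#' @slot groupSummary Group/condition means and SDs.
#' @slot kappaTable Per-rater kappa vs gold with group means.
#' @slot pairedTests Paired with/without-report contrasts.
#' @slot mcnemar McNemar test on pooled correct/incorrect discordants.
#' @slot reliability Cronbach's alpha and ICC (single, average) per condition.
#' @slot anova Confidence ANOVA tables.
#' @export
setClass("StudyResult",
  representation(perRater = "data.frame", groupSummary = "data.frame",
                 kappaTable = "data.frame", pairedTests = "data.frame",
                 mcnemar = "list", reliability = "data.frame",
                 anova = "list"))
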