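#' Accessors for imaging objects
#'
#' \code{imgData} returns the raw 3D array; \code{voxelSpacing} the per-axis
#' voxel size in mm; \code{voxelAffine} the 4x4 0-based voxel-index to
#' world-mm (RAS+) map; \code{imgMeta} the metadata list; \code{maskSide}
#' the side tag of a \linkS4class{LabelMask}.
#'
#' @param x A \linkS4class{Volume3D} or \linkS4class{LabelMask}.
#' @return See the individual descriptions.
#' @name imaging-accessors
#' @aliases imgData voxelSpacing voxelAffine imgMeta maskSide
NULL

#' @rdname imaging-accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname imaging-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname imaging-accessors
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))
#' @rdname imaging-accessors
#' @export
setGeneric("imgMeta", function(x) standardGeneric("imgMeta"))
#' @rdname imaging-accessors
#' @export
setGeneric("maskSide", function(x) standardGeneric("maskSide"))

#' @rdname imaging-accessors
setMethod("imgData", "Volume3D", function(x) x@data)
#' @rdname imaging-accessors
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)
#' @rdname imaging-accessors
setMethod("voxelAffine", "Volume3D", function(x) x@affine)
#' @rdname imaging-accessors
setMethod("imgMeta", "Volume3D", function(x) x@meta)
#' @rdname imaging-accessors
setMethod("maskSide", "LabelMask", function(x) x@side)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D %d x %d x %d, spacing %s mm\n", d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x ")))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMask (%s) %d x %d x %d, %d voxels set\n", object@side,
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "T2Map", function(object) {
  v <- object@valid == 1
  cat(sprintf("T2Map: %d valid voxels, clamp [%g, %g] ms\n", sum(v),
              object@clampRange[1], object@clampRange[2]))
  if (any(v))
    cat(sprintf("  in-map T2 median %.1f ms\n",
                stats::median(object@t2@data[v])))
})

setMethod("show", "FitQC", function(object) {
  cat(sprintf("FitQC: %d voxels fit, %.2f%% non-physical, %.2f%% clamped\n",
              object@nVoxelsFit, 100 * object@fracNonphysical,
              100 * object@fracClamped))
})

setMethod("show", "HippocampusProfile", function(object) {
  cat(sprintf("HippocampusProfile (%s): %d bins, total volume %.0f mm^3\n",
              object@side, length(object@positions), sum(object@binVolume)))
})

setMethod("show", "GlobalMetrics", function(object) {
  cat(sprintf(paste0("GlobalMetrics: vol L/R %.0f/%.0f mm^3 (L:R %.1f%%), ",
                     "qT2 L/R %.1f/%.1f ms (L:R %.1f%%)\n"),
              object@volLeft, object@volRight, object@lrVolRatioPct,
              object@qt2Left, object@qt2Right, object@lrQt2RatioPct))
})

setMethod("show", "NormativeModel", function(object) {
  cat(sprintf("NormativeModel: %d global metrics, %d profile bands, n = %s\n",
              nrow(object@global), nrow(object@profiles),
              as.character(object@provenance$n)))
})

setMethod("show", "FlagSet", function(object) {
  ab <- names(object@flags)[object@flags != "normal"]
  cat(sprintf("FlagSet: overall %s%s\n", object@overall,
              if (length(ab)) paste0(" (", paste(ab, collapse = ", "), ")")
              else ""))
})

setMethod("show", "PhantomSubject", function(object) {
  cat(sprintf("PhantomSubject: truth vol L/R %.0f/%.0f mm^3, T2 L/R %.1f/%.1f ms\n",
              object@truth$left$volume, object@truth$right$volume,
              object@truth$left$meanT2, object@truth$right$meanT2))
})

setMethod("show", "QReportDoc", function(object) {
  cat("QReportDoc:", paste(names(object@doc), collapse = ", "), "\n")
})

setMethod("show", "StudyResult", function(object) {
  cat(sprintf("StudyResult: %d rater/condition rows, overall kappa %s -> %s\n",
              nrow(object@perRater),
              signif(object@kappaTable$kappa[object@kappaTable$level == "total" &
                       object@kappaTable$condition == "without_report"], 3),
              signif(object@kappaTable$kappa[object@kappaTable$level == "total" &
                       object@kappaTable$condition == "with_report"], 3)))
})
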