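PIPELINE_VERSION <- "hippoquant-0.1.0"

REQUIRED_META <- c("age", "gender", "scan_date", "scanner", "hospital")

## Display rounding: ratios and qT2 to 1 decimal, volumes to whole mm^3.
displayRound <- function(metric, value) {
  if (grepl("^vol_", metric)) round(value) else round(value, 1)
}

#' Assemble a quantitative report document
#'
#' Deterministic JSON-first document combining non-identifying
#' demographics, fit QC, global metrics with their normative bands (or an
#' explicit no-reference marker), both long-axis profiles with per-bin
#' bands when the model carries them, and the normative flags. Raw values
#' are retained unrounded; display values are rounded (ratios/qT2 one
#' decimal, volumes whole mm^3).
#'
#' @param meta Named list with age (years), gender, scan_date, scanner,
#'   hospital.
#' @param metrics A \linkS4class{GlobalMetrics}.
#' @param profiles List with \code{left} and \code{right}
#'   \linkS4class{HippocampusProfile}.
#' @param model A \linkS4class{NormativeModel} (provenance required).
#' @param qc A \linkS4class{FitQC}.
#' @param flags A \linkS4class{FlagSet}.
#' @param snapshots Optional character vector of snapshot file references.
#' @return A \linkS4class{QReportDoc}.
#' @export
assembleReport <- function(meta, metrics, profiles, model, qc, flags,
                           snapshots = character(0)) {
  miss <- setdiff(REQUIRED_META, names(meta))
  if (length(miss))
    hqStop("hippoquant_missing_meta",
           "missing mandatory meta fields: ", paste(miss, collapse = ", "))
  if (is.null(model@provenance$n))
    hqStop("hippoquant_missing_provenance", "model provenance is required")
  vals <- metricValues(metrics)
  g <- model@global
  global <- lapply(names(vals), function(m) {
    i <- match(m, g$metric)
    if (!is.na(i))
      list(metric = m, value = vals[[m]],
           display = displayRound(m, vals[[m]]),
           lo = g$lo[i], hi = g$hi[i], reference = TRUE)
    else
      list(metric = m, value = vals[[m]],
           display = displayRound(m, vals[[m]]), reference = FALSE)
  })
  names(global) <- names(vals)
  profBlock <- lapply(c("left", "right"), function(side) {
    p <- profiles[[side]]
    bands <- NULL
    if (nrow(model@profiles)) {
      pb <- model@profiles[model@profiles$side == side, ]
      bands <- lapply(c("area", "qt2"), function(metric) {
        s <- pb[pb$metric == metric, ]
        if (nrow(s) != length(p@positions))
          hqStop("hippoquant_bin_mismatch",
                 "model profile bins do not match the subject profile")
        list(lo = s$lo, hi = s$hi)
      })
      names(bands) <- c("area", "qt2")
    }
    list(side = side, positions = p@positions, area = p@area, qt2 = p@qt2,
         binVolume = p@binVolume, bands = bands)
  })
  names(profBlock) <- c("left", "right")
  doc <- list(
    meta = meta[REQUIRED_META],
    qc = list(n_voxels_fit = qc@nVoxelsFit,
              frac_nonphysical = qc@fracNonphysical,
              frac_clamped = qc@fracClamped, note = qc@note),
    global = global,
    profiles = profBlock,
    flags = list(per_metric = as.list(flags@flags), overall = flags@overall,
                 note = "machine advice, not a diagnosis"),
    snapshots = as.list(snapshots),
    provenance = list(pipeline = PIPELINE_VERSION,
                      model = model@provenance))
  new("QReportDoc", doc = doc)
}

#' Serialise / parse a report document as JSON
#'
#' Serialisation is deterministic: the same document yields byte-identical
#' JSON; \code{parseReport(serialiseReport(doc))} restores the document.
#'
#' @param doc A \linkS4class{QReportDoc}.
#' @param path Output path; when NULL the JSON string is returned.
#' @return The JSON string (serialise) or a \linkS4class{QReportDoc}
#'   (parse).
#' @export
serialiseReport <- function(doc, path = NULL) {
  js <- jsonlite::toJSON(doc@doc, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (!is.null(path)) writeLines(js, path, useBytes = TRUE)
  invisible(as.character(js))
}

#' @rdname serialiseReport
#' @param json JSON string or path to a report JSON file.
#' @export
parseReport <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  new("QReportDoc", doc = x)
}

## 2D mask boundary: mask minus its 4-neighbour erosion.
maskBoundary2D <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  er <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  (m == 1) & !er
}

#' Segmentation snapshots
#'
#' Three orthogonal slices through the centroid voxel of each mask, with
#' the mask boundary (4-neighbour erosion difference) marked, per side: six
#' images.
#'
#' @param t1Like Structural \linkS4class{Volume3D}.
#' @param left,right \linkS4class{LabelMask} per side.
#' @return List of six records: \code{side}, \code{plane}, \code{slice}
#'   (0-based index), \code{image} (grayscale matrix in [0,1]),
#'   \code{outline} (logical matrix).
#' @export
renderSnapshots <- function(t1Like, left, right) {
  out <- list()
  for (mask in list(left, right)) {
    assertSameGrid(t1Like, mask)
    idx <- which(mask@data == 1, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      hqStop("hippoquant_empty_mask", "cannot snapshot an empty mask")
    ctr <- unname(round(colMeans(idx)))
    rng <- range(t1Like@data)
    norm <- if (diff(rng) > 0) (t1Like@data - rng[1]) / diff(rng)
            else t1Like@data * 0
    for (plane in c("sagittal", "coronal", "axial")) {
      sl <- switch(plane, sagittal = ctr[1], coronal = ctr[2],
                   axial = ctr[3])
      img <- switch(plane, sagittal = norm[sl, , ],
                    coronal = norm[, sl, ], axial = norm[, , sl])
      msl <- switch(plane, sagittal = mask@data[sl, , ],
                    coronal = mask@data[, sl, ], axial = mask@data[, , sl])
      out[[length(out) + 1L]] <- list(
        side = mask@side, plane = plane, slice = sl - 1L, image = img,
        outline = maskBoundary2D(msl))
    }
  }
  out
}

## Deterministic inline SVG of a profile curve over its normative band.
svgProfile <- function(positions, values, lo = NULL, hi = NULL,
                       title = "", width = 360, height = 220) {
  ok <- is.finite(values)
  yAll <- c(values[ok], lo, hi)
  yAll <- yAll[is.finite(yAll)]
  if (!length(yAll)) yAll <- c(0, 1)
  ylim <- range(yAll)
  if (diff(ylim) == 0) ylim <- ylim + c(-1, 1)
  ylim <- ylim + c(-0.08, 0.08) * diff(ylim)
  px <- function(x) sprintf("%.2f", 40 + x * (width - 55))
  py <- function(y) sprintf("%.2f",
    (height - 30) - (y - ylim[1]) / diff(ylim) * (height - 50))
  parts <- sprintf(
    '<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
    width, height)
  parts <- c(parts, sprintf(
    '<text x="%d" y="14" font-size="12" font-weight="bold">%s</text>',
    width %/% 2 - 60, title))
  if (!is.null(lo) && !is.null(hi)) {
    poly <- paste(c(paste(px(positions), py(hi), sep = ","),
                    rev(paste(px(positions), py(lo), sep = ","))),
                  collapse = " ")
    parts <- c(parts, sprintf(
      '<polygon points="%s" fill="#a8c8e8" fill-opacity="0.55"/>', poly))
  }
  if (any(ok)) {
    line <- paste(paste(px(positions[ok]), py(values[ok]), sep = ","),
                  collapse = " ")
    parts <- c(parts, sprintf(
      '<polyline points="%s" fill="none" stroke="black" stroke-width="1.5"/>',
      line))
  }
  parts <- c(parts, sprintf(
    '<text x="6" y="%d" font-size="10">P</text><text x="%d" y="%d" font-size="10">A</text>',
    height - 12, width - 18, height - 12),
    sprintf('<text x="2" y="%s" font-size="10">%.4g</text>', py(ylim[1]), ylim[1]),
    sprintf('<text x="2" y="%s" font-size="10">%.4g</text>', py(ylim[2]), ylim[2]),
    "</svg>")
  paste(parts, collapse = "")
}

## Base64-embed one snapshot as PNG (gray image with red outline).
snapshotPngB64 <- function(snap) {
  img <- snap$image
  rgb <- array(0, c(nrow(img), ncol(img), 3))
  rgb[, , 1] <- img; rgb[, , 2] <- img; rgb[, , 3] <- img
  o <- snap$outline == 1
  r1 <- rgb[, , 1]; g1 <- rgb[, , 2]; b1 <- rgb[, , 3]
  r1[o] <- 1; g1[o] <- 0.1; b1[o] <- 0.1
  rgb[, , 1] <- r1; rgb[, , 2] <- g1; rgb[, , 3] <- b1
  ## transpose to image row-major for PNG (rows = y, flipped for display)
  rgbT <- aperm(rgb[, ncol(img):1, , drop = FALSE], c(2, 1, 3))
  jsonlite::base64_enc(png::writePNG(rgbT))
}

#' Render a report document as self-contained HTML
#'
#' A pure, deterministic view of the JSON document: patient block, QC
#' block, global table (value with reference range in brackets, or a
#' no-reference marker), per-side cross-sectional area and qT2
#' posterior-anterior profile figures (subject curve in black over the
#' normative mean +/- 1.96 SD band in blue), normative flags, optional
#' embedded segmentation snapshots, and provenance. No value shown is
#' computed at render time.
#'
#' @param doc A \linkS4class{QReportDoc}.
#' @param snapshots Optional output of \code{\link{renderSnapshots}} to
#'   embed.
#' @param path Output HTML path.
#' @return \code{path}, invisibly.
#' @export
renderHtml <- function(doc, path, snapshots = NULL) {
  if (!dir.exists(dirname(path)))
    hqStop("hippoquant_unwritable_path", "directory does not exist: ",
           dirname(path))
  d <- doc@doc
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  h <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
         "<title>Quantitative hippocampal report</title>",
         "<style>body{font-family:sans-serif;margin:24px}table{border-collapse:collapse}",
         "td,th{border:1px solid #999;padding:4px 8px;font-size:13px}",
         "h2{border-bottom:1px solid #ccc}.flag{color:#b00;font-weight:bold}</style>",
         "</head><body>",
         "<h1>Quantitative hippocampal report</h1>")
  h <- c(h, "<h2>Patient</h2><table>",
         sprintf("<tr><th>%s</th><td>%s</td></tr>",
                 c("Age (years)", "Gender", "Scan date", "Scanner",
                   "Hospital"),
                 vapply(d$meta[REQUIRED_META], esc, character(1))),
         "</table>")
  h <- c(h, "<h2>Quality control</h2>",
         sprintf("<p>%s voxels fit; %s%% non-physical; %s%% clamped. %s</p>",
                 d$qc$n_voxels_fit,
                 format(round(100 * d$qc$frac_nonphysical, 2)),
                 format(round(100 * d$qc$frac_clamped, 2)),
                 esc(d$qc$note)))
  labels <- c(vol_left = "Left volume (mm&#179;)",
              vol_right = "Right volume (mm&#179;)",
              qt2_left = "Left qT2 (ms)", qt2_right = "Right qT2 (ms)",
              lr_vol_ratio_pct = "L:R volume ratio (%)",
              lr_qt2_ratio_pct = "L:R qT2 ratio (%)")
  rows <- vapply(names(d$global), function(m) {
    e <- d$global[[m]]
    band <- if (isTRUE(e$reference))
      sprintf("[%s&ndash;%s]", format(round(e$lo, 1)), format(round(e$hi, 1)))
    else "no reference"
    fl <- d$flags$per_metric[[m]]
    mark <- if (!is.null(fl) && fl != "normal")
      sprintf(" <span class='flag'>%s</span>", fl) else ""
    sprintf("<tr><td>%s</td><td>%s</td><td>%s</td>%s</tr>",
            labels[[m]], format(e$display), band,
            paste0("<td>", mark, "</td>"))
  }, character(1))
  h <- c(h, "<h2>Global analysis</h2>",
         "<table><tr><th>Metric</th><th>Value</th><th>Reference range</th><th>Flag</th></tr>",
         rows, "</table>",
         sprintf("<p>Overall impression (machine advice): <b>%s</b></p>",
                 esc(d$flags$overall)))
  h <- c(h, "<h2>Posterior&ndash;anterior profiles</h2>")
  for (side in c("left", "right")) {
    p <- d$profiles[[side]]
    bA <- p$bands$area; bQ <- p$bands$qt2
    h <- c(h, sprintf("<h3>%s hippocampus</h3>",
                      c(left = "Left", right = "Right")[[side]]),
           svgProfile(unlist(p$positions), unlist(p$area),
                      if (!is.null(bA)) unlist(bA$lo), if (!is.null(bA)) unlist(bA$hi),
                      title = "Cross-sectional area (mm&#178;)"),
           svgProfile(unlist(p$positions), unlist(p$qt2),
                      if (!is.null(bQ)) unlist(bQ$lo), if (!is.null(bQ)) unlist(bQ$hi),
                      title = "qT2 (ms)"))
  }
  if (!is.null(snapshots)) {
    h <- c(h, "<h2>Segmentation snapshots</h2>")
    for (s in snapshots)
      h <- c(h, sprintf(
        '<img alt="%s %s" style="image-rendering:pixelated;height:160px;margin:2px" src="data:image/png;base64,%s"/>',
        s$side, s$plane, snapshotPngB64(s)))
  }
  h <- c(h, sprintf(
    "<h2>Provenance</h2><p>Pipeline %s; normative model n = %s (%s).</p>",
    esc(d$provenance$pipeline), esc(d$provenance$model$n),
    esc(d$provenance$model$source)),
    "</body></html>")
  writeLines(h, path, useBytes = TRUE)
  invisible(path)
}
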