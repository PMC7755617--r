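#' Default phantom grid
#'
#' An axis-aligned 1 mm isotropic grid (RAS+) centred on the world origin,
#' large enough to hold both default hippocampi.
#'
#' @param shape Integer grid dimensions.
#' @param spacing Voxel size in mm (scalar or length 3).
#' @return A list with \code{shape}, \code{spacing} and \code{affine}.
#' @export
phantomGrid <- function(shape = c(76L, 60L, 36L), spacing = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- -(shape - 1) * spacing / 2
  list(shape = as.integer(shape), spacing = as.numeric(spacing), affine = aff)
}

## Default curved ("banana") centerlines, world mm, running posterior (tail)
## to anterior (head). Left is the x-mirror of right.
defaultCenterline <- function(side) {
  right <- cbind(x = c(26, 27, 25, 21, 17),
                 y = c(-20, -10, 0, 8, 14),
                 z = c(-6, -3, 0, 4, 9))
  if (side == "right") right else {
    left <- right; left[, 1] <- -left[, 1]; left
  }
}

#' Construct a HippocampusSpec
#'
#' Defaults describe a healthy hippocampus: a curved tube of base radius
#' 6 mm (elliptical cross-section, vertically flattened), ~40 mm long,
#' baseline T2 100 ms. Pathology knobs: \code{atrophyFactor} scales total
#' volume; \code{t2Elevation} multiplies T2, globally or focally (Gaussian
#' bump centred at \code{focalCenter} with SD \code{focalWidth} in arc
#' fraction) when \code{focalCenter} is set.
#'
#' @param side \code{"left"} or \code{"right"}.
#' @param centerline n x 3 control points in world mm (posterior first).
#' @param baseRadius,taper,ellipticity Tube geometry; see
#'   \linkS4class{HippocampusSpec}.
#' @param t2,s0 Baseline tissue T2 (ms) and TE=0 signal.
#' @param atrophyFactor,t2Elevation,focalCenter,focalWidth Pathology.
#' @return A \linkS4class{HippocampusSpec}.
#' @export
HippocampusSpec <- function(side, centerline = defaultCenterline(side),
                            baseRadius = 6, taper = 0.35, ellipticity = 0.75,
                            t2 = 100, s0 = 1000, atrophyFactor = 1,
                            t2Elevation = 1, focalCenter = NA_real_,
                            focalWidth = 0.1) {
  new("HippocampusSpec", side = side, centerline = centerline,
      baseRadius = baseRadius, taper = taper, ellipticity = ellipticity,
      t2 = t2, s0 = s0, atrophyFactor = atrophyFactor,
      t2Elevation = t2Elevation, focalCenter = focalCenter,
      focalWidth = focalWidth)
}

#' Construct an AcquisitionSpec
#'
#' Defaults mirror a coronal dual-contrast FSE T2-quantification protocol
#' with effective echo times 30 and 119 ms and TR 7600 ms, sampled here on
#' the phantom's isotropic grid.
#'
#' @param te1,te2,tr Timing in ms.
#' @param gridShape,spacing Phantom grid.
#' @param noiseSigma Additive Gaussian noise SD in signal units.
#' @param seed RNG seed (NA: use the current RNG state).
#' @return An \linkS4class{AcquisitionSpec}.
#' @export
AcquisitionSpec <- function(te1 = 30, te2 = 119, tr = 7600,
                            gridShape = c(76L, 60L, 36L), spacing = 1,
                            noiseSigma = 0, seed = NA_real_) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("AcquisitionSpec", te1 = te1, te2 = te2, tr = tr,
      gridShape = as.integer(gridShape), spacing = as.numeric(spacing),
      noiseSigma = noiseSigma, seed = as.numeric(seed))
}

## Resample a control-point centerline to nSamples points approximately
## uniform in arc length, via per-coordinate cubic splines.
resampleCenterline <- function(ctrl, nSamples = 200L) {
  n <- nrow(ctrl)
  chord <- c(0, cumsum(sqrt(rowSums((ctrl[-1, , drop = FALSE] -
                                     ctrl[-n, , drop = FALSE])^2))))
  tt <- chord / chord[n]
  dense <- seq(0, 1, length.out = 20L * nSamples)
  pts <- sapply(1:3, function(j)
    stats::spline(tt, ctrl[, j], xout = dense, method = "natural")$y)
  seg <- sqrt(rowSums((pts[-1, ] - pts[-nrow(pts), ])^2))
  arc <- c(0, cumsum(seg))
  target <- seq(0, arc[length(arc)], length.out = nSamples)
  idx <- findInterval(target, arc, all.inside = TRUE)
  w <- (target - arc[idx]) / pmax(arc[idx + 1] - arc[idx], 1e-12)
  out <- pts[idx, ] * (1 - w) + pts[idx + 1, ] * w
  list(points = out, arc = target / arc[length(arc)],
       length = arc[length(arc)])
}

## Taper profile: radius fraction at arc position s in [0,1].
taperProfile <- function(s, taper) taper + (1 - taper) * sin(pi * s)

## Voxelise the tube: returns the 0/1 array plus, for in-mask voxels, their
## arc positions (array, NaN outside). Radius is scaled by
## sqrt(atrophyFactor) so that volume scales linearly with atrophyFactor.
voxelizeTube <- function(spec, grid) {
  cl <- resampleCenterline(spec@centerline)
  C <- cl$points
  M <- nrow(C)
  rScale <- spec@baseRadius * sqrt(spec@atrophyFactor)
  if (rScale * spec@taper < 0 || rScale < max(grid$spacing))
    hqStop("hippoquant_subvoxel_radius",
           "tube radius ", format(rScale), " mm is below the voxel size")
  radii <- rScale * taperProfile(cl$arc, spec@taper)
  rmax <- max(radii)
  origin <- grid$affine[1:3, 4]
  sp <- grid$spacing
  worldLo <- origin
  worldHi <- origin + (grid$shape - 1) * sp
  if (any(apply(C, 2, min) - rmax < worldLo - sp / 2) ||
      any(apply(C, 2, max) + rmax > worldHi + sp / 2))
    hqStop("hippoquant_tube_exits_grid",
           "tube extends beyond the grid's world extent")
  ## candidate voxels: bounding box of the tube
  loIdx <- pmax(floor((apply(C, 2, min) - rmax - origin) / sp), 0)
  hiIdx <- pmin(ceiling((apply(C, 2, max) + rmax - origin) / sp),
                grid$shape - 1)
  ii <- loIdx[1]:hiIdx[1]; jj <- loIdx[2]:hiIdx[2]; kk <- loIdx[3]:hiIdx[3]
  cand <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  P <- sweep(cand, 2, sp, `*`)
  P <- sweep(P, 2, origin, `+`)
  n <- nrow(P)
  bestD2 <- rep(Inf, n); bestK <- rep(1L, n)
  for (k in seq_len(M)) {
    d2 <- (P[, 1] - C[k, 1])^2 + (P[, 2] - C[k, 2])^2 + (P[, 3] - C[k, 3])^2
    better <- d2 < bestD2
    bestD2[better] <- d2[better]
    bestK[better] <- k
  }
  near <- bestD2 <= (rmax + max(sp))^2
  inside <- logical(n)
  arcStep <- cl$length / (M - 1)
  ## tangents by central differences
  Tm <- rbind(C[2, ] - C[1, ],
              C[3:M, ] - C[1:(M - 2), ],
              C[M, ] - C[M - 1, ])
  Tm <- Tm / sqrt(rowSums(Tm^2))
  idxNear <- which(near)
  k <- bestK[idxNear]
  off <- P[idxNear, , drop = FALSE] - C[k, , drop = FALSE]
  tk <- Tm[k, , drop = FALSE]
  along <- rowSums(off * tk)
  perp <- off - along * tk
  ## local normal frame: n1 ~ superior (z orthogonalised against tangent)
  zc <- cbind(-tk[, 1] * tk[, 3], -tk[, 2] * tk[, 3], 1 - tk[, 3]^2)
  zn <- sqrt(rowSums(zc^2))
  deg <- zn < 1e-6
  if (any(deg)) {  # tangent parallel to z: fall back to x axis
    zc[deg, ] <- cbind(1 - tk[deg, 1]^2, -tk[deg, 1] * tk[deg, 2],
                       -tk[deg, 1] * tk[deg, 3])
    zn[deg] <- sqrt(rowSums(zc[deg, , drop = FALSE]^2))
  }
  n1 <- zc / zn
  n2 <- cbind(tk[, 2] * n1[, 3] - tk[, 3] * n1[, 2],
              tk[, 3] * n1[, 1] - tk[, 1] * n1[, 3],
              tk[, 1] * n1[, 2] - tk[, 2] * n1[, 1])
  u <- rowSums(perp * n1)   # vertical (flattened) semi-axis
  w <- rowSums(perp * n2)   # in-plane semi-axis
  rk <- radii[k]
  ok <- (w / rk)^2 + (u / (rk * spec@ellipticity))^2 <= 1 &
    abs(along) <= arcStep
  inside[idxNear] <- ok
  mask <- array(0, grid$shape)
  arcArr <- array(NaN, grid$shape)
  lin <- cand[, 1] + grid$shape[1] * (cand[, 2] + grid$shape[2] * cand[, 3]) + 1
  mask[lin[inside]] <- 1
  arcArr[lin[inside]] <- cl$arc[bestK[inside]]
  list(mask = mask, arc = arcArr, centerline = cl)
}

#' Voxelise one synthetic hippocampus mask
#'
#' Rasterises the tapered elliptical tube described by \code{spec} onto
#' \code{grid}. The radius is scaled by the square root of
#' \code{atrophyFactor}, so total volume scales (up to voxelisation error)
#' linearly with it.
#'
#' @param spec A \linkS4class{HippocampusSpec}.
#' @param grid A grid as returned by \code{\link{phantomGrid}}.
#' @return A \linkS4class{LabelMask}.
#' @export
makeHippocampusMask <- function(spec, grid = phantomGrid()) {
  vx <- voxelizeTube(spec, grid)
  LabelMask(vx$mask, spec@side, grid$spacing, grid$affine)
}

#' Synthesise the two effective-echo images
#'
#' Monoexponential decay plus i.i.d. additive Gaussian noise:
#' \eqn{E_k = S_0 e^{-TE_k/T_2} + \epsilon}, with one noise field drawn per
#' echo (echo 1 first) under \code{acq@seed}.
#'
#' @param s0Field,t2Field 3D arrays of TE=0 signal (>= 0) and T2 (> 0, ms).
#' @param acq An \linkS4class{AcquisitionSpec}.
#' @return List of two \linkS4class{Volume3D} (echo1, echo2) with \code{te}
#'   in their metadata.
#' @export
synthesizeDualEcho <- function(s0Field, t2Field, acq) {
  if (any(s0Field < 0) || any(t2Field <= 0))
    hqStop("hippoquant_bad_scene", "need S0 >= 0 and T2 > 0 everywhere")
  if (!is.na(acq@seed)) set.seed(as.integer(acq@seed))
  shape <- dim(s0Field)
  mk <- function(te) {
    sig <- s0Field * exp(-te / t2Field)
    if (acq@noiseSigma > 0)
      sig <- sig + array(stats::rnorm(prod(shape), 0, acq@noiseSigma), shape)
    Volume3D(sig, acq@spacing, phantomGrid(shape, acq@spacing)$affine,
             meta = list(te = te, tr = acq@tr))
  }
  list(echo1 = mk(acq@te1), echo2 = mk(acq@te2))
}

## Per-voxel T2 elevation factor at arc positions s.
elevationFactor <- function(spec, s) {
  if (is.na(spec@focalCenter)) rep(spec@t2Elevation, length(s))
  else 1 + (spec@t2Elevation - 1) *
    exp(-0.5 * ((s - spec@focalCenter) / spec@focalWidth)^2)
}

## True per-bin T2 profile from the generating field.
truthProfile <- function(arcVals, t2Vals, voxVol, nBins = 20L) {
  edges <- seq(0, 1, length.out = nBins + 1L)
  bin <- pmin(findInterval(arcVals, edges, rightmost.closed = TRUE), nBins)
  data.frame(
    position = (edges[-1] + edges[-(nBins + 1L)]) / 2,
    qt2 = sapply(seq_len(nBins), function(b)
      if (any(bin == b)) mean(t2Vals[bin == b]) else NaN),
    volume = sapply(seq_len(nBins), function(b) sum(bin == b) * voxVol))
}

#' Build one complete phantom subject
#'
#' Assembles a structural (T1-like) volume, the two echoes, the two masks
#' and a ground-truth record. Background is a single tissue ellipsoid
#' (defaults S0 800, T2 80 ms) with zero-signal exterior; hippocampal voxels
#' carry the side-specific T2 (baseline x elevation, focal or global).
#'
#' @param left,right \linkS4class{HippocampusSpec} for each side.
#' @param acq An \linkS4class{AcquisitionSpec}.
#' @param background List with \code{s0} and \code{t2} of the surrounding
#'   tissue.
#' @param nBins Bins used for the ground-truth profile.
#' @return A \linkS4class{PhantomSubject}.
#' @export
makePhantomSubject <- function(left, right, acq = AcquisitionSpec(),
                               background = list(s0 = 800, t2 = 80),
                               nBins = 20L) {
  if (left@side == right@side)
    hqStop("hippoquant_bad_spec", "left and right specs must differ in side")
  grid <- phantomGrid(acq@gridShape, acq@spacing)
  vxL <- voxelizeTube(left, grid)
  vxR <- voxelizeTube(right, grid)
  if (any(vxL$mask == 1 & vxR$mask == 1))
    hqStop("hippoquant_tube_overlap", "left and right tubes overlap")
  voxVol <- prod(grid$spacing)
  shape <- grid$shape
  ## background: inscribed ellipsoid of tissue, zero-signal exterior
  ctr <- (shape - 1) / 2
  ax <- pmax(ctr, 1) * 0.98
  ig <- expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                    k = 0:(shape[3] - 1))
  inBrain <- ((ig$i - ctr[1]) / ax[1])^2 + ((ig$j - ctr[2]) / ax[2])^2 +
    ((ig$k - ctr[3]) / ax[3])^2 <= 1
  s0 <- array(0, shape); t2 <- array(1, shape)
  s0[inBrain] <- background$s0
  t2[inBrain] <- background$t2
  sideField <- function(vx, spec) {
    sel <- vx$mask == 1
    s <- vx$arc[sel]
    t2v <- spec@t2 * elevationFactor(spec, s)
    s0[sel] <<- spec@s0
    t2[sel] <<- t2v
    list(volume = sum(sel) * voxVol, meanT2 = mean(t2v),
         profile = truthProfile(s, t2v, voxVol, nBins),
         atrophyFactor = spec@atrophyFactor, t2Elevation = spec@t2Elevation,
         focalCenter = spec@focalCenter)
  }
  truthL <- sideField(vxL, left)
  truthR <- sideField(vxR, right)
  echoes <- synthesizeDualEcho(s0, t2, acq)
  t1d <- array(0, shape)
  t1d[inBrain] <- 1000
  t1d[vxL$mask == 1 | vxR$mask == 1] <- 800
  truth <- list(left = truthL, right = truthR,
                lrVolRatioPct = 100 * truthL$volume / truthR$volume,
                lrQt2RatioPct = 100 * truthL$meanT2 / truthR$meanT2,
                te = c(acq@te1, acq@te2), noiseSigma = acq@noiseSigma,
                seed = acq@seed)
  new("PhantomSubject",
      t1Like = Volume3D(t1d, grid$spacing, grid$affine,
                        list(contrast = "t1-like")),
      echo1 = echoes$echo1, echo2 = echoes$echo2,
      leftMask = LabelMask(vxL$mask, "left", grid$spacing, grid$affine),
      rightMask = LabelMask(vxR$mask, "right", grid$spacing, grid$affine),
      truth = truth)
}

#' Generate a lesion-free reference cohort
#'
#' Draws n healthy subjects with Gaussian between-subject variability in
#' overall size, per-side radius scale and per-side baseline T2. Default
#' SDs (overall size 4\%, per-side radius 2\%, per-side T2 1.9\%) produce
#' left:right volume-ratio and qT2-ratio spreads comparable to a healthy
#' adult reference population (ratio SDs ~5.5\% and ~2.7\%).
#'
#' Draw order per subject (fixed contract for reproducibility): global size
#' scale, left radius jitter, right radius jitter, left T2 jitter, right T2
#' jitter; per-subject noise seeds are drawn for all subjects up front.
#'
#' @param n Cohort size (the shipped default normative model used 111).
#' @param variability List of SDs: \code{sizeSD}, \code{radiusSD},
#'   \code{t2SD} (fractional).
#' @param seed Integer seed governing every draw.
#' @param acq Acquisition template; per-subject noise seeds are derived.
#' @return List of \linkS4class{PhantomSubject}.
#' @export
makeReferenceCohort <- function(n, variability = list(sizeSD = 0.04,
                                                      radiusSD = 0.02,
                                                      t2SD = 0.019),
                                seed = 1L, acq = AcquisitionSpec(noiseSigma = 8)) {
  if (n < 1) hqStop("hippoquant_bad_n", "cohort size must be >= 1")
  set.seed(as.integer(seed))
  subSeeds <- sample.int(2^31 - 2, n)
  draws <- matrix(stats::rnorm(5L * n), ncol = 5L)
  lapply(seq_len(n), function(i) {
    size <- 1 + variability$sizeSD * draws[i, 1]
    rL <- size * (1 + variability$radiusSD * draws[i, 2])
    rR <- size * (1 + variability$radiusSD * draws[i, 3])
    t2L <- 100 * (1 + variability$t2SD * draws[i, 4])
    t2R <- 100 * (1 + variability$t2SD * draws[i, 5])
    acqi <- AcquisitionSpec(acq@te1, acq@te2, acq@tr, acq@gridShape,
                            acq@spacing, acq@noiseSigma, subSeeds[i])
    makePhantomSubject(HippocampusSpec("left", baseRadius = 6 * rL, t2 = t2L),
                       HippocampusSpec("right", baseRadius = 6 * rR, t2 = t2R),
                       acqi)
  })
}

#' Write a phantom subject to disk
#'
#' NIfTI-1 volumes and masks plus one JSON ground-truth sidecar.
#'
#' @param subject A \linkS4class{PhantomSubject}.
#' @param dir Output directory (created if absent).
#' @param id Subject identifier used as the filename stem.
#' @return Named character vector of file paths, invisibly.
#' @export
writePhantomSubject <- function(subject, dir, id = "subject") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(t1 = file.path(dir, paste0(id, "_t1.nii.gz")),
             echo1 = file.path(dir, paste0(id, "_echo1.nii.gz")),
             echo2 = file.path(dir, paste0(id, "_echo2.nii.gz")),
             maskL = file.path(dir, paste0(id, "_mask_left.nii.gz")),
             maskR = file.path(dir, paste0(id, "_mask_right.nii.gz")),
             truth = file.path(dir, paste0(id, "_truth.json")))
  writeVolume(subject@t1Like, paths["t1"])
  writeVolume(subject@echo1, paths["echo1"])
  writeVolume(subject@echo2, paths["echo2"])
  writeVolume(subject@leftMask, paths["maskL"])
  writeVolume(subject@rightMask, paths["maskR"])
  jsonlite::write_json(subject@truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
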