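#' Pipeline configuration
#'
#' Central defaults for the subject pipeline: acquisition echo times
#' (30/119 ms), fit clamp range and noise floor, profile bin count and
#' summary statistic, normative minimum cohort size. The normative band
#' multiplier is fixed at 1.96 by the model definition and is not a
#' configuration knob.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of configuration values.
#' @export
hippoquantConfig <- function(...) {
  cfg <- list(te1 = 30, te2 = 119, clamp = c(1, 2000), eps = 1e-6,
              nBins = 20L, stat = "mean", minN = 20L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    hqStop("hippoquant_bad_config",
           "unknown configuration fields: ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Run the full single-subject pipeline
#'
#' qT2 map, global metrics, long-axis profiles, QC, normative flags and the
#' assembled report, in one deterministic pass: identical inputs yield an
#' identical document.
#'
#' @param echo1,echo2 \linkS4class{Volume3D} (or NIfTI paths) of the two
#'   effective echoes.
#' @param leftMask,rightMask \linkS4class{LabelMask} (or NIfTI paths).
#' @param model A \linkS4class{NormativeModel}; defaults to the shipped
#'   ratio-band model.
#' @param meta Subject demographics (see \code{\link{assembleReport}}).
#' @param config From \code{\link{hippoquantConfig}}.
#' @param verbose Log stage progress.
#' @return A \linkS4class{QReportDoc}.
#' @export
runSubjectPipeline <- function(echo1, echo2, leftMask, rightMask,
                               model = defaultNormativeModel(),
                               meta = list(age = NA, gender = "unknown",
                                           scan_date = "unknown",
                                           scanner = "unknown",
                                           hospital = "unknown"),
                               config = hippoquantConfig(),
                               verbose = FALSE) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      hqStop("hippoquant_stage_failure",
             "stage '", name, "' failed: ", conditionMessage(e)))
    if (verbose)
      message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    r
  }
  if (is.character(echo1)) echo1 <- readVolume(echo1, meta = list(te = config$te1))
  if (is.character(echo2)) echo2 <- readVolume(echo2, meta = list(te = config$te2))
  if (is.character(leftMask)) leftMask <- readMask(leftMask, "left")
  if (is.character(rightMask)) rightMask <- readMask(rightMask, "right")
  stage("grid-check", {
    assertSameGrid(echo1, echo2); assertSameGrid(echo1, leftMask)
    assertSameGrid(echo1, rightMask)
  })
  roi <- leftMask@data + rightMask@data
  if (any(roi > 1))
    hqStop("hippoquant_grid_mismatch", "left and right masks overlap")
  t2map <- stage("qt2", computeT2Map(echo1, echo2, roi = roi,
                                     te1 = config$te1, te2 = config$te2,
                                     eps = config$eps, clamp = config$clamp))
  qc <- stage("qc", qcFit(t2map, roi))
  metrics <- stage("metrics",
                   computeGlobalMetrics(leftMask, rightMask, t2map,
                                        stat = config$stat))
  profiles <- stage("profiles", list(
    left = hippocampusProfile(leftMask, t2map, nBins = config$nBins),
    right = hippocampusProfile(rightMask, t2map, nBins = config$nBins)))
  flags <- stage("flags", flagSubject(metrics, model))
  stage("report",
        assembleReport(meta, metrics, profiles, model, qc, flags))
}

## Metrics + profiles for one phantom subject (no report assembly).
subjectMetrics <- function(subject, config = hippoquantConfig()) {
  roi <- subject@leftMask@data + subject@rightMask@data
  t2map <- computeT2Map(subject@echo1, subject@echo2, roi = roi,
                        te1 = config$te1, te2 = config$te2,
                        eps = config$eps, clamp = config$clamp)
  list(metrics = computeGlobalMetrics(subject@leftMask, subject@rightMask,
                                      t2map, stat = config$stat),
       profiles = list(
         left = hippocampusProfile(subject@leftMask, t2map,
                                   nBins = config$nBins),
         right = hippocampusProfile(subject@rightMask, t2map,
                                    nBins = config$nBins)))
}

#' Build a normative model from a cohort
#'
#' Runs metrics and profiles for every subject, then
#' \code{\link{buildNormative}}. Subjects may be
#' \linkS4class{PhantomSubject} objects or rows of a manifest data.frame
#' with file-path columns \code{echo1, echo2, mask_left, mask_right}.
#'
#' @param cohort List of \linkS4class{PhantomSubject} or a manifest
#'   data.frame.
#' @param config From \code{\link{hippoquantConfig}}.
#' @param seed Provenance: the seed that generated the cohort.
#' @param verbose Log progress.
#' @return A \linkS4class{NormativeModel}.
#' @export
runCohortBuild <- function(cohort, config = hippoquantConfig(), seed = NA,
                           verbose = FALSE) {
  if (is.data.frame(cohort)) {
    need <- c("echo1", "echo2", "mask_left", "mask_right")
    miss <- setdiff(need, names(cohort))
    if (length(miss))
      hqStop("hippoquant_bad_manifest",
             "manifest lacks columns: ", paste(miss, collapse = ", "))
    bad <- unlist(cohort[need])[!file.exists(unlist(cohort[need]))]
    if (length(bad))
      hqStop("hippoquant_missing_file",
             "unreadable cohort files: ", paste(bad, collapse = ", "))
    recs <- lapply(seq_len(nrow(cohort)), function(i) {
      if (verbose) message("subject ", i, "/", nrow(cohort))
      e1 <- readVolume(cohort$echo1[i], meta = list(te = config$te1))
      e2 <- readVolume(cohort$echo2[i], meta = list(te = config$te2))
      ml <- readMask(cohort$mask_left[i], "left")
      mr <- readMask(cohort$mask_right[i], "right")
      s <- new("PhantomSubject", t1Like = e1, echo1 = e1, echo2 = e2,
               leftMask = ml, rightMask = mr, truth = list())
      subjectMetrics(s, config)
    })
  } else {
    recs <- lapply(seq_along(cohort), function(i) {
      if (verbose) message("subject ", i, "/", length(cohort))
      subjectMetrics(cohort[[i]], config)
    })
  }
  buildNormative(recs, minN = config$minN, seed = seed)
}
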