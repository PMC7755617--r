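## Canonical metric names for the global normative table.
metricValues <- function(metrics) {
  c(vol_left = metrics@volLeft, vol_right = metrics@volRight,
    qt2_left = metrics@qt2Left, qt2_right = metrics@qt2Right,
    lr_vol_ratio_pct = metrics@lrVolRatioPct,
    lr_qt2_ratio_pct = metrics@lrQt2RatioPct)
}

normEntry <- function(metric, mean, sd, n) {
  data.frame(metric = metric, mean = mean, sd = sd, n = n,
              lo = mean - 1.96 * sd, hi = mean + 1.96 * sd)
}

#' Build a normative model from a reference cohort
#'
#' Per-metric (and per profile bin) mean and SD over the cohort, with
#' mean +/- 1.96 SD reference bands. Permutation-invariant in cohort order.
#'
#' @param cohort List of per-subject records, each a list with
#'   \code{metrics} (a \linkS4class{GlobalMetrics}) and optionally
#'   \code{profiles} (list with \code{left} and \code{right}
#'   \linkS4class{HippocampusProfile}, all with one common number of bins).
#' @param minN Minimum admissible cohort size (default 20; SD estimates
#'   below that are unstable).
#' @param seed Provenance only: the seed that generated the cohort.
#' @return A \linkS4class{NormativeModel}.
#' @export
buildNormative <- function(cohort, minN = 20L, seed = NA) {
  n <- length(cohort)
  if (n < minN)
    hqStop("hippoquant_cohort_too_small",
           "cohort has ", n, " subjects; minimum is ", minN)
  vals <- t(vapply(cohort, function(s) metricValues(s$metrics),
                   numeric(6)))
  glob <- do.call(rbind, lapply(colnames(vals), function(m)
    normEntry(m, mean(vals[, m]), stats::sd(vals[, m]), n)))
  prof <- data.frame()
  hasProf <- vapply(cohort, function(s) !is.null(s$profiles), logical(1))
  if (all(hasProf)) {
    nb <- vapply(cohort, function(s) length(s$profiles$left@positions),
                 integer(1))
    if (length(unique(nb)) > 1L)
      hqStop("hippoquant_bin_mismatch",
             "inconsistent n_bins across cohort subjects")
    for (side in c("left", "right")) {
      pos <- cohort[[1]]$profiles[[side]]@positions
      area <- t(vapply(cohort, function(s) s$profiles[[side]]@area,
                       numeric(nb[1])))
      qt2 <- t(vapply(cohort, function(s) s$profiles[[side]]@qt2,
                      numeric(nb[1])))
      for (metric in c("area", "qt2")) {
        m <- if (metric == "area") area else qt2
        mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
        prof <- rbind(prof, data.frame(side = side, position = pos,
                                       metric = metric, mean = mu, sd = sdv,
                                       lo = mu - 1.96 * sdv,
                                       hi = mu + 1.96 * sdv))
      }
    }
  }
  new("NormativeModel", global = glob, profiles = prof,
      provenance = list(n = n, seed = seed, date = "build",
                        source = "cohort"))
}

#' Reference band of a normative entry
#'
#' @param entry One row of a model's global table (or any list with
#'   \code{mean} and \code{sd}).
#' @return \code{c(lo, hi)} = mean -/+ 1.96 sd.
#' @export
referenceBand <- function(entry) {
  c(lo = entry$mean - 1.96 * entry$sd, hi = entry$mean + 1.96 * entry$sd)
}

#' The shipped default normative model (ratio metrics only)
#'
#' Reference ranges for the left:right volume ratio (88.9--110.6 percent)
#' and qT2 ratio (93.7--104.2 percent) from a healthy adult reference
#' cohort of 111 subjects, shipped with the package. Only the two ratio
#' metrics carry bands; absolute volumes and qT2 have no shipped reference
#' and are reported with a "no reference" marker.
#'
#' @return A \linkS4class{NormativeModel}.
#' @export
defaultNormativeModel <- function() {
  path <- system.file("extdata", "normative_ratio_bands.csv",
                      package = "hippoquant", mustWork = TRUE)
  tab <- utils::read.csv(path)
  glob <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    mean <- (tab$lo[i] + tab$hi[i]) / 2
    sd <- (tab$hi[i] - tab$lo[i]) / (2 * 1.96)
    normEntry(tab$metric[i], mean, sd, tab$n[i])
  }))
  new("NormativeModel", global = glob, profiles = data.frame(),
      provenance = list(n = tab$n[1], seed = NA, date = "shipped",
                        source = "shipped-ratio-bands"))
}

#' Flag a subject against a normative model
#'
#' Each model metric is flagged \code{low}/\code{high} when the subject's
#' value falls outside its mean +/- 1.96 SD band. The overall impression is
#' a pure function of the per-metric flags: an abnormal ratio names the
#' implicated side (lower volume, or higher qT2); both sides implicated, or
#' ratios normal while both sides' absolute volumes are low (or both qT2
#' high), gives \code{bilateral_abnormal}; otherwise \code{normal}. This
#' aggregation is machine advice for display, not a diagnosis.
#'
#' @param metrics A \linkS4class{GlobalMetrics}.
#' @param model A \linkS4class{NormativeModel}.
#' @param profiles Unused by the flag rule; accepted for interface symmetry.
#' @return A \linkS4class{FlagSet}.
#' @export
flagSubject <- function(metrics, model, profiles = NULL) {
  vals <- metricValues(metrics)
  g <- model@global
  flags <- character(0)
  for (i in seq_len(nrow(g))) {
    m <- g$metric[i]
    if (!m %in% names(vals)) next
    flags[m] <- if (vals[m] < g$lo[i]) "low"
                else if (vals[m] > g$hi[i]) "high" else "normal"
  }
  fl <- function(m) if (m %in% names(flags)) flags[[m]] else "normal"
  sides <- character(0)
  if (fl("lr_vol_ratio_pct") == "low") sides <- c(sides, "left")
  if (fl("lr_vol_ratio_pct") == "high") sides <- c(sides, "right")
  if (fl("lr_qt2_ratio_pct") == "high") sides <- c(sides, "left")
  if (fl("lr_qt2_ratio_pct") == "low") sides <- c(sides, "right")
  sides <- unique(sides)
  overall <- if (length(sides) == 2L) "bilateral_abnormal"
    else if (length(sides) == 1L) paste0(sides, "_abnormal")
    else if ((fl("vol_left") == "low" && fl("vol_right") == "low") ||
             (fl("qt2_left") == "high" && fl("qt2_right") == "high"))
      "bilateral_abnormal"
    else "normal"
  new("FlagSet", flags = unlist(flags), overall = overall)
}

#' Serialise / read a normative model as JSON
#'
#' @param model A \linkS4class{NormativeModel}.
#' @param path Output (input) JSON path.
#' @return \code{writeNormativeModel}: \code{path} invisibly;
#'   \code{readNormativeModel}: the model.
#' @export
writeNormativeModel <- function(model, path) {
  jsonlite::write_json(list(schema = "hippoquant-normative-1",
                            global = model@global,
                            profiles = model@profiles,
                            provenance = model@provenance),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeNormativeModel
#' @export
readNormativeModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "hippoquant-normative-1"))
    hqStop("hippoquant_bad_schema", "unrecognised normative model schema")
  prof <- if (length(x$profiles)) as.data.frame(x$profiles) else data.frame()
  new("NormativeModel", global = as.data.frame(x$global), profiles = prof,
      provenance = x$provenance)
}
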