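RATING_CATEGORIES <- c("normal", "right", "left", "bilateral")

## Coerce ratings/gold to named character vectors over matching cases.
alignRatings <- function(ratings, gold) {
  if (length(ratings) == 0L)
    hqStop("hippoquant_empty_ratings", "no ratings supplied")
  miss <- setdiff(names(gold), names(ratings))
  if (length(miss))
    hqStop("hippoquant_unmatched_cases",
           "cases without ratings: ", paste(miss, collapse = ", "))
  ratings[names(gold)]
}

#' Confusion counts against the gold standard
#'
#' Ratings are collapsed to a normal/abnormal dichotomy: any of right, left
#' or bilateral counts as "abnormal detected", so a wrong side on an
#' abnormal case is still a true positive here (lateralisation is scored
#' separately by \code{\link{lateralisationAccuracyPct}}).
#'
#' @param ratings Named character vector (case -> category).
#' @param gold Named character vector (case -> gold category).
#' @return List with integer \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusionCounts <- function(ratings, gold) {
  r <- alignRatings(ratings, gold)
  rAb <- r != "normal"; gAb <- gold != "normal"
  list(TP = sum(rAb & gAb), TN = sum(!rAb & !gAb),
       FP = sum(rAb & !gAb), FN = sum(!rAb & gAb))
}

#' Accuracy, sensitivity and specificity in percent
#'
#' \code{accuracyPct}: 100 (TP+TN)/(TP+TN+FP+FN);
#' \code{sensitivityPct}: 100 TP/(TP+FN);
#' \code{specificityPct}: 100 TN/(TN+FP).
#'
#' @param cc Confusion counts from \code{\link{confusionCounts}}.
#' @return Percent.
#' @export
accuracyPct <- function(cc) {
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  if (n == 0) hqStop("hippoquant_undefined_statistic", "no assessments")
  100 * (cc$TP + cc$TN) / n
}

#' @rdname accuracyPct
#' @export
sensitivityPct <- function(cc) {
  if (cc$TP + cc$FN == 0)
    hqStop("hippoquant_undefined_statistic", "no abnormal gold cases")
  100 * cc$TP / (cc$TP + cc$FN)
}

#' @rdname accuracyPct
#' @export
specificityPct <- function(cc) {
  if (cc$TN + cc$FP == 0)
    hqStop("hippoquant_undefined_statistic", "no normal gold cases")
  100 * cc$TN / (cc$TN + cc$FP)
}

#' Lateralisation accuracy in percent
#'
#' Share of abnormal gold cases whose exact category (right, left or
#' bilateral) was matched; detecting abnormality with the wrong side counts
#' as incorrect here.
#'
#' @inheritParams confusionCounts
#' @return Percent.
#' @export
lateralisationAccuracyPct <- function(ratings, gold) {
  r <- alignRatings(ratings, gold)
  ab <- gold != "normal"
  if (!any(ab))
    hqStop("hippoquant_undefined_statistic", "no abnormal gold cases")
  100 * sum(r[ab] == gold[ab]) / sum(ab)
}

#' Cohen's kappa for two categorical raters
#'
#' Unweighted multi-category kappa with chance agreement from the product
#' of marginals: \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. Perfect agreement
#' returns 1 even in the degenerate case \eqn{p_e = 1}; imperfect agreement
#' with \eqn{p_e = 1} is an error.
#'
#' @param a,b Character vectors of ratings over the same cases.
#' @param categories Category universe.
#' @return Kappa (<= 1).
#' @export
cohenKappa <- function(a, b, categories = RATING_CATEGORIES) {
  if (length(a) != length(b) || length(a) < 2L)
    hqStop("hippoquant_bad_input", "need >= 2 paired ratings")
  a <- factor(a, levels = categories); b <- factor(b, levels = categories)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) return(1)
    hqStop("hippoquant_undefined_kappa",
           "chance agreement is 1 with imperfect observed agreement")
  }
  (po - pe) / (1 - pe)
}

#' Agreement band for a kappa value
#'
#' 0.60--0.79 is "moderate" and 0.80--0.90 "strong"; the scale extends
#' below ("none" < 0.21, "minimal" 0.21--0.39, "weak" 0.40--0.59) and above
#' ("almost_perfect" > 0.90).
#'
#' @param kappa Kappa value (<= 1).
#' @return Character label.
#' @export
kappaBand <- function(kappa) {
  if (kappa > 1) hqStop("hippoquant_bad_input", "kappa cannot exceed 1")
  if (kappa > 0.90) "almost_perfect"
  else if (kappa >= 0.80) "strong"
  else if (kappa >= 0.60) "moderate"
  else if (kappa >= 0.40) "weak"
  else if (kappa >= 0.21) "minimal"
  else "none"
}

#' McNemar test from discordant-pair counts
#'
#' Exact two-sided binomial test when b + c < 25, otherwise the
#' continuity-corrected chi-square \eqn{(|b-c|-1)^2/(b+c)} on 1 df. With no
#' discordant pairs, p = 1 by convention.
#'
#' @param b,c Discordant counts (condition A correct / B incorrect, and
#'   vice versa).
#' @return List with \code{statistic}, \code{p}, \code{method}.
#' @export
mcnemarTest <- function(b, c) {
  if (b < 0 || c < 0) hqStop("hippoquant_bad_input", "counts must be >= 0")
  n <- b + c
  if (n == 0) return(list(statistic = 0, p = 1, method = "degenerate"))
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    list(statistic = min(b, c), p = p, method = "exact-binomial")
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
         method = "chi-square-cc")
  }
}

#' Paired t test with standardised effect sizes
#'
#' Two-sided paired t on x - y, with the paired-samples effect sizes
#' \eqn{d_z = \bar d / s_d} and Hedges' \eqn{g_z = d_z (1 - 3/(4 df - 1))},
#' plus the classical d (mean difference over the average of the two SDs),
#' all clearly labelled since the two d conventions differ.
#'
#' @param x,y Paired samples, n >= 2, with non-degenerate differences.
#' @return List: \code{t}, \code{df}, \code{p}, \code{meanDiff},
#'   \code{sdDiff}, \code{ci} (95 percent for the mean difference),
#'   \code{dz}, \code{gz}, \code{dav}.
#' @export
pairedTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    hqStop("hippoquant_bad_input", "need >= 2 pairs")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0)
    hqStop("hippoquant_zero_variance", "paired differences have zero variance")
  n <- length(d); df <- n - 1
  md <- mean(d)
  t <- md / (sdd / sqrt(n))
  dz <- md / sdd
  hw <- stats::qt(0.975, df) * sdd / sqrt(n)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       meanDiff = md, sdDiff = sdd, ci = c(md - hw, md + hw),
       dz = dz, gz = dz * (1 - 3 / (4 * df - 1)),
       dav = md / ((stats::sd(x) + stats::sd(y)) / 2))
}

#' Cronbach's alpha
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i \sigma_i^2 / \sigma_{total}^2)} with
#' \eqn{\sigma_{total}^2} the variance of case-wise sums.
#'
#' @param mat Numeric matrix, cases x raters (>= 2 each).
#' @return Alpha.
#' @export
cronbachAlpha <- function(mat) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k < 2L || nrow(mat) < 2L)
    hqStop("hippoquant_bad_input", "need >= 2 raters and >= 2 cases")
  vt <- stats::var(rowSums(mat))
  if (vt == 0)
    hqStop("hippoquant_zero_variance", "case-wise sums have zero variance")
  k / (k - 1) * (1 - sum(apply(mat, 2, stats::var)) / vt)
}

#' Intraclass correlation (two-way mixed, consistency)
#'
#' From the two-way ANOVA mean squares (rows = cases, columns = raters):
#' single measures \eqn{(MS_R - MS_E)/(MS_R + (k-1) MS_E)}, average
#' measures \eqn{(MS_R - MS_E)/MS_R}.
#'
#' @param mat Complete numeric matrix, cases x raters.
#' @param form \code{"single"} or \code{"average"}.
#' @return ICC value.
#' @export
icc <- function(mat, form = c("single", "average")) {
  form <- match.arg(form)
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L || n < 2L)
    hqStop("hippoquant_bad_input", "need >= 2 raters and >= 2 cases")
  if (any(is.na(mat)))
    hqStop("hippoquant_bad_input", "matrix must be complete")
  grand <- mean(mat)
  ssr <- k * sum((rowMeans(mat) - grand)^2)
  ssc <- n * sum((colMeans(mat) - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0)
    hqStop("hippoquant_degenerate_ms", "degenerate between-case mean square")
  if (form == "single") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / msr
}

#' Repeated-measures / mixed ANOVA on rater cell means
#'
#' Standard balanced sums-of-squares decomposition via \code{stats::aov}
#' with an \code{Error(subject/within)} stratum structure: within-subject
#' factors are tested against their subject x factor interaction strata, a
#' between-subjects factor against the subject-within-group stratum. Each
#' effect is reported with F, df, p and partial eta squared
#' \eqn{SS_{effect}/(SS_{effect}+SS_{error})}. Unbalanced designs are
#' rejected, not approximated.
#'
#' @param data Long-format data.frame of cell means: one row per subject x
#'   cell.
#' @param dv Column name of the response.
#' @param within Character vector of within-subject factor columns.
#' @param between Optional between-subjects factor column.
#' @param subject Column identifying the subject (rater).
#' @return data.frame: effect, df, dfError, ss, ssError, F, p, petaSq.
#' @export
confidenceAnova <- function(data, dv = "value", within, between = NULL,
                            subject = "subject") {
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  if (!is.null(between)) data[[between]] <- factor(data[[between]])
  ## balance: exactly one observation per subject x within-cell
  cellTab <- table(data[, c(subject, within)])
  if (!all(cellTab == 1L))
    hqStop("hippoquant_unbalanced_design",
           "design must have exactly one value per subject and cell")
  if (!is.null(between)) {
    g <- table(unique(data[, c(subject, between)])[[between]])
    if (length(unique(g)) != 1L || any(g < 2L))
      hqStop("hippoquant_unbalanced_design",
             "between groups must be equal-sized with >= 2 subjects each")
  }
  wterm <- paste(within, collapse = "*")
  fixed <- if (is.null(between)) wterm else paste(between, "*", wterm)
  fml <- stats::as.formula(paste(dv, "~", fixed, "+ Error(", subject,
                                 "/(", wterm, "))"))
  fit <- stats::aov(fml, data = data)
  out <- data.frame()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    resid <- rn == "Residuals"
    ssErr <- if (any(resid)) tab[resid, "Sum Sq"] else NA_real_
    dfErr <- if (any(resid)) tab[resid, "Df"] else NA_real_
    for (i in which(!resid)) {
      ss <- tab[i, "Sum Sq"]
      if (!is.na(ssErr) && ssErr < 1e-12 && ss < 1e-12) {
        Fv <- 0; p <- 1
      } else {
        Fv <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
      }
      out <- rbind(out, data.frame(
        effect = gsub(":", " x ", rn[i]), df = tab[i, "Df"], dfError = dfErr,
        ss = ss, ssError = ssErr, F = Fv, p = p,
        petaSq = if (ss < 1e-12) 0 else ss / (ss + ssErr)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate a rater study
#'
#' Parametric generator of per-(rater, case, condition) categorical ratings
#' and 1--5 confidences against a 4-category gold standard. For an abnormal
#' gold case the rater detects abnormality with probability sensitivity
#' (plus the report delta under \code{with_report}); a detected case gets
#' the exact category with probability lambda (plus its delta), otherwise a
#' uniform error among the remaining abnormal categories. A normal gold
#' case is called abnormal with probability 1 - specificity (minus its
#' delta), with uniform category. Confidences are discretised Gaussians
#' (clipped to 1..5) whose mean depends on correctness and condition.
#'
#' Defaults reproduce a reading-session design of 43 cases (23 normal, 6
#' left, 9 right, 5 bilateral HS) and nine raters in three experience
#' groups, two conditions: 774 records.
#'
#' @param design List: nNormal, nLeft, nRight, nBilateral.
#' @param raters data.frame with columns \code{rater}, \code{group}.
#' @param params List: \code{sensitivity}, \code{specificity},
#'   \code{lateralisation} (scalars or named per group),
#'   \code{reportDelta} (list with the three deltas), \code{confMean}
#'   (list: correct/incorrect, each c(without, with)), \code{confSD}.
#' @param seed Integer seed.
#' @return List with \code{table} (the rating records) and \code{gold}
#'   (named vector case -> category).
#' @export
simulateRaterStudy <- function(design = list(nNormal = 23, nLeft = 6,
                                             nRight = 9, nBilateral = 5),
                               raters = data.frame(
                                 rater = c("1a", "1b", "1c", "2a", "2b",
                                           "2c", "3a", "3b", "3c"),
                                 group = rep(c("experts", "trainees",
                                               "analysts"), each = 3)),
                               params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    sensitivity = 0.875, specificity = 0.874, lateralisation = 0.835,
    reportDelta = list(sensitivity = 0.025, specificity = 0.076,
                       lateralisation = 0.08),
    confMean = list(correct = c(without = 3.8, with = 4.15),
                    incorrect = c(without = 3.4, with = 3.25)),
    confSD = 0.9), params)
  groupPar <- function(x, g) if (length(x) > 1L) x[[g]] else x
  chk <- c(unlist(p[c("sensitivity", "specificity", "lateralisation")]))
  if (any(chk < 0 | chk > 1))
    hqStop("hippoquant_bad_probability", "probabilities must lie in [0,1]")
  gold <- c(rep("normal", design$nNormal), rep("left", design$nLeft),
            rep("right", design$nRight), rep("bilateral", design$nBilateral))
  names(gold) <- sprintf("case%02d", seq_along(gold))
  set.seed(as.integer(seed))
  conf <- function(correct, cond) {
    mu <- p$confMean[[if (correct) "correct" else "incorrect"]][[
      if (cond == "with_report") "with" else "without"]]
    min(5L, max(1L, as.integer(round(stats::rnorm(1, mu, p$confSD)))))
  }
  rows <- vector("list", nrow(raters) * length(gold) * 2L)
  i <- 0L
  for (r in seq_len(nrow(raters))) {
    g <- raters$group[r]
    sens <- groupPar(p$sensitivity, g)
    spec <- groupPar(p$specificity, g)
    lam <- groupPar(p$lateralisation, g)
    for (cs in names(gold)) {
      for (cond in c("without_report", "with_report")) {
        withR <- cond == "with_report"
        sens_c <- min(1, sens + if (withR) p$reportDelta$sensitivity else 0)
        spec_c <- min(1, spec + if (withR) p$reportDelta$specificity else 0)
        lam_c <- min(1, lam + if (withR) p$reportDelta$lateralisation else 0)
        gl <- gold[[cs]]
        if (gl == "normal") {
          rating <- if (stats::runif(1) < spec_c) "normal"
            else sample(c("right", "left", "bilateral"), 1L)
        } else {
          if (stats::runif(1) < sens_c) {
            rating <- if (stats::runif(1) < lam_c) gl
              else sample(setdiff(c("right", "left", "bilateral"), gl), 1L)
          } else rating <- "normal"
        }
        i <- i + 1L
        rows[[i]] <- data.frame(
          rater = raters$rater[r], group = g, case = cs, condition = cond,
          rating = rating,
          confidence_normality =
            conf((rating != "normal") == (gl != "normal"), cond),
          confidence_lateralisation = conf(rating == gl, cond))
      }
    }
  }
  list(table = do.call(rbind, rows), gold = gold)
}

## Rating matrix (cases x raters) of numeric category codes, one condition.
ratingMatrix <- function(table, cond,
                         codes = c(normal = 0, right = 1, left = 2,
                                   bilateral = 3)) {
  sub <- table[table$condition == cond, ]
  m <- tapply(codes[sub$rating], list(sub$case, sub$rater), mean)
  m[order(rownames(m)), , drop = FALSE]
}

#' Analyse a rater study
#'
#' Computes the full battery: per-rater accuracy, sensitivity, specificity,
#' lateralisation accuracy and kappa vs the gold standard in each
#' condition; group and total summaries (group kappa means are unweighted
#' means of the group's raters); a McNemar test on pooled
#' correct/incorrect discordant (rater, case) pairs between conditions;
#' paired t contrasts (with vs without report) with d_z, Hedges' g_z and
#' classical d; Cronbach's alpha and ICC (single/average, two-way mixed,
#' consistency) per condition on numerically coded ratings; and the
#' confidence ANOVAs (2 correctness x 2 condition within; 2 condition x 2
#' gold normality x 3 experience mixed, correct decisions only).
#'
#' @param table A rating table as produced by
#'   \code{\link{simulateRaterStudy}}.
#' @param gold Named character vector, case -> gold category.
#' @return A \linkS4class{StudyResult}.
#' @export
analyzeStudy <- function(table, gold) {
  conds <- c("without_report", "with_report")
  raters <- unique(table[, c("rater", "group")])
  perRater <- data.frame()
  for (r in seq_len(nrow(raters))) {
    for (cond in conds) {
      sub <- table[table$rater == raters$rater[r] &
                     table$condition == cond, ]
      rt <- stats::setNames(sub$rating, sub$case)
      cc <- confusionCounts(rt, gold)
      kp <- cohenKappa(rt[names(gold)], gold)
      perRater <- rbind(perRater, data.frame(
        rater = raters$rater[r], group = raters$group[r], condition = cond,
        accuracy = accuracyPct(cc), sensitivity = sensitivityPct(cc),
        specificity = specificityPct(cc),
        lateralisation = lateralisationAccuracyPct(rt, gold),
        kappa = kp, band = kappaBand(kp)))
    }
  }
  measures <- c("accuracy", "sensitivity", "specificity", "lateralisation",
                "kappa")
  groupSummary <- data.frame()
  for (g in c(unique(raters$group), "combined")) {
    sel <- if (g == "combined") rep(TRUE, nrow(perRater))
           else perRater$group == g
    for (cond in conds) {
      s <- perRater[sel & perRater$condition == cond, ]
      for (m in measures)
        groupSummary <- rbind(groupSummary, data.frame(
          group = g, condition = cond, measure = m,
          mean = mean(s[[m]]), sd = stats::sd(s[[m]])))
    }
  }
  kappaTable <- data.frame()
  for (cond in conds) {
    s <- perRater[perRater$condition == cond, ]
    kappaTable <- rbind(kappaTable,
      data.frame(level = "rater", group = s$group, rater = s$rater,
                 condition = cond, kappa = s$kappa, band = s$band))
    for (g in unique(raters$group)) {
      km <- mean(s$kappa[s$group == g])
      kappaTable <- rbind(kappaTable,
        data.frame(level = "group", group = g, rater = NA, condition = cond,
                   kappa = km, band = kappaBand(km)))
    }
    km <- mean(s$kappa)
    kappaTable <- rbind(kappaTable,
      data.frame(level = "total", group = NA, rater = NA, condition = cond,
                 kappa = km, band = kappaBand(km)))
  }
  pairedTests <- data.frame()
  for (m in measures) {
    w <- perRater[perRater$condition == "with_report", ]
    wo <- perRater[perRater$condition == "without_report", ]
    wo <- wo[match(w$rater, wo$rater), ]
    pt <- tryCatch(pairedTest(w[[m]], wo[[m]]), error = function(e) NULL)
    if (!is.null(pt))
      pairedTests <- rbind(pairedTests, data.frame(
        measure = m, meanWith = mean(w[[m]]), meanWithout = mean(wo[[m]]),
        delta = pt$meanDiff, t = pt$t, df = pt$df, p = pt$p, dz = pt$dz,
        gz = pt$gz, dav = pt$dav))
  }
  ## McNemar on pooled (rater, case) normality-correctness discordants
  corr <- function(cond) {
    sub <- table[table$condition == cond, ]
    (sub$rating != "normal") == (gold[sub$case] != "normal")
  }
  key <- function(cond) {
    sub <- table[table$condition == cond, ]
    paste(sub$rater, sub$case)
  }
  cw <- stats::setNames(corr("with_report"), key("with_report"))
  cwo <- stats::setNames(corr("without_report"), key("without_report"))
  cw <- cw[names(cwo)]
  b <- sum(cwo & !cw)   # correct without, incorrect with
  cc2 <- sum(!cwo & cw)
  mcn <- c(list(b = b, c = cc2), mcnemarTest(b, cc2))
  reliability <- data.frame()
  for (cond in conds) {
    m <- ratingMatrix(table, cond)
    reliability <- rbind(reliability, data.frame(
      condition = cond,
      alpha = cronbachAlpha(m),
      icc_single = icc(m, "single"),
      icc_average = icc(m, "average"),
      icc_model = "two-way mixed, consistency"))
  }
  ## confidence cell means per rater
  table$correct <- (table$rating != "normal") == (gold[table$case] != "normal")
  cm <- stats::aggregate(confidence_normality ~ rater + condition + correct,
                         data = table, FUN = mean)
  names(cm)[names(cm) == "confidence_normality"] <- "value"
  cm$correct <- ifelse(cm$correct, "correct", "incorrect")
  an1 <- tryCatch(
    confidenceAnova(cm, dv = "value", within = c("correct", "condition"),
                    subject = "rater"),
    error = function(e) conditionMessage(e))
  sub <- table[table$correct, ]
  sub$normality <- ifelse(gold[sub$case] == "normal", "normal", "abnormal")
  cm2 <- stats::aggregate(confidence_normality ~ rater + group + condition +
                            normality, data = sub, FUN = mean)
  names(cm2)[names(cm2) == "confidence_normality"] <- "value"
  an2 <- tryCatch(
    confidenceAnova(cm2, dv = "value", within = c("condition", "normality"),
                    between = "group", subject = "rater"),
    error = function(e) conditionMessage(e))
  new("StudyResult", perRater = perRater, groupSummary = groupSummary,
      kappaTable = kappaTable, pairedTests = pairedTests, mcnemar = mcn,
      reliability = reliability,
      anova = list(correctness_by_report = an1,
                   report_by_normality_by_experience = an2))
}

#' Write a study table / result to disk
#'
#' The rating table and gold standard as CSV; the result battery as JSON
#' plus the main tables as CSV.
#'
#' @param result A \linkS4class{StudyResult}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
writeStudyResult <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result@perRater, file.path(dir, "per_rater.csv"),
                   row.names = FALSE)
  utils::write.csv(result@groupSummary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result@kappaTable, file.path(dir, "kappa.csv"),
                   row.names = FALSE)
  utils::write.csv(result@pairedTests, file.path(dir, "paired_tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(perRater = result@perRater, groupSummary = result@groupSummary,
         kappaTable = result@kappaTable, pairedTests = result@pairedTests,
         mcnemar = result@mcnemar, reliability = result@reliability,
         anova = result@anova),
    file.path(dir, "study_result.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}
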