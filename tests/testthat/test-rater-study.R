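goldToy <- c(rep("normal", 23), rep("left", 6), rep("right", 9),
             rep("bilateral", 5))
names(goldToy) <- sprintf("case%02d", seq_along(goldToy))

test_that("confusion counts collapse to the normal/abnormal dichotomy", {
  perfect <- goldToy
  cc <- confusionCounts(perfect, goldToy)
  expect_identical(cc, list(TP = 20L, TN = 23L, FP = 0L, FN = 0L))
  ## wrong side on an abnormal case still counts as detected (TP)
  swapped <- goldToy
  swapped[goldToy == "left"] <- "right"
  cc2 <- confusionCounts(swapped, goldToy)
  expect_identical(cc2$TP, 20L)
  expect_identical(cc2$FN, 0L)
  expect_error(confusionCounts(character(0), goldToy),
               class = "hippoquant_empty_ratings")
  expect_error(confusionCounts(goldToy[-1], goldToy),
               class = "hippoquant_unmatched_cases")
})

test_that("accuracy, sensitivity and specificity follow the counting formulae", {
  cc <- list(TP = 35, TN = 5, FP = 1, FN = 2)
  expect_equal(accuracyPct(cc), 100 * 40 / 43)
  expect_equal(round(accuracyPct(cc), 2), 93.02)
  expect_equal(sensitivityPct(list(TP = 7, TN = 0, FP = 0, FN = 0)), 100)
  expect_error(accuracyPct(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               class = "hippoquant_undefined_statistic")
  expect_error(sensitivityPct(list(TP = 0, TN = 5, FP = 2, FN = 0)),
               class = "hippoquant_undefined_statistic")
})

test_that("lateralisation accuracy scores the exact category on abnormal cases", {
  expect_equal(lateralisationAccuracyPct(goldToy, goldToy), 100)
  one <- goldToy
  one[which(goldToy == "right")[1]] <- "left"
  expect_equal(lateralisationAccuracyPct(one, goldToy), 95)
  ## all detections right, every unilateral side swapped: TP yet incorrect here
  swapped <- goldToy
  swapped[goldToy == "left"] <- "right"
  swapped[goldToy == "right"] <- "left"
  expect_equal(lateralisationAccuracyPct(swapped, goldToy), 100 * 5 / 20)
  expect_error(lateralisationAccuracyPct(goldToy[1:23], goldToy[1:23]),
               class = "hippoquant_undefined_statistic")
})

test_that("Cohen's kappa matches hand computation and an independent library", {
  expect_identical(cohenKappa(goldToy, goldToy), 1)
  ## toy 2x2 confusion [[4,1],[1,4]]: po 0.8, pe 0.5, kappa 0.6
  a <- rep(c("normal", "right"), each = 5)
  b <- c(rep("normal", 4), "right", "normal", rep("right", 4))
  expect_equal(cohenKappa(a, b, categories = c("normal", "right")), 0.6,
               tolerance = 1e-12)
  ## independence: kappa ~ 0 (Monte-Carlo)
  set.seed(123)
  x <- sample(RATING_CATEGORIES, 1e5, TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  y <- sample(RATING_CATEGORIES, 1e5, TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  expect_lt(abs(cohenKappa(x, y)), 0.01)
  ## cross-check against e1071 on an arbitrary pair
  skip_if_not_installed("e1071")
  set.seed(9)
  x2 <- sample(RATING_CATEGORIES, 200, TRUE)
  y2 <- ifelse(runif(200) < 0.6, x2, sample(RATING_CATEGORIES, 200, TRUE))
  ours <- cohenKappa(x2, y2)
  ref <- e1071::classAgreement(table(factor(x2, RATING_CATEGORIES),
                                     factor(y2, RATING_CATEGORIES)))$kappa
  expect_equal(ours, ref, tolerance = 1e-12)
  ## label-permutation invariance
  perm <- c(normal = "left", right = "bilateral", left = "normal",
            bilateral = "right")
  expect_equal(cohenKappa(unname(perm[x2]), unname(perm[y2])), ours,
               tolerance = 1e-12)
  ## degenerate chance agreement (single shared category) with perfect
  ## observed agreement returns 1 rather than 0/0
  expect_identical(cohenKappa(rep("normal", 10), rep("normal", 10)), 1)
})

test_that("kappa bands follow the quoted agreement scale", {
  expect_identical(kappaBand(0.74), "moderate")
  expect_identical(kappaBand(0.86), "strong")
  expect_identical(kappaBand(0.60), "moderate")
  expect_identical(kappaBand(0.80), "strong")
  expect_identical(kappaBand(0.95), "almost_perfect")
  expect_identical(kappaBand(0.45), "weak")
  expect_identical(kappaBand(0.10), "none")
  expect_error(kappaBand(1.2), class = "hippoquant_bad_input")
})

test_that("McNemar switches between exact binomial and corrected chi-square", {
  expect_equal(mcnemarTest(5, 5)$p, 1)
  m <- mcnemarTest(8, 2)
  expect_identical(m$method, "exact-binomial")
  expect_equal(m$p, 0.109375, tolerance = 1e-12)
  big <- mcnemarTest(30, 10)
  expect_equal(big$statistic, 19^2 / 40, tolerance = 1e-12)
  ## cross-check the chi-square branch against stats::mcnemar.test
  ref <- stats::mcnemar.test(matrix(c(50, 30, 10, 50), 2), correct = TRUE)
  expect_equal(big$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(big$p, ref$p.value, tolerance = 1e-12)
  ## symmetry of the exact p
  expect_equal(mcnemarTest(2, 8)$p, mcnemarTest(8, 2)$p)
  expect_equal(mcnemarTest(0, 0)$p, 1)
})

test_that("paired t and its effect sizes match hand arithmetic and stats::t.test", {
  x <- c(11, 12, 13); y <- c(10, 10, 10)
  pt <- pairedTest(x, y)
  expect_equal(pt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(pt$df, 2)
  expect_equal(pt$dz, 2, tolerance = 1e-12)
  expect_equal(pt$gz, 2 * (1 - 3 / 7), tolerance = 1e-12)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(pt$p, ref$p.value, tolerance = 1e-12)
  expect_equal(pt$ci, as.numeric(ref$conf.int), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(pairedTest(x, x), class = "hippoquant_zero_variance")
})

test_that("Cronbach's alpha matches its closed forms", {
  m <- matrix(rnorm(50), 50, 1)[, c(1, 1, 1)]
  expect_equal(cronbachAlpha(m), 1, tolerance = 1e-12)
  set.seed(21)
  ind <- matrix(rnorm(3e5), ncol = 3)
  expect_lt(abs(cronbachAlpha(ind)), 0.02)
  ## Spearman-Brown: k=2 with correlation 0.5 gives alpha 2/3
  set.seed(22)
  z <- rnorm(2e5)
  pair <- cbind(z + rnorm(2e5), z + rnorm(2e5))  # rho = 0.5
  expect_lt(abs(cronbachAlpha(pair) - 2 / 3), 0.02)
  expect_error(cronbachAlpha(matrix(1, 10, 3)),
               class = "hippoquant_zero_variance")
})

test_that("ICC single and average follow the two-way mean squares", {
  m <- matrix(rnorm(40), 40, 1)[, c(1, 1, 1)]
  expect_equal(icc(m, "single"), 1, tolerance = 1e-12)
  expect_equal(icc(m, "average"), 1, tolerance = 1e-12)
  set.seed(23)
  ind <- matrix(rnorm(9e4), ncol = 3)
  expect_lt(abs(icc(ind, "single")), 0.02)
  ## average >= single whenever the case mean square dominates
  for (i in 1:10) {
    mm <- matrix(rnorm(60), 20, 3) + rnorm(20)
    expect_gte(icc(mm, "average"), icc(mm, "single"))
  }
})

test_that("the confidence ANOVA matches a brute-force SS decomposition", {
  ## constructed 2x2 within design: main effect A only, subject offsets
  subj <- factor(rep(1:6, each = 4))
  A <- factor(rep(c("a1", "a2"), times = 12))
  B <- factor(rep(rep(c("b1", "b2"), each = 2), times = 6))
  off <- rep(rnorm(6, 0, 0.5), each = 4)
  set.seed(33)
  val <- 3 + (A == "a2") * 1 + off + rnorm(24, 0, 0.05)
  d <- data.frame(subject = subj, A = A, B = B, value = val)
  out <- confidenceAnova(d, within = c("A", "B"))
  ssOracle <- bruteForceSS(d, "value", c("subject", "A", "B"))
  expect_equal(out$ss[out$effect == "A"], ssOracle[["A"]], tolerance = 1e-9)
  expect_equal(out$ss[out$effect == "B"], ssOracle[["B"]], tolerance = 1e-9)
  expect_equal(out$ss[out$effect == "A x B"], ssOracle[["A:B"]],
               tolerance = 1e-9)
  ## error strata are the subject x factor interactions
  expect_equal(out$ssError[out$effect == "A"], ssOracle[["subject:A"]],
               tolerance = 1e-9)
  ## F_A large, F_B negligible
  expect_gt(out$F[out$effect == "A"], 50)
  expect_lt(out$F[out$effect == "B"], 5)
  ## SS conservation: total = all effects + all error strata + subject
  total <- sum(out$ss) + sum(unique(out$ssError)) + ssOracle[["subject"]]
  expect_equal(total, ssOracle$total, tolerance = 1e-9)
  ## all cell means equal: F = 0, peta2 = 0
  d0 <- d; d0$value <- off
  out0 <- confidenceAnova(d0, within = c("A", "B"))
  expect_true(all(out0$F == 0))
  expect_true(all(out0$petaSq == 0))
  ## unbalanced designs are rejected, not approximated
  expect_error(confidenceAnova(d[-1, ], within = c("A", "B")),
               class = "hippoquant_unbalanced_design")
})

test_that("the mixed ANOVA tests between effects against the subject stratum", {
  set.seed(44)
  subj <- factor(rep(1:6, each = 2))
  grp <- factor(rep(c("g1", "g2"), each = 6))
  W <- factor(rep(c("w1", "w2"), times = 6))
  val <- 3 + (grp == "g2") * 0.8 + (W == "w2") * 0.3 +
    rep(rnorm(6, 0, 0.2), each = 2) + rnorm(12, 0, 0.05)
  d <- data.frame(subject = subj, grp = grp, W = W, value = val)
  out <- confidenceAnova(d, within = "W", between = "grp")
  ssOracle <- bruteForceSS(d, "value", c("subject", "grp", "W"))
  ## between effect SS; its error is subject-within-group = SS_subject - SS_grp
  expect_equal(out$ss[out$effect == "grp"], ssOracle[["grp"]],
               tolerance = 1e-9)
  expect_equal(out$ssError[out$effect == "grp"],
               ssOracle[["subject"]] - ssOracle[["grp"]], tolerance = 1e-9)
  expect_equal(out$ss[out$effect == "W"], ssOracle[["W"]], tolerance = 1e-9)
  expect_gt(out$F[out$effect == "grp"], 5)
})

test_that("the rater simulator reproduces its design and degenerate limits", {
  perfect <- simulateRaterStudy(params = list(sensitivity = 1,
                                              specificity = 1,
                                              lateralisation = 1,
                                              reportDelta = list(
                                                sensitivity = 0,
                                                specificity = 0,
                                                lateralisation = 0)),
                                seed = 3)
  expect_identical(nrow(perfect$table), 774L)
  res <- analyzeStudy(perfect$table, perfect$gold)
  expect_true(all(res@perRater$accuracy == 100))
  expect_true(all(res@perRater$kappa == 1))
  ## determinism
  s1 <- simulateRaterStudy(seed = 11)
  s2 <- simulateRaterStudy(seed = 11)
  expect_identical(s1$table, s2$table)
  expect_error(simulateRaterStudy(params = list(sensitivity = 1.4)),
               class = "hippoquant_bad_probability")
})

test_that("group kappa summaries are unweighted means of their raters", {
  st <- simulateRaterStudy(seed = 17)
  res <- analyzeStudy(st$table, st$gold)
  kt <- res@kappaTable
  for (cond in unique(kt$condition)) {
    for (g in c("experts", "trainees", "analysts")) {
      raters <- kt$kappa[kt$level == "rater" & kt$group == g &
                           kt$condition == cond]
      grp <- kt$kappa[kt$level == "group" & kt$group == g &
                        kt$condition == cond]
      expect_equal(grp, mean(raters), tolerance = 1e-12)
    }
    tot <- kt$kappa[kt$level == "total" & kt$condition == cond]
    expect_equal(tot, mean(kt$kappa[kt$level == "rater" &
                                      kt$condition == cond]),
                 tolerance = 1e-12)
  }
})

test_that("identical generating conditions yield calibrated paired-test p values", {
  ## type-I check: no report effect simulated, so rejections ~ alpha
  nulls <- list(reportDelta = list(sensitivity = 0, specificity = 0,
                                   lateralisation = 0),
                confMean = list(correct = c(without = 3.8, with = 3.8),
                                incorrect = c(without = 3.4, with = 3.4)))
  ps <- vapply(1:60, function(i) {
    st <- simulateRaterStudy(params = nulls, seed = 1000 + i)
    acc <- function(cond) {
      sub <- st$table[st$table$condition == cond, ]
      vapply(split(sub, sub$rater), function(s)
        accuracyPct(confusionCounts(setNames(s$rating, s$case), st$gold)),
        numeric(1))
    }
    w <- acc("with_report"); wo <- acc("without_report")
    if (sd(w - wo) == 0) NA_real_ else pairedTest(w, wo)$p
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.25)
})

test_that("the analyzer recovers generating detection parameters", {
  st <- simulateRaterStudy(seed = 29)
  res <- analyzeStudy(st$table, st$gold)
  gs <- res@groupSummary
  sens <- gs$mean[gs$group == "combined" & gs$measure == "sensitivity" &
                    gs$condition == "without_report"]
  ## 9 raters x 20 abnormal cases at p = 0.875
  se <- 100 * sqrt(0.875 * 0.125 / 180)
  expect_lt(abs(sens - 87.5), 3 * se + 1)
  expect_s4_class(res, "StudyResult")
  expect_true(is.data.frame(res@anova$correctness_by_report) ||
                is.character(res@anova$correctness_by_report))
})

test_that("study results serialise to CSV and JSON", {
  tmp <- withr::local_tempdir()
  st <- simulateRaterStudy(seed = 2)
  res <- analyzeStudy(st$table, st$gold)
  writeStudyResult(res, tmp)
  expect_true(file.exists(file.path(tmp, "per_rater.csv")))
  js <- jsonlite::read_json(file.path(tmp, "study_result.json"),
                            simplifyVector = TRUE)
  expect_equal(js$mcnemar$p, res@mcnemar$p)
})
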