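test_that("a zero-variability cohort collapses every band to its mean", {
  rec <- drawHealthyMetrics(1)[[1]]
  cohort <- rep(list(rec), 25)
  mod <- buildNormative(cohort)
  expect_true(all(mod@global$sd == 0))
  expect_equal(mod@global$lo, mod@global$mean)
  expect_equal(mod@global$hi, mod@global$mean)
})

test_that("Gaussian ratios produce the 1.96-sigma band", {
  set.seed(55)
  n <- 5000
  cohort <- lapply(seq_len(n), function(i) {
    r <- rnorm(1, 100, 5)
    list(metrics = new("GlobalMetrics", volLeft = 2000 * r / 100,
                       volRight = 2000, qt2Left = 100, qt2Right = 100,
                       lrVolRatioPct = r, lrQt2RatioPct = 100,
                       asymVolRatioPct = min(r, 1e4 / r),
                       asymQt2RatioPct = 100))
  })
  mod <- buildNormative(cohort)
  band <- mod@global[mod@global$metric == "lr_vol_ratio_pct", ]
  expect_equal(band$lo, 90.2, tolerance = 0.01)
  expect_equal(band$hi, 109.8, tolerance = 0.01)
  ## band width identity for every entry
  expect_equal(mod@global$hi - mod@global$lo, 2 * 1.96 * mod@global$sd,
               tolerance = 1e-12)
})

test_that("the shipped default model carries the reference ratio bands", {
  mod <- defaultNormativeModel()
  vol <- mod@global[mod@global$metric == "lr_vol_ratio_pct", ]
  qt2 <- mod@global[mod@global$metric == "lr_qt2_ratio_pct", ]
  expect_equal(c(vol$lo, vol$hi), c(88.9, 110.6), tolerance = 1e-9)
  expect_equal(c(qt2$lo, qt2$hi), c(93.7, 104.2), tolerance = 1e-9)
  expect_identical(mod@provenance$n, 111L)
  b <- referenceBand(vol)
  expect_equal(unname(b), c(88.9, 110.6), tolerance = 1e-9)
  expect_equal(referenceBand(list(mean = 100, sd = 0)),
               c(lo = 100, hi = 100))
  expect_equal(referenceBand(list(mean = 100, sd = 5)),
               c(lo = 90.2, hi = 109.8))
})

test_that("cohorts below the minimum size are refused", {
  expect_error(buildNormative(drawHealthyMetrics(10)),
               class = "hippoquant_cohort_too_small")
})

test_that("model building is permutation-invariant in cohort order", {
  set.seed(4)
  cohort <- drawHealthyMetrics(30)
  m1 <- buildNormative(cohort)
  m2 <- buildNormative(rev(cohort))
  expect_equal(m1@global, m2@global)
})

test_that("flags reproduce the side-naming and bilateral aggregation rules", {
  set.seed(6)
  mod <- buildNormative(drawHealthyMetrics(200))
  mkM <- function(vL, vR, qL, qR)
    new("GlobalMetrics", volLeft = vL, volRight = vR, qt2Left = qL,
        qt2Right = qR, lrVolRatioPct = 100 * vL / vR,
        lrQt2RatioPct = 100 * qL / qR,
        asymVolRatioPct = 100 * min(vL, vR) / max(vL, vR),
        asymQt2RatioPct = 100 * max(qL, qR) / min(qL, qR))
  ## at cohort means: everything normal
  g <- mod@global
  at <- function(m) g$mean[g$metric == m]
  fl <- flagSubject(mkM(at("vol_left"), at("vol_right"), at("qt2_left"),
                        at("qt2_right")), mod)
  expect_true(all(fl@flags == "normal"))
  expect_identical(fl@overall, "normal")
  ## left atrophy 0.7: ratio low, left named
  fl2 <- flagSubject(mkM(0.7 * at("vol_left"), at("vol_right"),
                         at("qt2_left"), at("qt2_right")), mod)
  expect_identical(unname(fl2@flags["lr_vol_ratio_pct"]), "low")
  expect_identical(fl2@overall, "left_abnormal")
  ## right T2 elevation: qT2 ratio low (left:right), right named
  fl3 <- flagSubject(mkM(at("vol_left"), at("vol_right"), at("qt2_left"),
                         1.10 * at("qt2_right")), mod)
  expect_identical(fl3@overall, "right_abnormal")
  ## bilateral: symmetric atrophy, ratios normal but both volumes low
  fl4 <- flagSubject(mkM(0.8 * at("vol_left"), 0.8 * at("vol_right"),
                         at("qt2_left"), at("qt2_right")), mod)
  expect_identical(unname(fl4@flags["lr_vol_ratio_pct"]), "normal")
  expect_identical(fl4@overall, "bilateral_abnormal")
  ## against the shipped ratio-only model, atrophy 0.7 flags the ratio
  ship <- defaultNormativeModel()
  fl5 <- flagSubject(mkM(0.7 * 2100, 2100, 100, 100), ship)
  expect_identical(fl5@overall, "left_abnormal")
})

test_that("lowering the left volume never turns an abnormal flag normal", {
  set.seed(7)
  mod <- buildNormative(drawHealthyMetrics(150))
  g <- mod@global
  at <- function(m) g$mean[g$metric == m]
  rank <- c(normal = 0, left_abnormal = 1, right_abnormal = 1,
            bilateral_abnormal = 1)
  prev <- 0
  for (f in seq(1, 0.5, by = -0.05)) {
    vL <- f * at("vol_left")
    m <- new("GlobalMetrics", volLeft = vL, volRight = at("vol_right"),
             qt2Left = at("qt2_left"), qt2Right = at("qt2_right"),
             lrVolRatioPct = 100 * vL / at("vol_right"),
             lrQt2RatioPct = 100,
             asymVolRatioPct = 100 * min(vL, at("vol_right")) /
               max(vL, at("vol_right")),
             asymQt2RatioPct = 100)
    cur <- rank[[flagSubject(m, mod)@overall]]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("healthy draws are flagged at the nominal 5 percent rate", {
  ## calibration averaged over replicate reference models: a single n=111
  ## model's band carries SD-estimation noise, so the expectation (not one
  ## realisation) is what must sit at ~5 percent
  set.seed(99)
  rates <- replicate(8, {
    mod <- buildNormative(drawHealthyMetrics(111))
    g <- mod@global
    draws <- drawHealthyMetrics(500)
    outside <- sapply(draws, function(d) {
      v <- hippoquant:::metricValues(d$metrics)
      v[g$metric] < g$lo | v[g$metric] > g$hi
    })
    rowMeans(outside)
  })
  expect_true(all(rowMeans(rates) > 0.03 & rowMeans(rates) < 0.07))
})

test_that("normative models round-trip through JSON", {
  tmp <- withr::local_tempdir()
  set.seed(12)
  mod <- buildNormative(drawHealthyMetrics(40), seed = 12)
  p <- file.path(tmp, "model.json")
  writeNormativeModel(mod, p)
  mod2 <- readNormativeModel(p)
  expect_equal(mod2@global$mean, mod@global$mean)
  expect_equal(mod2@global$sd, mod@global$sd)
  expect_identical(mod2@provenance$n, mod@provenance$n)
})
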