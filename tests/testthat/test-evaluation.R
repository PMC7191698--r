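test_that("confusion counts tabulate the standard 2x2", {
  expect_equal(confusionCounts(c(1, 1), c(1, 1)),
               c(tp = 2L, fp = 0L, tn = 0L, fn = 0L))
  expect_equal(confusionCounts(c(1, 0, 1, 0), c(1, 1, 0, 0)),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_error(confusionCounts(numeric(), numeric()), "empty")
  expect_error(confusionCounts(c(1, 0), c(1, NA)), "missing")
  # conservation: the four cells sum to the number of drugs evaluated
  set.seed(8)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    cc <- confusionCounts(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    expect_equal(sum(cc), n)
  }
})

test_that("metrics are integer percents with an undefined marker", {
  m <- classificationMetrics(c(tp = 1, fn = 1, fp = 1, tn = 1))
  expect_equal(unname(m), c(50, 50, 50, 50))
  expect_equal(unname(classificationMetrics(c(tp = 2, fn = 0, fp = 0, tn = 8))),
               c(100, 100, 100, 100))
  m2 <- classificationMetrics(c(tp = 0, fn = 2, fp = 0, tn = 3))
  expect_true(is.na(m2["ppv"]))                  # tp + fp == 0
  expect_equal(unname(m2["sensitivity"]), 0)
  # rounding is half away from zero: 1/3 -> 33, 2/3 -> 67
  m3 <- classificationMetrics(c(tp = 1, fn = 2, fp = 1, tn = 2))
  expect_equal(unname(m3["sensitivity"]), 33)
  expect_equal(unname(m3["specificity"]), 67)
})

test_that("distribution summaries use smallest-mode ties and nearest rank", {
  s <- summarizeSamples(c(100, 100, 50))
  expect_equal(s$mode, 100); expect_equal(s$median, 100)
  expect_equal(summarizeSamples(c(0, 100))$mode, 0)     # tie -> smallest
  s2 <- summarizeSamples(c(0, 25, 50, 75, 100))
  expect_equal(c(s2$q25, s2$median, s2$q75), c(25, 50, 75))
  s3 <- summarizeSamples(c(NA, 40, NA, 40, 60))
  expect_equal(s3$n_undefined, 2); expect_equal(s3$mode, 40)
  s4 <- summarizeSamples(c(NA_real_, NA_real_))
  expect_true(is.na(s4$mode)); expect_equal(s4$n_undefined, 2)
})

test_that("predictability requires a PPV mode strictly above 75", {
  expect_equal(classifyPredictability(100), "well_predicted")
  expect_equal(classifyPredictability(76), "well_predicted")
  expect_equal(classifyPredictability(75), "poorly_predicted")
  expect_equal(classifyPredictability(0), "poorly_predicted")
  expect_warning(out <- classifyPredictability(NA_real_), "undefined")
  expect_equal(out, "poorly_predicted")
  expect_equal(classifyPredictability(summarizeSamples(c(100, 100, 50))),
               "well_predicted")
})

test_that("bootstrap evaluation is deterministic under a fixed seed", {
  sim <- generateDataset(smallConfig(seed = 21))
  b1 <- bootstrapEvaluate(sim$dataset, iterations = 25, trainSize = 6,
                          testSize = 2, thresholds = c(0, 70), seed = 5)
  b2 <- bootstrapEvaluate(sim$dataset, iterations = 25, trainSize = 6,
                          testSize = 2, thresholds = c(0, 70), seed = 5)
  expect_identical(b1@samples, b2@samples)
  expect_identical(metricsSummary(b1), metricsSummary(b2))
  b3 <- bootstrapEvaluate(sim$dataset, iterations = 25, trainSize = 6,
                          testSize = 2, thresholds = c(0, 70), seed = 6)
  expect_false(identical(b1@samples, b3@samples))
})

test_that("bootstrap respects its configuration contract", {
  sim <- generateDataset(smallConfig(seed = 22))
  expect_error(bootstrapEvaluate(sim$dataset, iterations = 5, trainSize = 5,
                                 testSize = 2, thresholds = 70, seed = 1),
               "must equal")
  b <- bootstrapEvaluate(sim$dataset, iterations = 1, trainSize = 6,
                         testSize = 2, thresholds = 70, seed = 1)
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    smp <- b@samples[["70"]][[m]]
    expect_equal(nrow(smp), 1)                      # one iteration, <= 1 sample
    ok <- smp[!is.na(smp)]
    expect_true(all(ok >= 0 & ok <= 100 & ok == round(ok)))
  }
})

test_that("no event is called well-predicted when labels are coin flips", {
  # null calibration: prevalence 0.3, no planted structure
  sim <- generateDataset(smallConfig(seed = 31, nTestDrugs = 12, nPlanted = 0,
                                     pEventBaseline = 0.3))
  b <- bootstrapEvaluate(sim$dataset, iterations = 200, trainSize = 9,
                         testSize = 3, thresholds = 70, seed = 31)
  frac <- length(wellPredictedEvents(b, 70)) / length(b@aeGroups)
  expect_lt(frac, 0.2)
})

test_that("SLC percentages follow the two evaluation formulas", {
  # 10 combos: 4 changed (approval 0 -> reference 1), 2 of them predicted;
  # 6 negative-at-approval combos predicted positive overall
  atApproval <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1), 2, 5)
  reference  <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1), 2, 5)
  predicted  <- matrix(c(1, 1, 0, 0, 1, 1, 1, 1, 0, 0), 2, 5)
  res <- slcPercentages(atApproval, reference, predicted)
  expect_equal(res$n_changed, 4)
  expect_equal(res$n_changed_predicted, 2)
  expect_equal(res$n_negative_predicted, 6)
  expect_equal(res$pct_issued_predicted, 50)
  expect_equal(round(res$pct_predicted_issued), 33)

  none <- slcPercentages(atApproval, reference, matrix(0, 2, 5))
  expect_equal(none$pct_issued_predicted, 0)
  expect_true(is.na(none$pct_predicted_issued))    # empty denominator

  all_pred <- slcPercentages(atApproval, reference, reference)
  expect_equal(all_pred$pct_issued_predicted, 100)
})

test_that("leave-one-out SLC recovers deleted labels on strong signal", {
  cfg <- syntheticConfig(nTestDrugs = 14, comparatorsPerTest = c(2, 4),
                         nTargets = 8, nAeGroups = 16, nPlanted = 8,
                         pEventGivenTarget = 1, pEventBaseline = 0,
                         literatureFlipRate = 0, slcDeletionRate = 0.5,
                         seed = 17)
  sim <- generateDataset(cfg)
  res <- looSLC(sim$dataset, threshold = 50)
  expect_gte(res$pct_issued_predicted, 50)
  expect_equal(res$n_changed,
               sum(labelMatrix(sim$dataset, "test_at_approval")
                   [, eligibleAdverseEvents(sim$dataset)] == 0 &
                   labelMatrix(sim$dataset, "test_reference")
                   [, eligibleAdverseEvents(sim$dataset)] == 1))
})

test_that("the threshold sweep reports one row per threshold", {
  sim <- generateDataset(smallConfig(seed = 41))
  thr <- c(0, 10, 30, 50, 60, 70, 90)
  sw <- thresholdSweep(sim$dataset, iterations = 20, trainSize = 6,
                       testSize = 2, thresholds = thr, seed = 2)
  expect_equal(nrow(sw), 7)
  expect_equal(sw$threshold, thr)
  expect_true(all(sw$n_well_predicted >= 0))
  ok <- !is.na(sw$pct_issued_predicted)
  expect_true(all(sw$pct_issued_predicted[ok] >= 0 &
                    sw$pct_issued_predicted[ok] <= 100))
})
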