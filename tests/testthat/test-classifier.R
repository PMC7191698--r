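test_that("the prior is the class-1 training fraction", {
  m <- rbind(c(1, 1, 1), c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  model <- fitNaiveBayes(asFeatureRows(m))
  expect_equal(model@prior, 0.25)
})

test_that("single-class training falls back to prior-only prediction", {
  m0 <- rbind(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_warning(model <- fitNaiveBayes(asFeatureRows(m0)), "single|only class")
  p <- predictPairs(model, asFeatureRows(m0))
  expect_equal(p$posterior, rep(0, 3))   # prior 0 annihilates everything
  expect_equal(p$call, rep(0, 3))
  m1 <- rbind(c(1, 1, 1), c(0, 0, 1))
  expect_warning(model1 <- fitNaiveBayes(asFeatureRows(m1)), "single|only class")
  expect_equal(predictPairs(model1, asFeatureRows(m1))$posterior, c(1, 1))
})

test_that("a perfectly separating binary feature drives the posterior", {
  m <- rbind(c(1, 1, 1), c(1, 0, 1), c(0, 1, 0), c(0, 0, 0))
  model <- fitNaiveBayes(asFeatureRows(m))
  p <- predictPairs(model, asFeatureRows(rbind(c(1, 0, NA), c(0, 0, NA))))
  expect_gt(p$posterior[1], 0.99)
  expect_lt(p$posterior[2], 0.01)
})

test_that("symmetric evidence leaves the posterior at the prior; ties call negative", {
  m <- rbind(c(1, 1, 1), c(0, 0, 1), c(1, 1, 0), c(0, 0, 0))
  model <- fitNaiveBayes(asFeatureRows(m))
  p <- predictPairs(model, asFeatureRows(m))
  expect_equal(p$posterior, rep(0.5, 4), tolerance = 1e-12)
  expect_equal(p$call, rep(0, 4))        # exact tie predicts negative
})

test_that("posteriors match the exhaustive oracle on toy tables", {
  rowSpace <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:4, 1)
    m <- rowSpace[sample(nrow(rowSpace), n, replace = TRUE), , drop = FALSE]
    rows <- asFeatureRows(m)
    model <- suppressWarnings(fitNaiveBayes(rows))
    got <- predictPairs(model, rows)$posterior
    want <- nbOracleBinary(rows, rows)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("posteriors agree with the e1071 reference implementation", {
  # mixed categorical/Gaussian data in a benign regime: no zero cells, class
  # sds well above the pooled floor, densities above the guard
  set.seed(123)
  n <- 60
  lab <- rep(c(0, 1), each = n / 2)
  df <- data.frame(
    f_label = rbinom(n, 1, ifelse(lab == 1, 0.7, 0.3)),
    f_literature = rbinom(n, 1, ifelse(lab == 1, 0.6, 0.4)),
    f_structure = rnorm(n, ifelse(lab == 1, 0.6, 0.4), 0.3),
    f_target = rnorm(n, 0.5, 0.3),
    f_market_years = rnorm(n, ifelse(lab == 1, 20, 15), 8),
    label = lab)
  rows <- cbind(test_id = paste0("T", 1:n), comparator_id = paste0("C", 1:n),
                ae_group = "AE_TOY", df)
  # zeroGuard lowered so the density guard never binds: the reference
  # implementation only replaces exact-zero likelihoods
  model <- fitNaiveBayes(rows, zeroGuard = 1e-30)
  got <- predictPairs(model, rows)$posterior

  eds <- data.frame(f_label = factor(df$f_label),
                    f_literature = factor(df$f_literature),
                    f_structure = df$f_structure, f_target = df$f_target,
                    f_market_years = df$f_market_years)
  efit <- e1071::naiveBayes(eds, factor(df$label))
  want <- predict(efit, eds, type = "raw")[, "1"]
  expect_equal(got, unname(want), tolerance = 1e-6)
})

test_that("vote aggregation uses a strict threshold", {
  preds <- data.frame(test_id = rep("T1", 3), call = c(1, 1, 0))
  expect_equal(aggregateVotes(preds, 70)$call, 0)   # 66.7 < 70
  expect_equal(aggregateVotes(preds, 60)$call, 1)   # 66.7 > 60
  zero <- data.frame(test_id = rep("T1", 5), call = rep(0, 5))
  expect_equal(aggregateVotes(zero, 0)$call, 0)     # 0 is not > 0
  one <- data.frame(test_id = rep("T1", 5), call = c(1, 0, 0, 0, 0))
  expect_equal(aggregateVotes(one, 0)$call, 1)      # 20 > 0
  expect_error(aggregateVotes(preds[0, ], 50), "empty")
  # monotonicity: raising the threshold never turns a 0 into a 1
  set.seed(2)
  for (i in 1:20) {
    p <- data.frame(test_id = rep(paste0("T", 1:4), each = 5),
                    call = rbinom(20, 1, 0.5))
    prev <- NULL
    for (t in c(0, 10, 30, 50, 60, 70, 90)) {
      cur <- aggregateVotes(p, t)
      cur <- cur$test_id[cur$call == 1]
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("models serialize to YAML and back without loss", {
  m <- rbind(c(1, 1, 1), c(1, 0, 1), c(0, 1, 0), c(0, 0, 0))
  rows <- asFeatureRows(m)
  model <- fitNaiveBayes(rows, laplace = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeNaiveBayesModel(model, path)
  back <- readNaiveBayesModel(path)
  expect_equal(back@prior, model@prior)
  expect_equal(back@catTables, model@catTables)
  expect_equal(back@gaussParams, model@gaussParams, tolerance = 1e-12)
  expect_equal(predictPairs(back, rows)$posterior,
               predictPairs(model, rows)$posterior, tolerance = 1e-12)
})
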