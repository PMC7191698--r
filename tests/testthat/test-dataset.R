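test_that("a well-formed dataset validates and exposes its parts", {
  ds <- tinyDataset()
  expect_s4_class(ds, "AEDataset")
  expect_equal(nrow(drugs(ds)), 3)
  expect_equal(testDrugs(ds), "T1")
  expect_equal(comparatorDrugs(ds), c("C1", "C2"))
  expect_equal(nrow(drugPairs(ds)), 2)
})

test_that("referential integrity violations name the offending drug", {
  ds <- tinyDataset()
  lab <- ds@labels
  rownames(lab$comparator_at_test_approval)[1] <- "X"
  expect_error(
    AEDataset(drugs = drugs(ds), targetActions = targetActions(ds),
              vocabulary = vocabulary(ds), labels = lab,
              literature = literatureEvidence(ds), pairs = drugPairs(ds),
              fingerprints = fingerprints(ds)),
    "X")
})

test_that("write then read round-trips a dataset identically", {
  sim <- generateDataset(smallConfig(seed = 11))
  dir <- withr::local_tempdir()
  writeAEDataset(sim$dataset, dir)
  ds2 <- readAEDataset(dir)
  expect_equal(drugs(ds2), drugs(sim$dataset))
  expect_equal(targetActions(ds2), targetActions(sim$dataset))
  for (s in c("comparator_at_test_approval", "test_at_approval", "test_reference"))
    expect_equal(labelMatrix(ds2, s), labelMatrix(sim$dataset, s))
  expect_equal(drugPairs(ds2), drugPairs(sim$dataset))
  expect_equal(fingerprints(ds2)[, 1:166],
               unname(fingerprints(sim$dataset)[, 1:166]),
               ignore_attr = TRUE)
  lit1 <- literatureEvidence(sim$dataset); lit2 <- literatureEvidence(ds2)
  key <- function(x) sort(paste(x$comparator_id, x$test_id, x$ae_group, x$present))
  expect_equal(key(lit2), key(lit1))
})

test_that("per-comparator literature is broadcast over pairs with a warning", {
  ds <- tinyDataset()
  lit <- data.frame(comparator_id = "C1", ae_group = "NAUSEA", present = 1)
  expect_warning(
    ds2 <- AEDataset(drugs = drugs(ds), targetActions = targetActions(ds),
                     vocabulary = vocabulary(ds), labels = ds@labels,
                     literature = lit, pairs = drugPairs(ds),
                     fingerprints = fingerprints(ds)),
    "broadcast")
  expect_equal(literatureEvidence(ds2)$test_id, "T1")
})

test_that("comparator selection requires an identical-sign shared action", {
  ta <- data.frame(drug_id = c("A", "B", "C", "D", "E"),
                   target_id = c("T1", "T1", "T1", "T2", "T9"),
                   action = c(1L, 1L, -1L, 1L, 1L))
  # same action at the same target: selected
  expect_equal(selectComparators("A", ta), "B")
  # antagonist at the same target: sign mismatch, not selected
  expect_false("C" %in% selectComparators("A", ta))
  # agonist at a different target only: not selected
  expect_false("D" %in% selectComparators("A", ta))
  expect_error(selectComparators("Z", ta), "no target actions")
})

test_that("comparator matching is symmetric", {
  sim <- generateDataset(smallConfig(seed = 5))
  ta <- targetActions(sim$dataset)
  ids <- unique(ta$drug_id)
  for (a in ids[1:6]) {
    for (b in setdiff(ids[1:6], a)) {
      expect_equal(b %in% selectComparators(a, ta),
                   a %in% selectComparators(b, ta))
    }
  }
})

test_that("time on market follows day counts with the 36-year imputation", {
  ds <- tinyDataset()
  tom <- timeOnMarket(ds, "2017-01-01")
  expect_equal(unname(tom["C2"]), 36)            # pre-1982 flag
  expect_equal(unname(tom["T1"]),
               as.numeric(as.Date("2017-01-01") - as.Date("2010-01-01")) / 365.25)
  expect_equal(unname(timeOnMarket(ds, "2010-01-01", ids = "T1")), 0)
  expect_error(timeOnMarket(ds, "2005-01-01", ids = "T1"), "earlier")
})

test_that("adverse-event eligibility needs at least two positive test labels", {
  labels <- matrix(c(0, 0,   # never observed -> excluded
                     1, 0,   # observed once -> excluded
                     1, 1),  # observed twice -> included
                   2, 3, dimnames = list(c("T1", "T2"), c("g0", "g1", "g2")))
  expect_equal(eligibleAdverseEvents(labels, c("T1", "T2")), "g2")
  expect_error(eligibleAdverseEvents(labels, character()), "empty")

  # monotonicity: adding a positive label never removes a group
  for (i in 1:20) {
    m <- matrix(rbinom(24, 1, 0.3), 4, 6,
                dimnames = list(paste0("T", 1:4), paste0("g", 1:6)))
    before <- eligibleAdverseEvents(m, rownames(m))
    j <- sample(length(m), 1)
    m[j] <- 1
    expect_true(all(before %in% eligibleAdverseEvents(m, rownames(m))))
  }
})

test_that("prevalence is the positive fraction over the drug set", {
  m <- matrix(c(1, 0, 0, 0,
                1, 1, 1, 1,
                0, 0, 0, 0), 4, 3,
              dimnames = list(paste0("d", 1:4), c("a", "b", "c")))
  p <- aePrevalence(m, rownames(m))
  expect_equal(unname(p), c(0.25, 1, 0))
  expect_error(aePrevalence(m, character()), "non-empty")
})
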