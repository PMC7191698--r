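# Bootstrap performance-distribution evaluation, metric summaries,
# predictability classification, threshold sweep, and leave-one-out
# safety-label-change (SLC) evaluation.

.METRICS <- c("sensitivity", "specificity", "ppv", "npv")

#' 2x2 confusion counts for drug-level predictions
#'
#' @param calls 0/1 (or logical) drug-level predictions.
#' @param truth 0/1 reference labels, same length, no missing values.
#' @return named integer vector (tp, fp, tn, fn).
#' @export
confusionCounts <- function(calls, truth) {
  if (!length(calls)) .stopUser("empty prediction set")
  if (length(calls) != length(truth)) .stopUser("calls and truth differ in length")
  if (anyNA(truth)) .stopUser("missing truth value(s)")
  calls <- as.logical(calls); truth <- as.logical(truth)
  c(tp = sum(calls & truth), fp = sum(calls & !truth),
    tn = sum(!calls & !truth), fn = sum(!calls & truth))
}

#' Sensitivity, specificity, PPV and NPV as integer percents
#'
#' Each metric is computed from the 2x2 counts, multiplied by 100 and rounded
#' half-up to an integer, so that bootstrap distributions live on a discrete
#' support where the mode is well-defined. A metric whose denominator is zero
#' is undefined and returned as NA.
#'
#' @param counts named vector with tp, fp, tn, fn (see [confusionCounts()]).
#' @return named numeric vector (sensitivity, specificity, ppv, npv), NA
#'   where undefined.
#' @export
classificationMetrics <- function(counts) {
  f <- function(num, den) if (den == 0) NA_real_ else .roundHalfUp(100 * num / den)
  with(as.list(counts),
       c(sensitivity = f(tp, tp + fn), specificity = f(tn, tn + fp),
         ppv = f(tp, tp + fp), npv = f(tn, tn + fn)))
}

#' Summarize a bootstrap metric distribution
#'
#' The mode is the most frequent value, with ties broken toward the smallest
#' value (conservative: a borderline event is not over-claimed as
#' well-predicted). The median and the 25th/75th quantiles use the
#' nearest-rank rule on the sorted samples. NA entries (iterations on which
#' the metric was undefined) are excluded from the samples and counted.
#'
#' @param samples integer-percent values, NA where undefined.
#' @return list with mode, median, q25, q75, n, n_undefined (all NA summary
#'   values if every sample is undefined).
#' @examples
#' summarizeSamples(c(0, 100))  # tied mode -> 0
#' @export
summarizeSamples <- function(samples) {
  n_undef <- sum(is.na(samples))
  x <- samples[!is.na(samples)]
  if (!length(x))
    return(list(mode = NA_real_, median = NA_real_, q25 = NA_real_,
                q75 = NA_real_, n = 0L, n_undefined = n_undef))
  tb <- table(x)
  mode <- min(as.numeric(names(tb)[tb == max(tb)]))
  s <- sort(x); n <- length(s)
  nr <- function(p) s[max(1L, ceiling(p * n))]
  list(mode = mode, median = nr(0.5), q25 = nr(0.25), q75 = nr(0.75),
       n = n, n_undefined = n_undef)
}

#' Classify an adverse event as well- or poorly-predicted
#'
#' An event is well-predicted when its bootstrap PPV distribution is
#' left-skewed, operationalized as a mode strictly greater than 75 percent.
#' An undefined mode (no iteration produced a defined PPV) is classified as
#' poorly predicted, with a warning.
#'
#' @param ppv a summary from [summarizeSamples()], or a numeric mode.
#' @return "well_predicted" or "poorly_predicted".
#' @export
classifyPredictability <- function(ppv) {
  mode <- if (is.list(ppv)) ppv$mode else ppv
  if (is.na(mode)) {
    warning("undefined PPV mode; classifying as poorly_predicted")
    return("poorly_predicted")
  }
  if (mode > 75) "well_predicted" else "poorly_predicted"
}

# ---- shared matrix frame ----------------------------------------------------
# Everything the evaluators need, precomputed once per dataset:
#   tests      sorted test drug ids
#   pairTest   index of each pair's test drug in `tests`
#   cat        list of P x E binary feature matrices (f_label, f_literature)
#   num        list of length-P numeric pair features
#   Y, Yappr   tests x E reference / at-approval label matrices
.modelFrame <- function(dataset, aeGroups = NULL, referenceDate = "2017-01-01",
                        backend = NULL, needApproval = FALSE) {
  if (is.null(aeGroups)) aeGroups <- eligibleAdverseEvents(dataset)
  aeGroups <- as.character(aeGroups)
  pr <- dataset@pairs
  tests <- testDrugs(dataset)
  pf <- .pairFeatures(dataset, referenceDate, backend = backend)
  compLab <- .snapshotFor(dataset, "comparator_at_test_approval",
                          unique(pr$comparator_id), aeGroups)
  B_label <- compLab[match(pr$comparator_id, rownames(compLab)), , drop = FALSE]
  B_lit <- .literatureMatrix(dataset, aeGroups)
  Y <- .snapshotFor(dataset, "test_reference", tests, aeGroups)
  Yappr <- if (needApproval)
    .snapshotFor(dataset, "test_at_approval", tests, aeGroups) else NULL
  list(aeGroups = aeGroups, tests = tests, pairs = pr,
       pairTest = match(pr$test_id, tests),
       cat = list(f_label = unname(B_label), f_literature = B_lit),
       num = list(f_structure = pf$f_structure, f_target = pf$f_target,
                  f_market_years = pf$f_market_years),
       Y = Y, Yappr = Yappr)
}

# subset the frame's features to a set of pairs, in engine form
.frameFeatures <- function(frame, pairIdx, binaryMode) {
  cat <- lapply(frame$cat, function(B) B[pairIdx, , drop = FALSE])
  num <- lapply(frame$num, function(x) x[pairIdx])
  if (binaryMode == "categorical") list(cat = cat, num = num)
  else list(cat = list(), num = c(cat, num))
}

# fit on training pairs, return held-out drug-level positive vote fractions
# (length(drugIdx) x E) for the drugs indexed by `drugIdx` into frame$tests
.voteFractions <- function(frame, trainDrugIdx, drugIdx, laplace, varFloor,
                           zeroGuard, binaryMode) {
  trPairs <- which(frame$pairTest %in% trainDrugIdx)
  tePairs <- which(frame$pairTest %in% drugIdx)
  Ytr <- frame$Y[frame$pairTest[trPairs], , drop = FALSE]
  ftr <- .frameFeatures(frame, trPairs, binaryMode)
  fit <- .nbFitMat(ftr$cat, ftr$num, Ytr, laplace = laplace, varFloor = varFloor)
  fte <- .frameFeatures(frame, tePairs, binaryMode)
  votes <- .nbPredictMat(fit, fte$cat, fte$num, zeroGuard = zeroGuard) > 0.5
  grp <- factor(frame$pairTest[tePairs], levels = drugIdx)
  counts <- as.integer(table(grp))
  rowsum(votes + 0, grp) / counts
}

#' Bootstrap performance-distribution evaluation
#'
#' Repeatedly partitions the test drugs into a random training set of
#' \code{trainSize} and a held-out set of \code{testSize} drugs (drawn
#' without replacement, independently per iteration), fits one Naive Bayes
#' model per adverse event on the training drugs' comparator rows, predicts
#' the held-out drugs, aggregates comparator votes at each threshold, and
#' tabulates sensitivity, specificity, PPV and NPV over the held-out drugs.
#' Because the comparator votes do not depend on the threshold, votes are
#' computed once per iteration and the confusion counts for every threshold
#' are derived from the stored vote fractions.
#'
#' @param dataset an [AEDataset-class].
#' @param iterations number of bootstrap iterations.
#' @param trainSize,testSize partition sizes; must sum to the number of test
#'   drugs.
#' @param thresholds vote thresholds (percent) to evaluate.
#' @param seed integer seed; the evaluation is a pure function of
#'   (dataset, configuration, seed).
#' @param aeGroups groups to evaluate (default: the eligible ones).
#' @param referenceDate reference date for comparator market duration.
#' @param laplace,varFloor,zeroGuard,binaryMode classifier settings, see
#'   [fitNaiveBayes()].
#' @param backend optional fingerprint backend.
#' @return a [BootstrapResult-class].
#' @export
bootstrapEvaluate <- function(dataset, iterations = 10000, trainSize = 44,
                              testSize = 10,
                              thresholds = c(0, 10, 30, 50, 60, 70, 90),
                              seed = 1, aeGroups = NULL,
                              referenceDate = "2017-01-01", laplace = 0,
                              varFloor = 1e-9, zeroGuard = 1e-3,
                              binaryMode = c("categorical", "gaussian"),
                              backend = NULL) {
  binaryMode <- match.arg(binaryMode)
  iterations <- .checkCount(iterations, "iterations")
  trainSize <- .checkCount(trainSize, "trainSize")
  testSize <- .checkCount(testSize, "testSize")
  frame <- .modelFrame(dataset, aeGroups, referenceDate, backend)
  nT <- length(frame$tests)
  if (trainSize + testSize != nT)
    .stopUser("trainSize + testSize (%d) must equal the number of test drugs (%d)",
              trainSize + testSize, nT)
  E <- length(frame$aeGroups)
  thrKey <- as.character(thresholds)
  samples <- lapply(thrKey, function(t)
    lapply(stats::setNames(.METRICS, .METRICS), function(m)
      matrix(NA_real_, iterations, E, dimnames = list(NULL, frame$aeGroups))))
  names(samples) <- thrKey

  set.seed(as.integer(seed))
  for (it in seq_len(iterations)) {
    heldIdx <- sort(sample.int(nT, testSize))
    trainIdx <- setdiff(seq_len(nT), heldIdx)
    frac <- .voteFractions(frame, trainIdx, heldIdx, laplace, varFloor,
                           zeroGuard, binaryMode)
    truth <- frame$Y[heldIdx, , drop = FALSE] == 1
    for (k in seq_along(thresholds)) {
      calls <- 100 * frac > thresholds[k]
      tp <- colSums(calls & truth); fp <- colSums(calls & !truth)
      fn <- colSums(!calls & truth); tn <- colSums(!calls & !truth)
      met <- list(
        sensitivity = ifelse(tp + fn == 0, NA, .roundHalfUp(100 * tp / (tp + fn))),
        specificity = ifelse(tn + fp == 0, NA, .roundHalfUp(100 * tn / (tn + fp))),
        ppv = ifelse(tp + fp == 0, NA, .roundHalfUp(100 * tp / (tp + fp))),
        npv = ifelse(tn + fn == 0, NA, .roundHalfUp(100 * tn / (tn + fn))))
      for (m in .METRICS) samples[[k]][[m]][it, ] <- met[[m]]
    }
  }

  summary <- do.call(rbind, lapply(thrKey, function(t) {
    do.call(rbind, lapply(frame$aeGroups, function(g) {
      sums <- lapply(.METRICS, function(m) summarizeSamples(samples[[t]][[m]][, g]))
      names(sums) <- .METRICS
      pred <- suppressWarnings(classifyPredictability(sums$ppv))
      do.call(rbind, lapply(.METRICS, function(m) {
        s <- sums[[m]]
        data.frame(threshold = as.numeric(t), ae_group = g, metric = m,
                   mode = s$mode, median = s$median, q25 = s$q25, q75 = s$q75,
                   n_undefined = s$n_undefined, predictability = pred,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(summary) <- NULL
  new("BootstrapResult", aeGroups = frame$aeGroups,
      thresholds = as.numeric(thresholds), iterations = iterations,
      trainSize = trainSize, testSize = testSize, seed = as.integer(seed),
      samples = samples, summary = summary)
}

#' @describeIn BootstrapResult-class the per-threshold/event/metric summary
#'   table.
#' @param x a \code{BootstrapResult}.
#' @export
metricsSummary <- function(x) x@summary

#' @describeIn BootstrapResult-class events classified well-predicted at a
#'   threshold.
#' @param threshold one of the evaluated thresholds.
#' @export
wellPredictedEvents <- function(x, threshold) {
  s <- x@summary
  sub <- s[s$threshold == threshold & s$metric == "ppv" &
             s$predictability == "well_predicted", ]
  sort(unique(sub$ae_group))
}

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %d iterations (train %d / held out %d), %d events\n",
              object@iterations, object@trainSize, object@testSize,
              length(object@aeGroups)))
  for (t in object@thresholds)
    cat(sprintf("  threshold %3g%%: %d well-predicted event(s)\n", t,
                length(wellPredictedEvents(object, t))))
})

# ---- leave-one-out safety-label-change evaluation ---------------------------

#' Safety-label-change percentages from prediction matrices
#'
#' A (drug, event) combination is an FDA-issued safety label change when the
#' event was absent from the drug's label at approval but present on the
#' reference-date label. Given the two label snapshots and the model's
#' positive predictions, the two evaluation percentages are
#' \itemize{
#'   \item percent of issued safety label changes that were predicted:
#'     100 x |changed and predicted| / |changed|;
#'   \item percent of predicted safety label changes that were also issued:
#'     100 x |changed and predicted| / |negative at approval and predicted|.
#' }
#' A zero denominator yields NA for that percentage.
#'
#' @param atApproval,reference 0/1 drug-by-event label matrices at approval
#'   and at the reference date.
#' @param predicted 0/1 (or logical) matrix of positive predictions, same
#'   shape.
#' @return list with pct_issued_predicted, pct_predicted_issued and the
#'   underlying counts (n_changed_predicted, n_changed,
#'   n_negative_predicted).
#' @export
slcPercentages <- function(atApproval, reference, predicted) {
  stopifnot(all(dim(atApproval) == dim(reference)),
            all(dim(atApproval) == dim(predicted)))
  changed <- atApproval == 0 & reference == 1
  pos <- predicted == 1 | predicted == TRUE
  a <- sum(changed & pos)
  b <- sum(changed)
  d <- sum(atApproval == 0 & pos)
  list(pct_issued_predicted = if (b == 0) NA_real_ else 100 * a / b,
       pct_predicted_issued = if (d == 0) NA_real_ else 100 * a / d,
       n_changed_predicted = a, n_changed = b, n_negative_predicted = d)
}

# leave-one-out drug-level vote fractions (tests x E): each test drug is
# predicted by models trained on all other test drugs
.looFractions <- function(frame, laplace, varFloor, zeroGuard, binaryMode) {
  nT <- length(frame$tests); E <- length(frame$aeGroups)
  frac <- matrix(NA_real_, nT, E, dimnames = list(frame$tests, frame$aeGroups))
  for (i in seq_len(nT))
    frac[i, ] <- .voteFractions(frame, setdiff(seq_len(nT), i), i,
                                laplace, varFloor, zeroGuard, binaryMode)
  frac
}

#' Leave-one-out evaluation of safety-label-change prediction
#'
#' For each test drug in turn, per-event models are trained on all other test
#' drugs and the held-out drug's events are predicted at the given vote
#' threshold. Predictions are pooled over all (drug, event) combinations and
#' scored against the label changes between the at-approval and
#' reference-date snapshots with [slcPercentages()].
#'
#' @inheritParams bootstrapEvaluate
#' @param threshold vote threshold (percent).
#' @return list as from [slcPercentages()], plus \code{threshold}.
#' @export
looSLC <- function(dataset, threshold = 70, aeGroups = NULL,
                   referenceDate = "2017-01-01", laplace = 0, varFloor = 1e-9,
                   zeroGuard = 1e-3, binaryMode = c("categorical", "gaussian"),
                   backend = NULL) {
  binaryMode <- match.arg(binaryMode)
  threshold <- .checkNumber(threshold, "threshold", 0, 100)
  frame <- .modelFrame(dataset, aeGroups, referenceDate, backend,
                       needApproval = TRUE)
  frac <- .looFractions(frame, laplace, varFloor, zeroGuard, binaryMode)
  res <- slcPercentages(frame$Yappr, frame$Y, 100 * frac > threshold)
  c(list(threshold = threshold), res)
}

#' Threshold sweep: SLC percentages and well-predicted counts
#'
#' Evaluates the vote-threshold ladder: for each threshold, the two
#' leave-one-out safety-label-change percentages and the number of
#' adverse events whose bootstrap PPV mode exceeds 75 percent. The
#' leave-one-out vote fractions and the bootstrap votes are computed once and
#' re-aggregated per threshold.
#'
#' @inheritParams bootstrapEvaluate
#' @param bootstrap optionally, a precomputed [BootstrapResult-class]
#'   covering \code{thresholds} (avoids refitting when one is already at
#'   hand).
#' @return data.frame with one row per threshold: threshold,
#'   pct_issued_predicted, pct_predicted_issued, n_well_predicted.
#' @export
thresholdSweep <- function(dataset, iterations = 10000, trainSize = 44,
                           testSize = 10,
                           thresholds = c(0, 10, 30, 50, 60, 70, 90),
                           seed = 1, aeGroups = NULL,
                           referenceDate = "2017-01-01", laplace = 0,
                           varFloor = 1e-9, zeroGuard = 1e-3,
                           binaryMode = c("categorical", "gaussian"),
                           backend = NULL, bootstrap = NULL) {
  binaryMode <- match.arg(binaryMode)
  if (is.null(bootstrap))
    bootstrap <- bootstrapEvaluate(dataset, iterations = iterations,
                                   trainSize = trainSize, testSize = testSize,
                                   thresholds = thresholds, seed = seed,
                                   aeGroups = aeGroups,
                                   referenceDate = referenceDate,
                                   laplace = laplace, varFloor = varFloor,
                                   zeroGuard = zeroGuard,
                                   binaryMode = binaryMode, backend = backend)
  miss <- setdiff(thresholds, bootstrap@thresholds)
  if (length(miss))
    .stopUser("bootstrap result lacks threshold(s): %s", paste(miss, collapse = ", "))
  frame <- .modelFrame(dataset, aeGroups, referenceDate, backend,
                       needApproval = TRUE)
  frac <- .looFractions(frame, laplace, varFloor, zeroGuard, binaryMode)
  do.call(rbind, lapply(thresholds, function(t) {
    slc <- slcPercentages(frame$Yappr, frame$Y, 100 * frac > t)
    data.frame(threshold = t,
               pct_issued_predicted = slc$pct_issued_predicted,
               pct_predicted_issued = slc$pct_predicted_issued,
               n_well_predicted = length(wellPredictedEvents(bootstrap, t)))
  }))
}
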