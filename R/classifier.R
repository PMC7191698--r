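# Per-adverse-event Naive Bayes: fit, pair-level prediction, vote aggregation.
#
# The heavy lifting lives in a vectorized engine that fits/predicts all
# adverse events of a dataset simultaneously with matrix arithmetic (used by
# the bootstrap and leave-one-out evaluators); the exported single-event
# functions wrap the same engine with E = 1.

# ---- engine -----------------------------------------------------------------
# catFeats: named list of n x E 0/1 matrices (binary features, categorical)
# numFeats: named list of numeric features, each a length-n vector
#           (pair-level) or an n x E matrix
# Y: n x E 0/1 training labels
.nbFitMat <- function(catFeats, numFeats, Y, laplace = 0, varFloor = 1e-9) {
  n <- nrow(Y); E <- ncol(Y)
  n1 <- colSums(Y); n0 <- n - n1
  singleClass <- integer(E)
  singleClass[n1 == 0] <- -1L
  singleClass[n0 == 0] <- 1L
  cat_p <- lapply(catFeats, function(B) {
    list(p1 = (colSums(B * Y) + laplace) / (n1 + 2 * laplace),
         p0 = (colSums(B * (1 - Y)) + laplace) / (n0 + 2 * laplace))
  })
  gpar <- lapply(numFeats, function(x) {
    # class-conditional sds are floored at a tenth of the feature's pooled
    # sd: a class whose few training values happen to coincide (e.g. the
    # 36-year market imputation) must not collapse to a point mass
    sxa <- colSums((Y + (1 - Y)) * x); sxxa <- colSums((Y + (1 - Y)) * x^2)
    ma <- sxa / n
    va <- if (n > 1) (sxxa - n * ma^2) / (n - 1) else rep(0, E)
    floorSd <- pmax(0.1 * sqrt(pmax(va, 0)), varFloor)
    sx1 <- colSums(Y * x); sxx1 <- colSums(Y * x^2)
    sx0 <- colSums((1 - Y) * x); sxx0 <- colSums((1 - Y) * x^2)
    mom <- function(s, ss, k) {
      m <- s / k
      v <- ifelse(k > 1, (ss - k * m^2) / (k - 1), 0)
      list(m = m, s = pmax(sqrt(pmax(v, 0)), floorSd))
    }
    c1 <- mom(sx1, sxx1, n1); c0 <- mom(sx0, sxx0, n0)
    list(m1 = c1$m, s1 = c1$s, m0 = c0$m, s0 = c0$s)
  })
  list(prior1 = n1 / n, n1 = n1, n0 = n0, cat = cat_p, gauss = gpar,
       singleClass = singleClass, laplace = laplace, varFloor = varFloor)
}

# posterior P(class 1) for new rows; zero categorical cells are guarded with
# zeroGuard at use (log-space accumulation for stability)
.nbPredictMat <- function(fit, catFeats, numFeats, zeroGuard = 1e-3) {
  E <- length(fit$prior1)
  n <- if (length(catFeats)) nrow(catFeats[[1]]) else {
    x <- numFeats[[1]]; if (is.matrix(x)) nrow(x) else length(x)
  }
  g <- function(p) ifelse(p <= 0, zeroGuard, p)
  colmat <- function(v) matrix(v, n, E, byrow = TRUE)
  ll1 <- colmat(log(g(fit$prior1)))
  ll0 <- colmat(log(g(1 - fit$prior1)))
  for (nm in names(catFeats)) {
    B <- catFeats[[nm]]; p <- fit$cat[[nm]]
    ll1 <- ll1 + B * colmat(log(g(p$p1))) + (1 - B) * colmat(log(g(1 - p$p1)))
    ll0 <- ll0 + B * colmat(log(g(p$p0))) + (1 - B) * colmat(log(g(1 - p$p0)))
  }
  # Gaussian densities are bounded below by the same guard as categorical
  # cells, so one outlying continuous value cannot annihilate the posterior
  lg <- log(zeroGuard)
  for (nm in names(numFeats)) {
    x <- numFeats[[nm]]; p <- fit$gauss[[nm]]
    xt <- if (is.matrix(x)) t(x) else matrix(x, E, n, byrow = TRUE)
    ll1 <- ll1 + t(pmax(stats::dnorm(xt, mean = p$m1, sd = p$s1, log = TRUE), lg))
    ll0 <- ll0 + t(pmax(stats::dnorm(xt, mean = p$m0, sd = p$s0, log = TRUE), lg))
  }
  post <- 1 / (1 + exp(ll0 - ll1))
  # prior-only fallback where training saw a single class
  if (any(fit$singleClass != 0L)) {
    post[, fit$singleClass == 1L] <- 1
    post[, fit$singleClass == -1L] <- 0
  }
  post
}

# split a feature data.frame into the engine's (cat, num) lists according to
# the binary-feature mode
.engineFeatures <- function(rows, binaryMode) {
  bin <- lapply(rows[c("f_label", "f_literature")], function(v) matrix(v, ncol = 1))
  num <- lapply(rows[c("f_structure", "f_target", "f_market_years")], as.numeric)
  if (binaryMode == "categorical") list(cat = bin, num = num)
  else list(cat = list(), num = c(lapply(bin, as.numeric), num))
}

# ---- exported single-event interface ---------------------------------------

#' Fit a Naive Bayes classifier for one adverse event
#'
#' Trains on the feature rows of a single adverse-event group, using the test
#' drug's reference label as the class. The prior is the class-1 fraction of
#' the training rows (the event's prevalence among test-drug pairs), which is
#' what makes a Naive Bayes classifier attractive here: events range from
#' rare to near-universal and the prior carries that information. Binary
#' features (\code{f_label}, \code{f_literature}) are modeled as categorical
#' with an optional Laplace pseudo-count; continuous features
#' (\code{f_structure}, \code{f_target}, \code{f_market_years}) as
#' class-conditional Gaussians with the standard deviation floored at
#' \code{varFloor}. The -1 structural sentinel for biologics is an ordinary
#' feature value. With \code{binaryMode = "gaussian"} the binary features are
#' instead treated as numeric Gaussians (the convention of numeric-input
#' Naive Bayes implementations).
#'
#' If only one class is present in the training rows the model falls back to
#' prior-only prediction, with a warning.
#'
#' @param rows feature rows for one ae_group (see [assembleFeatureRows()]);
#'   rows with NA labels are refused.
#' @param laplace Laplace pseudo-count for the categorical tables (default 0).
#' @param varFloor lower bound on Gaussian standard deviations.
#' @param zeroGuard replacement for exact-zero categorical likelihoods at
#'   prediction time (guards degenerate posteriors when \code{laplace = 0}).
#' @param binaryMode "categorical" (default) or "gaussian".
#' @return a [NaiveBayesAEModel-class].
#' @export
fitNaiveBayes <- function(rows, laplace = 0, varFloor = 1e-9, zeroGuard = 1e-3,
                          binaryMode = c("categorical", "gaussian")) {
  binaryMode <- match.arg(binaryMode)
  group <- unique(rows$ae_group)
  if (length(group) != 1L)
    .stopUser("fitNaiveBayes expects rows of exactly one ae_group, got: %s",
              paste(group, collapse = ", "))
  if (!nrow(rows)) .stopUser("no training rows")
  if (anyNA(rows$label)) .stopUser("training rows with NA label")
  Y <- matrix(as.numeric(rows$label), ncol = 1)
  ef <- .engineFeatures(rows, binaryMode)
  fit <- .nbFitMat(ef$cat, ef$num, Y, laplace = laplace, varFloor = varFloor)
  if (fit$singleClass != 0L)
    warning(sprintf("ae_group %s: only class %d present in training; ",
                    group, as.integer(fit$singleClass == 1L)),
            "model falls back to prior-only prediction")
  catTables <- lapply(fit$cat, function(p) {
    tb <- cbind(`0` = c(1 - p$p0, p$p0), `1` = c(1 - p$p1, p$p1))
    rownames(tb) <- c("0", "1")
    tb[is.na(tb)] <- 0.5  # unseen class; never used (prior-only fallback)
    tb
  })
  gaussParams <- lapply(fit$gauss, function(p) {
    tb <- cbind(`0` = c(p$m0, p$s0), `1` = c(p$m1, p$s1))
    rownames(tb) <- c("mean", "sd")
    tb["mean", is.na(tb["mean", ])] <- 0
    tb["sd", is.na(tb["sd", ]) | tb["sd", ] < varFloor] <- varFloor
    tb
  })
  new("NaiveBayesAEModel", aeGroup = group, prior = unname(fit$prior1),
      catTables = catTables, gaussParams = gaussParams,
      laplace = laplace, varFloor = varFloor, zeroGuard = zeroGuard,
      binaryMode = binaryMode, singleClass = fit$singleClass,
      nTrain = nrow(rows))
}

setMethod("show", "NaiveBayesAEModel", function(object) {
  cat(sprintf("NaiveBayesAEModel for %s (n = %d, prior = %.4f, %s binaries)\n",
              object@aeGroup, object@nTrain, object@prior, object@binaryMode))
  if (object@singleClass != 0L)
    cat("  single-class training data: prior-only prediction\n")
})

# reconstruct the engine's fit structure from a model object
.modelToFit <- function(model) {
  list(prior1 = model@prior,
       cat = lapply(model@catTables, function(tb)
         list(p1 = tb["1", "1"], p0 = tb["1", "0"])),
       gauss = lapply(model@gaussParams, function(tb)
         list(m1 = tb["mean", "1"], s1 = tb["sd", "1"],
              m0 = tb["mean", "0"], s0 = tb["sd", "0"])),
       singleClass = model@singleClass)
}

#' Posterior prediction for comparator-test pairs
#'
#' Computes, for each feature row, the posterior probability that the test
#' drug's reference label carries the model's adverse event, given the
#' comparator's evidence: posterior proportional to prior times the product
#' of categorical likelihoods and Gaussian densities, normalized over the two
#' classes. The pair-level call is positive when the posterior strictly
#' exceeds 0.5 (an exact tie predicts negative).
#'
#' @param model a [NaiveBayesAEModel-class].
#' @param rows feature rows (same columns as the training rows; the label
#'   column is ignored and may be NA).
#' @return \code{rows} with the identifier columns plus \code{posterior} and
#'   0/1 \code{call}.
#' @export
predictPairs <- function(model, rows) {
  if (!nrow(rows)) .stopUser("no rows to predict")
  ef <- .engineFeatures(rows, model@binaryMode)
  post <- .nbPredictMat(.modelToFit(model), ef$cat, ef$num,
                        zeroGuard = model@zeroGuard)[, 1]
  data.frame(test_id = rows$test_id, comparator_id = rows$comparator_id,
             ae_group = rows$ae_group, posterior = post,
             call = as.numeric(post > 0.5), stringsAsFactors = FALSE)
}

#' Aggregate comparator votes into drug-level predictions
#'
#' A test drug can have several comparators and hence several pair-level
#' predictions for the same event. The event is called positive for the drug
#' when the percentage of positive comparator votes strictly exceeds
#' \code{threshold}; with threshold 0 a single positive comparator therefore
#' suffices, and no drug is called positive without at least one positive
#' vote.
#'
#' @param preds data.frame of pair predictions (needs \code{test_id} and
#'   \code{call}; from [predictPairs()]).
#' @param threshold vote percentage in \[0, 100\].
#' @return data.frame with one row per test drug: \code{positive_fraction}
#'   (mean of calls) and 0/1 \code{call}.
#' @export
aggregateVotes <- function(preds, threshold) {
  threshold <- .checkNumber(threshold, "threshold", 0, 100)
  if (!nrow(preds)) .stopUser("empty prediction set")
  frac <- tapply(preds$call, preds$test_id, mean)
  data.frame(test_id = names(frac),
             positive_fraction = as.numeric(frac),
             call = as.numeric(100 * as.numeric(frac) > threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- serialization ----------------------------------------------------------

#' Write / read a fitted model as human-readable YAML
#'
#' Serializes every parameter (prior, categorical tables, Gaussian
#' parameters) together with the smoothing, floor and guard settings and
#' training metadata, so fitted models can be audited and reloaded
#' reproducibly.
#'
#' @param model a [NaiveBayesAEModel-class].
#' @param path file path.
#' @return \code{path} invisibly; \code{readNaiveBayesModel} returns the
#'   model.
#' @export
writeNaiveBayesModel <- function(model, path) {
  obj <- list(
    format = "targetAE-naive-bayes-1",
    ae_group = model@aeGroup, prior = model@prior,
    categorical = lapply(model@catTables, function(tb)
      list(class0 = as.list(stats::setNames(tb[, "0"], rownames(tb))),
           class1 = as.list(stats::setNames(tb[, "1"], rownames(tb))))),
    gaussian = lapply(model@gaussParams, function(tb)
      list(class0 = list(mean = tb["mean", "0"], sd = tb["sd", "0"]),
           class1 = list(mean = tb["mean", "1"], sd = tb["sd", "1"]))),
    settings = list(laplace = model@laplace, var_floor = model@varFloor,
                    zero_guard = model@zeroGuard, binary_mode = model@binaryMode),
    training = list(n = model@nTrain, single_class = model@singleClass))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname writeNaiveBayesModel
#' @export
readNaiveBayesModel <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "targetAE-naive-bayes-1"))
    .stopUser("%s is not a serialized targetAE model", path)
  mk <- function(l) {
    tb <- cbind(`0` = unlist(l$class0), `1` = unlist(l$class1))
    rownames(tb) <- names(l$class0)
    tb
  }
  new("NaiveBayesAEModel", aeGroup = obj$ae_group, prior = obj$prior,
      catTables = lapply(obj$categorical, mk),
      gaussParams = lapply(obj$gaussian, function(l) {
        tb <- cbind(`0` = c(l$class0$mean, l$class0$sd),
                    `1` = c(l$class1$mean, l$class1$sd))
        rownames(tb) <- c("mean", "sd"); tb
      }),
      laplace = obj$settings$laplace, varFloor = obj$settings$var_floor,
      zeroGuard = obj$settings$zero_guard, binaryMode = obj$settings$binary_mode,
      singleClass = as.integer(obj$training$single_class),
      nTrain = as.integer(obj$training$n))
}
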