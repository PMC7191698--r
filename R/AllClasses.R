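#' @import methods
NULL

#' Adverse-event vocabulary: MedDRA Preferred Terms grouped into events
#'
#' Maps each MedDRA Preferred Term (PT) to exactly one adverse-event group.
#' Groups collect PTs that are mechanistically similar and reported
#' interchangeably (e.g. "PANCREATITIS" and "PANCREATITIS ACUTE" form the
#' single event "PANCREATITIS"), so a group is considered present on a label
#' as soon as any member PT is present.
#'
#' @slot mapping named character vector; names are Preferred Terms, values are
#'   adverse-event group names. Both are stored uppercased.
#'
#' @seealso [AEVocabulary()], [defaultVocabulary()], [mapPTsToGroups()]
#' @export
setClass("AEVocabulary", representation(mapping = "character"))

setValidity("AEVocabulary", function(object) {
  m <- object@mapping
  msgs <- character()
  if (length(m) == 0L) msgs <- c(msgs, "vocabulary is empty")
  if (is.null(names(m)) || any(!nzchar(names(m))))
    msgs <- c(msgs, "every Preferred Term must be a non-empty name")
  if (anyDuplicated(names(m)))
    msgs <- c(msgs, sprintf("Preferred Terms mapped to more than one group: %s",
                            paste(unique(names(m)[duplicated(names(m))]), collapse = ", ")))
  if (any(is.na(m) | !nzchar(m)))
    msgs <- c(msgs, "every group name must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Container for one study dataset
#'
#' Holds everything a prediction run needs: the drug registry (test and
#' comparator roles), the signed drug-target action table, the adverse-event
#' vocabulary, the three binary label snapshots, per-pair literature evidence,
#' the test/comparator pair list, and (optionally) precomputed 166-bit
#' structural fingerprints. Validity enforces referential integrity across all
#' tables.
#'
#' Label snapshots, each a binary drug-by-event matrix:
#' \describe{
#'   \item{comparator_at_test_approval}{comparator drug labels as they stood
#'     when the corresponding test drugs were approved.}
#'   \item{test_at_approval}{test drug labels at their own approval.}
#'   \item{test_reference}{test drug labels at the later reference date (the
#'     training label); the difference from \code{test_at_approval} defines
#'     safety label changes.}
#' }
#'
#' @slot drugs data.frame with columns drug_id, role ("test"/"comparator"),
#'   smiles (NA allowed), is_biologic (logical), approval_date (Date, NA for
#'   pre-1982 approvals), pre1982 (logical).
#' @slot targetActions data.frame with columns drug_id, target_id, action
#'   (+1 agonist, -1 antagonist).
#' @slot vocabulary an [AEVocabulary-class] object.
#' @slot labels named list of the three 0/1 matrices described above
#'   (rownames drug ids, colnames adverse-event groups).
#' @slot literature data.frame with columns comparator_id, test_id, ae_group,
#'   present (0/1): literature evidence accrued before the test drug's
#'   approval.
#' @slot pairs data.frame with columns test_id, comparator_id.
#' @slot fingerprints numeric 0/1 matrix (drugs x 166) of structural
#'   fingerprints, or a 0-row matrix when fingerprints are to be computed from
#'   SMILES on demand. Biologics carry no row.
#'
#' @seealso [AEDataset()], [readAEDataset()], [generateDataset()]
#' @export
setClass("AEDataset", representation(
  drugs = "data.frame",
  targetActions = "data.frame",
  vocabulary = "AEVocabulary",
  labels = "list",
  literature = "data.frame",
  pairs = "data.frame",
  fingerprints = "matrix"
))

.SNAPSHOTS <- c("comparator_at_test_approval", "test_at_approval", "test_reference")

setValidity("AEDataset", function(object) {
  msgs <- character()
  d <- object@drugs
  need <- c("drug_id", "role", "smiles", "is_biologic", "approval_date", "pre1982")
  if (!all(need %in% names(d)))
    return(sprintf("drugs is missing column(s): %s", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$drug_id))
    msgs <- c(msgs, sprintf("duplicated drug_id: %s",
                            paste(unique(d$drug_id[duplicated(d$drug_id)]), collapse = ", ")))
  if (!all(d$role %in% c("test", "comparator")))
    msgs <- c(msgs, "role must be 'test' or 'comparator'")
  nodate <- !d$pre1982 & is.na(d$approval_date)
  if (any(nodate))
    msgs <- c(msgs, sprintf("drug(s) without approval_date or pre-1982 flag: %s",
                            paste(d$drug_id[nodate], collapse = ", ")))
  bio_smiles <- d$is_biologic & !is.na(d$smiles)
  if (any(bio_smiles))
    msgs <- c(msgs, sprintf("biologic drug(s) must not carry SMILES: %s",
                            paste(d$drug_id[bio_smiles], collapse = ", ")))
  # a small molecule needs a structure source: SMILES or a precomputed fingerprint
  fps <- object@fingerprints
  nostruct <- !d$is_biologic & is.na(d$smiles) &
    !(d$drug_id %in% rownames(fps))
  if (any(nostruct))
    msgs <- c(msgs, sprintf("small-molecule drug(s) with neither SMILES nor fingerprint: %s",
                            paste(d$drug_id[nostruct], collapse = ", ")))
  ids <- d$drug_id

  ta <- object@targetActions
  if (!all(c("drug_id", "target_id", "action") %in% names(ta)))
    return("targetActions must have columns drug_id, target_id, action")
  if (nrow(ta)) {
    if (!all(ta$action %in% c(-1L, 1L)))
      msgs <- c(msgs, "action must be +1 (agonist) or -1 (antagonist)")
    if (anyDuplicated(ta[c("drug_id", "target_id")]))
      msgs <- c(msgs, "duplicate (drug_id, target_id) in targetActions")
    bad <- setdiff(ta$drug_id, ids)
    if (length(bad))
      msgs <- c(msgs, sprintf("targetActions references unknown drug(s): %s",
                              paste(bad, collapse = ", ")))
  }

  groups <- aeGroups(object@vocabulary)
  if (!identical(sort(names(object@labels)), sort(.SNAPSHOTS)))
    msgs <- c(msgs, sprintf("labels must be a named list with snapshots: %s",
                            paste(.SNAPSHOTS, collapse = ", ")))
  for (nm in intersect(names(object@labels), .SNAPSHOTS)) {
    L <- object@labels[[nm]]
    if (!is.matrix(L)) { msgs <- c(msgs, sprintf("labels$%s is not a matrix", nm)); next }
    if (length(L) && !all(L %in% c(0, 1)))
      msgs <- c(msgs, sprintf("labels$%s has values outside {0,1}", nm))
    bad <- setdiff(rownames(L), ids)
    if (length(bad))
      msgs <- c(msgs, sprintf("labels$%s references unknown drug(s): %s", nm,
                              paste(bad, collapse = ", ")))
    badg <- setdiff(colnames(L), groups)
    if (length(badg))
      msgs <- c(msgs, sprintf("labels$%s references unknown adverse-event group(s): %s",
                              nm, paste(badg, collapse = ", ")))
  }

  lit <- object@literature
  if (!all(c("comparator_id", "test_id", "ae_group", "present") %in% names(lit)))
    return("literature must have columns comparator_id, test_id, ae_group, present")
  if (nrow(lit)) {
    if (!all(lit$present %in% c(0, 1)))
      msgs <- c(msgs, "literature present must be 0/1")
    bad <- setdiff(c(lit$comparator_id, lit$test_id), ids)
    if (length(bad))
      msgs <- c(msgs, sprintf("literature references unknown drug(s): %s",
                              paste(unique(bad), collapse = ", ")))
    badg <- setdiff(lit$ae_group, groups)
    if (length(badg))
      msgs <- c(msgs, sprintf("literature references unknown adverse-event group(s): %s",
                              paste(unique(badg), collapse = ", ")))
  }

  pr <- object@pairs
  if (!all(c("test_id", "comparator_id") %in% names(pr)))
    return("pairs must have columns test_id, comparator_id")
  bad <- setdiff(c(pr$test_id, pr$comparator_id), ids)
  if (length(bad))
    msgs <- c(msgs, sprintf("pairs references unknown drug(s): %s",
                            paste(unique(bad), collapse = ", ")))
  test_ids <- d$drug_id[d$role == "test"]
  lonely <- setdiff(test_ids, pr$test_id)
  if (length(lonely))
    msgs <- c(msgs, sprintf("test drug(s) without any comparator: %s",
                            paste(lonely, collapse = ", ")))
  if (anyDuplicated(pr[c("test_id", "comparator_id")]))
    msgs <- c(msgs, "duplicate rows in pairs")

  if (ncol(fps) && ncol(fps) != 166L)
    msgs <- c(msgs, "fingerprints must have exactly 166 columns")
  if (nrow(fps)) {
    if (!all(fps %in% c(0, 1)))
      msgs <- c(msgs, "fingerprint bits must be 0/1")
    bad <- setdiff(rownames(fps), ids)
    if (length(bad))
      msgs <- c(msgs, sprintf("fingerprints reference unknown drug(s): %s",
                              paste(bad, collapse = ", ")))
  }

  if (length(msgs)) msgs else TRUE
})

#' Per-adverse-event Naive Bayes model
#'
#' One classifier per adverse-event group, fitted on
#' (comparator, test drug) feature rows. Binary features are modeled as
#' categorical tables (optionally Laplace-smoothed); continuous features as
#' class-conditional Gaussians with a floored standard deviation.
#'
#' @slot aeGroup adverse-event group the model was trained for.
#' @slot prior probability of label 1 in the training rows.
#' @slot catTables named list (one per binary feature) of 2x2 matrices:
#'   rows = feature value "0"/"1", columns = class "0"/"1"; each column sums
#'   to 1.
#' @slot gaussParams named list (one per continuous feature) of 2x2 matrices:
#'   rows = "mean"/"sd", columns = class "0"/"1".
#' @slot laplace Laplace pseudo-count used for the categorical tables.
#' @slot varFloor lower bound applied to Gaussian standard deviations.
#' @slot zeroGuard value substituted for exact-zero categorical likelihoods at
#'   prediction time.
#' @slot binaryMode "categorical" or "gaussian" treatment of the 0/1 features.
#' @slot singleClass 0 when both classes were present in training; +1/-1 when
#'   only class 1 / class 0 was seen (prediction falls back to the prior).
#' @slot nTrain number of training rows.
#' @seealso [fitNaiveBayes()], [predictPairs()]
#' @export
setClass("NaiveBayesAEModel", representation(
  aeGroup = "character", prior = "numeric",
  catTables = "list", gaussParams = "list",
  laplace = "numeric", varFloor = "numeric", zeroGuard = "numeric",
  binaryMode = "character", singleClass = "integer", nTrain = "integer"
))

setValidity("NaiveBayesAEModel", function(object) {
  msgs <- character()
  if (object@prior < 0 || object@prior > 1) msgs <- c(msgs, "prior must be in [0,1]")
  for (nm in names(object@catTables)) {
    tb <- object@catTables[[nm]]
    if (any(abs(colSums(tb) - 1) > 1e-8))
      msgs <- c(msgs, sprintf("conditional probabilities for %s do not sum to 1", nm))
  }
  for (nm in names(object@gaussParams)) {
    gp <- object@gaussParams[[nm]]
    if (any(gp["sd", ] < object@varFloor))
      msgs <- c(msgs, sprintf("sd for %s below the variance floor", nm))
  }
  if (!object@binaryMode %in% c("categorical", "gaussian"))
    msgs <- c(msgs, "binaryMode must be 'categorical' or 'gaussian'")
  if (length(msgs)) msgs else TRUE
})

#' Bootstrap evaluation result
#'
#' Distributions of the four performance metrics (sensitivity, specificity,
#' PPV, NPV) over bootstrap train/test partitions of the test drugs, per
#' adverse-event group and vote threshold, with mode/median/quartile
#' summaries. Metric values are integer percents; iterations on which a
#' metric's denominator was zero are excluded from the samples and counted in
#' \code{n_undefined}.
#'
#' @slot aeGroups adverse-event groups evaluated (the eligible ones).
#' @slot thresholds comparator-vote thresholds (percent) evaluated.
#' @slot iterations number of bootstrap iterations.
#' @slot trainSize,testSize train/test partition sizes (test drugs).
#' @slot seed random seed used.
#' @slot samples nested list: \code{samples[[as.character(threshold)]][[metric]]}
#'   is an iterations x groups integer matrix (NA where undefined).
#' @slot summary data.frame with columns threshold, ae_group, metric, mode,
#'   median, q25, q75, n_undefined, predictability.
#' @seealso [bootstrapEvaluate()], [summarizeSamples()]
#' @export
setClass("BootstrapResult", representation(
  aeGroups = "character", thresholds = "numeric", iterations = "integer",
  trainSize = "integer", testSize = "integer", seed = "integer",
  samples = "list", summary = "data.frame"
))
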