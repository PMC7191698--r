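# Assembly of the five-feature rows, one per (comparator, test drug, event).

# pair-level quantities: similarity features and market duration are
# computed once per pair and broadcast across adverse events
.pairFeatures <- function(dataset, referenceDate, backend = NULL) {
  pr <- dataset@pairs
  d <- dataset@drugs
  universe <- sort(unique(dataset@targetActions$target_id))
  tv <- lapply(unique(c(pr$test_id, pr$comparator_id)), function(id)
    targetVector(id, dataset, universe))
  names(tv) <- unique(c(pr$test_id, pr$comparator_id))
  years <- timeOnMarket(dataset, referenceDate, ids = unique(pr$comparator_id))
  f_structure <- f_target <- numeric(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    f_structure[i] <- structuralSimilarity(dataset, pr$test_id[i],
                                           pr$comparator_id[i], backend = backend)
    f_target[i] <- cosineSimilarity(tv[[pr$test_id[i]]], tv[[pr$comparator_id[i]]])
  }
  data.frame(test_id = pr$test_id, comparator_id = pr$comparator_id,
             f_structure = f_structure, f_target = f_target,
             f_market_years = unname(years[pr$comparator_id]),
             stringsAsFactors = FALSE)
}

# literature evidence as a pair-by-group 0/1 matrix (absent records are 0)
.literatureMatrix <- function(dataset, groups) {
  pr <- dataset@pairs
  key <- paste(pr$comparator_id, pr$test_id, sep = "\r")
  m <- matrix(0, nrow(pr), length(groups),
              dimnames = list(NULL, groups))
  lit <- dataset@literature
  if (nrow(lit)) {
    lit <- lit[lit$ae_group %in% groups, , drop = FALSE]
    i <- match(paste(lit$comparator_id, lit$test_id, sep = "\r"), key)
    keep <- !is.na(i)
    m[cbind(i[keep], match(lit$ae_group[keep], groups))] <- lit$present[keep]
  }
  m
}

# binary snapshot values for a set of drugs (rows of `ids`), zero-filled for
# drugs without a row in the snapshot unless require_all is set
.snapshotFor <- function(dataset, snapshot, ids, groups, require_all = TRUE) {
  L <- labelMatrix(dataset, snapshot)
  miss <- setdiff(ids, rownames(L))
  if (length(miss) && require_all)
    .stopUser("no %s labels for drug(s): %s", snapshot, paste(miss, collapse = ", "))
  out <- matrix(NA_real_, length(ids), length(groups),
                dimnames = list(ids, groups))
  have <- intersect(ids, rownames(L))
  gh <- intersect(groups, colnames(L))
  out[have, ] <- 0
  out[have, gh] <- L[have, gh]
  out
}

#' Assemble the five-feature rows for classification
#'
#' Produces exactly one row per (test drug, comparator) pair and adverse-event
#' group, carrying the five classifier features: comparator label presence
#' (\code{f_label}), comparator literature presence (\code{f_literature}),
#' structural similarity (\code{f_structure}; Tanimoto, or -1 for a biologic
#' pair), target cosine similarity (\code{f_target}), and the comparator's
#' years on the market (\code{f_market_years}). The training label
#' (\code{label}) is the test drug's reference-snapshot label for the group;
#' it is NA for test drugs absent from that snapshot (pure prediction).
#'
#' Similarity features and market duration are pair-level quantities: they are
#' computed once per pair and identical across groups.
#'
#' @param dataset an [AEDataset-class].
#' @param aeGroups adverse-event groups to include; defaults to the eligible
#'   groups (present in at least two test-drug reference labels).
#' @param referenceDate date to which comparator market duration is measured
#'   (the reference-snapshot date).
#' @param backend optional fingerprint backend, see [maccsFingerprint()].
#' @return data.frame with columns test_id, comparator_id, ae_group, f_label,
#'   f_literature, f_structure, f_target, f_market_years, label.
#' @export
assembleFeatureRows <- function(dataset, aeGroups = NULL,
                                referenceDate = "2017-01-01", backend = NULL) {
  if (is.null(aeGroups)) aeGroups <- eligibleAdverseEvents(dataset)
  aeGroups <- as.character(aeGroups)
  unknown <- setdiff(aeGroups, aeGroups(dataset@vocabulary))
  if (length(unknown))
    .stopUser("ae group(s) not in vocabulary: %s", paste(unknown, collapse = ", "))
  pf <- .pairFeatures(dataset, referenceDate, backend = backend)
  pr <- dataset@pairs
  E <- length(aeGroups); P <- nrow(pr)
  compLab <- .snapshotFor(dataset, "comparator_at_test_approval",
                          unique(pr$comparator_id), aeGroups)
  testLab <- .snapshotFor(dataset, "test_reference", unique(pr$test_id),
                          aeGroups, require_all = FALSE)
  lit <- .literatureMatrix(dataset, aeGroups)
  idx <- rep(seq_len(P), times = E)
  gidx <- rep(seq_len(E), each = P)
  data.frame(
    test_id = pr$test_id[idx],
    comparator_id = pr$comparator_id[idx],
    ae_group = aeGroups[gidx],
    f_label = compLab[cbind(match(pr$comparator_id[idx], rownames(compLab)), gidx)],
    f_literature = lit[cbind(idx, gidx)],
    f_structure = pf$f_structure[idx],
    f_target = pf$f_target[idx],
    f_market_years = pf$f_market_years[idx],
    label = testLab[cbind(match(pr$test_id[idx], rownames(testLab)), gidx)],
    stringsAsFactors = FALSE)
}

#' Write feature rows to CSV
#'
#' @param rows data.frame from [assembleFeatureRows()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFeatureRows <- function(rows, path) {
  cols <- c("test_id", "comparator_id", "ae_group", "f_label", "f_literature",
            "f_structure", "f_target", "f_market_years", "label")
  utils::write.csv(rows[, cols], path, row.names = FALSE)
  invisible(path)
}
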