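#' Construct an AEDataset
#'
#' Assembles and validates the tables of one study dataset. All referential
#' integrity rules are checked (unknown drug ids, unknown adverse-event
#' groups, test drugs without comparators, malformed label values) and
#' violations are reported naming the offending entries.
#'
#' @param drugs data.frame with columns drug_id, role, smiles, is_biologic,
#'   approval_date (Date or "YYYY-MM-DD"), pre1982.
#' @param targetActions data.frame with columns drug_id, target_id, action
#'   (+1/-1).
#' @param vocabulary an [AEVocabulary-class]; defaults to the packaged one.
#' @param labels named list of three 0/1 drug-by-group matrices:
#'   \code{comparator_at_test_approval}, \code{test_at_approval},
#'   \code{test_reference}.
#' @param literature data.frame with columns comparator_id, test_id, ae_group,
#'   present. A per-comparator-only table (no test_id column) is accepted and
#'   broadcast over that comparator's pairs, with a warning, since literature
#'   evidence is cut off at each test drug's approval date.
#' @param pairs data.frame with columns test_id, comparator_id.
#' @param fingerprints optional 0/1 matrix (rownames drug ids, 166 columns).
#' @return a validated [AEDataset-class] object.
#' @export
AEDataset <- function(drugs, targetActions, vocabulary = defaultVocabulary(),
                      labels, literature = NULL, pairs, fingerprints = NULL) {
  drugs <- as.data.frame(drugs)
  if (!"smiles" %in% names(drugs)) drugs$smiles <- NA_character_
  if (!"pre1982" %in% names(drugs)) drugs$pre1982 <- FALSE
  drugs$drug_id <- as.character(drugs$drug_id)
  drugs$smiles <- as.character(drugs$smiles)
  drugs$smiles[!is.na(drugs$smiles) & !nzchar(drugs$smiles)] <- NA_character_
  drugs$is_biologic <- as.logical(drugs$is_biologic)
  drugs$pre1982 <- as.logical(drugs$pre1982)
  drugs$approval_date <- as.Date(drugs$approval_date)

  targetActions <- as.data.frame(targetActions)
  if (nrow(targetActions)) {
    targetActions$drug_id <- as.character(targetActions$drug_id)
    targetActions$target_id <- as.character(targetActions$target_id)
    targetActions$action <- as.integer(targetActions$action)
  }

  if (is.null(literature))
    literature <- data.frame(comparator_id = character(), test_id = character(),
                             ae_group = character(), present = numeric())
  literature <- as.data.frame(literature)
  pairs <- as.data.frame(pairs)
  pairs$test_id <- as.character(pairs$test_id)
  pairs$comparator_id <- as.character(pairs$comparator_id)
  if (!"test_id" %in% names(literature) && nrow(literature)) {
    warning("literature table has no test_id column; broadcasting each ",
            "comparator's evidence over all of its test-drug pairs")
    literature <- merge(literature, pairs, by = "comparator_id")
  }
  if (nrow(literature)) {
    literature$comparator_id <- as.character(literature$comparator_id)
    literature$test_id <- as.character(literature$test_id)
    literature$ae_group <- toupper(as.character(literature$ae_group))
    literature$present <- as.numeric(literature$present)
  }

  labels <- lapply(labels, function(L) {
    L <- as.matrix(L)
    storage.mode(L) <- "numeric"
    colnames(L) <- toupper(colnames(L))
    L
  })

  if (is.null(fingerprints))
    fingerprints <- matrix(numeric(), 0, 166)
  fingerprints <- as.matrix(fingerprints)

  obj <- new("AEDataset", drugs = drugs, targetActions = targetActions,
             vocabulary = vocabulary, labels = labels,
             literature = literature, pairs = pairs,
             fingerprints = fingerprints)
  obj
}

#' @describeIn AEDataset-class the drug registry data.frame.
#' @param x an \code{AEDataset}.
#' @export
drugs <- function(x) x@drugs

#' @describeIn AEDataset-class the signed drug-target action table.
#' @export
targetActions <- function(x) x@targetActions

#' @describeIn AEDataset-class the vocabulary.
#' @export
vocabulary <- function(x) x@vocabulary

#' @describeIn AEDataset-class one binary label snapshot matrix.
#' @param snapshot one of "comparator_at_test_approval", "test_at_approval",
#'   "test_reference".
#' @export
labelMatrix <- function(x, snapshot) {
  snapshot <- match.arg(snapshot, .SNAPSHOTS)
  x@labels[[snapshot]]
}

#' @describeIn AEDataset-class the (test_id, comparator_id) pair table.
#' @export
drugPairs <- function(x) x@pairs

#' @describeIn AEDataset-class the per-pair literature evidence table.
#' @export
literatureEvidence <- function(x) x@literature

#' @describeIn AEDataset-class ids of test drugs (sorted).
#' @export
testDrugs <- function(x) sort(x@drugs$drug_id[x@drugs$role == "test"])

#' @describeIn AEDataset-class ids of comparator drugs (sorted).
#' @export
comparatorDrugs <- function(x) sort(x@drugs$drug_id[x@drugs$role == "comparator"])

#' @describeIn AEDataset-class precomputed fingerprint matrix (may have 0 rows).
#' @export
fingerprints <- function(x) x@fingerprints

setMethod("show", "AEDataset", function(object) {
  d <- object@drugs
  cat("AEDataset\n")
  cat(sprintf("  drugs:      %d (%d test, %d comparator; %d biologic)\n",
              nrow(d), sum(d$role == "test"), sum(d$role == "comparator"),
              sum(d$is_biologic)))
  cat(sprintf("  pairs:      %d test-comparator combinations\n", nrow(object@pairs)))
  cat(sprintf("  targets:    %d actions on %d targets\n",
              nrow(object@targetActions), length(unique(object@targetActions$target_id))))
  cat(sprintf("  vocabulary: %d adverse-event groups\n",
              length(aeGroups(object@vocabulary))))
  cat(sprintf("  literature: %d (comparator, test, event) records\n",
              nrow(object@literature)))
})

# ---- readers / writers ------------------------------------------------------

.readCsv <- function(path) {
  if (!file.exists(path)) .stopUser("missing input file: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.readLabelMatrix <- function(path) {
  df <- .readCsv(path)
  if (names(df)[1] != "drug_id")
    .stopUser("%s: first column must be drug_id", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df$drug_id)
  m
}

#' Read an AEDataset from a directory of CSV files
#'
#' Expects the documented bundle: \code{drugs.csv}, \code{target_actions.csv},
#' \code{pairs.csv}, \code{literature.csv}, one wide binary
#' \code{labels_<snapshot>.csv} per snapshot (first column \code{drug_id}),
#' and optionally \code{vocabulary.csv} (preferred_term, ae_group; the
#' packaged vocabulary is used when absent) and \code{fingerprints.csv}
#' (drug_id plus 166 bit columns). All tables are validated for referential
#' integrity; errors name the offending rows.
#'
#' @param dir directory containing the bundle.
#' @return an [AEDataset-class].
#' @seealso [writeAEDataset()]
#' @export
readAEDataset <- function(dir) {
  if (!dir.exists(dir)) .stopUser("no such directory: %s", dir)
  drugs <- .readCsv(file.path(dir, "drugs.csv"))
  need <- c("drug_id", "role", "is_biologic")
  miss <- setdiff(need, names(drugs))
  if (length(miss))
    .stopUser("drugs.csv is missing column(s): %s", paste(miss, collapse = ", "))
  ta <- .readCsv(file.path(dir, "target_actions.csv"))
  prs <- .readCsv(file.path(dir, "pairs.csv"))
  vpath <- file.path(dir, "vocabulary.csv")
  vocab <- if (file.exists(vpath)) {
    v <- .readCsv(vpath)
    AEVocabulary(v$preferred_term, v$ae_group)
  } else defaultVocabulary()
  labels <- lapply(.SNAPSHOTS, function(s)
    .readLabelMatrix(file.path(dir, sprintf("labels_%s.csv", s))))
  names(labels) <- .SNAPSHOTS
  lpath <- file.path(dir, "literature.csv")
  lit <- if (file.exists(lpath)) .readCsv(lpath) else NULL
  fpath <- file.path(dir, "fingerprints.csv")
  fps <- NULL
  if (file.exists(fpath)) {
    fdf <- .readCsv(fpath)
    fps <- as.matrix(fdf[, -1, drop = FALSE])
    storage.mode(fps) <- "numeric"
    rownames(fps) <- as.character(fdf$drug_id)
  }
  tryCatch(
    AEDataset(drugs = drugs, targetActions = ta, vocabulary = vocab,
              labels = labels, literature = lit, pairs = prs,
              fingerprints = fps),
    error = function(e) .stopUser("invalid dataset in %s: %s", dir, conditionMessage(e)))
}

#' Write an AEDataset to a directory of CSV files
#'
#' Inverse of [readAEDataset()]: writing then reading reproduces identical
#' content.
#'
#' @param dataset an [AEDataset-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeAEDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dataset@drugs
  d$approval_date <- format(d$approval_date)
  utils::write.csv(d, file.path(dir, "drugs.csv"), row.names = FALSE, quote = TRUE)
  utils::write.csv(dataset@targetActions, file.path(dir, "target_actions.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset@pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  v <- data.frame(preferred_term = preferredTerms(dataset@vocabulary),
                  ae_group = unname(dataset@vocabulary@mapping))
  utils::write.csv(v, file.path(dir, "vocabulary.csv"), row.names = FALSE)
  for (s in .SNAPSHOTS) {
    L <- dataset@labels[[s]]
    df <- data.frame(drug_id = rownames(L), L, check.names = FALSE)
    utils::write.csv(df, file.path(dir, sprintf("labels_%s.csv", s)),
                     row.names = FALSE)
  }
  utils::write.csv(dataset@literature, file.path(dir, "literature.csv"),
                   row.names = FALSE)
  fps <- dataset@fingerprints
  if (nrow(fps)) {
    df <- data.frame(drug_id = rownames(fps), fps, check.names = FALSE)
    colnames(df) <- c("drug_id", paste0("bit", seq_len(ncol(fps))))
    utils::write.csv(df, file.path(dir, "fingerprints.csv"), row.names = FALSE)
  }
  invisible(dir)
}

# ---- derived quantities -----------------------------------------------------

#' Select comparator drugs for a test drug
#'
#' Comparators are drugs with the same pharmacological activity (agonist or
#' antagonist, i.e. identical action sign) at one or more of the same targets
#' as the given drug.
#'
#' @param drugId drug whose comparators are sought.
#' @param targets an [AEDataset-class] or a target-action data.frame
#'   (drug_id, target_id, action).
#' @param candidates ids to consider (default: every other drug in the table).
#' @return sorted character vector of matching candidate ids.
#' @export
selectComparators <- function(drugId, targets, candidates = NULL) {
  ta <- if (is(targets, "AEDataset")) targets@targetActions else as.data.frame(targets)
  mine <- ta[ta$drug_id == drugId, , drop = FALSE]
  if (!nrow(mine))
    .stopUser("drug %s has no target actions; comparators cannot be defined", drugId)
  if (is.null(candidates)) candidates <- setdiff(unique(ta$drug_id), drugId)
  theirs <- ta[ta$drug_id %in% setdiff(candidates, drugId), , drop = FALSE]
  key <- function(df) paste(df$target_id, df$action)
  hits <- unique(theirs$drug_id[key(theirs) %in% key(mine)])
  sort(hits)
}

#' Years a drug has been on the market
#'
#' Fractional years between approval and a reference date (actual day count /
#' 365.25). Drugs flagged as approved before 1982 have no exact approval date
#' in the registry; their market duration is imputed as exactly 36 years
#' (1982 to the 2017 reference snapshot).
#'
#' @param x an [AEDataset-class] or a drugs data.frame.
#' @param referenceDate date up to which time on market is measured.
#' @param ids drug ids to compute (default: all drugs in \code{x}).
#' @return named numeric vector of years.
#' @export
timeOnMarket <- function(x, referenceDate, ids = NULL) {
  d <- if (is(x, "AEDataset")) x@drugs else as.data.frame(x)
  if (!is.null(ids)) {
    miss <- setdiff(ids, d$drug_id)
    if (length(miss)) .stopUser("unknown drug id(s): %s", paste(miss, collapse = ", "))
    d <- d[match(ids, d$drug_id), , drop = FALSE]
  }
  referenceDate <- as.Date(referenceDate)
  out <- rep(NA_real_, nrow(d))
  pre <- which(d$pre1982)
  out[pre] <- 36
  rest <- which(!d$pre1982)
  if (length(rest)) {
    late <- rest[d$approval_date[rest] > referenceDate]
    if (length(late))
      .stopUser("reference date %s is earlier than the approval date of: %s",
                format(referenceDate), paste(d$drug_id[late], collapse = ", "))
    out[rest] <- as.numeric(referenceDate - d$approval_date[rest]) / 365.25
  }
  names(out) <- d$drug_id
  out
}

#' Adverse events eligible for modeling
#'
#' Events seen in too few test-drug reference labels cannot support a
#' classifier; events present in fewer than \code{minPositive} test-drug
#' reference labels (default 2, i.e. not observed or observed in only one
#' label) are excluded.
#'
#' @param labels the \code{test_reference} label matrix, or an
#'   [AEDataset-class] from which it is taken.
#' @param testIds test drug ids to count over (default: all rows / all test
#'   drugs).
#' @param minPositive minimum number of positive test-drug labels.
#' @return sorted character vector of eligible group names.
#' @export
eligibleAdverseEvents <- function(labels, testIds = NULL, minPositive = 2) {
  if (is(labels, "AEDataset")) {
    if (is.null(testIds)) testIds <- testDrugs(labels)
    labels <- labelMatrix(labels, "test_reference")
  }
  if (is.null(testIds)) testIds <- rownames(labels)
  if (!length(testIds)) .stopUser("empty test drug set")
  miss <- setdiff(testIds, rownames(labels))
  if (length(miss)) .stopUser("no labels for drug(s): %s", paste(miss, collapse = ", "))
  counts <- colSums(labels[testIds, , drop = FALSE])
  sort(names(counts)[counts >= minPositive])
}

#' Per-event label prevalence within a drug set
#'
#' @param labels a 0/1 drug-by-group label matrix or an [AEDataset-class]
#'   (with \code{snapshot} choosing the matrix).
#' @param drugIds drugs to average over.
#' @param snapshot snapshot name when \code{labels} is a dataset.
#' @return named numeric vector in \[0, 1\]: fraction of the drugs whose label
#'   carries each event.
#' @export
aePrevalence <- function(labels, drugIds = NULL, snapshot = "test_reference") {
  if (is(labels, "AEDataset")) labels <- labelMatrix(labels, snapshot)
  if (is.null(drugIds)) drugIds <- rownames(labels)
  if (!length(drugIds)) .stopUser("drugIds must be non-empty")
  miss <- setdiff(drugIds, rownames(labels))
  if (length(miss)) .stopUser("no labels for drug(s): %s", paste(miss, collapse = ", "))
  colMeans(labels[drugIds, , drop = FALSE])
}
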