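# Seeded generator of complete synthetic datasets with planted
# target-to-adverse-event structure. The generator's defaults define the
# study conditions every pipeline stage is tested under; they emulate the
# statistical structure the classifier assumes - drugs with the same action
# at the same targets share adverse events - without any claim to
# pharmacological realism.

#' Configuration for the synthetic-data generator
#'
#' @param nTargets number of molecular targets in the universe. The default
#'   is small relative to the drug count so that targets define drug classes
#'   shared by several drugs, as pharmacological target families do.
#' @param nTestDrugs number of test drugs.
#' @param comparatorsPerTest length-2 integer range; per-test comparator
#'   counts are drawn from this range, uniformly when
#'   \code{comparatorCountSkew = 0}, otherwise with probability proportional
#'   to \eqn{k^{-skew}} (small counts modal, the pattern of real comparator
#'   availability).
#' @param comparatorCountSkew power-law exponent for the comparator-count
#'   distribution (0 = uniform).
#' @param nAeGroups number of adverse-event groups.
#' @param nPlanted number of groups given a driving target: drugs acting on
#'   that target carry the event with probability
#'   \code{pEventGivenTarget}, all other drug-event combinations with
#'   \code{pEventBaseline}.
#' @param pEventGivenTarget,pEventBaseline label presence probabilities; the
#'   former must exceed the latter for the planted signal to be meaningful.
#' @param literatureFlipRate probability that a pair's literature evidence
#'   disagrees with the comparator's label (independent flips).
#' @param biologicFraction probability that a drug is a biologic (no
#'   fingerprint; structural similarity becomes the -1 sentinel).
#' @param approvalYearRange comparator approval-year range (test drugs are
#'   approved 2008-2013, mirroring a post-SPL approval window).
#' @param pre1982Fraction fraction of comparators flagged as approved before
#'   1982 (market duration imputed as 36 years).
#' @param slcDeletionRate fraction of positive reference labels deleted from
#'   the test drugs' at-approval snapshot, creating known safety label
#'   changes for the leave-one-out evaluator.
#' @param seed master seed; each generated table draws from its own named
#'   substream so adding a table does not perturb the others.
#' @return validated configuration (a \code{SyntheticConfig} list).
#' @seealso [generateDataset()], [defaultStudyScale()]
#' @export
syntheticConfig <- function(nTargets = 12, nTestDrugs = 20,
                            comparatorsPerTest = c(1, 5),
                            comparatorCountSkew = 0, nAeGroups = 30,
                            nPlanted = 10, pEventGivenTarget = 0.9,
                            pEventBaseline = 0.05, literatureFlipRate = 0.1,
                            biologicFraction = 0.05,
                            approvalYearRange = c(1982, 2012),
                            pre1982Fraction = 0.3, slcDeletionRate = 0.3,
                            seed = 1) {
  cfg <- list(
    nTargets = .checkCount(nTargets, "nTargets"),
    nTestDrugs = .checkCount(nTestDrugs, "nTestDrugs", 2L),
    comparatorsPerTest = c(.checkCount(comparatorsPerTest[1], "comparatorsPerTest[1]"),
                           .checkCount(comparatorsPerTest[2], "comparatorsPerTest[2]")),
    comparatorCountSkew = .checkNumber(comparatorCountSkew, "comparatorCountSkew", 0, 10),
    nAeGroups = .checkCount(nAeGroups, "nAeGroups"),
    nPlanted = .checkCount(nPlanted, "nPlanted", 0L),
    pEventGivenTarget = .checkNumber(pEventGivenTarget, "pEventGivenTarget", 0, 1),
    pEventBaseline = .checkNumber(pEventBaseline, "pEventBaseline", 0, 1),
    literatureFlipRate = .checkNumber(literatureFlipRate, "literatureFlipRate", 0, 1),
    biologicFraction = .checkNumber(biologicFraction, "biologicFraction", 0, 1),
    approvalYearRange = as.integer(approvalYearRange),
    pre1982Fraction = .checkNumber(pre1982Fraction, "pre1982Fraction", 0, 1),
    slcDeletionRate = .checkNumber(slcDeletionRate, "slcDeletionRate", 0, 1),
    seed = .checkCount(seed, "seed", 0L))
  if (cfg$comparatorsPerTest[1] > cfg$comparatorsPerTest[2])
    .stopUser("comparatorsPerTest range is reversed")
  if (cfg$nPlanted > cfg$nAeGroups)
    .stopUser("nPlanted (%d) exceeds nAeGroups (%d)", cfg$nPlanted, cfg$nAeGroups)
  if (cfg$nPlanted > 0 && cfg$pEventGivenTarget <= cfg$pEventBaseline)
    .stopUser("pEventGivenTarget must exceed pEventBaseline for a meaningful signal")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Study-scale synthetic configuration
#'
#' A configuration producing 54 test drugs with comparator counts skewed
#' toward one or two per drug (range up to 37), 135 adverse-event groups over
#' a universe of 30 class-defining targets, with roughly a third of
#' comparators flagged
#' pre-1982 (36-year market imputation) and a small biologic fraction.
#'
#' @param seed master seed.
#' @return a \code{SyntheticConfig}.
#' @export
defaultStudyScale <- function(seed = 1) {
  syntheticConfig(nTargets = 30, nTestDrugs = 54,
                  comparatorsPerTest = c(1, 37), comparatorCountSkew = 1.5,
                  nAeGroups = 135,
                  nPlanted = 40, pEventGivenTarget = 0.9,
                  pEventBaseline = 0.1, literatureFlipRate = 0.1,
                  biologicFraction = 0.03, approvalYearRange = c(1982, 2012),
                  pre1982Fraction = 0.37, slcDeletionRate = 0.3, seed = seed)
}

#' Generate a synthetic dataset with planted target-event associations
#'
#' Produces a complete, referentially consistent [AEDataset-class] plus the
#' planted ground truth. Test drugs receive one to three random signed target
#' actions (skewed toward one, the primary-target case). Each comparator
#' belongs to its test drug's pharmacological class: it inherits the test
#' drug's full action set (guaranteeing the shared same-sign action that
#' defines a comparator) and gains Poisson(0.2) extra random targets -
#' same-class drugs share their core target profile but accumulate
#' individual secondary targets. Fingerprints are synthesized directly as
#' OR-combined per-target 166-bit templates with 12 percent bit noise, so
#' shared-target pairs have elevated Tanimoto similarity without requiring a
#' chemistry toolkit. For each planted event a driving target is drawn among
#' targets carried by at least two test drugs, weighted by the squared
#' carrier count (well-characterized target-event relationships belong to
#' class-defining targets); any drug acting on it carries the
#' event with probability \code{pEventGivenTarget}, otherwise
#' \code{pEventBaseline}. The at-approval test snapshot deletes a
#' \code{slcDeletionRate} fraction of reference positives (known safety label
#' changes), and literature evidence flips comparator labels independently at
#' \code{literatureFlipRate}.
#'
#' @param config a \code{SyntheticConfig} from [syntheticConfig()].
#' @return list with elements \code{dataset} (an [AEDataset-class]) and
#'   \code{truth} (data.frame ae_group, target_id for the planted events).
#' @export
generateDataset <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(syntheticConfig, as.list(config))
  cfg <- config
  sub <- function(name) set.seed(.substreamSeed(cfg$seed, name))
  targets <- sprintf("TGT%03d", seq_len(cfg$nTargets))
  groups <- sprintf("AE%03d", seq_len(cfg$nAeGroups))
  tests <- sprintf("T%03d", seq_len(cfg$nTestDrugs))

  # -- test drug pharmacology
  sub("test_targets")
  testActs <- lapply(tests, function(id) {
    k <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    data.frame(drug_id = id, target_id = sample(targets, k),
               action = sample(c(-1L, 1L), k, replace = TRUE))
  })

  # -- comparators: per test drug, profiles derived from the test drug's
  sub("comparators")
  lo <- cfg$comparatorsPerTest[1]; hi <- cfg$comparatorsPerTest[2]
  kk <- lo:hi
  pk <- kk^-cfg$comparatorCountSkew
  counts <- sample(kk, cfg$nTestDrugs, replace = TRUE, prob = pk / sum(pk))
  compActs <- list(); pairs <- list(); ci <- 0L
  for (i in seq_along(tests)) {
    ta <- testActs[[i]]
    for (j in seq_len(counts[i])) {
      ci <- ci + 1L
      id <- sprintf("C%04d", ci)
      acts <- ta[, c("target_id", "action"), drop = FALSE]
      nExtra <- stats::rpois(1, 0.2)
      extra <- setdiff(sample(targets, min(nExtra, cfg$nTargets)), acts$target_id)
      if (length(extra))
        acts <- rbind(acts, data.frame(target_id = extra,
                                       action = sample(c(-1L, 1L), length(extra),
                                                       replace = TRUE)))
      compActs[[ci]] <- data.frame(drug_id = id, target_id = acts$target_id,
                                   action = acts$action)
      pairs[[ci]] <- data.frame(test_id = tests[i], comparator_id = id)
    }
  }
  comps <- vapply(compActs, function(df) df$drug_id[1], character(1))
  pairs <- do.call(rbind, pairs)
  targetActions <- do.call(rbind, c(testActs, compActs))
  allDrugs <- c(tests, comps)
  hasTarget <- matrix(FALSE, length(allDrugs), cfg$nTargets,
                      dimnames = list(allDrugs, targets))
  hasTarget[cbind(match(targetActions$drug_id, allDrugs),
                  match(targetActions$target_id, targets))] <- TRUE

  # -- biologic flags and approval dates
  sub("registry")
  isBio <- stats::runif(length(allDrugs)) < cfg$biologicFraction
  names(isBio) <- allDrugs
  testDates <- as.Date("2008-01-01") +
    floor(stats::runif(length(tests)) * as.numeric(as.Date("2013-12-31") - as.Date("2008-01-01")))
  pre1982 <- c(rep(FALSE, length(tests)),
               stats::runif(length(comps)) < cfg$pre1982Fraction)
  y0 <- cfg$approvalYearRange[1]; y1 <- cfg$approvalYearRange[2]
  compDates <- as.Date(sprintf("%d-01-01", y0)) +
    floor(stats::runif(length(comps)) *
            as.numeric(as.Date(sprintf("%d-12-31", y1)) - as.Date(sprintf("%d-01-01", y0))))
  dates <- c(testDates, compDates)
  dates[pre1982] <- NA
  drugs <- data.frame(
    drug_id = allDrugs,
    role = c(rep("test", length(tests)), rep("comparator", length(comps))),
    smiles = NA_character_, is_biologic = unname(isBio),
    approval_date = dates, pre1982 = pre1982, stringsAsFactors = FALSE)

  # -- fingerprints: per-target bit templates, OR-combined, plus bit noise
  sub("fingerprints")
  templates <- matrix(stats::runif(cfg$nTargets * 166) < 0.25, cfg$nTargets, 166)
  sm <- allDrugs[!isBio]
  fps <- matrix(0, length(sm), 166, dimnames = list(sm, NULL))
  for (id in sm) {
    tg <- which(hasTarget[id, ])
    base <- if (length(tg)) as.numeric(colSums(templates[tg, , drop = FALSE]) > 0)
            else numeric(166)
    # 12% per-bit noise puts same-class Tanimoto near 0.5 on average while
    # keeping shared-target pairs well above unrelated ones
    noise <- stats::runif(166) < 0.12
    fps[id, ] <- abs(base - noise)
  }

  # -- planted target-event associations
  sub("planting")
  testCarriers <- colSums(hasTarget[tests, , drop = FALSE])
  # class-defining targets: prefer those carried by a substantial fraction
  # of the test drugs, falling back to the >= 2 eligibility minimum
  minCarry <- max(2, ceiling(0.15 * cfg$nTestDrugs))
  candidates <- targets[testCarriers >= minCarry]
  if (!length(candidates)) candidates <- targets[testCarriers >= 2]
  truth <- data.frame(ae_group = character(), target_id = character())
  if (cfg$nPlanted > 0) {
    if (!length(candidates))
      .stopUser("no target is carried by >= 2 test drugs; cannot plant associations")
    planted <- groups[sample.int(cfg$nAeGroups, cfg$nPlanted)]
    # well-characterized target-event relationships belong to class-defining
    # targets: weight driver choice by how many test drugs carry the target
    w <- testCarriers[match(candidates, targets)]^2
    drivers <- candidates[sample.int(length(candidates), cfg$nPlanted,
                                     replace = TRUE, prob = w / sum(w))]
    truth <- data.frame(ae_group = planted, target_id = drivers,
                        stringsAsFactors = FALSE)
  }

  # -- label matrices
  probFor <- function(ids) {
    p <- matrix(cfg$pEventBaseline, length(ids), cfg$nAeGroups,
                dimnames = list(ids, groups))
    for (r in seq_len(nrow(truth)))
      p[hasTarget[ids, truth$target_id[r]], truth$ae_group[r]] <- cfg$pEventGivenTarget
    p
  }
  sub("labels_comparator")
  pC <- probFor(comps)
  compLab <- (matrix(stats::runif(length(pC)), nrow(pC)) < pC) + 0
  dimnames(compLab) <- dimnames(pC)
  sub("labels_test")
  pT <- probFor(tests)
  testRef <- (matrix(stats::runif(length(pT)), nrow(pT)) < pT) + 0
  dimnames(testRef) <- dimnames(pT)
  sub("labels_approval")
  del <- matrix(stats::runif(length(testRef)), nrow(testRef)) < cfg$slcDeletionRate
  testAppr <- testRef * (1 - (testRef == 1 & del))

  # -- literature: comparator labels with independent flips, per pair
  sub("literature")
  litBase <- compLab[pairs$comparator_id, , drop = FALSE]
  flips <- matrix(stats::runif(length(litBase)), nrow(litBase)) < cfg$literatureFlipRate
  litMat <- abs(litBase - flips)
  lit <- data.frame(
    comparator_id = rep(pairs$comparator_id, times = cfg$nAeGroups),
    test_id = rep(pairs$test_id, times = cfg$nAeGroups),
    ae_group = rep(groups, each = nrow(pairs)),
    present = as.numeric(litMat), stringsAsFactors = FALSE)
  lit <- lit[lit$present == 1, , drop = FALSE]  # absent records default to 0
  rownames(lit) <- NULL

  vocab <- AEVocabulary(groups, groups)
  ds <- AEDataset(drugs = drugs, targetActions = targetActions,
                  vocabulary = vocab,
                  labels = list(comparator_at_test_approval = compLab,
                                test_at_approval = testAppr,
                                test_reference = testRef),
                  literature = lit, pairs = pairs, fingerprints = fps)
  list(dataset = ds, truth = truth)
}

#' Write a synthetic dataset bundle to disk
#'
#' Writes the full CSV bundle consumed by [readAEDataset()], plus
#' \code{planted_truth.csv}.
#'
#' @param sim result of [generateDataset()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticBundle <- function(sim, dir) {
  writeAEDataset(sim$dataset, dir)
  utils::write.csv(sim$truth, file.path(dir, "planted_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
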