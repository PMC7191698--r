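# Hand-built miniature dataset used across tests: one test drug (T1) with two
# comparators (C1 small molecule, C2 biologic), three adverse-event groups.
tinyVocabulary <- function() {
  AEVocabulary(c("HEADACHE", "NAUSEA", "RASH"),
               c("HEADACHE", "NAUSEA", "RASH"))
}

tinyDataset <- function() {
  drugs <- data.frame(
    drug_id = c("T1", "C1", "C2"),
    role = c("test", "comparator", "comparator"),
    smiles = NA_character_,
    is_biologic = c(FALSE, FALSE, TRUE),
    approval_date = as.Date(c("2010-01-01", "2000-06-15", NA)),
    pre1982 = c(FALSE, FALSE, TRUE))
  ta <- data.frame(drug_id = c("T1", "T1", "C1", "C2"),
                   target_id = c("TGT1", "TGT2", "TGT1", "TGT1"),
                   action = c(1L, -1L, 1L, 1L))
  lab <- function(ids, m) matrix(m, length(ids), 3, byrow = TRUE,
                                 dimnames = list(ids, c("HEADACHE", "NAUSEA", "RASH")))
  labels <- list(
    comparator_at_test_approval = lab(c("C1", "C2"), c(1, 0, 1,
                                                       0, 1, 0)),
    test_at_approval = lab("T1", c(0, 0, 1)),
    test_reference = lab("T1", c(1, 0, 1)))
  lit <- data.frame(comparator_id = "C1", test_id = "T1",
                    ae_group = "HEADACHE", present = 1)
  pairs <- data.frame(test_id = c("T1", "T1"), comparator_id = c("C1", "C2"))
  fps <- matrix(0, 2, 166, dimnames = list(c("T1", "C1"), NULL))
  fps["T1", 1:8] <- 1
  fps["C1", 5:12] <- 1
  AEDataset(drugs = drugs, targetActions = ta, vocabulary = tinyVocabulary(),
            labels = labels, literature = lit, pairs = pairs,
            fingerprints = fps)
}

# small synthetic configuration that keeps property loops fast
smallConfig <- function(seed, ...) {
  args <- list(nTestDrugs = 8, comparatorsPerTest = c(1, 3), nTargets = 6,
               nAeGroups = 12, nPlanted = 4, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(syntheticConfig, args)
}
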