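test_that("tanimoto identities hold", {
  a <- c(1, 1, 0, 0); b <- c(0, 1, 1, 0)
  expect_equal(tanimoto(a, a), 1)                    # identity
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)        # disjoint
  expect_equal(tanimoto(a, b), 1 / 3)                # {1,2} vs {2,3}
  expect_equal(tanimoto(rep(0, 4), rep(0, 4)), 0)    # 0/0 convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("tanimoto matches a brute-force popcount oracle on random pairs", {
  set.seed(42)
  for (i in 1:25) {
    a <- rbinom(166, 1, runif(1, 0.05, 0.5))
    b <- rbinom(166, 1, runif(1, 0.05, 0.5))
    expect_identical(tanimoto(a, b), popcountTanimoto(a, b))
    expect_identical(tanimoto(a, b), tanimoto(b, a))  # symmetry
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
  }
})

test_that("cosine similarity identities hold", {
  expect_equal(cosineSimilarity(c(1, 0, -1), c(1, 0, -1)), 1)
  expect_equal(cosineSimilarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosineSimilarity(c(1, 0, -1), c(1, 0, 0)), 1 / sqrt(2))
  u <- c(1, -1, 0, 1)
  expect_equal(cosineSimilarity(u, -u), -1)
  expect_error(cosineSimilarity(c(0, 0), c(1, 0)), "all-zero")
  # |cosine| = 1 iff parallel
  set.seed(7)
  for (i in 1:10) {
    u <- sample(c(-1, 0, 1), 5, replace = TRUE)
    v <- sample(c(-1, 0, 1), 5, replace = TRUE)
    if (all(u == 0) || all(v == 0)) next
    cs <- cosineSimilarity(u, v)
    expect_lte(abs(cs), 1 + 1e-12)
    if (abs(abs(cs) - 1) < 1e-12)
      expect_true(all(outer(u, v) == outer(v, u)))  # rank-1 => parallel
  }
})

test_that("target vectors are trivalent over the universe", {
  ta <- data.frame(drug_id = c("A", "B"), target_id = c("T1", "T2"),
                   action = c(1L, -1L))
  expect_equal(unname(targetVector("A", ta, c("T1", "T2", "T3"))), c(1, 0, 0))
  expect_equal(unname(targetVector("B", ta, c("T1", "T2", "T3"))), c(0, -1, 0))
  expect_equal(unname(targetVector("C", ta, c("T1", "T2", "T3"))), c(0, 0, 0))
  expect_error(targetVector("A", ta, c("T2", "T3")), "outside the universe")
})

test_that("structural similarity uses fingerprints and the biologic sentinel", {
  ds <- tinyDataset()
  expect_equal(structuralSimilarity(ds, "T1", "T1"), 1)      # self-similarity
  expect_equal(structuralSimilarity(ds, "T1", "C2"), -1)     # biologic pair
  # T1 bits 1:8, C1 bits 5:12 -> intersection 4, union 12
  expect_equal(structuralSimilarity(ds, "T1", "C1"), 4 / 12)
  expect_error(structuralSimilarity(ds, "T1", "nope"), "nope")
})

test_that("MACCS fingerprinting of SMILES is deterministic, 166 bits", {
  smi <- utils::read.csv(system.file("extdata", "example_smiles.csv",
                                     package = "targetAE"))
  fp1 <- maccsFingerprint(stats::setNames(smi$smiles[1:3], smi$drug_id[1:3]))
  fp2 <- maccsFingerprint(stats::setNames(smi$smiles[1:3], smi$drug_id[1:3]))
  expect_identical(fp1, fp2)
  expect_equal(dim(fp1), c(3L, 166L))
  expect_true(all(fp1 %in% c(0, 1)))
  # identical molecules score Tanimoto 1 downstream
  fpc <- maccsFingerprint(c("CCO", "CCO"))
  expect_equal(tanimoto(fpc[1, ], fpc[2, ]), 1)
  expect_error(maccsFingerprint(""), "empty")
  # structurally close pair scores higher than a dissimilar one
  t_nsaid <- tanimoto(fp1["ibuprofen", ], fp1["naproxen", ])
  t_far <- tanimoto(fp1["ibuprofen", ], fp1["aspirin", ])
  expect_gt(t_nsaid, 0); expect_lte(t_nsaid, 1)
  expect_gt(t_nsaid, t_far * 0.99)
})

test_that("a pluggable backend bypasses the chemistry toolkit", {
  fake <- function(smiles) matrix(1, length(smiles), 166)
  fp <- maccsFingerprint(c(a = "CCO"), backend = fake)
  expect_equal(unname(fp[1, ]), rep(1, 166))
  bad <- function(smiles) matrix(1, length(smiles), 10)
  expect_error(maccsFingerprint("CCO", backend = bad), "166")
})
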