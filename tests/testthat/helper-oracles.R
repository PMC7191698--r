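# Independent oracles, written as plain probability arithmetic with loops so
# they share no code path with the package implementation.

# brute-force Tanimoto by explicit popcount
popcountTanimoto <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1 || b[i] == 1) uni <- uni + 1
  }
  if (uni == 0) 0 else inter / uni
}

# exhaustive Naive Bayes posterior for tables whose continuous features are
# constant (their class-conditional densities cancel): per row, prior times
# the product of empirical categorical likelihoods, normalized over the two
# classes; exact-zero cells are replaced by `guard` at use, matching the
# model definition
nbOracleBinary <- function(train, newdata, guard = 1e-3) {
  n <- nrow(train)
  n1 <- sum(train$label == 1); n0 <- n - n1
  prior1 <- n1 / n
  if (n1 == 0) return(rep(0, nrow(newdata)))
  if (n0 == 0) return(rep(1, nrow(newdata)))
  feats <- c("f_label", "f_literature")
  sapply(seq_len(nrow(newdata)), function(i) {
    like1 <- prior1; like0 <- 1 - prior1
    for (f in feats) {
      v <- newdata[[f]][i]
      p1 <- sum(train$label == 1 & train[[f]] == v) / n1
      p0 <- sum(train$label == 0 & train[[f]] == v) / n0
      if (p1 == 0) p1 <- guard
      if (p0 == 0) p0 <- guard
      like1 <- like1 * p1; like0 <- like0 * p0
    }
    like1 / (like1 + like0)
  })
}

# turn a matrix of binary feature/label rows into a feature data.frame with
# constant continuous features (so only the categorical part matters)
asFeatureRows <- function(m, group = "AE_TOY") {
  data.frame(test_id = paste0("T", seq_len(nrow(m))),
             comparator_id = paste0("C", seq_len(nrow(m))),
             ae_group = group,
             f_label = m[, 1], f_literature = m[, 2],
             f_structure = 0.5, f_target = 0.5, f_market_years = 10,
             label = m[, 3])
}
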