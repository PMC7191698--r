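# Structural (MACCS/Tanimoto) and target (trivalent cosine) similarity kernels.

#' MACCS 166-bit structural fingerprint of a molecule
#'
#' Converts a SMILES string to the standard 166-key MACCS fingerprint. The
#' default backend delegates to OpenBabel via ChemmineOB (OpenBabel stores the
#' keys in a 256-bit container; bits 1-166 carry the keys and are returned).
#' Alternative backends can be injected through \code{backend}, which must map
#' a character vector of SMILES to a 0/1 matrix with 166 columns - this keeps
#' the chemistry toolkit out of code paths (and tests) that supply
#' precomputed fingerprints.
#'
#' @param smiles character vector of SMILES strings.
#' @param backend function(character) -> 0/1 matrix with 166 columns, or NULL
#'   for the OpenBabel default.
#' @return 0/1 matrix, one row per input (rownames = names(smiles) if set),
#'   166 columns.
#' @export
maccsFingerprint <- function(smiles, backend = NULL) {
  if (!length(smiles)) .stopUser("no SMILES given")
  bad <- is.na(smiles) | !nzchar(trimws(smiles))
  if (any(bad))
    .stopUser("empty or missing SMILES at position(s): %s",
              paste(which(bad), collapse = ", "))
  if (is.null(backend)) backend <- .openbabelMaccs
  m <- backend(as.character(smiles))
  if (!is.matrix(m) || ncol(m) != 166L || nrow(m) != length(smiles))
    stop("fingerprint backend must return one 166-bit row per molecule")
  storage.mode(m) <- "numeric"
  rownames(m) <- names(smiles)
  m
}

.openbabelMaccs <- function(smiles) {
  for (pkg in c("ChemmineR", "ChemmineOB"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop(sprintf("package '%s' is required for SMILES fingerprinting; ",
                   pkg), "supply precomputed fingerprints or a custom backend")
  nm <- sprintf("mol%03d", seq_along(smiles))
  sdf <- tryCatch(ChemmineR::smiles2sdf(stats::setNames(smiles, nm)),
                  error = function(e)
                    .stopUser("unparsable SMILES among: %s (%s)",
                              paste(smiles, collapse = ", "), conditionMessage(e)))
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok))
    .stopUser("unparsable SMILES: %s", paste(smiles[!ok], collapse = ", "))
  fp <- ChemmineR::fingerprintOB(sdf, "MACCS")
  # FPset's as.matrix method is S4; fetch it without attaching ChemmineR
  m <- methods::getMethod("as.matrix", "FPset")(fp)
  m[, 1:166, drop = FALSE]
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|} over the fingerprint bits. Two all-zero
#' fingerprints (a 0/0 case the formula leaves undefined) score 0.
#'
#' @param a,b 0/1 vectors of equal length (or single-row matrices).
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0), c(0, 1, 1))  # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    .stopUser("fingerprint lengths differ (%d vs %d)", length(a), length(b))
  if (!all(c(a, b) %in% c(0, 1))) .stopUser("fingerprints must be binary")
  union <- sum(a + b > 0)
  if (union == 0) return(0)
  sum(a + b == 2) / union
}

#' Structural similarity between two drugs
#'
#' Tanimoto similarity of the drugs' MACCS fingerprints when both are small
#' molecules. When either drug is a biologic no structure-based score exists
#' and the sentinel value -1 is returned; the sentinel is deliberately an
#' ordinary numeric value so that downstream classifiers treat "biologic
#' pair" as an informative feature level rather than missing data.
#'
#' @param dataset an [AEDataset-class].
#' @param drugA,drugB drug ids.
#' @param backend optional fingerprint backend (see [maccsFingerprint()]) used
#'   when a drug has SMILES but no precomputed fingerprint.
#' @return numeric similarity in \[0, 1\], or exactly -1 for a biologic pair.
#' @export
structuralSimilarity <- function(dataset, drugA, drugB, backend = NULL) {
  d <- dataset@drugs
  rows <- match(c(drugA, drugB), d$drug_id)
  if (anyNA(rows))
    .stopUser("unknown drug id(s): %s",
              paste(c(drugA, drugB)[is.na(rows)], collapse = ", "))
  if (any(d$is_biologic[rows])) return(-1)
  fp <- lapply(c(drugA, drugB), function(id) .drugFingerprint(dataset, id, backend))
  tanimoto(fp[[1]], fp[[2]])
}

.drugFingerprint <- function(dataset, id, backend = NULL) {
  fps <- dataset@fingerprints
  if (id %in% rownames(fps)) return(fps[id, ])
  smi <- dataset@drugs$smiles[match(id, dataset@drugs$drug_id)]
  if (is.na(smi))
    .stopUser("drug %s has neither a precomputed fingerprint nor SMILES", id)
  maccsFingerprint(stats::setNames(smi, id), backend = backend)[1, ]
}

#' Trivalent target-action vector of a drug
#'
#' Over an ordered target universe: +1 where the drug activates the target
#' (agonist), -1 where it inhibits it (antagonist), 0 where it has no
#' pharmacological activity.
#'
#' @param drugId drug id.
#' @param targets an [AEDataset-class] or target-action data.frame.
#' @param universe ordered character vector of target ids; defaults to all
#'   targets in the table, sorted, so vectors are reproducible across runs.
#' @return named integer vector over \code{universe}.
#' @export
targetVector <- function(drugId, targets, universe = NULL) {
  ta <- if (is(targets, "AEDataset")) targets@targetActions else as.data.frame(targets)
  if (is.null(universe)) universe <- sort(unique(ta$target_id))
  mine <- ta[ta$drug_id == drugId, , drop = FALSE]
  outside <- setdiff(mine$target_id, universe)
  if (length(outside))
    .stopUser("target(s) of %s outside the universe: %s", drugId,
              paste(outside, collapse = ", "))
  v <- stats::setNames(integer(length(universe)), universe)
  v[mine$target_id] <- as.integer(mine$action)
  v
}

#' Cosine similarity between two target-action vectors
#'
#' \eqn{(u \cdot v) / (\lVert u\rVert \lVert v\rVert)}. Because comparator
#' drugs share at least one same-sign action with their test drug, an
#' all-zero vector signals malformed input and is an error (its norm is
#' zero).
#'
#' @param u,v numeric vectors of equal length.
#' @return cosine similarity in \[-1, 1\].
#' @examples
#' cosineSimilarity(c(1, 0, -1), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v))
    .stopUser("vector lengths differ (%d vs %d)", length(u), length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    .stopUser("cosine similarity undefined for an all-zero target vector")
  # clamp rounding spill just past +/-1
  min(max(sum(u * v) / (nu * nv), -1), 1)
}
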