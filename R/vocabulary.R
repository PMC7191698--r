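#' Construct an adverse-event vocabulary
#'
#' @param preferredTerms character vector of MedDRA Preferred Terms.
#' @param groups character vector (same length) of adverse-event group names;
#'   each Preferred Term must map to exactly one group. Both are uppercased.
#' @return an [AEVocabulary-class] object.
#' @examples
#' v <- AEVocabulary(c("PANCREATITIS", "PANCREATITIS ACUTE"),
#'                   c("PANCREATITIS", "PANCREATITIS"))
#' aeGroups(v)
#' @export
AEVocabulary <- function(preferredTerms, groups) {
  if (length(preferredTerms) != length(groups))
    .stopUser("preferredTerms and groups must have the same length")
  m <- toupper(trimws(as.character(groups)))
  names(m) <- toupper(trimws(as.character(preferredTerms)))
  new("AEVocabulary", mapping = m)
}

#' The packaged 135-event vocabulary
#'
#' Loads the packaged grouping of 167 MedDRA Preferred Terms into 135
#' adverse-event groups of high priority to regulatory safety review,
#' in which mechanistically similar, interchangeably reported terms are
#' collapsed into one event.
#'
#' @return an [AEVocabulary-class] with 167 Preferred Terms and 135 groups.
#' @examples
#' v <- defaultVocabulary()
#' length(preferredTerms(v))  # 167
#' length(aeGroups(v))        # 135
#' @export
defaultVocabulary <- function() {
  path <- system.file("extdata", "ae_vocabulary.csv", package = "targetAE",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  AEVocabulary(df$preferred_term, df$ae_group)
}

#' @describeIn AEVocabulary-class adverse-event group names (sorted, unique).
#' @param x an \code{AEVocabulary}.
#' @export
aeGroups <- function(x) sort(unique(unname(x@mapping)))

#' @describeIn AEVocabulary-class Preferred Terms in the vocabulary.
#' @export
preferredTerms <- function(x) names(x@mapping)

#' @describeIn AEVocabulary-class the group a Preferred Term belongs to.
#' @param pt character vector of Preferred Terms.
#' @export
groupOf <- function(x, pt) {
  pt <- toupper(trimws(pt))
  missing <- setdiff(pt, names(x@mapping))
  if (length(missing))
    .stopUser("Preferred Term(s) not in vocabulary: %s", paste(missing, collapse = ", "))
  unname(x@mapping[pt])
}

setMethod("show", "AEVocabulary", function(object) {
  cat(sprintf("AEVocabulary: %d Preferred Terms in %d adverse-event groups\n",
              length(object@mapping), length(unique(object@mapping))))
})

#' Collapse Preferred-Term presence to adverse-event group presence
#'
#' A group is present for a drug if any of its member Preferred Terms is
#' present (logical OR), so interchangeable terms count once.
#'
#' @param ptPresence 0/1 matrix, rows = drugs (rownames drug ids),
#'   columns = Preferred Terms.
#' @param vocab an [AEVocabulary-class].
#' @return 0/1 matrix with the same rows and one column per group that has at
#'   least one member column in the input; columns ordered by group name.
#' @examples
#' v <- AEVocabulary(c("PANCREATITIS", "PANCREATITIS ACUTE"),
#'                   c("PANCREATITIS", "PANCREATITIS"))
#' m <- matrix(c(1, 0), 1, 2,
#'             dimnames = list("drugA", c("PANCREATITIS", "PANCREATITIS ACUTE")))
#' mapPTsToGroups(m, v)  # PANCREATITIS = 1
#' @export
mapPTsToGroups <- function(ptPresence, vocab) {
  if (!is.matrix(ptPresence)) ptPresence <- as.matrix(ptPresence)
  if (is.null(colnames(ptPresence)))
    .stopUser("ptPresence must have Preferred Terms as column names")
  if (length(ptPresence) && !all(ptPresence %in% c(0, 1)))
    .stopUser("ptPresence must be binary (0/1)")
  pts <- toupper(trimws(colnames(ptPresence)))
  unmapped <- setdiff(pts, names(vocab@mapping))
  if (length(unmapped))
    .stopUser("Preferred Term(s) not in vocabulary: %s",
              paste(unmapped, collapse = ", "))
  grp <- unname(vocab@mapping[pts])
  out_groups <- sort(unique(grp))
  out <- matrix(0, nrow(ptPresence), length(out_groups),
                dimnames = list(rownames(ptPresence), out_groups))
  for (g in out_groups) {
    cols <- which(grp == g)
    out[, g] <- as.numeric(rowSums(ptPresence[, cols, drop = FALSE]) > 0)
  }
  out
}
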