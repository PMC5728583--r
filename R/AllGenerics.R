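#' Are two character values shared?
#'
#' @param a,b [ChaetoValue-class] objects.
#' @return `"not_comparable"` if either value is unknown, otherwise
#'   `"shared"` when the closed count ranges `[min, max]` intersect and
#'   `"unshared"` when they are disjoint. Mesochaeta extras and letter
#'   flags never influence sharing.
#' @examples
#' valuesShared(chaetoValue(5), chaetoValue(4, 8))  # "shared"
#' valuesShared(chaetoValue(0), chaetoValue(1))     # "unshared"
#' valuesShared(unknownValue(), chaetoValue(7))     # "not_comparable"
#' @export
setGeneric("valuesShared", function(a, b) standardGeneric("valuesShared"))

#' Unshared-character dissimilarity between two profiles
#'
#' Counts the diagnostic characters whose recorded count ranges do not
#' overlap between two species. Characters unknown in either profile are
#' excluded from both numerator and denominator.
#'
#' @param p,q [ChaetoProfile-class] objects.
#' @return A [ChaetoDissimilarity-class].
#' @export
setGeneric("dissimilarity", function(p, q) standardGeneric("dissimilarity"))

#' All pairwise dissimilarities of a character matrix
#'
#' @param x a [ChaetoMatrix-class] with at least two profiles.
#' @return A [ChaetoDissimilarityMatrix-class].
#' @export
setGeneric("dissimilarityMatrix",
           function(x) standardGeneric("dissimilarityMatrix"))

#' Export a character matrix as a NEXUS CHARACTERS block
#'
#' @param x a [ChaetoMatrix-class].
#' @param file optional path; when given the document is written there.
#' @param ... unused.
#' @return The NEXUS document as a single character string (invisibly
#'   when `file` is given).
#' @export
setGeneric("exportNexus", function(x, file = NULL, ...)
  standardGeneric("exportNexus"))

#' Species names of a container
#' @param x a [ChaetoMatrix-class] or [ChaetoDissimilarityMatrix-class].
#' @return character vector of species names.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Source formula string of a profile
#' @param x a [ChaetoProfile-class].
#' @return character(1), `NA` when the profile was not built from a
#'   formula.
#' @export
setGeneric("formulaText", function(x) standardGeneric("formulaText"))

#' Character states of a profile as a data frame
#' @param x a [ChaetoProfile-class].
#' @return data.frame with columns `character`, `min`, `max`, `mcExtra`,
#'   `flags`, `observed`.
#' @export
setGeneric("characterValues", function(x) standardGeneric("characterValues"))

#' Unshared-character counts of a dissimilarity matrix
#' @param x a [ChaetoDissimilarityMatrix-class].
#' @return integer matrix.
#' @export
setGeneric("dissimCounts", function(x) standardGeneric("dissimCounts"))

#' Rounded dissimilarity percentages of a dissimilarity matrix
#' @param x a [ChaetoDissimilarityMatrix-class].
#' @return numeric matrix.
#' @export
setGeneric("dissimPercent", function(x) standardGeneric("dissimPercent"))
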