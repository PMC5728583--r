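#' @import methods
NULL

#' Single diagnostic character state
#'
#' A `ChaetoValue` records one chaetotaxic character for one species or
#' specimen: either *unknown*, or an observed macrochaeta count range
#' `[min, max]` (chaetae), optionally with an extra mesochaeta count (from
#' starred parentheticals such as `0(2*)`) and single-letter annotation
#' flags (such as the `b` in `1b`).
#'
#' @slot unknown logical(1); `TRUE` when the state was not recorded.
#' @slot min,max integer(1) chaetae; `max >= min`. `NA` when unknown.
#' @slot mcExtra integer(1); additional mesochaetae, `NA` when absent.
#' @slot flags character; zero or more single-letter annotations.
#'
#' @seealso [chaetoValue()], [unknownValue()], [valuesShared()]
#' @export
setClass("ChaetoValue",
  representation(
    unknown = "logical",
    min     = "integer",
    max     = "integer",
    mcExtra = "integer",
    flags   = "character"
  ),
  prototype(unknown = FALSE, min = 0L, max = 0L,
            mcExtra = NA_integer_, flags = character())
)

setValidity("ChaetoValue", function(object) {
  msg <- character()
  if (length(object@unknown) != 1L)
    msg <- c(msg, "'unknown' must be a single logical")
  if (isTRUE(object@unknown)) {
    if (!is.na(object@min) || !is.na(object@max))
      msg <- c(msg, "unknown state carries no counts")
    if (!is.na(object@mcExtra) || length(object@flags))
      msg <- c(msg, "unknown state carries no annotations")
  } else {
    if (is.na(object@min) || is.na(object@max))
      msg <- c(msg, "observed state requires counts")
    else {
      if (object@min < 0L) msg <- c(msg, "counts must be non-negative")
      if (object@max < object@min) msg <- c(msg, "max must be >= min")
    }
    if (!is.na(object@mcExtra) && object@mcExtra < 0L)
      msg <- c(msg, "mcExtra must be non-negative")
    if (length(object@flags) && any(!grepl("^[A-Za-z]$", object@flags)))
      msg <- c(msg, "flags must be single letters")
  }
  if (length(msg)) msg else TRUE
})

#' Parsed simplified Mc formula
#'
#' A `MacroFormula` is the structured form of a "simplified Mc formula"
#' string: an ordered list of body segments (canonically head, Th II,
#' Abd II, Abd III, Abd IV), each an ordered list of fields. Every field is
#' a [ChaetoValue-class] with an optional unpaired-chaeta prefix (the
#' `1_0_` marker, permitted on Abd IV only).
#'
#' Fields are stored column-wise in a data frame (`segment`, `field`,
#' `prefix`, `unknown`, `min`, `max`, `mcExtra`, `flags`) so formulas can
#' be compared, reserialized and mapped to character profiles cheaply.
#'
#' @slot fields data.frame with one row per field, columns as above.
#' @slot warnings character; deviations recorded during lenient parsing.
#' @slot strict logical(1); whether the formula has the canonical
#'   (6, 2, 2, 3, 5) segment shape.
#' @seealso [parseFormula()], [formatFormula()], [formulaToProfile()]
#' @export
setClass("MacroFormula",
  representation(
    fields   = "data.frame",
    warnings = "character",
    strict   = "logical"
  )
)

setValidity("MacroFormula", function(object) {
  fd <- object@fields
  need <- c("segment", "field", "prefix", "unknown", "min", "max",
            "mcExtra", "flags")
  if (!all(need %in% names(fd)))
    return(paste("fields must have columns:", paste(need, collapse = ", ")))
  if (nrow(fd) == 0L) return("a formula needs at least one field")
  obs <- !fd$unknown
  if (any(obs & (is.na(fd$min) | is.na(fd$max))))
    return("observed fields require counts")
  if (any(obs & fd$max < fd$min, na.rm = TRUE))
    return("max must be >= min in every observed field")
  if (any(!obs & (!is.na(fd$min) | !is.na(fd$mcExtra) | nzchar(fd$flags))))
    return("unknown fields carry no counts or annotations")
  if (any(!is.na(fd$prefix) & fd$prefix < 0L))
    return("unpaired prefixes must be non-negative")
  TRUE
})

#' Species profile over the 22 diagnostic characters
#'
#' A `ChaetoProfile` holds a species' states for the 22-character
#' diagnostic system (head areas H1-H6, Th II areas T1-T2, claw teeth,
#' Abd II-IV areas A1-A10 with unpaired/lateral splits), stored as
#' parallel vectors of length 22.
#'
#' @slot name character(1); species name.
#' @slot min,max integer(22); count ranges, `NA` where unknown.
#' @slot mcExtra integer(22); extra mesochaetae, `NA` where absent.
#' @slot flags character(22); letter annotations, `""` where absent.
#' @slot observed logical(22); `FALSE` marks unknown characters.
#' @slot formulaText character(1); source formula string or `NA`.
#' @seealso [builtinMatrix()], [formulaToProfile()], [dissimilarity()]
#' @export
setClass("ChaetoProfile",
  representation(
    name        = "character",
    min         = "integer",
    max         = "integer",
    mcExtra     = "integer",
    flags       = "character",
    observed    = "logical",
    formulaText = "character"
  )
)

setValidity("ChaetoProfile", function(object) {
  n <- 22L
  if (length(object@name) != 1L || !nzchar(object@name))
    return("profile needs a non-empty name")
  lens <- c(length(object@min), length(object@max), length(object@mcExtra),
            length(object@flags), length(object@observed))
  if (any(lens != n))
    return(sprintf("profiles carry exactly %d characters", n))
  obs <- object@observed
  if (any(obs & (is.na(object@min) | is.na(object@max))))
    return("observed characters require counts")
  if (any(obs & object@max < object@min, na.rm = TRUE))
    return("max must be >= min in every observed character")
  if (any(!obs & (!is.na(object@min) | !is.na(object@mcExtra) |
                  nzchar(object@flags))))
    return("unknown characters carry no counts or annotations")
  TRUE
})

#' Diagnostic character matrix
#'
#' A `ChaetoMatrix` is an ordered collection of [ChaetoProfile-class]
#' objects with unique species names: the in-memory form of a species-by-
#' character diagnostic table.
#'
#' @slot profiles named list of `ChaetoProfile`.
#' @seealso [builtinMatrix()], [readCharacterMatrix()],
#'   [dissimilarityMatrix()], [exportNexus()]
#' @export
setClass("ChaetoMatrix", representation(profiles = "list"))

setValidity("ChaetoMatrix", function(object) {
  ps <- object@profiles
  if (!length(ps)) return("a matrix needs at least one profile")
  if (!all(vapply(ps, is, logical(1), "ChaetoProfile")))
    return("all elements must be ChaetoProfile objects")
  nm <- unname(vapply(ps, function(p) p@name, character(1)))
  if (anyDuplicated(nm)) return("duplicate species names")
  if (!identical(names(ps), nm)) return("list names must equal profile names")
  TRUE
})

#' Pairwise dissimilarity between two species profiles
#'
#' Result of comparing two [ChaetoProfile-class] objects character by
#' character: the number of comparable characters (unknowns excluded), the
#' unshared-character count, the rounded percentage, and the indices of
#' the mismatching characters.
#'
#' @slot speciesA,speciesB character(1).
#' @slot compared,unsharedCount integer(1).
#' @slot percent numeric(1); `round(100 * unshared / compared)`, half away
#'   from zero.
#' @slot mismatches integer; ascending character indices.
#' @seealso [dissimilarity()]
#' @export
setClass("ChaetoDissimilarity",
  representation(
    speciesA      = "character",
    speciesB      = "character",
    compared      = "integer",
    unsharedCount = "integer",
    percent       = "numeric",
    mismatches    = "integer"
  )
)

setValidity("ChaetoDissimilarity", function(object) {
  if (object@unsharedCount < 0L || object@unsharedCount > object@compared ||
      object@compared > 22L)
    return("need 0 <= unshared <= compared <= 22")
  if (length(object@mismatches) != object@unsharedCount)
    return("mismatch list must have unsharedCount entries")
  if (is.unsorted(object@mismatches, strictly = TRUE) &&
      length(object@mismatches) > 1L)
    return("mismatches must be strictly ascending")
  TRUE
})

#' All pairwise dissimilarities of a character matrix
#'
#' Symmetric container for the [dissimilarity()] of every species pair in
#' a [ChaetoMatrix-class]: count, percent and compared matrices plus the
#' per-pair mismatch ledgers.
#'
#' @slot species character; row/column order.
#' @slot counts,percent,compared numeric matrices with zero diagonal.
#' @slot pairs named list of [ChaetoDissimilarity-class] (one per
#'   unordered pair, names `"a|b"`).
#' @seealso [dissimilarityMatrix()], [auditPublished()]
#' @export
setClass("ChaetoDissimilarityMatrix",
  representation(
    species  = "character",
    counts   = "matrix",
    percent  = "matrix",
    compared = "matrix",
    pairs    = "list"
  )
)

setValidity("ChaetoDissimilarityMatrix", function(object) {
  n <- length(object@species)
  for (m in list(object@counts, object@percent, object@compared))
    if (!identical(dim(m), c(n, n))) return("matrix dimensions must match species")
  if (!isSymmetric(unname(object@counts))) return("counts must be symmetric")
  if (any(diag(object@counts) != 0)) return("diagonal must be zero")
  TRUE
})
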