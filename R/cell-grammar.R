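## Micro-grammar shared by Table-2-style matrix cells and formula fields:
##   "?"      unknown
##   "5"      min = max = 5
##   "2(9)"   min 2, max 9 (parenthetical without star = maximum)
##   "0(2*)"  min = max = 0, plus 2 mesochaetae (starred parenthetical)
##   "1b"     min = max = 1, letter flag "b"
## Formula fields may additionally carry an unpaired prefix "1_0_" which is
## handled by the formula parser, not here.

.CELL_RE <- "^([0-9]+)([A-Za-z]*)(?:\\(([0-9]+)(\\*?)\\))?$"

#' Construct a character value
#'
#' @param min,max non-negative chaeta counts; `max` defaults to `min`.
#' @param mcExtra optional extra mesochaeta count (starred parenthetical).
#' @param flags character vector of single-letter annotations.
#' @return A [ChaetoValue-class].
#' @examples
#' chaetoValue(2, 9)
#' chaetoValue(0, mcExtra = 2)
#' @export
chaetoValue <- function(min, max = min, mcExtra = NA, flags = character()) {
  new("ChaetoValue", unknown = FALSE, min = as.integer(min),
      max = as.integer(max), mcExtra = as.integer(mcExtra),
      flags = as.character(flags))
}

#' Construct an unknown character value
#' @return A [ChaetoValue-class] in the unknown state.
#' @export
unknownValue <- function() {
  new("ChaetoValue", unknown = TRUE, min = NA_integer_, max = NA_integer_,
      mcExtra = NA_integer_, flags = character())
}

## Parse one cell token into a list(unknown, min, max, mcExtra, flags).
## Returns NULL on malformed input so callers can name the position.
.parseCellToken <- function(token) {
  token <- gsub("[[:space:]]+", "", token)
  if (identical(token, "?"))
    return(list(unknown = TRUE, min = NA_integer_, max = NA_integer_,
                mcExtra = NA_integer_, flags = ""))
  m <- regmatches(token, regexec(.CELL_RE, token))[[1]]
  if (!length(m)) return(NULL)
  base <- as.integer(m[2])
  flags <- m[3]
  paren <- m[4]
  star <- nzchar(m[5])
  if (!nzchar(paren)) {
    list(unknown = FALSE, min = base, max = base, mcExtra = NA_integer_,
         flags = flags)
  } else if (star) {
    list(unknown = FALSE, min = base, max = base,
         mcExtra = as.integer(paren), flags = flags)
  } else {
    pmax <- as.integer(paren)
    if (pmax < base) return(NULL)  # a non-starred parenthetical is a maximum
    list(unknown = FALSE, min = base, max = pmax, mcExtra = NA_integer_,
         flags = flags)
  }
}

## Serialize the canonical cell form. 'parts' is a list as returned by
## .parseCellToken (or a row of a fields data.frame).
.formatCellToken <- function(unknown, min, max, mcExtra, flags) {
  if (isTRUE(unknown)) return("?")
  if (!is.na(mcExtra) && max > min)
    stop("cannot serialize a value with both a range maximum and a ",
         "mesochaeta extra", call. = FALSE)
  out <- paste0(min, flags)
  if (max > min) out <- paste0(out, "(", max, ")")
  else if (!is.na(mcExtra)) out <- paste0(out, "(", mcExtra, "*)")
  out
}

#' Parse a matrix-cell token into a character value
#'
#' @param cell a cell string such as `"5"`, `"2(9)"`, `"0(2*)"`, `"1b"`
#'   or `"?"`.
#' @return A [ChaetoValue-class].
#' @export
parseCharacterCell <- function(cell) {
  p <- .parseCellToken(cell)
  if (is.null(p)) stop("malformed cell token '", cell, "'", call. = FALSE)
  if (p$unknown) return(unknownValue())
  chaetoValue(p$min, p$max, p$mcExtra,
              if (nzchar(p$flags)) strsplit(p$flags, "")[[1]] else character())
}

#' Serialize a character value to its cell token
#' @param value a [ChaetoValue-class].
#' @return character(1) in the canonical cell syntax.
#' @export
formatCharacterCell <- function(value) {
  stopifnot(is(value, "ChaetoValue"))
  .formatCellToken(value@unknown, value@min, value@max, value@mcExtra,
                   paste(value@flags, collapse = ""))
}

## Vectorized sharing test on parallel range vectors; NA where either side
## is unobserved.
.rangesShared <- function(min1, max1, obs1, min2, max2, obs2) {
  out <- max1 >= min2 & max2 >= min1
  out[!(obs1 & obs2)] <- NA
  out
}

#' @describeIn valuesShared range-intersection rule on two values.
setMethod("valuesShared", signature("ChaetoValue", "ChaetoValue"),
  function(a, b) {
    if (a@unknown || b@unknown) return("not_comparable")
    if (a@max >= b@min && b@max >= a@min) "shared" else "unshared"
  })

setMethod("show", "ChaetoValue", function(object) {
  if (object@unknown) cat("ChaetoValue: ?\n")
  else cat("ChaetoValue:", formatCharacterCell(object), "\n")
})
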