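## Simplified Mc formula grammar:
##   segments separated by "/", fields by "-"; canonical shape
##   (head 6, Th II 2, Abd II 2, Abd III 3, Abd IV 5).
##   Field = [INT "_0_"] ( "?" | COUNT [flags] [ "(" INT ["*"] ")" ] ).
##   The "N_0_" prefix marks unpaired chaetae and is valid on Abd IV only.

.SEGMENT_NAMES <- c("head", "Th II", "Abd II", "Abd III", "Abd IV")
.SEGMENT_SHAPE <- c(6L, 2L, 2L, 3L, 5L)

.segmentLabel <- function(i, nseg) {
  if (nseg == length(.SEGMENT_NAMES)) {
    sprintf("segment %d (%s)", i, .SEGMENT_NAMES[i])
  } else sprintf("segment %d", i)
}

#' Parse a simplified Mc formula
#'
#' Parses the compact macrochaetotaxy notation (e.g.
#' `"5-3-0-2-1b-2/7-7/4-3/1-2-3/0-3-1-0-0(2*)"`) into a structured
#' [MacroFormula-class]. In `"strict"` mode the canonical segment shape
#' (6, 2, 2, 3, 5) is enforced and unpaired prefixes are accepted on
#' Abd IV only; in `"lenient"` mode deviations are recorded as warnings
#' attached to the result instead of failing (needed for formulas
#' compiled from older literature).
#'
#' @param text a non-empty formula string. Whitespace around separators
#'   is ignored; separators are ASCII hyphen and slash only.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A [MacroFormula-class].
#' @examples
#' f <- parseFormula("5-3-0-2-1b-2/7-7/4-3/1-2-3/0-3-1-0-0(2*)")
#' formatFormula(f)
#' @export
parseFormula <- function(text, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("formula text must be a non-empty string", call. = FALSE)
  text <- gsub("[[:space:]]+", "", text)

  segs <- strsplit(text, "/", fixed = TRUE)[[1]]
  if (!length(segs) || any(!nzchar(segs)))
    stop("empty segment in formula '", text, "'", call. = FALSE)
  nseg <- length(segs)
  warnings <- character()

  rows <- list()
  for (i in seq_along(segs)) {
    toks <- strsplit(segs[i], "-", fixed = TRUE)[[1]]
    if (!length(toks) || any(!nzchar(toks)))
      stop(.segmentLabel(i, nseg), ": empty field", call. = FALSE)
    for (j in seq_along(toks)) {
      tok <- toks[j]
      prefix <- NA_integer_
      pm <- regmatches(tok, regexec("^([0-9]+)_0_(.+)$", tok))[[1]]
      if (length(pm)) {
        prefix <- as.integer(pm[2])
        tok <- pm[3]
      }
      p <- .parseCellToken(tok)
      if (is.null(p))
        stop(.segmentLabel(i, nseg), ", field ", j,
             ": malformed token '", toks[j], "'", call. = FALSE)
      if (!is.na(prefix) && p$unknown)
        stop(.segmentLabel(i, nseg), ", field ", j,
             ": unpaired prefix on an unknown field", call. = FALSE)
      if (!is.na(prefix) && i != nseg) {
        msg <- paste0(.segmentLabel(i, nseg), ", field ", j,
                      ": unpaired prefix outside Abd IV")
        if (mode == "strict") stop(msg, call. = FALSE)
        warnings <- c(warnings, msg)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        segment = i, field = j, prefix = prefix, unknown = p$unknown,
        min = p$min, max = p$max, mcExtra = p$mcExtra, flags = p$flags,
        stringsAsFactors = FALSE)
    }
  }
  fields <- do.call(rbind, rows)

  shapeOk <- nseg == 5L &&
    identical(as.integer(tabulate(fields$segment, 5L)), .SEGMENT_SHAPE)
  if (!shapeOk) {
    if (nseg != 5L) {
      msg <- sprintf("formula has %d segments, expected 5", nseg)
      if (mode == "strict") stop(msg, call. = FALSE)
      warnings <- c(warnings, msg)
    } else {
      got <- tabulate(fields$segment, 5L)
      for (i in which(got != .SEGMENT_SHAPE)) {
        msg <- sprintf("%s has %d fields, expected %d",
                       .segmentLabel(i, 5L), got[i], .SEGMENT_SHAPE[i])
        if (mode == "strict") stop(msg, call. = FALSE)
        warnings <- c(warnings, msg)
      }
    }
  }

  new("MacroFormula", fields = fields, warnings = warnings,
      strict = shapeOk)
}

#' Serialize a formula to its canonical string
#'
#' Inverse of [parseFormula()]: `parseFormula(formatFormula(f))`
#' reproduces `f` field for field.
#'
#' @param f a [MacroFormula-class].
#' @return character(1) formula string.
#' @export
formatFormula <- function(f) {
  stopifnot(is(f, "MacroFormula"))
  fd <- f@fields
  toks <- vapply(seq_len(nrow(fd)), function(k) {
    tok <- .formatCellToken(fd$unknown[k], fd$min[k], fd$max[k],
                            fd$mcExtra[k], fd$flags[k])
    if (!is.na(fd$prefix[k])) tok <- paste0(fd$prefix[k], "_0_", tok)
    tok
  }, character(1))
  paste(vapply(split(toks, fd$segment), paste, character(1), collapse = "-"),
        collapse = "/")
}

setMethod("show", "MacroFormula", function(object) {
  cat("MacroFormula:", formatFormula(object), "\n")
  cat(sprintf("  %d segments, %d fields%s\n",
              max(object@fields$segment), nrow(object@fields),
              if (object@strict) " (canonical shape)" else ""))
  for (w in object@warnings) cat("  warning:", w, "\n")
})

#' Convert a strict formula to a 22-character species profile
#'
#' Maps formula fields onto the diagnostic character indices: head fields
#' to characters 1-6, Th II to 7-8, claw teeth (character 9, outside the
#' formula by construction) from `clawTeeth`, Abd II to 10-11, Abd III to
#' 12-14, Abd IV fields 1-2 to 15-16, and Abd IV fields 3-5 split into
#' unpaired prefix / paired count pairs (17, 18), (19, 20), (21, 22). An
#' absent prefix maps to zero; an unknown field leaves both of its
#' characters unknown.
#'
#' @param f a [MacroFormula-class] with the canonical shape.
#' @param clawTeeth character 9: a [ChaetoValue-class], a cell token such
#'   as `"3(4)"`, or a single count.
#' @param name species name for the profile.
#' @return A [ChaetoProfile-class].
#' @export
formulaToProfile <- function(f, clawTeeth, name) {
  stopifnot(is(f, "MacroFormula"))
  if (!f@strict)
    stop("profile mapping requires the canonical (6,2,2,3,5) shape",
         call. = FALSE)
  if (is.numeric(clawTeeth)) clawTeeth <- chaetoValue(clawTeeth)
  if (is.character(clawTeeth)) clawTeeth <- parseCharacterCell(clawTeeth)
  stopifnot(is(clawTeeth, "ChaetoValue"))

  mn <- mx <- mc <- rep(NA_integer_, 22L)
  fl <- rep("", 22L)
  obs <- rep(FALSE, 22L)
  fd <- f@fields

  putValue <- function(idx, row) {
    if (fd$unknown[row]) return()
    mn[idx] <<- fd$min[row]; mx[idx] <<- fd$max[row]
    mc[idx] <<- fd$mcExtra[row]; fl[idx] <<- fd$flags[row]
    obs[idx] <<- TRUE
  }
  putPrefix <- function(idx, row) {
    if (fd$unknown[row]) return()
    p <- fd$prefix[row]
    if (is.na(p)) p <- 0L
    mn[idx] <<- p; mx[idx] <<- p; obs[idx] <<- TRUE
  }

  rowAt <- function(seg, field) which(fd$segment == seg & fd$field == field)
  for (j in 1:6) putValue(j, rowAt(1L, j))
  putValue(7L, rowAt(2L, 1L)); putValue(8L, rowAt(2L, 2L))
  putValue(10L, rowAt(3L, 1L)); putValue(11L, rowAt(3L, 2L))
  for (j in 1:3) putValue(11L + j, rowAt(4L, j))
  putValue(15L, rowAt(5L, 1L)); putValue(16L, rowAt(5L, 2L))
  for (j in 3:5) {
    r <- rowAt(5L, j)
    putPrefix(17L + 2L * (j - 3L), r)
    putValue(18L + 2L * (j - 3L), r)
  }
  if (!clawTeeth@unknown) {
    mn[9L] <- clawTeeth@min; mx[9L] <- clawTeeth@max
    mc[9L] <- clawTeeth@mcExtra
    fl[9L] <- paste(clawTeeth@flags, collapse = "")
    obs[9L] <- TRUE
  }

  new("ChaetoProfile", name = name, min = mn, max = mx, mcExtra = mc,
      flags = fl, observed = obs, formulaText = formatFormula(f))
}

#' Read a formulas table
#'
#' Reads a TSV with columns `species`, `formula`, `claw_teeth`,
#' `source_section` and optionally `parse_mode` and `note`. Formulas are
#' parsed in the per-row mode (default strict).
#'
#' @param path TSV file path.
#' @return data.frame with the file's columns plus a list-column
#'   `parsed` of [MacroFormula-class] objects and a logical `strict`.
#' @export
readFormulas <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                          na.strings = character())
  need <- c("species", "formula", "claw_teeth")
  if (!all(need %in% names(tb)))
    stop("formulas table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(tb$parse_mode)) tb$parse_mode <- "strict"
  tb$parsed <- lapply(seq_len(nrow(tb)), function(i)
    parseFormula(tb$formula[i], mode = tb$parse_mode[i]))
  tb$strict <- vapply(tb$parsed, function(f) f@strict, logical(1))
  tb
}

#' The study's printed simplified Mc formulas
#'
#' The five formulas printed in the species accounts (O. mesovoides,
#' O. colluvialis, O. villosa, O. cincta, O. eolia) plus the partial
#' O. flavescens formula compiled from earlier literature, with claw
#' tooth counts and parse modes. O. villosa is loaded lenient-only
#' because its printed formula conflicts with the reference matrix row;
#' O. flavescens because its head segment has five fields where six
#' areas exist.
#'
#' @return data.frame as from [readFormulas()].
#' @export
builtinFormulas <- function() {
  readFormulas(system.file("extdata", "formulas.tsv", package = "chaetokey",
                           mustWork = TRUE))
}

#' Compare two profiles character by character
#'
#' Classifies each of the 22 characters as `identical` (same recorded
#' `[min, max]` range), `compatible` (ranges differ but intersect),
#' `conflict` (disjoint ranges) or `not_comparable` (unknown on either
#' side). Mesochaeta extras and flags are ignored, as in
#' [dissimilarity()].
#'
#' @param a,b [ChaetoProfile-class] objects.
#' @return data.frame with columns `character`, `a_min`, `a_max`,
#'   `b_min`, `b_max`, `status`.
#' @export
compareProfiles <- function(a, b) {
  stopifnot(is(a, "ChaetoProfile"), is(b, "ChaetoProfile"))
  shared <- .rangesShared(a@min, a@max, a@observed, b@min, b@max, b@observed)
  status <- ifelse(is.na(shared), "not_comparable",
            ifelse(!shared, "conflict",
            ifelse(a@min == b@min & a@max == b@max, "identical",
                   "compatible")))
  data.frame(character = 1:22, a_min = a@min, a_max = a@max,
             b_min = b@min, b_max = b@max, status = status,
             stringsAsFactors = FALSE)
}

#' Audit the printed formulas against the reference character matrix
#'
#' For every formula species present in the matrix: parses the formula,
#' verifies the canonical-string round trip, derives the 22-character
#' profile ([formulaToProfile()], claw teeth from the matrix row where
#' the formulas table gives `"?"`), and compares it with the matrix row.
#' Agreement means the recorded ranges are not in conflict (they
#' intersect); every character whose range is not byte-identical is
#' listed in the discrepancy ledger.
#'
#' @param formulas data.frame as from [builtinFormulas()].
#' @param matrix a [ChaetoMatrix-class]; defaults to [builtinMatrix()].
#' @return list with `summary` (per species: parse mode, round-trip flag,
#'   characters compared / agreeing / identical) and `discrepancies`
#'   (one row per non-identical character with both ranges and status).
#' @export
formulaAudit <- function(formulas = builtinFormulas(),
                         matrix = builtinMatrix()) {
  sm <- list(); disc <- list()
  for (i in seq_len(nrow(formulas))) {
    sp <- formulas$species[i]
    f <- formulas$parsed[[i]]
    roundTrip <- identical(formatFormula(f),
                           gsub("[[:space:]]+", "", formulas$formula[i]))
    inMatrix <- sp %in% speciesNames(matrix)
    agree <- ident <- comp <- NA_integer_
    if (inMatrix && f@strict) {
      ref <- matrix[[sp]]
      claw <- formulas$claw_teeth[i]
      if (identical(claw, "?"))
        claw <- chaetoValue(ref@min[9L], ref@max[9L])
      prof <- formulaToProfile(f, claw, sp)
      cmp <- compareProfiles(prof, ref)
      comp <- sum(cmp$status != "not_comparable")
      agree <- sum(cmp$status %in% c("identical", "compatible"))
      ident <- sum(cmp$status == "identical")
      bad <- cmp[cmp$status %in% c("compatible", "conflict"), , drop = FALSE]
      if (nrow(bad)) {
        bad$species <- sp
        disc[[length(disc) + 1L]] <- bad
      }
    }
    sm[[length(sm) + 1L]] <- data.frame(
      species = sp, parse_mode = formulas$parse_mode[i],
      strict_shape = f@strict, round_trip = roundTrip,
      n_warnings = length(f@warnings), in_matrix = inMatrix,
      compared = comp, agreeing = agree, identical = ident,
      stringsAsFactors = FALSE)
  }
  discrepancies <- if (length(disc)) {
    d <- do.call(rbind, disc)
    rownames(d) <- NULL
    d[, c("species", "character", "a_min", "a_max", "b_min", "b_max",
          "status")]
  } else {
    data.frame(species = character(), character = integer(),
               a_min = integer(), a_max = integer(), b_min = integer(),
               b_max = integer(), status = character())
  }
  names(discrepancies)[3:6] <- c("formula_min", "formula_max",
                                 "matrix_min", "matrix_max")
  list(summary = do.call(rbind, sm), discrepancies = discrepancies)
}
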