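#' The 22-character diagnostic system
#'
#' Definitions of the diagnostic characters: body region, area code
#' (head areas H1-H6, Th II areas T1-T2, the claw, Abd II-IV areas
#' A1-A10 with unpaired/lateral qualifiers), the chaeta series counted,
#' and the footnote cap where the published legend states one ("N if
#' >N-1"). Caps are metadata only: printed cell values exceed some of
#' them, so they are never applied to the data.
#'
#' @return data.frame with columns `index`, `body_region`, `area_code`,
#'   `description`, `footnote_cap`.
#' @export
characterDefinitions <- function() {
  data.frame(
    index = 1:22,
    body_region = c(rep("head", 6), rep("thorax II", 2), "claw",
                    rep("abdomen II", 2), rep("abdomen III", 3),
                    rep("abdomen IV", 8)),
    area_code = c("H1", "H2", "H3", "H4", "H5", "H6", "T1", "T2", "claw",
                  "A1", "A2", "A3", "A4", "A5", "A6", "A7", "A8 unpaired",
                  "A8", "A9 unpaired", "A9", "A9 lateral", "A10"),
    description = c(
      "Mc on series sd'4-sd'4' (An2-An3), total number",
      "Mc on series sd4-sd'3a (A5-A7), total number",
      "Mc on series d'0 (S'0), total number",
      "Mc on series d1-sd1-sd'1 (S1-S3-S4), total number",
      "Mc on series v1-v3-v4 (Ps2-Ps3-Ps5), total number",
      "Mc on series S0-S2 and accessory, total number",
      "Mc on series m1-m2i2, total number",
      "Mc on series a5-m5, total number",
      "claw internal teeth, total number",
      "Mc on series a2-a3, total number",
      "Mc on m3 series, total number",
      "Mc on series a1, total number",
      "Mc on series above m2, total number",
      "Mc on m3-m4 series, total number",
      "Mc on series a1-a5 (A1-E1a), total number",
      "Mc on series ma1-ma4 (A2-E1), total number",
      "unpaired Mc on series m0 (A04), total number",
      "Mc on series m1-m3 (A4p-C4), total number",
      "unpaired Mc on series mp0 (A05), total number",
      "Mc on series mp1-mp3 (A5-B5), total number",
      "lateral Mc, total number",
      "Mc on series p1a-p3 (A6i-B6), total number"),
    footnote_cap = c(NA, NA, NA, NA, NA, NA, 5L, 9L, NA, NA, NA, NA, NA,
                     NA, 9L, 10L, NA, NA, NA, 6L, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Read a species-by-character matrix from TSV
#'
#' The file needs a `species` column and `char_01` .. `char_22` columns
#' in the cell micro-grammar (`"5"`, `"2(9)"`, `"0(2*)"`, `"1b"`, `"?"`).
#'
#' @param path TSV file path.
#' @return A [ChaetoMatrix-class].
#' @export
readCharacterMatrix <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character())
  cols <- sprintf("char_%02d", 1:22)
  if (!all(c("species", cols) %in% names(tb)))
    stop("matrix table needs columns species, char_01..char_22",
         call. = FALSE)
  profiles <- lapply(seq_len(nrow(tb)), function(i) {
    mn <- mx <- mc <- rep(NA_integer_, 22L)
    fl <- rep("", 22L); obs <- rep(FALSE, 22L)
    for (j in 1:22) {
      p <- .parseCellToken(tb[[cols[j]]][i])
      if (is.null(p))
        stop("species '", tb$species[i], "', character ", j,
             ": malformed cell '", tb[[cols[j]]][i], "'", call. = FALSE)
      if (!p$unknown) {
        mn[j] <- p$min; mx[j] <- p$max; mc[j] <- p$mcExtra
        fl[j] <- p$flags; obs[j] <- TRUE
      }
    }
    new("ChaetoProfile", name = tb$species[i], min = mn, max = mx,
        mcExtra = mc, flags = fl, observed = obs,
        formulaText = NA_character_)
  })
  names(profiles) <- tb$species
  new("ChaetoMatrix", profiles = profiles)
}

#' The packaged reference character matrix
#'
#' Five Orchesella species (O. cincta, O. colluvialis, O. eolia,
#' O. mesovoides, O. villosa) scored for the 22 diagnostic characters,
#' with count ranges preserved (e.g. O. mesovoides character 1 is 5..7).
#'
#' @return A [ChaetoMatrix-class] of five profiles.
#' @examples
#' cm <- builtinMatrix()
#' speciesNames(cm)
#' dissimilarity(cm[["O. cincta"]], cm[["O. colluvialis"]])
#' @export
builtinMatrix <- function() {
  readCharacterMatrix(system.file("extdata", "table2_matrix.tsv",
                                  package = "chaetokey", mustWork = TRUE))
}

#' @describeIn ChaetoMatrix-class species names in matrix order.
#' @param x a `ChaetoMatrix`.
#' @export
setMethod("speciesNames", "ChaetoMatrix", function(x) names(x@profiles))

#' @export
setMethod("length", "ChaetoMatrix", function(x) length(x@profiles))

#' Extract a profile by species name or position
#' @param x a [ChaetoMatrix-class].
#' @param i species name or index.
#' @param j,... unused.
#' @return A [ChaetoProfile-class].
#' @export
setMethod("[[", "ChaetoMatrix", function(x, i, j, ...) {
  p <- x@profiles[[i]]
  if (is.null(p)) stop("no species '", i, "' in matrix", call. = FALSE)
  p
})

setMethod("show", "ChaetoMatrix", function(object) {
  cat(sprintf("ChaetoMatrix with %d species x 22 characters\n",
              length(object)))
  cat("  ", paste(speciesNames(object), collapse = ", "), "\n")
})

setMethod("show", "ChaetoProfile", function(object) {
  cells <- vapply(1:22, function(j) {
    if (!object@observed[j]) return("?")
    .formatCellToken(FALSE, object@min[j], object@max[j],
                     object@mcExtra[j], object@flags[j])
  }, character(1))
  cat("ChaetoProfile:", object@name, "\n ", paste(cells, collapse = " "),
      "\n")
  if (!is.na(object@formulaText))
    cat("  from formula:", object@formulaText, "\n")
})

#' @describeIn formulaText source formula of a profile.
#' @export
setMethod("formulaText", "ChaetoProfile", function(x) x@formulaText)

#' @describeIn characterValues profile states as a data frame.
#' @export
setMethod("characterValues", "ChaetoProfile", function(x) {
  data.frame(character = 1:22, min = x@min, max = x@max,
             mcExtra = x@mcExtra, flags = x@flags, observed = x@observed,
             stringsAsFactors = FALSE)
})

#' @describeIn dissimilarity range-intersection rule over the 22
#'   characters; unknowns excluded from numerator and denominator.
setMethod("dissimilarity", signature("ChaetoProfile", "ChaetoProfile"),
  function(p, q) {
    shared <- .rangesShared(p@min, p@max, p@observed, q@min, q@max,
                            q@observed)
    compared <- sum(!is.na(shared))
    if (compared == 0L)
      stop("no comparable characters between '", p@name, "' and '",
           q@name, "': percent dissimilarity undefined", call. = FALSE)
    mism <- which(!is.na(shared) & !shared)
    new("ChaetoDissimilarity", speciesA = p@name, speciesB = q@name,
        compared = as.integer(compared),
        unsharedCount = length(mism),
        percent = roundHalfUp(100 * length(mism) / compared),
        mismatches = as.integer(mism))
  })

setMethod("show", "ChaetoDissimilarity", function(object) {
  cat(sprintf("%s vs %s: %d/%d characters unshared (%g%%)\n",
              object@speciesA, object@speciesB, object@unsharedCount,
              object@compared, object@percent))
  if (length(object@mismatches))
    cat("  mismatching characters:",
        paste(object@mismatches, collapse = ", "), "\n")
})

#' @describeIn dissimilarityMatrix all pairs of a character matrix.
setMethod("dissimilarityMatrix", "ChaetoMatrix", function(x) {
  sp <- speciesNames(x)
  if (length(sp) < 2L) stop("need at least two profiles", call. = FALSE)
  n <- length(sp)
  counts <- percent <- matrix(0, n, n, dimnames = list(sp, sp))
  compared <- matrix(22L, n, n, dimnames = list(sp, sp))
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    d <- dissimilarity(x[[sp[i]]], x[[sp[j]]])
    counts[i, j] <- counts[j, i] <- d@unsharedCount
    percent[i, j] <- percent[j, i] <- d@percent
    compared[i, j] <- compared[j, i] <- d@compared
    pairs[[paste(sp[i], sp[j], sep = "|")]] <- d
  }
  diag(compared) <- 22L
  new("ChaetoDissimilarityMatrix", species = sp, counts = counts,
      percent = percent, compared = compared, pairs = pairs)
})

#' @describeIn ChaetoDissimilarityMatrix-class species order.
#' @param x a `ChaetoDissimilarityMatrix`.
#' @export
setMethod("speciesNames", "ChaetoDissimilarityMatrix",
          function(x) x@species)

#' @export
setMethod("dissimCounts", "ChaetoDissimilarityMatrix", function(x) x@counts)

#' @export
setMethod("dissimPercent", "ChaetoDissimilarityMatrix",
          function(x) x@percent)

setMethod("show", "ChaetoDissimilarityMatrix", function(object) {
  cat("ChaetoDissimilarityMatrix (unshared-character counts)\n")
  print(object@counts)
})

#' Published pairwise dissimilarity values
#'
#' The published comparison table for the five reference species: the
#' unshared-character count and the printed dissimilarity percentage for
#' each of the 10 unordered pairs. Used as the reference for
#' [auditPublished()]; several printed entries are not reproducible from
#' the character matrix and are flagged there rather than repaired.
#'
#' @return data.frame with columns `species_a`, `species_b`,
#'   `published_count`, `published_percent`.
#' @export
publishedDissimilarity <- function() {
  data.frame(
    species_a = c("O. cincta", "O. cincta", "O. cincta", "O. cincta",
                  "O. colluvialis", "O. colluvialis", "O. colluvialis",
                  "O. eolia", "O. eolia", "O. mesovoides"),
    species_b = c("O. colluvialis", "O. eolia", "O. mesovoides",
                  "O. villosa", "O. eolia", "O. mesovoides", "O. villosa",
                  "O. mesovoides", "O. villosa", "O. villosa"),
    published_count = c(13L, 10L, 12L, 7L, 13L, 10L, 7L, 12L, 10L, 9L),
    published_percent = c(59L, 46L, 56L, 31L, 59L, 46L, 31L, 55L, 46L,
                          41L),
    stringsAsFactors = FALSE
  )
}

#' Audit computed dissimilarities against published values
#'
#' For each published pair, reports the computed and published
#' unshared-character count and percentage, whether they match, and an
#' internal-consistency flag testing whether the published percentage
#' equals `round(100 * published_count / 22)` (half away from zero).
#'
#' @param dm a [ChaetoDissimilarityMatrix-class].
#' @param published reference table as from [publishedDissimilarity()].
#' @return data.frame with one row per published pair and columns
#'   `species_a`, `species_b`, `computed_count`, `published_count`,
#'   `count_match`, `computed_percent`, `published_percent`,
#'   `percent_match`, `published_consistent`.
#' @export
auditPublished <- function(dm, published = publishedDissimilarity()) {
  stopifnot(is(dm, "ChaetoDissimilarityMatrix"))
  if (nrow(published) == 0L)
    return(data.frame(species_a = character(), species_b = character(),
                      computed_count = integer(),
                      published_count = integer(),
                      count_match = logical(),
                      computed_percent = numeric(),
                      published_percent = integer(),
                      percent_match = logical(),
                      published_consistent = logical()))
  cc <- dm@counts[cbind(published$species_a, published$species_b)]
  cp <- dm@percent[cbind(published$species_a, published$species_b)]
  data.frame(
    species_a = published$species_a,
    species_b = published$species_b,
    computed_count = as.integer(cc),
    published_count = published$published_count,
    count_match = as.integer(cc) == published$published_count,
    computed_percent = cp,
    published_percent = published$published_percent,
    percent_match = cp == published$published_percent,
    published_consistent = published$published_percent ==
      roundHalfUp(100 * published$published_count / 22),
    stringsAsFactors = FALSE
  )
}

## Normalize the accepted observation formats to a data.frame
## (character, min, max).
.asObservation <- function(observation) {
  if (is.data.frame(observation)) {
    stopifnot("character" %in% names(observation))
    obs <- observation
    if (is.null(obs$max)) obs$max <- obs$min
    obs <- obs[, c("character", "min", "max")]
  } else if (is.list(observation)) {
    idx <- as.integer(names(observation))
    obs <- data.frame(
      character = idx,
      min = vapply(observation, function(v) v@min, integer(1)),
      max = vapply(observation, function(v) v@max, integer(1)))
    obs <- obs[!vapply(observation, function(v) v@unknown, logical(1)), ]
  } else if (is.numeric(observation)) {
    obs <- data.frame(character = as.integer(names(observation)),
                      min = as.integer(observation),
                      max = as.integer(observation))
  } else stop("unsupported observation format", call. = FALSE)
  if (nrow(obs) == 0L) stop("observation is empty", call. = FALSE)
  if (anyNA(obs$character) || any(obs$character < 1L | obs$character > 22L))
    stop("observed character indices must be in 1..22", call. = FALSE)
  if (anyDuplicated(obs$character))
    stop("duplicate character indices in observation", call. = FALSE)
  obs
}

#' Identify a specimen from a partial character observation
#'
#' Scores each reference species by the fraction of comparable observed
#' characters whose ranges intersect the species' recorded ranges
#' (compatibility score in `[0, 1]`). Species are ranked by score
#' descending, then matched-character count descending, then name
#' ascending.
#'
#' @param observation observed characters: a data.frame with columns
#'   `character`, `min` (and optionally `max`), a named numeric vector
#'   (names = character indices), or a named list of
#'   [ChaetoValue-class] objects.
#' @param matrix a [ChaetoMatrix-class] of reference profiles; defaults
#'   to [builtinMatrix()].
#' @return data.frame with columns `species`, `score`, `matched`,
#'   `compared`, ranked best first.
#' @examples
#' identifySpecies(c(`7` = 12, `8` = 9))
#' @export
identifySpecies <- function(observation, matrix = builtinMatrix()) {
  obs <- .asObservation(observation)
  sp <- speciesNames(matrix)
  rows <- lapply(sp, function(s) {
    p <- matrix[[s]]
    k <- obs$character
    shared <- .rangesShared(obs$min, obs$max, rep(TRUE, nrow(obs)),
                            p@min[k], p@max[k], p@observed[k])
    compared <- sum(!is.na(shared))
    matched <- sum(shared, na.rm = TRUE)
    data.frame(species = s,
               score = if (compared > 0L) matched / compared else NA_real_,
               matched = matched, compared = compared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(out$compared == 0L))
    stop("no comparable characters for any species", call. = FALSE)
  out <- out[order(-out$score, -out$matched, out$species), ]
  rownames(out) <- NULL
  out
}

.NEXUS_SYMBOLS <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUV", "")[[1]]

#' @describeIn exportNexus standard morphological CHARACTERS block.
#'   Integer states map to the symbol alphabet `0-9A-V`; a range
#'   `min..max` with `max > min` becomes a polymorphic state set over the
#'   integer states it spans (e.g. `0..1` is `(01)`), and unknown
#'   characters become `?`. States beyond the 32-symbol alphabet raise an
#'   error naming the character.
setMethod("exportNexus", "ChaetoMatrix", function(x, file = NULL, ...) {
  sp <- speciesNames(x)
  defs <- characterDefinitions()
  cells <- vapply(sp, function(s) {
    p <- x[[s]]
    paste(vapply(1:22, function(j) {
      if (!p@observed[j]) return("?")
      if (p@max[j] >= length(.NEXUS_SYMBOLS))
        stop("character ", j, " of '", s, "' has state ", p@max[j],
             ", beyond the symbol alphabet", call. = FALSE)
      states <- .NEXUS_SYMBOLS[(p@min[j]:p@max[j]) + 1L]
      if (length(states) > 1L)
        paste0("(", paste(states, collapse = ""), ")")
      else states
    }, character(1)), collapse = "")
  }, character(1))
  quote1 <- function(s) paste0("'", gsub("'", "''", s), "'")
  labels <- paste0("    [", defs$index, "] ",
                   quote1(paste0(defs$area_code, ": ", defs$description)))
  doc <- paste0(
    "#NEXUS\n",
    "BEGIN TAXA;\n",
    "  DIMENSIONS NTAX=", length(sp), ";\n",
    "  TAXLABELS\n",
    paste0("    ", vapply(sp, quote1, character(1)), collapse = "\n"),
    "\n  ;\nEND;\n",
    "BEGIN CHARACTERS;\n",
    "  DIMENSIONS NCHAR=22;\n",
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"",
    paste(.NEXUS_SYMBOLS, collapse = ""), "\" MISSING=? GAP=-;\n",
    "  CHARLABELS\n", paste(labels, collapse = "\n"), "\n  ;\n",
    "  MATRIX\n",
    paste0("    ", format(vapply(sp, quote1, character(1))), " ", cells,
           collapse = "\n"),
    "\n  ;\nEND;\n")
  if (!is.null(file)) {
    writeLines(doc, file, sep = "")
    return(invisible(doc))
  }
  doc
})

#' Write a dissimilarity matrix as TSV
#'
#' @param dm a [ChaetoDissimilarityMatrix-class].
#' @param path output file.
#' @param form `"long"` (one row per pair, with mismatch ledger) or
#'   `"square"` (counts above the diagonal, percentages below, as the
#'   published layout).
#' @param header optional character vector of `#` comment lines written
#'   before the table.
#' @return the output path, invisibly.
#' @export
writeDissimilarity <- function(dm, path, form = c("long", "square"),
                               header = character()) {
  form <- match.arg(form)
  stopifnot(is(dm, "ChaetoDissimilarityMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  if (form == "long") {
    rows <- lapply(dm@pairs, function(d) data.frame(
      species_a = d@speciesA, species_b = d@speciesB,
      compared = d@compared, unshared_count = d@unsharedCount,
      percent = d@percent,
      mismatches = paste(d@mismatches, collapse = ","),
      stringsAsFactors = FALSE))
    tb <- do.call(rbind, rows)
    rownames(tb) <- NULL
  } else {
    n <- length(dm@species)
    sq <- matrix("", n, n, dimnames = list(dm@species, dm@species))
    sq[upper.tri(sq)] <- dm@counts[upper.tri(sq)]
    sq[lower.tri(sq)] <- paste0(dm@percent[lower.tri(sq)], "%")
    tb <- data.frame(species = dm@species, sq, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  utils::write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
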