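# Shared test utilities: independent oracles and random-object
# generators used by the property-style tests.

# Independent unshared-character oracle: expands each count range to its
# integer set and tests set intersection, character by character.
bruteDissim <- function(p, q) {
  unshared <- integer()
  compared <- 0L
  for (j in 1:22) {
    if (!p@observed[j] || !q@observed[j]) next
    compared <- compared + 1L
    a <- seq(p@min[j], p@max[j])
    b <- seq(q@min[j], q@max[j])
    if (length(intersect(a, b)) == 0L) unshared <- c(unshared, j)
  }
  list(compared = compared, unshared = unshared,
       percent = floor(100 * length(unshared) / compared + 0.5))
}

# Random fully/partially observed profile for oracle comparisons.
randomProfile <- function(name, pUnknown = 0.15) {
  mn <- mx <- rep(NA_integer_, 22L)
  obs <- runif(22) > pUnknown
  mn[obs] <- sample(0:8, sum(obs), replace = TRUE)
  mx[obs] <- mn[obs] + sample(0:4, sum(obs), replace = TRUE)
  new("ChaetoProfile", name = name, min = mn, max = mx,
      mcExtra = rep(NA_integer_, 22L), flags = rep("", 22L),
      observed = obs, formulaText = NA_character_)
}

# Random canonical-shape formula exercising ranges, mesochaeta extras,
# flags, unknowns and Abd IV unpaired prefixes.
randomFormula <- function() {
  shape <- c(6L, 2L, 2L, 3L, 5L)
  rows <- list()
  for (s in seq_along(shape)) for (f in seq_len(shape[s])) {
    unknown <- runif(1) < 0.1
    if (unknown) {
      row <- data.frame(segment = s, field = f, prefix = NA_integer_,
                        unknown = TRUE, min = NA_integer_,
                        max = NA_integer_, mcExtra = NA_integer_,
                        flags = "", stringsAsFactors = FALSE)
    } else {
      mn <- sample(0:9, 1)
      mx <- if (runif(1) < 0.3) mn + sample(1:3, 1) else mn
      mc <- if (mx == mn && runif(1) < 0.15) sample(1:4, 1) else NA_integer_
      fl <- if (runif(1) < 0.1) sample(letters, 1) else ""
      pre <- if (s == 5L && runif(1) < 0.25) sample(1:2, 1) else NA_integer_
      row <- data.frame(segment = s, field = f, prefix = pre,
                        unknown = FALSE, min = mn, max = mx, mcExtra = mc,
                        flags = fl, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- row
  }
  fields <- do.call(rbind, rows)
  rownames(fields) <- NULL
  new("MacroFormula", fields = fields, warnings = character(),
      strict = TRUE)
}

# Character matrix from inline cell rows (named list species -> 22 cells).
matrixFromCells <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- paste(c("species", sprintf("char_%02d", 1:22)),
                  collapse = "\t")
  lines <- vapply(names(rows), function(nm)
    paste(c(nm, rows[[nm]]), collapse = "\t"), character(1))
  writeLines(c(header, lines), path)
  readCharacterMatrix(path)
}
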