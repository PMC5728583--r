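## Pitfall-trap community summaries: species totals, per-trap maxima,
## altitude-band abundance profiles and compass resultant vectors for
## SSD/TSP trap networks.

.WINDS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
.WIND_BEARING <- c(N = 0, NE = 45, E = 90, SE = 135, S = 180, SW = 225,
                   W = 270, NW = 315)
.ORIENT_WORDS <- c(North = "N", Northeast = "NE", East = "E",
                   Southeast = "SE", Sourtheast = "SE", South = "S",
                   Southwest = "SW", West = "W", Northwest = "NW",
                   Crest = "Crest")

#' Read a trap-location table
#'
#' Reads trap metadata (code, depth, UTM square, altitude, toponym,
#' province, installation and recovery dates, orientation, massif).
#' Orientation words are normalized to the 8-wind codes plus `Crest`;
#' the known misspelling "Sourtheast" is normalized to `SE` and noted in
#' the `orientation_note` column.
#'
#' @param path TSV with the columns of the packaged `table1_traps.tsv`.
#' @return data.frame of trap records, one row per trap, with
#'   `orientation` as a factor over `N, NE, E, SE, S, SW, W, NW, Crest`.
#' @export
readTraps <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "depth_m", "altitude_m", "orientation", "massif")
  if (!all(need %in% names(tb)))
    stop("trap table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tb$code))
    stop("trap codes must be unique", call. = FALSE)
  raw <- tb$orientation
  known <- raw %in% names(.ORIENT_WORDS) | raw %in% c(.WINDS, "Crest")
  if (any(!known))
    stop("unknown orientation value(s): ",
         paste(unique(raw[!known]), collapse = ", "), call. = FALSE)
  norm <- ifelse(raw %in% names(.ORIENT_WORDS), .ORIENT_WORDS[raw], raw)
  tb$orientation_note <- ifelse(
    raw == "Sourtheast", "normalized from printed 'Sourtheast'", "")
  tb$orientation <- factor(norm, levels = c(.WINDS, "Crest"))
  for (col in c("install_date", "recovery_date"))
    if (col %in% names(tb)) tb[[col]] <- as.Date(tb[[col]])
  tb
}

#' Read a captures table
#'
#' @param path TSV with columns `trap_code`, `species`, `count`.
#' @param traps optional trap table; when given, every `trap_code` must
#'   resolve to a trap record.
#' @return data.frame of catch records.
#' @export
readCatches <- function(path, traps = NULL) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trap_code", "species", "count")
  if (!all(need %in% names(tb)))
    stop("catch table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(tb$count < 0) || anyNA(tb$count))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!is.null(traps)) {
    bad <- setdiff(tb$trap_code, traps$code)
    if (length(bad))
      stop("catch records reference unknown traps: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  tb
}

#' The packaged trap network
#'
#' The 39 traps of the survey: 33 one-metre subterranean sampling
#' devices (SSD-1..SSD-33), four half-metre SSDs at the La Mujer Muerta
#' double stations, and two talus-slope pitfalls (TSP-1, TSP-2), with
#' altitudes 1375-2301 m a.s.l., 8-wind orientations (SSD-29 and SSD-30
#' sit on crests) and massif groups.
#'
#' @return data.frame as from [readTraps()].
#' @export
builtinTraps <- function() {
  readTraps(system.file("extdata", "table1_traps.tsv",
                        package = "chaetokey", mustWork = TRUE))
}

#' The packaged capture counts
#'
#' Per-trap captures of O. mesovoides and O. colluvialis over the whole
#' network (78 records: 39 traps x 2 species).
#'
#' @return data.frame as from [readCatches()].
#' @export
builtinCatches <- function() {
  readCatches(system.file("extdata", "table4_catches.tsv",
                          package = "chaetokey", mustWork = TRUE),
              traps = builtinTraps())
}

.checkSpecies <- function(catches, species) {
  if (!species %in% catches$species)
    stop("species '", species, "' not present in catch records",
         call. = FALSE)
}

#' Total captures of a species
#'
#' @param catches catch records (as [builtinCatches()]).
#' @param species species name.
#' @return integer total number of specimens.
#' @examples
#' totalCaptures(builtinCatches(), "O. mesovoides")  # 1956
#' @export
totalCaptures <- function(catches, species) {
  if (nrow(catches) == 0L) return(0L)
  .checkSpecies(catches, species)
  as.integer(sum(catches$count[catches$species == species]))
}

#' Largest single-trap catch of a species
#'
#' @inheritParams totalCaptures
#' @return list with `trap_code` and `count`; ties broken by trap code
#'   ascending.
#' @examples
#' maxSingleTrap(builtinCatches(), "O. colluvialis")  # SSD-31, 700
#' @export
maxSingleTrap <- function(catches, species) {
  .checkSpecies(catches, species)
  cc <- catches[catches$species == species, ]
  cc <- cc[order(-cc$count, cc$trap_code), ]
  list(trap_code = cc$trap_code[1], count = as.integer(cc$count[1]))
}

#' Altitude-band abundance profile
#'
#' Bins traps into half-open altitude bands `[origin + k*bandWidth,
#' origin + (k+1)*bandWidth)` and reports, per band, the number of traps,
#' the total specimens and the mean specimens per trap (the mean weighs
#' abundance by the number of traps placed in the band). All traps
#' count, including zero-catch and half-metre devices, unless the caller
#' filters them first. Bands inside the data range with no traps are
#' reported with zero traps and an undefined mean, never dropped.
#'
#' @param traps trap records.
#' @param catches catch records.
#' @param species species name.
#' @param bandWidth band width in metres (> 0); default 200.
#' @param origin lower anchor of the banding in metres; default 1200.
#' @return data.frame with columns `band_lo`, `band_hi`, `n_traps`,
#'   `total`, `mean`.
#' @export
altitudeProfile <- function(traps, catches, species, bandWidth = 200,
                            origin = 1200) {
  if (bandWidth <= 0) stop("bandWidth must be > 0", call. = FALSE)
  if (nrow(traps) == 0L) stop("no traps", call. = FALSE)
  .checkSpecies(catches, species)
  cc <- catches[catches$species == species, ]
  cnt <- cc$count[match(traps$code, cc$trap_code)]
  cnt[is.na(cnt)] <- 0
  k <- floor((traps$altitude_m - origin) / bandWidth)
  ks <- seq(min(k), max(k))
  out <- data.frame(
    band_lo = origin + ks * bandWidth,
    band_hi = origin + (ks + 1) * bandWidth,
    n_traps = vapply(ks, function(b) sum(k == b), integer(1)),
    total = vapply(ks, function(b) sum(cnt[k == b]), numeric(1)))
  out$mean <- ifelse(out$n_traps > 0, out$total / out$n_traps, NA_real_)
  out
}

#' Compass resultant vector of a species' abundance
#'
#' Computes the mean specimens per trap for each of the 8 winds (to
#' weigh abundance by the number of traps per orientation), maps each
#' wind to a unit vector at its bearing (N = 0 degrees, clockwise), and
#' sums `mean x unit` over the winds. Crest traps face no compass
#' direction and are excluded; winds with no traps contribute nothing.
#'
#' @inheritParams altitudeProfile
#' @return list with `means` (named vector over the 8 winds, `NA` where
#'   no traps face that wind), `n_traps` (traps per wind), `east`,
#'   `north` (resultant components, specimens), `magnitude` (specimens)
#'   and `bearing` (degrees clockwise from north in `[0, 360)`).
#' @examples
#' orientationResultant(builtinTraps(), builtinCatches(), "O. mesovoides")
#' @export
orientationResultant <- function(traps, catches, species) {
  .checkSpecies(catches, species)
  tr <- traps[traps$orientation != "Crest", ]
  if (nrow(tr) == 0L)
    stop("no non-Crest traps: bearing undefined", call. = FALSE)
  cc <- catches[catches$species == species, ]
  cnt <- cc$count[match(tr$code, cc$trap_code)]
  cnt[is.na(cnt)] <- 0
  ori <- factor(as.character(tr$orientation), levels = .WINDS)
  nTraps <- tapply(rep(1L, nrow(tr)), ori, sum, default = 0L)
  totals <- tapply(cnt, ori, sum, default = 0)
  means <- ifelse(nTraps > 0, totals / nTraps, NA_real_)
  contrib <- ifelse(is.na(means), 0, means)
  theta <- .WIND_BEARING[.WINDS] * pi / 180
  east <- sum(contrib * sin(theta))
  north <- sum(contrib * cos(theta))
  magnitude <- sqrt(east^2 + north^2)
  if (magnitude <= sqrt(.Machine$double.eps))
    stop("all orientation means are zero: bearing undefined",
         call. = FALSE)
  bearing <- (atan2(east, north) * 180 / pi) %% 360
  list(species = species, means = means, n_traps = nTraps,
       east = east, north = north, magnitude = magnitude,
       bearing = bearing)
}

#' Fraction of captures belonging to a focal taxon
#'
#' @param taxonCount specimens of the focal taxon (e.g. Collembola).
#' @param totalCount all specimens captured; must be positive and at
#'   least `taxonCount`.
#' @return list with `percent` (exact) and `percent_rounded` (integer,
#'   half away from zero).
#' @examples
#' collembolaFraction(42240, 61038)  # 69.2 -> 69
#' @export
collembolaFraction <- function(taxonCount, totalCount) {
  if (totalCount <= 0) stop("total count must be positive", call. = FALSE)
  if (taxonCount < 0 || taxonCount > totalCount)
    stop("taxon count must be in [0, total]", call. = FALSE)
  pct <- 100 * taxonCount / totalCount
  list(percent = pct, percent_rounded = roundHalfUp(pct))
}
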