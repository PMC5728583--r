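## Synthetic-data generators. All are pure functions of their arguments
## and seed: the same spec and seed reproduce the same output, and the
## caller's RNG stream is left untouched.

#' Generate a profile pair with a controlled number of unshared characters
#'
#' Builds two fully observed species profiles whose count ranges
#' intersect on exactly `nCharacters - kUnshared` characters and are
#' disjoint on exactly `kUnshared`: the generator and the
#' unshared-character statistic are inverse by construction, which makes
#' the dissimilarity machinery testable at any chosen dissimilarity.
#' Only the first 22 characters are meaningful to downstream profile
#' containers, so `nCharacters` is fixed at 22.
#'
#' @param kUnshared number of characters with disjoint ranges (0..22).
#' @param maxRangeWidth maximum of `max - min` per character; default 3,
#'   mirroring the `N(M)` convention of the reference matrix.
#' @param seed integer seed; the pair is deterministic given the seed.
#' @param names length-2 character vector of species names.
#' @return list of two [ChaetoProfile-class] objects (`a`, `b`).
#' @examples
#' pr <- makeProfilePair(13, seed = 1)
#' dissimilarity(pr$a, pr$b)  # 13/22 unshared, 59%
#' @export
makeProfilePair <- function(kUnshared, maxRangeWidth = 3, seed = NULL,
                            names = c("sim_A", "sim_B")) {
  n <- 22L
  kUnshared <- as.integer(kUnshared)
  if (is.na(kUnshared) || kUnshared < 0L || kUnshared > n)
    stop("kUnshared must be in 0..", n, call. = FALSE)
  if (maxRangeWidth < 0) stop("maxRangeWidth must be >= 0", call. = FALSE)
  .withSeed(seed, {
    unshared <- sort(sample.int(n, kUnshared))
    aMin <- aMax <- bMin <- bMax <- integer(n)
    for (j in seq_len(n)) {
      wA <- sample.int(maxRangeWidth + 1L, 1L) - 1L
      wB <- sample.int(maxRangeWidth + 1L, 1L) - 1L
      lo <- sample.int(5L, 1L) - 1L
      a <- c(lo, lo + wA)
      if (j %in% unshared) {
        gap <- sample.int(3L, 1L)
        b <- c(a[2] + gap, a[2] + gap + wB)
        if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
      } else {
        p <- if (wA > 0L) a[1] + sample.int(wA + 1L, 1L) - 1L else a[1]
        d <- sample.int(wB + 1L, 1L) - 1L
        b <- c(max(0L, p - d), max(0L, p - d) + wB)
      }
      aMin[j] <- a[1]; aMax[j] <- a[2]; bMin[j] <- b[1]; bMax[j] <- b[2]
    }
    mk <- function(nm, mn, mx) new(
      "ChaetoProfile", name = nm, min = mn, max = mx,
      mcExtra = rep(NA_integer_, n), flags = rep("", n),
      observed = rep(TRUE, n), formulaText = NA_character_)
    list(a = mk(names[1], aMin, aMax), b = mk(names[2], bMin, bMax))
  })
}

#' Simulate a pitfall-trap campaign
#'
#' Places traps uniformly over an altitude range with orientations drawn
#' uniformly from the 8 winds, then draws per-trap counts for each
#' simulated species from a negative binomial whose mean combines a
#' Gaussian altitude response with a von-Mises-shaped orientation
#' multiplier:
#' \deqn{\mu_i = \mu \exp\!\left(-\frac{(z_i - z_0)^2}{2 b^2}\right)
#'   \frac{\exp(\kappa \cos(\theta_i - \theta_0))}{I_0(\kappa)}}
#' where \eqn{z_i} is trap altitude, \eqn{z_0} the altitude optimum,
#' \eqn{b} the breadth, \eqn{\theta_i} the trap bearing,
#' \eqn{\theta_0} the preferred bearing, \eqn{\kappa \ge 0} the
#' orientation concentration (0 = no preference; the \eqn{I_0}
#' normalizer keeps the mean over uniform orientations equal to the
#' altitude term) and counts are `rnbinom(mu, size)` — overdispersed, as
#' real trap catches are.
#'
#' @param nTraps number of traps.
#' @param altitudeRange length-2 metres a.s.l.; default `c(1200, 2450)`.
#' @param species list of per-species parameter lists with elements
#'   `name`, `optimum` (m), `breadth` (m, may be `Inf`), `bearing`
#'   (degrees), `kappa` (>= 0), `mu` (> 0 mean abundance), `size`
#'   (> 0 negative-binomial dispersion). Missing elements take the
#'   defaults of `list(name = "sim_sp1", optimum = 1800, breadth = 200,
#'   bearing = 0, kappa = 1, mu = 50, size = 0.4)`.
#' @param seed integer seed; the campaign is deterministic given it.
#' @return list with `traps` (code, depth_m, altitude_m, orientation,
#'   massif) and `catches` (trap_code, species, count) data frames using
#'   the same schemas as the packaged fixtures.
#' @export
makeTrapCampaign <- function(nTraps, altitudeRange = c(1200, 2450),
                             species = list(list()), seed = NULL) {
  if (nTraps < 1L) stop("need at least one trap", call. = FALSE)
  defaults <- list(name = "sim_sp1", optimum = 1800, breadth = 200,
                   bearing = 0, kappa = 1, mu = 50, size = 0.4)
  species <- lapply(seq_along(species), function(i) {
    sp <- utils::modifyList(defaults, species[[i]])
    if (identical(sp$name, "sim_sp1") && i > 1L)
      sp$name <- sprintf("sim_sp%d", i)
    if (sp$mu <= 0) stop("mu must be > 0", call. = FALSE)
    if (sp$size <= 0) stop("size must be > 0", call. = FALSE)
    if (sp$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
    if (sp$breadth <= 0) stop("breadth must be > 0", call. = FALSE)
    sp
  })
  .withSeed(seed, {
    traps <- data.frame(
      code = sprintf("SIM-%d", seq_len(nTraps)),
      depth_m = 1,
      altitude_m = stats::runif(nTraps, altitudeRange[1], altitudeRange[2]),
      orientation = factor(sample(.WINDS, nTraps, replace = TRUE),
                           levels = c(.WINDS, "Crest")),
      massif = "simulated",
      stringsAsFactors = FALSE)
    theta <- .WIND_BEARING[as.character(traps$orientation)] * pi / 180
    catches <- do.call(rbind, lapply(species, function(sp) {
      altTerm <- if (is.infinite(sp$breadth)) 1 else
        exp(-(traps$altitude_m - sp$optimum)^2 / (2 * sp$breadth^2))
      oriTerm <- if (sp$kappa == 0) 1 else
        exp(sp$kappa * cos(theta - sp$bearing * pi / 180)) /
          besselI(sp$kappa, 0)
      mu <- sp$mu * altTerm * oriTerm
      data.frame(trap_code = traps$code, species = sp$name,
                 count = stats::rnbinom(nTraps, size = sp$size, mu = mu),
                 stringsAsFactors = FALSE)
    }))
    rownames(catches) <- NULL
    list(traps = traps, catches = catches)
  })
}

#' Draw a partial observation from a species profile
#'
#' Samples a random subset of the profile's observed characters, as a
#' field observation of a specimen would record only some areas.
#' With `noise = "none"` the observation is exactly compatible with its
#' source profile, so [identifySpecies()] ranks the source first with
#' score 1; `noise = "widen"` widens each observed range by one chaeta
#' on each side (floored at zero).
#'
#' @param profile a [ChaetoProfile-class].
#' @param nObserved number of characters to observe (1..22, at most the
#'   profile's observed characters).
#' @param noise `"none"` or `"widen"`.
#' @param seed integer seed; the observation is deterministic given it.
#' @return data.frame with columns `character`, `min`, `max`, suitable
#'   for [identifySpecies()].
#' @export
makeObservation <- function(profile, nObserved, noise = c("none", "widen"),
                            seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(is(profile, "ChaetoProfile"))
  avail <- which(profile@observed)
  if (nObserved < 1L || nObserved > 22L)
    stop("nObserved must be in 1..22", call. = FALSE)
  if (nObserved > length(avail))
    stop("profile has only ", length(avail), " observed characters",
         call. = FALSE)
  .withSeed(seed, {
    k <- sort(sample(avail, nObserved))
    mn <- profile@min[k]; mx <- profile@max[k]
    if (noise == "widen") {
      mn <- pmax(0L, mn - 1L)
      mx <- mx + 1L
    }
    data.frame(character = k, min = mn, max = mx)
  })
}
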