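# Pitfall-trap community summaries on the packaged trap network.

traps <- builtinTraps()
catches <- builtinCatches()

test_that("the packaged trap network matches the printed tables", {
  expect_equal(nrow(traps), 39)
  expect_equal(sum(traps$depth_m == 1), 33)   # one-metre SSDs
  expect_equal(sum(traps$depth_m == 0.5), 4)  # half-metre SSDs
  expect_equal(sum(traps$depth_m == 0.8), 2)  # talus-slope pitfalls
  expect_false(anyDuplicated(traps$code) > 0)
  expect_true(all(traps$altitude_m >= 1200 & traps$altitude_m <= 2450))
  s31 <- traps[traps$code == "SSD-31", ]
  expect_equal(s31$altitude_m, 1946)
  expect_equal(as.character(s31$orientation), "N")
  # the printed misspelling is normalized with a provenance note
  s23 <- traps[traps$code == "SSD-23", ]
  expect_equal(as.character(s23$orientation), "SE")
  expect_match(s23$orientation_note, "Sourtheast")
  expect_equal(nrow(catches), 78)
  expect_equal(catches$count[catches$trap_code == "SSD-31" &
                               catches$species == "O. colluvialis"], 700)
  zeros <- catches[catches$trap_code == "SSD-23", ]
  expect_true(all(zeros$count == 0))
})

test_that("species totals and per-trap maxima match the printed summary", {
  expect_equal(totalCaptures(catches, "O. mesovoides"), 1956L)
  expect_equal(totalCaptures(catches, "O. colluvialis"), 5929L)
  expect_equal(totalCaptures(catches[0, ], "anything"), 0L)
  expect_error(totalCaptures(catches, "O. nothing"), "not present")
  expect_equal(maxSingleTrap(catches, "O. colluvialis"),
               list(trap_code = "SSD-31", count = 700L))
  expect_equal(maxSingleTrap(catches, "O. mesovoides"),
               list(trap_code = "SSD-2", count = 468L))
  allZero <- data.frame(trap_code = c("B", "A"), species = "sp",
                        count = c(0L, 0L))
  expect_equal(maxSingleTrap(allZero, "sp"),
               list(trap_code = "A", count = 0L))  # ties by code ascending
})

test_that("altitude bands partition the traps and conserve totals", {
  ap <- altitudeProfile(traps, catches, "O. mesovoides")
  band <- ap[ap$band_lo == 1800, ]
  expect_equal(band$n_traps, 16)
  expect_equal(band$total, 1343)
  expect_equal(band$mean, 1343 / 16)
  # membership of the [2200, 2400) band follows the trap altitudes
  k <- floor((traps$altitude_m - 1200) / 200)
  expect_setequal(traps$code[k == 5], c("SSD-9", "SSD-29", "SSD-30"))
  apc <- altitudeProfile(traps, catches, "O. colluvialis")
  expect_equal(apc$total[apc$band_lo == 2200], 163 + 135 + 73)
  # conservation under arbitrary banding
  for (bw in c(50, 137, 200, 400))
    expect_equal(sum(altitudeProfile(traps, catches, "O. colluvialis",
                                     bandWidth = bw, origin = 1111)$total),
                 5929)
  # empty bands are reported, not dropped
  fine <- altitudeProfile(traps, catches, "O. mesovoides", bandWidth = 25)
  expect_true(any(fine$n_traps == 0))
  expect_true(all(is.na(fine$mean[fine$n_traps == 0])))
  expect_error(altitudeProfile(traps, catches, "O. mesovoides",
                               bandWidth = 0), "bandWidth")
  one <- data.frame(code = "T", depth_m = 1, altitude_m = 1500,
                    orientation = factor("N"), massif = "m")
  oneCatch <- data.frame(trap_code = "T", species = "sp", count = 7L)
  expect_equal(altitudeProfile(one, oneCatch, "sp")$mean, 7)
})

test_that("orientation resultants reproduce the stated compass sectors", {
  vm <- orientationResultant(traps, catches, "O. mesovoides")
  expect_gt(vm$bearing, 0)
  expect_lt(vm$bearing, 45)      # N-NE
  vc <- orientationResultant(traps, catches, "O. colluvialis")
  expect_gte(vc$bearing, 270)
  expect_lt(vc$bearing, 337.5)   # W-NW
  # mean-per-trap weighting: the S sector has no traps
  expect_true(is.na(vm$means["S"]))
  expect_equal(sum(vm$n_traps), 37)  # Crest traps excluded
})

test_that("the resultant is permutation invariant and scales linearly", {
  vc <- orientationResultant(traps, catches, "O. colluvialis")
  set.seed(3)
  perm <- sample(nrow(catches))
  vcp <- orientationResultant(traps[sample(nrow(traps)), ], catches[perm, ],
                              "O. colluvialis")
  expect_equal(vcp$bearing, vc$bearing)
  expect_equal(vcp$magnitude, vc$magnitude)
  scaled <- catches
  scaled$count <- scaled$count * 3
  vcs <- orientationResultant(traps, scaled, "O. colluvialis")
  expect_equal(vcs$bearing, vc$bearing)
  expect_equal(vcs$magnitude, 3 * vc$magnitude)
})

test_that("crest traps never influence the bearing", {
  vm <- orientationResultant(traps, catches, "O. mesovoides")
  extraTrap <- data.frame(code = "SSD-99", depth_m = 1, altitude_m = 2000,
                          orientation = factor("Crest",
                                               levels = levels(traps$orientation)),
                          massif = "extra")
  shared <- intersect(names(traps), names(extraTrap))
  traps2 <- rbind(traps[, shared], extraTrap[, shared])
  catches2 <- rbind(catches,
                    data.frame(trap_code = "SSD-99",
                               species = "O. mesovoides", count = 10000L))
  vm2 <- orientationResultant(traps2, catches2, "O. mesovoides")
  expect_equal(vm2$bearing, vm$bearing)
  expect_equal(vm2$magnitude, vm$magnitude)
  # but totals do include Crest traps
  expect_equal(totalCaptures(catches2, "O. mesovoides"), 1956L + 10000L)
})

test_that("degenerate orientation inputs raise the stated errors", {
  one <- data.frame(code = "T", depth_m = 1, altitude_m = 1500,
                    orientation = factor("N", levels = c("N", "Crest")),
                    massif = "m")
  oneCatch <- data.frame(trap_code = "T", species = "sp", count = 10L)
  v <- orientationResultant(one, oneCatch, "sp")
  expect_equal(v$bearing, 0)
  expect_equal(v$magnitude, 10)
  zero <- oneCatch
  zero$count <- 0L
  expect_error(orientationResultant(one, zero, "sp"),
               "bearing undefined")
  crestOnly <- one
  crestOnly$orientation <- factor("Crest", levels = c("N", "Crest"))
  expect_error(orientationResultant(crestOnly, oneCatch, "sp"),
               "non-Crest")
})

test_that("the focal-taxon capture fraction rounds half away from zero", {
  f <- collembolaFraction(42240, 61038)
  expect_equal(f$percent_rounded, 69)
  expect_equal(f$percent, 100 * 42240 / 61038, tolerance = 1e-12)
  expect_equal(collembolaFraction(0, 100)$percent_rounded, 0)
  expect_equal(collembolaFraction(100, 100)$percent_rounded, 100)
  expect_error(collembolaFraction(1, 0), "positive")
  expect_error(collembolaFraction(101, 100), "\\[0, total\\]")
})
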