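# The 22-character diagnostic matrix, the range-intersection sharing
# rule, the pairwise dissimilarity statistic and its audit.

cm <- builtinMatrix()

test_that("the packaged matrix reproduces the printed cells", {
  expect_setequal(speciesNames(cm),
                  c("O. cincta", "O. colluvialis", "O. eolia",
                    "O. mesovoides", "O. villosa"))
  mes <- cm[["O. mesovoides"]]
  expect_equal(mes@min[7], 12)
  expect_equal(mes@max[7], 12)
  expect_equal(c(mes@min[1], mes@max[1]), c(5, 7))
  expect_equal(c(mes@min[18], mes@max[18]), c(3, 6))
  vil <- cm[["O. villosa"]]
  expect_equal(c(vil@min[12], vil@max[12]), c(0, 1))
  for (s in speciesNames(cm)) {
    d <- dissimilarity(cm[[s]], cm[[s]])
    expect_equal(d@compared, 22L)
    expect_equal(d@unsharedCount, 0L)
    expect_equal(d@percent, 0)
  }
})

test_that("sharing is range intersection, unknowns are not comparable", {
  expect_equal(valuesShared(chaetoValue(5), chaetoValue(4, 8)), "shared")
  expect_equal(valuesShared(chaetoValue(3), chaetoValue(3)), "shared")
  expect_equal(valuesShared(chaetoValue(0), chaetoValue(1)), "unshared")
  expect_equal(valuesShared(unknownValue(), chaetoValue(7)),
               "not_comparable")
  # annotations never influence sharing
  expect_equal(valuesShared(chaetoValue(0, mcExtra = 2), chaetoValue(0)),
               "shared")
  expect_equal(
    valuesShared(parseCharacterCell("1b"), parseCharacterCell("1")),
    "shared")
})

test_that("dissimilarity matches the per-character brute-force oracle", {
  set.seed(11)
  for (i in 1:50) {
    p <- randomProfile("p")
    q <- randomProfile("q")
    ref <- bruteDissim(p, q)
    if (ref$compared == 0L) {
      expect_error(dissimilarity(p, q), "no comparable characters")
      next
    }
    d <- dissimilarity(p, q)
    expect_equal(d@compared, ref$compared)
    expect_equal(d@mismatches, ref$unshared)
    expect_equal(d@percent, ref$percent)
  }
})

test_that("reference pairs reproduce the reconcilable published counts", {
  dm <- dissimilarityMatrix(cm)
  counts <- dissimCounts(dm)
  expect_equal(counts["O. cincta", "O. colluvialis"], 13)
  expect_equal(counts["O. cincta", "O. eolia"], 10)
  expect_equal(counts["O. colluvialis", "O. eolia"], 13)
  expect_equal(counts["O. colluvialis", "O. mesovoides"], 10)
  # the cincta-villosa published 7 is not reproducible under this rule
  expect_equal(counts["O. cincta", "O. villosa"], 9)
  expect_true(isSymmetric(unname(counts)))
  expect_true(all(diag(counts) == 0))
  expect_equal(dissimPercent(dm)["O. colluvialis", "O. cincta"], 59)
})

test_that("duplicate species names are rejected", {
  p <- cm[["O. cincta"]]
  expect_error(new("ChaetoMatrix",
                   profiles = stats::setNames(list(p, p),
                                              rep(p@name, 2))),
               "duplicate")
})

test_that("the audit reconciles four pairs and flags the other six", {
  dm <- dissimilarityMatrix(cm)
  audit <- auditPublished(dm)
  expect_equal(nrow(audit), 10)
  expect_equal(sum(audit$count_match), 4)
  expect_equal(sum(!audit$count_match), 6)
  matched <- audit[audit$count_match,
                   c("species_a", "species_b", "published_count")]
  expect_setequal(
    paste(matched$species_a, matched$species_b, matched$published_count),
    c("O. cincta O. colluvialis 13", "O. cincta O. eolia 10",
      "O. colluvialis O. eolia 13", "O. colluvialis O. mesovoides 10"))
  # internal consistency of the published percentages themselves
  row <- function(a, b) audit[audit$species_a == a & audit$species_b == b, ]
  expect_true(row("O. cincta", "O. colluvialis")$published_consistent)
  expect_false(row("O. cincta", "O. mesovoides")$published_consistent)
  # empty reference table gives an empty report
  expect_equal(nrow(auditPublished(dm, publishedDissimilarity()[0, ])), 0)
})

test_that("identification ranks compatible species first", {
  # a full reference row identifies itself with score 1 at rank 1
  for (s in speciesNames(cm)) {
    p <- cm[[s]]
    obs <- data.frame(character = 1:22, min = p@min, max = p@max)
    r <- identifySpecies(obs, cm)
    expect_equal(r$species[1], s)
    expect_equal(r$score[1], 1)
  }
  # characters 7+8 at 12 and 9 single out one species
  r <- identifySpecies(c(`7` = 12, `8` = 9), cm)
  expect_equal(r$species[r$score == 1], "O. mesovoides")
  # character 3 = 0 is ambiguous between exactly two species
  r <- identifySpecies(c(`3` = 0), cm)
  expect_setequal(r$species[r$score == 1], c("O. cincta", "O. eolia"))
  expect_true(all(diff(r$score) <= 0))
})

test_that("identification validates its inputs", {
  expect_error(identifySpecies(c(`23` = 1), cm), "1\\.\\.22")
  expect_error(identifySpecies(data.frame(character = integer(),
                                          min = integer()), cm),
               "empty")
  blank <- matrixFromCells(list(allUnknown = c("5", rep("?", 21))))
  expect_error(identifySpecies(c(`2` = 1), blank), "no comparable")
})

test_that("dropping a conflicting character restores a perfect score", {
  mes <- cm[["O. mesovoides"]]
  obs <- data.frame(character = c(7, 8, 1), min = c(12, 9, 20),
                    max = c(12, 9, 20))  # character 1 conflicts
  r1 <- identifySpecies(obs, cm)
  expect_lt(r1$score[r1$species == "O. mesovoides"], 1)
  r2 <- identifySpecies(obs[obs$character != 1, ], cm)
  expect_equal(r2$score[r2$species == "O. mesovoides"], 1)
  expect_equal(r2$species[1], "O. mesovoides")
})

test_that("NEXUS export encodes ranges as polymorphic state sets", {
  nx <- exportNexus(cm)
  expect_match(nx, "^#NEXUS")
  expect_match(nx, "DIMENSIONS NTAX=5;")
  expect_match(nx, "DIMENSIONS NCHAR=22;")
  expect_match(nx, "DATATYPE=STANDARD")
  # O. villosa character 12 is 0..1 -> polymorphism (01)
  vilRow <- regmatches(nx, regexpr("'O. villosa' [^\n]+", nx))
  expect_match(vilRow, "\\(01\\)")
  # O. mesovoides character 7 = 12 -> symbol C
  mesRow <- regmatches(nx, regexpr("'O. mesovoides' +[^\n]+", nx))
  mesCells <- sub("'O. mesovoides' +", "", mesRow)
  cells <- regmatches(mesCells,
                      gregexpr("\\([0-9A-V]+\\)|[0-9A-V?]", mesCells))[[1]]
  expect_length(cells, 22)
  expect_equal(cells[7], "C")
  expect_equal(cells[1], "(567)")
  # unknown characters export as ?
  partial <- matrixFromCells(list(partial = c(rep("?", 5), rep("1", 17))))
  cellsP <- regmatches(exportNexus(partial),
                       gregexpr(" ([?1]{22})\n", exportNexus(partial)))
  expect_match(exportNexus(partial), "\\?\\?\\?\\?\\?1{17}")
  # states beyond the symbol alphabet are refused with the character named
  big <- matrixFromCells(list(big = c("40", rep("0", 21))))
  expect_error(exportNexus(big), "character 1")
  # file writing round-trips the text
  tmp <- tempfile(fileext = ".nex")
  exportNexus(cm, file = tmp)
  expect_identical(paste(readLines(tmp), collapse = "\n"),
                   sub("\n$", "", nx))
})

test_that("profile comparison classifies ranges four ways", {
  a <- matrixFromCells(list(x = c("2", "2(4)", "5", "?", rep("1", 18))))[["x"]]
  b <- matrixFromCells(list(y = c("2", "3", "7", "1", rep("1", 18))))[["y"]]
  cmp <- compareProfiles(a, b)
  expect_equal(cmp$status[1:4],
               c("identical", "compatible", "conflict", "not_comparable"))
})
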