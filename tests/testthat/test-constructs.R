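test_that("the packaged construct panel loads with the expected cut sites", {
  expect_length(fixturePanel, 12L)
  sites <- vapply(fixturePanel[c("H", "Ha", "A", "B", "C", "D", "De",
                                 "dE", "E")],
                  function(x) x@cleavageSites, integer(1))
  expect_equal(unname(sites),
               c(168L, 189L, 247L, 305L, 358L, 409L, 445L, 463L, 483L))
  expect_true(all(vapply(fixturePanel, function(x) x@length,
                         integer(1)) == 721L))
  expect_identical(fixturePanel[["UT"]]@tag, "none")
  expect_identical(fixturePanel[["CT"]]@tag, "C")
  expect_equal(fixturePanel[["CT"]]@tagMassShift, 5.7)
  # NT is the same molecule as construct C
  expect_equal(fixturePanel[["NT"]]@cleavageSites,
               fixturePanel[["C"]]@cleavageSites)
})

test_that("construct table validation rejects malformed rows", {
  write2 <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
  }
  hdr <- "name\tlength\tcleavage_sites\ttag\ttag_mass_shift"
  expect_error(loadConstructs(write2(c(hdr, "X\t100\t100\tN\t2.3"))),
               "cleavage sites")
  expect_error(loadConstructs(write2(c(hdr, "X\t100\t50\tQ\t2.3"))),
               "tag")
  expect_error(loadConstructs(write2(c(hdr, "X\t100\t50\tN\t2.3",
                                       "X\t100\t60\tN\t2.3"))),
               "duplicate")
  # empty site list is a valid no-cut construct
  panel <- loadConstructs(write2(c(hdr, "X\t100\t\tnone\t0")))
  expect_length(panel[["X"]]@cleavageSites, 0L)
  expect_equal(nrow(digest(panel[["X"]])), 1L)
})

test_that("digestion tiles the protein and labels termini and tags", {
  fr <- digest(fixturePanel[["C"]])
  expect_equal(fr$start, c(1L, 359L))
  expect_equal(fr$end, c(358L, 721L))
  expect_equal(fr$terminus, c("N", "C"))
  expect_equal(fr$tagged, c(TRUE, FALSE))   # N-FLAG construct

  fr3 <- digest(ProteinConstruct("two", 721, c(168, 483)))
  expect_equal(fr3$start, c(1L, 169L, 484L))
  expect_equal(fr3$end, c(168L, 483L, 721L))
  expect_equal(fr3$terminus, c("N", "internal", "C"))

  fr1 <- digest(ProteinConstruct("uncut", 721, tag = "C",
                                 tagMassShift = 5.7))
  expect_equal(fr1$terminus, "N+C")
  expect_true(fr1$tagged)
})

test_that("digestion tiling holds for randomized constructs", {
  set.seed(101)
  for (i in 1:50) {
    L <- sample(50:900, 1)
    k <- sample(0:5, 1)
    sites <- sort(sample.int(L - 1L, k))
    fr <- digest(ProteinConstruct("r", L, sites))
    expect_equal(nrow(fr), k + 1L)
    expect_equal(fr$start[1], 1L)
    expect_equal(fr$end[nrow(fr)], L)
    if (nrow(fr) > 1L)
      expect_equal(fr$start[-1], fr$end[-nrow(fr)] + 1L)
  }
})

test_that("band ordering across the panel mirrors the blot ladders", {
  gm <- GelModel()
  ordered <- fixturePanel[c("H", "Ha", "A", "B", "C", "D", "De", "dE", "E")]
  nMass <- vapply(ordered, function(cc)
    predictMass(digest(cc)[1, ], gm, cc), numeric(1))
  cMass <- vapply(ordered, function(cc)
    predictMass(digest(cc)[2, ], gm, cc), numeric(1))
  expect_true(all(diff(nMass) > 0))   # N fragments grow H -> E
  expect_true(all(diff(cMass) < 0))   # C fragments shrink H -> E
})
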