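helix13 <- buildHelix(13)

test_that("the U1/U6 comparison recovers the stated contact differences", {
  dd <- diffArchitectures(u1Architecture(), u6Architecture(), helix13)
  expect_equal(dd$uniqueToB, c(2L, 4L, 11L, 13L, 19L))  # U6-only contacts
  expect_equal(dd$uniqueToA, 20L)                        # U1-only contact
  expect_true(all(c(3, 5, 7, 8, 10, 12) %in% dd$shared))
})

test_that("domain shifts carry the narrated directions", {
  u1 <- u1Architecture(); u6 <- u6Architecture()
  rc <- domainShift("Rc", u1, u6, helix13)
  expect_equal(rc$phosphatesA, 8L)
  expect_equal(rc$phosphatesB, c(8L, 11L, 13L))
  expect_gt(rc$axialShiftBp, 0)    # downstream, toward the start site
  ra <- domainShift("Ra", u1, u6, helix13)
  expect_equal(ra$phosphatesB, c(2L, 4L, 7L))
  expect_lt(ra$axialShiftBp, 0)    # upstream
  # the N-terminal domain swaps phosphate 20 for 19 and turns clockwise
  nt <- domainShift("N_term", u1, u6, helix13)
  expect_gt(nt$rotationDeg, 0)
  # a domain empty on one side yields an explicit undefined result
  ct <- domainShift("C_term", u1, u6, helix13)
  expect_false(ct$defined)
  expect_true(is.na(ct$axialShiftBp))
})

test_that("self-comparison is the identity and swapping negates", {
  u6 <- u6Architecture(); u1 <- u1Architecture()
  self <- diffArchitectures(u6, u6, helix13)
  expect_length(self$uniqueToA, 0L)
  expect_length(self$uniqueToB, 0L)
  pd <- self$perDomain
  expect_true(all(pd$axialShiftBp[pd$nA > 0] == 0))
  expect_true(all(pd$rotationDeg[pd$nA > 0] == 0))

  ab <- diffArchitectures(u1, u6, helix13)
  ba <- diffArchitectures(u6, u1, helix13)
  expect_equal(ab$uniqueToA, ba$uniqueToB)
  expect_equal(ab$uniqueToB, ba$uniqueToA)
  both <- ab$perDomain$nA > 0 & ab$perDomain$nB > 0
  expect_equal(ab$perDomain$axialShiftBp[both],
               -ba$perDomain$axialShiftBp[both])
  expect_equal(ab$perDomain$rotationDeg[both],
               -ba$perDomain$rotationDeg[both])
})

test_that("a one-bp index shift reads out as one rise and one twist", {
  # same contact interval observed two phosphate indices (one bp) later
  panel <- fixturePanel
  cuts <- sort(unique(unlist(lapply(panel, function(x) x@cleavageSites))))
  mkArch <- function(phosphates) {
    contacts <- lapply(phosphates, function(ph) {
      iv <- IRanges::IRanges(306L, 358L)
      S4Vectors::mcols(iv)$grade <- "strong"
      iv
    })
    names(contacts) <- as.character(phosphates)
    truth <- new("GroundTruth", proteinLength = 721L, promoter = "SYN",
                 contacts = contacts)
    obs <- simulateObservations(truth, panel, seed = 99L)
    assignments <- lapply(phosphates, function(ph)
      inferContacts(obs[obs$phosphate == ph, ], panel))
    ContactArchitecture(assignments, snap190Domains())
  }
  a <- mkArch(c(5L, 7L, 9L))
  b <- mkArch(c(7L, 9L, 11L))
  s <- domainShift("Rb", a, b, helix13)
  expect_equal(s$axialShiftBp, 1)
  expect_equal(s$rotationDeg, 36, tolerance = 1e-9)
})

test_that("circular means match direct vector averaging", {
  set.seed(31)
  for (i in 1:20) {
    ang <- stats::runif(sample(2:8, 1), 0, 360)
    direct <- atan2(mean(sin(ang * pi / 180)),
                    mean(cos(ang * pi / 180))) * 180 / pi
    expect_equal(xlinkmap:::circularMeanDeg(ang), direct)
  }
})

test_that("mismatched proteins are refused", {
  u6 <- u6Architecture()
  small <- u6
  small@proteinLength <- 500L
  expect_error(diffArchitectures(small, u6, helix13), "length")
})
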