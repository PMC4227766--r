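test_that("a single lane constrains both sides of its cleavage site", {
  cc <- fixturePanel[["D"]]   # cut 409
  cons <- observationConstraint(
    lane(3, "D", "not_crosslinked", "crosslinked", cInt = "strong"), cc)
  expect_equal(IRanges::start(cons$mustContact), 410L)
  expect_equal(IRanges::end(cons$mustContact), 721L)
  expect_equal(IRanges::start(cons$noContact), 1L)
  expect_equal(IRanges::end(cons$noContact), 409L)

  occluded <- observationConstraint(lane(3, "D", "occluded", "occluded"),
                                    cc)
  expect_length(occluded$mustContact, 0L)
  expect_length(occluded$noContact, 0L)
})

test_that("a lone both-sides lane guarantees one contact per side", {
  obs <- lane(3, "C", "crosslinked", "crosslinked", "strong", "strong")
  a <- inferContacts(obs, fixturePanel)
  # at the one-cut grid each side is a single segment that every
  # observation-consistent contact map must touch (enumeration agrees)
  bf <- bruteForceConsistentSets(obs, fixturePanel)
  expect_equal(a@segments$status, bf$status)
  expect_equal(a@segments$status, c("required", "required"))
  iv <- expectedIntervalFrame(a)
  expect_equal(iv$start, c(1L, 359L))
  expect_equal(iv$end, c(358L, 721L))
})

test_that("mutually unsatisfiable lanes produce conflict records", {
  obs <- rbind(
    lane(3, "C", "crosslinked", "not_crosslinked", "strong"),
    lane(3, "UT", "not_crosslinked", "crosslinked", cInt = "strong"))
  a <- inferContacts(obs, fixturePanel)
  expect_gt(length(conflicts(a)), 0L)
  expect_length(contactIntervals(a), 0L)
})

test_that("occluded lanes are uninformative, not negative", {
  base <- rbind(lane(3, "B", "not_crosslinked", "crosslinked",
                     cInt = "strong"),
                lane(3, "D", "crosslinked", "not_crosslinked", "strong"))
  a1 <- inferContacts(base, fixturePanel)
  withOcc <- rbind(base, lane(3, "C", "occluded", "occluded"))
  a2 <- inferContacts(withOcc, fixturePanel)
  expect_equal(expectedIntervalFrame(a1)[c("start", "end")],
               expectedIntervalFrame(a2)[c("start", "end")])
})

test_that("untested regions shrink as informative lanes are added", {
  empty <- fixtureObs[0, ]
  expect_equal(as.data.frame(
    untestedRegions(empty, fixturePanel, proteinLength = 721))[, 1:2],
    data.frame(start = 1L, end = 721L))
  oneLane <- lane(3, "H", "occluded", "crosslinked", cInt = "strong")
  u <- untestedRegions(oneLane, fixturePanel)
  expect_equal(IRanges::start(u), 1L)
  expect_equal(IRanges::end(u), 168L)   # only the occluded side untested
  full <- obsFor(3)
  expect_length(untestedRegions(full, fixturePanel), 0L)
})

test_that("the pre-trio panel leaves the region beyond the mid cleavage open", {
  pre <- obsFor(7)
  pre <- pre[!pre$construct %in% c("UT", "NT", "CT"), ]
  a <- inferContacts(pre, fixturePanel)
  open <- c(a@ambiguous, contactIntervals(a)[
    !S4Vectors::mcols(contactIntervals(a))$resolved])
  expect_true(any(IRanges::start(open) <= 359 & IRanges::end(open) >= 409))
  # the tag-trio lanes close it
  post <- inferContacts(obsFor(7), fixturePanel)
  expect_true(any(IRanges::start(post@excluded) <= 359 &
                    IRanges::end(post@excluded) >= 409))
})

test_that("tentative negatives refine but do not constrain", {
  a <- inferContacts(obsFor(17), fixturePanel)
  iv <- expectedIntervalFrame(a)
  expect_equal(iv$end, 189L)            # formal conclusion
  expect_equal(IRanges::start(a@likely), 1L)
  expect_equal(IRanges::end(a@likely), 168L)  # suggested refinement
  # dropping the tentative row removes the refinement, not the interval
  noTent <- obsFor(17)
  noTent <- noTent[!(noTent$construct == "H" & noTent$fragment == "C"), ]
  noTent <- rbind(noTent, obsRow(17, "H", "C", "occluded",
                                 promoter = "U6"))
  b <- inferContacts(noTent, fixturePanel)
  expect_equal(expectedIntervalFrame(b)$end, 189L)
  expect_length(b@likely, 0L)
})

test_that("intensity triangulation pins the strong domain at position 14", {
  a <- inferContacts(obsFor(14), fixturePanel)
  iv <- expectedIntervalFrame(a)
  expect_equal(iv[iv$grade == "strong", "start"], 190L)
  expect_equal(iv[iv$grade == "strong", "end"], 247L)
  # without grading the strong domain cannot be isolated
  u <- inferContacts(obsFor(14), fixturePanel, grade = FALSE)
  ivu <- expectedIntervalFrame(u)
  expect_false(any(ivu$start == 190L & ivu$end == 247L))
})

test_that("gradeIntensity upgrades an ungraded assignment", {
  ungraded <- inferContacts(obsFor(7), fixturePanel, grade = FALSE)
  graded <- gradeIntensity(ungraded, fixtureObs, fixturePanel)
  iv <- expectedIntervalFrame(graded)
  expect_equal(iv$grade, c("strong", "weak"))
})

test_that("inference output matches the intensity-world oracle on fixtures", {
  for (ph in c(2, 7, 14, 19, 22, 24)) {
    obs <- obsFor(ph)
    used <- fixturePanel[unique(obs$construct)]
    orc <- gradedOracle(obs, used, 721L)
    a <- inferContacts(obs, fixturePanel)
    expect_length(a@warnings, 0L)
    expect_equal(a@segments$status, orc$status,
                 info = paste("position", ph))
    det <- which(!is.na(orc$determined) & orc$status == "required")
    for (j in det)
      expect_equal(match(a@segments$grade[j],
                         c("very_weak", "weak", "strong")),
                   orc$determined[j], info = paste("position", ph,
                                                   "segment", j))
  }
})
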