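panelCuts <- sort(unique(unlist(lapply(fixturePanel,
                                       function(x) x@cleavageSites))))

mkTruth <- function(spec, promoter = "SYN") {
  contacts <- lapply(spec, function(tab) {
    iv <- IRanges::IRanges(tab$start, tab$end)
    S4Vectors::mcols(iv)$grade <- tab$grade
    iv
  })
  new("GroundTruth", proteinLength = 721L, promoter = promoter,
      contacts = contacts)
}

test_that("the forward model reproduces the single-domain lane pattern", {
  truth <- mkTruth(list(`3` = data.frame(start = 410, end = 483,
                                         grade = "strong")))
  obs <- simulateObservations(truth, fixturePanel, seed = 3L)
  pick <- function(cc, frag)
    obs$call[obs$construct == cc & obs$fragment == frag]
  # C-terminal fragments cross-link for every cut 5' of the domain,
  # the N-terminal fragment only for the cut 3' of it
  for (cc in c("H", "A", "B", "C", "D")) {
    expect_identical(pick(cc, "C"), "crosslinked")
    expect_identical(pick(cc, "N"), "not_crosslinked")
  }
  expect_identical(pick("E", "N"), "crosslinked")
  expect_identical(pick("E", "C"), "not_crosslinked")
  expect_true(all(obs$intensity[obs$call == "crosslinked"] == "strong"))
})

test_that("zero-noise observations invert to the simulated truth", {
  set.seed(9)
  for (i in 1:25) {
    truth <- sampleGroundTruth(c(3L, 8L), panelCuts, 721L,
                               maxIntervals = 2L)
    obs <- simulateObservations(truth, fixturePanel, seed = 1000L + i)
    part <- segmentPartition(panelCuts, 721L)
    for (ph in c(3L, 8L)) {
      a <- inferContacts(obs[obs$phosphate == ph, ], fixturePanel,
                         grade = FALSE)
      expect_length(conflicts(a), 0L)
      reqSegs <- which(a@segments$status == "required")
      iv <- truth@contacts[[as.character(ph)]]
      trueSegs <- which(vapply(seq_len(nrow(part)), function(s)
        any(IRanges::start(iv) <= part$end[s] &
              IRanges::end(iv) >= part$start[s]), logical(1)))
      expect_equal(reqSegs, trueSegs)
    }
  }
})

test_that("inference stays sound for truths beyond the identifiable regime", {
  # with three contacted segments the middle one may be unprovable, but the
  # answer must bracket the truth: required within it, nothing excluded
  set.seed(13)
  for (i in 1:20) {
    truth <- sampleGroundTruth(3L, panelCuts, 721L, maxIntervals = 3L)
    obs <- simulateObservations(truth, fixturePanel, seed = 2000L + i)
    part <- segmentPartition(panelCuts, 721L)
    a <- inferContacts(obs[obs$phosphate == 3L, ], fixturePanel,
                       grade = FALSE)
    expect_length(conflicts(a), 0L)
    iv <- truth@contacts[["3"]]
    trueSegs <- which(vapply(seq_len(nrow(part)), function(s)
      any(IRanges::start(iv) <= part$end[s] &
            IRanges::end(iv) >= part$start[s]), logical(1)))
    reqSegs <- which(a@segments$status == "required")
    exclSegs <- which(a@segments$status == "excluded")
    expect_true(all(reqSegs %in% trueSegs))
    expect_length(intersect(exclSegs, trueSegs), 0L)
  }
})

test_that("simulation is deterministic given the seed", {
  truth <- mkTruth(list(`3` = data.frame(start = c(1, 410),
                                         end = c(168, 483),
                                         grade = c("weak", "strong"))))
  noise <- NoiseModel(pFalseNegative = 0.3, pIntensityMisgrade = 0.3)
  o1 <- simulateObservations(truth, fixturePanel, noise = noise, seed = 7L)
  o2 <- simulateObservations(truth, fixturePanel, noise = noise, seed = 7L)
  expect_identical(o1, o2)
  o3 <- simulateObservations(truth, fixturePanel, noise = noise, seed = 8L)
  expect_false(identical(o1$call, o3$call))
})

test_that("total dropout silences every call", {
  truth <- mkTruth(list(`3` = data.frame(start = 410, end = 483,
                                         grade = "strong")))
  obs <- simulateObservations(truth, fixturePanel,
                              noise = NoiseModel(pFalseNegative = 1),
                              seed = 5L)
  expect_true(all(obs$call == "not_crosslinked"))
  a <- inferContacts(obs, fixturePanel, grade = FALSE)
  expect_length(contactIntervals(a), 0L)
  expect_equal(sum(IRanges::width(a@excluded)), 721L)
})

test_that("occlusion hides bands but never invents cross-links", {
  truth <- mkTruth(list(`3` = data.frame(start = 410, end = 483,
                                         grade = "strong")))
  gm <- GelModel()
  # occluder co-migrating with construct H's C fragment (553 aa, 60.8 kDa)
  noise <- NoiseModel(occluders = data.frame(label = "other", mass = 60.8))
  occ <- simulateObservations(truth, fixturePanel, gm, noise, seed = 5L)
  clean <- simulateObservations(truth, fixturePanel, gm, NoiseModel(),
                                seed = 5L)
  expect_identical(occ$call[occ$construct == "H" & occ$fragment == "C"],
                   "occluded")
  # occluded rows were cross-linked or silent before, never the reverse
  flipped <- occ$call == "crosslinked" & clean$call != "crosslinked"
  expect_false(any(flipped))
})

test_that("recovery degrades monotonically with dropout noise", {
  rec <- recoveryExperiment(40, fixturePanel,
                            noiseGrid = c(0, 0.1, 0.4), seed = 11L,
                            phosphates = 3L, maxIntervals = 2L)
  expect_equal(rec$recovery[1], 1.0)
  expect_true(all(diff(rec$recovery) <= 0.05))  # Monte-Carlo jitter margin
  expect_gt(rec$conflictRate[3], 0)
  # reproducible
  rec2 <- recoveryExperiment(40, fixturePanel,
                             noiseGrid = c(0, 0.1, 0.4), seed = 11L,
                             phosphates = 3L, maxIntervals = 2L)
  expect_identical(rec, rec2)
})
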