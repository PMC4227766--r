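gm <- GelModel()

test_that("fragment masses follow the average-residue model plus tag shift", {
  cc <- fixturePanel[["C"]]   # cut 358, N-tagged (+2.3)
  fr <- digest(cc)
  # independent arithmetic: residues x 0.110 (+ tag)
  expect_equal(predictMass(fr[1, ], gm, stripped <- ProteinConstruct(
    "u", 721, 358)), 358 * 0.110, tolerance = 1e-12)
  expect_equal(predictMass(fr[1, ], gm, cc), 358 * 0.110 + 2.3,
               tolerance = 1e-12)
  expect_equal(predictMass(fr[2, ], gm, cc), 363 * 0.110,
               tolerance = 1e-12)
  expect_error(predictMass(data.frame(start = 5, end = 4, tagged = FALSE),
                           gm), "zero-length")
})

test_that("sequence-based masses override the average model", {
  cc <- ProteinConstruct("seq", 6, 3, sequence = "GGGWWW")
  fr <- digest(cc)
  # 3 glycines + water vs 3 tryptophans + water
  expect_equal(predictMass(fr[1, ], gm, cc), 3 * 0.0570519 + 0.018,
               tolerance = 1e-6)
  expect_equal(predictMass(fr[2, ], gm, cc), 3 * 0.1862132 + 0.018,
               tolerance = 1e-6)
})

test_that("mass prediction is strictly increasing in fragment length", {
  cc <- ProteinConstruct("m", 500, c(100, 250, 450))
  fr <- digest(cc)
  masses <- predictMass(fr, gm, cc)
  lens <- fr$end - fr$start + 1L
  expect_true(all(diff(masses[order(lens)]) > 0))
})

test_that("the mid-protein cleavage co-migrates but the distal one resolves", {
  pairsC <- comigrationPairs(fixturePanel[["C"]], gm)
  expect_equal(nrow(pairsC), 1L)
  expect_lt(pairsC$relDiff, 0.05)
  expect_gt(pairsC$relDiff, 0.04)   # ~4.2 % for 41.68 vs 39.93 kDa

  pairsE <- comigrationPairs(fixturePanel[["E"]], gm)
  expect_equal(nrow(pairsE), 0L)

  same <- data.frame(label = c("a", "b"), mass = c(10, 10))
  expect_equal(comigrationPairs(same, gm)$relDiff, 0)
})

test_that("co-migration detection honours extra bands from other subunits", {
  gmX <- GelModel(extraBands = data.frame(label = "other", mass = 26.2))
  pairs <- comigrationPairs(fixturePanel[["E"]], gmX)
  expect_equal(nrow(pairs), 1L)     # the 26.18 kDa C fragment is occludable
  expect_true(any(grepl("other", c(pairs$label1, pairs$label2))))
})

test_that("tag-variant design resolves the ambiguity or reports failure", {
  d <- designTagResolution(fixturePanel[["C"]], gm)
  expect_true(d$resolvable)
  expect_equal(d$variants$variant, c("UT", "NT", "CT"))
  # the N tag shifts only the N band, the C tag only the C band
  ut <- d$variants[d$variants$variant == "UT", ]
  nt <- d$variants[d$variants$variant == "NT", ]
  ct <- d$variants[d$variants$variant == "CT", ]
  expect_equal(nt$nMass - ut$nMass, 2.3)
  expect_equal(nt$cMass, ut$cMass)
  expect_equal(ct$cMass - ut$cMass, 5.7)
  expect_equal(ct$nMass, ut$nMass)

  noPair <- designTagResolution(fixturePanel[["E"]], gm)
  expect_true(noPair$resolvable)
  expect_equal(nrow(noPair$variants), 0L)

  stuck <- designTagResolution(fixturePanel[["C"]], gm,
                               tagShifts = c(N = 0, C = 0))
  expect_false(stuck$resolvable)
})
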