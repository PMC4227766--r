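h <- buildHelix(13)

test_that("helix construction obeys helical symmetry", {
  co <- h@coords
  nt <- co[co$strand == "non_template", ]
  # one full turn: same azimuth, 10 x 3.34 A higher
  expect_equal(nt$faceAngle[nt$bp == 11], nt$faceAngle[nt$bp == 1])
  expect_equal(nt$z[nt$bp == 11] - nt$z[nt$bp == 1], 33.4)
  # rotating by k turns of twist + translating k rises maps bp i to i+k
  p <- h@params
  for (k in c(1, 3, 7)) {
    th <- k * p@twistDeg * pi / 180
    rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    for (strand in c("non_template", "template")) {
      s <- co[co$strand == strand, ]
      from <- s[s$bp <= 13 - k, ]
      to <- s[s$bp >= k + 1, ]
      moved <- as.matrix(from[, c("x", "y")]) %*% t(rot)
      expect_equal(unname(moved), unname(as.matrix(to[, c("x", "y")])),
                   tolerance = 1e-9)
      expect_equal(from$z + k * p@riseA, to$z)
    }
  }
})

test_that("adjacent same-strand phosphates sit at the closed-form distance", {
  # chord 2 r sin(18 deg) combined with one rise
  expected <- sqrt((2 * 9.4 * sin(pi / 10))^2 + 3.34^2)
  got <- grooveRelationship(1, 3, h)
  expect_equal(got$distanceA, expected, tolerance = 1e-12)
  expect_identical(got$class, "same_strand_track")
})

test_that("degenerate helix inputs are rejected", {
  expect_error(buildHelix(1), ">= 2")
  expect_error(HelixParams(twistDeg = 0), "twist")
  expect_error(HelixParams(riseA = -1), "rise")
})

test_that("model generation is bit-reproducible", {
  h2 <- buildHelix(13)
  expect_identical(h@coords, h2@coords)
})

test_that("cross-strand pairs classify by the groove the arc crosses", {
  expect_identical(grooveRelationship(8, 11, h)$class, "minor_groove_span")
  expect_identical(grooveRelationship(8, 13, h)$class, "minor_groove_span")
  expect_identical(grooveRelationship(7, 2, h)$class, "minor_groove_span")
  expect_identical(grooveRelationship(7, 4, h)$class, "minor_groove_span")
  expect_identical(grooveRelationship(19, 20, h)$class, "opposite_face")
  # minor-groove spans are within protein reach; distances are realistic
  for (pair in list(c(8, 11), c(8, 13), c(7, 2), c(7, 4))) {
    rel <- grooveRelationship(pair[1], pair[2], h)
    expect_true(rel$withinReach)
    expect_gt(rel$distanceA, 10)
    expect_lt(rel$distanceA, 18)
  }
  # same phosphate: zero distance on its own track
  self <- grooveRelationship(8, 8, h)
  expect_identical(self$class, "same_strand_track")
  expect_equal(self$distanceA, 0)
})

test_that("classification is invariant under translation along the helix", {
  for (shift in c(2L, 4L)) {
    a <- grooveRelationship(8, 11, h)
    b <- grooveRelationship(8 + 2L * shift, 11 + 2L * shift, h)
    expect_identical(a$class, b$class)
    expect_equal(a$distanceA, b$distanceA, tolerance = 1e-9)
  }
})

test_that("swapping the strand roles flips minor to major", {
  # template bp 4 / non-template bp 6 spans the minor groove; the mirrored
  # arrangement (non-template bp 4 / template bp 6) must span the major one
  expect_identical(grooveRelationship(8, 11, h)$class, "minor_groove_span")
  expect_identical(grooveRelationship(7, 12, h)$class, "major_groove_span")
})

test_that("architecture projection annotates every contacted phosphate", {
  arch <- u6Architecture()
  ann <- projectArchitecture(arch, h)
  expect_equal(nrow(ann), 16L)
  expect_setequal(ann$phosphate, as.integer(names(arch@assignments)))
  expect_true(all(ann$domain %in% names(arch@domains)))
  # strongest-domain colouring: position 8 belongs to the repeat spanning
  # residues 359-409, position 17 to the N-terminal region
  expect_identical(ann$domain[ann$phosphate == 8], "Rc")
  expect_identical(ann$domain[ann$phosphate == 17], "N_term")
  expect_error(projectArchitecture(arch, buildHelix(3)), "outside")
})

test_that("PDB export is deterministic and viewer-ready", {
  arch <- u6Architecture()
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  projectArchitecture(arch, h, pdbPath = f1)
  projectArchitecture(arch, h, pdbPath = f2)
  expect_identical(readLines(f1), readLines(f2))
  atoms <- grep("^ATOM", readLines(f1), value = TRUE)
  expect_length(atoms, 2L * h@nBp)
})
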