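#' Create an observation noise model
#'
#' @param pFalseNegative Per-fragment probability that a truly cross-linked
#'   band is missed (default 0).
#' @param pIntensityMisgrade Per-call probability that a cross-linked call's
#'   ordinal intensity shifts one level up or down (default 0).
#' @param occluders `data.frame` (`label`, `mass` in kDa) of labelled bands
#'   from other species; any fragment co-migrating with one (at the gel
#'   model's tolerance) is called `occluded`.
#' @return A validated [NoiseModel-class].
#' @export
NoiseModel <- function(pFalseNegative = 0, pIntensityMisgrade = 0,
                       occluders = data.frame(label = character(),
                                              mass = numeric())) {
  new("NoiseModel", pFalseNegative = pFalseNegative,
      pIntensityMisgrade = pIntensityMisgrade, occluders = occluders)
}

#' Sample a random ground-truth contact map
#'
#' Draws, for each phosphate, 1-3 contact intervals on the segment grid
#' defined by `cutSites` (uniform interval count, uniform segment choice,
#' uniform ordinal intensity), mirroring the 1-3 contacted domains per
#' position seen in real footprints. Adjacent drawn segments merge into one
#' interval carrying the stronger grade. Uses the current RNG state; seed
#' control belongs to the caller (see [recoveryExperiment()]).
#'
#' @param phosphates Integer phosphate indices to populate.
#' @param cutSites Cleavage-site grid of the construct panel.
#' @param proteinLength Residue count.
#' @param maxIntervals Maximum contacted segments per phosphate (default 3).
#' @param promoter Label stored on the result.
#' @return A [GroundTruth-class].
#' @export
sampleGroundTruth <- function(phosphates, cutSites, proteinLength,
                              maxIntervals = 3L, promoter = "synthetic") {
  part <- segmentPartition(cutSites, proteinLength)
  nseg <- nrow(part)
  contacts <- lapply(phosphates, function(ph) {
    k <- sample.int(min(maxIntervals, nseg), 1L)
    segs <- sort(sample.int(nseg, k))
    iv <- asIRanges(part$start[segs], part$end[segs])
    grades <- sample(INTENSITY_LEVELS, k, replace = TRUE)
    merged <- IRanges::reduce(iv)
    hits <- IRanges::findOverlaps(iv, merged)
    mg <- vapply(seq_along(merged), function(i) {
      max(intensityCode(grades[S4Vectors::queryHits(hits)[
        S4Vectors::subjectHits(hits) == i]]))
    }, integer(1))
    mcols(merged)$grade <- intensityLabel(mg)
    merged
  })
  names(contacts) <- as.character(phosphates)
  new("GroundTruth", proteinLength = as.integer(proteinLength),
      promoter = promoter, contacts = contacts)
}

#' Simulate an observation table from a ground truth
#'
#' The forward model of the cross-link/cleave experiment: for every
#' (construct, phosphate) pair, a digestion fragment is truly cross-linked
#' iff it overlaps at least one true contact interval, with intensity equal
#' to the strongest overlapped grade. False negatives then silence
#' cross-linked calls, misgrades shift intensities by one level, and any
#' fragment co-migrating with an occluder band is reported `occluded`
#' (occlusion replaces the call, so it can hide but never invent a
#' cross-link). Deterministic given `seed`.
#'
#' @param truth A [GroundTruth-class].
#' @param constructs Construct panel (named list of
#'   [ProteinConstruct-class]).
#' @param gelModel A [GelModel-class] (used for occluder co-migration).
#' @param noise A [NoiseModel-class].
#' @param seed Integer seed; recorded in the result's `"seed"` attribute.
#' @return Observation `data.frame` in [readObservations()] layout.
#' @export
simulateObservations <- function(truth, constructs, gelModel = GelModel(),
                                 noise = NoiseModel(), seed = 1L) {
  validObject(truth); validObject(noise)
  set.seed(seed)
  digests <- lapply(constructs, function(cc) {
    fr <- digest(cc)
    if (nrow(fr) >= 2L) {
      fr$fragment[1L] <- "N"
      fr$fragment[nrow(fr)] <- "C"
    }
    fr
  })
  allFrags <- do.call(rbind, digests)
  allMass <- unlist(lapply(names(constructs), function(cn)
    predictMass(digests[[cn]], gelModel, constructs[[cn]])),
    use.names = FALSE)
  occludedFrag <- rep(FALSE, nrow(allFrags))
  if (nrow(noise@occluders)) {
    for (i in seq_len(nrow(allFrags))) {
      rel <- abs(noise@occluders$mass - allMass[i]) /
        pmax(noise@occluders$mass, allMass[i])
      occludedFrag[i] <- any(rel <= gelModel@relTolerance)
    }
  }
  nf <- nrow(allFrags)
  keys <- names(truth@contacts)
  blocks <- lapply(keys, function(key) {
    ph <- as.integer(key)
    iv <- truth@contacts[[key]]
    gradeCode <- intensityCode(mcols(iv)$grade)
    fragGrade <- vapply(seq_len(nf), function(i) {
      hit <- start(iv) <= allFrags$end[i] & end(iv) >= allFrags$start[i]
      if (any(hit)) max(gradeCode[hit]) else 0L
    }, integer(1))
    call <- ifelse(fragGrade > 0L, "crosslinked", "not_crosslinked")
    drop <- fragGrade > 0L & stats::runif(nf) < noise@pFalseNegative
    call[drop] <- "not_crosslinked"; fragGrade[drop] <- 0L
    mis <- fragGrade > 0L & stats::runif(nf) < noise@pIntensityMisgrade
    if (any(mis)) {
      shift <- sample(c(-1L, 1L), sum(mis), replace = TRUE)
      fragGrade[mis] <- pmin(pmax(fragGrade[mis] + shift, 1L), 3L)
    }
    call[occludedFrag] <- "occluded"; fragGrade[occludedFrag] <- 0L
    data.frame(
      promoter = truth@promoter, phosphate = ph,
      strand = phosphateStrand(ph), construct = allFrags$parent,
      fragment = allFrags$fragment, call = call,
      intensity = ifelse(fragGrade > 0L, INTENSITY_LEVELS[fragGrade],
                         NA_character_),
      tentative = FALSE, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

# Segment-level contacted set implied by a ground truth for one phosphate.
truthSegments <- function(truth, key, partition) {
  iv <- truth@contacts[[key]]
  which(vapply(seq_len(nrow(partition)), function(i)
    any(start(iv) <= partition$end[i] & end(iv) >= partition$start[i]),
    logical(1)))
}

#' Noise-robustness experiment: simulate, invert, score
#'
#' For each noise level, repeatedly samples a ground truth, simulates an
#' observation table, runs [inferContacts()] per phosphate, and scores the
#' inversion at segment resolution: `recovery` is the fraction of replicates
#' in which every phosphate's `required` segment set equals the true
#' contacted set, `meanSegError` the mean number of misclassified segments
#' per phosphate, and `conflictRate` the fraction of per-phosphate
#' inferences that ended in conflict. Reproducible given `seed`.
#'
#' Note the identifiability limit of the assay geometry: with single-cut
#' constructs, a contacted segment lying strictly between two other
#' contacted segments of the same phosphate can never be *required* by
#' presence logic (the minimal consistent map omits it), so exact recovery
#' of arbitrary 3-segment truths is impossible even without noise. Truths
#' with at most two contacted segments per phosphate (`maxIntervals = 2`)
#' are always exactly recoverable at zero noise.
#'
#' @param nReplicates Replicates per noise level.
#' @param constructs Construct panel whose cut sites define the grid.
#' @param noiseGrid Numeric vector of `pFalseNegative` values.
#' @param seed Integer master seed (recorded in the result).
#' @param phosphates Phosphate indices per truth (default `c(3, 8, 17)`).
#' @param gelModel A [GelModel-class].
#' @param maxIntervals Passed to [sampleGroundTruth()] (default 3; use 2 for
#'   the fully identifiable regime).
#' @return `data.frame` with one row per noise level: `pFalseNegative`,
#'   `recovery`, `meanSegError`, `conflictRate`, `nReplicates`, `seed`.
#' @export
recoveryExperiment <- function(nReplicates, constructs, noiseGrid = 0,
                               seed = 1L, phosphates = c(3L, 8L, 17L),
                               gelModel = GelModel(), maxIntervals = 3L) {
  stopifnot(nReplicates >= 1L)
  L <- unique(vapply(constructs, function(x) x@length, integer(1)))
  stopifnot(length(L) == 1L)
  cutSites <- sort(unique(unlist(lapply(constructs,
                                        function(x) x@cleavageSites))))
  part <- segmentPartition(cutSites, L)
  out <- lapply(seq_along(noiseGrid), function(gi) {
    p <- noiseGrid[gi]
    exact <- logical(nReplicates)
    segErr <- numeric(nReplicates)
    confl <- numeric(nReplicates)
    for (r in seq_len(nReplicates)) {
      repSeed <- (seed + 7919L * gi + r) %% .Machine$integer.max
      set.seed(repSeed)
      truth <- sampleGroundTruth(phosphates, cutSites, L,
                                 maxIntervals = maxIntervals)
      obs <- simulateObservations(truth, constructs, gelModel,
                                  NoiseModel(pFalseNegative = p),
                                  seed = repSeed + 1L)
      okAll <- TRUE; errs <- numeric(); conflicted <- 0L
      for (ph in phosphates) {
        sub <- obs[obs$phosphate == ph, , drop = FALSE]
        a <- inferContacts(sub, constructs, proteinLength = L,
                           grade = FALSE)
        trueSegs <- truthSegments(truth, as.character(ph), part)
        if (length(conflicts(a))) {
          conflicted <- conflicted + 1L
          okAll <- FALSE
          errs <- c(errs, length(trueSegs))
          next
        }
        reqSegs <- which(a@segments$status == "required")
        errs <- c(errs, length(union(setdiff(reqSegs, trueSegs),
                                     setdiff(trueSegs, reqSegs))))
        if (!setequal(reqSegs, trueSegs)) okAll <- FALSE
      }
      exact[r] <- okAll
      segErr[r] <- mean(errs)
      confl[r] <- conflicted / length(phosphates)
    }
    data.frame(pFalseNegative = p, recovery = mean(exact),
               meanSegError = mean(segErr), conflictRate = mean(confl),
               nReplicates = nReplicates, seed = seed)
  })
  do.call(rbind, out)
}
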