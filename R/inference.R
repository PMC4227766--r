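#' Segment partition induced by a set of cleavage sites
#'
#' The resolution grid of the mapping method: cut sites partition the protein
#' `[1, L]` into `length(cutSites) + 1` closed segments whose boundaries are
#' the sites themselves. Every inference result is expressed on this grid.
#'
#' @param cutSites Integer residue indices (cleavage after each).
#' @param proteinLength Residue count `L`.
#' @return `data.frame` with columns `start`, `end`, one row per segment.
#' @export
segmentPartition <- function(cutSites, proteinLength) {
  s <- sort(unique(as.integer(cutSites)))
  if (any(s < 1L | s >= proteinLength))
    stop("cut sites must satisfy 1 <= site < proteinLength")
  data.frame(start = c(1L, s + 1L), end = c(s, as.integer(proteinLength)))
}

# Map a residue interval aligned to the cut grid onto segment indices.
segmentsWithin <- function(partition, start, end) {
  which(partition$start >= start & partition$end <= end)
}

# Translate an observation table for one probe into constraint atoms on the
# segment grid. Returns a list:
#   partition    segment grid (union of referenced constructs' cut sites)
#   positives    list of (segs, gamma, label) for cross-linked fragments
#   exclusions   list of (segs, label) for hard missing bands
#   tentative    list of (segs, label) for tentative missing bands
#   covered      segment indices touched by any informative call
constraintAtoms <- function(observations, constructs, proteinLength) {
  cn <- unique(observations$construct)
  unknown <- setdiff(cn, names(constructs))
  if (length(unknown))
    stop("unknown construct(s) in observations: ",
         paste(unknown, collapse = ", "))
  cutSites <- sort(unique(unlist(lapply(constructs[cn],
                                        function(x) x@cleavageSites))))
  partition <- segmentPartition(cutSites, proteinLength)
  positives <- list(); exclusions <- list(); tentative <- list()
  covered <- integer()
  for (name in cn) {
    sub <- observations[observations$construct == name, , drop = FALSE]
    cons <- observationConstraint(sub, constructs[[name]])
    addAtoms <- function(ranges, what) {
      lapply(seq_along(ranges), function(i) {
        segs <- segmentsWithin(partition, start(ranges)[i], end(ranges)[i])
        label <- sprintf("%s[%d,%d]", name, start(ranges)[i], end(ranges)[i])
        list(segs = segs, label = label,
             gamma = if (what == "positive")
               intensityCode(mcols(ranges)$intensity[i]) else NA_integer_)
      })
    }
    pos <- addAtoms(cons$mustContact, "positive")
    exc <- addAtoms(cons$noContact, "negative")
    ten <- addAtoms(cons$tentativeNoContact, "tentative")
    positives <- c(positives, pos)
    exclusions <- c(exclusions, exc)
    tentative <- c(tentative, ten)
    covered <- union(covered, unlist(lapply(c(pos, exc), `[[`, "segs")))
  }
  list(partition = partition, positives = positives, exclusions = exclusions,
       tentative = tentative, covered = sort(covered))
}

# Binary possible-world analysis (presence semantics). Complete for this
# constraint class: a segment is required iff some cross-linked fragment's
# support shrinks to that single segment after removing excluded segments,
# and excluded iff inside some hard missing-band fragment.
binaryStage <- function(atoms, extraExclusions = list()) {
  nseg <- nrow(atoms$partition)
  excluded <- sort(unique(unlist(c(
    lapply(atoms$exclusions, `[[`, "segs"),
    lapply(extraExclusions, `[[`, "segs")))))
  conflicts <- character()
  supports <- lapply(atoms$positives, function(p) setdiff(p$segs, excluded))
  for (i in seq_along(supports)) {
    if (length(supports[[i]]) == 0L)
      conflicts <- c(conflicts, sprintf(
        "cross-linked fragment %s has no allowed contact segment",
        atoms$positives[[i]]$label))
  }
  required <- sort(unique(unlist(
    supports[lengths(supports) == 1L])))
  list(nseg = nseg, excluded = excluded, required = required,
       supports = supports, conflicts = conflicts)
}

# Graded refinement: ordinal intensity triangulation on top of the binary
# result. Weak/strong band intensities act as equality constraints on the
# within-fragment maximum contact grade; very-weak bands contribute presence
# only (faint-band intensities are unreliable). When the weak/strong
# constraints are jointly unsatisfiable the fewest (faintest-first) are
# demoted to presence-only, with a warning.
gradedStage <- function(atoms, binary) {
  positives <- atoms$positives
  supports <- binary$supports
  gammas <- vapply(positives, `[[`, integer(1), "gamma")
  gradedIdx <- which(gammas >= 2L & lengths(supports) > 0L)
  evalDrop <- function(drop) {
    keep <- setdiff(gradedIdx, drop)
    caps <- rep(Inf, binary$nseg)
    for (i in keep)
      caps[supports[[i]]] <- pmin(caps[supports[[i]]], gammas[i])
    forced <- rep(NA_integer_, binary$nseg)
    for (i in keep) {
      cand <- supports[[i]][caps[supports[[i]]] >= gammas[i]]
      if (length(cand) == 0L) return(NULL)         # unsatisfiable
      if (length(cand) == 1L) {
        if (!is.na(forced[cand]) && forced[cand] != gammas[i]) return(NULL)
        forced[cand] <- gammas[i]
      }
    }
    list(caps = caps, forced = forced, dropped = drop)
  }
  sol <- evalDrop(integer())
  warnings <- character()
  if (is.null(sol) && length(gradedIdx)) {
    found <- NULL
    for (k in 1L:min(3L, length(gradedIdx))) {
      combos <- utils::combn(gradedIdx, k, simplify = FALSE)
      ord <- order(vapply(combos, function(d) sum(gammas[d]), numeric(1)))
      for (d in combos[ord]) {
        cand <- evalDrop(d)
        if (!is.null(cand)) { found <- cand; break }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      found <- list(caps = rep(Inf, binary$nseg),
                    forced = rep(NA_integer_, binary$nseg),
                    dropped = gradedIdx)
    }
    sol <- found
    labels <- vapply(positives[sol$dropped], `[[`, character(1), "label")
    warnings <- sprintf(
      "band intensity of %s inconsistent with other lanes; used as presence evidence only",
      labels)
  }
  if (is.null(sol))
    sol <- list(caps = rep(Inf, binary$nseg),
                forced = rep(NA_integer_, binary$nseg), dropped = integer())
  c(sol, list(warnings = warnings))
}

newAssignment <- function(phosphate, strand, promoter, proteinLength,
                          cutSites, intervals, ambiguous, excluded, untested,
                          likely, conflicts, warnings, segments) {
  new("ContactAssignment", phosphate = as.integer(phosphate),
      strand = strand, promoter = promoter,
      proteinLength = as.integer(proteinLength),
      cutSites = as.integer(cutSites), intervals = intervals,
      ambiguous = ambiguous, excluded = excluded, untested = untested,
      likely = likely, conflicts = conflicts, warnings = warnings,
      segments = segments)
}

emptyGradedIRanges <- function() {
  iv <- IRanges::IRanges()
  mcols(iv) <- S4Vectors::DataFrame(grade = character(),
                                    resolved = logical())
  iv
}

#' Infer the contact assignment for one phosphate position
#'
#' The core deduction of the mapping method. Each construct lane constrains
#' where contacts can lie: a cross-linked fragment demands at least one
#' contact inside it, a missing band forbids contact anywhere inside it, and
#' an occluded band says nothing. The engine computes, on the segment grid
#' defined by the panel's cut sites, which segments are contacted in every
#' observation-consistent contact map (`required`), in none (`excluded`), or
#' undetermined (`ambiguous`), and reports contact intervals as (i) the
#' required segments, each under its own grade (grid-adjacent required
#' segments stay separate, the way gel summaries report regions on either
#' side of a cut site), and (ii) *entailed runs* --
#' contiguous undetermined stretches that every consistent map must touch,
#' whose internal boundaries the panel cannot resolve (reported with
#' `resolved = FALSE`).
#'
#' With `grade = TRUE`, ordinal band intensities are triangulated: a weak or
#' strong band pins the maximum contact grade within its fragment, which can
#' localize a strong contact that presence logic alone cannot (a strong band
#' over a fragment whose remaining segments are capped weak forces the strong
#' contact into the uncapped segment). Very-weak bands are treated as
#' presence evidence only. Mutually unsatisfiable presence constraints yield
#' conflict records and no intervals; unsatisfiable intensity patterns are
#' resolved by demoting the fewest, faintest intensity readings with a
#' warning.
#'
#' Tentative negatives (suggestive missing bands) are not used as hard
#' constraints; when adding them back would shrink a reported interval, the
#' shrunken version is recorded in the assignment's `likely` slot.
#'
#' @param observations Observation table rows for a single probe (see
#'   [readObservations()]).
#' @param constructs Construct panel (named list of
#'   [ProteinConstruct-class]).
#' @param proteinLength Residue count of the mapped protein. Defaults to the
#'   common length of the referenced constructs.
#' @param grade Apply intensity triangulation (default `TRUE`).
#' @return A [ContactAssignment-class].
#' @examples
#' panel <- u6ConstructPanel()
#' obs <- u6Observations()
#' pos3 <- inferContacts(obs[obs$phosphate == 3, ], panel)
#' contactIntervals(pos3)   # single interval [410, 483], strong
#' @export
inferContacts <- function(observations, constructs,
                          proteinLength = NULL, grade = TRUE) {
  stopifnot(nrow(observations) > 0L)
  ph <- unique(observations$phosphate)
  st <- unique(observations$strand)
  pr <- unique(observations$promoter)
  if (length(ph) != 1L || length(st) != 1L || length(pr) != 1L)
    stop("'observations' must describe a single probe; got ",
         length(ph), " phosphate position(s)")
  used <- constructs[intersect(names(constructs),
                               unique(observations$construct))]
  lens <- unique(vapply(used, function(x) x@length, integer(1)))
  if (is.null(proteinLength)) {
    if (length(lens) != 1L)
      stop("constructs disagree on protein length; pass 'proteinLength'")
    proteinLength <- lens
  }
  validateObservations(observations, constructs)
  atoms <- constraintAtoms(observations, constructs, proteinLength)
  part <- atoms$partition
  nseg <- nrow(part)
  cutSites <- part$end[-nseg]
  binary <- binaryStage(atoms)

  segFrame <- function(status, gradeLab) {
    data.frame(start = part$start, end = part$end, status = status,
               grade = gradeLab, stringsAsFactors = FALSE)
  }

  if (length(binary$conflicts)) {
    return(newAssignment(ph, st, pr, proteinLength, cutSites,
                         emptyGradedIRanges(), IRanges::IRanges(),
                         IRanges::IRanges(), IRanges::IRanges(),
                         IRanges::IRanges(), binary$conflicts, character(),
                         segFrame("conflict", NA_character_)))
  }

  graded <- if (grade) gradedStage(atoms, binary) else
    list(caps = rep(Inf, nseg), forced = rep(NA_integer_, nseg),
         dropped = integer(), warnings = character())

  required <- sort(union(binary$required, which(!is.na(graded$forced))))
  excluded <- binary$excluded
  untested <- setdiff(seq_len(nseg), union(atoms$covered, excluded))
  ambiguous <- setdiff(seq_len(nseg), c(required, excluded, untested))

  # per-segment grade for required segments
  gammas <- vapply(atoms$positives, `[[`, integer(1), "gamma")
  segGrade <- rep(NA_integer_, nseg)
  segGrade[!is.na(graded$forced)] <- graded$forced[!is.na(graded$forced)]
  for (i in seq_along(binary$supports)) {
    sup <- binary$supports[[i]]
    if (length(sup) == 1L && is.na(segGrade[sup]))
      segGrade[sup] <- gammas[i]
  }

  status <- rep("ambiguous", nseg)
  status[required] <- "required"
  status[excluded] <- "excluded"
  status[untested] <- "untested"

  # assemble reported intervals
  ivStart <- integer(); ivEnd <- integer(); ivGrade <- character()
  ivResolved <- logical()
  ambStart <- integer(); ambEnd <- integer()
  i <- 1L
  while (i <= nseg) {
    if (status[i] == "required") {
      ivStart <- c(ivStart, part$start[i]); ivEnd <- c(ivEnd, part$end[i])
      ivGrade <- c(ivGrade,
                   if (is.na(segGrade[i])) "unresolved"
                   else intensityLabel(segGrade[i]))
      ivResolved <- c(ivResolved, TRUE)
      i <- i + 1L
    } else if (status[i] == "ambiguous") {
      j <- i
      while (j < nseg && status[j + 1L] == "ambiguous") j <- j + 1L
      block <- i:j
      inBlock <- vapply(binary$supports, function(s)
        length(s) > 0L && all(s %in% block), logical(1))
      if (any(inBlock)) {
        g <- max(gammas[inBlock])
        ivStart <- c(ivStart, part$start[i]); ivEnd <- c(ivEnd, part$end[j])
        ivGrade <- c(ivGrade, intensityLabel(g))
        ivResolved <- c(ivResolved, FALSE)
      } else {
        ambStart <- c(ambStart, part$start[i]); ambEnd <- c(ambEnd, part$end[j])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  intervals <- asIRanges(ivStart, ivEnd)
  mcols(intervals) <- S4Vectors::DataFrame(grade = ivGrade,
                                           resolved = ivResolved)
  ambRanges <- asIRanges(ambStart, ambEnd)
  exclRanges <- if (length(excluded))
    segmentsToRanges(part[excluded, , drop = FALSE]) else IRanges::IRanges()
  untRanges <- if (length(untested))
    segmentsToRanges(part[untested, , drop = FALSE]) else IRanges::IRanges()

  # tentative refinement: would the suggestive missing bands shrink any
  # reported interval?
  likely <- IRanges::IRanges()
  if (length(atoms$tentative)) {
    refined <- binaryStage(atoms, extraExclusions = atoms$tentative)
    if (!length(refined$conflicts)) {
      tentSegs <- sort(unique(unlist(lapply(atoms$tentative, `[[`, "segs"))))
      cut <- setdiff(refined$excluded, binary$excluded)
      if (length(cut)) {
        cutRanges <- segmentsToRanges(part[cut, , drop = FALSE])
        shrunk <- IRanges::setdiff(intervals, cutRanges)
        keep <- shrunk[IRanges::overlapsAny(shrunk, intervals)]
        changed <- !identical(as.data.frame(IRanges::reduce(keep)),
                              as.data.frame(IRanges::reduce(intervals)))
        if (changed && length(keep)) likely <- keep
      }
    }
  }

  segments <- segFrame(status,
                       ifelse(is.na(segGrade), NA_character_,
                              INTENSITY_LEVELS[ifelse(is.na(segGrade), 1L,
                                                      segGrade)]))

  newAssignment(ph, st, pr, proteinLength, cutSites, intervals, ambRanges,
                exclRanges, untRanges, likely, character(), graded$warnings,
                segments)
}

#' Grade (or re-grade) a contact assignment from its observations
#'
#' Applies the intensity-triangulation stage to an assignment's underlying
#' observations: equivalent to `inferContacts(observations, constructs,
#' grade = TRUE)` for the assignment's probe, with a consistency check
#' against the supplied ungraded assignment.
#'
#' @param assignment A [ContactAssignment-class] (typically from
#'   `inferContacts(..., grade = FALSE)`).
#' @param observations The observation rows for the assignment's probe.
#' @param constructs Construct panel.
#' @return A graded [ContactAssignment-class].
#' @export
gradeIntensity <- function(assignment, observations, constructs) {
  sub <- observations[observations$phosphate == assignment@phosphate &
                        observations$promoter == assignment@promoter, ,
                      drop = FALSE]
  if (!nrow(sub)) stop("no observations match the assignment's probe")
  graded <- inferContacts(sub, constructs,
                          proteinLength = assignment@proteinLength,
                          grade = TRUE)
  ungraded <- inferContacts(sub, constructs,
                            proteinLength = assignment@proteinLength,
                            grade = FALSE)
  if (!identical(as.data.frame(ungraded@excluded),
                 as.data.frame(assignment@excluded)))
    warning("assignment does not match these observations; re-inferred")
  graded
}

#' Brute-force enumeration of observation-consistent contact maps
#'
#' The definitional (possible-world) semantics of the presence logic: every
#' subset of segments is tested against all constraints, and the per-segment
#' statuses are read off the surviving subsets. The propagation engine in
#' [inferContacts()] must agree with this enumeration; it exists as the
#' verification oracle and is limited to 20 segments.
#'
#' @inheritParams inferContacts
#' @return A list: `partition` (segment grid), `consistent` (logical matrix,
#'   one row per consistent subset), `status` (per-segment:
#'   `required`/`excluded`/`ambiguous`/`untested`), `conflict` (`TRUE` when
#'   no subset satisfies the constraints).
#' @export
bruteForceConsistentSets <- function(observations, constructs,
                                     proteinLength = NULL) {
  used <- constructs[intersect(names(constructs),
                               unique(observations$construct))]
  if (is.null(proteinLength)) {
    lens <- unique(vapply(used, function(x) x@length, integer(1)))
    if (length(lens) != 1L)
      stop("constructs disagree on protein length; pass 'proteinLength'")
    proteinLength <- lens
  }
  atoms <- constraintAtoms(observations, constructs, proteinLength)
  nseg <- nrow(atoms$partition)
  if (nseg > 20L)
    stop("refusing brute-force enumeration over ", nseg, " segments (> 20)")
  worlds <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nseg),
                                  KEEP.OUT.ATTRS = FALSE))
  colnames(worlds) <- NULL
  ok <- rep(TRUE, nrow(worlds))
  for (e in atoms$exclusions)
    if (length(e$segs))
      ok <- ok & rowSums(worlds[, e$segs, drop = FALSE]) == 0L
  for (p in atoms$positives)
    ok <- ok & rowSums(worlds[, p$segs, drop = FALSE]) > 0L
  consistent <- worlds[ok, , drop = FALSE]
  conflict <- nrow(consistent) == 0L
  status <- rep("ambiguous", nseg)
  if (!conflict) {
    always <- colSums(consistent) == nrow(consistent)
    never <- colSums(consistent) == 0L
    status[always] <- "required"
    status[never] <- "excluded"
    untested <- setdiff(seq_len(nseg),
                        union(atoms$covered, which(never)))
    status[untested] <- "untested"
  } else {
    status <- rep("conflict", nseg)
  }
  list(partition = atoms$partition, consistent = consistent,
       status = status, conflict = conflict)
}

#' Regions untouched by any informative observation
#'
#' Segments of the panel grid that no cross-linked or (hard) missing-band
#' call constrains; these shrink as lanes are added.
#'
#' @inheritParams inferContacts
#' @return `IRanges` of untested regions (the whole protein for an empty
#'   table).
#' @export
untestedRegions <- function(observations, constructs, proteinLength = NULL) {
  if (nrow(observations) == 0L) {
    if (is.null(proteinLength))
      stop("pass 'proteinLength' for an empty observation table")
    return(IRanges::IRanges(1L, as.integer(proteinLength)))
  }
  used <- constructs[intersect(names(constructs),
                               unique(observations$construct))]
  if (is.null(proteinLength))
    proteinLength <- unique(vapply(used, function(x) x@length, integer(1)))
  atoms <- constraintAtoms(observations, constructs, proteinLength)
  idx <- setdiff(seq_len(nrow(atoms$partition)), atoms$covered)
  if (!length(idx)) return(IRanges::IRanges())
  segmentsToRanges(atoms$partition[idx, , drop = FALSE])
}
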