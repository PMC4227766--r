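#' @import methods
#' @importFrom IRanges IRanges start end width reduce findOverlaps
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
NULL

INTENSITY_LEVELS <- c("very_weak", "weak", "strong")
GRADE_LEVELS <- c(INTENSITY_LEVELS, "unresolved")
CALL_LEVELS <- c("crosslinked", "not_crosslinked", "occluded")
STRAND_LEVELS <- c("non_template", "template")
TAG_LEVELS <- c("none", "N", "C")

#' A tagged protein variant with engineered cleavage sites
#'
#' One member of a cleavage-site construct panel: a full-length protein
#' carrying zero or more single-residue cleavage sites (hydroxylamine-cleavable
#' Asn-Gly bonds in the packaged panel) and at most one terminal affinity tag.
#' Cleavage "at residue s" severs the peptide bond between residues s and s+1,
#' so a single-site construct digests into fragments [1, s] and [s+1, L].
#'
#' @slot name Short construct label (e.g. "H", "A", "CT").
#' @slot length Residue count of the full-length protein.
#' @slot cleavageSites Strictly increasing residue indices; cleavage occurs
#'   after each listed residue. May be empty (no-cut control).
#' @slot tag One of `"none"`, `"N"`, `"C"`.
#' @slot tagMassShift Mass added by the tag, kDa (0 if untagged).
#' @slot sequence Optional one-letter amino-acid sequence of length `length`,
#'   or `NA_character_`.
#' @exportClass ProteinConstruct
setClass("ProteinConstruct",
  representation(
    name = "character",
    length = "integer",
    cleavageSites = "integer",
    tag = "character",
    tagMassShift = "numeric",
    sequence = "character"
  ),
  prototype(
    cleavageSites = integer(),
    tag = "none",
    tagMassShift = 0,
    sequence = NA_character_
  )
)

setValidity("ProteinConstruct", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@length) != 1L || is.na(object@length) || object@length < 1L)
    msg <- c(msg, "'length' must be a single positive integer")
  s <- object@cleavageSites
  if (anyNA(s) || any(s < 1L) || any(s >= object@length))
    msg <- c(msg, sprintf(
      "cleavage sites must satisfy 1 <= site < length (%d); got: %s",
      object@length, paste(s, collapse = ", ")))
  if (is.unsorted(s, strictly = TRUE))
    msg <- c(msg, "cleavage sites must be strictly increasing")
  if (!(object@tag %in% TAG_LEVELS))
    msg <- c(msg, sprintf("unknown tag code '%s'", object@tag))
  if (object@tagMassShift < 0)
    msg <- c(msg, "'tagMassShift' must be >= 0")
  if (object@tag == "none" && object@tagMassShift != 0)
    msg <- c(msg, "untagged construct cannot carry a tag mass shift")
  if (!is.na(object@sequence) && nchar(object@sequence) != object@length)
    msg <- c(msg, "sequence length does not equal 'length'")
  if (length(msg)) msg else TRUE
})

#' A duplex DNA photo-cross-linking probe
#'
#' A double-stranded probe whose non-template strand is stored 5'->3'; the
#' azidophenacyl cross-linker sits on one numbered backbone phosphate of the
#' promoter-element-aligned numbering. The parity convention is fixed by the
#' experimental design: odd-numbered phosphates lie on the non-template
#' strand, even-numbered phosphates on the template strand.
#'
#' @slot phosphate Phosphate index within the element-aligned numbering.
#' @slot strand `"non_template"` or `"template"`.
#' @slot promoter Free-text promoter label (e.g. "U6").
#' @slot duplex `DNAString` of the non-template strand.
#' @slot pseaOffset 1-based offset of element base 1 within `duplex`.
#' @slot pseaLength Length of the recognition element in bp.
#' @slot radiolabelOffset Phosphate positions 5' of the cross-linker carrying
#'   the radiolabel on the same strand.
#' @exportClass CrossLinkProbe
setClass("CrossLinkProbe",
  representation(
    phosphate = "integer",
    strand = "character",
    promoter = "character",
    duplex = "DNAString",
    pseaOffset = "integer",
    pseaLength = "integer",
    radiolabelOffset = "integer"
  ),
  prototype(promoter = "U6", pseaLength = 21L, radiolabelOffset = 2L)
)

setValidity("CrossLinkProbe", function(object) {
  msg <- character()
  k <- object@phosphate
  if (length(k) != 1L || is.na(k) || k < 2L)
    msg <- c(msg, "'phosphate' must be a single integer >= 2")
  if (!(object@strand %in% STRAND_LEVELS))
    msg <- c(msg, sprintf("unknown strand '%s'", object@strand))
  expected <- if (k %% 2L == 1L) "non_template" else "template"
  if (length(k) == 1L && !is.na(k) && object@strand != expected)
    msg <- c(msg, sprintf(
      "parity violation: phosphate %d must be on the %s strand", k, expected))
  if (object@pseaOffset < 1L ||
      object@pseaOffset + object@pseaLength - 1L > length(object@duplex))
    msg <- c(msg, "recognition element does not fit inside the duplex")
  bp <- phosphateBp(k)
  if (object@pseaOffset + bp - 1L > length(object@duplex))
    msg <- c(msg, sprintf("phosphate %d maps outside the duplex", k))
  if (length(msg)) msg else TRUE
})

#' Gel migration model
#'
#' Pure mass-to-mobility model for denaturing protein gels: fragment mass is
#' residue count times an average residue mass (plus any tag shift), and two
#' bands are indistinguishable when their relative mass difference falls below
#' `relTolerance`. `extraBands` lists co-migrating labelled species from other
#' proteins in the complex that can occlude fragments of interest.
#'
#' @slot avgResidueMass kDa per residue (default 0.110).
#' @slot relTolerance Fractional mass difference below which two bands
#'   co-migrate (default 0.05).
#' @slot extraBands `data.frame` with columns `label`, `mass`.
#' @exportClass GelModel
setClass("GelModel",
  representation(
    avgResidueMass = "numeric",
    relTolerance = "numeric",
    extraBands = "data.frame"
  ),
  prototype(
    avgResidueMass = 0.110,
    relTolerance = 0.05,
    extraBands = data.frame(label = character(), mass = numeric())
  )
)

setValidity("GelModel", function(object) {
  msg <- character()
  if (object@avgResidueMass <= 0)
    msg <- c(msg, "'avgResidueMass' must be > 0")
  if (object@relTolerance <= 0 || object@relTolerance >= 1)
    msg <- c(msg, "'relTolerance' must be in (0, 1)")
  if (!all(c("label", "mass") %in% names(object@extraBands)))
    msg <- c(msg, "'extraBands' needs columns 'label' and 'mass'")
  if (length(msg)) msg else TRUE
})

#' Residue-interval contact assignment for one phosphate
#'
#' The inferred answer for a single probe: which residue intervals of the
#' protein contact that phosphate, at what ordinal intensity, plus everything
#' the construct panel could *not* decide. Interval boundaries always coincide
#' with cleavage sites or the protein termini: the panel's cut-site grid is
#' the resolution limit of the method.
#'
#' @slot phosphate,strand,promoter Probe identity.
#' @slot proteinLength Residue count of the mapped protein.
#' @slot cutSites Cut sites informing this assignment (the segment grid).
#' @slot intervals `IRanges` of contact intervals, with metadata columns
#'   `grade` (`very_weak`/`weak`/`strong`/`unresolved`) and `resolved`
#'   (`TRUE` for runs of individually required segments, `FALSE` for entailed
#'   runs whose internal boundaries the panel could not resolve).
#' @slot ambiguous `IRanges`: regions that may or may not be contacted.
#' @slot excluded `IRanges`: regions proven contact-free.
#' @slot untested `IRanges`: regions no informative lane constrains.
#' @slot likely `IRanges`: tentative refinements of `intervals` supported only
#'   by soft (tentative) negative evidence.
#' @slot conflicts Human-readable records of mutually unsatisfiable lanes.
#' @slot warnings Notes, e.g. intensity constraints dropped during grading.
#' @slot segments Per-segment table (`start`, `end`, `status`, `grade`).
#' @exportClass ContactAssignment
setClass("ContactAssignment",
  representation(
    phosphate = "integer",
    strand = "character",
    promoter = "character",
    proteinLength = "integer",
    cutSites = "integer",
    intervals = "IRanges",
    ambiguous = "IRanges",
    excluded = "IRanges",
    untested = "IRanges",
    likely = "IRanges",
    conflicts = "character",
    warnings = "character",
    segments = "data.frame"
  ),
  prototype(
    conflicts = character(),
    warnings = character(),
    likely = IRanges::IRanges()
  )
)

setValidity("ContactAssignment", function(object) {
  msg <- character()
  iv <- object@intervals
  if (length(iv)) {
    if (!all(c("grade", "resolved") %in% names(mcols(iv))))
      msg <- c(msg, "'intervals' needs metadata columns 'grade' and 'resolved'")
    else if (!all(mcols(iv)$grade %in% GRADE_LEVELS))
      msg <- c(msg, "invalid grade level in 'intervals'")
    if (!IRanges::isDisjoint(iv))
      msg <- c(msg, "'intervals' must be pairwise disjoint")
  }
  L <- object@proteinLength
  boundariesOk <- function(r) {
    ok <- (start(r) == 1L | (start(r) - 1L) %in% object@cutSites) &
      (end(r) == L | end(r) %in% object@cutSites)
    all(ok)
  }
  if (length(iv) && !boundariesOk(iv))
    msg <- c(msg, "interval boundaries must coincide with cut sites or termini")
  covered <- reduce(c(object@intervals, object@ambiguous, object@excluded,
                      object@untested))
  if (length(object@conflicts) == 0L &&
      !(length(covered) == 1L && start(covered) == 1L && end(covered) == L))
    msg <- c(msg, "intervals + ambiguous + excluded + untested must tile [1, L]")
  if (length(msg)) msg else TRUE
})

#' A full contact architecture on one promoter
#'
#' The map from phosphate positions to contact assignments for one protein
#' subunit bound to one promoter element, together with a named domain
#' annotation used for display grouping and for per-domain comparisons.
#' Positions the underlying study probed but found not to cross-link are
#' listed in `knownAbsent`; positions never probed (or probed but with no
#' usable statement) are `unstated` and are ignored by comparisons.
#'
#' @slot promoter Promoter label (free string, e.g. "U1", "U6").
#' @slot subunit Protein subunit label.
#' @slot proteinLength Residue count.
#' @slot assignments Named list of [ContactAssignment-class] keyed by
#'   phosphate index (as character).
#' @slot domains Named `IRanges` tiling `[1, proteinLength]`.
#' @slot knownAbsent Integer phosphate indices with a stated non-contact.
#' @slot unstated Integer phosphate indices with no usable statement.
#' @exportClass ContactArchitecture
setClass("ContactArchitecture",
  representation(
    promoter = "character",
    subunit = "character",
    proteinLength = "integer",
    assignments = "list",
    domains = "IRanges",
    knownAbsent = "integer",
    unstated = "integer"
  ),
  prototype(knownAbsent = integer(), unstated = integer())
)

setValidity("ContactArchitecture", function(object) {
  msg <- character()
  if (!all(vapply(object@assignments, is, logical(1), "ContactAssignment")))
    msg <- c(msg, "'assignments' must all be ContactAssignment objects")
  ph <- vapply(object@assignments, function(a) a@phosphate, integer(1))
  if (anyDuplicated(ph))
    msg <- c(msg, "duplicate phosphate keys in 'assignments'")
  if (length(object@assignments) &&
      !identical(names(object@assignments), as.character(unname(ph))))
    msg <- c(msg, "'assignments' names must equal their phosphate indices")
  d <- object@domains
  if (length(d)) {
    if (is.null(names(d)) || any(!nzchar(names(d))))
      msg <- c(msg, "'domains' must be named")
    tile <- reduce(d)
    if (!(length(tile) == 1L && start(tile) == 1L &&
          end(tile) == object@proteinLength))
      msg <- c(msg, "'domains' must tile [1, proteinLength]")
  }
  if (length(intersect(ph, object@knownAbsent)))
    msg <- c(msg, "a phosphate cannot be both assigned and knownAbsent")
  if (length(msg)) msg else TRUE
})

#' Ideal B-form helix parameters
#'
#' Geometric constants of an ideal, unbent B-form double helix used to place
#' backbone phosphates in 3D. `interstrandOffsetDeg` is the azimuthal offset
#' of the template-strand phosphate from the non-template-strand phosphate of
#' the same base pair, measured across the minor groove in the direction of
#' helical rotation.
#'
#' @slot twistDeg Helical twist per bp, degrees (default 36).
#' @slot riseA Rise per bp, Angstrom (default 3.34).
#' @slot radiusA Phosphate radius from the axis, Angstrom (default 9.4).
#' @slot interstrandOffsetDeg Cross-strand phosphate offset, degrees
#'   (default 154).
#' @slot handedness `"right"`.
#' @exportClass HelixParams
setClass("HelixParams",
  representation(
    twistDeg = "numeric",
    riseA = "numeric",
    radiusA = "numeric",
    interstrandOffsetDeg = "numeric",
    handedness = "character"
  ),
  prototype(
    twistDeg = 36.0,
    riseA = 3.34,
    radiusA = 9.4,
    interstrandOffsetDeg = 154.0,
    handedness = "right"
  )
)

setValidity("HelixParams", function(object) {
  msg <- character()
  if (object@twistDeg <= 0 || object@twistDeg > 45)
    msg <- c(msg, "'twistDeg' must be in (0, 45]")
  if (object@riseA <= 0) msg <- c(msg, "'riseA' must be > 0")
  if (object@radiusA <= 0) msg <- c(msg, "'radiusA' must be > 0")
  if (object@interstrandOffsetDeg <= 0 || object@interstrandOffsetDeg >= 360)
    msg <- c(msg, "'interstrandOffsetDeg' must be in (0, 360)")
  if (!identical(object@handedness, "right"))
    msg <- c(msg, "only right-handed helices are supported")
  if (length(msg)) msg else TRUE
})

#' Ideal B-form helix model with phosphate coordinates
#'
#' @slot params [HelixParams-class] used to generate the model.
#' @slot nBp Number of base pairs.
#' @slot coords `data.frame` with one row per phosphate: `phosphate` (index,
#'   parity convention), `strand`, `bp`, `x`, `y`, `z`, `faceAngle` (azimuth
#'   in degrees, mod 360).
#' @exportClass HelixModel
setClass("HelixModel",
  representation(params = "HelixParams", nBp = "integer",
                 coords = "data.frame"))

#' Observation noise model for simulated gels
#'
#' @slot pFalseNegative Probability a truly cross-linked fragment call drops
#'   out (band missed).
#' @slot pIntensityMisgrade Probability a cross-linked call's ordinal
#'   intensity shifts by one level.
#' @slot occluders `data.frame` (`label`, `mass`): labelled bands from other
#'   species that occlude any co-migrating fragment.
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(
    pFalseNegative = "numeric",
    pIntensityMisgrade = "numeric",
    occluders = "data.frame"
  ),
  prototype(
    pFalseNegative = 0,
    pIntensityMisgrade = 0,
    occluders = data.frame(label = character(), mass = numeric())
  )
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@pFalseNegative < 0 || object@pFalseNegative > 1)
    msg <- c(msg, "'pFalseNegative' must be in [0, 1]")
  if (object@pIntensityMisgrade < 0 || object@pIntensityMisgrade > 1)
    msg <- c(msg, "'pIntensityMisgrade' must be in [0, 1]")
  if (!all(c("label", "mass") %in% names(object@occluders)))
    msg <- c(msg, "'occluders' needs columns 'label' and 'mass'")
  if (length(msg)) msg else TRUE
})

#' Ground-truth contact map for simulation
#'
#' @slot proteinLength Residue count.
#' @slot promoter Promoter label.
#' @slot contacts Named list keyed by phosphate index (character): each an
#'   `IRanges` of pairwise-disjoint contact intervals with metadata column
#'   `grade` in `very_weak`/`weak`/`strong`.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    proteinLength = "integer",
    promoter = "character",
    contacts = "list"
  ),
  prototype(promoter = "synthetic")
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  for (key in names(object@contacts)) {
    iv <- object@contacts[[key]]
    if (!is(iv, "IRanges")) {
      msg <- c(msg, sprintf("contacts[['%s']] is not an IRanges", key))
      next
    }
    if (length(iv)) {
      if (any(start(iv) < 1L) || any(end(iv) > object@proteinLength))
        msg <- c(msg, sprintf("contacts[['%s']] outside [1, L]", key))
      if (!IRanges::isDisjoint(iv))
        msg <- c(msg, sprintf("contacts[['%s']] intervals overlap", key))
      if (!all(mcols(iv)$grade %in% INTENSITY_LEVELS))
        msg <- c(msg, sprintf("contacts[['%s']] has invalid grades", key))
    }
  }
  if (length(msg)) msg else TRUE
})
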