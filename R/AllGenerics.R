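#' @importClassesFrom Biostrings DNAString
NULL

#' Digest a construct into its expected cleavage fragments
#'
#' @param x A [ProteinConstruct-class].
#' @param ... Unused.
#' @return A `data.frame` with one row per fragment: `parent`, `start`,
#'   `end`, `terminus` (`"N"`, `"internal"`, `"C"`, or `"N+C"` for an uncut
#'   construct), `tagged`, `fragment` (identifier `"F1"`, `"F2"`, ...).
#'   Fragments tile `[1, length]` in order.
#' @export
setGeneric("digest", function(x, ...) standardGeneric("digest"))

#' Contact intervals of an assignment
#'
#' @param x A [ContactAssignment-class] or [ContactArchitecture-class].
#' @param ... For the architecture method, `phosphate` selects one position.
#' @return An `IRanges` with metadata columns `grade` and `resolved`.
#' @export
setGeneric("contactIntervals",
           function(x, ...) standardGeneric("contactIntervals"))

#' Conflict records of an assignment
#' @param x A [ContactAssignment-class].
#' @return Character vector (empty when the observations were satisfiable).
#' @export
setGeneric("conflicts", function(x) standardGeneric("conflicts"))

#' Promoter label accessor
#' @param x A probe, assignment, architecture or ground truth object.
#' @return Single character label.
#' @export
setGeneric("promoterLabel", function(x) standardGeneric("promoterLabel"))

#' Phosphate index accessor
#' @param x A [CrossLinkProbe-class] or [ContactAssignment-class].
#' @return Integer phosphate index.
#' @export
setGeneric("phosphateIndex", function(x) standardGeneric("phosphateIndex"))

setMethod("promoterLabel", "CrossLinkProbe", function(x) x@promoter)
setMethod("promoterLabel", "ContactAssignment", function(x) x@promoter)
setMethod("promoterLabel", "ContactArchitecture", function(x) x@promoter)
setMethod("promoterLabel", "GroundTruth", function(x) x@promoter)

setMethod("phosphateIndex", "CrossLinkProbe", function(x) x@phosphate)
setMethod("phosphateIndex", "ContactAssignment", function(x) x@phosphate)

setMethod("contactIntervals", "ContactAssignment", function(x, ...) x@intervals)
setMethod("contactIntervals", "ContactArchitecture",
  function(x, phosphate, ...) {
    key <- as.character(phosphate)
    if (!key %in% names(x@assignments))
      stop("no assignment for phosphate ", phosphate)
    x@assignments[[key]]@intervals
  })

setMethod("conflicts", "ContactAssignment", function(x) x@conflicts)

setMethod("show", "ProteinConstruct", function(object) {
  cat(sprintf("ProteinConstruct '%s': %d aa, tag=%s", object@name,
              object@length, object@tag))
  if (object@tagMassShift > 0)
    cat(sprintf(" (+%.1f kDa)", object@tagMassShift))
  cat("\n  cleavage after residue(s): ",
      if (length(object@cleavageSites))
        paste(object@cleavageSites, collapse = ", ") else "(none)",
      "\n", sep = "")
})

setMethod("show", "CrossLinkProbe", function(object) {
  cat(sprintf(
    "CrossLinkProbe: %s phosphate %d (%s strand), duplex %d nt, element at %d\n",
    object@promoter, object@phosphate, object@strand,
    length(object@duplex), object@pseaOffset))
})

setMethod("show", "GelModel", function(object) {
  cat(sprintf(
    "GelModel: %.3f kDa/residue, co-migration tolerance %.1f%%, %d extra band(s)\n",
    object@avgResidueMass, 100 * object@relTolerance,
    nrow(object@extraBands)))
})

setMethod("show", "ContactAssignment", function(object) {
  cat(sprintf("ContactAssignment: %s phosphate %d (%s strand)\n",
              object@promoter, object@phosphate, object@strand))
  if (length(object@conflicts)) {
    cat("  CONFLICT:\n")
    for (cf in object@conflicts) cat("   - ", cf, "\n", sep = "")
    return(invisible(NULL))
  }
  iv <- object@intervals
  if (!length(iv)) {
    cat("  no contact intervals\n")
  } else {
    for (i in seq_along(iv)) {
      cat(sprintf("  [%d, %d] %s%s\n", start(iv)[i], end(iv)[i],
                  mcols(iv)$grade[i],
                  if (mcols(iv)$resolved[i]) "" else " (unresolved span)"))
    }
  }
  if (length(object@likely))
    cat(sprintf("  likely sub-interval(s): %s\n",
                paste(sprintf("[%d, %d]", start(object@likely),
                              end(object@likely)), collapse = ", ")))
  if (length(object@ambiguous))
    cat(sprintf("  ambiguous: %s\n",
                paste(sprintf("[%d, %d]", start(object@ambiguous),
                              end(object@ambiguous)), collapse = ", ")))
  if (length(object@warnings))
    for (w in object@warnings) cat("  note: ", w, "\n", sep = "")
})

setMethod("show", "ContactArchitecture", function(object) {
  cat(sprintf("ContactArchitecture: %s on %s (%d aa)\n", object@subunit,
              object@promoter, object@proteinLength))
  cat(sprintf("  %d assigned phosphate position(s): %s\n",
              length(object@assignments),
              paste(names(object@assignments), collapse = ", ")))
  if (length(object@knownAbsent))
    cat("  known absent: ", paste(object@knownAbsent, collapse = ", "), "\n",
        sep = "")
  if (length(object@domains))
    cat("  domains: ", paste(names(object@domains), collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "HelixParams", function(object) {
  cat(sprintf(
    "HelixParams: twist %.1f deg, rise %.2f A, radius %.1f A, interstrand %.1f deg (%s-handed)\n",
    object@twistDeg, object@riseA, object@radiusA,
    object@interstrandOffsetDeg, object@handedness))
})

setMethod("show", "HelixModel", function(object) {
  cat(sprintf("HelixModel: %d bp, %d phosphates\n", object@nBp,
              nrow(object@coords)))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: P(false negative)=%.3f, P(misgrade)=%.3f, %d occluder(s)\n",
    object@pFalseNegative, object@pIntensityMisgrade, nrow(object@occluders)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %s, protein %d aa, %d phosphate position(s)\n",
              object@promoter, object@proteinLength, length(object@contacts)))
})
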