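# Phosphates with at least one contact interval, with the domain of the
# strongest interval (ties broken by interval order; grade "unresolved"
# ranks below very_weak).
strongestDomainTable <- function(architecture) {
  rows <- lapply(architecture@assignments, function(a) {
    iv <- a@intervals
    if (!length(iv)) return(NULL)
    code <- match(mcols(iv)$grade, INTENSITY_LEVELS)
    code[is.na(code)] <- 0L
    top <- which.max(code)
    data.frame(phosphate = a@phosphate,
               domain = domainOfInterval(architecture@domains, iv[top]),
               grade = mcols(iv)$grade[top], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(phosphate = integer(), domain = character(),
                      grade = character())
  rownames(out) <- NULL
  out
}

contactedPhosphates <- function(architecture) {
  strongestDomainTable(architecture)$phosphate
}

circularMeanDeg <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' Compare two contact architectures
#'
#' Exact set arithmetic on contacted phosphate positions plus per-domain
#' geometry summaries. A position counts as unique to one architecture only
#' when the other architecture makes a definite statement about it (it is
#' contacted, known absent, or covered by an assignment with no intervals);
#' positions the other architecture leaves unstated are reported separately
#' and never counted as differences.
#'
#' Per domain, the contacted phosphate sets are those whose *strongest*
#' contact interval overlaps the domain most, mirroring the usual
#' color-by-strongest-domain display. Axial displacement is the difference
#' of mean base-pair positions (B minus A; positive = downstream, toward
#' the transcription start site) and rotation is the circular-mean
#' difference of face angles (positive = clockwise viewed from upstream,
#' i.e. the direction of helical twist), wrapped to (-180, 180].
#'
#' @param A,B [ContactArchitecture-class] objects built on the same protein.
#' @param helix A [HelixModel-class] covering all contacted phosphates.
#' @return A list: `shared`, `uniqueToA`, `uniqueToB`, `unstated` (positions
#'   skipped for lack of a statement), and `perDomain` -- a `data.frame`
#'   with per-domain contact counts, `axialShiftBp`, `rotationDeg` and
#'   `lowConfidence` (either side has a single contact). Shift columns are
#'   `NA` when a domain contacts nothing in one architecture.
#' @examples
#' helix <- buildHelix(13)
#' diffArchitectures(u1Architecture(), u6Architecture(), helix)$uniqueToB
#' @export
diffArchitectures <- function(A, B, helix) {
  if (A@proteinLength != B@proteinLength)
    stop("architectures map different proteins (lengths ",
         A@proteinLength, " vs ", B@proteinLength, ")")
  contactedA <- contactedPhosphates(A)
  contactedB <- contactedPhosphates(B)
  statedA <- sort(unique(c(contactedA, A@knownAbsent,
                           as.integer(names(A@assignments)))))
  statedB <- sort(unique(c(contactedB, B@knownAbsent,
                           as.integer(names(B@assignments)))))
  shared <- intersect(contactedA, contactedB)
  uniqueToA <- intersect(setdiff(contactedA, contactedB), statedB)
  uniqueToB <- intersect(setdiff(contactedB, contactedA), statedA)
  unstated <- sort(union(setdiff(contactedA, statedB),
                         setdiff(contactedB, statedA)))
  domains <- names(A@domains)
  per <- lapply(domains, function(d) {
    s <- domainShift(d, A, B, helix)
    data.frame(domain = d, nA = s$nA, nB = s$nB,
               phosphatesA = paste(s$phosphatesA, collapse = ","),
               phosphatesB = paste(s$phosphatesB, collapse = ","),
               axialShiftBp = s$axialShiftBp,
               rotationDeg = s$rotationDeg,
               lowConfidence = s$lowConfidence,
               stringsAsFactors = FALSE)
  })
  list(shared = sort(shared), uniqueToA = sort(uniqueToA),
       uniqueToB = sort(uniqueToB), unstated = unstated,
       perDomain = do.call(rbind, per))
}

#' Axial and rotational shift of one domain between two architectures
#'
#' @param domain Domain name (must exist in both architectures' annotation).
#' @param A,B [ContactArchitecture-class] objects.
#' @param helix A [HelixModel-class].
#' @return A list: `phosphatesA`, `phosphatesB`, `nA`, `nB`, `axialShiftBp`
#'   (mean bp in B minus mean bp in A; `NA` with `defined = FALSE` when a
#'   side is empty), `rotationDeg` (circular-mean face-angle difference,
#'   wrapped to (-180, 180]), `lowConfidence`, `defined`.
#' @export
domainShift <- function(domain, A, B, helix) {
  tabA <- strongestDomainTable(A)
  tabB <- strongestDomainTable(B)
  phA <- tabA$phosphate[tabA$domain == domain]
  phB <- tabB$phosphate[tabB$domain == domain]
  if (!length(phA) || !length(phB))
    return(list(phosphatesA = phA, phosphatesB = phB,
                nA = length(phA), nB = length(phB),
                axialShiftBp = NA_real_, rotationDeg = NA_real_,
                lowConfidence = TRUE, defined = FALSE))
  coordOf <- function(ph) helix@coords[match(ph, helix@coords$phosphate), ,
                                       drop = FALSE]
  ca <- coordOf(phA); cb <- coordOf(phB)
  if (anyNA(ca$bp) || anyNA(cb$bp))
    stop("contacted phosphate outside the helix model")
  axial <- mean(cb$bp) - mean(ca$bp)
  rot <- wrapAngle(circularMeanDeg(cb$faceAngle) -
                     circularMeanDeg(ca$faceAngle))
  list(phosphatesA = sort(phA), phosphatesB = sort(phB),
       nA = length(phA), nB = length(phB),
       axialShiftBp = axial, rotationDeg = rot,
       lowConfidence = length(phA) == 1L || length(phB) == 1L,
       defined = TRUE)
}
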