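#' Create helix parameters
#'
#' Standard B-form defaults: 36 degrees twist and 3.34 Angstrom rise per bp,
#' phosphates at 9.4 Angstrom from the axis, and a 154-degree azimuthal
#' offset between the two strands' phosphates of one base pair measured
#' across the minor groove. All values are configurable; classifications
#' derived from them are geometric conventions, not measurements.
#'
#' @param twistDeg,riseA,radiusA,interstrandOffsetDeg,handedness See
#'   [HelixParams-class].
#' @return A validated [HelixParams-class].
#' @export
HelixParams <- function(twistDeg = 36.0, riseA = 3.34, radiusA = 9.4,
                        interstrandOffsetDeg = 154.0, handedness = "right") {
  new("HelixParams", twistDeg = twistDeg, riseA = riseA, radiusA = radiusA,
      interstrandOffsetDeg = interstrandOffsetDeg, handedness = handedness)
}

#' Build an ideal B-form helix model
#'
#' Places the two backbone phosphates of every base pair on an ideal helix:
#' the non-template phosphate of bp `i` sits at azimuth `(i-1) * twist` and
#' height `(i-1) * rise`; the template phosphate of the same bp leads it by
#' `interstrandOffsetDeg` (measured across the minor groove in the rotation
#' direction). Phosphate indices follow the parity convention (odd =
#' non-template, even = template; phosphate `k` belongs to bp
#' `ceiling(k/2)`), so a model of `n` bp carries phosphates `1 .. 2n`.
#' Regenerating a model with identical parameters reproduces coordinates
#' bit-identically.
#'
#' @param nBp Number of base pairs (>= 2).
#' @param params A [HelixParams-class].
#' @return A [HelixModel-class].
#' @examples
#' h <- buildHelix(21)
#' head(h@coords)
#' @export
buildHelix <- function(nBp, params = HelixParams()) {
  validObject(params)
  nBp <- as.integer(nBp)
  if (is.na(nBp) || nBp < 2L) stop("'nBp' must be >= 2")
  bp <- seq_len(nBp)
  phos <- data.frame(
    phosphate = c(2L * bp - 1L, 2L * bp),
    strand = rep(c("non_template", "template"), each = nBp),
    bp = c(bp, bp))
  angle <- (phos$bp - 1L) * params@twistDeg +
    ifelse(phos$strand == "template", params@interstrandOffsetDeg, 0)
  phos$faceAngle <- angle %% 360
  rad <- angle * pi / 180
  phos$x <- params@radiusA * cos(rad)
  phos$y <- params@radiusA * sin(rad)
  phos$z <- (phos$bp - 1L) * params@riseA
  phos <- phos[order(phos$phosphate), c("phosphate", "strand", "bp",
                                        "x", "y", "z", "faceAngle")]
  rownames(phos) <- NULL
  new("HelixModel", params = params, nBp = nBp, coords = phos)
}

phosphateCoord <- function(helix, phosphate, strand = NULL) {
  row <- helix@coords[helix@coords$phosphate == phosphate, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("phosphate ", phosphate, " not in the helix model")
  if (!is.null(strand) && row$strand != strand)
    stop(sprintf("phosphate %d lies on the %s strand, not %s", phosphate,
                 row$strand, strand))
  row
}

#' Classify the geometric relationship of two phosphates
#'
#' For phosphates on the same strand the class is `same_strand_track`. For
#' cross-strand pairs the signed azimuthal offset from the template-strand
#' phosphate to the non-template-strand phosphate (wrapped to
#' (-180, 180]) decides the class: offsets near +/-180 degrees mean the two
#' phosphates sit on nearly `opposite_face`s of the duplex; otherwise a
#' negative offset places the shorter inter-backbone arc across the minor
#' groove (`minor_groove_span`) and a positive offset across the major
#' groove (`major_groove_span`). The 3D phosphate-to-phosphate distance is
#' reported alongside; spans farther apart than `maxSpanA` are flagged
#' `withinReach = FALSE`.
#'
#' @param p1,p2 Phosphate indices (parity convention).
#' @param helix A [HelixModel-class].
#' @param oppositeFaceMinDeg Face-angle separation (degrees) from which a
#'   pair counts as opposite faces (default 150).
#' @param maxSpanA Maximum 3D distance (Angstrom) for a plausible
#'   groove-spanning protein contact (default 18).
#' @return A list: `class`, `distanceA`, `deltaFaceDeg` (signed,
#'   template -> non-template), `withinReach`.
#' @examples
#' h <- buildHelix(13)
#' grooveRelationship(8, 11, h)$class   # minor_groove_span
#' grooveRelationship(19, 20, h)$class  # opposite_face
#' @export
grooveRelationship <- function(p1, p2, helix, oppositeFaceMinDeg = 150,
                               maxSpanA = 18) {
  a <- phosphateCoord(helix, p1)
  b <- phosphateCoord(helix, p2)
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  if (a$strand == b$strand) {
    return(list(class = "same_strand_track", distanceA = d,
                deltaFaceDeg = wrapAngle(a$faceAngle - b$faceAngle),
                withinReach = d <= maxSpanA))
  }
  nt <- if (a$strand == "non_template") a else b
  tp <- if (a$strand == "template") a else b
  delta <- wrapAngle(nt$faceAngle - tp$faceAngle)
  cls <- if (abs(delta) >= oppositeFaceMinDeg) "opposite_face"
  else if (delta < 0) "minor_groove_span"
  else "major_groove_span"
  list(class = cls, distanceA = d, deltaFaceDeg = delta,
       withinReach = d <= maxSpanA)
}

#' Project a contact architecture onto a helix model
#'
#' One record per contacted phosphate: coordinates, face angle, the domain
#' whose intervals overlap the strongest contact interval, and the interval
#' grade. Optionally writes a pseudo-atom PDB model (one P atom per
#' phosphate of the helix; contacted phosphates carry the contact grade in
#' the occupancy field and the domain index in the B-factor field), which is
#' viewable in any structure viewer and byte-identical across re-exports.
#'
#' @param architecture A [ContactArchitecture-class].
#' @param helix A [HelixModel-class] covering all contacted phosphates.
#' @param pdbPath Optional output PDB path.
#' @return `data.frame` of annotated contacted phosphates (invisibly returns
#'   the same when only writing the PDB).
#' @export
projectArchitecture <- function(architecture, helix, pdbPath = NULL) {
  validObject(architecture)
  ph <- as.integer(names(architecture@assignments))
  outside <- setdiff(ph, helix@coords$phosphate)
  if (length(outside))
    stop("phosphate(s) outside the helix model: ",
         paste(outside, collapse = ", "))
  rows <- lapply(architecture@assignments, function(a) {
    iv <- a@intervals
    if (!length(iv)) return(NULL)
    gradeCode <- match(mcols(iv)$grade, GRADE_LEVELS)
    top <- which.max(ifelse(is.na(gradeCode), 0L,
                            ifelse(gradeCode == 4L, 0L, gradeCode)))
    dom <- domainOfInterval(architecture@domains, iv[top])
    coord <- phosphateCoord(helix, a@phosphate)
    data.frame(phosphate = a@phosphate, strand = a@strand, bp = coord$bp,
               x = coord$x, y = coord$y, z = coord$z,
               faceAngle = coord$faceAngle, domain = dom,
               grade = mcols(iv)$grade[top], stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(ann) <- NULL
  if (!is.null(pdbPath)) writeHelixPDB(helix, ann, architecture, pdbPath)
  ann
}

# Domain with the largest overlap with an interval.
domainOfInterval <- function(domains, interval) {
  ovw <- vapply(seq_along(domains), function(i) {
    lo <- max(start(interval), start(domains)[i])
    hi <- min(end(interval), end(domains)[i])
    max(0L, hi - lo + 1L)
  }, integer(1))
  names(domains)[which.max(ovw)]
}

#' Export a helix model (with optional contact annotations) as PDB
#'
#' @param helix A [HelixModel-class].
#' @param annotations Optional `data.frame` from [projectArchitecture()].
#' @param architecture Optional architecture supplying the domain ordering
#'   encoded in the B-factor field.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHelixPDB <- function(helix, annotations = NULL, architecture = NULL,
                          path) {
  co <- helix@coords
  occ <- rep(0, nrow(co))
  bf <- rep(0, nrow(co))
  if (!is.null(annotations) && nrow(annotations)) {
    idx <- match(annotations$phosphate, co$phosphate)
    occ[idx] <- match(annotations$grade, GRADE_LEVELS)
    occ[is.na(occ)] <- 0
    if (!is.null(architecture))
      bf[idx] <- match(annotations$domain, names(architecture@domains))
  }
  chain <- ifelse(co$strand == "non_template", "A", "B")
  xyz <- as.numeric(t(as.matrix(co[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = round(xyz, 3), type = rep("ATOM", nrow(co)),
    resno = co$bp, resid = rep("DN", nrow(co)),
    eleno = seq_len(nrow(co)), elety = rep("P", nrow(co)),
    chain = chain, o = occ, b = bf, append = FALSE)
  invisible(path)
}
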