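#' Create a gel migration model
#'
#' @param avgResidueMass kDa per residue; the 0.110 default is a standard
#'   average residue mass, adequate because only relative migration matters.
#' @param relTolerance Fractional mass difference below which two bands are
#'   indistinguishable on the gel. The 0.05 default is calibrated so that a
#'   mid-protein cleavage (construct C of the packaged panel, N-tagged)
#'   produces a co-migrating fragment pair while a distal cleavage
#'   (construct E) does not.
#' @param extraBands `data.frame` with columns `label` and `mass` (kDa):
#'   labelled species from other proteins that run on the same gel.
#' @return A validated [GelModel-class].
#' @export
GelModel <- function(avgResidueMass = 0.110, relTolerance = 0.05,
                     extraBands = data.frame(label = character(),
                                             mass = numeric())) {
  new("GelModel", avgResidueMass = avgResidueMass,
      relTolerance = relTolerance, extraBands = extraBands)
}

# Standard average residue masses (Da) for mass prediction when a construct
# sequence is available.
AA_RESIDUE_MASS_KDA <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
) / 1000

#' Predict the gel mass of a digestion fragment
#'
#' Fragment mass is the residue count times the model's average residue mass,
#' plus the construct's tag shift if the fragment carries the tag. When the
#' parent construct supplies a sequence, per-residue average masses are summed
#' instead (plus one water).
#'
#' @param fragment One row of a [digest()] result (a `data.frame` row with
#'   `start`, `end`, `tagged`).
#' @param gelModel A [GelModel-class].
#' @param construct The parent [ProteinConstruct-class] (needed for the tag
#'   shift and the optional sequence).
#' @return Predicted mass in kDa.
#' @examples
#' gm <- GelModel()
#' cc <- ProteinConstruct("C", 721, 358, tag = "N", tagMassShift = 2.3)
#' fr <- digest(cc)
#' predictMass(fr[1, ], gm, cc)  # 358 residues + 2.3 kDa tag
#' @export
predictMass <- function(fragment, gelModel = GelModel(), construct = NULL) {
  nres <- fragment$end - fragment$start + 1L
  if (any(nres <= 0L)) stop("zero-length fragment")
  if (!is.null(construct) && !is.na(construct@sequence)) {
    aa <- strsplit(construct@sequence, "")[[1]]
    mass <- vapply(seq_len(nrow(fragment)), function(i) {
      sum(AA_RESIDUE_MASS_KDA[aa[fragment$start[i]:fragment$end[i]]]) +
        0.0180
    }, numeric(1))
  } else {
    mass <- nres * gelModel@avgResidueMass
  }
  shift <- if (!is.null(construct)) construct@tagMassShift else 0
  mass + ifelse(fragment$tagged, shift, 0)
}

# Band table for a construct digestion plus any extra species on the gel.
bandTable <- function(construct, gelModel = GelModel()) {
  frags <- digest(construct)
  masses <- predictMass(frags, gelModel, construct)
  bands <- data.frame(
    label = sprintf("%s:%s[%d,%d]%s", frags$parent, frags$fragment,
                    frags$start, frags$end,
                    ifelse(frags$tagged, "+tag", "")),
    fragment = frags$fragment, mass = masses, stringsAsFactors = FALSE)
  if (nrow(gelModel@extraBands))
    bands <- rbind(bands, data.frame(label = gelModel@extraBands$label,
                                     fragment = NA_character_,
                                     mass = gelModel@extraBands$mass))
  bands
}

#' Find co-migrating band pairs
#'
#' All unordered pairs of bands whose relative mass difference (relative to
#' the heavier band) does not exceed the gel model's tolerance, sorted by
#' increasing difference. Input bands may come from [digest()] fragments of
#' one construct plus the model's `extraBands`.
#'
#' @param construct A [ProteinConstruct-class] whose digestion products are
#'   examined, or a `data.frame` of bands with columns `label` and `mass`.
#' @param gelModel A [GelModel-class].
#' @return `data.frame` with columns `label1`, `label2`, `mass1`, `mass2`,
#'   `relDiff`; zero rows when all bands resolve.
#' @examples
#' cc <- ProteinConstruct("C", 721, 358, tag = "N", tagMassShift = 2.3)
#' comigrationPairs(cc)   # the N+tag / C fragment pair co-migrates
#' @export
comigrationPairs <- function(construct, gelModel = GelModel()) {
  bands <- if (is.data.frame(construct)) construct else
    bandTable(construct, gelModel)
  if (nrow(bands) < 2L)
    return(data.frame(label1 = character(), label2 = character(),
                      mass1 = numeric(), mass2 = numeric(),
                      relDiff = numeric()))
  idx <- utils::combn(nrow(bands), 2L)
  m1 <- bands$mass[idx[1L, ]]
  m2 <- bands$mass[idx[2L, ]]
  rel <- abs(m1 - m2) / pmax(m1, m2)
  keep <- rel <= gelModel@relTolerance
  out <- data.frame(
    label1 = bands$label[idx[1L, keep]], label2 = bands$label[idx[2L, keep]],
    mass1 = m1[keep], mass2 = m2[keep], relDiff = rel[keep],
    stringsAsFactors = FALSE)
  out[order(out$relDiff), , drop = FALSE]
}

#' Design tag variants to resolve a co-migration ambiguity
#'
#' When the N- and C-terminal fragments of a construct co-migrate, the
#' cross-linked band cannot be attributed to either side of the cleavage
#' site. Running untagged (UT), N-tagged (NT) and C-tagged (CT) versions of
#' the construct side by side resolves this: the cross-linked band shifts
#' up in the NT lane if and only if the N-terminal fragment cross-linked,
#' and in the CT lane if and only if the C-terminal fragment did. Each
#' terminus therefore needs a tag whose mobility shift is itself resolvable
#' at the gel tolerance.
#'
#' @param construct A [ProteinConstruct-class] with at least one
#'   co-migrating fragment pair.
#' @param gelModel A [GelModel-class].
#' @param tagShifts Named numeric, kDa added by the N and C tags
#'   (defaults `c(N = 2.3, C = 5.7)`, the shifts of the packaged panel's
#'   FLAG-tag constructs).
#' @return A list with elements `resolvable` (logical), `variants` (a
#'   `data.frame` of recommended constructs with predicted N- and C-fragment
#'   band masses, empty when there is no ambiguity) and `ambiguousPairs`
#'   (the [comigrationPairs()] table that motivated the design).
#' @export
designTagResolution <- function(construct, gelModel = GelModel(),
                                tagShifts = c(N = 2.3, C = 5.7)) {
  pairs <- comigrationPairs(construct, gelModel)
  if (nrow(pairs) == 0L)
    return(list(resolvable = TRUE,
                variants = data.frame(),
                ambiguousPairs = pairs))
  base <- stripTag(construct)
  variants <- list(
    UT = base,
    NT = retag(base, "N", tagShifts[["N"]]),
    CT = retag(base, "C", tagShifts[["C"]]))
  rows <- lapply(names(variants), function(v) {
    frags <- digest(variants[[v]])
    masses <- predictMass(frags, gelModel, variants[[v]])
    data.frame(variant = v, nMass = masses[1L], cMass = masses[nrow(frags)],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # a terminus is diagnosable when its tag shift moves the band by more than
  # the co-migration tolerance relative to the untagged band
  nShift <- tagShifts[["N"]] / tab$nMass[tab$variant == "UT"]
  cShift <- tagShifts[["C"]] / tab$cMass[tab$variant == "UT"]
  resolvable <- nShift > gelModel@relTolerance && cShift > gelModel@relTolerance
  list(resolvable = resolvable,
       variants = if (resolvable) tab else data.frame(),
       ambiguousPairs = pairs,
       detail = if (resolvable)
         "run UT, NT and CT side by side; an NT-lane upshift marks an N-side cross-link, a CT-lane upshift a C-side cross-link"
       else "unresolvable: tag shifts do not exceed the gel tolerance")
}

stripTag <- function(construct) {
  initialize(construct, tag = "none", tagMassShift = 0)
}

retag <- function(construct, tag, shift) {
  initialize(construct, tag = tag, tagMassShift = as.numeric(shift))
}
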