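extdata <- function(file) {
  path <- system.file("extdata", file, package = "xlinkmap",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("packaged fixture not found: ", file)
  path
}

#' Packaged SNAP190 construct panel
#'
#' The twelve SNAP190 constructs used to map the U6 PSEA: nine N-FLAG-tagged
#' single-NG-site constructs (H, Ha, A, B, C, D, De, dE, E; cleavage after
#' residues 168, 189, 247, 305, 358, 409, 445, 463 and 483 of the 721-residue
#' protein) plus the untagged (UT), N-tagged (NT) and C-tagged (CT) variants
#' of the 358-site construct used to resolve its co-migrating fragment pair.
#' NT and C are the same molecule under two names. Tag shifts are the stated
#' approximate values (+2.3 kDa N, +5.7 kDa C).
#'
#' @return Named list of [ProteinConstruct-class].
#' @export
u6ConstructPanel <- function() {
  loadConstructs(extdata("constructs_u6.tsv"))
}

#' Packaged U6 probe set
#'
#' The sixteen phosphate positions of the U6 PSEA region that cross-link to
#' SNAP190, on the shared 78-nt duplex (21-bp PSEA at offset 31).
#'
#' @return Named list of [CrossLinkProbe-class], keyed by phosphate index.
#' @export
u6ProbeSet <- function() {
  loadProbeSet(extdata("u6_duplex.fasta"), extdata("probes_u6.tsv"),
               pseaOffset = 31L, pseaLength = 21L)
}

#' Packaged U6 observation table
#'
#' The per-lane cross-link calls for all sixteen U6 phosphate positions,
#' transcribed from the narrated autoradiograms (constructs H through E,
#' the UT/NT/CT tag trio, and the Ha/De/dE lanes where they were run).
#' Occluded calls mark bands hidden by co-migrating SNAP50/SNAP43 digestion
#' products or by the construct-C co-migrating fragment pair; the single
#' tentative call records a suggestively absent band that was not treated
#' as conclusive.
#'
#' @return Observation `data.frame` (see [readObservations()]).
#' @export
u6Observations <- function() {
  readObservations(extdata("obs_u6.tsv"), u6ConstructPanel())
}

#' SNAP190 domain annotation
#'
#' Display/comparison domains bounded by the panel's cleavage sites: the
#' N-terminal domain, the Myb half repeat Rh, the full Myb repeats Ra-Rd,
#' and the C-terminal domain, tiling residues 1-721.
#'
#' @return Named `IRanges`.
#' @export
snap190Domains <- function() {
  d <- asIRanges(c(1L, 169L, 248L, 306L, 359L, 410L, 484L),
                 c(168L, 247L, 305L, 358L, 409L, 483L, 721L))
  names(d) <- c("N_term", "Rh", "Ra", "Rb", "Rc", "Rd", "C_term")
  d
}

#' Inferred U6 contact architecture
#'
#' Runs [inferContacts()] on the packaged observation table for every U6
#' probe position and assembles the resulting assignments into a
#' [ContactArchitecture-class]. Phosphate 20 is recorded as a stated
#' non-contact on U6; positions never probed are marked unstated.
#'
#' @param grade Apply intensity grading (default `TRUE`).
#' @return A [ContactArchitecture-class].
#' @export
u6Architecture <- function(grade = TRUE) {
  panel <- u6ConstructPanel()
  obs <- u6Observations()
  positions <- sort(unique(obs$phosphate))
  assignments <- lapply(positions, function(ph)
    inferContacts(obs[obs$phosphate == ph, , drop = FALSE], panel,
                  grade = grade))
  knownAbsent <- 20L
  unstated <- setdiff(1:26, c(positions, knownAbsent))
  ContactArchitecture(assignments, snap190Domains(), subunit = "SNAP190",
                      knownAbsent = knownAbsent, unstated = unstated)
}

u1Stated <- function() {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
               grade = INTENSITY_LEVELS[as.integer(m[, 3])])
  }
  list(
    `3` = iv(410, 483, 3),
    `5` = iv(306, 358, 3),
    `7` = iv(248, 305, 3, 306, 358, 2),
    `8` = iv(359, 409, 3),
    `10` = iv(306, 358, 3),
    `12` = iv(306, 358, 3),
    `14` = iv(190, 247, 3, 1, 189, 2, 248, 305, 2),
    `17` = iv(1, 189, 3),
    `20` = iv(1, 189, 3),
    `22` = iv(1, 189, 3, 190, 247, 1),
    `24` = iv(1, 189, 3, 190, 247, 3),
    `25` = iv(1, 189, 3, 190, 247, 2)
  )
}

#' Stated U1 contact architecture
#'
#' The U1 PSEA contact architecture of SNAP190 as restated alongside the U6
#' mapping: positions 3, 5, 7, 8, 10 and 12 contact the same Myb-repeat
#' intervals as on U6; positions 14, 17, 20, 22, 24 and 25 contact the
#' N-terminal/Rh region. Positions 2, 4, 11, 13 and 19 are stated
#' non-contacts on U1. This is a transcription of stated results, not an
#' inference from packaged gels (no U1 lanes ship with this package);
#' regions without a stated status are carried as ambiguous, and the
#' remaining phosphate positions are marked unstated.
#'
#' @return A [ContactArchitecture-class].
#' @export
u1Architecture <- function() {
  L <- 721L
  cutSites <- c(168L, 189L, 247L, 305L, 358L, 409L, 483L)
  part <- segmentPartition(cutSites, L)
  stated <- u1Stated()
  assignments <- lapply(names(stated), function(key) {
    tab <- stated[[key]]
    intervals <- asIRanges(tab$start, tab$end)
    resolved <- vapply(seq_len(nrow(tab)), function(i)
      sum(part$start >= tab$start[i] & part$end <= tab$end[i]) == 1L,
      logical(1))
    mcols(intervals) <- S4Vectors::DataFrame(grade = tab$grade,
                                             resolved = resolved)
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, L), intervals)
    ph <- as.integer(key)
    segGrade <- rep(NA_character_, nrow(part))
    status <- rep("ambiguous", nrow(part))
    for (i in seq_len(nrow(tab))) {
      segs <- which(part$start >= tab$start[i] & part$end <= tab$end[i])
      status[segs] <- "required"
      segGrade[segs] <- tab$grade[i]
    }
    newAssignment(ph, phosphateStrand(ph), "U1", L, cutSites, intervals,
                  gaps, IRanges::IRanges(), IRanges::IRanges(),
                  IRanges::IRanges(), character(), character(),
                  data.frame(start = part$start, end = part$end,
                             status = status, grade = segGrade,
                             stringsAsFactors = FALSE))
  })
  knownAbsent <- c(2L, 4L, 11L, 13L, 19L)
  unstated <- setdiff(1:26, c(as.integer(names(stated)), knownAbsent))
  ContactArchitecture(assignments, snap190Domains(), subunit = "SNAP190",
                      knownAbsent = knownAbsent, unstated = unstated)
}

#' Validate a directory of fixture files
#'
#' Checks that a directory contains a loadable construct table
#' (`constructs*.tsv`), probe set (`*.fasta` plus `probes*.tsv`) and
#' observation table (`obs*.tsv`), and that all cross-file invariants hold
#' (parity rule, digestion tiling, complete per-construct calls).
#'
#' @param dir Directory to validate.
#' @return Invisibly `TRUE`; errors describe the first failing file.
#' @export
validateFixtures <- function(dir) {
  find1 <- function(pattern) {
    f <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    if (!length(f)) stop("no file matching '", pattern, "' in ", dir)
    f[[1]]
  }
  constructs <- loadConstructs(find1("^constructs.*\\.tsv$"))
  for (cc in constructs) {
    frags <- digest(cc)
    stopifnot(frags$start[1] == 1L, frags$end[nrow(frags)] == cc@length)
    if (nrow(frags) > 1L)
      stopifnot(all(frags$start[-1] == frags$end[-nrow(frags)] + 1L))
  }
  probes <- loadProbeSet(find1("\\.fasta$"), find1("^probes.*\\.tsv$"))
  obs <- readObservations(find1("^obs.*\\.tsv$"), constructs)
  message(sprintf(
    "fixtures OK: %d constructs, %d probes, %d observation rows",
    length(constructs), length(probes), nrow(obs)))
  invisible(TRUE)
}
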