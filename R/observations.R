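#' Read a cross-linking observation table
#'
#' An observation table transcribes gel lanes: for each probe (promoter +
#' phosphate + strand) and construct, one call per digestion fragment.
#' Columns: `promoter`, `phosphate`, `strand`, `construct`, `fragment`
#' (`"N"`, `"C"` or `"F<k>"`), `call` (`crosslinked` / `not_crosslinked` /
#' `occluded`), `intensity` (`very_weak` / `weak` / `strong`; required iff
#' the call is `crosslinked`), optional `tentative` (logical; a tentative
#' `not_crosslinked` is a suggestive missing band that is not used as a hard
#' constraint) and optional `note`.
#'
#' @param path TSV file.
#' @param constructs Construct panel (named list of
#'   [ProteinConstruct-class]) used to validate that every fragment of each
#'   referenced construct receives exactly one call.
#' @return `data.frame` of validated observations.
#' @seealso [u6Observations()] for the packaged table.
#' @export
readObservations <- function(path, constructs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("promoter", "phosphate", "strand", "construct", "fragment",
              "call")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("observation table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (!"intensity" %in% names(tab)) tab$intensity <- NA_character_
  if (!"tentative" %in% names(tab)) tab$tentative <- FALSE
  tab$tentative <- as.logical(tab$tentative)
  tab$tentative[is.na(tab$tentative)] <- FALSE
  if (!"note" %in% names(tab)) tab$note <- ""
  tab$intensity[!is.na(tab$intensity) & !nzchar(tab$intensity)] <-
    NA_character_
  validateObservations(tab, constructs)
  tab
}

validateObservations <- function(tab, constructs = NULL) {
  bad <- !tab$call %in% CALL_LEVELS
  if (any(bad))
    stop("unknown call(s): ", paste(unique(tab$call[bad]), collapse = ", "))
  xl <- tab$call == "crosslinked"
  if (any(xl & is.na(tab$intensity)))
    stop("crosslinked calls must carry an intensity")
  if (any(!xl & !is.na(tab$intensity)))
    stop("intensity present on a call that is not 'crosslinked'")
  if (!all(tab$intensity[xl] %in% INTENSITY_LEVELS))
    stop("unknown intensity level(s): ",
         paste(setdiff(unique(tab$intensity[xl]), INTENSITY_LEVELS),
               collapse = ", "))
  badStrand <- !tab$strand %in% STRAND_LEVELS
  if (any(badStrand))
    stop("unknown strand(s): ",
         paste(unique(tab$strand[badStrand]), collapse = ", "))
  parity <- phosphateStrand(tab$phosphate)
  if (any(parity != tab$strand))
    stop("parity violation for phosphate(s): ",
         paste(unique(tab$phosphate[parity != tab$strand]), collapse = ", "))
  if (!is.null(constructs)) {
    key <- paste(tab$promoter, tab$phosphate, tab$construct)
    for (k in unique(key)) {
      sub <- tab[key == k, , drop = FALSE]
      cname <- sub$construct[1L]
      if (!cname %in% names(constructs))
        stop("observation references unknown construct '", cname, "'")
      frags <- digest(constructs[[cname]])
      got <- sort(vapply(sub$fragment, function(f)
        resolveFragment(frags, f), integer(1)))
      if (!identical(unname(got), seq_len(nrow(frags))))
        stop(sprintf(
          "observations for %s must call each of the %d fragment(s) of '%s' exactly once",
          k, nrow(frags), cname))
    }
  }
  invisible(tab)
}

#' The logical constraint contributed by one construct's lane
#'
#' Translates the fragment calls of a single (construct, probe) observation
#' into residue-interval constraints: a cross-linked fragment implies at
#' least one contact within it; a (non-tentative) missing band implies no
#' contact anywhere within it; an occluded band implies nothing.
#'
#' @param observation `data.frame` of calls for one construct at one probe
#'   (columns as in [readObservations()]).
#' @param construct The matching [ProteinConstruct-class].
#' @return A list with elements `mustContact` (`IRanges`, one range per
#'   cross-linked fragment, metadata column `intensity`), `noContact`
#'   (`IRanges` from hard negatives) and `tentativeNoContact` (`IRanges`
#'   from tentative negatives).
#' @export
observationConstraint <- function(observation, construct) {
  frags <- digest(construct)
  idx <- vapply(observation$fragment, function(f) resolveFragment(frags, f),
                integer(1))
  pos <- observation$call == "crosslinked"
  hardNeg <- observation$call == "not_crosslinked" & !observation$tentative
  softNeg <- observation$call == "not_crosslinked" & observation$tentative
  must <- asIRanges(frags$start[idx[pos]], frags$end[idx[pos]])
  mcols(must)$intensity <- observation$intensity[pos]
  list(
    mustContact = must,
    noContact = asIRanges(frags$start[idx[hardNeg]], frags$end[idx[hardNeg]]),
    tentativeNoContact = asIRanges(frags$start[idx[softNeg]],
                                   frags$end[idx[softNeg]]))
}
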