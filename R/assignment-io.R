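rangesToList <- function(r, extra = NULL) {
  if (!length(r)) return(list())
  out <- lapply(seq_along(r), function(i) {
    rec <- list(start = start(r)[i], end = end(r)[i])
    if (!is.null(extra))
      for (col in extra) rec[[col]] <- mcols(r)[[col]][i]
    rec
  })
  out
}

listToRanges <- function(lst, extra = NULL) {
  if (!length(lst)) {
    r <- IRanges::IRanges()
    if (!is.null(extra)) {
      df <- S4Vectors::DataFrame(
        grade = character(), resolved = logical())[, extra, drop = FALSE]
      mcols(r) <- df
    }
    return(r)
  }
  r <- asIRanges(vapply(lst, `[[`, numeric(1), "start"),
                 vapply(lst, `[[`, numeric(1), "end"))
  if (!is.null(extra)) {
    df <- S4Vectors::DataFrame(row.names = seq_along(r))
    for (col in extra)
      df[[col]] <- unlist(lapply(lst, `[[`, col))
    mcols(r) <- df
  }
  r
}

assignmentToList <- function(a) {
  list(
    promoter = a@promoter, phosphate = a@phosphate, strand = a@strand,
    protein_length = a@proteinLength, cut_sites = as.list(a@cutSites),
    intervals = rangesToList(a@intervals, c("grade", "resolved")),
    ambiguous = rangesToList(a@ambiguous),
    excluded = rangesToList(a@excluded),
    untested = rangesToList(a@untested),
    likely = rangesToList(a@likely),
    conflicts = as.list(a@conflicts),
    warnings = as.list(a@warnings),
    segments = lapply(seq_len(nrow(a@segments)), function(i)
      as.list(a@segments[i, , drop = FALSE]))
  )
}

listToAssignment <- function(lst) {
  seg <- if (length(lst$segments))
    do.call(rbind, lapply(lst$segments, function(s)
      data.frame(start = as.integer(s$start), end = as.integer(s$end),
                 status = as.character(s$status),
                 grade = if (is.null(s$grade) || is.na(s$grade))
                   NA_character_ else as.character(s$grade),
                 stringsAsFactors = FALSE)))
  else data.frame(start = integer(), end = integer(),
                  status = character(), grade = character())
  newAssignment(
    lst$phosphate, lst$strand, lst$promoter, lst$protein_length,
    unlist(lst$cut_sites) %||% integer(),
    listToRanges(lst$intervals, c("grade", "resolved")),
    listToRanges(lst$ambiguous), listToRanges(lst$excluded),
    listToRanges(lst$untested), listToRanges(lst$likely),
    as.character(unlist(lst$conflicts)), as.character(unlist(lst$warnings)),
    seg)
}

#' Write a contact assignment to JSON
#'
#' The JSON record round-trips losslessly through [readAssignment()].
#'
#' @param assignment A [ContactAssignment-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAssignment <- function(assignment, path) {
  validObject(assignment)
  jsonlite::write_json(assignmentToList(assignment), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a contact assignment from JSON
#'
#' @param path File written by [writeAssignment()].
#' @return A [ContactAssignment-class].
#' @export
readAssignment <- function(path) {
  lst <- jsonlite::read_json(path)
  a <- listToAssignment(lst)
  validObject(a)
  a
}

#' Assemble a contact architecture from assignments
#'
#' @param assignments List of [ContactAssignment-class] for one promoter.
#' @param domains Named `IRanges` tiling the protein (display grouping and
#'   per-domain comparison units).
#' @param subunit Protein subunit label.
#' @param knownAbsent Phosphate indices with a stated non-contact.
#' @param unstated Phosphate indices with no usable statement.
#' @return A [ContactArchitecture-class].
#' @export
ContactArchitecture <- function(assignments, domains, subunit = "SNAP190",
                                knownAbsent = integer(),
                                unstated = integer()) {
  stopifnot(length(assignments) > 0L)
  promoter <- unique(vapply(assignments, function(a) a@promoter,
                            character(1)))
  if (length(promoter) != 1L)
    stop("assignments span multiple promoters: ",
         paste(promoter, collapse = ", "))
  L <- unique(vapply(assignments, function(a) a@proteinLength, integer(1)))
  if (length(L) != 1L) stop("assignments disagree on protein length")
  ph <- vapply(assignments, function(a) a@phosphate, integer(1))
  ord <- order(ph)
  assignments <- assignments[ord]
  names(assignments) <- as.character(ph[ord])
  new("ContactArchitecture", promoter = promoter, subunit = subunit,
      proteinLength = L, assignments = assignments, domains = domains,
      knownAbsent = as.integer(knownAbsent),
      unstated = as.integer(unstated))
}

#' Write / read a contact architecture as JSON
#'
#' @param architecture A [ContactArchitecture-class].
#' @param path File path.
#' @return `path` invisibly (writer); the architecture (reader).
#' @export
writeArchitecture <- function(architecture, path) {
  validObject(architecture)
  d <- architecture@domains
  lst <- list(
    promoter = architecture@promoter, subunit = architecture@subunit,
    protein_length = architecture@proteinLength,
    domains = lapply(seq_along(d), function(i)
      list(name = names(d)[i], start = start(d)[i], end = end(d)[i])),
    known_absent = as.list(architecture@knownAbsent),
    unstated = as.list(architecture@unstated),
    assignments = lapply(architecture@assignments, assignmentToList))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeArchitecture
#' @export
readArchitecture <- function(path) {
  lst <- jsonlite::read_json(path)
  domains <- listToRanges(lst$domains, extra = NULL)
  names(domains) <- vapply(lst$domains, `[[`, character(1), "name")
  assignments <- lapply(unname(lst$assignments), listToAssignment)
  arch <- ContactArchitecture(
    assignments, domains, subunit = lst$subunit,
    knownAbsent = as.integer(unlist(lst$known_absent)),
    unstated = as.integer(unlist(lst$unstated)))
  validObject(arch)
  arch
}
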