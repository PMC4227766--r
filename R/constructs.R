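#' Create a protein construct
#'
#' @param name Short construct label.
#' @param length Residue count of the full-length protein.
#' @param cleavageSites Integer vector of residue indices; cleavage occurs
#'   after each listed residue. Empty for a no-cut construct.
#' @param tag `"none"`, `"N"` or `"C"`.
#' @param tagMassShift kDa added by the tag.
#' @param sequence Optional amino-acid sequence (length must equal `length`).
#' @return A validated [ProteinConstruct-class].
#' @examples
#' ProteinConstruct("C", 721, 358, tag = "N", tagMassShift = 2.3)
#' @export
ProteinConstruct <- function(name, length, cleavageSites = integer(),
                             tag = "none", tagMassShift = 0,
                             sequence = NA_character_) {
  new("ProteinConstruct", name = as.character(name),
      length = as.integer(length),
      cleavageSites = as.integer(sort(cleavageSites)),
      tag = as.character(tag), tagMassShift = as.numeric(tagMassShift),
      sequence = as.character(sequence))
}

#' Load a construct panel from a TSV file
#'
#' Expects a header row with columns `name`, `length`, `cleavage_sites`
#' (`;`-separated residue indices, empty for none), `tag` and
#' `tag_mass_shift`; an optional `sequence` column is honoured. Each row is
#' validated (sites inside the protein, known tag codes) and duplicate names
#' are rejected.
#'
#' @param path Path to the TSV file.
#' @return Named list of [ProteinConstruct-class] objects, in file order.
#' @seealso [u6ConstructPanel()] for the packaged panel.
#' @export
loadConstructs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("name", "length", "cleavage_sites", "tag", "tag_mass_shift")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("construct table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate construct name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sites <- tab$cleavage_sites[i]
    sites <- if (is.na(sites) || !nzchar(trimws(sites))) integer() else
      as.integer(strsplit(trimws(sites), ";", fixed = TRUE)[[1]])
    out[[i]] <- tryCatch(
      ProteinConstruct(
        name = tab$name[i], length = as.integer(tab$length[i]),
        cleavageSites = sites, tag = tab$tag[i],
        tagMassShift = as.numeric(tab$tag_mass_shift[i]),
        sequence = if ("sequence" %in% names(tab) &&
                       nzchar(tab$sequence[i] %||% "")) tab$sequence[i]
                   else NA_character_),
      error = function(e) stop(sprintf("row %d ('%s'): %s", i, tab$name[i],
                                       conditionMessage(e)), call. = FALSE))
  }
  names(out) <- tab$name
  out
}

#' @describeIn digest Fragments of a single construct. A construct with `k`
#'   cleavage sites yields `k + 1` fragments tiling `[1, length]`; the
#'   fragment containing the tagged terminus carries `tagged = TRUE`.
#' @export
setMethod("digest", "ProteinConstruct", function(x, ...) {
  validObject(x)
  s <- x@cleavageSites
  starts <- c(1L, s + 1L)
  ends <- c(s, x@length)
  n <- length(starts)
  terminus <- if (n == 1L) "N+C" else
    c("N", rep("internal", max(0L, n - 2L)), "C")
  tagged <- rep(FALSE, n)
  if (x@tag == "N") tagged[1L] <- TRUE
  if (x@tag == "C") tagged[n] <- TRUE
  data.frame(
    parent = x@name, start = starts, end = ends, terminus = terminus,
    tagged = tagged, fragment = paste0("F", seq_len(n)),
    stringsAsFactors = FALSE)
})

# Resolve a fragment identifier ("N", "C", or "F<k>") against a digestion.
resolveFragment <- function(frags, id) {
  n <- nrow(frags)
  i <- switch(id, N = 1L, C = n, match(id, frags$fragment))
  if (is.na(i) || i < 1L || i > n)
    stop(sprintf("construct '%s' produces no fragment '%s'",
                 frags$parent[1], id))
  i
}
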