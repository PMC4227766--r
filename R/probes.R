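#' Create a cross-linking probe
#'
#' @param phosphate Phosphate index (element-aligned numbering). The parity
#'   rule is enforced: odd indices lie on the non-template strand, even
#'   indices on the template strand.
#' @param strand `"non_template"` or `"template"`. Defaults to the strand the
#'   parity rule implies.
#' @param duplex Non-template strand sequence, 5'->3' (`DNAString` or
#'   character).
#' @param pseaOffset 1-based position of element base 1 within the duplex.
#' @param promoter Promoter label.
#' @param pseaLength Element length in bp (default 21).
#' @param radiolabelOffset Radiolabel placement, phosphates 5' of the
#'   cross-linker (default 2).
#' @return A validated [CrossLinkProbe-class].
#' @export
CrossLinkProbe <- function(phosphate, strand = phosphateStrand(phosphate),
                           duplex, pseaOffset, promoter = "U6",
                           pseaLength = 21L, radiolabelOffset = 2L) {
  if (is.character(duplex)) duplex <- Biostrings::DNAString(duplex)
  new("CrossLinkProbe", phosphate = as.integer(phosphate),
      strand = strand, promoter = promoter, duplex = duplex,
      pseaOffset = as.integer(pseaOffset),
      pseaLength = as.integer(pseaLength),
      radiolabelOffset = as.integer(radiolabelOffset))
}

#' Load a probe set from a FASTA duplex and a probe table
#'
#' The FASTA file holds the probe's non-template strand (first record); the
#' TSV table has columns `phosphate` and `strand` (plus optional `promoter`).
#' Every probe is validated against the parity rule (odd = non-template,
#' even = template) and against the duplex bounds, and the recognition
#' element must fit at the declared offset.
#'
#' @param fastaPath FASTA file with the duplex non-template strand.
#' @param tablePath TSV file with one row per probe.
#' @param pseaOffset 1-based offset of element base 1 within the duplex.
#' @param pseaLength Element length in bp.
#' @return Named list of [CrossLinkProbe-class], keyed by phosphate index.
#' @seealso [u6ProbeSet()] for the packaged probe set.
#' @export
loadProbeSet <- function(fastaPath, tablePath, pseaOffset = 31L,
                         pseaLength = 21L) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (!length(seqs)) stop("no sequence in ", fastaPath)
  duplex <- seqs[[1L]]
  tab <- utils::read.delim(tablePath, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("phosphate", "strand") %in% names(tab)))
    stop("probe table needs columns 'phosphate' and 'strand'")
  promoter <- if ("promoter" %in% names(tab)) tab$promoter else
    rep("U6", nrow(tab))
  probes <- lapply(seq_len(nrow(tab)), function(i) {
    CrossLinkProbe(phosphate = tab$phosphate[i], strand = tab$strand[i],
                   duplex = duplex, pseaOffset = pseaOffset,
                   promoter = promoter[i], pseaLength = pseaLength)
  })
  names(probes) <- as.character(tab$phosphate)
  probes
}
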