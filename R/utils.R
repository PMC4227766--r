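# Internal helpers shared across modules.

# Base-pair index of phosphate k under the element-aligned numbering adapter:
# phosphate k sits immediately 5' of nucleotide ceiling(k/2) of its strand,
# so consecutive odd (non-template) and even (template) indices pair up at
# the same base-pair rung. Only the parity rule (odd = non-template) is fixed
# by the experimental design; this bp mapping is the package's documented
# convention and is confined to this adapter.
phosphateBp <- function(k) as.integer(ceiling(k / 2))

# Strand implied by the parity rule.
phosphateStrand <- function(k) {
  ifelse(k %% 2L == 1L, "non_template", "template")
}

intensityCode <- function(x) {
  code <- match(x, INTENSITY_LEVELS)
  if (anyNA(code)) stop("unknown intensity level: ",
                        paste(unique(x[is.na(code)]), collapse = ", "))
  code
}

intensityLabel <- function(code) INTENSITY_LEVELS[code]

# Wrap an angle in degrees into (-180, 180].
wrapAngle <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w <= -180, w + 360, w)
}

# Closed residue intervals as IRanges from start/end vectors.
asIRanges <- function(starts, ends) {
  IRanges::IRanges(start = as.integer(starts), end = as.integer(ends))
}

# Merge adjacent/contiguous integer segments (rows of a start/end frame)
# belonging to one logical run into a single interval.
segmentsToRanges <- function(seg) {
  if (nrow(seg) == 0L) return(IRanges::IRanges())
  IRanges::reduce(asIRanges(seg$start, seg$end), min.gapwidth = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
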