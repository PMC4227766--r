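# Builders shared across test files. Panel/observation fixtures are loaded
# once per test run.

fixturePanel <- u6ConstructPanel()
fixtureObs <- u6Observations()

obsFor <- function(phosphate) {
  fixtureObs[fixtureObs$phosphate == phosphate, , drop = FALSE]
}

# A synthetic single-cut construct panel on protein [1, L].
mkPanel <- function(sites, L = 120L, tag = "N", shift = 2.3) {
  panel <- lapply(sites, function(s)
    ProteinConstruct(paste0("s", s), L, s, tag = tag, tagMassShift = shift))
  names(panel) <- vapply(panel, function(x) x@name, character(1))
  panel
}

# One observation row in readObservations() layout.
obsRow <- function(phosphate, construct, fragment, call,
                   intensity = NA_character_, tentative = FALSE,
                   promoter = "SYN") {
  data.frame(promoter = promoter, phosphate = phosphate,
             strand = ifelse(phosphate %% 2 == 1, "non_template",
                             "template"),
             construct = construct, fragment = fragment, call = call,
             intensity = intensity, tentative = tentative, note = "",
             stringsAsFactors = FALSE)
}

obsTable <- function(...) do.call(rbind, list(...))

# A full lane for one single-cut construct: calls for its N and C fragment.
lane <- function(phosphate, construct, nCall, cCall,
                 nInt = NA_character_, cInt = NA_character_,
                 nTent = FALSE, cTent = FALSE) {
  rbind(obsRow(phosphate, construct, "N", nCall, nInt, nTent),
        obsRow(phosphate, construct, "C", cCall, cInt, cTent))
}

# Random observation table over a random single-cut panel; used for the
# propagation-vs-enumeration equivalence checks. Returns list(obs, panel, L).
randomObsCase <- function(maxSegments = 12L, L = 240L) {
  nCuts <- sample.int(maxSegments - 1L, 1L)
  sites <- sort(sample.int(L - 1L, nCuts))
  panel <- mkPanel(sites, L)
  rows <- lapply(names(panel), function(nm) {
    calls <- sample(c("crosslinked", "not_crosslinked", "occluded"), 2L,
                    replace = TRUE, prob = c(0.45, 0.45, 0.10))
    ints <- ifelse(calls == "crosslinked",
                   sample(c("very_weak", "weak", "strong"), 2L,
                          replace = TRUE), NA_character_)
    lane(3L, nm, calls[1], calls[2], ints[1], ints[2])
  })
  list(obs = do.call(rbind, rows), panel = panel, L = L)
}

expectedIntervalFrame <- function(assignment) {
  iv <- contactIntervals(assignment)
  data.frame(start = IRanges::start(iv), end = IRanges::end(iv),
             grade = S4Vectors::mcols(iv)$grade,
             resolved = S4Vectors::mcols(iv)$resolved,
             stringsAsFactors = FALSE)
}
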