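# Independent graded possible-world oracle, implemented from scratch on the
# observation-table layout (no use of the package's inference internals).
# World: one grade in {0 = none, 1 = very weak, 2 = weak, 3 = strong} per
# segment. Constraint semantics mirrors the documented model:
#   - hard not_crosslinked: every segment of the fragment is 0;
#   - crosslinked very_weak: at least one segment of the fragment is > 0;
#   - crosslinked weak/strong: the maximum over the fragment equals the
#     observed level;
#   - occluded / tentative calls: no constraint.
# Returns per-segment statuses and, where constant across worlds, the grade.
gradedOracle <- function(obs, panel, L) {
  sites <- sort(unique(unlist(lapply(panel, function(x) x@cleavageSites))))
  segStart <- c(1L, sites + 1L)
  segEnd <- c(sites, L)
  nseg <- length(segStart)
  stopifnot(nseg <= 9L)  # 4^9 worlds at most
  worlds <- as.matrix(expand.grid(rep(list(0:3), nseg),
                                  KEEP.OUT.ATTRS = FALSE))
  ok <- rep(TRUE, nrow(worlds))
  covered <- integer()
  for (i in seq_len(nrow(obs))) {
    cc <- panel[[obs$construct[i]]]
    s <- cc@cleavageSites
    frag <- if (length(s) == 0L) c(1L, cc@length)
    else if (obs$fragment[i] == "N") c(1L, s[1]) else c(s[length(s)] + 1L,
                                                        cc@length)
    segs <- which(segStart >= frag[1] & segEnd <= frag[2])
    if (obs$call[i] == "occluded") next
    if (obs$call[i] == "not_crosslinked") {
      if (!obs$tentative[i]) {
        ok <- ok & rowSums(worlds[, segs, drop = FALSE] > 0) == 0L
        covered <- union(covered, segs)
      }
      next
    }
    covered <- union(covered, segs)
    gamma <- match(obs$intensity[i], c("very_weak", "weak", "strong"))
    mx <- do.call(pmax, as.data.frame(worlds[, segs, drop = FALSE]))
    ok <- ok & if (gamma == 1L) mx >= 1L else mx == gamma
  }
  cw <- worlds[ok, , drop = FALSE]
  if (nrow(cw) == 0L)
    return(list(conflict = TRUE, nseg = nseg))
  contactedAlways <- colSums(cw > 0) == nrow(cw)
  contactedNever <- colSums(cw > 0) == 0L
  status <- rep("ambiguous", nseg)
  status[contactedAlways] <- "required"
  status[contactedNever] <- "excluded"
  status[setdiff(seq_len(nseg), union(covered, which(contactedNever)))] <-
    "untested"
  determined <- vapply(seq_len(nseg), function(j) {
    g <- unique(cw[, j])
    if (length(g) == 1L) g else NA_integer_
  }, integer(1))
  list(conflict = FALSE, nseg = nseg, status = status,
       determined = determined, segStart = segStart, segEnd = segEnd)
}
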