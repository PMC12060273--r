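#' Linker DNA length represented by a bead count
#'
#' Linker DNA is discretized as `n_beads` interior beads joined by
#' `n_beads + 1` segments of equilibrium length 3 nm (the two outer segments
#' connect the chain to the nucleosome entry/exit sites). The represented
#' contour length in base pairs is `(n_beads + 1) * 3 / 0.34`, i.e. about
#' 8.82 bp per segment, so 2..8 beads give the series 26.47, 35.29, 44.12,
#' 52.94, 61.76, 70.59, 79.41 bp.
#'
#' @param n_beads integer vector, number of linker beads (>= 2; shorter
#'   chains are outside the validity of the wormlike-chain discretization).
#' @return numeric vector of linker lengths in base pairs.
#' @seealso [beads_for_length()] for the inverse mapping.
#' @export
#' @examples
#' linker_length_bp(2:8)
linker_length_bp <- function(n_beads) {
  if (length(n_beads) == 0) return(numeric(0))
  if (any(!is.finite(n_beads)) || any(n_beads != round(n_beads)))
    stop("`n_beads` must be whole numbers", call. = FALSE)
  if (any(n_beads < 2))
    stop("`n_beads` must be >= 2 (wormlike chain model validity)", call. = FALSE)
  (n_beads + 1) * bp_per_segment()
}

#' Bead count best representing a target linker length
#'
#' Inverse of [linker_length_bp()]: returns the bead count whose represented
#' length is nearest the target, floored at 2 beads (the shortest linker the
#' model admits, 26.47 bp).
#'
#' @param target_bp numeric vector of desired linker lengths, bp (> 0).
#' @return integer vector of bead counts (>= 2).
#' @export
#' @examples
#' beads_for_length(c(26.47, 44, 60))
beads_for_length <- function(target_bp) {
  if (length(target_bp) == 0) return(integer(0))
  if (any(!is.finite(target_bp)) || any(target_bp <= 0))
    stop("`target_bp` must be positive and finite", call. = FALSE)
  n <- round(target_bp / bp_per_segment()) - 1L
  pmax(as.integer(n), 2L)
}

#' Filter overlapping nucleosome dyad positions
#'
#' Greedy left-to-right pass retaining a nucleosome only if its 147 bp
#' footprint starts at or after 20 bp before the previously retained
#' nucleosome's end, i.e. an overlap of at most 20 bp is tolerated
#' (dyad-to-dyad spacing >= 127 bp).
#'
#' @param dyads numeric vector of dyad coordinates in bp, sorted ascending.
#' @param footprint nucleosome footprint in bp (default 147).
#' @param max_overlap maximal tolerated footprint overlap in bp (default 20).
#' @return the retained dyads (numeric vector).
#' @export
filter_positions <- function(dyads, footprint = .mf$nuc_bp, max_overlap = 20) {
  if (length(dyads) == 0) return(numeric(0))
  if (is.unsorted(dyads))
    stop("`dyads` must be sorted ascending", call. = FALSE)
  min_gap <- footprint - max_overlap
  keep <- dyads[1]
  last <- dyads[1]
  for (d in dyads[-1]) {
    if (d - last >= min_gap) {
      keep <- c(keep, d)
      last <- d
    }
  }
  keep
}
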