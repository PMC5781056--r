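# Peptide windows around lysines, with mirror padding at protein termini.

#' Resolve the peptide window around a residue
#'
#' A lysine at `center` is described by the 31-residue peptide covering the 15
#' residues upstream and 15 downstream. Near a terminus the missing positions
#' are filled by the mirror effect: a nominal position p outside the sequence
#' is reflected about the nearest terminal residue, p < 1 -> 2 - p and
#' p > L -> 2L - p, applied iteratively for proteins shorter than the window.
#'
#' @param L protein length (>= 2).
#' @param center 1-based position of the central residue.
#' @param flank residues on each side (default 15, giving a 31-residue window).
#' @param padding `"mirror-terminus"` (default; reflection about the terminal
#'   residue) or `"mirror-center"` (out-of-range slot s first tries the
#'   opposite-side position center - s; kept as a sensitivity option).
#' @return a `peptide_window`: list with `center`, `flank`,
#'   `resolved` (length 2*flank+1 vector of 1-based positions; the middle
#'   slot is `center`) and `padded` (logical, TRUE where a slot was remapped).
#' @export
window_indices <- function(L, center, flank = 15,
                           padding = c("mirror-terminus", "mirror-center")) {
  padding <- match.arg(padding)
  if (L < 2) stop("cannot pad a window for a protein of length < 2")
  if (center < 1 || center > L) stop("center ", center, " outside [1, ", L, "]")
  slots <- seq.int(-flank, flank)
  nominal <- center + slots
  resolved <- nominal
  if (padding == "mirror-center") {
    out <- resolved < 1 | resolved > L
    resolved[out] <- center - slots[out]
  }
  for (j in seq_along(resolved)) {
    p <- resolved[[j]]
    while (p < 1 || p > L) {
      if (p < 1) p <- 2 - p else p <- 2 * L - p
    }
    resolved[[j]] <- p
  }
  structure(list(center = center, flank = flank, resolved = resolved,
                 padded = resolved != nominal),
            class = "peptide_window")
}

#' Extract per-residue tracks over a peptide window
#'
#' Row j of each output is the track row at `window$resolved[j]`, so padded
#' slots carry the mirrored residue's values.
#'
#' @param window a `peptide_window`.
#' @param pssm a `pssm_matrix` for the same protein.
#' @param profile a `structural_profile` for the same protein.
#' @return list with `pssm` (31 x 20), `ss` (31 x 3, columns ph, pe, pc) and
#'   `struct` (31 x 8, columns ASA, ph, pe, pc, phi, psi, theta, tau).
#' @export
extract_window_tracks <- function(window, pssm, profile) {
  L <- nrow(pssm$values)
  if (length(profile$asa) != L) {
    stop("PSSM (", L, " rows) and structural profile (", length(profile$asa),
         " rows) disagree in length")
  }
  if (max(window$resolved) > L) {
    stop("window for center ", window$center,
         " does not fit tracks of length ", L)
  }
  idx <- window$resolved
  ws <- cbind(ASA = profile$asa[idx],
              profile$ss_probs[idx, c("ph", "pe", "pc"), drop = FALSE],
              profile$angles[idx, , drop = FALSE])
  list(pssm = pssm$values[idx, , drop = FALSE],
       ss = profile$ss_probs[idx, , drop = FALSE],
       struct = ws)
}
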