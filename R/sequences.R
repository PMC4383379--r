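# TM sequence composition helpers and synthetic plexin TM sequence models.

#' Count beta-branched residues in a sequence
#'
#' Beta-branched residues (Val, Ile, Thr; branched at the beta carbon) are
#' statistically helix-destabilizing in membranes, so their density in a TM
#' segment is a quick flag for helices likely to distort or dissociate.
#'
#' @param sequence one-letter amino-acid string (or vector of strings).
#' @return integer count(s) of V/I/T residues.
#' @export
count_beta_branched <- function(sequence) {
  vapply(sequence, function(s) {
    sum(strsplit(toupper(s), "")[[1]] %in% c("V", "I", "T"))
  }, integer(1), USE.NAMES = !is.null(names(sequence)))
}

#' Helical turns spanned by an axial distance
#'
#' Converts an axial separation along a canonical alpha-helix into helical
#' turns, using the generator defaults (1.5 A rise and 100 degree twist per
#' residue, i.e. 3.6 residues and 5.4 A per turn). For example, a 23 A
#' lateral offset between two junction points corresponds to about 4.3
#' turns of an antiparallel helix bridging them.
#'
#' @param distance axial distance (A).
#' @param rise_per_residue rise per residue (A), default 1.5.
#' @param twist_per_residue twist per residue (degrees), default 100.
#' @return number of helical turns.
#' @export
helical_turns <- function(distance, rise_per_residue = 1.5,
                          twist_per_residue = 100) {
  rise_per_turn <- rise_per_residue * 360 / twist_per_residue
  distance / rise_per_turn
}

#' Synthetic plexin TM sequence models
#'
#' One-letter TM segment sequences for plexin-B1, -B2 and -B3 used by the
#' demonstration analyses. These are *synthetic reconstructions*, not
#' database sequences: they are built to satisfy the qualitative features
#' reported for these segments - lengths (24, 22, 24 residues), the
#' plexin-B2 SLILP motif with prolines at positions 13 and 18 and the
#' bulky C-terminal YCYW, its 11 beta-branched residues out of 22, the
#' plexin-B1 AxxxGxxxG motif with the offset QxxxGxxxS alternative and the
#' central Thr19-Ser20 pair, and the plexin-B3 variant (Glu replacing the
#' motif Ala, 6 beta-branched residues). Positional properties beyond
#' these constraints are invented.
#'
#' @return named character vector with elements `B1`, `B2`, `B3`.
#' @export
plexin_tm_sequences <- function() {
  c(B1 = "LAVQLGLGFGLSLLVLALTSLVFW",
    B2 = "VTIVTIVLSLILPVIFVPYCYW",
    B3 = "LEVQLGLGFGLSIVVLALTSLVFW")
}
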