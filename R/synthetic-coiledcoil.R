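# Crick-parameterized coiled-coil generator: the construction oracle for
# the knobs-into-holes detector and for supercoil handedness calls.

#' Generate a Crick-parameterized coiled coil
#'
#' Each chain's minor helix (2.3 A CA radius, 3.5 residues per turn in the
#' supercoiling frame, 1.5 A rise along the chain) is wound onto a
#' superhelix of the given radius and pitch. Positive pitch produces a
#' left-handed supercoil (the phase of each chain decreases along +z),
#' the geometry of classical coiled coils; negative pitch gives a
#' right-handed supercoil; infinite pitch gives straight parallel helices.
#' Residues at heptad `a`/`d` positions carry leucine, all others alanine,
#' with the `a`/`d` sidechains facing the bundle core, so a well-formed
#' output presents knobs-into-holes packing by construction.
#'
#' @param n_chains 2 or 3 chains.
#' @param pitch superhelical pitch (A); `Inf` for straight helices,
#'   positive for a left-handed supercoil.
#' @param superhelix_radius distance of each chain's local axis from the
#'   bundle axis (A); chain axes are about twice this apart for a dimer.
#' @param heptad_register heptad letters of successive residues, recycled
#'   (default `"abcdefg"`, residue 1 at position a).
#' @param n_residues residues per chain (default 28, four heptads).
#' @return A [structure_model()] with chains A, B (and C).
#' @export
make_coiled_coil <- function(n_chains = 2, pitch = 140,
                             superhelix_radius = 4.9,
                             heptad_register = "abcdefg",
                             n_residues = 28) {
  stopifnot(n_chains %in% c(2, 3), superhelix_radius > 0, n_residues >= 8)
  letters7 <- strsplit(heptad_register, "")[[1]]
  if (!all(letters7 %in% letters[1:7])) {
    stop("heptad_register must use letters a-g", call. = FALSE)
  }
  hep <- letters7[((seq_len(n_residues + 2) - 1) %% length(letters7)) + 1]
  resids <- ifelse(hep %in% c("a", "d"), "LEU", "ALA")[seq_len(n_residues)]
  ia <- match("a", hep)
  if (is.na(ia)) ia <- 1
  rise <- 1.5
  lambda <- if (is.finite(pitch)) atan(2 * pi * superhelix_radius / pitch) else 0
  dz <- rise * cos(lambda)
  psi_step <- 360 / 3.5

  chain_atoms <- function(chain_id, theta0_deg) {
    idx <- 0:(n_residues + 1)
    z <- idx * dz
    theta <- deg2rad(theta0_deg) -
      (if (is.finite(pitch)) 2 * pi * z / pitch else 0 * z)
    atom_mat <- function(r_at, dphi, dz_at) {
      m <- matrix(NA_real_, length(idx), 3)
      for (j in seq_along(idx)) {
        th <- theta[j]
        ctr <- c(superhelix_radius * cos(th), superhelix_radius * sin(th),
                 z[j])
        Tv <- unitv(c(
          if (is.finite(pitch)) superhelix_radius * sin(th) * 2 * pi / pitch else 0,
          if (is.finite(pitch)) -superhelix_radius * cos(th) * 2 * pi / pitch else 0,
          1))
        Ninw <- -c(cos(th), sin(th), 0)
        Bv <- vcross(Tv, Ninw)
        psi <- deg2rad(25.714 + (idx[j] - ia) * psi_step + dphi)
        m[j, ] <- ctr + dz_at * Tv +
          r_at * (cos(psi) * Ninw + sin(psi) * Bv)
      }
      m
    }
    CAm <- atom_mat(2.3, 0, 0)
    Nm <- atom_mat(.BB_OFFSETS$N["r"], .BB_OFFSETS$N["dphi"],
                   .BB_OFFSETS$N["dz"])
    Cm <- atom_mat(.BB_OFFSETS$C["r"], .BB_OFFSETS$C["dphi"],
                   .BB_OFFSETS$C["dz"])
    decorate_backbone(Nm, CAm, Cm, resids, chain_id)
  }

  chains <- c("A", "B", "C")[seq_len(n_chains)]
  thetas <- 90 + (seq_len(n_chains) - 1) * 360 / n_chains
  atoms <- do.call(rbind, Map(chain_atoms, chains, thetas))
  structure_model(atoms, metadata = list(
    coiled_coil = list(pitch = pitch, superhelix_radius = superhelix_radius,
                       heptad_register = heptad_register)))
}
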