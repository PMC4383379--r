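# Dimer and trimer generators with prescribed, recoverable geometry.

#' Specification of a synthetic TM helix dimer
#'
#' Ground-truth parameters for [make_dimer()]. The crossing angle is signed
#' with the convention used throughout the package: negative values denote
#' right-handed crossings, positive left-handed. Per-helix rotations are
#' azimuthal rotations about each helix's own axis, measured from its
#' partner-facing direction; the register shift slides helix B along its
#' axis towards its C-terminus (one canonical turn = 5.4 A).
#'
#' @param n_residues residues per helix.
#' @param inter_axial_distance closest-approach distance between the helix
#'   axes (A), > 0.
#' @param crossing_angle signed crossing angle (degrees), |value| <= 90.
#' @param rotation_a,rotation_b per-helix rotation (degrees).
#' @param register_shift axial shift of helix B (A).
#' @param sequence one-letter sequence passed to [make_ideal_helix()].
#' @param seed integer seed carried for downstream stochastic use.
#' @return An object of class `dimer_spec`.
#' @export
dimer_spec <- function(n_residues = 24, inter_axial_distance = 10,
                       crossing_angle = 0, rotation_a = 0, rotation_b = 0,
                       register_shift = 0, sequence = NULL, seed = 1L) {
  if (abs(crossing_angle) > 90) {
    stop("parameter error: |crossing_angle| must be <= 90 degrees",
         call. = FALSE)
  }
  if (inter_axial_distance <= 0) {
    stop("parameter error: inter_axial_distance must be > 0", call. = FALSE)
  }
  structure(list(n_residues = as.integer(n_residues),
                 inter_axial_distance = inter_axial_distance,
                 crossing_angle = crossing_angle,
                 rotation_a = rotation_a, rotation_b = rotation_b,
                 register_shift = register_shift,
                 sequence = sequence, seed = as.integer(seed)),
            class = "dimer_spec")
}

# template helix rotated about its own (z) axis so that, at rotation = 0,
# residue 1 faces the direction `facing_deg` (degrees from +x)
.oriented_helix <- function(spec, chain_id, facing_deg, rotation) {
  h <- make_ideal_helix(spec$n_residues, sequence = spec$sequence,
                        chain_id = chain_id)
  xyz <- as.matrix(h$atoms[, c("x", "y", "z")])
  xyz <- rotate_coords(xyz, c(0, 0, 1), facing_deg + rotation)
  h$atoms[, c("x", "y", "z")] <- xyz
  h$atoms
}

#' Generate a two-helix (dimer) model with prescribed geometry
#'
#' Builds chains A and B from ideal helices so that every geometric
#' descriptor is recoverable by analysis: the axes are separated by
#' `inter_axial_distance` along their mutual perpendicular, helix B is slid
#' by `register_shift` along its own axis and then rotated about the mutual
#' perpendicular at the dimer midpoint by `crossing_angle` (right-hand rule
#' about the A-to-B direction, which makes positive angles left-handed
#' crossings). Each helix is azimuthally rotated about its own axis by
#' `rotation_a` / `rotation_b`, measured from the partner-facing direction.
#'
#' @param spec a [dimer_spec()].
#' @return A [structure_model()] with chains A and B; the generating spec is
#'   carried in `metadata$dimer_spec`.
#' @export
make_dimer <- function(spec) {
  stopifnot(inherits(spec, "dimer_spec"))
  d <- spec$inter_axial_distance
  zc <- (spec$n_residues - 1) * 1.5 / 2
  a <- .oriented_helix(spec, "A", facing_deg = 0, rotation = spec$rotation_a)
  a$x <- a$x - d / 2
  b <- .oriented_helix(spec, "B", facing_deg = 180,
                       rotation = spec$rotation_b)
  b$x <- b$x + d / 2
  b$z <- b$z + spec$register_shift
  xyz <- rotate_coords(as.matrix(b[, c("x", "y", "z")]), c(1, 0, 0),
                       spec$crossing_angle, center = c(0, 0, zc))
  b[, c("x", "y", "z")] <- xyz
  structure_model(rbind(a, b), metadata = list(dimer_spec = spec))
}

#' Generate a three-helix (trimer) model with prescribed geometry
#'
#' Places three copies of an ideal helix at 120 degree spacing around a
#' central axis, tilted tangentially so that each neighboring pair shows the
#' prescribed signed crossing angle, with the bundle radius solved so the
#' pairwise inter-axial (closest-approach) distances equal
#' `inter_axial_distance`. `handedness` sets the order in which chains A, B,
#' C are encountered when viewed from the N-terminal side looking along the
#' bundle axis.
#'
#' @param spec a [dimer_spec()]; `crossing_angle` is the pairwise crossing,
#'   `inter_axial_distance` the pairwise axis separation. Register shifts
#'   are applied cumulatively (chain B by one, chain C by two shifts).
#' @param handedness `"clockwise"` or `"anticlockwise"` chain order.
#' @param rotation_c azimuthal rotation of chain C (defaults to
#'   `spec$rotation_b`).
#' @return A [structure_model()] with chains A, B, C.
#' @export
make_trimer <- function(spec, handedness = c("anticlockwise", "clockwise"),
                        rotation_c = NULL) {
  stopifnot(inherits(spec, "dimer_spec"))
  handedness <- match.arg(handedness)
  if (is.null(rotation_c)) rotation_c <- spec$rotation_b
  omega <- spec$crossing_angle
  beta <- rad2deg(asin(sqrt((1 - cos(deg2rad(abs(omega)))) / 1.5)))
  zc <- (spec$n_residues - 1) * 1.5 / 2
  step <- if (handedness == "clockwise") 120 else -120
  phis <- 90 + step * (0:2)
  rotations <- c(spec$rotation_a, spec$rotation_b, rotation_c)

  axes_for <- function(rho, s) {
    lapply(seq_len(3), function(k) {
      phi <- deg2rad(phis[k])
      point <- c(rho * cos(phi), rho * sin(phi), zc)
      tang <- c(-sin(phi), cos(phi), 0)
      dir <- cos(deg2rad(beta)) * c(0, 0, 1) +
        s * sin(deg2rad(beta)) * tang
      list(point = point, dir = unitv(dir))
    })
  }
  # pick the tangential tilt sense that reproduces the requested sign
  s <- 1
  if (omega != 0) {
    ax <- axes_for(1, 1)
    cr <- .signed_crossing(ax[[1]]$point, ax[[1]]$dir,
                           ax[[2]]$point, ax[[2]]$dir)
    if (sign(cr) != sign(omega)) s <- -1
  }
  # pairwise closest-approach distance scales linearly with bundle radius
  ax1 <- axes_for(1, s)
  d1 <- .line_closest_approach(ax1[[1]]$point, ax1[[1]]$dir,
                               ax1[[2]]$point, ax1[[2]]$dir)$distance
  rho <- spec$inter_axial_distance / d1

  chains <- c("A", "B", "C")
  parts <- vector("list", 3)
  for (k in 1:3) {
    phi <- phis[k]
    at <- .oriented_helix(spec, chains[k], facing_deg = phi + 180,
                          rotation = rotations[k])
    at$x <- at$x + rho * cos(deg2rad(phi))
    at$y <- at$y + rho * sin(deg2rad(phi))
    at$z <- at$z + (k - 1) * spec$register_shift
    radial <- c(cos(deg2rad(phi)), sin(deg2rad(phi)), 0)
    center <- c(rho * cos(deg2rad(phi)), rho * sin(deg2rad(phi)), zc)
    xyz <- rotate_coords(as.matrix(at[, c("x", "y", "z")]), radial,
                         -s * beta, center = center)
    at[, c("x", "y", "z")] <- xyz
    parts[[k]] <- at
  }
  structure_model(do.call(rbind, parts),
                  metadata = list(dimer_spec = spec, handedness = handedness))
}
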