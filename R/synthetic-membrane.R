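# Two-leaflet pseudo-membrane slab of headgroup atoms.

#' Generate a pseudo-membrane slab
#'
#' Places phosphate-like headgroup pseudo-atoms on square grids at the
#' upper and lower leaflet planes, with grid spacing `sqrt(area_per_lipid)`
#' and the grid centered on the z-axis. Defaults mirror a POPC bilayer
#' build with 72 lipids per leaflet at a target area per lipid of
#' 64.3 A^2. The slab stands in for lipid headgroups in membrane-distance
#' analyses; it has no tails, no dynamics and no chemistry.
#'
#' @param z_upper,z_lower leaflet plane heights (A), `z_upper > z_lower`.
#' @param area_per_lipid area per lipid (A^2).
#' @param lipids_per_leaflet headgroup atoms per leaflet.
#' @return An object of class `membrane_slab` with `upper` and `lower`
#'   `n x 3` coordinate matrices, `spacing`, and the input parameters.
#' @export
make_membrane_slab <- function(z_upper = 20, z_lower = -20,
                               area_per_lipid = 64.3,
                               lipids_per_leaflet = 72) {
  if (z_upper <= z_lower) {
    stop("parameter error: z_upper must exceed z_lower", call. = FALSE)
  }
  if (area_per_lipid <= 0 || lipids_per_leaflet < 1) {
    stop("parameter error: positive area and lipid count required",
         call. = FALSE)
  }
  s <- sqrt(area_per_lipid)
  k <- ceiling(sqrt(lipids_per_leaflet))
  g <- (seq_len(k) - (k + 1) / 2) * s
  grid <- as.matrix(expand.grid(x = g, y = g))[seq_len(lipids_per_leaflet), ,
                                               drop = FALSE]
  structure(list(
    z_upper = z_upper, z_lower = z_lower,
    area_per_lipid = area_per_lipid, spacing = s,
    lipids_per_leaflet = lipids_per_leaflet,
    upper = cbind(grid, z = z_upper),
    lower = cbind(grid, z = z_lower)),
    class = "membrane_slab")
}

#' Convert a membrane slab to a structure model
#'
#' Headgroup pseudo-atoms become HETATM records (residue `POP`, atom `P`),
#' chains `U` (upper leaflet) and `L` (lower), so a slab can be written to
#' PDB alongside protein chains.
#'
#' @param slab a [make_membrane_slab()] result.
#' @return A [structure_model()].
#' @export
slab_as_model <- function(slab) {
  stopifnot(inherits(slab, "membrane_slab"))
  mk <- function(m, ch) {
    data.frame(chain = ch, resno = seq_len(nrow(m)), resid = "POP",
               elety = "P", x = m[, 1], y = m[, 2], z = m[, 3],
               type = "HETATM", stringsAsFactors = FALSE)
  }
  structure_model(rbind(mk(slab$upper, "U"), mk(slab$lower, "L")))
}

#' Distance from a point to the nearest headgroup atom of one leaflet
#'
#' @param point 3-vector (A).
#' @param slab a [make_membrane_slab()] result.
#' @param leaflet `"lower"` or `"upper"`.
#' @return minimum Euclidean distance (A).
#' @export
distance_to_leaflet <- function(point, slab, leaflet = c("lower", "upper")) {
  stopifnot(inherits(slab, "membrane_slab"))
  leaflet <- match.arg(leaflet)
  m <- if (leaflet == "lower") slab$lower else slab$upper
  sqrt(min(rowSums(sweep(m, 2, point)^2)))
}
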