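# Ideal alpha-helix generator and shared backbone decoration.
#
# CA atoms are placed exactly on the parametric helix (user radius/rise/
# twist); N and C ride on companion helices at cylindrical offsets derived
# once from an internal-coordinate build of the canonical helix
# (phi = -57, psi = -47, ideal bond geometry). O, H, CB and Ser/Thr OG are
# then placed from their bonded neighbors by standard peptide geometry.

# cylindrical offsets of N and C relative to the same residue's CA
.BB_OFFSETS <- list(
  N = c(r = 1.551, dphi = -26.77, dz = -0.919),
  C = c(r = 1.666, dphi = 26.74, dz = 1.069)
)

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

expand_sequence <- function(sequence, n) {
  if (is.null(sequence)) sequence <- "L"
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) == 1) letters1 <- rep(letters1, n)
  if (length(letters1) != n) {
    stop("sequence length (", length(letters1),
         ") does not match n_residues (", n, ")", call. = FALSE)
  }
  bad <- setdiff(letters1, names(.AA1TO3))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  unname(.AA1TO3[letters1])
}

# Given per-residue N/CA/C coordinate matrices for residues 0..n+1 (rows),
# return the decorated atom table for residues 1..n. Row i of the matrices
# corresponds to residue i-1 (virtual flanking residues 0 and n+1 provide
# neighbors for O and H placement at the termini).
decorate_backbone <- function(Nm, CAm, Cm, resids, chain_id) {
  n <- length(resids)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- i + 1  # matrix row of residue i
    Ni <- Nm[k, ]; CAi <- CAm[k, ]; Ci <- Cm[k, ]
    Nn <- Nm[k + 1, ]          # next residue N (virtual at i = n)
    Cp <- Cm[k - 1, ]          # previous residue C (virtual at i = 1)
    Oi <- Ci + 1.231 * unitv(-(unitv(CAi - Ci) + unitv(Nn - Ci)))
    res <- resids[i]
    atoms <- list(N = Ni, CA = CAi, C = Ci, O = Oi)
    if (res != "PRO") {
      atoms$H <- Ni + 1.01 * unitv(unitv(Ni - Cp) + unitv(Ni - CAi))
    }
    if (res != "GLY") {
      CB <- place_atom(Ci, Ni, CAi, 1.53, 109.5, -122.69)
      atoms$CB <- CB
      if (res == "SER") {
        atoms$OG <- place_atom(Ni, CAi, CB, 1.417, 110.1, 180)
      } else if (res == "THR") {
        atoms$OG1 <- place_atom(Ni, CAi, CB, 1.433, 109.5, 180)
      }
    }
    order <- intersect(c("N", "H", "CA", "CB", "OG", "OG1", "C", "O"),
                       names(atoms))
    m <- do.call(rbind, atoms[order])
    rows[[i]] <- data.frame(chain = chain_id, resno = i, resid = res,
                            elety = order, x = m[, 1], y = m[, 2],
                            z = m[, 3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate an ideal alpha-helix
#'
#' Builds a regular helix along +z with CA atoms exactly on a cylinder of
#' the given radius: residue i sits at twist angle `(i-1) * twist` and
#' height `(i-1) * rise`, so the CA z-extent is `(n-1) * rise`. Backbone N
#' and C ride on companion helices; O, amide H, CB and Ser/Thr hydroxyl
#' oxygens (OG/OG1) are placed by standard peptide geometry. Defaults are
#' the canonical alpha-helix: 1.5 A rise and 100 deg twist per residue
#' (3.6 residues and 5.4 A per turn) on a 2.3 A CA radius.
#'
#' @param n_residues number of residues (>= 8).
#' @param rise_per_residue axial rise per residue (A).
#' @param twist_per_residue twist per residue (degrees).
#' @param radius CA cylinder radius (A).
#' @param sequence one-letter sequence (single letter recycled, default
#'   poly-Leu); Ser/Thr receive hydroxyl pseudo-atoms for contact analysis.
#' @param chain_id chain identifier.
#' @return A [structure_model()] with backbone N, H, CA, C, O plus CB and
#'   Ser/Thr OG/OG1.
#' @export
make_ideal_helix <- function(n_residues, rise_per_residue = 1.5,
                             twist_per_residue = 100, radius = 2.3,
                             sequence = NULL, chain_id = "A") {
  if (n_residues < 8) {
    stop("parameter error: n_residues must be >= 8", call. = FALSE)
  }
  if (rise_per_residue <= 0 || radius <= 0) {
    stop("parameter error: rise and radius must be positive", call. = FALSE)
  }
  resids <- expand_sequence(sequence, n_residues)
  idx <- 0:(n_residues + 1)  # virtual flanks for terminal O/H placement
  helix_xyz <- function(r, dphi, dz) {
    a <- deg2rad((idx - 1) * twist_per_residue + dphi)
    cbind(r * cos(a), r * sin(a), (idx - 1) * rise_per_residue + dz)
  }
  CAm <- helix_xyz(radius, 0, 0)
  Nm <- helix_xyz(.BB_OFFSETS$N["r"], .BB_OFFSETS$N["dphi"],
                  .BB_OFFSETS$N["dz"])
  Cm <- helix_xyz(.BB_OFFSETS$C["r"], .BB_OFFSETS$C["dphi"],
                  .BB_OFFSETS$C["dz"])
  atoms <- decorate_backbone(Nm, CAm, Cm, resids, chain_id)
  structure_model(atoms, metadata = list(
    helix_params = list(rise = rise_per_residue, twist = twist_per_residue,
                        radius = radius)))
}
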