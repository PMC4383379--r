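#' Labeled atom coordinate set for one conformation
#'
#' A `structure_model` holds one conformation as a flat atom table, the
#' native container for all analyses in this package. Column names follow
#' the bio3d convention: `chain`, `resno` (residue index), `resid`
#' (3-letter residue name), `elety` (atom name) and `x`, `y`, `z` in
#' Angstrom. Arbitrary metadata (e.g. a packing score carried through from
#' an upstream predictor) travels untouched in `metadata`.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @param model_id integer model number (1 for single-model structures).
#' @param metadata optional named list carried through unchanged.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L, metadata = list()) {
  required <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms))) {
    stop("`atoms` must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  keep <- c(required, intersect("type", names(atoms)))
  atoms <- as.data.frame(atoms)[, keep]
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  atoms$resno <- as.integer(atoms$resno)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) {
    stop("all atom positions must be finite", call. = FALSE)
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate atom key (chain, resno, elety): ",
         key[duplicated(key)][1], call. = FALSE)
  }
  structure(list(model_id = as.integer(model_id), atoms = atoms,
                 metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: model", x$model_id, "-", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s) [",
      paste(unique(x$atoms$chain), collapse = ","), "]\n")
  invisible(x)
}

#' Helix segment selection
#'
#' Names a contiguous helical stretch by chain and residue range. Segments
#' are the unit of selection everywhere: axis fitting, RMSD regions,
#' rotation-angle references. A minimum of 8 residues (about two helical
#' turns) is required so that an axis can be fitted.
#'
#' @param chain_id chain identifier.
#' @param first_residue,last_residue first and last residue index
#'   (inclusive, original numbering).
#' @param label optional display label.
#' @return An object of class `helix_segment`.
#' @export
helix_segment <- function(chain_id, first_residue, last_residue,
                          label = NULL) {
  first_residue <- as.integer(first_residue)
  last_residue <- as.integer(last_residue)
  if (last_residue - first_residue + 1L < 8L) {
    stop("a helix segment needs at least 8 residues (~2 turns) for axis fitting",
         call. = FALSE)
  }
  if (is.null(label)) label <- paste0(chain_id, first_residue, "-", last_residue)
  structure(list(chain_id = as.character(chain_id),
                 first_residue = first_residue,
                 last_residue = last_residue,
                 label = label),
            class = "helix_segment")
}

#' Select a helix segment from a model, renumbered to start at 1
#'
#' Extracts the requested atoms for a residue range and re-indexes residues
#' so the segment's first residue becomes residue 1 (the renumbering
#' convention used for all reported per-residue quantities: "residue 4" of a
#' TM helix always means the 4th residue of the selected segment). The
#' stored model is never mutated; renumbering is applied at selection only.
#'
#' @param model a [structure_model()].
#' @param segment a [helix_segment()].
#' @param atom_filter `"CA"`, `"backbone"` (N, CA, C, O), `"heavy"`
#'   (all non-hydrogen atoms), or a character vector of atom names.
#' @return data.frame with columns `resno` (renumbered 1..n), `resno_orig`,
#'   `resid`, `elety`, `x`, `y`, `z`; ordered N to C.
#' @export
select_segment <- function(model, segment, atom_filter = "CA") {
  stopifnot(inherits(model, "structure_model"),
            inherits(segment, "helix_segment"))
  at <- model$atoms
  at <- at[at$chain == segment$chain_id, , drop = FALSE]
  if (nrow(at) == 0) {
    stop("selection error: chain '", segment$chain_id,
         "' absent from model", call. = FALSE)
  }
  wanted <- segment$first_residue:segment$last_residue
  missing <- setdiff(wanted, unique(at$resno))
  if (length(missing) > 0) {
    stop("selection error: residue ", missing[1], " of chain ",
         segment$chain_id, " absent from model", call. = FALSE)
  }
  at <- at[at$resno %in% wanted, , drop = FALSE]
  at <- switch(atom_filter[1],
    CA = if (length(atom_filter) == 1) at[at$elety == "CA", , drop = FALSE] else
      at[at$elety %in% atom_filter, , drop = FALSE],
    backbone = at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE],
    heavy = at[!grepl("^[0-9]*H", at$elety), , drop = FALSE],
    at[at$elety %in% atom_filter, , drop = FALSE])
  if (nrow(at) == 0) {
    stop("selection error: atom filter [",
         paste(atom_filter, collapse = ","),
         "] matches no atoms in segment ", segment$label, call. = FALSE)
  }
  # residues lacking the requested atoms are a selection error too
  if (identical(atom_filter, "CA") || identical(atom_filter, "backbone")) {
    per_res <- table(at$resno)
    need <- if (identical(atom_filter, "CA")) 1L else 4L
    bad <- wanted[!(wanted %in% as.integer(names(per_res))) |
                    per_res[as.character(wanted)] < need]
    bad <- bad[!is.na(bad)]
    if (length(bad) > 0) {
      stop("selection error: residue ", bad[1], " of chain ",
           segment$chain_id, " lacks requested atoms", call. = FALSE)
    }
  }
  out <- data.frame(
    resno = at$resno - segment$first_residue + 1L,
    resno_orig = at$resno,
    resid = at$resid,
    elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "segment") <- segment
  out
}

#' CA coordinate matrix of a segment selection
#'
#' Extracts the CA rows of a [select_segment()] result as an `n x 3`
#' matrix whose rownames are the renumbered residue indices — the input
#' format of [fit_helix_axis()].
#'
#' @param seg_coords a [select_segment()] result containing CA atoms.
#' @return numeric matrix, one row per residue.
#' @export
ca_matrix <- function(seg_coords) {
  ca <- seg_coords[seg_coords$elety == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

#' Reconstruct missing amide hydrogens
#'
#' Adds an H atom to every residue that has a preceding peptide carbonyl
#' carbon, an N and a CA but no H, placing it 1.01 Angstrom from N along the
#' in-plane direction opposed to the bisector of the C(prev)-N and CA-N
#' bonds. Existing hydrogens are left untouched (the operation is
#' idempotent); prolines and chain-initial residues are skipped. Needed for
#' NH order-parameter analysis of structures stripped of hydrogens.
#'
#' @param model a [structure_model()].
#' @return A new `structure_model` with H atoms added where reconstructible.
#' @export
reconstruct_amide_h <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  added <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    resnos <- sort(unique(sub$resno))
    for (i in seq_along(resnos)[-1]) {
      rn <- resnos[i]; rp <- resnos[i - 1]
      if (rn - rp != 1L) next
      rows <- sub[sub$resno == rn, , drop = FALSE]
      if (any(rows$elety == "H")) next
      if (rows$resid[1] == "PRO") next
      N <- unlist(rows[rows$elety == "N", c("x", "y", "z")])
      CA <- unlist(rows[rows$elety == "CA", c("x", "y", "z")])
      Cprev <- unlist(sub[sub$resno == rp & sub$elety == "C",
                          c("x", "y", "z")])
      if (length(N) != 3 || length(CA) != 3 || length(Cprev) != 3) next
      h <- N + 1.01 * unitv(unitv(N - Cprev) + unitv(N - CA))
      added[[length(added) + 1]] <- data.frame(
        chain = ch, resno = rn, resid = rows$resid[1], elety = "H",
        x = h[1], y = h[2], z = h[3],
        type = if (!is.null(rows$type)) rows$type[1] else "ATOM",
        stringsAsFactors = FALSE)
    }
  }
  if (length(added) == 0) return(model)
  at <- rbind(at, do.call(rbind, added))
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  structure_model(at, model_id = model$model_id, metadata = model$metadata)
}

#' Time-ordered trajectory of structure models
#'
#' Bundles frames sharing identical atom labeling with strictly increasing
#' timestamps in nanoseconds. Internally coordinates are stored as an
#' `n_atoms x 3 x n_frames` array for fast per-frame analysis.
#'
#' @param frames list of [structure_model()] objects with identical atom
#'   labeling, or a single model (repeated labeling is then implied).
#' @param times_ns numeric vector of frame times (ns), strictly increasing.
#' @return An object of class `trajectory` with elements `atoms` (label
#'   table), `xyz` (coordinate array) and `times_ns`.
#' @export
trajectory <- function(frames, times_ns) {
  if (inherits(frames, "structure_model")) frames <- list(frames)
  stopifnot(length(frames) >= 1, all(vapply(frames, inherits, TRUE,
                                            "structure_model")))
  if (length(times_ns) != length(frames)) {
    stop("times_ns must have one entry per frame", call. = FALSE)
  }
  if (length(times_ns) > 1 && any(diff(times_ns) <= 0)) {
    stop("times_ns must be strictly increasing", call. = FALSE)
  }
  lab0 <- frames[[1]]$atoms[, c("chain", "resno", "resid", "elety")]
  xyz <- array(NA_real_, dim = c(nrow(lab0), 3, length(frames)))
  for (k in seq_along(frames)) {
    ak <- frames[[k]]$atoms
    if (!identical(ak[, c("chain", "resno", "resid", "elety")], lab0)) {
      stop("frame ", k, " does not share the atom labeling of frame 1",
           call. = FALSE)
    }
    xyz[, , k] <- as.matrix(ak[, c("x", "y", "z")])
  }
  structure(list(atoms = lab0, xyz = xyz, times_ns = as.numeric(times_ns)),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$xyz)[3]
}

#' Extract one frame of a trajectory as a structure model
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return A [structure_model()].
#' @export
frame_model <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"), i >= 1, i <= n_frames(traj))
  at <- traj$atoms
  at$x <- traj$xyz[, 1, i]; at$y <- traj$xyz[, 2, i]; at$z <- traj$xyz[, 3, i]
  structure_model(at, model_id = as.integer(i))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames,", nrow(x$atoms), "atoms,",
      "t =", x$times_ns[1], "..", x$times_ns[length(x$times_ns)], "ns\n")
  invisible(x)
}
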