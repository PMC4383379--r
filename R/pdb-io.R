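#' Read a PDB coordinate file into structure models
#'
#' Parses a single- or multi-model PDB file (wwPDB v3.3 fixed columns,
#' MODEL/ENDMDL delimited) into a list of [structure_model()] objects, one
#' per MODEL record (one in total for single-model files). HETATM records
#' (e.g. lipid headgroup pseudo-atoms) are retained under their residue
#' names with `type = "HETATM"`. Files using insertion codes are rejected.
#'
#' @param path path to an existing PDB file.
#' @param format currently only `"pdb"`.
#' @return list of [structure_model()].
#' @export
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("I/O error: cannot read '", path, "'", call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("format error parsing '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0 || !any(at$type == "ATOM")) {
    stop("format error: '", path, "' contains no ATOM records", call. = FALSE)
  }
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & ins != "")) {
    stop("format error: insertion codes are not supported ('", path, "')",
         call. = FALSE)
  }
  chain <- at$chain
  chain[is.na(chain)] <- " "
  lab <- data.frame(chain = chain, resno = at$resno, resid = at$resid,
                    elety = at$elety, type = at$type,
                    stringsAsFactors = FALSE)
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(k) {
    m <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    atoms <- cbind(lab[, c("chain", "resno", "resid", "elety")],
                   data.frame(x = m[, 1], y = m[, 2], z = m[, 3]),
                   type = lab$type)
    structure_model(atoms, model_id = k)
  })
}

#' Write structure models to a PDB file
#'
#' Writes one or more models as a fixed-column PDB file; multiple models are
#' delimited by MODEL/ENDMDL so the output is re-readable by
#' [read_structure()] with coordinates preserved to 3 decimals. Label fields
#' that overflow the format (chain ids longer than one character, residue
#' names longer than 3, atom names longer than 4, residue numbers beyond
#' 9999) are a format error.
#'
#' @param models a [structure_model()] or list of them (identical labeling).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(models, path) {
  if (inherits(models, "structure_model")) models <- list(models)
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, TRUE, "structure_model")))
  at <- models[[1]]$atoms
  if (any(nchar(as.character(at$chain)) > 1)) {
    stop("format error: chain id longer than the 1-character PDB field",
         call. = FALSE)
  }
  if (any(nchar(as.character(at$resid)) > 3)) {
    stop("format error: residue name longer than the 3-character PDB field",
         call. = FALSE)
  }
  if (any(nchar(as.character(at$elety)) > 4)) {
    stop("format error: atom name longer than the 4-character PDB field",
         call. = FALSE)
  }
  if (any(at$resno > 9999 | at$resno < -999)) {
    stop("format error: residue number outside the PDB field range",
         call. = FALSE)
  }
  xyz <- do.call(rbind, lapply(models, function(m) {
    as.vector(t(as.matrix(m$atoms[, c("x", "y", "z")])))
  }))
  type <- if (!is.null(at$type)) at$type else rep("ATOM", nrow(at))
  bio3d::write.pdb(file = path, xyz = xyz, type = type,
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Convenience wrapper: [read_structure()] followed by [trajectory()].
#' MODEL-delimited multi-model PDB is the package's trajectory exchange
#' format.
#'
#' @param path PDB file path.
#' @param times_ns frame times (ns); defaults to `0, dt, 2 dt, ...`.
#' @param dt_ns frame spacing used when `times_ns` is not given.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, times_ns = NULL, dt_ns = 1) {
  models <- read_structure(path)
  if (is.null(times_ns)) times_ns <- (seq_along(models) - 1) * dt_ns
  trajectory(models, times_ns)
}
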