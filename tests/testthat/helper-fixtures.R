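# Shared fixtures: everything is generated in code at test time.

B1_SEQ <- "LAVQLGLGFGLSLLVLALTSLVFW"

# a small, fast dimer used across tests
tiny_dimer <- function(crossing = -30, ...) {
  make_dimer(dimer_spec(n_residues = 24, inter_axial_distance = 10,
                        crossing_angle = crossing, sequence = B1_SEQ, ...))
}

# raw PDB text lines for hand-built parser tests
pdb_line <- function(serial, elety, resid, chain, resno, x, y, z,
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, elety, resid, chain, resno, x, y, z)
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

segment_axes <- function(model, atom_filter = "CA") {
  lapply(tmhelix:::default_segments(model), function(s) {
    fit_helix_axis(select_segment(model, s, atom_filter))
  })
}

rigid_move <- function(model, axis = c(1, 2, 3), angle = 25,
                       shift = c(5, -3, 7)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- tmhelix:::rotate_coords(xyz, axis, angle)
  xyz <- sweep(xyz, 2, shift, "+")
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}

mirror_x <- function(model) {
  model$atoms$x <- -model$atoms$x
  model
}

circular_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}
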