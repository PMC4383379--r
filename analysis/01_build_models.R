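#!/usr/bin/env Rscript
# Build the candidate model set: synthetic TM dimers spanning the observed
# crossing-angle range (about -55 to +63 deg, both handednesses, plus
# near-parallel structures), two trimer arrangements, and a coiled-coil
# JM-like bundle. Writes PDBs and the generating parameters under
# results/models/.

suppressMessages(library(tmhelix))

out <- "results/models"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
sq <- plexin_tm_sequences()

# candidate dimers: crossing angles and face rotations spanning the range
# reported for predicted TM dimers (right-handed = negative)
params <- data.frame(
  label = c("d_rh55", "d_rh40", "d_rh25", "d_par0", "d_lh10", "d_lh25",
            "d_lh40", "d_lh60"),
  crossing = c(-55, -40, -25, 0, 10, 25, 40, 60),
  rot_a = c(75, 45, 105, -130, 100, -145, 40, -100),
  rot_b = c(95, 5, 105, -130, -25, -145, 65, -105),
  register = c(0, 0, 0, 0, 0, 2.7, 5.4, 0))

models <- list()
for (i in seq_len(nrow(params))) {
  sp <- dimer_spec(24, inter_axial_distance = 10,
                   crossing_angle = params$crossing[i],
                   rotation_a = params$rot_a[i],
                   rotation_b = params$rot_b[i],
                   register_shift = params$register[i],
                   sequence = sq[["B1"]])
  m <- make_dimer(sp)
  models[[params$label[i]]] <- m
  write_structure(m, file.path(out, paste0(params$label[i], ".pdb")))
}

# the two trimer arrangements built for the three-helix receptor model
for (hand in c("clockwise", "anticlockwise")) {
  tm <- make_trimer(dimer_spec(24, inter_axial_distance = 9.5,
                               crossing_angle = if (hand == "clockwise")
                                 20 else -20,
                               sequence = sq[["B1"]]), hand)
  write_structure(tm, file.path(out, paste0("trimer_", hand, ".pdb")))
}

# a JM-like left-handed coiled-coil dimer and its straight control
write_structure(make_coiled_coil(2, pitch = 140),
                file.path(out, "jm_coiled_coil.pdb"))
write_structure(make_coiled_coil(2, pitch = Inf),
                file.path(out, "jm_straight.pdb"))

write.table(params, file.path(out, "dimer_parameters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("built", nrow(params), "dimers, 2 trimers and 2 JM bundles under",
    out, "\n")
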