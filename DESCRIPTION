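Package: tmhelix
Title: Geometry, Similarity and Dynamics Analysis of Transmembrane Helix Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of transmembrane (TM) helix
    dimers and trimers and their juxtamembrane (JM) extensions: helix axis
    fitting and pair geometry (signed crossing angle, per-residue rotation
    angle, register shift, tilt, inter-axial distance), identity-scaled
    normalized RMSD with threshold grouping of candidate models, trajectory
    equilibration assessment, per-residue RMSF and NH S2 order-parameter
    profiles, Ser/Thr hydroxyl contact statistics, membrane-distance series,
    and a simplified knobs-into-holes coiled-coil detector. A synthetic-data
    module generates ideal helices, dimers/trimers with prescribed geometry,
    Crick-parameterized coiled coils, noisy or drifting trajectories and
    pseudo-membrane slabs with known ground truth, so every analysis stage
    has a recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
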