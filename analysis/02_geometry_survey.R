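#!/usr/bin/env Rscript
# Geometry survey and structure grouping of the candidate dimers built by
# 01_build_models.R: per-model crossing/rotation/register/tilt table,
# pairwise normalized-RMSD matrix and 3.5 A single-linkage grouping.
# Run after analysis/01_build_models.R.

suppressMessages(library(tmhelix))

model_dir <- "results/models"
stopifnot(dir.exists(model_dir))
paths <- list.files(model_dir, pattern = "^d_.*\\.pdb$", full.names = TRUE)

res <- run_analysis(list(
  models = lapply(paths, function(p) {
    list(path = p, label = sub("\\.pdb$", "", basename(p)))
  }),
  central_region = c(6, 19),  # centered 14-residue TM core
  output_dir = "results/geometry"))

cat("\nPer-model helix-pair geometry (deg / A):\n")
print(cbind(res$geometry[, 1:2],
            round(res$geometry[, -(1:2)], 1)), row.names = FALSE)
cat("\nGroups at 3.5 A normalized RMSD:\n")
for (i in seq_along(res$grouping$groups)) {
  cat(sprintf("  group %d (rep %s): %s\n", i,
              res$grouping$representatives[i],
              paste(res$grouping$groups[[i]], collapse = ", ")))
}
cat(sprintf("\n%d group(s) at the 3.5 A threshold (single linkage chains\n",
            length(res$grouping$groups)))
cat("models through their nearest neighbours along the crossing-angle\n")
cat("spectrum). Tables under results/geometry/\n")
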