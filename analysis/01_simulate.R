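#!/usr/bin/env Rscript
# Generate the synthetic study trajectories: a GTP-condition run (two
# conformer clusters: T-T-T and T-T-R, bottom interface closed, top open)
# and a GDP-condition run (three clusters: R-R-R, R-R-T, R-T-R with open
# interfaces), 600 frames each at 0.5 ns spacing, written as multi-model
# PDB plus ground-truth tables under results/fixtures/.

suppressPackageStartupMessages(library(ftszdyn))

out_dir <- "results/fixtures"
n_frames <- 600
seed <- 20260919

specs <- list(
  trajectory_spec("GTP", n_frames = n_frames, seed = seed),
  trajectory_spec("GDP", n_frames = n_frames, seed = seed + 1))

manifest <- write_fixture_set(out_dir, specs)
cat("Wrote", nrow(manifest), "fixture files to", out_dir, "\n")
print(manifest)

for (sp in specs) {
  g <- generate_trajectory(sp)
  cat(sprintf("%s: %d frames, clusters populated: %s\n", sp$mode,
              n_frames,
              paste(sort(unique(g$ground_truth$cluster_label)),
                    collapse = ", ")))
}
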