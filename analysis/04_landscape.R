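#!/usr/bin/env Rscript
# Free-energy landscapes over the essential plane (top two singular
# vectors of the pairwise-distance features) with funnel detection, and
# decorrelation-adjusted regressions coupling the inter-domain distance to
# twist, bend and interface tightness.

suppressPackageStartupMessages(library(ftszdyn))

fix_dir <- "results/fixtures"
out_dir <- "results/landscape"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

tpl <- subunit_template()
model <- template_model(tpl, 3)
ref <- build_filament(tpl, 3)

for (mode in c("GTP", "GDP")) {
  stem <- if (mode == "GTP") "traj_01_GTP" else "traj_02_GDP"
  traj <- read_pdb_trajectory(file.path(fix_dir, paste0(stem, ".pdb")))
  traj$reference <- ref

  pr <- svd_project(distance_features(traj))
  f <- fel(pr)
  cat(sprintf("%s: PC1/PC2 explain %.1f%% / %.1f%%; %d funnels\n", mode,
              100 * pr$explained[1], 100 * pr$explained[2], f$n_funnels))

  grid <- expand.grid(x_bin = seq_len(nrow(f$free_energy)),
                      y_bin = seq_len(ncol(f$free_energy)))
  grid$pc1 <- (f$x_edges[grid$x_bin] + f$x_edges[grid$x_bin + 1]) / 2
  grid$pc2 <- (f$y_edges[grid$y_bin] + f$y_edges[grid$y_bin + 1]) / 2
  grid$F_kBT <- as.numeric(f$free_energy)
  grid$count <- as.numeric(f$counts)
  write.table(grid[grid$count > 0, ],
              file.path(out_dir, paste0("fel_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(f$minima, file.path(out_dir, paste0("minima_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # couplings: inter-domain distance of the top subunit against the top
  # interface twist/bend and buried area (1-ns decorrelation for p-values)
  idd <- interdomain_distance(traj, model, "top")$distance
  ang <- decompose_interface_rotation(traj, model, "top")
  bur <- interface_series(traj, model, "top")$series$buried_A2
  rows <- lapply(list(list("theta1", ang$theta1), list("theta2", ang$theta2),
                      list("buried_A2", bur)), function(p) {
    r <- adjusted_regression(p[[2]], idd, frame_dt = traj$frame_dt)
    data.frame(predictor = p[[1]], slope = r$slope, r = r$r,
               n_eff = r$n_eff, p_adjusted = r$p_adjusted)
  })
  reg <- do.call(rbind, rows)
  write.table(reg, file.path(out_dir, paste0("coupling_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s couplings (inter-domain distance vs predictor):\n", mode))
  print(reg, digits = 3)
}
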