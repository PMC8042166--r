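# Synthetic filament-trajectory generator with known ground truth.
#
# Every frame is built from the straight reference filament by (i) sampling
# a conformer cluster, (ii) rotating the two end subunits about the
# middle-subunit filament frame by the cluster's (theta1, theta2, theta3)
# triples (plus Gaussian angle noise), (iii) translating the C-domain of
# the cluster's R-state subunits toward the N-domain (T-to-R emulation),
# (iv) shifting everything above each designated open interface along +z
# (interface opening), and (v) adding per-atom Gaussian jitter. All
# randomness derives from (seed, frame) so outputs are a pure function of
# the spec.

#' Define a conformer cluster
#'
#' @param theta_top,theta_bottom (theta1, theta2, theta3) in degrees for
#'   the top and bottom interface; `theta_bottom` defaults to `theta_top`
#'   (the single-triple form).
#' @param r_subunits labels of subunits held in the R (closed-cleft) state.
#' @param open_interfaces interfaces held open (`"top"`, `"bottom"`).
#' @param label cluster name.
#' @export
conformer_cluster <- function(theta_top, theta_bottom = theta_top,
                              r_subunits = character(0),
                              open_interfaces = character(0),
                              label = NA_character_) {
  stopifnot(length(theta_top) == 3L, length(theta_bottom) == 3L)
  list(theta_top = as.numeric(theta_top),
       theta_bottom = as.numeric(theta_bottom),
       r_subunits = r_subunits, open_interfaces = open_interfaces,
       label = label)
}

# Default conformer clusters. Twist means are the reported per-interface
# theta1 peaks (GTP-IF1 -6.1, GTP-IF2 -35.7, GDP-IF1 -9.4, GDP-IF2 -33.1
# degrees); bending means are the per-state (theta2, theta3) means (GTP:
# 2.8, 0.6; GDP: 13.7, 3.8 degrees). GTP trajectories populate two
# conformer clusters (T-T-T and T-T-R, both with the top interface open
# and the bottom one closed); GDP trajectories populate three (R-R-R
# closed-ish, R-R-T open, R-T-R open with the opposite theta2 bend).
default_clusters <- function(mode) {
  switch(mode,
    GTP = list(
      conformer_cluster(theta_top = c(-35.7, 2.8, 0.6),
                        theta_bottom = c(-6.1, 2.8, 0.6),
                        open_interfaces = "top", label = "TTT"),
      conformer_cluster(theta_top = c(-35.7, 2.8, 0.6),
                        theta_bottom = c(-6.1, 2.8, 0.6),
                        r_subunits = "top", open_interfaces = "top",
                        label = "TTR")),
    GDP = list(
      conformer_cluster(theta_top = c(-9.4, 13.7, 3.8),
                        r_subunits = c("bottom", "middle", "top"),
                        label = "RRR"),
      conformer_cluster(theta_top = c(-33.1, 13.7, 3.8),
                        r_subunits = c("bottom", "middle"),
                        open_interfaces = c("bottom", "top"),
                        label = "RRT"),
      conformer_cluster(theta_top = c(-33.1, -13.7, 3.8),
                        r_subunits = c("bottom", "top"),
                        open_interfaces = c("bottom", "top"),
                        label = "RTR")),
    stop_ftsz("custom mode requires an explicit cluster list",
              class = "invalid_spec_error"))
}

#' Define a synthetic trajectory specification
#'
#' @param mode `"GTP"` (two conformer clusters), `"GDP"` (three) or
#'   `"custom"` (supply `clusters`).
#' @param n_frames frame count (>= 1).
#' @param n_subunits subunit count (default 3).
#' @param frame_dt frame spacing in ns.
#' @param clusters list of [conformer_cluster()]s; defaults by mode.
#' @param cluster_weights sampling probabilities (sum to 1).
#' @param noise_sd per-atom Gaussian jitter, Angstrom.
#' @param angle_sd Gaussian noise on the imposed rotation angles, degrees.
#' @param closure_delta T-to-R inter-domain reduction, Angstrom (default
#'   3.0, beyond the 2.5 Angstrom R-state classifier threshold).
#' @param interface_gap opening translation along +z, Angstrom (default
#'   5.0, enough to drop the buried area below the open threshold).
#' @param seed integer seed.
#' @param template a `subunit_template`.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(mode = c("GTP", "GDP", "custom"), n_frames,
                            n_subunits = 3, frame_dt = 0.5,
                            clusters = NULL, cluster_weights = NULL,
                            noise_sd = 0.3, angle_sd = 2,
                            closure_delta = 3.0, interface_gap = 5.0,
                            seed = 1, template = subunit_template()) {
  mode <- match.arg(mode)
  n_frames <- assert_count(n_frames, "n_frames")
  n_subunits <- assert_count(n_subunits, "n_subunits")
  assert_positive(frame_dt, "frame_dt")
  if (is.null(clusters)) clusters <- default_clusters(mode)
  if (length(clusters) == 0L) {
    stop_ftsz("empty cluster list", class = "invalid_spec_error")
  }
  if (is.null(cluster_weights)) {
    cluster_weights <- rep(1 / length(clusters), length(clusters))
  }
  if (length(cluster_weights) != length(clusters) ||
      abs(sum(cluster_weights) - 1) > 1e-12) {
    stop_ftsz("cluster_weights must match clusters and sum to 1",
              class = "invalid_spec_error")
  }
  labels <- subunit_labels(n_subunits)
  for (cl in clusters) {
    if (!all(cl$r_subunits %in% labels)) {
      stop_ftsz("unknown subunit label in r_subunits",
                class = "invalid_spec_error")
    }
  }
  structure(list(mode = mode, n_subunits = n_subunits, n_frames = n_frames,
                 frame_dt = frame_dt, clusters = clusters,
                 cluster_weights = cluster_weights, noise_sd = noise_sd,
                 angle_sd = angle_sd, closure_delta = closure_delta,
                 interface_gap = interface_gap, seed = as.integer(seed),
                 template = template),
            class = "trajectory_spec")
}

#' Generate a synthetic trajectory with ground truth
#'
#' @param spec a [trajectory_spec()].
#' @return list with `trajectory` (a `fil_trajectory` whose `reference` is
#'   the straight filament), `ground_truth` (one row per frame: cluster
#'   label, imposed angles per interface, imposed inter-domain reduction
#'   per subunit, state string ordered bottom-middle-top), and `model`
#'   (the matching `filament_model`).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  tpl <- spec$template
  ref <- build_filament(tpl, spec$n_subunits)
  model <- template_model(tpl, spec$n_subunits)
  labels <- model$order
  n_at <- nrow(ref$atoms)
  has_ends <- spec$n_subunits >= 2L
  anchor <- labels[ceiling(length(labels) / 2)]

  frame0 <- if (has_ends) filament_frame(ref, model, anchor) else NULL
  B <- if (has_ends) frame0$basis else diag(3)
  sub_sel <- lapply(labels, function(lb) select_atoms(ref, model, lb))
  names(sub_sel) <- labels
  sub_cent <- lapply(sub_sel, function(s) centroid(ref$xyz[s, , drop = FALSE]))
  cdom_sel <- lapply(labels, function(lb) select_atoms(ref, model, lb, "C"))
  names(cdom_sel) <- labels
  # closure direction: C-domain centroid toward N-domain centroid
  close_dir <- lapply(labels, function(lb) {
    cn <- centroid(ref$xyz[select_atoms(ref, model, lb, "N"), , drop = FALSE])
    cc <- centroid(ref$xyz[cdom_sel[[lb]], , drop = FALSE])
    unit3(cn - cc)
  })
  names(close_dir) <- labels

  rotate_about <- function(xyz, sel, R, origin) {
    xyz[sel, ] <- sweep(sweep(xyz[sel, , drop = FALSE], 2, origin) %*% t(R),
                        2, origin, `+`)
    xyz
  }

  nf <- spec$n_frames
  coords <- matrix(NA_real_, nf, 3L * n_at)
  gt <- data.frame(frame = seq_len(nf), cluster = NA_integer_,
                   cluster_label = NA_character_,
                   theta1_top = 0, theta2_top = 0, theta3_top = 0,
                   theta1_bottom = 0, theta2_bottom = 0, theta3_bottom = 0,
                   state = NA_character_, open_interfaces = "",
                   stringsAsFactors = FALSE)
  red_cols <- paste0("reduction_", labels)
  for (cc in red_cols) gt[[cc]] <- 0

  for (f in seq_len(nf)) {
    with_seed(derive_seed(spec$seed, f), {
      ci <- sample.int(length(spec$clusters), 1L,
                       prob = spec$cluster_weights)
      cl <- spec$clusters[[ci]]
      ang_noise <- rnorm(6L, sd = spec$angle_sd)
      th_top <- cl$theta_top + ang_noise[1:3]
      th_bot <- cl$theta_bottom + ang_noise[4:6]
      xyz <- ref$xyz

      if (has_ends) {
        top_lb <- labels[length(labels)]
        bot_lb <- labels[1L]
        if (top_lb != anchor) {
          R <- B %*% compose_zxy(th_top[1], th_top[2], th_top[3]) %*% t(B)
          origin <- (sub_cent[[anchor]] + sub_cent[[top_lb]]) / 2
          xyz <- rotate_about(xyz, sub_sel[[top_lb]], R, origin)
        }
        if (bot_lb != anchor) {
          R <- B %*% compose_zxy(th_bot[1], th_bot[2], th_bot[3]) %*% t(B)
          origin <- (sub_cent[[anchor]] + sub_cent[[bot_lb]]) / 2
          xyz <- rotate_about(xyz, sub_sel[[bot_lb]], R, origin)
        }
      }
      for (lb in cl$r_subunits) {
        sel <- cdom_sel[[lb]]
        xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2,
                            spec$closure_delta * close_dir[[lb]], `+`)
        gt[[paste0("reduction_", lb)]][f] <- spec$closure_delta
      }
      for (itf in cl$open_interfaces) {
        above <- if (itf == "top") length(labels) else 2L:length(labels)
        for (k in above) {
          sel <- sub_sel[[labels[k]]]
          xyz[sel, 3] <- xyz[sel, 3] + spec$interface_gap
        }
      }
      if (spec$noise_sd > 0) {
        xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$noise_sd),
                            ncol = 3L)
      }
      coords[f, ] <- mat2vec(xyz)
      gt$cluster[f] <- ci
      gt$cluster_label[f] <- cl$label
      gt[f, c("theta1_top", "theta2_top", "theta3_top")] <- th_top
      gt[f, c("theta1_bottom", "theta2_bottom", "theta3_bottom")] <- th_bot
      gt$state[f] <- paste(ifelse(labels %in% cl$r_subunits, "R", "T"),
                            collapse = "-")
      gt$open_interfaces[f] <- paste(cl$open_interfaces, collapse = ",")
    })
  }
  traj <- fil_trajectory(ref$atoms, coords, frame_dt = spec$frame_dt,
                         reference = ref)
  list(trajectory = traj, ground_truth = gt, model = model)
}

#' Write a set of synthetic fixtures to disk
#'
#' Per spec: a multi-model PDB, a ground-truth TSV, a YAML spec echo, plus
#' a manifest TSV of all files with md5 checksums.
#'
#' @param out_dir output directory (created if missing).
#' @param specs list of [trajectory_spec()]s.
#' @return data.frame manifest (`file`, `md5`), invisibly also written to
#'   `manifest.tsv`.
#' @export
write_fixture_set <- function(out_dir, specs) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop_ftsz("cannot create output directory ", out_dir, class = "io_error")
  }
  files <- character(0)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    gen <- generate_trajectory(sp)
    stem <- sprintf("traj_%02d_%s", i, sp$mode)
    pdb <- file.path(out_dir, paste0(stem, ".pdb"))
    tsv <- file.path(out_dir, paste0(stem, "_truth.tsv"))
    yml <- file.path(out_dir, paste0(stem, "_spec.yaml"))
    write_pdb_trajectory(gen$trajectory, pdb)
    write.table(gen$ground_truth, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    echo <- sp[setdiff(names(sp), c("clusters", "template"))]
    echo$clusters <- lapply(sp$clusters, function(cl) {
      list(label = cl$label, theta_top = cl$theta_top,
           theta_bottom = cl$theta_bottom, r_subunits = cl$r_subunits,
           open_interfaces = cl$open_interfaces)
    })
    yaml::write_yaml(echo, yml)
    files <- c(files, pdb, tsv, yml)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}
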