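# Superposition, fluctuation measures, the filament-frame rotation
# decomposition, inter-domain geometry, and helix pitch/twist conversion.

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference`. The
#' returned rotation is always proper (det +1; reflections are excluded by
#' sign-correcting the smallest singular value).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3, maps centred mobile onto centred
#'   reference), `translation` (so `mobile %*% t(R) + translation`
#'   superposes), and `rmsd` in Angstrom.
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop_ftsz("mobile and reference must be equal-sized N x 3 matrices",
              class = "shape_error")
  }
  n <- nrow(mobile)
  if (n < 3L) {
    stop_ftsz("at least 3 points are required", class = "insufficient_data_error")
  }
  w <- if (is.null(weights)) rep(1, n) else weights / sum(weights) * n
  cm_m <- colSums(mobile * w) / sum(w)
  cm_r <- colSums(reference * w) / sum(w)
  A <- sweep(mobile, 2, cm_m)
  B <- sweep(reference, 2, cm_r)
  H <- crossprod(A * w, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)) / sum(w))
  list(rotation = R, translation = cm_r - as.numeric(R %*% cm_m), rmsd = rmsd)
}

apply_fit <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Per-frame RMSD against a reference
#'
#' Each frame is independently superposed (on the selection) before the
#' deviation is measured, so the series is invariant to rigid motion of
#' whole frames.
#'
#' @param traj a `fil_trajectory`.
#' @param reference a `fil_structure` congruent with the trajectory;
#'   defaults to the trajectory reference.
#' @param selection integer atom indices; non-empty.
#' @return data.frame with `frame`, `time_ns`, `rmsd`.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL) {
  reference <- reference %||% traj$reference
  selection <- selection %||% seq_len(nrow(traj$atoms))
  if (length(selection) == 0L) {
    stop_ftsz("empty selection", class = "invalid_spec_error")
  }
  ref <- reference$xyz[selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch(frame_coords(traj, f)[selection, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  data.frame(frame = seq_along(vals),
             time_ns = (seq_along(vals) - 1) * traj$frame_dt, rmsd = vals)
}

#' Per-residue RMSF about the mean structure
#'
#' Frames are iteratively superposed onto their running mean structure
#' (tolerance 1e-6 Angstrom on the mean, at most 20 iterations) and the
#' fluctuation of each selected atom about the converged mean is returned.
#'
#' @inheritParams rmsd_series
#' @return data.frame with `index` (atom index into the selection order)
#'   and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL) {
  selection <- selection %||% seq_len(nrow(traj$atoms))
  nf <- n_frames(traj)
  if (nf < 2L) {
    stop_ftsz("RMSF needs at least 2 frames", class = "insufficient_data_error")
  }
  frames <- lapply(seq_len(nf), function(f) {
    frame_coords(traj, f)[selection, , drop = FALSE]
  })
  mean_str <- frames[[1]]
  for (it in seq_len(20L)) {
    aligned <- lapply(frames, function(x) apply_fit(x, kabsch(x, mean_str)))
    new_mean <- Reduce(`+`, aligned) / nf
    shift <- max(abs(new_mean - mean_str))
    mean_str <- new_mean
    if (shift < 1e-6) break
  }
  aligned <- lapply(frames, function(x) apply_fit(x, kabsch(x, mean_str)))
  dev2 <- Reduce(`+`, lapply(aligned, function(x) rowSums((x - mean_str)^2)))
  data.frame(index = selection, rmsf = sqrt(dev2 / nf))
}

#' Per-residue RMSF difference with flexibility flags
#'
#' Positive differences mean the first ensemble is the more flexible one.
#' Residues are flagged strictly where `|delta| > flag_threshold`.
#'
#' @param a,b RMSF data.frames from [rmsf()] over the same residue set.
#' @param flag_threshold Angstrom; default 1.0.
#' @return data.frame with `index`, `delta`, `flag`.
#' @export
delta_rmsf <- function(a, b, flag_threshold = 1.0) {
  if (!identical(a$index, b$index)) {
    stop_ftsz("RMSF inputs cover different residue sets",
              class = "invalid_spec_error")
  }
  delta <- a$rmsf - b$rmsf
  data.frame(index = a$index, delta = delta,
             flag = abs(delta) > flag_threshold)
}

## ---------------------------------------------------------------------------
## Filament frame and Euler-like decomposition

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Compose intrinsic z-x-y rotations
#'
#' `R = Rz(theta1) Rx(theta2) Ry(theta3)`: twist about the filament z axis
#' first, then the two bending rotations. Angles in degrees.
#' @param theta1,theta2,theta3 angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
compose_zxy <- function(theta1, theta2, theta3) {
  d <- pi / 180
  rot_z(theta1 * d) %*% rot_x(theta2 * d) %*% rot_y(theta3 * d)
}

#' Decompose a rotation into intrinsic z-x-y angles
#'
#' Inverse of [compose_zxy()]: theta1, theta3 in (-180, 180], theta2 in
#' \[-90, 90\] degrees. Near gimbal lock (|theta2| > 89.9 deg) the result
#' carries a `degenerate` flag.
#' @param R 3 x 3 proper rotation matrix.
#' @return list with `theta1`, `theta2`, `theta3` (degrees), `degenerate`.
#' @export
decompose_zxy <- function(R) {
  d <- 180 / pi
  s2 <- max(-1, min(1, R[3, 2]))
  theta2 <- asin(s2) * d
  degenerate <- abs(theta2) > 89.9
  if (abs(cos(asin(s2))) < 1e-10) {
    # gimbal: only theta1 +/- theta3 defined; fix theta3 = 0
    theta1 <- atan2(R[2, 1], R[1, 1]) * d
    theta3 <- 0
  } else {
    theta1 <- atan2(-R[1, 2], R[2, 2]) * d
    theta3 <- atan2(-R[3, 1], R[3, 3]) * d
  }
  list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
       degenerate = degenerate)
}

#' Filament-anchored coordinate frame
#'
#' z runs along the filament axis (from the centroid of the subunit below
#' the anchor to the one above; end anchors use the anchor itself as the
#' missing neighbour), x is the projection of the anchor's C-domain offset
#' onto the plane perpendicular to z (the preferred bending direction), and
#' y completes a right-handed triad. The origin is the anchor centroid.
#'
#' @param structure a `fil_structure` with >= 2 subunits.
#' @param model a `filament_model`.
#' @param anchor subunit label; default the middle of the order.
#' @return list with `origin`, `x`, `y`, `z`, and `basis` (3 x 3 with
#'   columns x, y, z).
#' @export
filament_frame <- function(structure, model,
                           anchor = model$order[ceiling(length(model$order) / 2)]) {
  if (length(model$order) < 2L) {
    stop_ftsz("a filament frame needs at least 2 subunits",
              class = "geometry_error")
  }
  cent <- function(label, domain = NULL) {
    centroid(structure$xyz[select_atoms(structure, model, label, domain), ,
                           drop = FALSE])
  }
  idx <- match(anchor, model$order)
  if (is.na(idx)) stop_ftsz("unknown anchor: ", anchor, class = "lookup_error")
  below <- if (idx > 1L) cent(model$order[idx - 1L]) else cent(anchor)
  above <- if (idx < length(model$order)) cent(model$order[idx + 1L]) else cent(anchor)
  z <- unit3(above - below)
  off <- cent(anchor, "C") - cent(anchor)
  xraw <- off - sum(off * z) * z
  x <- unit3(xraw)
  y <- cross3(z, x)
  list(origin = cent(anchor), x = x, y = y, z = z, basis = cbind(x, y, z))
}

#' Inter-subunit rotation angles along a trajectory
#'
#' Implements the filament-frame rotation bookkeeping: per frame the middle
#' (anchor) subunit is superposed onto the straight reference, the moving
#' subunit (top or bottom) is Kabsch-fitted onto its reference pose, and
#' the resulting rotation, expressed in the reference filament-frame basis,
#' is decomposed as intrinsic z (theta1, twist), x (theta2), y (theta3)
#' rotations.
#'
#' @param traj a `fil_trajectory`.
#' @param model a `filament_model` (>= 3 subunits for top and bottom, the
#'   anchor being the middle of the order).
#' @param which `"top"` or `"bottom"`: the moving subunit.
#' @param reference straight reference structure; defaults to the
#'   trajectory reference.
#' @param atom_name selection used for fitting (default CA; synthetic
#'   pseudo-residues are all CA).
#' @return data.frame with `frame`, `time_ns`, `theta1`, `theta2`,
#'   `theta3`, `degenerate`, plus attributes `interface` and `order`
#'   (`"zxy"`, the decomposition order).
#' @export
decompose_interface_rotation <- function(traj, model,
                                         which = c("top", "bottom"),
                                         reference = NULL,
                                         atom_name = "CA") {
  which <- match.arg(which)
  reference <- reference %||% traj$reference
  ord <- model$order
  if (length(ord) < 2L) {
    stop_ftsz("need at least 2 subunits", class = "invalid_spec_error")
  }
  anchor <- ord[ceiling(length(ord) / 2)]
  moving <- if (which == "top") ord[length(ord)] else ord[1L]
  if (moving == anchor) {
    stop_ftsz("missing ", which, " subunit", class = "lookup_error")
  }
  sel_a <- select_atoms(traj, model, anchor, atom_name = atom_name)
  sel_m <- select_atoms(traj, model, moving, atom_name = atom_name)
  if (!length(sel_a) || !length(sel_m)) {
    stop_ftsz("empty subunit selection", class = "lookup_error")
  }
  frame0 <- filament_frame(reference, model, anchor)
  B <- frame0$basis
  ref_a <- reference$xyz[sel_a, , drop = FALSE]
  ref_m <- reference$xyz[sel_m, , drop = FALSE]

  nf <- n_frames(traj)
  out <- data.frame(frame = seq_len(nf),
                    time_ns = (seq_len(nf) - 1) * traj$frame_dt,
                    theta1 = NA_real_, theta2 = NA_real_,
                    theta3 = NA_real_, degenerate = FALSE)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    fit_mid <- kabsch(xyz[sel_a, , drop = FALSE], ref_a)
    aligned_m <- apply_fit(xyz[sel_m, , drop = FALSE], fit_mid)
    fit_mov <- kabsch(aligned_m, ref_m)
    # fit_mov aligns the displaced subunit back onto its reference pose;
    # the imposed rotation is its inverse, expressed in the frame basis
    R_world <- t(fit_mov$rotation)
    ang <- decompose_zxy(t(B) %*% R_world %*% B)
    out$theta1[f] <- ang$theta1
    out$theta2[f] <- ang$theta2
    out$theta3[f] <- ang$theta3
    out$degenerate[f] <- ang$degenerate
  }
  attr(out, "interface") <- which
  attr(out, "order") <- "zxy"
  out
}

#' Inter-domain distance series of one subunit
#'
#' Euclidean distance between the CA centroids of the N- and C-terminal
#' domain point sets, per frame. Invariant to rigid motion of the whole
#' subunit.
#'
#' @param traj a `fil_trajectory`.
#' @param model a `filament_model` with the domain split defined.
#' @param subunit subunit label.
#' @param atom_name atom selection (default CA).
#' @return data.frame with `frame`, `time_ns`, `distance`, plus attribute
#'   `subunit`.
#' @export
interdomain_distance <- function(traj, model, subunit, atom_name = "CA") {
  sel_n <- select_atoms(traj, model, subunit, "N", atom_name)
  sel_c <- select_atoms(traj, model, subunit, "C", atom_name)
  if (!length(sel_n) || !length(sel_c)) {
    stop_ftsz("empty domain set for subunit ", subunit,
              class = "invalid_spec_error")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    sqrt(sum((centroid(xyz[sel_n, , drop = FALSE]) -
                centroid(xyz[sel_c, , drop = FALSE]))^2))
  }, numeric(1))
  out <- data.frame(frame = seq_along(vals),
                    time_ns = (seq_along(vals) - 1) * traj$frame_dt,
                    distance = vals)
  attr(out, "subunit") <- subunit
  out
}

#' Domain rotation angle between two conformations
#'
#' Superposes the two conformations on the N-terminal domain, Kabsch-fits
#' the C-terminal domain, and returns the axis-angle magnitude of the
#' resulting proper rotation (degrees in \[0, 180\]). This is the best-fit
#' rigid-domain measure of a T-to-R cleft closure.
#'
#' @param conf_a,conf_b `fil_structure`s over the same atoms.
#' @param model a `filament_model`.
#' @param subunit subunit label.
#' @param atom_name atom selection (default CA).
#' @return rotation angle in degrees.
#' @export
domain_rotation_angle <- function(conf_a, conf_b, model, subunit,
                                  atom_name = "CA") {
  sel_n <- select_atoms(conf_a, model, subunit, "N", atom_name)
  sel_c <- select_atoms(conf_a, model, subunit, "C", atom_name)
  if (length(sel_n) < 3L || length(sel_c) < 3L) {
    stop_ftsz("degenerate domain selections", class = "insufficient_data_error")
  }
  fit_n <- kabsch(conf_b$xyz[sel_n, , drop = FALSE],
                  conf_a$xyz[sel_n, , drop = FALSE])
  b_c_aligned <- apply_fit(conf_b$xyz[sel_c, , drop = FALSE], fit_n)
  R <- kabsch(b_c_aligned, conf_a$xyz[sel_c, , drop = FALSE])$rotation
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  ang * 180 / pi
}

#' Convert between helix pitch and per-subunit twist
#'
#' Under the full-turn convention one helical turn covers 360 degrees, so
#' `twist = 360 * rise / pitch`; under the half-turn convention a pitch
#' repeat covers 180 degrees (`twist = 180 * rise / pitch`), which is the
#' convention under which published FtsZ pitch/twist pairs (six subunits
#' per turn at about 4 nm rise giving about 30 degrees per subunit) are
#' internally consistent. Neither is asserted as the "right" one; both are
#' exposed.
#'
#' @param rise subunit rise in nm.
#' @param value pitch in nm (`direction = "pitch_to_twist"`) or twist in
#'   degrees (`direction = "twist_to_pitch"`).
#' @param direction conversion direction.
#' @param convention `"full"` (360 degrees per turn) or `"half"` (180).
#' @return twist in degrees, or pitch in nm.
#' @export
twist_pitch <- function(rise, value,
                        direction = c("pitch_to_twist", "twist_to_pitch"),
                        convention = c("full", "half")) {
  direction <- match.arg(direction)
  convention <- match.arg(convention)
  assert_positive(rise, "rise")
  turn <- if (convention == "full") 360 else 180
  if (direction == "pitch_to_twist") {
    assert_positive(value, "pitch")
    turn * rise / value
  } else {
    if (!is.numeric(value) || value == 0) {
      stop_ftsz("pitch is undefined for zero twist",
                class = "undefined_pitch_error")
    }
    turn * rise / value
  }
}
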