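# Synthetic subunit template and straight-filament construction.
#
# A pseudo-subunit is two rigid point clouds ("domains") on jittered
# spherical shells: an N-terminal shell of `n_domain_points` pseudo-residues
# and a C-terminal shell of `c_domain_points`. The two domain centroids sit
# `domain_separation` Angstrom apart along an axis tilted off the filament
# (z) axis, so the C-domain offset defines a preferred bending direction
# (+x) and consecutive subunits mesh at a compact interface that buries
# enough surface area to register as a closed interface.

# Fibonacci lattice on the unit sphere (deterministic, platform independent)
fib_sphere <- function(n) {
  k <- seq_len(n) - 1L
  z <- 1 - (2 * k + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  cbind(r * cos(ga * k), r * sin(ga * k), z)
}

#' Define a synthetic two-domain subunit template
#'
#' The default template has 30 N-domain and 24 C-domain pseudo-residues (54
#' per subunit, 162 in a trimer), a 30 Angstrom inter-domain distance in the
#' reference (T) conformation and a 40 Angstrom longitudinal rise, roughly
#' the 4 nm spacing of FtsZ subunits along a protofilament. Domain shells
#' carry a small deterministic jitter so the clouds have no exact symmetry.
#'
#' @param n_domain_points pseudo-residue count of the N-terminal domain.
#' @param c_domain_points pseudo-residue count of the C-terminal domain.
#' @param domain_separation Angstrom between the two domain centroids in the
#'   reference (T) conformation.
#' @param bead_radius pseudo-atom radius in Angstrom (used for SASA).
#' @param subunit_rise longitudinal extent / stacking spacing in Angstrom.
#' @param shell_radius shell semi-axes in Angstrom: a scalar gives a
#'   sphere, `c(transverse, axial)` a prolate ellipsoid with its long axis
#'   along the filament. The default `c(7.5, 14)` makes each domain long
#'   enough that the N- and C-domain tips of one subunit stay within a
#'   15 Angstrom network cutoff of each other (a connected contact graph)
#'   while consecutive subunits still interdigitate densely at the
#'   interface.
#' @param axial_offset half the z-distance between the two domain
#'   centroids; together with `domain_separation` it fixes the tilt of the
#'   inter-domain axis (the x-offset is derived). Must satisfy
#'   `2 * axial_offset < domain_separation`. The default (0.4985 x
#'   separation) puts the inter-domain axis nearly along the filament so
#'   consecutive subunits interdigitate: with the default separation the
#'   straight filament buries about 1190 Angstrom^2 per interface (a
#'   closed interface) and a 5 Angstrom opening drops it to about 930.
#' @param jitter_sd deterministic point jitter on the shells, Angstrom.
#' @return object of class `subunit_template`.
#' @export
subunit_template <- function(n_domain_points = 30, c_domain_points = 24,
                             domain_separation = 38, bead_radius = 1.9,
                             subunit_rise = 40, shell_radius = c(7.5, 14),
                             axial_offset = 0.4985 * domain_separation,
                             jitter_sd = 0.5) {
  n_domain_points <- assert_count(n_domain_points, "n_domain_points", min = 4)
  c_domain_points <- assert_count(c_domain_points, "c_domain_points", min = 4)
  assert_positive(domain_separation, "domain_separation")
  assert_positive(bead_radius, "bead_radius")
  assert_positive(subunit_rise, "subunit_rise")
  if (2 * axial_offset >= domain_separation) {
    stop_ftsz("2 * axial_offset must be < domain_separation ",
              "(the C-domain must be offset in x)",
              class = "invalid_spec_error")
  }
  half_x <- sqrt((domain_separation / 2)^2 - axial_offset^2)
  # scalar radius -> sphere; length 2 -> prolate ellipsoid
  # (transverse, axial) with the long axis along the filament
  if (length(shell_radius) == 1L) shell_radius <- rep(shell_radius, 2L)

  jitter <- function(pts, seed) {
    with_seed(seed, pts + matrix(rnorm(length(pts), sd = jitter_sd),
                                 ncol = 3L))
  }
  scale_shell <- function(pts) {
    pts %*% diag(c(shell_radius[1], shell_radius[1], shell_radius[2]))
  }
  # fixed internal seeds: the template is deterministic by construction
  n_pts <- jitter(scale_shell(fib_sphere(n_domain_points)), 20201L)
  c_pts <- jitter(scale_shell(fib_sphere(c_domain_points)), 20202L)
  # re-centre so domain centroids are exact
  n_pts <- sweep(n_pts, 2, colMeans(n_pts))
  c_pts <- sweep(c_pts, 2, colMeans(c_pts))
  n_pts <- sweep(n_pts, 2, c(-half_x, 0, -axial_offset), `+`)
  c_pts <- sweep(c_pts, 2, c(+half_x, 0, +axial_offset), `+`)

  structure(list(n_domain_points = n_domain_points,
                 c_domain_points = c_domain_points,
                 domain_separation = domain_separation,
                 bead_radius = bead_radius,
                 subunit_rise = subunit_rise,
                 shell_radius = shell_radius,
                 axial_offset = axial_offset,
                 jitter_sd = jitter_sd,
                 xyz = rbind(n_pts, c_pts)),
            class = "subunit_template")
}

#' Filament annotation matching [build_filament()] output
#'
#' Chains A, B, C, ... bottom to top; residues 1..(n+c) per chain with the
#' N-domain first.
#' @param template a `subunit_template`.
#' @param n_subunits subunit count.
#' @export
template_model <- function(template, n_subunits) {
  n_subunits <- assert_count(n_subunits, "n_subunits")
  np <- template$n_domain_points
  tot <- np + template$c_domain_points
  labels <- subunit_labels(n_subunits)
  subs <- lapply(seq_len(n_subunits), function(k) {
    list(chain = LETTERS[k], resno = c(1, tot), n_domain = c(1, np),
         c_domain = c(np + 1, tot))
  })
  names(subs) <- labels
  filament_model(subs)
}

#' Build a straight synthetic filament
#'
#' Subunits are stacked along +z at `subunit_rise` spacing, chains A
#' (bottom) upward, one pseudo-residue per CA record. Deterministic given
#' the template.
#'
#' @param template a `subunit_template`.
#' @param n_subunits subunit count (>= 1).
#' @return a `fil_structure` with domain annotation available through
#'   [template_model()].
#' @export
build_filament <- function(template, n_subunits = 3) {
  n_subunits <- assert_count(n_subunits, "n_subunits")
  tot <- nrow(template$xyz)
  xyz <- do.call(rbind, lapply(seq_len(n_subunits), function(k) {
    sweep(template$xyz, 2, c(0, 0, (k - 1) * template$subunit_rise), `+`)
  }))
  atoms <- data.frame(
    eleno = seq_len(tot * n_subunits),
    elety = "CA",
    resid = "GLY",
    chain = rep(LETTERS[seq_len(n_subunits)], each = tot),
    resno = rep(seq_len(tot), n_subunits),
    o = 1, b = 0,
    stringsAsFactors = FALSE)
  fil_structure(atoms, xyz)
}
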