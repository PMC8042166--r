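# Solvent-accessible surface area and buried interface area.
#
# SASA uses Shrake-Rupley sphere-point quadrature (compiled kernel) on a
# deterministic Fibonacci lattice: identical point sets on every call, so
# areas are exactly reproducible. The buried interface area between two
# subunits is (M1 + M2 - M12) / 2, i.e. half the total area each partner
# loses on forming the complex.

default_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)

#' Per-atom radii for a structure
#'
#' Synthetic pseudo-atoms get the uniform template bead radius; real
#' structures are assigned by leading element letter from a small built-in
#' table. Every atom must resolve to a radius.
#' @param structure a `fil_structure`.
#' @param uniform if not `NULL`, a single radius used for all atoms.
#' @return numeric vector of radii (Angstrom).
#' @export
atom_radii <- function(structure, uniform = NULL) {
  if (!is.null(uniform)) {
    return(rep(assert_positive(uniform, "uniform radius"),
               nrow(structure$atoms)))
  }
  el <- substr(gsub("[^A-Za-z].*", "", structure$atoms$elety), 1, 1)
  r <- default_radii[toupper(el)]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop_ftsz("no radius for atom ", structure$atoms$elety[bad],
              " (index ", bad, ")", class = "invalid_spec_error")
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param structure a `fil_structure` (or plain N x 3 matrix, in which case
#'   `radii` is required).
#' @param radii per-atom radii in Angstrom; default 1.9 Angstrom uniform
#'   (synthetic pseudo-atoms).
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points quadrature points per atom (>= 32).
#' @return list of class `sasa_record`: `atom_area` (per atom, Angstrom^2),
#'   `total`, `probe`, `n_points`.
#' @export
sasa <- function(structure, radii = NULL, probe = 1.4, n_points = 960) {
  xyz <- if (inherits(structure, "fil_structure")) structure$xyz
         else as.matrix(structure)
  n_points <- assert_count(n_points, "n_points", min = 32)
  if (is.null(radii)) radii <- rep(1.9, nrow(xyz))
  if (length(radii) == 1L) radii <- rep(radii, nrow(xyz))
  if (length(radii) != nrow(xyz)) {
    stop_ftsz("one radius per atom required", class = "invalid_spec_error")
  }
  if (any(radii <= 0)) {
    bad <- which(radii <= 0)[1]
    stop_ftsz("non-positive radius for atom ", bad,
              class = "invalid_spec_error")
  }
  area <- .sasa_atoms(xyz, as.numeric(radii), probe, n_points)
  structure(list(atom_area = area, total = sum(area), probe = probe,
                 n_points = n_points), class = "sasa_record")
}

#' Buried interface area between two subunits
#'
#' Computes the SASA of each subunit in isolation (M1, M2) and of the pair
#' (M12) and returns `(M1 + M2 - M12) / 2`. Symmetric in its two subunits
#' and invariant under rigid motion of the complex.
#'
#' @param structure a `fil_structure` containing both subunits.
#' @param model a `filament_model`.
#' @param subunit_a,subunit_b subunit labels (disjoint atom sets).
#' @param radii,probe,n_points forwarded to [sasa()].
#' @return buried area in Angstrom^2.
#' @export
buried_sasa <- function(structure, model, subunit_a, subunit_b,
                        radii = NULL, probe = 1.4, n_points = 960) {
  ia <- select_atoms(structure, model, subunit_a)
  ib <- select_atoms(structure, model, subunit_b)
  if (length(intersect(ia, ib))) {
    stop_ftsz("subunits overlap", class = "invalid_spec_error")
  }
  if (is.null(radii)) radii <- rep(1.9, nrow(structure$atoms))
  if (length(radii) == 1L) radii <- rep(radii, nrow(structure$atoms))
  m1 <- sasa(structure$xyz[ia, , drop = FALSE], radii[ia], probe, n_points)$total
  m2 <- sasa(structure$xyz[ib, , drop = FALSE], radii[ib], probe, n_points)$total
  iab <- c(ia, ib)
  m12 <- sasa(structure$xyz[iab, , drop = FALSE], radii[iab], probe,
              n_points)$total
  (m1 + m2 - m12) / 2
}

#' Per-frame buried interface area
#'
#' @param traj a `fil_trajectory`.
#' @param model a `filament_model`.
#' @param interface `"top"` (middle-top pair) or `"bottom"` (bottom-middle
#'   pair); with other subunit counts, any label of the form `"i-j"` naming
#'   two subunit labels also works.
#' @param radii,probe,n_points forwarded to [sasa()].
#' @param breaks histogram bin width in Angstrom^2 for the empirical
#'   distribution carried with the series.
#' @return list of class `interface_series`: `interface`, `series`
#'   (data.frame `frame`, `time_ns`, `buried_A2`), `histogram`
#'   (`graphics::hist`-style counts over fixed-width bins).
#' @export
interface_series <- function(traj, model, interface = c("top", "bottom"),
                             radii = NULL, probe = 1.4, n_points = 960,
                             breaks = 25) {
  ord <- model$order
  pair <- if (interface[1] == "top") {
    c(ord[length(ord) - 1L], ord[length(ord)])
  } else if (interface[1] == "bottom") {
    c(ord[1L], ord[2L])
  } else {
    p <- strsplit(interface[1], "-", fixed = TRUE)[[1]]
    if (length(p) != 2L || !all(p %in% ord)) {
      stop_ftsz("unknown interface label: ", interface[1],
                class = "lookup_error")
    }
    p
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    buried_sasa(frame_structure(traj, f), model, pair[1], pair[2],
                radii = radii, probe = probe, n_points = n_points)
  }, numeric(1))
  edges <- seq(floor(min(vals) / breaks) * breaks,
               ceiling(max(vals) / breaks) * breaks + breaks, by = breaks)
  h <- graphics::hist(vals, breaks = edges, plot = FALSE)
  structure(list(interface = interface[1], pair = pair,
                 series = data.frame(frame = seq_along(vals),
                                     time_ns = (seq_along(vals) - 1) *
                                       traj$frame_dt,
                                     buried_A2 = vals),
                 histogram = h),
            class = "interface_series")
}
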