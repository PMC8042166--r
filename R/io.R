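# Structures, trajectories, filament annotations and standard-format I/O.
#
# A structure holds an atom table plus an N x 3 coordinate matrix (Angstrom).
# A trajectory holds the shared atom table, a frames x 3N coordinate matrix
# (the multi-row xyz convention of bio3d) and the frame spacing in ns.

#' Build a structure object
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno` and optionally `o`, `b` (occupancy and B-factor are carried
#'   through I/O untouched).
#' @param xyz numeric N x 3 matrix of coordinates in Angstrom.
#' @return object of class `fil_structure`.
#' @export
fil_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != nrow(atoms)) {
    stop_ftsz("xyz must be an N x 3 matrix congruent with the atom table",
              class = "shape_error")
  }
  if (!all(is.finite(xyz))) {
    stop_ftsz("coordinates must be finite", class = "invalid_spec_error")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stop_ftsz("(chain, resno, atom name) must be unique",
              class = "invalid_spec_error")
  }
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  structure(list(atoms = atoms, xyz = unname(xyz)), class = "fil_structure")
}

#' Build a trajectory object
#'
#' @param atoms shared atom table (see [fil_structure()]).
#' @param coords frames x 3N matrix; row i holds frame i as
#'   (x1, y1, z1, x2, ...).
#' @param frame_dt frame spacing in ns.
#' @param reference optional `fil_structure` used as the straight reference
#'   for superposition-based analyses; defaults to frame 1.
#' @return object of class `fil_trajectory`.
#' @export
fil_trajectory <- function(atoms, coords, frame_dt = 1, reference = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L * nrow(atoms)) {
    stop_ftsz("coordinate columns must equal 3 x atom count",
              class = "shape_error")
  }
  assert_positive(frame_dt, "frame_dt")
  if (is.null(reference)) {
    reference <- fil_structure(atoms, vec2mat(coords[1L, ]))
  }
  structure(list(atoms = atoms, coords = unname(coords),
                 frame_dt = as.numeric(frame_dt), reference = reference),
            class = "fil_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `fil_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$coords)

#' Coordinates of one frame as an N x 3 matrix
#' @param traj a `fil_trajectory`.
#' @param i frame index (1-based).
#' @export
frame_coords <- function(traj, i) vec2mat(traj$coords[i, ])

#' Extract one frame as a structure
#' @inheritParams frame_coords
#' @export
frame_structure <- function(traj, i) fil_structure(traj$atoms, frame_coords(traj, i))

#' @export
print.fil_structure <- function(x, ...) {
  cat("fil_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' @export
print.fil_trajectory <- function(x, ...) {
  cat("fil_trajectory:", n_frames(x), "frames x", nrow(x$atoms),
      "atoms, dt =", x$frame_dt, "ns\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Filament annotation

#' Define a filament annotation
#'
#' Maps atoms to subunits (ordered bottom to top) and splits each subunit
#' into an N-terminal and a C-terminal domain. Residue numbering is 1-based
#' and ranges are inclusive on both ends. The N/C split is always supplied
#' explicitly (it cannot be inferred from coordinates).
#'
#' @param subunits named list, ordered bottom to top; each element is a list
#'   with `chain` (single chain id), `resno` (inclusive range `c(lo, hi)`),
#'   `n_domain` and `c_domain` (residue vectors or inclusive ranges given as
#'   `c(lo, hi)` that partition `resno`).
#' @return object of class `filament_model`.
#' @export
filament_model <- function(subunits) {
  if (length(subunits) < 1L || is.null(names(subunits))) {
    stop_ftsz("subunits must be a non-empty named list",
              class = "invalid_spec_error")
  }
  expand <- function(v) if (length(v) == 2L) seq(v[1], v[2]) else as.integer(v)
  subs <- lapply(subunits, function(s) {
    rng <- expand(s$resno)
    nd <- expand(s$n_domain)
    cd <- expand(s$c_domain)
    if (length(intersect(nd, cd)) > 0L || !setequal(c(nd, cd), rng)) {
      stop_ftsz("domain sets must partition the subunit residue range",
                class = "invalid_spec_error")
    }
    list(chain = s$chain, resno = rng, n_domain = nd, c_domain = cd)
  })
  structure(list(subunits = subs, order = names(subs)),
            class = "filament_model")
}

#' Standard subunit labels for an n-subunit filament
#'
#' `bottom`, (`middle` | `middle1`, `middle2`, ...), `top`; a single subunit
#' is labelled `subunit`.
#' @param n subunit count.
#' @export
subunit_labels <- function(n) {
  n <- assert_count(n, "n")
  if (n == 1L) return("subunit")
  if (n == 2L) return(c("bottom", "top"))
  mids <- if (n == 3L) "middle" else paste0("middle", seq_len(n - 2L))
  c("bottom", mids, "top")
}

#' Select atom indices by subunit, domain and atom name
#'
#' Filters compose by intersection; the result is a stable sorted index set
#' into the atom table.
#'
#' @param x a `fil_structure` or `fil_trajectory`.
#' @param model a `filament_model`.
#' @param subunit subunit label (must exist in `model`); `NULL` for all.
#' @param domain `"N"`, `"C"` or `NULL` for both.
#' @param atom_name atom name filter (e.g. `"CA"`); `NULL` for all.
#' @return sorted integer vector of atom indices.
#' @export
select_atoms <- function(x, model, subunit = NULL, domain = NULL,
                         atom_name = NULL) {
  atoms <- x$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(subunit)) {
    if (!subunit %in% model$order) {
      stop_ftsz("unknown subunit label: ", subunit, class = "lookup_error")
    }
    s <- model$subunits[[subunit]]
    keep <- keep & atoms$chain == s$chain & atoms$resno %in% s$resno
    if (!is.null(domain)) {
      set <- switch(match.arg(domain, c("N", "C")),
                    N = s$n_domain, C = s$c_domain)
      keep <- keep & atoms$resno %in% set
    }
  } else if (!is.null(domain)) {
    set <- unlist(lapply(model$subunits, function(s) {
      switch(match.arg(domain, c("N", "C")), N = s$n_domain, C = s$c_domain)
    }))
    keep <- keep & atoms$resno %in% set
  }
  if (!is.null(atom_name)) keep <- keep & atoms$elety %in% atom_name
  sort(which(keep))
}

#' Read a filament annotation from a YAML config
#'
#' The config is a list of subunit entries, ordered bottom to top, each with
#' `label`, `chain`, `resno: [lo, hi]`, `n_domain: [lo, hi]`,
#' `c_domain: [lo, hi]`.
#' @param path file path.
#' @export
read_filament_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  subs <- cfg$subunits
  names(subs) <- vapply(subs, function(s) s$label, character(1))
  filament_model(lapply(subs, function(s) s[c("chain", "resno", "n_domain",
                                              "c_domain")]))
}

#' Write a filament annotation as YAML
#' @param model a `filament_model`.
#' @param path file path.
#' @export
write_filament_model <- function(model, path) {
  rng <- function(v) c(min(v), max(v))
  subs <- lapply(model$order, function(lb) {
    s <- model$subunits[[lb]]
    list(label = lb, chain = s$chain, resno = rng(s$resno),
         n_domain = rng(s$n_domain), c_domain = rng(s$c_domain))
  })
  yaml::write_yaml(list(subunits = subs), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## PDB I/O

#' Read a multi-model PDB file as a trajectory
#'
#' Models become frames ordered by MODEL index; a single-model file yields a
#' one-frame trajectory. All models must list the same atoms; a model with a
#' deviating atom count raises a format error naming the model. Parsing of
#' the atom records is delegated to [bio3d::read.pdb()]; alternate locations
#' keep the highest-occupancy conformer (first on ties).
#'
#' @param path PDB file.
#' @param frame_dt frame spacing in ns; if the file carries a
#'   `REMARK 250 FRAME_DT_NS` record (written by [write_pdb_trajectory()])
#'   that value wins.
#' @return a `fil_trajectory`.
#' @export
read_pdb_trajectory <- function(path, frame_dt = 1) {
  if (!file.exists(path)) {
    stop_ftsz("file not found: ", path, class = "io_error")
  }
  lines <- readLines(path)
  dt_line <- grep("^REMARK 250 FRAME_DT_NS", lines, value = TRUE)
  if (length(dt_line)) {
    frame_dt <- as.numeric(sub(".*FRAME_DT_NS *", "", dt_line[1]))
  }
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts)) {
      stop_ftsz("unbalanced MODEL/ENDMDL records", class = "format_error")
    }
    counts <- mapply(function(s, e) {
      sum(grepl("^(ATOM|HETATM)", lines[s:e]))
    }, model_starts, ends)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop_ftsz("inconsistent atom count in model ", bad, " (", counts[bad],
                " vs ", counts[1], " in model 1)", class = "format_error")
    }
  }
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  )
  atoms <- data.frame(eleno = pdb$atom$eleno, elety = pdb$atom$elety,
                      resid = pdb$atom$resid, chain = pdb$atom$chain,
                      resno = pdb$atom$resno, o = pdb$atom$o, b = pdb$atom$b,
                      stringsAsFactors = FALSE)
  coords <- pdb$xyz
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1L)
  fil_trajectory(atoms, coords, frame_dt = frame_dt)
}

fmt_atom_line <- function(a, xyz, serial) {
  # fixed PDB columns: name 13-16, resName 18-20, chain 22, resSeq 23-26
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial,
          ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
          a$resid, a$chain, a$resno, xyz[1], xyz[2], xyz[3], a$o, a$b)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-format ATOM records with 0.001
#' Angstrom precision, and a `REMARK 250 FRAME_DT_NS` record so the frame
#' spacing survives the round trip.
#'
#' @param traj a `fil_trajectory` (or a `fil_structure` for a single model).
#' @param path output file.
#' @export
write_pdb_trajectory <- function(traj, path) {
  if (inherits(traj, "fil_structure")) {
    traj <- fil_trajectory(traj$atoms, matrix(mat2vec(traj$xyz), nrow = 1L))
  }
  atoms <- traj$atoms
  n <- nrow(atoms)
  out <- c(sprintf("REMARK 250 FRAME_DT_NS %g", traj$frame_dt))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    out <- c(out, sprintf("MODEL     %4d", f),
             vapply(seq_len(n), function(i) {
               fmt_atom_line(atoms[i, ], xyz[i, ], i)
             }, character(1)),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## XYZ I/O (lightweight dialect: frame blocks of "element x y z")

#' Write a trajectory in XYZ format
#'
#' Standard XYZ frame blocks: atom count line, comment line (carries the
#' frame time), then `element x y z` per atom.
#' @inheritParams write_pdb_trajectory
#' @export
write_xyz_trajectory <- function(traj, path) {
  atoms <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(c(sprintf("%d", nrow(atoms)),
                 sprintf("frame %d dt_ns %g", f, traj$frame_dt),
                 sprintf("%-4s %12.6f %12.6f %12.6f", atoms$elety,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [write_xyz_trajectory()]
#'
#' Element names are kept as atom names; chains/residue numbers are not part
#' of the XYZ dialect, so a template atom table can be supplied.
#' @param path file path.
#' @param atoms optional atom table congruent with the file.
#' @param frame_dt frame spacing in ns (the comment line wins if present).
#' @export
read_xyz_trajectory <- function(path, atoms = NULL, frame_dt = 1) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  elety <- NULL
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop_ftsz("bad atom-count line at line ", i,
                            class = "format_error")
    cmt <- lines[i + 1L]
    m <- regmatches(cmt, regexec("dt_ns ([0-9.eE+-]+)", cmt))[[1]]
    if (length(m) == 2L) frame_dt <- as.numeric(m[2])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    elety <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- mat2vec(xyz)
    i <- i + 2L + n
  }
  if (is.null(atoms)) {
    atoms <- data.frame(eleno = seq_along(elety), elety = elety,
                        resid = "GLY", chain = "A",
                        resno = seq_along(elety), o = 1, b = 0,
                        stringsAsFactors = FALSE)
  }
  fil_trajectory(atoms, do.call(rbind, frames), frame_dt = frame_dt)
}
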