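# Anisotropic network model: Hessian assembly, mode decomposition and
# residue-residue cross-correlations from the low-frequency modes.

#' Build an anisotropic network model
#'
#' Standard ANM super-element Hessian: for a node pair (i, j) within the
#' cutoff the off-diagonal 3x3 block is `-gamma / d^2 * (r_ij %o% r_ij)`
#' and diagonal blocks are minus the sum of the off-diagonal blocks of
#' their row. The eigendecomposition is attached with eigenvalues
#' ascending. Zero modes are identified by the relative threshold
#' `|lambda| < 1e-8 * lambda_max`; a connected, non-collinear structure has
#' exactly six.
#'
#' @param coords N x 3 node coordinates (Angstrom) or a `fil_structure`.
#' @param cutoff interaction cutoff in Angstrom (default 15).
#' @param gamma spring constant (arbitrary units; cancels in correlations).
#' @param nodes optional data.frame of per-node annotation (e.g. subunit
#'   and domain labels) carried into downstream summaries.
#' @return list of class `anm_model`: `coords`, `cutoff`, `gamma`,
#'   `hessian`, `eigenvalues`, `eigenvectors`, `n_zero_modes`,
#'   `connected`, `nodes`.
#' @export
build_anm <- function(coords, cutoff = 15, gamma = 1, nodes = NULL) {
  if (inherits(coords, "fil_structure")) {
    if (is.null(nodes)) {
      nodes <- coords$atoms[, c("chain", "resno")]
    }
    coords <- coords$xyz
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop_ftsz("need at least 3 nodes", class = "insufficient_data_error")
  sv_rank <- qr(sweep(coords, 2, colMeans(coords)))$rank
  if (sv_rank < 2L) {
    stop_ftsz("collinear node coordinates", class = "geometry_error")
  }
  H <- matrix(0, 3 * n, 3 * n)
  d <- as.matrix(dist(coords))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- d[i, j]
      if (dij > cutoff || dij == 0) next
      r <- coords[j, ] - coords[i, ]
      blk <- -gamma / dij^2 * tcrossprod(r)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  ev <- rev(eig$values)
  vec <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  n_zero <- sum(abs(ev) < 1e-8 * max(abs(ev)))
  connected <- n_zero <= 6L
  if (!connected) {
    warning("contact graph appears disconnected: ", n_zero,
            " near-zero modes (expected 6)")
  }
  structure(list(coords = coords, cutoff = cutoff, gamma = gamma,
                 hessian = H, eigenvalues = ev, eigenvectors = vec,
                 n_zero_modes = n_zero, connected = connected,
                 nodes = nodes),
            class = "anm_model")
}

#' Residue-residue cross-correlation map from ANM modes
#'
#' Covariance from the lowest `n_modes` non-zero modes,
#' `cov_ij = sum_k lambda_k^-1 * (v_k,i . v_k,j)` (trace of the 3x3 block),
#' normalised to `C_ij = cov_ij / sqrt(cov_ii cov_jj)`. Entries lie in
#' \[-1, 1\] with unit diagonal; the spring constant cancels.
#'
#' @param model an `anm_model`.
#' @param n_modes non-zero modes used (default 45); silently truncated to
#'   the available count with a warning.
#' @return list of class `correlation_map`: `C` (N x N), `n_modes`,
#'   `nodes`.
#' @export
cross_correlation <- function(model, n_modes = 45) {
  n <- nrow(model$coords)
  nz <- which(abs(model$eigenvalues) >= 1e-8 * max(abs(model$eigenvalues)))
  if (n_modes > length(nz)) {
    warning("only ", length(nz), " non-zero modes available; truncating")
    n_modes <- length(nz)
  }
  use <- nz[seq_len(n_modes)]
  cov <- matrix(0, n, n)
  for (k in use) {
    v <- matrix(model$eigenvectors[, k], nrow = 3L)  # 3 x N
    cov <- cov + crossprod(v) / model$eigenvalues[k]
  }
  dg <- diag(cov)
  if (any(dg <= 0)) {
    stop_ftsz("degenerate node with zero diagonal covariance",
              class = "degenerate_node_error")
  }
  C <- cov / sqrt(tcrossprod(dg))
  structure(list(C = C, n_modes = n_modes, nodes = model$nodes),
            class = "correlation_map")
}

#' Domain-coupling summary across oligomer sizes
#'
#' For a list of correlation maps computed on filaments of increasing
#' subunit count built from one template, summarises per size the mean
#' |C_ij| between the N- and C-domain node sets within each end subunit
#' and between the two end subunits — the quantitative handle on
#' polymerisation-enhanced assembly cooperativity.
#'
#' @param maps list of `correlation_map`s whose `nodes` annotation has
#'   `subunit` and `domain` columns; all maps must share the same per-
#'   subunit node layout.
#' @return data.frame with one row per map: `n_subunits`,
#'   `intra_end_nc` (mean |C| between N and C nodes, averaged over the end
#'   subunits), `inter_end` (mean |C| between the two end subunits; `NA`
#'   for a monomer).
#' @export
coupling_profile <- function(maps) {
  per_sub_layout <- NULL
  rows <- lapply(maps, function(m) {
    nd <- m$nodes
    if (is.null(nd$subunit) || is.null(nd$domain)) {
      stop_ftsz("maps need nodes with subunit and domain columns",
                class = "invalid_spec_error")
    }
    layout <- table(nd$domain[nd$subunit == nd$subunit[1]])
    if (is.null(per_sub_layout)) {
      per_sub_layout <<- layout
    } else if (!identical(as.integer(layout), as.integer(per_sub_layout))) {
      stop_ftsz("inconsistent subunit templates across maps",
                class = "invalid_spec_error")
    }
    subs <- unique(nd$subunit)
    ends <- unique(c(subs[1], subs[length(subs)]))
    intra <- mean(vapply(ends, function(s) {
      i_n <- which(nd$subunit == s & nd$domain == "N")
      i_c <- which(nd$subunit == s & nd$domain == "C")
      mean(abs(m$C[i_n, i_c]))
    }, numeric(1)))
    inter <- if (length(subs) >= 2L) {
      i_a <- which(nd$subunit == subs[1])
      i_b <- which(nd$subunit == subs[length(subs)])
      mean(abs(m$C[i_a, i_b]))
    } else NA_real_
    data.frame(n_subunits = length(subs), intra_end_nc = intra,
               inter_end = inter)
  })
  do.call(rbind, rows)
}

#' ANM node annotation for a synthetic filament
#'
#' Subunit and domain labels for the nodes of [build_filament()] output,
#' for use with [coupling_profile()].
#' @param template a `subunit_template`.
#' @param n_subunits subunit count.
#' @export
template_nodes <- function(template, n_subunits) {
  per <- template$n_domain_points + template$c_domain_points
  data.frame(
    subunit = rep(subunit_labels(n_subunits), each = per),
    domain = rep(rep(c("N", "C"), c(template$n_domain_points,
                                    template$c_domain_points)), n_subunits),
    stringsAsFactors = FALSE)
}
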