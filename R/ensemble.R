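# Ensemble-level analyses: distance-matrix features, SVD projection,
# free-energy landscapes with funnel detection, decorrelation-adjusted
# regression, and contact-rearrangement bookkeeping.

#' Pairwise-distance feature matrix
#'
#' Row i holds the flattened upper triangle of the frame-i pairwise
#' distance matrix over the selection. Rigid-motion invariant by
#' construction.
#'
#' @param traj a `fil_trajectory`.
#' @param selection integer atom indices (>= 2 atoms).
#' @return matrix frames x n(n-1)/2 of class `feature_matrix` with
#'   attribute `selection`.
#' @export
distance_features <- function(traj, selection = NULL) {
  selection <- selection %||% seq_len(nrow(traj$atoms))
  if (length(selection) < 2L) {
    stop_ftsz("need at least 2 selected atoms", class = "invalid_spec_error")
  }
  feats <- t(vapply(seq_len(n_frames(traj)), function(f) {
    as.numeric(dist(frame_coords(traj, f)[selection, , drop = FALSE]))
  }, numeric(length(selection) * (length(selection) - 1) / 2)))
  structure(feats, selection = selection, class = c("feature_matrix",
                                                    "matrix", "array"))
}

#' Project frames onto the top singular vectors
#'
#' Columns are mean-centred, a thin SVD is taken, and frames are projected
#' as left singular vectors scaled by singular values. The sign of each
#' component is fixed so its largest-magnitude feature loading is positive.
#'
#' @param features a frames x features matrix (e.g. [distance_features()]).
#' @param k number of components kept (default 2).
#' @return list of class `pc_projection`: `scores` (frames x k),
#'   `singular_values` (all), `explained` (variance fractions, all),
#'   `center` (column means), `loadings` (features x k).
#' @export
svd_project <- function(features, k = 2) {
  X <- unclass(as.matrix(features))
  if (nrow(X) < 2L) {
    stop_ftsz("need at least 2 frames", class = "insufficient_data_error")
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  r <- min(dim(Xc))
  keep <- min(k, r)
  sv <- svd(Xc, nu = keep, nv = keep)
  dvals <- sv$d
  scores <- sv$u %*% diag(dvals[seq_len(keep)], keep)
  loadings <- sv$v
  for (j in seq_len(keep)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (keep < k) {
    warning("requested ", k, " components but rank is ", keep,
            "; zero-padding")
    scores <- cbind(scores, matrix(0, nrow(scores), k - keep))
    loadings <- cbind(loadings, matrix(0, nrow(loadings), k - keep))
  }
  tot <- sum(dvals^2)
  structure(list(scores = scores, singular_values = dvals,
                 explained = if (tot > 0) dvals^2 / tot else dvals * 0,
                 center = ctr, loadings = loadings),
            class = "pc_projection")
}

#' Free-energy landscape over the essential plane
#'
#' Bins the (PC1, PC2) projections on an `n_bins` x `n_bins` grid, smooths
#' the counts with a small Gaussian kernel, and converts occupancy to free
#' energy `F = -ln(P / Pmax)` in kBT (minimum over occupied bins is exactly
#' 0; unoccupied bins carry a sentinel above the occupied maximum). Funnels
#' are basins of the landscape: local minima that survive a
#' watershed-by-flooding merge of basins separated by less than
#' `barrier_kbt` (persistence criterion).
#'
#' @param projection a `pc_projection`, or a 2-column matrix of scores.
#' @param n_bins bins per axis (>= 2).
#' @param smooth_sd Gaussian smoothing in bin units (0 disables).
#' @param barrier_kbt minimum barrier depth (kBT) for a basin to count as a
#'   separate funnel.
#' @param min_occupancy minimum fraction of all frames a basin must hold to
#'   count as a funnel (guards against isolated outlier frames, which are
#'   disconnected from every saddle and would otherwise always survive).
#' @return list of class `fel_grid`: `x_edges`, `y_edges`, `free_energy`
#'   (matrix, kBT), `counts`, `minima` (data.frame `x_bin`, `y_bin`,
#'   `pc1`, `pc2`, `free_energy`), `n_funnels`.
#' @export
fel <- function(projection, n_bins = 40, smooth_sd = 1.0, barrier_kbt = 1.0,
                min_occupancy = 0.01) {
  scores <- if (inherits(projection, "pc_projection")) {
    projection$scores[, 1:2, drop = FALSE]
  } else as.matrix(projection)[, 1:2, drop = FALSE]
  if (n_bins < 2L) stop_ftsz("n_bins must be >= 2", class = "invalid_spec_error")
  pad <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    rng + c(-1, 1) * diff(rng) * 1e-9
  }
  xr <- pad(scores[, 1]); yr <- pad(scores[, 2])
  xe <- seq(xr[1], xr[2], length.out = n_bins + 1L)
  ye <- seq(yr[1], yr[2], length.out = n_bins + 1L)
  ix <- pmin(n_bins, pmax(1L, findInterval(scores[, 1], xe,
                                           rightmost.closed = TRUE)))
  iy <- pmin(n_bins, pmax(1L, findInterval(scores[, 2], ye,
                                           rightmost.closed = TRUE)))
  counts <- matrix(0, n_bins, n_bins)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1

  dens <- counts
  if (smooth_sd > 0) {
    half <- max(1L, ceiling(3 * smooth_sd))
    g <- exp(-((-half):half)^2 / (2 * smooth_sd^2))
    g <- g / sum(g)
    smooth1 <- function(m) {
      # reflect-pad separable convolution along rows
      n <- nrow(m)
      idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
      idx <- pmin(n, pmax(1L, idx))
      mp <- m[idx, , drop = FALSE]
      out <- m * 0
      for (s in seq_along(g)) {
        out <- out + g[s] * mp[(s - 1) + seq_len(n), , drop = FALSE]
      }
      out
    }
    dens <- t(smooth1(t(smooth1(dens))))
  }

  occupied <- counts > 0
  # the smoothing halo (support) bridges sampling gaps so basins are not
  # fragmented by unvisited bins; reported energies cover occupied bins only
  support <- dens > 0
  fe_flood <- matrix(NA_real_, n_bins, n_bins)
  pmax_ <- max(dens[support])
  fe_flood[support] <- -log(dens[support] / pmax_)
  fe <- matrix(NA_real_, n_bins, n_bins)
  fe[occupied] <- fe_flood[occupied]
  fe[occupied] <- fe[occupied] - min(fe[occupied])
  sentinel <- max(fe[occupied]) + barrier_kbt + 1
  fe[!occupied] <- sentinel

  basins <- detect_funnels(fe_flood, support, barrier_kbt, counts,
                           min_occupancy * sum(counts))
  minima <- basins$minima
  if (nrow(minima)) {
    minima$pc1 <- (xe[minima$x_bin] + xe[minima$x_bin + 1L]) / 2
    minima$pc2 <- (ye[minima$y_bin] + ye[minima$y_bin + 1L]) / 2
  }
  structure(list(x_edges = xe, y_edges = ye, free_energy = fe,
                 counts = counts, minima = minima,
                 n_funnels = nrow(minima), barrier_kbt = barrier_kbt),
            class = "fel_grid")
}

# Watershed-by-flooding over occupied bins with persistence-based merging:
# bins are flooded in order of increasing free energy; when a basin first
# meets a deeper one, it survives as a separate funnel only if the saddle
# lies at least `barrier` above its own minimum. Basins holding fewer than
# `min_counts` frames are discarded as outliers.
detect_funnels <- function(fe, occupied, barrier, counts = NULL,
                           min_counts = 0) {
  nb <- nrow(fe)
  ord <- order(fe)
  ord <- ord[occupied[ord]]
  label <- matrix(0L, nb, nb)
  basin_min <- numeric(0)
  basin_seed <- integer(0)
  alive <- logical(0)
  parent <- integer(0)
  find_root <- function(b) {
    while (parent[b] != b) b <- parent[b]
    b
  }
  for (cell in ord) {
    i <- (cell - 1L) %% nb + 1L
    j <- (cell - 1L) %/% nb + 1L
    nbrs <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nb || jj < 1 || jj > nb) next
      if (label[ii, jj] > 0L) nbrs <- c(nbrs, find_root(label[ii, jj]))
    }
    nbrs <- unique(nbrs)
    if (length(nbrs) == 0L) {
      b <- length(basin_min) + 1L
      basin_min[b] <- fe[i, j]
      basin_seed[b] <- cell
      alive[b] <- TRUE
      parent[b] <- b
      label[i, j] <- b
    } else if (length(nbrs) == 1L) {
      label[i, j] <- nbrs
    } else {
      # saddle: merge shallow basins lacking persistence into the deepest
      depths <- basin_min[nbrs]
      keep <- nbrs[which.min(depths)]
      for (b in setdiff(nbrs, keep)) {
        if (fe[i, j] - basin_min[b] < barrier) alive[b] <- FALSE
        parent[b] <- keep
      }
      label[i, j] <- keep
    }
  }
  surv <- which(alive)
  if (!is.null(counts) && min_counts > 0 && length(surv)) {
    # frames in the basin's own catchment (cells claimed before any merge)
    occ <- vapply(surv, function(b) sum(counts[label == b]), numeric(1))
    # the deepest basin always stays, whatever its share
    keep <- occ >= min_counts
    keep[which.min(basin_min[surv])] <- TRUE
    surv <- surv[keep]
  }
  minima <- data.frame(
    x_bin = (basin_seed[surv] - 1L) %% nb + 1L,
    y_bin = (basin_seed[surv] - 1L) %/% nb + 1L,
    free_energy = basin_min[surv])
  list(minima = minima[order(minima$free_energy), , drop = FALSE],
       label = label)
}

#' Linear regression with decorrelation-adjusted significance
#'
#' Ordinary least squares on all points; the F-statistic p-value is
#' computed with an effective sample size `n_eff = floor(total_time /
#' decorrelation)` (degrees of freedom 1 and `n_eff - 2`), treating frames
#' closer than the decorrelation time as dependent. With
#' `decorrelation = frame_dt` this reduces to the classical F-test.
#'
#' @param x,y numeric series of equal length >= 3; `x` must vary.
#' @param frame_dt frame spacing in ns.
#' @param decorrelation decorrelation interval in ns (default 1).
#' @return list with `slope`, `intercept`, `r`, `f_statistic`,
#'   `p_adjusted`, `n_eff`, `p_defined` (FALSE when `n_eff < 4`, in which
#'   case `p_adjusted` is `NA`).
#' @export
adjusted_regression <- function(x, y, frame_dt, decorrelation = 1.0) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_ftsz("x and y must have equal length >= 3", class = "shape_error")
  }
  if (sd(x) == 0) {
    stop_ftsz("constant predictor", class = "degenerate_predictor_error")
  }
  fit <- lm(y ~ x)
  r <- suppressWarnings(cor(x, y))
  n_eff <- floor(length(x) * frame_dt / decorrelation)
  if (n_eff < 4) {
    return(list(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]), r = r,
                f_statistic = NA_real_, p_adjusted = NA_real_,
                n_eff = n_eff, p_defined = FALSE))
  }
  r2 <- r^2
  f_stat <- if (r2 >= 1) Inf else r2 / (1 - r2) * (n_eff - 2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r, f_statistic = f_stat,
       p_adjusted = pf(f_stat, 1, n_eff - 2, lower.tail = FALSE),
       n_eff = n_eff, p_defined = TRUE)
}

#' Residue contact set of one conformation
#'
#' Unordered residue pairs whose minimum inter-atom distance is at most
#' `cutoff`. Pairs on the same chain closer than 3 in sequence are
#' excluded; inter-chain pairs are always eligible.
#'
#' @param structure a `fil_structure`.
#' @param selection atom indices considered (default all).
#' @param cutoff Angstrom (> 0).
#' @return data.frame `chain_i`, `resno_i`, `chain_j`, `resno_j`, `key`.
#' @export
contact_map <- function(structure, selection = NULL, cutoff = 4.5) {
  assert_positive(cutoff, "cutoff")
  selection <- selection %||% seq_len(nrow(structure$atoms))
  at <- structure$atoms[selection, , drop = FALSE]
  xyz <- structure$xyz[selection, , drop = FALSE]
  res_key <- paste(at$chain, at$resno, sep = ":")
  res <- unique(res_key)
  d <- as.matrix(dist(xyz))
  pairs <- list()
  for (a in seq_along(res)) {
    ia <- which(res_key == res[a])
    for (b in seq_along(res)) {
      if (b <= a) next
      ka <- strsplit(res[a], ":")[[1]]; kb <- strsplit(res[b], ":")[[1]]
      if (ka[1] == kb[1] &&
          abs(as.integer(ka[2]) - as.integer(kb[2])) < 3) next
      ib <- which(res_key == res[b])
      if (min(d[ia, ib]) <= cutoff) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          chain_i = ka[1], resno_i = as.integer(ka[2]),
          chain_j = kb[1], resno_j = as.integer(kb[2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(chain_i = character(0), resno_i = integer(0),
               chain_j = character(0), resno_j = integer(0),
               stringsAsFactors = FALSE)
  }
  out$key <- paste(out$chain_i, out$resno_i, out$chain_j, out$resno_j)
  out
}

#' Gained and lost persistent contacts between two ensembles
#'
#' A residue pair is "present" in an ensemble when its contact persists in
#' at least `persistence` of the frames. Lost = present in `traj_a` only;
#' gained = present in `traj_b` only.
#'
#' @param traj_a,traj_b `fil_trajectory`s.
#' @param selection atom indices considered.
#' @param cutoff contact cutoff in Angstrom.
#' @param persistence frame fraction in (0, 1].
#' @return list of class `contact_diff`: `present_a`, `present_b`,
#'   `gained`, `lost` (vectors of pair keys), `persistence`.
#' @export
contact_diff <- function(traj_a, traj_b, selection = NULL, cutoff = 4.5,
                         persistence = 0.7) {
  persistent <- function(traj) {
    nf <- n_frames(traj)
    tab <- table(unlist(lapply(seq_len(nf), function(f) {
      contact_map(frame_structure(traj, f), selection, cutoff)$key
    })))
    names(tab)[tab / nf >= persistence]
  }
  pa <- persistent(traj_a)
  pb <- persistent(traj_b)
  structure(list(present_a = pa, present_b = pb,
                 gained = setdiff(pb, pa), lost = setdiff(pa, pb),
                 persistence = persistence),
            class = "contact_diff")
}
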