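# Distance features, SVD projection, free-energy landscape, adjusted
# regression, contact bookkeeping.

test_that("distance features have the right shape and rigid invariance", {
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  f2 <- rbind(c(0, 0, 0), c(3.5, 0, 0), c(0, 5, 0))
  traj <- traj_from_frames(list(base, f2), toy_atoms(3))
  ft <- distance_features(traj)
  expect_equal(dim(ft), c(2L, 3L))
  # hand-computed distances (dist order: 1-2, 1-3, 2-3)
  expect_equal(ft[1, ], c(3, 4, 5), tolerance = 1e-12)
  expect_equal(ft[2, ], c(3.5, 5, sqrt(3.5^2 + 25)), tolerance = 1e-12)

  set.seed(2)
  Rg <- random_rotation()
  moved <- traj_from_frames(lapply(list(base, f2), function(m) {
    sweep(m %*% t(Rg), 2, c(5, 6, 7), `+`)
  }), toy_atoms(3))
  expect_equal(distance_features(moved), ft, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(distance_features(traj, selection = 1L),
               class = "invalid_spec_error")
})

test_that("svd projection centres, orders variance and reconstructs", {
  set.seed(8)
  n <- 40
  X <- cbind(rnorm(n, sd = 5)) %*% rbind(runif(6)) +
    matrix(rnorm(n * 6, sd = 0.01), n, 6)
  pr <- svd_project(X, k = 2)
  expect_true(all(diff(pr$explained) <= 1e-12))
  expect_gt(pr$explained[1], 0.99)
  # rank-1 data: second component explains (almost) nothing
  X1 <- cbind(1:10) %*% rbind(c(1, 2, 3))
  pr1 <- svd_project(X1, k = 2)
  expect_lt(pr1$explained[2], 1e-20)
  # centring
  Xc <- sweep(unclass(X), 2, pr$center)
  expect_lt(max(abs(colMeans(Xc))), 1e-10)
  # full-rank reconstruction from all components
  prf <- svd_project(X, k = 6)
  rec <- prf$scores %*% t(prf$loadings)
  expect_equal(rec, Xc, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("well-separated frame clusters split cleanly on PC1", {
  set.seed(12)
  a <- matrix(rnorm(20 * 5, mean = 0, sd = 0.1), 20, 5)
  b <- matrix(rnorm(20 * 5, mean = 4, sd = 0.1), 20, 5)
  pr <- svd_project(rbind(a, b))
  s1 <- pr$scores[1:20, 1]
  s2 <- pr$scores[21:40, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("the landscape floor is zero and shifts leave it unchanged", {
  set.seed(14)
  pts <- cbind(rnorm(400), rnorm(400))
  f1 <- fel(pts)
  occ <- f1$counts > 0
  expect_equal(min(f1$free_energy[occ]), 0)
  expect_true(all(f1$free_energy[!occ] >= max(f1$free_energy[occ])))
  f2 <- fel(sweep(pts, 2, c(100, -50), `+`))
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-12)
  expect_error(fel(pts, n_bins = 1), class = "invalid_spec_error")
})

test_that("degenerate landscapes yield a single funnel", {
  same <- matrix(1, 50, 2)
  f <- fel(same)
  expect_equal(sum(f$counts > 0), 1L)
  expect_equal(f$n_funnels, 1L)
  expect_equal(f$minima$free_energy, 0)

  set.seed(15)
  flat <- cbind(runif(4000), runif(4000))
  expect_equal(fel(flat)$n_funnels, 1L)
})

test_that("a three-Gaussian mixture yields exactly three funnels", {
  set.seed(16)
  centers <- rbind(c(0, 0), c(8, 0), c(4, 8))
  pts <- do.call(rbind, lapply(1:3, function(i) {
    cbind(rnorm(300, centers[i, 1], 1), rnorm(300, centers[i, 2], 1))
  }))
  expect_equal(fel(pts)$n_funnels, 3L)
})

test_that("funnel counts 1-4 are recovered across seeds at 6 sd separation", {
  for (k in 1:4) {
    centers <- cbind(6 * (0:(k - 1)), 6 * (0:(k - 1)) %% 2 * 6)
    hits <- vapply(1:20, function(s) {
      set.seed(1000 + 37 * s + k)
      pts <- do.call(rbind, lapply(seq_len(k), function(i) {
        cbind(rnorm(1000, centers[i, 1]), rnorm(1000, centers[i, 2]))
      }))
      fel(pts)$n_funnels
    }, numeric(1))
    expect_true(all(hits == k),
                info = sprintf("k=%d counts: %s", k,
                               paste(hits, collapse = ",")))
  }
})

test_that("regression recovers exact fits and the effective sample size", {
  x <- seq(0, 10, length.out = 50)
  out <- adjusted_regression(x, 2 * x, frame_dt = 0.1)
  expect_equal(out$slope, 2, tolerance = 1e-10)
  expect_equal(out$r, 1, tolerance = 1e-10)
  # 4500 frames at 0.1 ns with a 1-ns decorrelation interval
  set.seed(17)
  xl <- rnorm(4500)
  out2 <- adjusted_regression(xl, rnorm(4500), frame_dt = 0.1)
  expect_equal(out2$n_eff, 450)
  expect_error(adjusted_regression(rep(1, 10), rnorm(10), 0.1),
               class = "degenerate_predictor_error")
  # n_eff below 4: p undefined
  out3 <- adjusted_regression(rnorm(30), rnorm(30), frame_dt = 0.1)
  expect_false(out3$p_defined)
  expect_true(is.na(out3$p_adjusted))
})

test_that("with decorrelation = frame_dt the classical F-test is recovered", {
  set.seed(18)
  x <- rnorm(25)
  y <- 0.3 * x + rnorm(25)
  out <- adjusted_regression(x, y, frame_dt = 1, decorrelation = 1)
  sm <- summary(lm(y ~ x))
  expect_equal(out$f_statistic, unname(sm$fstatistic["value"]),
               tolerance = 1e-9)
  expect_equal(out$p_adjusted,
               unname(pf(sm$fstatistic["value"], 1, 23, lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("contact maps match an exhaustive oracle", {
  set.seed(19)
  n <- 12
  xyz <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
  st <- fil_structure(toy_atoms(n), xyz)
  got <- contact_map(st, cutoff = 4.5)$key
  d <- as.matrix(dist(xyz))
  oracle <- character(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i >= 3 && d[i, j] <= 4.5) {
        oracle <- c(oracle, paste("A", i, "A", j))
      }
    }
  }
  expect_setequal(got, oracle)

  # two residues 3 Angstrom apart on different chains
  at2 <- toy_atoms(2)
  at2$chain <- c("A", "B")
  st2 <- fil_structure(at2, rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(nrow(contact_map(st2, cutoff = 4.5)), 1L)
  expect_equal(nrow(contact_map(st2, cutoff = 2)), 0L)
})

test_that("contact persistence straddles the threshold correctly", {
  base <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(30, 0, 0),
                c(0, 0, 30))
  apart <- base
  apart[4, ] <- c(3, 1, 0)  # residue 4 contacts 1/2/3 in some frames
  n_frames <- 10
  make <- function(n_contact) {
    traj_from_frames(c(replicate(n_contact, apart, simplify = FALSE),
                       replicate(n_frames - n_contact, base,
                                 simplify = FALSE)), toy_atoms(5))
  }
  ident <- contact_diff(make(0), make(0))
  expect_length(ident$gained, 0)
  expect_length(ident$lost, 0)
  # 80% persistence in A, 60% in B: key "A 1 A 4" is lost at 0.7
  d <- contact_diff(make(8), make(6), cutoff = 4.5, persistence = 0.7)
  expect_true("A 1 A 4" %in% d$lost)
  expect_length(d$gained, 0)
  # broken everywhere in B by construction
  d2 <- contact_diff(make(10), make(0))
  expect_true("A 1 A 4" %in% d2$lost)
})
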