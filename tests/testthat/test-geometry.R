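# Superposition, rotation decomposition, distances, pitch/twist.

test_that("kabsch recovers identity and known rotations", {
  set.seed(1)
  ref <- matrix(rnorm(30), ncol = 3)
  fit <- kabsch(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)

  R25 <- rotation_about_axis(c(0.2, -0.5, 1), 25)
  mob <- ref %*% t(R25)
  fit2 <- kabsch(mob, ref)
  # fitting the rotated copy back recovers the inverse rotation
  expect_equal(fit2$rotation, t(R25), tolerance = 1e-8)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-8)
})

test_that("kabsch rmsd matches a brute-force rotational search", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), c(0, 0, 0, 0))
  distorted <- cbind(c(0, 1.1, 1.05, -0.1), c(-0.05, 0, 1.1, 0.9),
                     c(0.02, -0.03, 0.01, 0))
  got <- kabsch(distorted, square)$rmsd

  # independent oracle: minimise rmsd over explicit Euler rotations
  obj <- function(p) {
    R <- rotation_about_axis(c(1, 0, 0), p[1] * 180 / pi) %*%
      rotation_about_axis(c(0, 1, 0), p[2] * 180 / pi) %*%
      rotation_about_axis(c(0, 0, 1), p[3] * 180 / pi)
    a <- sweep(distorted, 2, colMeans(distorted)) %*% t(R)
    b <- sweep(square, 2, colMeans(square))
    sqrt(mean(rowSums((a - b)^2)))
  }
  best <- Inf
  for (s1 in seq(-pi, pi, length.out = 5)) {
    for (s2 in seq(-pi / 2, pi / 2, length.out = 4)) {
      for (s3 in seq(-pi, pi, length.out = 5)) {
        o <- optim(c(s1, s2, s3), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000))
        best <- min(best, o$value)
      }
    }
  }
  expect_equal(got, best, tolerance = 1e-6)
  expect_error(kabsch(square[1:2, ], square[1:2, ]),
               class = "insufficient_data_error")
  expect_error(kabsch(square, square[1:3, ]), class = "shape_error")
})

test_that("rmsd series is zero for static or rigidly moved frames", {
  ref <- fil3$xyz
  shifted <- sweep(ref, 2, c(5, 0, 0), `+`)
  set.seed(4)
  Rg <- random_rotation()
  rotated <- ref %*% t(Rg)
  traj <- traj_from_frames(list(ref, shifted, rotated), fil3$atoms)
  out <- rmsd_series(traj, fil3)
  expect_equal(out$rmsd, rep(0, 3), tolerance = 1e-8)
})

test_that("rmsd series matches the bio3d superposition oracle", {
  set.seed(11)
  frames <- lapply(1:4, function(i) {
    fil3$xyz + matrix(rnorm(length(fil3$xyz), sd = 0.5), ncol = 3)
  })
  traj <- traj_from_frames(frames, fil3$atoms)
  got <- rmsd_series(traj, fil3)$rmsd
  oracle <- vapply(frames, function(fr) {
    bio3d::rmsd(as.numeric(t(fil3$xyz)), as.numeric(t(fr)), fit = TRUE)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-3)  # bio3d prints 3 decimals
})

test_that("rmsf is zero for static ensembles and flags the noisy residue", {
  static <- traj_from_frames(list(fil3$xyz, fil3$xyz, fil3$xyz), fil3$atoms)
  expect_equal(rmsf(static)$rmsf, rep(0, 162), tolerance = 1e-10)
  expect_error(rmsf(traj_from_frames(list(fil3$xyz), fil3$atoms)),
               class = "insufficient_data_error")

  set.seed(7)
  frames <- lapply(1:30, function(i) {
    x <- fil3$xyz + matrix(rnorm(length(fil3$xyz), sd = 0.1), ncol = 3)
    x[25, ] <- fil3$xyz[25, ] + rnorm(3, sd = 2)
    x
  })
  noisy <- traj_from_frames(frames, fil3$atoms)
  out <- rmsf(noisy)
  expect_equal(which.max(out$rmsf), 25L)
})

test_that("rmsf matches hand computation on a pre-aligned toy", {
  # opposed radial displacements of atoms 1 and 2: zero net translation
  # and zero net torque, so the superposition stays the identity and the
  # hand-computed deviation about the mean is exact
  base <- rbind(c(10, 0, 0), c(-10, 0, 0), c(0, 10, 0), c(0, -10, 0))
  d <- c(-0.3, 0.1, 0.2)
  frames <- lapply(d, function(dx) {
    x <- base
    x[1, 1] <- x[1, 1] + dx
    x[2, 1] <- x[2, 1] - dx
    x
  })
  out <- rmsf(traj_from_frames(frames, toy_atoms(4)))
  expect_equal(out$rmsf[1], sqrt(mean((d - mean(d))^2)), tolerance = 1e-8)
  expect_equal(out$rmsf[2], sqrt(mean((d - mean(d))^2)), tolerance = 1e-8)
  expect_equal(out$rmsf[3:4], c(0, 0), tolerance = 1e-8)
})

test_that("delta rmsf flags strictly above the threshold", {
  a <- data.frame(index = 1:4, rmsf = c(1, 2, 3, 2))
  expect_equal(delta_rmsf(a, a)$delta, rep(0, 4))
  expect_false(any(delta_rmsf(a, a)$flag))
  b <- data.frame(index = 1:4, rmsf = c(1, 0.8, 2, 3.2))
  d <- delta_rmsf(a, b)
  expect_equal(d$delta, c(0, 1.2, 1, -1.2))
  expect_identical(d$flag, c(FALSE, TRUE, FALSE, TRUE))  # 1.0 is not > 1.0
  expect_error(delta_rmsf(a, data.frame(index = 2:5, rmsf = 1:4)),
               class = "invalid_spec_error")
})

test_that("the filament frame is orthonormal and matches construction", {
  ff <- filament_frame(fil3, mod3)
  expect_equal(ff$z, c(0, 0, 1), tolerance = 1e-10)
  expect_equal(ff$x, c(1, 0, 0), tolerance = 1e-10)
  expect_equal(unname(crossprod(ff$basis)), diag(3), tolerance = 1e-10)
  # remains orthonormal for arbitrarily rotated filaments
  set.seed(21)
  for (i in 1:5) {
    Rg <- random_rotation()
    fr <- fil_structure(fil3$atoms, fil3$xyz %*% t(Rg))
    ffr <- filament_frame(fr, mod3)
    expect_equal(unname(crossprod(ffr$basis)), diag(3), tolerance = 1e-10)
    expect_equal(ffr$z, as.numeric(Rg %*% c(0, 0, 1)), tolerance = 1e-10)
  }
})

test_that("compose/decompose round-trips over random angle triples", {
  set.seed(31)
  n <- 10000
  t1 <- runif(n, -179, 179)
  t2 <- runif(n, -85, 85)
  t3 <- runif(n, -179, 179)
  worst <- 0
  for (i in seq_len(n)) {
    R <- compose_zxy(t1[i], t2[i], t3[i])
    a <- decompose_zxy(R)
    worst <- max(worst, max(abs(c(a$theta1 - t1[i], a$theta2 - t2[i],
                                  a$theta3 - t3[i]))))
    if (i <= 100) {
      expect_equal(compose_zxy(a$theta1, a$theta2, a$theta3), R,
                   tolerance = 1e-8)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("interface rotations are recovered exactly without noise", {
  # identity pose
  sp0 <- trajectory_spec("custom", n_frames = 1,
                         clusters = list(conformer_cluster(c(0, 0, 0))),
                         noise_sd = 0, angle_sd = 0, closure_delta = 0,
                         seed = 1)
  g0 <- generate_trajectory(sp0)
  a0 <- decompose_interface_rotation(g0$trajectory, g0$model, "top")
  expect_equal(c(a0$theta1, a0$theta2, a0$theta3), c(0, 0, 0),
               tolerance = 1e-9)

  # pure twist
  spz <- trajectory_spec("custom", n_frames = 1,
                         clusters = list(conformer_cluster(c(10, 0, 0))),
                         noise_sd = 0, angle_sd = 0, closure_delta = 0,
                         seed = 1)
  gz <- generate_trajectory(spz)
  az <- decompose_interface_rotation(gz$trajectory, gz$model, "top")
  expect_equal(c(az$theta1, az$theta2, az$theta3), c(10, 0, 0),
               tolerance = 1e-6)

  # the reported GDP-state mean triple, imposed and recovered
  spg <- trajectory_spec("custom", n_frames = 1,
                         clusters = list(conformer_cluster(c(-24.7, 13.7, 3.8))),
                         noise_sd = 0, angle_sd = 0, closure_delta = 0,
                         seed = 1)
  gg <- generate_trajectory(spg)
  at <- decompose_interface_rotation(gg$trajectory, gg$model, "top")
  ab <- decompose_interface_rotation(gg$trajectory, gg$model, "bottom")
  expect_equal(c(at$theta1, at$theta2, at$theta3), c(-24.7, 13.7, 3.8),
               tolerance = 1e-6)
  expect_equal(c(ab$theta1, ab$theta2, ab$theta3), c(-24.7, 13.7, 3.8),
               tolerance = 1e-6)
})

test_that("angle recovery stays within a degree under atomic jitter", {
  sp <- trajectory_spec("custom", n_frames = 40,
                        clusters = list(conformer_cluster(c(-21.2, 2.8, 0.6))),
                        noise_sd = 0.3, angle_sd = 0, closure_delta = 0,
                        seed = 13)
  g <- generate_trajectory(sp)
  a <- decompose_interface_rotation(g$trajectory, g$model, "top")
  err <- abs(cbind(a$theta1 + 21.2, a$theta2 - 2.8, a$theta3 - 0.6))
  expect_lt(mean(err), 1)
})

test_that("inter-domain distances track imposed closure and resist rigid motion", {
  tpl30 <- subunit_template(domain_separation = 30)
  fil <- build_filament(tpl30, 3)
  mod <- template_model(tpl30, 3)
  selc <- select_atoms(fil, mod, "middle", "C")
  seln <- select_atoms(fil, mod, "middle", "N")
  axis <- colMeans(fil$xyz[seln, ]) - colMeans(fil$xyz[selc, ])
  axis <- axis / sqrt(sum(axis^2))
  closed <- fil$xyz
  closed[selc, ] <- sweep(closed[selc, ], 2, 3 * axis, `+`)
  set.seed(5)
  Rg <- random_rotation()
  moved <- sweep(fil$xyz %*% t(Rg), 2, c(3, -7, 2), `+`)
  traj <- traj_from_frames(list(fil$xyz, closed, moved), fil$atoms)
  d <- interdomain_distance(traj, mod, "middle")$distance
  expect_equal(d, c(30, 27, 30), tolerance = 1e-9)

  # oracle: direct centroid arithmetic on a noisy frame
  noisy <- fil$xyz + matrix(rnorm(length(fil$xyz), sd = 0.4), ncol = 3)
  tn <- traj_from_frames(list(noisy), fil$atoms)
  expect_equal(interdomain_distance(tn, mod, "middle")$distance,
               sqrt(sum((colMeans(noisy[seln, ]) -
                           colMeans(noisy[selc, ]))^2)),
               tolerance = 1e-12)
})

test_that("domain rotation angle recovers imposed C-domain rotations", {
  fil1 <- build_filament(tpl_default, 1)
  mod1 <- template_model(tpl_default, 1)
  expect_equal(domain_rotation_angle(fil1, fil1, mod1, "subunit"), 0,
               tolerance = 1e-5)  # acos round-off near trace 3
  selc <- select_atoms(fil1, mod1, "subunit", "C")
  cc <- colMeans(fil1$xyz[selc, ])
  spin <- function(deg, axis) {
    R <- rotation_about_axis(axis, deg)
    f2 <- fil1
    f2$xyz[selc, ] <- sweep(sweep(fil1$xyz[selc, ], 2, cc) %*% t(R), 2, cc,
                            `+`)
    f2
  }
  expect_equal(domain_rotation_angle(fil1, spin(19, c(1, 1, 0)), mod1,
                                     "subunit"), 19, tolerance = 1e-6)
  expect_equal(domain_rotation_angle(fil1, spin(90, c(0.3, -1, 2)), mod1,
                                     "subunit"), 90, tolerance = 1e-6)
})

test_that("pitch/twist conversion is exact in both conventions", {
  expect_equal(twist_pitch(4, 24, "pitch_to_twist", "full"), 60)
  # half convention: 24 nm pitch at 4 nm rise gives 30 degrees per subunit
  expect_equal(twist_pitch(4, 24, "pitch_to_twist", "half"), 30)
  tw <- twist_pitch(4, 150, "pitch_to_twist", "half")
  expect_equal(tw, 4.8, tolerance = 1e-12)
  # exact round trip
  p <- twist_pitch(4, tw, "twist_to_pitch", "half")
  expect_equal(p, 150, tolerance = 1e-12)
  expect_error(twist_pitch(4, 0, "twist_to_pitch"),
               class = "undefined_pitch_error")
})
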