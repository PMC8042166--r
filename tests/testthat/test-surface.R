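# Shrake-Rupley quadrature and buried interface area.

test_that("an isolated sphere reproduces its analytic area", {
  s <- sasa(matrix(0, 1, 3), radii = 1.9)
  analytic <- 4 * pi * 3.3^2
  expect_lt(abs(s$total - analytic) / analytic, 0.01)
  expect_equal(s$total, sum(s$atom_area), tolerance = 1e-6)
})

test_that("separated atoms are additive, overlapping ones match the cap formula", {
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sasa(far, radii = 1.9)$total, 2 * 4 * pi * 3.3^2,
               tolerance = 1e-6)
  for (d in c(2, 3.5, 5)) {
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
    got <- sasa(xyz, radii = 1.9)$total
    oracle <- two_sphere_area(3.3, 3.3, d)
    expect_lt(abs(got - oracle) / oracle, 0.02)
  }
  # unequal radii
  got <- sasa(rbind(c(0, 0, 0), c(3, 0, 0)), radii = c(1.9, 1.2))$total
  expect_lt(abs(got - two_sphere_area(3.3, 2.6, 3)) /
              two_sphere_area(3.3, 2.6, 3), 0.02)
})

test_that("quadrature converges: doubling the points changes little", {
  set.seed(3)
  xyz <- matrix(rnorm(45, sd = 3), ncol = 3)
  a <- sasa(xyz, radii = 1.9, n_points = 960)$total
  b <- sasa(xyz, radii = 1.9, n_points = 1920)$total
  expect_lt(abs(a - b) / a, 0.01)
})

test_that("sasa input validation catches missing or bad radii", {
  expect_error(sasa(matrix(0, 2, 3), radii = c(1.9, -1)),
               class = "invalid_spec_error")
  expect_error(sasa(matrix(0, 2, 3), radii = c(1.9, 1.9, 1.9)),
               class = "invalid_spec_error")
  expect_error(sasa(matrix(0, 1, 3), radii = 1.9, n_points = 8),
               class = "invalid_spec_error")
})

test_that("element radii resolve from atom names", {
  atoms <- toy_atoms(3)
  atoms$elety <- c("CA", "N", "OG1")
  st <- fil_structure(atoms, matrix(rnorm(9), 3))
  expect_equal(atom_radii(st), c(1.7, 1.55, 1.52))
  expect_equal(atom_radii(st, uniform = 2), rep(2, 3))
})

test_that("buried area follows the half-difference identity", {
  # far apart: no burial
  far <- build_filament(subunit_template(), 2)
  modf <- template_model(subunit_template(), 2)
  sel_top <- select_atoms(far, modf, "top")
  far$xyz[sel_top, 3] <- far$xyz[sel_top, 3] + 100
  expect_lt(abs(buried_sasa(far, modf, "bottom", "top")), 1)

  # (near-)coincident identical subunits: M12 -> M1, so buried -> M1 / 2
  # (a tiny offset keeps the pointwise quadrature well defined)
  tpl <- subunit_template()
  one <- build_filament(tpl, 1)
  dup_atoms <- rbind(one$atoms, transform(one$atoms, chain = "B"))
  dup_atoms$eleno <- seq_len(nrow(dup_atoms))
  dup <- fil_structure(dup_atoms, rbind(one$xyz, one$xyz + 0.01))
  modd <- filament_model(list(
    bottom = list(chain = "A", resno = c(1, 54), n_domain = c(1, 30),
                  c_domain = c(31, 54)),
    top = list(chain = "B", resno = c(1, 54), n_domain = c(1, 30),
               c_domain = c(31, 54))))
  m1 <- sasa(one$xyz, radii = 1.9)$total
  expect_equal(buried_sasa(dup, modd, "bottom", "top"), m1 / 2,
               tolerance = 0.01)

  # two single-bead "subunits": equals the analytic two-sphere oracle
  atoms2 <- toy_atoms(2)
  atoms2$chain <- c("A", "B")
  pair <- fil_structure(atoms2, rbind(c(0, 0, 0), c(4, 0, 0)))
  mod2 <- filament_model(list(
    bottom = list(chain = "A", resno = c(1, 1), n_domain = c(1, 1),
                  c_domain = integer(0)),
    top = list(chain = "B", resno = c(2, 2), n_domain = c(2, 2),
               c_domain = integer(0))))
  iso <- 2 * 4 * pi * 3.3^2
  oracle <- (iso - two_sphere_area(3.3, 3.3, 4)) / 2
  expect_equal(buried_sasa(pair, mod2, "bottom", "top"), oracle,
               tolerance = oracle * 0.02)
})

test_that("buried area is symmetric, rigid-motion invariant and monotone", {
  b0 <- buried_sasa(fil3, mod3, "middle", "top")
  expect_equal(buried_sasa(fil3, mod3, "top", "middle"), b0,
               tolerance = 1e-9)
  set.seed(9)
  Rg <- random_rotation()
  moved <- fil_structure(fil3$atoms,
                         sweep(fil3$xyz %*% t(Rg), 2, c(10, -4, 2), `+`))
  # the fixed quadrature lattice is orientation dependent at the sub-percent
  # level; rigid motion must not change the area beyond that
  expect_equal(buried_sasa(moved, mod3, "middle", "top"), b0,
               tolerance = 0.01)

  # non-increasing along a 0-20 Angstrom separation scan
  sel <- select_atoms(fil3, mod3, "top")
  axis <- colMeans(fil3$xyz[sel, ]) -
    colMeans(fil3$xyz[select_atoms(fil3, mod3, "middle"), ])
  axis <- axis / sqrt(sum(axis^2))
  vals <- vapply(seq(0, 20, by = 2), function(s) {
    f <- fil3
    f$xyz[sel, ] <- sweep(f$xyz[sel, ], 2, s * axis, `+`)
    buried_sasa(f, mod3, "middle", "top")
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-6))
})

test_that("interface series matches one-shot calls and tracks openings", {
  # static closed interface: constant series
  sp <- trajectory_spec("custom", n_frames = 3,
                        clusters = list(conformer_cluster(c(0, 0, 0))),
                        noise_sd = 0, angle_sd = 0, closure_delta = 0,
                        seed = 1)
  g <- generate_trajectory(sp)
  st <- interface_series(g$trajectory, g$model, "top")
  expect_equal(diff(range(st$series$buried_A2)), 0, tolerance = 1e-9)

  # imposed opening from frame 2 on: strictly lower afterwards
  open_cl <- conformer_cluster(c(0, 0, 0), open_interfaces = "top")
  closed_frames <- generate_trajectory(sp)$trajectory
  spo <- trajectory_spec("custom", n_frames = 2,
                         clusters = list(open_cl), noise_sd = 0,
                         angle_sd = 0, closure_delta = 0, seed = 1)
  go <- generate_trajectory(spo)
  mixed <- fil_trajectory(closed_frames$atoms,
                          rbind(closed_frames$coords[1:2, ],
                                go$trajectory$coords),
                          frame_dt = 0.5, reference = closed_frames$reference)
  ms <- interface_series(mixed, g$model, "top")$series$buried_A2
  expect_true(all(ms[3:4] < ms[1:2] - 100))

  # per-frame values equal one-shot buried_sasa calls
  one_shot <- vapply(1:2, function(f) {
    buried_sasa(frame_structure(mixed, f), g$model, "middle", "top")
  }, numeric(1))
  expect_equal(ms[1:2], one_shot, tolerance = 1e-9)
})
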