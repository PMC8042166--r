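# Shared fixtures and small independent oracles, built in code at test time.

tpl_default <- subunit_template()
fil3 <- build_filament(tpl_default, 3)
mod3 <- template_model(tpl_default, 3)

# Rodrigues rotation about a unit axis (independent of the package's
# compose/decompose path)
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# trajectory from a list of N x 3 frames
traj_from_frames <- function(frames, atoms, dt = 1) {
  fil_trajectory(atoms, do.call(rbind, lapply(frames, function(m) {
    as.numeric(t(m))
  })), frame_dt = dt)
}

# analytic accessible area of two spheres with extended radii ra, rb at
# centre distance d (isolated-cap formula)
two_sphere_area <- function(ra, rb, d) {
  if (d >= ra + rb) return(4 * pi * (ra^2 + rb^2))
  cap <- function(r1, r2) {
    h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
    2 * pi * r1 * max(0, h)
  }
  4 * pi * ra^2 - cap(ra, rb) + 4 * pi * rb^2 - cap(rb, ra)
}

# toy atom table for bare coordinate sets
toy_atoms <- function(n, chain = "A") {
  data.frame(eleno = seq_len(n), elety = "CA", resid = "GLY", chain = chain,
             resno = seq_len(n), o = 1, b = 0, stringsAsFactors = FALSE)
}
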