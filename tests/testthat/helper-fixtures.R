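# Fixture builders shared across the test files. Everything is generated in
# code; tests that need randomness set their own seed.

random_plane <- function(name = "axial", center = runif(3, -40, 40)) {
  R <- random_rotation()
  standard_plane(name, center, R[, 1], R[, 2])
}

random_triplet <- function(region = "ankle") {
  pose <- sample_pose(rot_deg = 45, trans_mm = 20)
  spec <- phantom_spec(oblique = region == "calcaneus")
  trip <- apply_rigid_to_triplet(canonical_triplet(spec), pose)
  plane_triplet(region, trip$planes)
}

# angle (degrees) between two directions, precise for tiny angles
dir_angle_deg <- function(a, b) {
  cr <- mprreg:::cross3(a, b)
  atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
}

# rotate a plane's frame about an arbitrary axis (axis-angle, degrees)
rotate_plane <- function(plane, axis, angle_deg, about_center = TRUE) {
  th <- angle_deg * pi / 180
  rot <- function(v) mprreg:::rotate_about_axis(v, axis, th)
  standard_plane(plane$name, plane$center, rot(plane$e_u), rot(plane$e_v))
}

# in-plane twist: rotate the frame about the plane's own normal
twist_plane <- function(plane, angle_deg) {
  rotate_plane(plane, plane_normal(plane), angle_deg)
}

# small low-resolution phantom used where rendering cost matters
tiny_phantom_spec <- function(...) {
  phantom_spec(shape = 32, spacing = 5, noise_sd = 0, ...)
}

# compactly supported smooth intensity field (sum of Gaussian blobs) for
# interpolation-equivalence checks: bounded curvature, air at the boundary
smooth_test_volume <- function(n = 64, sp = 2.5) {
  g <- volume_geometry(c(n, n, n), sp)
  ax <- (0:(n - 1) - (n - 1) / 2) * sp
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  v <- -1000 +
    2200 * exp(-((X - 5)^2 / (2 * 16^2) + Y^2 / (2 * 12^2) +
                   (Z + 10)^2 / (2 * 15^2))) +
    500 * exp(-((X + 15)^2 + (Y - 10)^2 + Z^2) / (2 * 10^2))
  list(volume = v, geom = g)
}
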