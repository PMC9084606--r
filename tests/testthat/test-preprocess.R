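# independent label oracle: plain homogeneous-matrix algebra
affine_label_oracle <- function(triplet, m, mirror) {
  A <- if (mirror) diag(c(-1, 1, 1, 1)) %*% solve(m) else solve(m)
  L <- A[1:3, 1:3]
  plane_triplet(triplet$region, lapply(triplet$planes, function(p) {
    un <- function(v) v / sqrt(sum(v^2))
    standard_plane(p$name, as.numeric(A %*% c(p$center, 1))[1:3],
                   un(as.numeric(L %*% p$e_u)), un(as.numeric(L %*% p$e_v)))
  }))
}

test_that("composed transform is the exact ordered product of its factors", {
  set.seed(501)
  R <- random_rotation(); t <- runif(3, -12, 12); s <- 1.03; cr <- 0.9
  ct <- composed_transform(R, t, s, cr)
  with(ct$components,
       expect_equal(ct$matrix, T_r %*% T_s %*% T_t %*% T_R))
  expect_equal(ct$components$T_R[1:3, 1:3], R)
  expect_equal(ct$components$T_t[1:3, 4], t)
  expect_equal(composed_transform()$matrix, diag(4))
})

test_that("augmentation sampling is reproducible and respects ranges", {
  cfg <- augmentation_config()
  set.seed(502); a1 <- sample_augmentation(cfg)
  set.seed(502); a2 <- sample_augmentation(cfg)
  expect_identical(a1$transform$matrix, a2$transform$matrix)
  expect_identical(a1$mirror, a2$mirror)
  expect_identical(a1$intensity_factor, a2$intensity_factor)
  set.seed(503)
  for (i in 1:50) {
    a <- sample_augmentation(cfg)
    expect_true(all(abs(a$params$angles) <= 45 * pi / 180))
    expect_true(a$params$scale >= 0.95 && a$params$scale <= 1.05)
    expect_true(all(abs(a$params$translation) <= 12))
    expect_true(a$intensity_factor >= 0.95 && a$intensity_factor <= 1.05)
    # inactive ops contribute identity factors
    if (!a$params$active[2]) expect_equal(a$params$scale, 1)
    if (!a$params$active[3]) expect_equal(a$params$translation, c(0, 0, 0))
  }
})

test_that("per-op activation frequency matches the configured probability", {
  set.seed(504)
  acts <- replicate(4000, sample_augmentation(augmentation_config())$params$active)
  expect_equal(unname(rowMeans(acts)), rep(0.5, 3), tolerance = 0.05)
})

test_that("resampling: constant volume, singular rejection, exact 90-degree permutation", {
  g <- volume_geometry(c(20, 20, 20), 2)
  vol <- array(42, c(20, 20, 20))
  out <- resample_volume(vol, g, composed_transform(), c(10, 10, 10))
  expect_true(all(out == 42))
  expect_error(resample_volume(vol, g, matrix(0, 4, 4), c(10, 10, 10)),
               "singular")
  set.seed(505)
  v <- array(rnorm(20^3), c(20, 20, 20))
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rot <- resample_volume(v, g, composed_transform(Rz90), c(20, 20, 20))
  n <- 20
  perm <- array(0, dim(v))
  for (i in 1:n) for (j in 1:n) perm[i, j, ] <- v[n + 1 - j, i, ]
  expect_equal(rot, perm, tolerance = 1e-12)
})

test_that("mirror resampling is an exact x-flip for the identity transform", {
  set.seed(506)
  g <- volume_geometry(c(16, 16, 16), 2)
  v <- array(rnorm(16^3), c(16, 16, 16))
  m <- resample_volume(v, g, composed_transform(), c(16, 16, 16),
                       mirror = TRUE)
  expect_equal(m, v[16:1, , ], tolerance = 1e-12)
})

test_that("label transform: identity, translation pull-back sign, mirror algebra", {
  set.seed(507)
  trip <- random_triplet("ankle")
  same <- transform_labels(trip, composed_transform(), mirror = FALSE)
  expect_equal(same$planes[[1]]$center, trip$planes[[1]]$center)
  # translation-only T_m shifts content and labels by minus the shift
  u <- c(5, 0, 0)
  moved <- transform_labels(trip, composed_transform(translation = u))
  for (j in 1:3) {
    expect_equal(moved$planes[[j]]$center, trip$planes[[j]]$center - u)
    expect_equal(moved$planes[[j]]$e_u, trip$planes[[j]]$e_u)
  }
  # mirror of the canonical axial plane: e_u x-component negated, frame
  # still orthonormal with det +1 (normal re-derived, handedness flip)
  ax <- standard_plane("axial", c(2, 0, 0), c(1, 0, 0), c(0, 1, 0))
  tm <- plane_triplet("ankle", list(ax,
    standard_plane("coronal", c(0, 0, 0), c(-1, 0, 0), c(0, 0, 1)),
    standard_plane("sagittal", c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))))
  mir <- transform_labels(tm, composed_transform(), mirror = TRUE)
  expect_equal(mir$planes[[1]]$e_u, c(-1, 0, 0))
  expect_equal(mir$planes[[1]]$center, c(-2, 0, 0))
  R <- cbind(mir$planes[[1]]$e_u, mir$planes[[1]]$e_v,
             plane_normal(mir$planes[[1]]))
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("labels stay consistent with the volume for sampled augmentations", {
  set.seed(508)
  spec <- tiny_phantom_spec()
  pose <- sample_pose(30, 10)
  ph <- render_phantom(spec, pose)
  for (i in 1:25) {
    aug <- sample_augmentation(augmentation_config())
    got <- transform_labels(ph$triplet, aug$transform, aug$mirror)
    want <- affine_label_oracle(ph$triplet, aug$transform$matrix, aug$mirror)
    expect_lt(score_value(plane_score(got, want)), 1e-6)
  }
})

test_that("composed resampling matches the sequential four-pass pipeline", {
  set.seed(509)
  # smooth, compactly supported field: bounded curvature so the comparison
  # measures interpolation error, air at the boundary so intermediate-pass
  # clipping is invisible
  sm <- smooth_test_volume()
  g <- sm$geom
  R <- mprreg:::rot_z(0.3) %*% mprreg:::rot_x(-0.2)
  ct <- composed_transform(R, c(4, -6, 3), 1.04, 1)
  one <- resample_volume(sm$volume, g, ct, c(32, 32, 32))
  # sequential pulls compose left to right: pulling first through T_s and
  # then through T_t samples vol(T_s T_t p), so the leftmost factor of the
  # product is applied first and T_R last (with the final subsampling)
  seqv <- resample_volume(sm$volume, g, ct$components$T_s, g$shape)
  seqv <- resample_volume(seqv, g, ct$components$T_t, g$shape)
  seqv <- resample_volume(seqv, g, ct$components$T_R, c(32, 32, 32))
  dyn <- diff(range(sm$volume))
  expect_lt(max(abs(one - seqv)), 0.02 * dyn)
  # on an exactly trilinear (affine) field the two pipelines agree to
  # machine precision away from the fill region
  vlin <- array(0, c(16, 16, 16))
  axl <- (0:15 - 7.5) * 10
  for (k in 1:16) vlin[, , k] <- outer(axl, axl, function(x, y)
    2 + 0.03 * x - 0.02 * y) + 0.011 * axl[k]
  gl <- volume_geometry(c(16, 16, 16), 10)
  ct2 <- composed_transform(mprreg:::rot_z(0.2), c(3, -2, 1), 1.02, 1)
  a <- resample_volume(vlin, gl, ct2, c(16, 16, 16), fill = NA)
  b <- resample_volume(vlin, gl, ct2$components$T_s, gl$shape, fill = NA)
  b <- resample_volume(b, gl, ct2$components$T_t, gl$shape, fill = NA)
  b <- resample_volume(b, gl, ct2$components$T_R, c(16, 16, 16), fill = NA)
  expect_lt(max(abs(a - b), na.rm = TRUE), 1e-10)
})

test_that("intensity windowing matches its closed forms and symmetry", {
  cfg <- intensity_window_config()
  expect_equal(cfg$g, log(49) / 0.4, tolerance = 1e-12)
  # midpoint of the rescaled range maps to 1/2 (765 HU shifted = 1275)
  mid_hu <- (510 + 2040) / 2 - 1000
  expect_equal(as.numeric(intensity_normalize(mid_hu, cfg)), 0.5,
               tolerance = 1e-12)
  expect_equal(as.numeric(intensity_normalize(-1000, cfg)),
               1 / (1 + exp(0.5 * cfg$g)), tolerance = 1e-12)
  expect_equal(as.numeric(intensity_normalize(3000, cfg)),
               1 / (1 + exp(-0.5 * cfg$g)), tolerance = 1e-12)
  expect_equal(as.numeric(intensity_normalize(-1000, cfg) +
                            intensity_normalize(3000, cfg)), 1,
               tolerance = 1e-12)
  # monotone over a dense grid, strictly inside (0, 1)
  hu <- seq(-2000, 4000, by = 10)
  w <- as.numeric(intensity_normalize(hu, cfg))
  expect_true(all(diff(w) >= 0))
  expect_true(all(w > 0 & w < 1))
  # the augmentation factor rescales before clipping
  expect_equal(as.numeric(intensity_normalize(275, cfg, f = 1.05)),
               as.numeric(intensity_normalize(1.05 * 1275 - 1000, cfg, f = 1)),
               tolerance = 1e-12)
})
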