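# Synthetic phantom generator: determinism, geometry truth, noise.

test_that("identical seeds give identical scenes, meshes and volumes", {
  s1 <- phantom_scene(n_teeth = 2, seed = 7)
  s2 <- phantom_scene(n_teeth = 2, seed = 7)
  expect_equal(s1$modality$R, s2$modality$R)
  expect_equal(s1$teeth[[1]]$a, s2$teeth[[1]]$a)
  m1 <- sample_laser_mesh(s1, pitch = 0.2)
  m2 <- sample_laser_mesh(s2, pitch = 0.2)
  expect_identical(m1$mesh$vertices, m2$mesh$vertices)
  v1 <- voxelize_ct(s1, voxel = 0.4)
  v2 <- voxelize_ct(s2, voxel = 0.4)
  expect_identical(v1$volume$intensity, v2$volume$intensity)
  s3 <- phantom_scene(n_teeth = 2, seed = 8)
  expect_false(isTRUE(all.equal(s1$modality$R, s3$modality$R)))
})

test_that("phantom RNG is private: the session RNG state is untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(phantom_scene(n_teeth = 2, seed = 99))
  invisible(sample_laser_mesh(phantom_scene(seed = 1), pitch = 0.3))
  expect_identical(.Random.seed, before)
})

test_that("laser mesh vertices lie on the analytic surface (no jitter)", {
  sc <- phantom_scene(n_teeth = 1, seed = 3)
  lm <- sample_laser_mesh(sc, pitch = 0.15, jitter_sd = 0)
  sh <- toothfusion:::.scene_height(sc, lm$mesh$vertices[, 1],
                                    lm$mesh$vertices[, 2])
  expect_lt(max(abs(lm$mesh$vertices[, 3] - sh$z)), 1e-12)
  # labels: faces above the cervix carry the generating tooth id
  expect_true(all(lm$labels %in% c(0L, 1L)))
  expect_gt(sum(lm$labels == 1L), 0)
  expect_error(sample_laser_mesh(sc, pitch = 10), "pitch larger")
})

test_that("groove edges between two teeth exceed the intra-crown median H", {
  sc <- phantom_scene(n_teeth = 2, seed = 5)
  lm <- sample_laser_mesh(sc, pitch = 0.1)
  hf <- compute_height_field(lm$mesh)
  ef <- hf$edge_faces
  groove <- lm$labels[ef[, 1]] != lm$labels[ef[, 2]] &
    lm$labels[ef[, 1]] > 0 | lm$labels[ef[, 2]] > 0
  groove <- which(lm$labels[ef[, 1]] != lm$labels[ef[, 2]])
  intra <- which(lm$labels[ef[, 1]] == 1L & lm$labels[ef[, 2]] == 1L)
  expect_gt(stats::median(hf$H[groove]), stats::median(hf$H[intra]))
})

test_that("noiseless voxelization thresholds back to exact occupancy", {
  sc <- phantom_scene(n_teeth = 1, seed = 2)
  vx <- voxelize_ct(sc, voxel = 0.3, noise_sd = 0, blur_sigma = 0)
  expect_identical(unname(vx$volume$intensity > 500),
                   unname(vx$labels > 0L))
  # fixed seed -> bit-identical noise
  a <- voxelize_ct(sc, voxel = 0.4)
  b <- voxelize_ct(sc, voxel = 0.4)
  expect_identical(a$volume$intensity, b$volume$intensity)
})

test_that("voxelized sphere-like volume matches the analytic solid volume", {
  # use a single tooth and compare voxel count to a fine analytic estimate
  sc <- phantom_scene(n_teeth = 1, seed = 4, modality_rotation_deg = 0,
                      modality_translation_mm = 0)
  vx <- voxelize_ct(sc, voxel = 0.125, noise_sd = 0, blur_sigma = 0)
  vol_vox <- sum(vx$labels > 0) * 0.125^3
  # analytic volume by fine midpoint integration in the laser frame
  s <- sc$teeth[[1]]
  h <- 0.05
  xs <- seq(s$center[1] - s$a - s$bulge, s$center[1] + s$a + s$bulge, by = h)
  ys <- seq(s$center[2] - s$b - s$bulge, s$center[2] + s$b + s$bulge, by = h)
  zs <- seq(-s$lr, s$hc, by = h)
  acc <- 0
  for (z in zs) {
    g <- expand.grid(xs, ys)
    acc <- acc + sum(tooth_inside(s, g[, 1], g[, 2], rep(z, nrow(g)))) * h^3
  }
  expect_lt(abs(vol_vox / acc - 1), 0.02)
})

test_that("ground-truth transform round-trips and seeds are well placed", {
  sc <- phantom_scene(n_teeth = 3, seed = 6)
  gt <- scene_ground_truth(sc)
  comp <- compose_transform(gt$modality_transform, gt$inverse_transform)
  expect_lt(rotation_angle(comp), 1e-12)
  expect_lt(max(abs(comp$t)), 1e-12)
  expect_equal(gt$tooth_ids, 1:3)
  # laser seeds sit on the crown tips
  lm <- sample_laser_mesh(sc, pitch = 0.15)
  lab <- watershed_segment(lm$mesh, gt$laser_seeds)
  expect_equal(sort(unique(as.integer(lab[lab != 0]))), 1:3)
  # ct seeds land inside their own tooth in the volume
  vx <- voxelize_ct(sc, voxel = 0.25)
  cs <- phantom_ct_seeds(sc, vx$volume)
  for (i in 1:3) {
    lab_at <- vx$labels[round(cs$seeds$x[i]), round(cs$seeds$y[i]),
                        cs$start_slice]
    expect_equal(lab_at, i)
  }
})

test_that("a dense sampling of the true surface has zero self-distance", {
  sc <- phantom_scene(n_teeth = 1, seed = 9)
  m <- true_crown_mesh(sc, 1, pitch = 0.2)
  expect_equal(average_distance(m, m)$mean, 0, tolerance = 1e-12)
})
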