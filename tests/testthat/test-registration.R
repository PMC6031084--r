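# Plane sectioning, PCA coarse registration, quaternion ICP.

crown_cloud <- function(n = 400) {
  # anisotropic crown-like cloud with distinct eigenvalues
  sc <- phantom_scene(n_teeth = 1, seed = 3)
  m <- true_crown_mesh(sc, 1, pitch = 0.2)
  P <- m$vertices
  P[round(seq(1, nrow(P), length.out = n)), ]
}

test_that("sectioning a sphere at the equator yields a hemisphere", {
  m <- sphere_mesh(2000, r = 5)
  hemi <- section_crown(m, c(0, 0, 0), c(0, 0, 1))
  expect_true(all(hemi$vertices[, 3] >= -1e-6))
  expect_lt(abs(mesh_surface_area(hemi) / (2 * pi * 25) - 1), 0.02)
  # the open boundary lies on the plane
  top <- mesh_topology(hemi)
  expect_gt(top$n_boundary_edges, 0)
  F <- hemi$faces
  nv <- nrow(hemi$vertices)
  ea <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- (pmin(ea[, 1], ea[, 2]) - 1) * nv + pmax(ea[, 1], ea[, 2])
  bnd <- names(which(table(key) == 1))
  bverts <- unique(as.vector(ea[key %in% bnd, ]))
  expect_lt(max(abs(hemi$vertices[bverts, 3])), 1e-6)
})

test_that("sectioning below the mesh is the identity; above is an error", {
  m <- sphere_mesh(300, r = 2)
  same <- section_crown(m, c(0, 0, -5), c(0, 0, 1))
  expect_equal(nrow(same$faces), nrow(m$faces))
  expect_error(section_crown(m, c(0, 0, 5), c(0, 0, 1)), "no mesh")
})

test_that("PCA frame invariants and degenerate detection", {
  P <- crown_cloud()
  f <- pca_frame(P)
  expect_lt(max(abs(crossprod(f$eigenvectors) - diag(3))), 1e-9)
  expect_equal(det(f$eigenvectors), 1, tolerance = 1e-9)
  expect_true(all(diff(f$eigenvalues) <= 0))
  # coplanar points: rank deficiency names axis 3
  flat <- cbind(matrix(rnorm(60), ncol = 2), 0)
  expect_error(pca_frame(flat), "axis 3")
  # cylinder: two equal eigenvalues -> ambiguous
  a <- seq(0, 2 * pi, length.out = 41)[-41]
  cyl <- cbind(rep(cos(a), 5), rep(sin(a), 5), rep(seq(-2, 2, 1), each = 40))
  expect_error(pca_frame(cyl), "ambiguous")
})

test_that("self-registration is the identity", {
  P <- crown_cloud()
  tr <- pca_coarse_register(P, P)
  expect_lt(max(abs(tr$R - diag(3))), 1e-9)
  expect_lt(max(abs(tr$t)), 1e-9)
  icp <- icp_fine_register(P, P)
  expect_lt(icp$E_C, 1e-20)
  expect_true(icp$converged)
  expect_lt(max(abs(icp$transform$R - diag(3))), 1e-9)
})

test_that("PCA coarse registration undoes a known rigid transform", {
  P <- crown_cloud()
  R0 <- rotation_about(c(1, -2, 0.5), 18)
  t0 <- c(1.5, -2, 0.7)
  moved <- apply_transform(P, rigid_transform(R0, t0))
  rec <- pca_coarse_register(moved, P)
  comp <- compose_transform(rec, rigid_transform(R0, t0))
  expect_lt(rotation_angle(comp), 1e-5)
  expect_lt(sqrt(sum(comp$t^2)), 1e-5)
})

test_that("ICP recovers a pure translation to machine precision", {
  P <- crown_cloud()
  t0 <- c(0.5, -0.3, 0.2)
  moved <- sweep(P, 2, -t0)
  icp <- icp_fine_register(moved, P, E_th = 1e-10)
  expect_lt(icp$E_C, 1e-10)
  expect_lt(max(abs(icp$transform$t + t0)), 1e-6)
})

test_that("coarse+fine recovers rotation with subsampling", {
  P <- crown_cloud(900)
  R0 <- rotation_about(c(0, 0, 1), 10)
  moved <- apply_transform(P, rigid_transform(R0, c(0, 0, 0)))
  sub <- moved[seq(1, nrow(moved), by = 5), ]   # 20% noise-free subsample
  coarse <- pca_coarse_register(sub, P)
  fine <- icp_fine_register(apply_transform(sub, coarse), P, E_th = 1e-12,
                            max_iter = 200)
  tot <- compose_transform(fine$transform, coarse)
  comp <- compose_transform(tot, rigid_transform(R0, c(0, 0, 0)))
  expect_lt(rotation_angle(comp), 0.1)
  expect_lt(sqrt(sum(comp$t^2)), 0.01)
})

test_that("E_C trace is non-increasing and M constant", {
  P <- crown_cloud()
  moved <- apply_transform(P, rigid_transform(rotation_about(c(1, 1, 0), 12),
                                              c(0.4, 0.1, -0.6)))
  icp <- icp_fine_register(moved, P, E_th = 0, max_iter = 40)
  expect_true(all(diff(icp$trace$E_C) <= 1e-12))
  expect_true(all(icp$trace$M == nrow(P)))
  expect_false(icp$converged)   # E_th = 0 unreachable: flag, not error
})

test_that("applied transforms are rigid: pairwise distances preserved", {
  P <- crown_cloud(120)
  moved <- apply_transform(P, rigid_transform(rotation_about(c(2, 1, 1), 25),
                                              c(1, 2, 3)))
  icp <- icp_fine_register(moved, P, max_iter = 20)
  out <- apply_transform(moved, icp$transform)
  expect_equal(as.numeric(dist(out)), as.numeric(dist(moved)),
               tolerance = 1e-9)
})

test_that("transform JSON round-trips", {
  tr <- rigid_transform(rotation_about(c(1, 2, 3), 33), c(-1, 2, 0.5))
  p <- tempfile(fileext = ".json")
  write_transform_json(tr, p)
  tr2 <- read_transform_json(p)
  expect_equal(tr2$R, tr$R, tolerance = 1e-12)
  expect_equal(tr2$t, tr$t, tolerance = 1e-12)
})

test_that("register_crowns on an identical pair is near-identity", {
  sc <- phantom_scene(n_teeth = 1, seed = 5)
  crown <- true_crown_mesh(sc, 1, pitch = 0.15)
  tooth <- crown   # the "CT tooth" is the crown itself
  reg <- register_crowns(tooth, crown, plane = list(point = c(0, 0, -10),
                                                    normal = c(0, 0, 1)),
                         max_points = 1500)
  expect_lt(rotation_angle(reg$transform), 0.5)
  expect_lt(sqrt(sum(reg$transform$t^2)), 0.05)
})
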