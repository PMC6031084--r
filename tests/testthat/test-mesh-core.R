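# Mesh container, STL I/O, areas, adjacency, curvature score.

cube_soup <- function() {
  # 12 faces x 3 duplicated corner vertices (raw STL-style soup)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tri <- rbind(
    c(1, 3, 4), c(1, 4, 2),     # z = 0
    c(5, 6, 8), c(5, 8, 7),     # z = 1
    c(1, 2, 6), c(1, 6, 5),     # y = 0
    c(3, 7, 8), c(3, 8, 4),     # y = 1
    c(1, 5, 7), c(1, 7, 3),     # x = 0
    c(2, 4, 8), c(2, 8, 6))     # x = 1
  V <- corners[t(tri), , drop = FALSE]
  F <- matrix(seq_len(36), ncol = 3, byrow = TRUE)
  list(V = V, F = F)
}

test_that("welding collapses a duplicated-corner cube to 8 vertices, 12 faces", {
  s <- cube_soup()
  m <- tooth_mesh(s$V, s$F, weld = TRUE, weld_tol = 1e-6)
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)
  top <- mesh_topology(m)
  expect_true(top$closed)
  expect_equal(top$euler, 2L)
  expect_equal(abs(mesh_volume(m)), 1, tolerance = 1e-12)
})

test_that("single-triangle ASCII STL reads as 3 vertices / 1 face", {
  p <- tempfile(fileext = ".stl")
  writeLines(c(
    "solid tri",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid tri"), p)
  m <- read_stl(p)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_equal(facet_area(m, 1), 0.5)
})

test_that("STL round-trips coordinates in both dialects", {
  s <- cube_soup()
  m <- tooth_mesh(s$V + 0.123456, s$F)
  for (bin in c(TRUE, FALSE)) {
    p <- tempfile(fileext = ".stl")
    write_stl(m, p, binary = bin)
    m2 <- read_stl(p)
    expect_equal(nrow(m2$vertices), nrow(m$vertices))
    nn <- RANN::nn2(m2$vertices, m$vertices, k = 1)
    expect_lt(max(nn$nn.dists), 1e-6)
    expect_equal(mesh_surface_area(m2), mesh_surface_area(m),
                 tolerance = 1e-6)
  }
})

test_that("malformed STL errors name the offending location", {
  p <- tempfile(fileext = ".stl")
  writeLines(c("solid bad", "  vertex 0 0 0", "  vertex 1 0 0",
               "endsolid"), p)
  expect_error(read_stl(p), "multiple of 3")
  p2 <- tempfile(fileext = ".stl")
  file.create(p2)
  expect_error(read_stl(p2), "empty")
})

test_that("facet areas match closed forms and Heron's formula", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(2, 0, 1), c(0, 2, 1), c(-2, 0, 1))
  F <- rbind(c(1, 2, 3), c(4, 5, 6))
  m <- tooth_mesh(V, F, weld = FALSE, orient = FALSE)
  expect_equal(facet_area(m, 1), 0.5)
  # equilateral, side 2: sqrt(3)
  Ve <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0))
  me <- tooth_mesh(Ve, matrix(1:3, 1), weld = FALSE, orient = FALSE)
  expect_equal(facet_area(me, 1), sqrt(3), tolerance = 1e-12)
  # random triangles against Heron
  set.seed(11)
  for (i in 1:20) {
    Vr <- matrix(rnorm(9), 3)
    mr <- tooth_mesh(Vr, matrix(1:3, 1), weld = FALSE, orient = FALSE)
    e <- c(sqrt(sum((Vr[1, ] - Vr[2, ])^2)),
           sqrt(sum((Vr[2, ] - Vr[3, ])^2)),
           sqrt(sum((Vr[3, ] - Vr[1, ])^2)))
    s <- sum(e) / 2
    expect_equal(facet_area(mr, 1), sqrt(s * prod(s - e)), tolerance = 1e-9)
  }
})

test_that("total surface area is invariant under rigid motion", {
  m <- sphere_mesh(300, r = 2)
  tr <- rigid_transform(rotation_about(c(1, 2, 3), 37), c(4, -5, 6))
  m2 <- apply_transform(m, tr)
  expect_equal(mesh_surface_area(m2), mesh_surface_area(m),
               tolerance = 1e-9)
})

test_that("adjacency is symmetric with 2 faces per interior edge", {
  s <- cube_soup()
  m <- tooth_mesh(s$V, s$F)
  adj <- facet_adjacency(m)
  expect_true(all(!is.na(adj$edge_faces)))   # closed: every edge interior
  for (f in seq_len(nrow(m$faces)))
    for (g in adj$neighbors[[f]])
      expect_true(f %in% adj$neighbors[[g]])
})

test_that("facet pair curvature: coplanar zero, concavity ranking, symmetry", {
  fold <- function(deg) {
    # two faces sharing edge y in [0,1] at x=0; second tilted by deg
    # (positive deg folds upward into a concave valley)
    a <- deg * pi / 180
    V <- rbind(c(-1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0),
               c(cos(a), 0, sin(a)), c(cos(a), 1, sin(a)))
    F <- rbind(c(1, 2, 3), c(2, 5, 3))
    tooth_mesh(V, F, weld = FALSE, orient = FALSE)
  }
  mf <- fold(0)
  expect_equal(facet_pair_curvature(mf, 1, 2), 0, tolerance = 1e-12)
  c90 <- facet_pair_curvature(fold(90), 1, 2)    # fold by 90 deg, concave
  c45 <- facet_pair_curvature(fold(45), 1, 2)
  expect_gt(c90, c45)
  expect_equal(c90, 0.5, tolerance = 1e-12)
  expect_equal(facet_pair_curvature(fold(60), 1, 2),
               facet_pair_curvature(fold(60), 2, 1))
  # convex folds attenuate by convex_frac
  cc <- facet_pair_curvature(fold(-90), 1, 2, convex_frac = 0.2)
  expect_equal(cc, 0.2 * 0.5, tolerance = 1e-12)
  expect_error(facet_pair_curvature(mf, 1, 1), "share an edge")
  # monotone over sampled concave angles
  angs <- seq(10, 170, by = 20)
  vals <- vapply(angs, function(a) facet_pair_curvature(fold(a), 1, 2),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})
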