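# Directed average distance and error reports.

test_that("AD of a mesh to itself is zero; parallel planes give the offset", {
  m <- sphere_mesh(300, r = 2)
  expect_equal(average_distance(m, m)$mean, 0, tolerance = 1e-12)
  sq <- function(z) {
    V <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), z)
    tooth_mesh(V, rbind(c(1, 2, 3), c(1, 3, 4)), weld = FALSE,
               orient = FALSE)
  }
  ad <- average_distance(sq(0.25), sq(0))
  expect_equal(ad$mean, 0.25, tolerance = 1e-9)
  expect_equal(ad$max, 0.25, tolerance = 1e-9)
})

test_that("per-vertex distances equal the brute-force point-to-triangle oracle", {
  set.seed(41)
  V <- matrix(rnorm(18), ncol = 3)
  Ft <- rbind(c(1, 2, 3), c(4, 5, 6))
  target <- tooth_mesh(V, Ft, weld = FALSE, orient = FALSE)
  src <- matrix(rnorm(60), ncol = 3)
  srcm <- tooth_mesh(rbind(src, src + 10), # faces irrelevant: use vertices
                     matrix(rep(seq_len(nrow(src)), 3)[1:3], 1),
                     weld = FALSE, orient = FALSE)
  d <- toothfusion:::.point_mesh_distance_cpp(src, target$vertices,
                                              target$faces)$distance
  for (i in seq_len(nrow(src))) {
    ref <- min(bf_point_tri_dist(src[i, ], V[1, ], V[2, ], V[3, ]),
               bf_point_tri_dist(src[i, ], V[4, ], V[5, ], V[6, ]))
    expect_equal(d[i], ref, tolerance = 1e-10)
  }
})

test_that("triangle-inclusive distance never exceeds vertex-to-vertex distance", {
  set.seed(43)
  src <- sphere_mesh(120, r = 1.5)
  tgt <- sphere_mesh(150, r = 1.3)
  d <- average_distance(src, tgt)$distance
  dv <- RANN::nn2(tgt$vertices, src$vertices, k = 1)$nn.dists[, 1]
  expect_true(all(d <= dv + 1e-12))
})

test_that("AD is invariant under a common rigid transform", {
  src <- sphere_mesh(150, r = 2)
  tgt <- sphere_mesh(220, r = 1.8)
  ad0 <- average_distance(src, tgt)$mean
  tr <- rigid_transform(rotation_about(c(3, 1, 2), 41), c(5, -2, 1))
  ad1 <- average_distance(apply_transform(src, tr),
                          apply_transform(tgt, tr))$mean
  expect_equal(ad1, ad0, tolerance = 1e-9)
})

test_that("error map summary is self-consistent and exports correctly", {
  src <- sphere_mesh(200, r = 2.1)
  tgt <- sphere_mesh(200, r = 2)
  em <- average_distance(src, tgt)
  expect_equal(em$mean, mean(em$distance), tolerance = 1e-12)
  expect_true(all(em$distance >= 0))
  expect_equal(sum(em$counts), em$n)
  dir <- tempfile()
  dir.create(dir)
  files <- export_error_report(em, file.path(dir, "reg"))
  expect_true(all(file.exists(files)))
  d <- utils::read.csv(files[1])
  expect_equal(nrow(d), em$n)
  js <- jsonlite::fromJSON(files[2])
  expect_equal(js$mean_mm, mean(d$distance_mm), tolerance = 1e-12)
  expect_error(export_error_report(em, file.path(dir, "no/such/dir/x")),
               "directory")
})

test_that("symmetric variant averages the two directions", {
  a <- sphere_mesh(150, r = 2)
  b <- sphere_mesh(150, r = 1.5)
  em <- average_distance(a, b, symmetric = TRUE)
  rev <- average_distance(b, a)
  expect_equal(em$symmetric_mean, (em$mean + rev$mean) / 2,
               tolerance = 1e-12)
})
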