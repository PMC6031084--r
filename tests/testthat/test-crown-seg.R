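# Height function, pre-segmentation, watershed.

test_that("height field matches per-pair re-evaluation of the formula", {
  set.seed(21)
  m <- two_bump_mesh(pitch = 0.5)$mesh
  w <- 0.16
  adj <- facet_adjacency(m)
  hf <- compute_height_field(m, w = w)
  areas <- facet_area(m)
  # independent scalar evaluation per ordered pair
  for (k in sample(nrow(hf$edge_faces), 50)) {
    t1 <- hf$edge_faces[k, 1]
    t2 <- hf$edge_faces[k, 2]
    C <- facet_pair_curvature(m, t1, t2, adjacency = adj)
    for (ord in list(c(t1, t2), c(t2, t1))) {
      nb <- c(ord[1], adj$neighbors[[ord[1]]])
      A <- (areas[ord[1]] + areas[ord[2]]) / max(areas[nb])
      Href <- w * A + (1 - w) * C
      got <- if (ord[1] == t1) hf$H12[k] else hf$H21[k]
      expect_equal(got, Href, tolerance = 1e-12)
    }
    expect_equal(hf$H[k], max(hf$H12[k], hf$H21[k]), tolerance = 1e-15)
  }
})

test_that("flat equal-area mesh gives H = 2w + 0 everywhere; w = 0 is pure curvature", {
  # flat plane grid: all faces congruent right triangles, C = 0
  xs <- seq(0, 2, by = 0.5)
  nx <- length(xs)
  V <- cbind(rep(xs, nx), rep(xs, each = nx), 0)
  i <- rep(seq_len(nx - 1), nx - 1)
  j <- rep(seq_len(nx - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  F <- rbind(cbind(v00, v00 + 1L, v00 + nx + 1L),
             cbind(v00, v00 + nx + 1L, v00 + nx))
  m <- tooth_mesh(V, F, weld = FALSE, orient = FALSE)
  hf <- compute_height_field(m, w = 0.16)
  expect_true(all(abs(hf$H - 0.32) < 1e-12))
  bump <- two_bump_mesh(pitch = 0.4)$mesh
  hf0 <- compute_height_field(bump, w = 0)
  expect_equal(as.numeric(hf0$H12), as.numeric(hf0$C), tolerance = 1e-15)
})

test_that("raising w raises H monotonically at fixed curvature", {
  m <- two_bump_mesh(pitch = 0.4)$mesh
  h1 <- compute_height_field(m, w = 0.1)
  h2 <- compute_height_field(m, w = 0.3)
  delta <- h2$H12 - h1$H12
  A <- (h1$H12 - (1 - 0.1) * h1$C) / 0.1
  expect_true(all(delta[A > h1$C] > 0))
  expect_true(all(delta[A < h1$C] < 0))
})

test_that("pre-segmentation floods everything without barriers, nothing at 0", {
  flat <- {
    xs <- seq(0, 3, by = 0.5)
    nx <- length(xs)
    V <- cbind(rep(xs, nx), rep(xs, each = nx), 0)
    i <- rep(seq_len(nx - 1), nx - 1)
    j <- rep(seq_len(nx - 1), each = nx - 1)
    v00 <- (j - 1) * nx + i
    F <- rbind(cbind(v00, v00 + 1L, v00 + nx + 1L),
               cbind(v00, v00 + nx + 1L, v00 + nx))
    tooth_mesh(V, F, weld = FALSE, orient = FALSE)
  }
  s1 <- seed_points(1L, 1.5, 1.5, 0)
  all_in <- preseg_occlusal(flat, s1, growth_threshold = 1)
  expect_true(all(unclass(all_in) == 1L))
  only_seed <- preseg_occlusal(flat, s1, growth_threshold = 0)
  expect_equal(sum(only_seed != 0L), 1L)
})

test_that("pre-segmentation caps stay within their bumps and match a brute-force flood", {
  tb <- two_bump_mesh(pitch = 0.35)
  hf <- compute_height_field(tb$mesh)
  thr <- stats::quantile(hf$H, 0.5, names = FALSE)
  pre <- preseg_occlusal(tb$mesh, tb$seeds, growth_threshold = thr,
                         height_field = hf)
  # caps never cross into the wrong bump
  expect_equal(sum(unclass(pre) == 1L & tb$labels == 2L), 0L)
  expect_equal(sum(unclass(pre) == 2L & tb$labels == 1L), 0L)
  # equals the independent priority-flood with the same admission rule
  sf <- attr(pre, "seed_faces")
  ref <- bf_priority_flood(tb$mesh, hf, sf, tb$seeds$tooth_id, thr)
  expect_equal(as.integer(pre), ref)
})

test_that("two seeds on the same face is an error naming the tooth ids", {
  tb <- two_bump_mesh(pitch = 0.35)
  s <- seed_points(c(1L, 2L), c(-2, -2), c(0, 0), c(1.6, 1.6))
  expect_error(preseg_occlusal(tb$mesh, s), "1, 2")
  expect_error(preseg_occlusal(tb$mesh, tb$seeds[0, ]), "empty seed")
})

test_that("watershed labels the two-bump phantom to >= 95% truth agreement", {
  tb <- two_bump_mesh(pitch = 0.15)
  lab <- watershed_segment(tb$mesh, tb$seeds)
  expect_gte(mean(unclass(lab) == tb$labels), 0.95)
  # partition: every face exactly one label
  expect_equal(length(lab), nrow(tb$mesh$faces))
  expect_true(all(unclass(lab) %in% c(0L, 1L, 2L)))
  # each tooth's region is connected and contains its seed
  adj <- facet_adjacency(tb$mesh)
  for (id in 1:2) {
    faces <- which(lab == id)
    expect_true(attr(lab, "seed_faces")[id] %in% faces)
    seen <- faces[1]
    frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(adj$neighbors[frontier]), faces), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    expect_setequal(seen, faces)
  }
})

test_that("watershed is deterministic and label-equivariant", {
  tb <- two_bump_mesh(pitch = 0.25)
  l1 <- watershed_segment(tb$mesh, tb$seeds)
  l2 <- watershed_segment(tb$mesh, tb$seeds)
  expect_identical(as.integer(l1), as.integer(l2))
  swapped <- tb$seeds
  swapped$tooth_id <- c(2L, 1L)
  l3 <- watershed_segment(tb$mesh, swapped)
  remap <- c(0L, 2L, 1L)[as.integer(l3) + 1L]
  expect_identical(as.integer(l1), remap)
})

test_that("one marker floods the whole bump mesh", {
  tb <- two_bump_mesh(pitch = 0.3)
  one <- watershed_segment(tb$mesh, tb$seeds[1, ],
                           background_marker = FALSE,
                           gingival_crease = Inf)
  expect_true(all(unclass(one) == 1L))
})

test_that("watershed equals brute-force priority flood on small meshes", {
  tb <- two_bump_mesh(pitch = 0.75)  # <= 200 faces
  expect_lte(nrow(tb$mesh$faces), 200)
  hf <- compute_height_field(tb$mesh)
  got <- watershed_segment(tb$mesh, tb$seeds, background_marker = FALSE,
                           gingival_crease = Inf, height_field = hf)
  thr <- stats::quantile(hf$H, 0.6, names = FALSE)
  sf <- attr(got, "seed_faces")
  pre <- bf_priority_flood(tb$mesh, hf, sf, tb$seeds$tooth_id, thr)
  ref <- bf_priority_flood(tb$mesh, hf, sf, tb$seeds$tooth_id, Inf,
                           init_labels = pre)
  expect_equal(as.integer(got), ref)
})

test_that("labels export as CSV and split into per-tooth meshes", {
  tb <- two_bump_mesh(pitch = 0.3)
  lab <- watershed_segment(tb$mesh, tb$seeds)
  p <- tempfile(fileext = ".csv")
  write_labels_csv(lab, p)
  d <- utils::read.csv(p)
  expect_equal(nrow(d), nrow(tb$mesh$faces))
  expect_equal(d$tooth_id, as.integer(lab))
  crowns <- split_crowns(tb$mesh, lab)
  expect_setequal(names(crowns), c("1", "2"))
  expect_equal(sum(vapply(crowns, function(m) nrow(m$faces), numeric(1))),
               sum(lab != 0L))
})
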