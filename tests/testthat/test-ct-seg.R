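# Radon separation line, level-set slice segmentation, propagation,
# isosurface reconstruction.

two_disk_slice <- function(n = 64, r = 10, sep = 22, angle = 0, gap_val = 0,
                           val = 1) {
  ctr <- (n + 1) / 2
  img <- matrix(gap_val, n, n)
  a <- angle * pi / 180
  c1 <- ctr + sep / 2 * c(cos(a), sin(a))
  c2 <- ctr - sep / 2 * c(cos(a), sin(a))
  x <- row(img); y <- col(img)
  img[(x - c1[1])^2 + (y - c1[2])^2 < r^2] <- val
  img[(x - c2[1])^2 + (y - c2[2])^2 < r^2] <- val
  list(img = img, c1 = c1, c2 = c2, ctr = c(ctr, ctr))
}

test_that("separation line of two disks is the darkest path between them", {
  s <- two_disk_slice()
  L <- radon_separation_line(s$img)
  # the line separates the centroids and passes near the midpoint
  sides <- line_side(L, rbind(s$c1, s$c2))
  expect_true(prod(sides) < 0)
  mid_off <- abs(line_side(L, rbind(s$ctr)))
  expect_lt(mid_off, 1)
  # line direction within 5 degrees of perpendicular to the center axis
  expect_lt(abs(sum(L$direction * c(1, 0))), sin(5 * pi / 180))
  # exhaustive scan oracle: sample points along candidate lines directly,
  # with the same transversality preference among equally dark paths
  cands <- NULL
  for (ang in seq(0, 179, by = 1)) {
    aa <- ang * pi / 180
    nrm <- c(cos(aa), sin(aa))
    dirv <- c(-sin(aa), cos(aa))
    for (off in seq(-14, 14, by = 0.5)) {
      p1 <- sum((s$c1 - s$ctr) * nrm); p2 <- sum((s$c2 - s$ctr) * nrm)
      if (!(min(p1, p2) < off && off < max(p1, p2))) next
      pts <- sweep(outer(seq(-30, 30, by = 0.5), dirv), 2,
                   s$ctr + off * nrm, "+")
      ok <- pts[, 1] >= 1 & pts[, 1] <= 64 & pts[, 2] >= 1 & pts[, 2] <= 64
      v <- mean(s$img[cbind(round(pts[ok, 1]), round(pts[ok, 2]))])
      cands <- rbind(cands, c(ang, off, v))
    }
  }
  vstar <- min(cands[, 3])
  tied <- cands[cands[, 3] <= vstar + 1e-9, , drop = FALSE]
  axis <- (s$c2 - s$c1) / sqrt(sum((s$c2 - s$c1)^2))
  al <- abs(cos(tied[, 1] * pi / 180) * axis[1] +
              sin(tied[, 1] * pi / 180) * axis[2])
  besto <- tied[order(-al, abs(tied[, 2]), tied[, 1]), ][1, ]
  ang_diff <- min(abs(L$angle_deg - besto[1]),
                  180 - abs(L$angle_deg - besto[1]))
  expect_lte(ang_diff, 5)
  expect_lte(abs(L$offset - besto[2]), 1)
})

test_that("separation line is equivariant under scene rotation", {
  L0 <- radon_separation_line(two_disk_slice(angle = 0)$img)
  L30 <- radon_separation_line(two_disk_slice(angle = 30)$img)
  a0 <- L0$angle_deg
  a30 <- L30$angle_deg
  d <- abs(((a30 - a0) %% 180) - 30)
  expect_lt(min(d, 180 - d), 6)
})

test_that("degenerate gaps are rejected or flagged", {
  one <- two_disk_slice(sep = 0)
  expect_error(radon_separation_line(one$img), "fewer than two")
  # heavily overlapping disks with a bright floor: either a merged-blob
  # error or an explicit overlap error; in flag mode a low-confidence result
  overlap <- two_disk_slice(sep = 18, gap_val = 0.85)
  expect_error(radon_separation_line(overlap$img, on_overlap = "error"))
  L <- tryCatch(radon_separation_line(overlap$img, on_overlap = "flag"),
                error = function(e) e)
  if (inherits(L, "separation_line")) expect_false(L$confidence_ok)
})

disk_image <- function(n = 64, r = 20, cx = NULL) {
  if (is.null(cx)) cx <- (n + 1) / 2
  img <- matrix(0, n, n)
  img[(row(img) - cx)^2 + (col(img) - cx)^2 < r^2] <- 1
  img
}

circle_poly <- function(cx, cy, r, n = 40) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(cx + r * cos(a), cy + r * sin(a))
}

test_that("level set recovers a disk boundary within 1 px mean radial error", {
  img <- disk_image()
  ctr <- 32.5
  ct <- levelset_segment_slice(img, circle_poly(ctr, ctr, 15))
  rad <- sqrt(rowSums(sweep(ct$polygon, 2, c(ctr, ctr))^2))
  expect_lt(mean(abs(rad - 20)), 1)
  # initialized at the true boundary: stays there
  ct2 <- levelset_segment_slice(img, circle_poly(ctr, ctr, 20))
  rad2 <- sqrt(rowSums(sweep(ct2$polygon, 2, c(ctr, ctr))^2))
  expect_lt(mean(abs(rad2 - 20)), 0.5)
})

test_that("separation-line constraint confines each contour to its half-plane", {
  s <- two_disk_slice(n = 64, r = 10, sep = 22)
  L <- radon_separation_line(s$img)
  side1 <- sign(line_side(L, rbind(s$c1)))
  ct1 <- levelset_segment_slice(s$img, circle_poly(s$c1[1], s$c1[2], 6),
                                constraint = L, keep_side = side1)
  expect_true(all(line_side(L, ct1$polygon) * side1 > -1.5))
  # mean radial error of the constrained contour still small
  rad <- sqrt(rowSums(sweep(ct1$polygon, 2, s$c1)^2))
  expect_lt(mean(abs(rad - 10)), 1.5)
})

test_that("a vanishing contour raises a lost-tooth condition", {
  img <- matrix(0, 48, 48)   # nothing to segment
  expect_error(
    levelset_segment_slice(img, circle_poly(24, 24, 6)),
    class = "lost_tooth_error")
})

cylinder_volume <- function(r_px = 8, n = 36, slices = 30, val = 1000,
                            taper = FALSE) {
  vol <- array(0, c(n, n, slices))
  ctr <- (n + 1) / 2
  for (k in seq_len(slices)) {
    rk <- if (taper) r_px * (slices - k + 1) / slices else r_px
    sl <- matrix(0, n, n)
    sl[(row(sl) - ctr)^2 + (col(sl) - ctr)^2 < rk^2] <- val
    vol[, , k] <- sl
  }
  voxel_volume(vol, 0.5)
}

test_that("propagation through a cylinder keeps contour areas constant", {
  vol <- cylinder_volume()
  seeds <- seed_points(1L, 18.5, 18.5)
  cs <- propagate_contours(vol, 15, seeds)
  areas <- vapply(cs[["1"]], `[[`, numeric(1), "area")
  expect_equal(length(areas), 30L)
  expect_lt(diff(range(areas)) / mean(areas), 0.05)
})

test_that("propagation down a tapered cone shrinks and stops near the apex", {
  vol <- cylinder_volume(r_px = 9, slices = 40, taper = TRUE)
  seeds <- seed_points(1L, 18.5, 18.5)
  cs <- propagate_contours(vol, 5, seeds)
  ks <- as.integer(names(cs[["1"]]))
  areas <- vapply(cs[["1"]], `[[`, numeric(1), "area")
  o <- order(ks)
  # strictly decreasing toward the apex (allow small discretization wiggle)
  fit <- stats::coef(stats::lm(areas[o] ~ ks[o]))[2]
  expect_lt(fit, 0)
  # stops within a couple slices of the apex (area < 4 voxels at k ~ 37+)
  expect_gte(max(ks), 33)
  # start at the volume boundary: one-directional, no error
  cs2 <- propagate_contours(vol, 1, seeds)
  expect_gte(length(cs2[["1"]]), 10)
})

test_that("seed outside the bright region errors", {
  vol <- cylinder_volume()
  expect_error(propagate_contours(vol, 15, seed_points(1L, 2, 2)),
               "outside the bright")
})

test_that("reconstructed sphere is watertight with accurate area and volume", {
  r <- 10; vox <- 0.5
  n <- ceiling(2 * (r + 2) / vox)
  xs <- (seq_len(n) - 0.5) * vox - (r + 2)
  occ <- array(0, c(n, n, n))
  occ[] <- as.numeric(outer(outer(xs^2, xs^2, "+"), xs^2, "+") < r^2)
  m <- reconstruct_surface(occ, vox, origin = rep(-(r + 2), 3))
  top <- mesh_topology(m)
  expect_true(top$closed)
  expect_equal(top$euler, 2L)
  d <- sqrt(rowSums(m$vertices^2))
  expect_true(all(abs(d - r) < 0.5))
  expect_lt(abs(mesh_surface_area(m) / (4 * pi * r^2) - 1), 0.05)
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * r^3) - 1), 0.10)
})

test_that("a single filled voxel reconstructs to a small closed cell", {
  occ <- array(0, c(5, 5, 5))
  occ[3, 3, 3] <- 1
  m <- reconstruct_surface(occ, 1, smooth_sigma = 0, taubin_iters = 0)
  expect_true(mesh_topology(m)$closed)
  v <- abs(mesh_volume(m))
  expect_gte(v, 0.5)
  expect_lte(v, 2)
  expect_error(reconstruct_surface(array(0, c(4, 4, 4))), "empty occupancy")
})

test_that("contour containment: slice-to-slice centroids never teleport", {
  vol <- cylinder_volume(r_px = 9, slices = 25, taper = TRUE)
  cs <- propagate_contours(vol, 3, seed_points(1L, 18.5, 18.5))
  ks <- sort(as.integer(names(cs[["1"]])))
  for (i in seq_along(ks)[-1]) {
    prev <- cs[["1"]][[as.character(ks[i - 1])]]
    cur <- cs[["1"]][[as.character(ks[i])]]
    bb <- apply(prev$polygon, 2, range)
    cen <- colMeans(cur$polygon)
    half <- pmax(bb[2, ] - bb[1, ], 2)
    expect_true(all(cen >= bb[1, ] - half) && all(cen <= bb[2, ] + half))
  }
})
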