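#' CT voxel volume
#'
#' A grayscale CT volume stored as a 3D array indexed `[x, y, slice]`, with
#' transverse slices along the third axis (the tooth long axis, crown toward
#' increasing slice index). Voxel index `(i, j, k)` (1-based) maps to mm as
#' `origin + (index - 0.5) * voxel_size` (voxel-centre convention).
#'
#' @param intensity 3D numeric array.
#' @param voxel_size mm per axis; scalar for isotropic voxels or length 3.
#' @param origin position of the volume corner in mm (length 3, default 0).
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensity, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(dim(intensity)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  structure(list(intensity = intensity, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Convert voxel indices to mm coordinates (voxel-centre convention)
#' @param volume a [voxel_volume].
#' @param index n x 3 matrix of (possibly fractional) 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(volume, index) {
  sweep(sweep(as.matrix(index) - 0.5, 2, volume$voxel_size, "*"),
        2, volume$origin, "+")
}

#' Write / read a raw volume with a JSON sidecar
#'
#' The volume is stored as little-endian float64 raw data plus a JSON sidecar
#' holding `dim`, `voxel_size`, `origin` and `dtype`.
#'
#' @param volume a [voxel_volume].
#' @param path base path; writes `path.raw` and `path.json`.
#' @return base path invisibly / the read [voxel_volume].
#' @export
write_volume_raw <- function(volume, path) {
  con <- file(paste0(path, ".raw"), "wb")
  writeBin(as.numeric(volume$intensity), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(dim = dim(volume$intensity),
                            voxel_size = volume$voxel_size,
                            origin = volume$origin, dtype = "float64"),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_volume_raw
#' @export
read_volume_raw <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- prod(meta$dim)
  con <- file(paste0(path, ".raw"), "rb")
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  voxel_volume(array(v, dim = meta$dim), meta$voxel_size, meta$origin)
}

# ---- separation line ---------------------------------------------------

#' Separation line between two neighbouring teeth on a CT slice
#'
#' Finds the darkest straight path between the two bright (tooth) blobs of a
#' region of interest: the minimum of the Radon sinogram (mean intensity per
#' line, accumulated by pixel binning over angle and offset), restricted to
#' lines that separate the two blob centroids.
#'
#' @param slice 2D numeric matrix (image, indexed `[x, y]` in pixels).
#' @param roi optional `c(x0, x1, y0, y1)` pixel bounds of the region around
#'   the two teeth; default whole slice.
#' @param angle_step sinogram angle resolution in degrees (default 1).
#' @param low_confidence_frac if the darkest separating line's mean intensity
#'   exceeds this fraction of the mean blob intensity the gap is considered
#'   closed (default 0.6).
#' @param on_overlap what to do when the gap is closed: `"error"` (default)
#'   or `"flag"` (return the line with `confidence_ok = FALSE`).
#' @return an object of class `separation_line`: list with `point` (x, y in
#'   px on the full slice), `direction` (unit), `normal` (unit), `angle_deg`,
#'   `offset`, `centroids` (2 x 2, one blob per row), `line_mean`,
#'   `confidence_ok`.
#' @export
radon_separation_line <- function(slice, roi = NULL, angle_step = 1,
                                  low_confidence_frac = 0.6,
                                  on_overlap = c("error", "flag")) {
  on_overlap <- match.arg(on_overlap)
  if (is.null(roi)) roi <- c(1, nrow(slice), 1, ncol(slice))
  roi <- round(roi)
  img <- slice[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  rng <- range(img)
  if (diff(rng) <= 0) stop("flat region of interest: no teeth found")
  norm <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  bw <- norm > thr
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  big <- order(sizes, decreasing = TRUE)
  big <- big[sizes[big] >= 4]
  if (length(big) < 2)
    stop("no gap found: region of interest contains fewer than two tooth blobs")
  cen <- t(vapply(big[1:2], function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  ctr <- colMeans(cen)
  xs <- row(img) - ctr[1]
  ys <- col(img) - ctr[2]
  blob_mean <- mean(norm[bw])
  cand <- data.frame(angle = numeric(0), offset = numeric(0),
                     val = numeric(0))
  for (ang in seq(0, 180 - angle_step, by = angle_step)) {
    a <- ang * pi / 180
    nrm <- c(cos(a), sin(a))
    s <- xs * nrm[1] + ys * nrm[2]
    p1 <- sum((cen[1, ] - ctr) * nrm)
    p2 <- sum((cen[2, ] - ctr) * nrm)
    lohi <- sort(c(p1, p2))
    bin <- round(s)                     # 1 px offset bins
    sel <- bin > lohi[1] & bin < lohi[2]
    if (!any(sel)) next
    sums <- tapply(norm[sel], bin[sel], mean)
    counts <- tapply(norm[sel], bin[sel], length)
    sums <- sums[counts >= 3]
    if (!length(sums)) next
    k <- which.min(sums)
    cand[nrow(cand) + 1, ] <- c(ang, as.numeric(names(sums)[k]), sums[k])
  }
  if (!nrow(cand)) stop("no separating line found between the blobs")
  # a clean gap admits a family of equally dark paths; prefer, among them,
  # the one most transverse to the interproximal (centroid) axis, then the
  # smallest offset — deterministic and anatomically the separation plane
  vstar <- min(cand$val)
  tied <- cand[cand$val <= vstar + 1e-9, , drop = FALSE]
  axis <- cen[2, ] - cen[1, ]
  axis <- axis / sqrt(sum(axis^2))
  align <- abs(cos(tied$angle * pi / 180) * axis[1] +
                 sin(tied$angle * pi / 180) * axis[2])
  tied <- tied[order(-align, abs(tied$offset), tied$angle), ]
  best <- list(val = tied$val[1], angle = tied$angle[1],
               offset = tied$offset[1])
  ok <- best$val <= low_confidence_frac * blob_mean
  if (!ok && on_overlap == "error")
    stop(sprintf(
      "teeth overlap: darkest separating path (%.2f) is not darker than %.2f of the blob intensity",
      best$val, low_confidence_frac))
  a <- best$angle * pi / 180
  nrm <- c(cos(a), sin(a))
  point <- ctr + best$offset * nrm + c(roi[1] - 1, roi[3] - 1)
  structure(list(point = point,
                 direction = c(-nrm[2], nrm[1]),
                 normal = nrm,
                 angle_deg = best$angle,
                 offset = best$offset,
                 centroids = sweep(cen, 2, -c(roi[1] - 1, roi[3] - 1)),
                 line_mean = best$val,
                 confidence_ok = ok),
            class = "separation_line")
}

#' Signed side of points relative to a separation line
#' @param line a `separation_line`.
#' @param pts n x 2 matrix of (x, y) pixel points.
#' @return signed distances (px); sign identifies the half-plane.
#' @export
line_side <- function(line, pts) {
  as.numeric(sweep(as.matrix(pts), 2, line$point) %*% line$normal)
}

# ---- level set ---------------------------------------------------------

#' Level-set parameters
#'
#' Coefficients of the hybrid energy: a region term pulling the contour
#' toward the Otsu split between tooth and background intensities
#' (`lambda1`), an edge term advecting it toward gradient maxima
#' (`lambda2`), and curvature smoothing (`mu`).
#'
#' @param lambda1 region-term weight (default 1).
#' @param lambda2 edge-term weight (default 1).
#' @param mu curvature-smoothing weight (default 0.2).
#' @param max_iter maximum iterations (default 200).
#' @param dt time step in px (default 0.45; explicit scheme, keep below 0.5).
#' @param sigma_grad Gaussian pre-smoothing for the edge map, px (default 1.5).
#' @param reinit_every reinitialize the level set to a signed distance every
#'   this many iterations (default 25).
#' @param conv_tol stop when the mean absolute level-set update near the
#'   contour falls below this (default 2e-3).
#' @return a list of class `levelset_params`.
#' @export
levelset_params <- function(lambda1 = 1, lambda2 = 1, mu = 0.2,
                            max_iter = 200, dt = 0.45, sigma_grad = 1.5,
                            reinit_every = 25, conv_tol = 2e-3) {
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu,
                 max_iter = max_iter, dt = dt, sigma_grad = sigma_grad,
                 reinit_every = reinit_every, conv_tol = conv_tol),
            class = "levelset_params")
}

# parity ray-crossing point-in-polygon, vectorized over query points
.in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# signed distance to polygon (positive inside), on the pixel grid of dims
.signed_distance <- function(poly, nx, ny) {
  px <- as.vector(row(matrix(0, nx, ny)))
  py <- as.vector(col(matrix(0, nx, ny)))
  d <- rep(Inf, nx * ny)
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    t <- if (len2 < 1e-300) rep(0, length(px)) else
      pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
    dx <- px - (a[1] + t * abx)
    dy <- py - (a[2] + t * aby)
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  s <- ifelse(.in_polygon(px, py, poly), 1, -1)
  matrix(s * d, nx, ny)
}

.grad_central <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  gx <- (m[c(2:nx, nx), ] - m[c(1, 1:(nx - 1)), ]) / 2
  gy <- (m[, c(2:ny, ny)] - m[, c(1, 1:(ny - 1))]) / 2
  list(x = gx, y = gy)
}

.gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
  conv1 <- function(x) stats::filter(pad(x, r), k, sides = 2)[(r + 1):(r + length(x))]
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Segment one tooth contour on a CT slice with a hybrid level set
#'
#' Evolves an implicit contour under a hybrid energy (Otsu-split region term
#' + gradient edge term + curvature smoothing) from an initial polygon. A
#' separation-line constraint, when given, acts as a hard wall: the level set
#' is clamped negative outside the assigned half-plane, so the contour can
#' never invade the neighbouring tooth.
#'
#' @param slice 2D numeric matrix `[x, y]` (pixels).
#' @param init initial contour: an n x 2 polygon (x, y in px) or a
#'   `slice_contour`.
#' @param constraint a `separation_line`, or a list of them, or NULL.
#' @param keep_side sign(s) of [line_side] of the tooth's own half-plane, one
#'   per constraint; default taken from the init polygon centroid.
#' @param params a [levelset_params].
#' @return an object of class `slice_contour`: list with `polygon` (closed,
#'   simple loop, n x 2 px), `area` (px^2), `slice_index` (NA here),
#'   `iterations`.
#' @export
levelset_segment_slice <- function(slice, init, constraint = NULL,
                                   keep_side = NULL,
                                   params = levelset_params()) {
  poly <- if (inherits(init, "slice_contour")) init$polygon else as.matrix(init)
  if (nrow(poly) < 3) stop("initial contour needs at least 3 points")
  nx <- nrow(slice); ny <- ncol(slice)
  if (min(poly[, 1]) < 1 || max(poly[, 1]) > nx ||
      min(poly[, 2]) < 1 || max(poly[, 2]) > ny)
    stop("initial contour outside the slice")
  constraints <- if (is.null(constraint)) list()
                 else if (inherits(constraint, "separation_line")) list(constraint)
                 else constraint
  cen <- colMeans(poly)
  if (is.null(keep_side) && length(constraints))
    keep_side <- vapply(constraints,
                        function(L) sign(line_side(L, rbind(cen))), numeric(1))
  rng <- range(slice)
  I <- if (diff(rng) > 0) (slice - rng[1]) / diff(rng) else slice * 0
  if (diff(rng) > 0) {
    thr <- EBImage::otsu(I, range = c(0, 1))
    m1 <- mean(I[I > thr]); m2 <- mean(I[I <= thr])
    r_term <- pmin(pmax((I - (m1 + m2) / 2) / max((m1 - m2) / 2, 1e-6),
                        -1), 1)
  } else {
    r_term <- matrix(-1, nx, ny)   # featureless slice: contour must shrink
  }
  Is <- .gauss_blur2d(I, params$sigma_grad)
  gI <- .grad_central(Is)
  gmag <- sqrt(gI$x^2 + gI$y^2)
  g <- 1 / (1 + (gmag / max(mean(gmag), 1e-9))^2)
  gg <- .grad_central(g)
  wall <- NULL
  if (length(constraints)) {
    pxm <- row(slice); pym <- col(slice)
    wall <- matrix(FALSE, nx, ny)
    for (ci in seq_along(constraints)) {
      L <- constraints[[ci]]
      sd <- (pxm - L$point[1]) * L$normal[1] + (pym - L$point[2]) * L$normal[2]
      wall <- wall | (sd * keep_side[ci] < 0)
    }
  }
  phi <- .signed_distance(poly, nx, ny)
  clampwall <- function(phi) {
    if (!is.null(wall)) phi[wall] <- pmin(phi[wall], -0.5)
    phi
  }
  phi <- clampwall(phi)
  iter_done <- 0L
  for (it in seq_len(params$max_iter)) {
    gp <- .grad_central(phi)
    ng <- sqrt(gp$x^2 + gp$y^2)
    ngs <- pmax(ng, 1e-9)
    nxf <- gp$x / ngs; nyf <- gp$y / ngs
    dnx <- .grad_central(nxf)$x
    dny <- .grad_central(nyf)$y
    kappa <- pmin(pmax(dnx + dny, -1), 1)
    dphi <- params$lambda1 * r_term * ng +
      params$mu * kappa * ng +
      params$lambda2 * (gg$x * gp$x + gg$y * gp$y)
    phi <- clampwall(phi + params$dt * dphi)
    iter_done <- it
    band <- abs(phi) < 2
    delta <- if (any(band)) mean(abs(dphi[band])) * params$dt else Inf
    if (it %% params$reinit_every == 0 || delta < params$conv_tol) {
      pl <- .largest_contour(phi)
      if (is.null(pl)) .lost_tooth()
      phi <- clampwall(.signed_distance(pl, nx, ny))
      if (delta < params$conv_tol) break
    }
  }
  pl <- .largest_contour(phi)
  if (is.null(pl)) .lost_tooth()
  slice_contour(pl, slice_index = NA_integer_, iterations = iter_done)
}

.lost_tooth <- function() {
  stop(structure(
    list(message = "contour vanished during level-set evolution", call = NULL),
    class = c("lost_tooth_error", "error", "condition")))
}

# largest closed zero-level contour of phi, or NULL
.largest_contour <- function(phi) {
  cl <- grDevices::contourLines(x = seq_len(nrow(phi)), y = seq_len(ncol(phi)),
                                z = phi, levels = 0)
  if (!length(cl)) return(NULL)
  areas <- vapply(cl, function(c0) {
    x <- c0$x; y <- c0$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  best <- cl[[which.max(areas)]]
  if (max(areas) < 1) return(NULL)
  cbind(best$x, best$y)
}

#' Slice contour
#' @param polygon n x 2 closed simple loop, pixel coordinates (x, y).
#' @param slice_index slice number the contour lives on.
#' @param tooth_id optional tooth label.
#' @param iterations level-set iterations used (bookkeeping).
#' @return object of class `slice_contour` with `area` (px^2, shoelace).
#' @export
slice_contour <- function(polygon, slice_index = NA_integer_,
                          tooth_id = NA_integer_, iterations = NA_integer_) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) stop("polygon needs at least 3 points")
  # drop a duplicated closing point
  if (all(polygon[1, ] == polygon[nrow(polygon), ]))
    polygon <- polygon[-nrow(polygon), , drop = FALSE]
  x <- polygon[, 1]; y <- polygon[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area <= 0) stop("degenerate contour: zero area")
  structure(list(polygon = polygon, slice_index = slice_index,
                 tooth_id = tooth_id, area = area, iterations = iterations),
            class = "slice_contour")
}

#' @export
print.slice_contour <- function(x, ...) {
  cat(sprintf("slice_contour: slice %s tooth %s, %d points, area %.1f px^2\n",
              x$slice_index, x$tooth_id, nrow(x$polygon), x$area))
  invisible(x)
}

# ---- propagation -------------------------------------------------------

#' Propagate tooth contours through a CT volume slice-by-slice
#'
#' Segments the starting slice from seed points (one per tooth; a small
#' circle around each seed initializes the level set), then marches toward
#' the crown end and the root end separately, initializing each slice with
#' the previous slice's contour (shape prior). For every slice, separation
#' lines between nearby tooth pairs are extracted by
#' [radon_separation_line] and enforced as hard constraints. A tooth's
#' propagation stops when its contour area drops below `min_area_vox` (root
#' apex), when the contour is lost, or at the volume end.
#'
#' @param volume a [voxel_volume].
#' @param start_slice starting slice index (pick one inside the crown).
#' @param seeds a [seed_points] data frame with x/y in PIXELS of the
#'   starting slice.
#' @param params a [levelset_params].
#' @param min_area_vox apex stop threshold, voxels (default 4).
#' @param init_radius_px radius of the seed initialization circle (default 4).
#' @param pair_dist_px max centroid distance for a separation line between
#'   two teeth (default 40 px).
#' @return a list of class `contour_set`: per tooth (named by id), a list of
#'   `slice_contour`s keyed by slice index; attribute `dims`.
#' @export
propagate_contours <- function(volume, start_slice, seeds,
                               params = levelset_params(),
                               min_area_vox = 4, init_radius_px = 4,
                               pair_dist_px = 40) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$intensity)
  if (start_slice < 1 || start_slice > d[3]) stop("start_slice out of range")
  ids <- seeds$tooth_id
  img0 <- volume$intensity[, , start_slice]
  thr0 <- EBImage::otsu((img0 - min(img0)) / max(diff(range(img0)), 1e-9),
                        range = c(0, 1))
  for (i in seq_len(nrow(seeds))) {
    v <- (img0[round(seeds$x[i]), round(seeds$y[i])] - min(img0)) /
      max(diff(range(img0)), 1e-9)
    if (v <= thr0)
      stop(sprintf("seed of tooth %d lies outside the bright (tooth) region",
                   ids[i]))
  }
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  circ <- function(cx, cy) cbind(cx + init_radius_px * cos(ang),
                                 cy + init_radius_px * sin(ang))
  segment_slice <- function(k, inits) {
    # inits: named list tooth_id -> polygon; returns named list of contours
    cents <- t(vapply(inits, colMeans, numeric(2)))
    img <- volume$intensity[, , k]
    out <- list()
    for (i in seq_along(inits)) {
      id <- names(inits)[i]
      cons <- list(); sides <- numeric(0)
      for (j in seq_along(inits)) {
        if (i == j) next
        if (sqrt(sum((cents[i, ] - cents[j, ])^2)) > pair_dist_px) next
        lim <- function(v, n) pmin(pmax(round(v), 1), n)
        pad <- pair_dist_px / 2
        roi <- c(lim(min(cents[c(i, j), 1]) - pad, d[1]),
                 lim(max(cents[c(i, j), 1]) + pad, d[1]),
                 lim(min(cents[c(i, j), 2]) - pad, d[2]),
                 lim(max(cents[c(i, j), 2]) + pad, d[2]))
        L <- tryCatch(
          radon_separation_line(img, roi = roi, on_overlap = "flag"),
          error = function(e) NULL)
        if (!is.null(L)) {
          cons <- c(cons, list(L))
          sides <- c(sides, sign(line_side(L, rbind(cents[i, ]))))
        }
      }
      ct <- tryCatch(
        levelset_segment_slice(img, inits[[i]],
                               constraint = if (length(cons)) cons else NULL,
                               keep_side = if (length(cons)) sides else NULL,
                               params = params),
        lost_tooth_error = function(e) NULL)
      if (!is.null(ct)) {
        ct$slice_index <- k
        ct$tooth_id <- as.integer(id)
        out[[id]] <- ct
      }
    }
    out
  }
  inits0 <- stats::setNames(
    lapply(seq_len(nrow(seeds)), function(i) circ(seeds$x[i], seeds$y[i])),
    as.character(ids))
  first <- segment_slice(start_slice, inits0)
  if (!length(first))
    stop("segmentation failed on the starting slice for every tooth")
  result <- stats::setNames(vector("list", length(ids)), as.character(ids))
  for (id in names(first)) result[[id]][[as.character(start_slice)]] <- first[[id]]
  march <- function(dirn) {
    active <- first
    k <- start_slice + dirn
    while (length(active) && k >= 1 && k <= d[3]) {
      inits <- lapply(active, function(ct) ct$polygon)
      got <- segment_slice(k, inits)
      keep <- list()
      for (id in names(got)) {
        ct <- got[[id]]
        if (ct$area < min_area_vox) next      # apex reached
        # containment sanity: centroid must stay near the previous contour
        prev <- active[[id]]
        bb <- apply(prev$polygon, 2, range)
        cen <- colMeans(ct$polygon)
        half <- pmax((bb[2, ] - bb[1, ]), 2)
        if (any(cen < bb[1, ] - half) || any(cen > bb[2, ] + half)) next
        result[[id]][[as.character(k)]] <<- ct
        keep[[id]] <- ct
      }
      active <- keep
      k <- k + dirn
    }
  }
  march(+1L)
  march(-1L)
  structure(result, dims = d, class = "contour_set")
}

#' Rasterize a contour set into a per-tooth binary occupancy volume
#' @param contours a `contour_set` from [propagate_contours].
#' @param tooth_id which tooth.
#' @param dims volume dims; default from the contour set.
#' @return logical 3D array.
#' @export
contours_to_mask <- function(contours, tooth_id, dims = attr(contours, "dims")) {
  cs <- contours[[as.character(tooth_id)]]
  if (is.null(cs) || !length(cs)) stop("no contours for tooth ", tooth_id)
  mask <- array(FALSE, dims)
  for (ct in cs) {
    poly <- ct$polygon
    bb <- apply(poly, 2, range)
    xs <- max(1, floor(bb[1, 1])):min(dims[1], ceiling(bb[2, 1]))
    ys <- max(1, floor(bb[1, 2])):min(dims[2], ceiling(bb[2, 2]))
    if (!length(xs) || !length(ys)) next
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    inside <- .in_polygon(gx, gy, poly)
    mask[cbind(gx[inside], gy[inside], ct$slice_index)] <- TRUE
  }
  mask
}

#' Reconstruct a triangle surface from a binary occupancy volume
#'
#' Light Gaussian smoothing of the occupancy followed by isosurface
#' extraction at the 0.5 level (tetrahedral marching-cubes variant),
#' producing a closed, consistently outward-oriented mesh in mm coordinates
#' (voxel-centre convention).
#'
#' @param x logical/numeric 3D occupancy array, or a [voxel_volume] holding
#'   one.
#' @param voxel_size mm per axis (ignored when `x` is a [voxel_volume]).
#' @param origin volume origin in mm.
#' @param iso iso level (default 0.5).
#' @param smooth_sigma occupancy smoothing in voxels (default 1; 0 disables —
#'   the raw binary staircase is then extracted).
#' @param snap interpolation clamp: isosurface vertices are kept at least
#'   this fraction of a lattice step away from the lattice corners (default
#'   0.2), so downstream triangulations see no near-duplicate vertices; the
#'   positional bias is below `snap` voxels.
#' @param taubin_iters iterations of shrink-free Taubin vertex smoothing
#'   applied to the extracted mesh (default 10; 0 disables). Removes the
#'   voxel-scale staircase ripple of the raw isosurface.
#' @return a [tooth_mesh].
#' @export
reconstruct_surface <- function(x, voxel_size = 1, origin = c(0, 0, 0),
                                iso = 0.5, smooth_sigma = 1, snap = 0.2,
                                taubin_iters = 10) {
  if (inherits(x, "voxel_volume")) {
    voxel_size <- x$voxel_size
    origin <- x$origin
    x <- x$intensity
  }
  occ <- array(as.numeric(x), dim(x))
  if (sum(occ > iso) == 0) stop("empty occupancy: nothing to reconstruct")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  # pad so the surface closes at the volume border
  d <- dim(occ)
  padded <- array(0, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  if (smooth_sigma > 0)
    padded <- .gauss_blur3d_cpp(padded, dim(padded),
                                rep_len(smooth_sigma, 3))
  res <- .marching_tetra_cpp(as.numeric(padded), dim(padded), iso,
                             voxel_size, origin - voxel_size, snap)
  if (nrow(res$faces) == 0) stop("iso level produced an empty surface")
  mesh <- tooth_mesh(res$vertices, res$faces, weld = FALSE, orient = TRUE)
  if (taubin_iters > 0) mesh <- taubin_smooth(mesh, iterations = taubin_iters)
  mesh
}

#' Shrink-free (Taubin) mesh smoothing
#'
#' Alternating positive/negative Laplacian steps (lambda then mu), which
#' smooths surface ripple without the volume shrinkage of plain Laplacian
#' smoothing. Connectivity is unchanged.
#'
#' @param mesh a [tooth_mesh].
#' @param iterations lambda/mu pairs to run (default 10).
#' @param lambda positive step (default 0.5).
#' @param mu negative step (default -0.53).
#' @return the smoothed [tooth_mesh].
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  V <- mesh$vertices
  F <- mesh$faces
  i <- c(F[, 1], F[, 2], F[, 2], F[, 3], F[, 3], F[, 1])
  j <- c(F[, 2], F[, 1], F[, 3], F[, 2], F[, 1], F[, 3])
  dup <- duplicated(cbind(i, j))
  i <- i[!dup]; j <- j[!dup]
  deg <- tabulate(i, nrow(V))
  deg[deg == 0] <- 1
  step <- function(V, w) {
    nb <- rowsum(V[j, , drop = FALSE], i, reorder = TRUE)
    M <- matrix(0, nrow(V), 3)
    M[as.integer(rownames(nb)), ] <- nb
    V + w * (M / deg - V)
  }
  for (it in seq_len(iterations)) {
    V <- step(V, lambda)
    V <- step(V, mu)
  }
  mesh$vertices <- V
  mesh
}
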