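# Synthetic dental phantom: analytic multi-tooth arches with known ground
# truth, paired as (a) a laser-analog crown surface mesh sampled at intraoral
# resolution and (b) a CT-analog voxel volume in a rigidly displaced frame.

# run fn() with a private RNG stream; the caller's RNG state is untouched
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Analytic tooth shape
#'
#' A tooth is modelled in a local frame (z the long axis, cervix at z = 0) as
#' a superelliptic crown capped by a cusped occlusal dome, whose lateral wall
#' bulges outward over `bulge` mm between the occlusal rim and the cervix
#' (the emergence profile: steepest, ~80 degrees, right at the cervix line),
#' continued below the cervix by a tapered root with a rounded apex.
#'
#' @param center (x, y) of the tooth axis in the arch plane, mm.
#' @param width,depth mesiodistal / buccolingual crown size, mm.
#' @param crown_height cervix-to-cusp-tip height, mm.
#' @param root_length cervix-to-apex length, mm.
#' @param cusp_amp occlusal cusp amplitude, mm.
#' @param n_cusps number of cusps around the occlusal table.
#' @param asym buccolingual asymmetry of the occlusal table as a fraction of
#'   the crown height (default 0.15): lingual cusps sit lower than buccal
#'   ones, as on real molars, which also removes the 180-degree rotational
#'   ambiguity a symmetric crown would present to registration.
#' @param se_power superellipse exponent (2 = ellipse; default 3, squarish).
#' @param root_power taper exponent of the root profile (default 0.8).
#' @param bulge lateral extent of the crown wall bulge, mm (default 0.6).
#' @param tooth_id positive integer label.
#' @return a list of class `tooth_shape`.
#' @export
tooth_shape <- function(center = c(0, 0), width = 4, depth = 3.5,
                        crown_height = 3.5, root_length = 7,
                        cusp_amp = 0.3, n_cusps = 4, se_power = 3,
                        root_power = 0.8, bulge = 0.6, asym = 0.15,
                        tooth_id = 1L) {
  stopifnot(width > 0, depth > 0, crown_height > 0, root_length > 0,
            cusp_amp >= 0, tooth_id >= 1)
  structure(list(center = center, a = width / 2, b = depth / 2,
                 hc = crown_height, lr = root_length,
                 cusp_amp = cusp_amp, n_cusps = n_cusps, p = se_power,
                 q = root_power, rim = 0.65 * crown_height,
                 bulge = bulge, asym = asym,
                 tooth_id = as.integer(tooth_id)),
            class = "tooth_shape")
}

# superelliptic radial coordinate and azimuth of (x, y) in tooth-local frame
.tooth_rho <- function(shape, x, y) {
  dx <- x - shape$center[1]
  dy <- y - shape$center[2]
  rho <- ((abs(dx) / shape$a)^shape$p +
            (abs(dy) / shape$b)^shape$p)^(1 / shape$p)
  theta <- atan2(dy / shape$b, dx / shape$a)
  list(rho = rho, theta = theta)
}

# occlusal dome height over (rho, theta); valid for rho <= 1
.tooth_dome <- function(shape, rho, theta) {
  shape$hc * (1 - 0.35 * rho^2) +
    shape$cusp_amp * cos(shape$n_cusps * theta) * 4 * rho^2 * (1 - rho^2) -
    shape$asym * shape$hc * sin(theta) * 2 * rho * (1 - rho^2)
}

#' Laser height-field of a tooth (crown-only analog), vectorized
#' @param shape a [tooth_shape].
#' @param x,y coordinates in the arch plane, mm.
#' @return surface height z in mm (unbounded negative far from the tooth).
#' @export
tooth_height <- function(shape, x, y) {
  rt <- .tooth_rho(shape, x, y)
  rho <- rt$rho
  h <- .tooth_dome(shape, pmin(rho, 1), rt$theta)
  rw <- shape$bulge / max(shape$a, shape$b)
  wall <- rho > 1 & rho <= 1 + rw
  u <- (rho[wall] - 1) / rw
  h[wall] <- shape$rim * (1 - u^2)        # quadratic emergence profile
  beyond <- rho > 1 + rw
  slope_end <- 2 * shape$rim / rw         # wall slope at the cervix, per rho
  h[beyond] <- -slope_end * (rho[beyond] - (1 + rw))
  h
}

#' Solid inside-test of a tooth (CT analog), vectorized
#' @param shape a [tooth_shape].
#' @param x,y,z mm coordinates (laser/anatomy frame).
#' @return logical vector.
#' @export
tooth_inside <- function(shape, x, y, z) {
  rt <- .tooth_rho(shape, x, y)
  rho <- rt$rho
  inside <- rep(FALSE, length(rho))
  low <- z <= 0 & z >= -shape$lr
  if (any(low)) {
    s <- ((z[low] + shape$lr) / shape$lr)^shape$q
    inside[low] <- rho[low] <= s
  }
  rw <- shape$bulge / max(shape$a, shape$b)
  lo_wall <- z > 0 & z < shape$rim
  if (any(lo_wall))
    inside[lo_wall] <- rho[lo_wall] <= 1 + rw * sqrt(1 - z[lo_wall] / shape$rim)
  up <- z >= shape$rim
  if (any(up))
    inside[up] <- rho[up] <= 1 &
      z[up] <= .tooth_dome(shape, rho[up], rt$theta[up])
  inside
}

#' Synthetic multi-tooth phantom scene
#'
#' A row of teeth along the x axis with a configurable inter-tooth gap
#' (which may be <= 0 for crowded arches), a gingiva floor, a ground-truth
#' rigid modality transform between the CT frame and the laser frame, and
#' noise settings matching the two modalities. All randomness (per-tooth
#' size variation, modality pose) derives from `seed`.
#'
#' @param n_teeth number of teeth (default 3).
#' @param seed integer seed; drives every random element of the scene.
#' @param gap inter-tooth gap in mm (default 0.3).
#' @param tooth_width,tooth_depth,crown_height,root_length nominal tooth
#'   dimensions in mm (each tooth varies by +-5 %).
#' @param cusp_amp,n_cusps occlusal cusp geometry.
#' @param gingiva_z gingiva floor level, mm (default -0.8).
#' @param gingiva_slope_deg slope of the gingival collar that rises from the
#'   floor to meet each tooth exactly at its cervix line (default 20); the
#'   crown/gingiva junction is therefore a concave crease at the margin, as
#'   on real intraoral scans.
#' @param modality_rotation_deg rotation magnitude of the CT-to-laser
#'   transform; drawn uniformly in (4, 8) degrees when NULL (default).
#' @param modality_translation_mm translation magnitude cap, mm (default 2).
#' @param ct_noise_sd CT additive Gaussian noise sd (intensity units; teeth
#'   are 1000, background 0; default 30).
#' @param ct_blur_mm CT Gaussian blur sigma in mm (default 0.1).
#' @param laser_jitter laser vertex jitter sd in mm (default 0.005).
#' @return a list of class `phantom_scene` with `teeth` (list of
#'   [tooth_shape]), `modality` ([rigid_transform], CT frame -> laser frame),
#'   noise settings and `seed`.
#' @export
phantom_scene <- function(n_teeth = 3, seed = 1, gap = 0.3,
                          tooth_width = 4, tooth_depth = 3.5,
                          crown_height = 3.5, root_length = 7,
                          cusp_amp = 0.3, n_cusps = 4, gingiva_z = -0.8,
                          gingiva_slope_deg = 20,
                          modality_rotation_deg = NULL,
                          modality_translation_mm = 2,
                          ct_noise_sd = 30, ct_blur_mm = 0.1,
                          laser_jitter = 0.005) {
  .with_seed(seed, function() {
    sizes <- stats::runif(n_teeth, 0.95, 1.05)
    widths <- tooth_width * sizes
    bulge <- 0.6
    # gap is the clearance between the crowns at their widest (the cervical
    # bulge), so centre spacing adds the bulge of both neighbours
    xs <- cumsum(c(0, (widths[-n_teeth] + widths[-1]) / 2 + 2 * bulge + gap))
    xs <- xs - mean(xs)
    teeth <- lapply(seq_len(n_teeth), function(i) {
      tooth_shape(center = c(xs[i], 0), width = widths[i],
                  depth = tooth_depth * sizes[i],
                  crown_height = crown_height * sizes[i],
                  root_length = root_length * sizes[i],
                  cusp_amp = cusp_amp, n_cusps = n_cusps, bulge = bulge,
                  tooth_id = i)
    })
    ang <- if (is.null(modality_rotation_deg))
      stats::runif(1, 4, 8) else modality_rotation_deg
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    R <- .axis_angle(ax, ang * pi / 180)
    t <- stats::runif(3, -modality_translation_mm, modality_translation_mm)
    structure(list(teeth = teeth, gap = gap, gingiva_z = gingiva_z,
                   gingiva_slope_deg = gingiva_slope_deg,
                   modality = rigid_transform(R, t),
                   ct_noise_sd = ct_noise_sd, ct_blur_mm = ct_blur_mm,
                   laser_jitter = laser_jitter, seed = seed),
              class = "phantom_scene")
  })
}

.axis_angle <- function(axis, angle) {
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c0 <- cos(angle); s <- sin(angle); C <- 1 - c0
  matrix(c(x*x*C + c0,   x*y*C - z*s, x*z*C + y*s,
           y*x*C + z*s,  y*y*C + c0,  y*z*C - x*s,
           z*x*C - y*s,  z*y*C + x*s, z*z*C + c0), 3, 3, byrow = TRUE)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "phantom_scene: %d teeth, gap %.2f mm, modality rotation %.2f deg, seed %d\n",
    length(x$teeth), x$gap, rotation_angle(x$modality), x$seed))
  invisible(x)
}

# arch height field: teeth plus a gingival collar that attaches to each
# tooth at its cervix line (local z = 0) and falls away at a gentle slope to
# the gingiva floor.  The crown/gingiva boundary is therefore a concave
# crease exactly at the label switch.  Labels: winning tooth when the tooth
# surface is above the gingiva, else 0.
.scene_height <- function(scene, x, y) {
  H <- vapply(scene$teeth, function(s) tooth_height(s, x, y),
              numeric(length(x)))
  if (is.null(dim(H))) H <- matrix(H, nrow = length(x))
  slope <- tan(scene$gingiva_slope_deg * pi / 180)
  G <- vapply(scene$teeth, function(s) {
    rt <- .tooth_rho(s, x, y)
    rm <- 1 + s$bulge / max(s$a, s$b)     # cervix line of the crown wall
    -slope * pmax(rt$rho - rm, 0) * max(s$a, s$b)
  }, numeric(length(x)))
  if (is.null(dim(G))) G <- matrix(G, nrow = length(x))
  g <- pmax(apply(G, 1, max), scene$gingiva_z)
  win <- max.col(H, ties.method = "first")
  hmax <- H[cbind(seq_along(x), win)]
  tooth_wins <- hmax >= g
  z <- pmax(hmax, g)
  label <- ifelse(tooth_wins, vapply(scene$teeth, `[[`,
                                     integer(1), "tooth_id")[win], 0L)
  list(z = z, label = as.integer(label))
}

#' Sample the laser-analog arch surface mesh
#'
#' Triangulates the scene's crown-and-gingiva height field on a regular grid
#' at the scanner pitch (default 0.05 mm, the resolution of intraoral
#' scans), adds Gaussian vertex jitter along z, and returns the mesh with
#' ground-truth per-face crown labels (tooth id above the cervix, 0 on
#' gingiva).
#'
#' @param scene a [phantom_scene].
#' @param pitch grid spacing in mm (default 0.05).
#' @param jitter_sd vertex jitter sd in mm; default the scene's setting.
#' @param margin extra border around the teeth, mm (default 1).
#' @param grid_angle_deg rotation of the sampling lattice relative to the
#'   arch axis, degrees (default 0); a scanner's lattice has no anatomical
#'   alignment, so tests may exercise oblique sampling.
#' @param seed jitter seed; default derived from the scene seed.
#' @return list with `mesh` (a [tooth_mesh]), `labels` (integer per face,
#'   the ground-truth `crown_labeling`), `grid` (x/y vectors).
#' @export
sample_laser_mesh <- function(scene, pitch = 0.05,
                              jitter_sd = scene$laser_jitter, margin = 1,
                              grid_angle_deg = 0,
                              seed = scene$seed + 1L) {
  stopifnot(inherits(scene, "phantom_scene"), pitch > 0)
  cen <- t(vapply(scene$teeth, `[[`, numeric(2), "center"))
  bl <- max(vapply(scene$teeth, `[[`, numeric(1), "bulge"))
  amax <- max(vapply(scene$teeth, `[[`, numeric(1), "a")) + bl
  bmax <- max(vapply(scene$teeth, `[[`, numeric(1), "b")) + bl
  if (pitch > min(vapply(scene$teeth, `[[`, numeric(1), "a")))
    stop("pitch larger than the tooth size")
  phi <- grid_angle_deg * pi / 180
  xr <- c(min(cen[, 1]) - amax - margin, max(cen[, 1]) + amax + margin)
  yr <- c(min(cen[, 2]) - bmax - margin, max(cen[, 2]) + bmax + margin)
  # lattice bounds covering the rotated region
  corners <- cbind(c(xr[1], xr[2], xr[1], xr[2]), c(yr[1], yr[1], yr[2], yr[2]))
  uc <- corners[, 1] * cos(phi) + corners[, 2] * sin(phi)
  vc <- -corners[, 1] * sin(phi) + corners[, 2] * cos(phi)
  xs <- seq(min(uc), max(uc), by = pitch)
  ys <- seq(min(vc), max(vc), by = pitch)
  nx <- length(xs); ny <- length(ys)
  gu <- rep(xs, times = ny)
  gv <- rep(ys, each = nx)
  gx <- gu * cos(phi) - gv * sin(phi)
  gy <- gu * sin(phi) + gv * cos(phi)
  sh <- .scene_height(scene, gx, gy)
  z <- sh$z
  if (jitter_sd > 0)
    z <- z + .with_seed(seed, function() stats::rnorm(length(z), 0, jitter_sd))
  V <- cbind(gx, gy, z)
  # two consistently wound (upward) triangles per grid cell
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  F <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  mesh <- structure(list(vertices = V, faces = F), class = "tooth_mesh")
  cx <- (V[F[, 1], 1] + V[F[, 2], 1] + V[F[, 3], 1]) / 3
  cy <- (V[F[, 1], 2] + V[F[, 2], 2] + V[F[, 3], 2]) / 3
  labels <- .scene_height(scene, cx, cy)$label
  list(mesh = mesh, labels = labels, grid = list(x = xs, y = ys))
}

#' Voxelize the phantom into a CT-analog volume
#'
#' Builds the CT-frame voxel grid covering the (rigidly displaced) teeth,
#' fills tooth voxels with intensity 1000 on a 0 background from the
#' analytic solid, applies Gaussian blur and additive Gaussian noise, and
#' returns the ground-truth per-voxel label volume alongside.
#'
#' @param scene a [phantom_scene].
#' @param voxel voxel size in mm (default 0.125, CBCT-like).
#' @param noise_sd,blur_sigma noise / blur overrides (defaults from scene;
#'   blur in mm).
#' @param margin border in mm (default 0.8).
#' @param seed noise seed; default derived from the scene seed.
#' @return list with `volume` (a [voxel_volume] in the CT frame), `labels`
#'   (integer array, 0 background), `tooth_intensity` (1000).
#' @export
voxelize_ct <- function(scene, voxel = 0.125, noise_sd = scene$ct_noise_sd,
                        blur_sigma = scene$ct_blur_mm, margin = 0.8,
                        seed = scene$seed + 2L) {
  stopifnot(inherits(scene, "phantom_scene"), voxel > 0)
  cen <- t(vapply(scene$teeth, `[[`, numeric(2), "center"))
  bl <- max(vapply(scene$teeth, `[[`, numeric(1), "bulge"))
  amax <- max(vapply(scene$teeth, `[[`, numeric(1), "a")) + bl
  bmax <- max(vapply(scene$teeth, `[[`, numeric(1), "b")) + bl
  hmax <- max(vapply(scene$teeth, `[[`, numeric(1), "hc"))
  lmax <- max(vapply(scene$teeth, `[[`, numeric(1), "lr"))
  # laser-frame bbox corners -> CT frame
  bb <- rbind(c(min(cen[, 1]) - amax, min(cen[, 2]) - bmax, -lmax),
              c(max(cen[, 1]) + amax, max(cen[, 2]) + bmax, hmax))
  corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
  inv <- invert_transform(scene$modality)
  cct <- apply_transform(corners, inv)
  lo <- apply(cct, 2, min) - margin
  hi <- apply(cct, 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / voxel), 2)
  xs <- lo[1] + (seq_len(dims[1]) - 0.5) * voxel
  ys <- lo[2] + (seq_len(dims[2]) - 0.5) * voxel
  zs <- lo[3] + (seq_len(dims[3]) - 0.5) * voxel
  labels <- array(0L, dims)
  # slice-wise to bound memory
  for (k in seq_len(dims[3])) {
    g <- cbind(rep(xs, times = dims[2]), rep(ys, each = dims[1]), zs[k])
    gl <- apply_transform(g, scene$modality)
    lab <- integer(nrow(g))
    for (s in scene$teeth) {
      hit <- tooth_inside(s, gl[, 1], gl[, 2], gl[, 3])
      lab[hit] <- s$tooth_id
    }
    labels[, , k] <- lab
  }
  intensity <- array(1000 * (labels > 0), dims)
  if (blur_sigma > 0)
    intensity <- .gauss_blur3d_cpp(intensity, dims,
                                   rep(blur_sigma / voxel, 3))
  if (noise_sd > 0)
    intensity <- intensity +
      .with_seed(seed, function() array(stats::rnorm(prod(dims), 0, noise_sd),
                                        dims))
  list(volume = voxel_volume(intensity, voxel, origin = lo),
       labels = labels, tooth_intensity = 1000)
}

#' Ground truth bundle of a phantom scene
#'
#' Everything an end-to-end validation compares against: the modality
#' transform (CT frame -> laser frame) and its inverse, per-tooth laser seed
#' points (crown tips), and the tooth list.
#'
#' @param scene a [phantom_scene].
#' @return list with `modality_transform`, `inverse_transform`,
#'   `laser_seeds` ([seed_points], mm), `tooth_ids`.
#' @export
scene_ground_truth <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  cen <- t(vapply(scene$teeth, `[[`, numeric(2), "center"))
  ids <- vapply(scene$teeth, `[[`, integer(1), "tooth_id")
  hc <- vapply(scene$teeth, `[[`, numeric(1), "hc")
  list(modality_transform = scene$modality,
       inverse_transform = invert_transform(scene$modality),
       laser_seeds = seed_points(ids, cen[, 1], cen[, 2], hc),
       tooth_ids = ids)
}

#' CT starting slice and per-tooth seed pixels for a phantom volume
#'
#' Picks a starting slice through the crowns (local height 0.45 of the crown
#' height on each tooth axis, mapped into the CT frame) and returns the
#' per-tooth seed pixel coordinates on that slice.
#'
#' @param scene a [phantom_scene].
#' @param volume the [voxel_volume] from [voxelize_ct].
#' @return list with `start_slice` and `seeds` (a [seed_points] data frame,
#'   x/y in pixels).
#' @export
phantom_ct_seeds <- function(scene, volume) {
  inv <- invert_transform(scene$modality)
  pts <- t(vapply(scene$teeth, function(s)
    c(s$center, 0.45 * s$hc), numeric(3)))
  pct <- apply_transform(pts, inv)
  idx <- sweep(sweep(pct, 2, volume$origin), 2, volume$voxel_size, "/") + 0.5
  k <- round(mean(idx[, 3]))
  # re-solve each tooth's axis point at that slice height
  zk <- volume$origin[3] + (k - 0.5) * volume$voxel_size[3]
  seeds <- t(vapply(seq_along(scene$teeth), function(i) {
    s <- scene$teeth[[i]]
    # tooth axis in CT frame: p(t) = inv(center_x, center_y, t)
    p0 <- apply_transform(rbind(c(s$center, 0)), inv)
    p1 <- apply_transform(rbind(c(s$center, 1)), inv)
    dz <- p1[3] - p0[3]
    t0 <- if (abs(dz) > 1e-9) (zk - p0[3]) / dz else 0.45 * s$hc
    t0 <- min(max(t0, 0.1 * s$hc), 0.8 * s$hc)
    p <- p0 + t0 * (p1 - p0)
    (p[1:2] - volume$origin[1:2]) / volume$voxel_size[1:2] + 0.5
  }, numeric(2)))
  list(start_slice = as.integer(k),
       seeds = seed_points(vapply(scene$teeth, `[[`, integer(1), "tooth_id"),
                           seeds[, 1], seeds[, 2]))
}

#' True crown surface mesh of one phantom tooth
#'
#' The analytic (jitter-free) crown surface of a single tooth sampled at the
#' given pitch — the reference surface for accuracy evaluation.
#'
#' @param scene a [phantom_scene].
#' @param tooth_id which tooth.
#' @param pitch sampling pitch in mm (default 0.05).
#' @return a [tooth_mesh].
#' @export
true_crown_mesh <- function(scene, tooth_id, pitch = 0.05) {
  lm <- sample_laser_mesh(scene, pitch = pitch, jitter_sd = 0)
  keep <- which(lm$labels == tooth_id)
  if (!length(keep)) stop("no faces for tooth ", tooth_id)
  submesh(lm$mesh, keep)
}
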