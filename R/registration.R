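#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t translation 3-vector in mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("R is not orthonormal")
  if (abs(det(R) - 1) > 1e-9)
    stop("R is not a proper rotation (det != +1)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rotation %.4f deg, translation %.4f mm\n",
              rotation_angle(x), sqrt(sum(x$t^2))))
  invisible(x)
}

#' Rotation angle of a rigid transform, in degrees
#' @param transform a [rigid_transform].
#' @return angle in degrees.
#' @export
rotation_angle <- function(transform) {
  tr <- sum(diag(transform$R))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

#' Apply a rigid transform to points or a mesh
#' @param x n x 3 point matrix or a [tooth_mesh].
#' @param transform a [rigid_transform].
#' @return transformed points / mesh.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "tooth_mesh")) {
    x$vertices <- apply_transform(x$vertices, transform)
    return(x)
  }
  sweep(as.matrix(x) %*% t(transform$R), 2, -transform$t)
}

#' Compose two rigid transforms: `compose(b, a)` applies `a` first.
#' @param b,a [rigid_transform] objects.
#' @return the composed [rigid_transform].
#' @export
compose_transform <- function(b, a) {
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$t) + b$t)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform].
#' @return the inverse [rigid_transform].
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$R), -as.numeric(t(transform$R) %*% transform$t))
}

#' Serialize / read a rigid transform as a 4x4 homogeneous JSON matrix
#' @param transform a [rigid_transform].
#' @param path JSON path.
#' @return `path` invisibly / the read [rigid_transform].
#' @export
write_transform_json <- function(transform, path) {
  M <- rbind(cbind(transform$R, transform$t), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = M), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  M <- jsonlite::fromJSON(path)$matrix
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}

#' Principal-axes frame of a point cloud
#'
#' Covariance matrix, eigenvector frame (columns ordered by descending
#' eigenvalue) and centroid — the body-fitted coordinate system used by the
#' coarse registration. Eigenvector signs are fixed deterministically: each
#' axis is oriented so the point cloud's third moment (skewness) along it is
#' positive — a sign that survives subsampling, unlike the single farthest
#' point, which is used only as a fallback for symmetric clouds; if the
#' resulting frame is left-handed its last column is flipped.
#'
#' @param P n x 3 point matrix (n >= 4, non-coplanar).
#' @param ambiguity_tol relative eigenvalue-gap tolerance below which the
#'   frame is declared ambiguous (default 1e-9).
#' @return an object of class `pca_frame`: list with `covariance`,
#'   `eigenvectors`, `eigenvalues`, `centroid`.
#' @export
pca_frame <- function(P, ambiguity_tol = 1e-9) {
  P <- as.matrix(P)
  if (nrow(P) < 4) stop("need at least 4 points")
  centroid <- colMeans(P)
  X <- sweep(P, 2, centroid)
  CM <- crossprod(X) / nrow(P)
  e <- eigen(CM, symmetric = TRUE)
  ev <- e$values               # already descending
  if (ev[1] <= 0) stop("degenerate point set: zero covariance")
  rel <- ev / ev[1]
  if (rel[3] < 1e-12)
    stop("degenerate covariance: points are coplanar (axis 3 rank-deficient)")
  gaps <- (ev[1:2] - ev[2:3]) / ev[1]
  if (any(gaps < ambiguity_tol)) {
    ax <- which(gaps < ambiguity_tol)[1]
    stop(sprintf(
      "ambiguous principal axes: eigenvalues %d and %d coincide", ax, ax + 1))
  }
  EM <- e$vectors
  d2 <- rowSums(X^2)
  far <- X[which.max(d2), ]
  scale3 <- mean(d2)^1.5
  for (k in 1:3) {
    skew <- mean(as.numeric(X %*% EM[, k])^3)
    s <- if (abs(skew) > 1e-9 * scale3) skew else sum(EM[, k] * far)
    if (s < 0) EM[, k] <- -EM[, k]
  }
  if (det(EM) < 0) EM[, 3] <- -EM[, 3]
  structure(list(covariance = CM, eigenvectors = EM, eigenvalues = ev,
                 centroid = centroid),
            class = "pca_frame")
}

#' Coarse rigid registration by principal component analysis
#'
#' Aligns the body-fitted eigenvector frames of the two clouds:
#' `R1 = EM_fixed %*% solve(EM_moving)` and
#' `t1 = centroid(fixed) - R1 %*% centroid(moving)`. The moving cloud is the
#' CT crown; the fixed cloud is the laser crown, which is never moved.
#'
#' @param P_ct moving point cloud (CT crown vertices), n x 3 mm.
#' @param P_laser fixed point cloud (laser crown vertices), n x 3 mm.
#' @param ambiguity_tol see [pca_frame].
#' @return a [rigid_transform] mapping `P_ct` onto `P_laser`.
#' @export
pca_coarse_register <- function(P_ct, P_laser, ambiguity_tol = 1e-9) {
  f_ct <- pca_frame(P_ct, ambiguity_tol)
  f_laser <- pca_frame(P_laser, ambiguity_tol)
  R1 <- f_laser$eigenvectors %*% solve(f_ct$eigenvectors)
  t1 <- f_laser$centroid - as.numeric(R1 %*% f_ct$centroid)
  rigid_transform(R1, t1)
}

# closed-form least-squares rigid fit (Horn's quaternion method)
.quaternion_fit <- function(P, Q) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  S <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
  t <- qc - as.numeric(R %*% pc)
  rigid_transform(R, t)
}

#' Fine rigid registration by iterative closest point (ICP)
#'
#' Classical point-to-point ICP with kd-tree nearest-neighbour
#' correspondences and the closed-form quaternion rigid fit. After each
#' applied transform the registration error `E_C = mean(D_ij^2)` (MSE of
#' nearest-neighbour distances, mm^2) is recorded; iteration stops when
#' `E_C < E_th` or after `max_iter` iterations (then `converged` is FALSE —
#' not an error). `E_C` is non-increasing across iterations.
#'
#' @param P_cct moving cloud (coarsely registered CT crown vertices), n x 3.
#' @param P_laser fixed cloud (laser crown vertices), n x 3.
#' @param E_th convergence threshold on the MSE, mm^2 (default 1e-4).
#' @param max_iter maximum iterations (default 100).
#' @param trim optional fraction in (0, 1): drop this fraction of the worst
#'   correspondences from each fit (partial-overlap robustness; default NULL,
#'   plain nearest-neighbour as in classical ICP).
#' @return list with `transform` (cumulative [rigid_transform]), `trace`
#'   (class `icp_trace`: data frame iteration / E_C / M), `converged`, `E_C`.
#' @export
icp_fine_register <- function(P_cct, P_laser, E_th = 1e-4, max_iter = 100,
                              trim = NULL) {
  P_cct <- as.matrix(P_cct)
  P_laser <- as.matrix(P_laser)
  if (nrow(P_cct) == 0 || nrow(P_laser) == 0) stop("empty point set")
  M <- nrow(P_cct)
  cur <- P_cct
  total <- rigid_transform()
  trace <- data.frame(iteration = integer(0), E_C = numeric(0),
                      M = integer(0))
  nn <- RANN::nn2(P_laser, cur, k = 1)
  E_C <- mean(nn$nn.dists^2)
  converged <- E_C < E_th
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    match <- P_laser[nn$nn.idx[, 1], , drop = FALSE]
    if (!is.null(trim) && trim > 0) {
      keep <- nn$nn.dists[, 1] <= stats::quantile(nn$nn.dists[, 1], 1 - trim)
      step <- .quaternion_fit(cur[keep, , drop = FALSE],
                              match[keep, , drop = FALSE])
    } else {
      step <- .quaternion_fit(cur, match)
    }
    cur <- apply_transform(cur, step)
    total <- compose_transform(step, total)
    nn <- RANN::nn2(P_laser, cur, k = 1)
    E_new <- mean(nn$nn.dists^2)
    trace <- rbind(trace,
                   data.frame(iteration = iter, E_C = E_new, M = M))
    if (E_new < E_th) {
      converged <- TRUE
    } else if (E_C - E_new < 1e-15 * (1 + E_C)) {
      break  # stalled below machine precision
    }
    E_C <- E_new
  }
  E_C <- if (nrow(trace)) trace$E_C[nrow(trace)] else E_C
  class(trace) <- c("icp_trace", "data.frame")
  list(transform = total, trace = trace, converged = converged, E_C = E_C)
}

#' Section a tooth mesh with a plane
#'
#' Keeps the part of the mesh on the positive side of the plane (the side the
#' normal points to), clipping crossing triangles at the plane. Used to cut
#' the crown portion off a CT tooth model before registration, and the root
#' portion (flip the normal) before fusion.
#'
#' @param mesh a [tooth_mesh].
#' @param point a point on the plane (mm).
#' @param normal plane normal; the kept side.
#' @return the clipped [tooth_mesh].
#' @export
section_crown <- function(mesh, point, normal) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  normal <- normal / sqrt(sum(normal^2))
  V <- mesh$vertices
  F <- mesh$faces
  d <- as.numeric(sweep(V, 2, point) %*% normal)
  side <- d >= 0
  ns <- rowSums(matrix(side[F], ncol = 3))
  if (all(ns == 0L)) stop("plane leaves no mesh on the kept side")
  if (all(ns == 3L)) return(mesh)
  keepV <- list(V)
  newF <- list(F[ns == 3L, , drop = FALSE])
  nV <- nrow(V)
  addV <- list()
  cut <- which(ns == 1L | ns == 2L)
  for (fi in cut) {
    idx <- F[fi, ]
    dv <- d[idx]
    # rotate so the triangle starts on a kept vertex
    while (dv[1] < 0) {
      idx <- idx[c(2, 3, 1)]
      dv <- dv[c(2, 3, 1)]
    }
    interp <- function(i, j) {
      t <- dv[i] / (dv[i] - dv[j])
      V[idx[i], ] + t * (V[idx[j], ] - V[idx[i], ])
    }
    if (ns[fi] == 1L) {       # one vertex kept: single clipped triangle
      # order so vertices 2,3 are dropped
      if (dv[2] >= 0) { idx <- idx[c(2, 3, 1)]; dv <- dv[c(2, 3, 1)] }
      if (dv[2] >= 0) { idx <- idx[c(2, 3, 1)]; dv <- dv[c(2, 3, 1)] }
      a <- interp(1, 2)
      b <- interp(1, 3)
      addV <- c(addV, list(a, b))
      newF <- c(newF, list(matrix(c(idx[1], nV + length(addV) - 1L,
                                    nV + length(addV)), 1)))
    } else {                  # two vertices kept: clipped quad -> 2 triangles
      if (dv[2] < 0) { idx <- idx[c(3, 1, 2)]; dv <- dv[c(3, 1, 2)] }
      # now vertices 1,2 kept, 3 dropped
      a <- interp(2, 3)
      b <- interp(1, 3)
      addV <- c(addV, list(a, b))
      ia <- nV + length(addV) - 1L
      ib <- nV + length(addV)
      newF <- c(newF, list(matrix(c(idx[1], idx[2], ia,
                                    idx[1], ia, ib), 2, byrow = TRUE)))
    }
  }
  Vall <- rbind(V, do.call(rbind, addV))
  Fall <- do.call(rbind, newF)
  tooth_mesh(Vall, Fall, weld = TRUE, weld_tol = 1e-9, orient = FALSE)
}

#' Register a CT tooth model to a laser crown model
#'
#' The full registration stage: the CT tooth is sectioned with a plane to
#' keep its crown portion, coarsely aligned to the (fixed) laser crown by
#' [pca_coarse_register], and refined by [icp_fine_register]. Returns the
#' composed transform that maps the original CT tooth into the laser frame.
#'
#' @param ct_tooth CT tooth [tooth_mesh] (complete crown + root).
#' @param laser_crown laser crown [tooth_mesh]; held fixed.
#' @param crown_axis approximate crown-up direction in the CT frame, used to
#'   orient the sectioning axis (default +z).
#' @param plane optional list(point, normal) overriding the automatic
#'   sectioning plane (normal pointing to the crown side).
#' @param plane_offset lift of the automatic plane toward the crown, mm
#'   (default 0.3): keeps the sectioned CT part inside the region the laser
#'   scan also covers, so ICP is not pulled by one-sided geometry.
#' @param E_th,max_iter,trim ICP parameters, see [icp_fine_register].
#' @param max_points vertex subsample cap per cloud for the ICP (evenly
#'   spaced, deterministic; default 3000).
#' @return list with `transform` ([rigid_transform] CT -> laser), `coarse`,
#'   `fine`, `trace`, `converged`, `ct_crown` (the sectioned crown mesh).
#' @export
register_crowns <- function(ct_tooth, laser_crown, crown_axis = c(0, 0, 1),
                            plane = NULL, E_th = 1e-4, max_iter = 100,
                            trim = NULL, max_points = 3000,
                            multi_start = TRUE, plane_offset = 0.3) {
  stopifnot(inherits(ct_tooth, "tooth_mesh"),
            inherits(laser_crown, "tooth_mesh"))
  if (is.null(plane)) {
    plane <- crown_plane(ct_tooth, crown_axis)
    plane$point <- plane$point + plane_offset * plane$normal
  }
  crown <- section_crown(ct_tooth, plane$point, plane$normal)
  sub <- function(P, cap) {
    if (nrow(P) <= cap) return(P)
    P[round(seq(1, nrow(P), length.out = cap)), , drop = FALSE]
  }
  P_ct <- sub(crown$vertices, max_points)
  P_laser <- sub(laser_crown$vertices, max_points)
  coarse <- pca_coarse_register(P_ct, P_laser)
  if (multi_start) {
    # The two clouds cover different parts of the crown, so their principal
    # axes can come out permuted or flipped relative to each other.  Try the
    # 24 proper axis relabelings of the CT frame, score each with a few ICP
    # iterations on a small subsample, and keep the best coarse start.
    f_ct <- pca_frame(P_ct)
    f_laser <- pca_frame(P_laser)
    Pq <- sub(P_ct, 600L)
    Lq <- sub(P_laser, 600L)
    best <- NULL
    for (D in .proper_axis_relabelings()) {
      R1 <- f_laser$eigenvectors %*% D %*% t(f_ct$eigenvectors)
      t1 <- f_laser$centroid - as.numeric(R1 %*% f_ct$centroid)
      cand <- rigid_transform(R1, t1)
      probe <- icp_fine_register(apply_transform(Pq, cand), Lq,
                                 E_th = 0, max_iter = 10, trim = trim)
      # two-way error: a directed score alone favours false optima where one
      # cloud nests inside a subset of the other
      moved <- apply_transform(apply_transform(Pq, cand), probe$transform)
      score <- mean(RANN::nn2(Lq, moved, k = 1)$nn.dists^2) +
        mean(RANN::nn2(moved, Lq, k = 1)$nn.dists^2)
      if (is.null(best) || score < best$score)
        best <- list(coarse = cand, score = score)
    }
    coarse <- best$coarse
  }
  fine <- icp_fine_register(apply_transform(P_ct, coarse), P_laser,
                            E_th = E_th, max_iter = max_iter, trim = trim)
  total <- compose_transform(fine$transform, coarse)
  list(transform = total, coarse = coarse, fine = fine$transform,
       trace = fine$trace, converged = fine$converged, E_C = fine$E_C,
       ct_crown = crown, plane = plane)
}

# the 24 rotation matrices permuting/flipping coordinate axes (det +1)
.proper_axis_relabelings <- function() {
  out <- list()
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    Pm <- diag(3)[, p]
    for (s in 0:7) {
      D <- Pm %*% diag(c(ifelse(bitwAnd(s, 1L) > 0, -1, 1),
                         ifelse(bitwAnd(s, 2L) > 0, -1, 1),
                         ifelse(bitwAnd(s, 4L) > 0, -1, 1)))
      if (abs(det(D) - 1) < 1e-12) out[[length(out) + 1L]] <- D
    }
  }
  out
}

#' Automatic crown sectioning plane for a CT tooth
#'
#' Plane perpendicular to the tooth's principal axis, placed at the axial
#' position where the cross-sectional area (convex-hull area of thin slabs)
#' is maximal — a proxy for the cervical bulge. Among slabs within 1% of the
#' maximal area the one lowest along the crown direction is chosen, so the
#' kept (positive) side is the whole anatomical crown.
#'
#' @param mesh the CT tooth [tooth_mesh].
#' @param crown_axis approximate crown-up direction (default +z).
#' @param n_slabs number of slabs along the axis (default 40).
#' @return list with `point` and `normal` (pointing to the crown side).
#' @export
crown_plane <- function(mesh, crown_axis = c(0, 0, 1), n_slabs = 40) {
  V <- mesh$vertices
  ax <- eigen(stats::cov(V), symmetric = TRUE)$vectors[, 1]
  if (sum(ax * crown_axis) < 0) ax <- -ax
  # in-plane basis
  u <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- u - sum(u * ax) * ax
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(ax[2] * b1[3] - ax[3] * b1[2],
          ax[3] * b1[1] - ax[1] * b1[3],
          ax[1] * b1[2] - ax[2] * b1[1])
  h <- as.numeric(V %*% ax)
  br <- range(h)
  edges <- seq(br[1], br[2], length.out = n_slabs + 1)
  slab <- cut(h, edges, include.lowest = TRUE, labels = FALSE)
  area <- vapply(seq_len(n_slabs), function(k) {
    P <- cbind(as.numeric(V %*% b1), as.numeric(V %*% b2))[slab == k, ,
                                                           drop = FALSE]
    if (nrow(P) < 3) return(0)
    ch <- grDevices::chull(P)
    Q <- P[ch, , drop = FALSE]
    abs(sum(Q[, 1] * Q[c(2:nrow(Q), 1), 2] -
              Q[c(2:nrow(Q), 1), 1] * Q[, 2])) / 2
  }, numeric(1))
  best <- which(area >= 0.99 * max(area))[1]
  h0 <- (edges[best] + edges[best + 1]) / 2
  centroid <- colMeans(V)
  point <- centroid + (h0 - sum(centroid * ax)) * ax
  list(point = point, normal = ax)
}
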