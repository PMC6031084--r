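# Shared geometric fixtures and independent oracles, all built in code.

# near-uniform sphere sampling (Fibonacci spiral)
fib_sphere <- function(n, r = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  r * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

# closed sphere mesh: DBRG growth over the Delaunay facets of a Fibonacci
# sampling (verified closed in the fusion tests)
sphere_mesh <- function(n = 500, r = 1) {
  P <- fib_sphere(n, r)
  cand <- delaunay_candidates(P)
  res <- toothfusion:::.dbrg_cpp(P, unclass(cand),
                                 toothfusion:::.local_spacing(P))
  m <- tooth_mesh(P, res$faces, weld = FALSE, orient = TRUE)
  m
}

# faces of a DBRG resurfacing of a bare point set (test harness)
dbrg_resurface_faces <- function(P) {
  cand <- delaunay_candidates(P)
  toothfusion:::.dbrg_cpp(P, unclass(cand),
                          toothfusion:::.local_spacing(P))$faces
}

# orient an open mesh "outward" from the origin (test harness convenience)
orient_outward <- function(m) {
  N <- vertex_normals(m)
  if (sum(N * m$vertices) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# small double-bump crown phantom: two smooth bumps on a plate separated by
# a deep concave groove, with analytic ground-truth labels
two_bump_mesh <- function(pitch = 0.15, sep = 4, rad = 1.8, height = 1.6) {
  xs <- seq(-sep / 2 - rad - 1, sep / 2 + rad + 1, by = pitch)
  ys <- seq(-rad - 1, rad + 1, by = pitch)
  nx <- length(xs); ny <- length(ys)
  gx <- rep(xs, times = ny)
  gy <- rep(ys, each = nx)
  bump <- function(cx) {
    d2 <- (gx - cx)^2 + gy^2
    ifelse(d2 < rad^2, height * cos(pi / 2 * sqrt(d2) / rad)^1.5, 0)
  }
  h1 <- bump(-sep / 2)
  h2 <- bump(sep / 2)
  z <- pmax(h1, h2)
  V <- cbind(gx, gy, z)
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  F <- rbind(cbind(v00, v00 + 1L, v00 + nx + 1L),
             cbind(v00, v00 + nx + 1L, v00 + nx))
  mesh <- structure(list(vertices = V, faces = F), class = "tooth_mesh")
  cx <- (V[F[, 1], 1] + V[F[, 2], 1] + V[F[, 3], 1]) / 3
  cy <- (V[F[, 1], 2] + V[F[, 2], 2] + V[F[, 3], 2]) / 3
  lab <- integer(nrow(F))
  lab[(cx + sep / 2)^2 + cy^2 < rad^2] <- 1L
  lab[(cx - sep / 2)^2 + cy^2 < rad^2] <- 2L
  list(mesh = mesh, labels = lab,
       seeds = seed_points(c(1L, 2L), c(-sep / 2, sep / 2), c(0, 0),
                           c(height, height)))
}

# brute-force Delaunay facets by empty-circumsphere enumeration (<= ~30 pts)
bf_delaunay_facets <- function(P, tol = 1e-9) {
  n <- nrow(P)
  keys <- character(0)
  cmb <- utils::combn(n, 4)
  for (i in seq_len(ncol(cmb))) {
    id <- cmb[, i]
    A <- P[id, ]
    M <- rbind(A[2, ] - A[1, ], A[3, ] - A[1, ], A[4, ] - A[1, ])
    if (abs(det(M)) < 1e-12) next
    u <- solve(M, 0.5 * rowSums(M^2))
    cen <- A[1, ] + u
    r2 <- sum(u^2)
    d2 <- rowSums(sweep(P, 2, cen)^2)
    d2[id] <- Inf
    if (all(d2 > r2 * (1 + tol))) {
      f <- utils::combn(sort(id), 3)
      keys <- c(keys, apply(f, 2, paste, collapse = "-"))
    }
  }
  sort(unique(keys))
}

facet_keys <- function(facets) {
  facets <- unclass(facets)
  sort(apply(facets, 1, function(r) paste(sort(r), collapse = "-")))
}

# independent point-to-triangle distance: plane projection with barycentric
# containment, else closed-form distances to the three segments
bf_point_tri_dist <- function(p, a, b, c) {
  n <- pracma::cross(b - a, c - a)
  nn <- sum(n^2)
  seg <- function(u, v) {
    t <- sum((p - u) * (v - u)) / sum((v - u)^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * (v - u)))^2))
  }
  d <- min(seg(a, b), seg(b, c), seg(c, a))
  if (nn > 1e-300) {
    q <- p - sum((p - a) * n) / nn * n
    # barycentric coordinates of q
    v0 <- b - a; v1 <- c - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) d <- min(d, sqrt(sum((p - q)^2)))
  }
  d
}

# independent priority-flood simulation (same admission rules, written
# separately from the C++ engine); small meshes only
bf_priority_flood <- function(mesh, hf, seed_faces, seed_labels, threshold,
                              init_labels = NULL) {
  nf <- nrow(mesh$faces)
  lab <- integer(nf)
  if (!is.null(init_labels)) lab <- as.integer(init_labels)
  lab[seed_faces] <- seed_labels
  ef <- hf$edge_faces
  queue <- data.frame(h = numeric(0), seq = numeric(0), lab = integer(0),
                      f = integer(0))
  seqno <- 0
  push <- function(face, label) {
    for (k in which(ef[, 1] == face | ef[, 2] == face)) {
      nb <- if (ef[k, 1] == face) ef[k, 2] else ef[k, 1]
      if (lab[nb] == 0) {
        seqno <<- seqno + 1
        queue[nrow(queue) + 1, ] <<- list(hf$H[k], seqno, label, nb)
      }
    }
  }
  for (f in which(lab != 0)) push(f, lab[f])
  while (nrow(queue) > 0) {
    o <- order(queue$h, queue$seq, queue$lab, queue$f)[1]
    top <- queue[o, ]
    queue <- queue[-o, ]
    if (lab[top$f] != 0) next
    if (top$h >= threshold) next
    lab[top$f] <- top$lab
    push(top$f, top$lab)
  }
  lab
}

rotation_about <- function(axis, deg) {
  toothfusion:::.axis_angle(axis / sqrt(sum(axis^2)), deg * pi / 180)
}
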