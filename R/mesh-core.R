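#' Indexed triangle mesh
#'
#' The central surface container of the package: an indexed triangle mesh in
#' millimetres, as produced by intraoral (laser) scanners in STL form, by the
#' CT reconstruction stage, and by the crown/root fusion stage. Construction
#' welds duplicate vertices (STL stores no connectivity), removes degenerate
#' faces, and makes face orientation consistent on each connected component.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per face, 1-based vertex indices.
#' @param weld logical; merge vertices closer than `weld_tol` (default TRUE).
#' @param weld_tol weld tolerance in mm. Vertices closer than this are merged
#'   (the first occurrence's coordinates are kept, so welding never moves a
#'   surviving vertex).
#' @param orient logical; make face winding consistent per component and turn
#'   closed components outward (positive enclosed volume).
#' @return An object of class `tooth_mesh`: a list with elements `vertices`
#'   (n x 3) and `faces` (m x 3).
#' @export
tooth_mesh <- function(vertices, faces, weld = TRUE, weld_tol = 1e-6,
                       orient = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (weld && nrow(vertices) > 1L) {
    rep_idx <- .weld_map(vertices, weld_tol)
    keep <- sort(unique(rep_idx))
    remap <- integer(nrow(vertices))
    remap[keep] <- seq_along(keep)
    vertices <- vertices[keep, , drop = FALSE]
    faces[] <- remap[rep_idx[faces]]
  }
  # drop degenerate faces (repeated vertex or ~zero area)
  dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(dup)) faces <- faces[!dup, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate")
  a <- .tri_areas(vertices, faces)
  scale <- max(apply(vertices, 2, function(v) diff(range(v))), 1e-12)
  tiny <- a < (1e-9 * scale)^2
  if (any(tiny)) faces <- faces[!tiny, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate")
  faces <- .drop_duplicate_faces(faces)
  if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate")
  # drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  if (length(used) < nrow(vertices)) {
    remap <- integer(nrow(vertices))
    remap[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    faces[] <- remap[faces]
  }
  if (orient) faces <- .orient_faces_cpp(vertices, faces)
  structure(list(vertices = vertices, faces = faces), class = "tooth_mesh")
}

# representative index per vertex after tolerance welding
.weld_map <- function(V, tol) {
  n <- nrow(V)
  rep_idx <- seq_len(n)
  if (tol <= 0) return(rep_idx)
  nn <- RANN::nn2(V, V, k = min(16L, n), searchtype = "radius", radius = tol)
  # union-find over close pairs
  find <- function(x) {
    while (rep_idx[x] != x) {
      rep_idx[x] <<- rep_idx[rep_idx[x]]
      x <- rep_idx[x]
    }
    x
  }
  idx <- nn$nn.idx
  for (j in seq_len(ncol(idx))) {
    pair <- which(idx[, j] > 0 & idx[, j] != seq_len(n))
    for (i in pair) {
      a <- find(i)
      b <- find(idx[i, j])
      if (a != b) rep_idx[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# faces sharing one vertex set: equal winding collapses to one copy, a pair
# of opposite windings is a zero-thickness fin and is removed entirely
# (welding folded geometry produces both)
.drop_duplicate_faces <- function(F) {
  key <- apply(F, 1, function(r) paste(sort(r), collapse = "-"))
  if (!anyDuplicated(key)) return(F)
  keep <- rep(TRUE, nrow(F))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    ref <- F[idx[1], ]
    same <- vapply(idx, function(i) {
      f <- F[i, ]
      any(vapply(0:2, function(s) all(f == ref[c(1:3, 1:3)[s + 1:3]]),
                 logical(1)))
    }, logical(1))
    n_same <- sum(same)
    n_opp <- length(idx) - n_same
    keep[idx] <- FALSE
    # fins cancel in pairs; a leftover unpaired face survives
    if (n_same != n_opp) {
      survivor <- if (n_same > n_opp) idx[same][1] else idx[!same][1]
      keep[survivor] <- TRUE
    }
  }
  F[keep, , drop = FALSE]
}

.tri_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.tooth_mesh <- function(x, ...) {
  cat(sprintf("tooth_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Facet area
#'
#' Area of one or more triangular facets (half the cross-product magnitude of
#' two edge vectors), in square millimetres.
#'
#' @param mesh a [tooth_mesh].
#' @param f face index or vector of indices; `NULL` (default) for all faces.
#' @return numeric vector of areas in mm^2.
#' @export
facet_area <- function(mesh, f = NULL) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  F <- mesh$faces
  if (!is.null(f)) {
    if (any(f < 1L | f > nrow(F))) stop("invalid face index")
    F <- F[f, , drop = FALSE]
  }
  a <- .tri_areas(mesh$vertices, F)
  if (any(a <= 0)) stop("degenerate face encountered")
  a
}

#' Per-face unit normals
#' @param mesh a [tooth_mesh].
#' @return m x 3 matrix of unit normals (right-hand rule on the stored
#'   vertex winding).
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Edge and face adjacency of a triangle mesh
#'
#' Enumerates the unique edges of a mesh and, per edge, its one or two
#' incident faces; also returns, per face, its edge-sharing (first-order)
#' neighbour faces.
#'
#' @param mesh a [tooth_mesh].
#' @return a list of class `facet_adjacency` with elements:
#'   * `edges`: E x 2 matrix of vertex index pairs (sorted within row),
#'   * `edge_faces`: E x 2 matrix of incident faces (`NA` second entry for a
#'     boundary edge),
#'   * `neighbors`: list of integer vectors, edge-sharing faces per face.
#' @export
facet_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  F <- mesh$faces
  nv <- nrow(mesh$vertices)
  ea <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  fid <- rep.int(seq_len(nrow(F)), 3L)
  lo <- pmin(ea[, 1], ea[, 2])
  hi <- pmax(ea[, 1], ea[, 2])
  key <- (as.numeric(lo) - 1) * nv + as.numeric(hi)
  o <- order(key, fid)
  key <- key[o]
  fid <- fid[o]
  lo <- lo[o]
  hi <- hi[o]
  grp <- cumsum(!duplicated(key))
  cnt <- tabulate(grp)
  if (any(cnt > 2L))
    stop("non-manifold input: an edge has more than 2 incident faces")
  first <- which(!duplicated(key))
  edges <- cbind(lo[first], hi[first])
  ef <- matrix(NA_integer_, nrow(edges), 2L)
  ef[, 1] <- fid[first]
  second <- first + 1L
  has2 <- cnt == 2L
  ef[has2, 2] <- fid[second[has2]]
  nb <- vector("list", nrow(F))
  int <- which(has2)
  for (k in int) {
    a <- ef[k, 1]; b <- ef[k, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  structure(list(edges = edges, edge_faces = ef, neighbors = nb),
            class = "facet_adjacency")
}

#' Pairwise facet curvature score
#'
#' Dihedral-based curvature between two edge-sharing facets, normalized to
#' \[0, 1\]: 0 for coplanar faces, rising with the fold angle, with concave
#' folds (the geometry of inter-tooth valleys) scoring higher than convex
#' ridges. The score is `clamp(fac * theta / pi, 0, 1)` where `theta` is the
#' angle between the two face normals and `fac` is 1 for a concave fold and
#' `convex_frac` for a convex one.
#'
#' @param mesh a [tooth_mesh].
#' @param f1,f2 face indices (vectors of equal length for vectorized use).
#' @param convex_frac attenuation applied to convex folds (default 0.2).
#' @param adjacency optional precomputed [facet_adjacency].
#' @return numeric curvature scores in \[0, 1\].
#' @export
facet_pair_curvature <- function(mesh, f1, f2, convex_frac = 0.2,
                                 adjacency = NULL) {
  stopifnot(inherits(mesh, "tooth_mesh"), length(f1) == length(f2))
  if (is.null(adjacency)) adjacency <- facet_adjacency(mesh)
  for (i in seq_along(f1)) {
    if (!(f2[i] %in% adjacency$neighbors[[f1[i]]]))
      stop(sprintf("faces %d and %d do not share an edge", f1[i], f2[i]))
  }
  as.numeric(.pair_curvature(mesh, f1, f2, convex_frac))
}

# no adjacency validation: internal vectorized core; the returned score
# carries `raw` (unattenuated theta/pi) and `concave` attributes
.pair_curvature <- function(mesh, f1, f2, convex_frac) {
  n <- face_normals(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  cent <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
             V[F[, 3], , drop = FALSE]) / 3
  d <- pmin(pmax(rowSums(n[f1, , drop = FALSE] * n[f2, , drop = FALSE]),
                 -1), 1)
  theta <- acos(d)
  dc <- cent[f2, , drop = FALSE] - cent[f1, , drop = FALSE]
  concave <- rowSums(n[f1, , drop = FALSE] * dc) > 0
  fac <- ifelse(concave, 1, convex_frac)
  structure(pmin(pmax(fac * theta / pi, 0), 1),
            raw = pmin(pmax(theta / pi, 0), 1), concave = concave)
}

#' Total surface area of a mesh
#' @param mesh a [tooth_mesh].
#' @return total area in mm^2.
#' @export
mesh_surface_area <- function(mesh) sum(facet_area(mesh))

#' Signed enclosed volume of a closed mesh
#' @param mesh a [tooth_mesh]; meaningful for closed, outward-oriented meshes.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Mesh topology summary
#'
#' Boundary-edge count, non-manifold-edge count and Euler characteristic
#' (V - E + F), used to verify that reconstructed and fused surfaces are
#' watertight / edge-manifold.
#'
#' @param mesh a [tooth_mesh].
#' @return list with `n_vertices`, `n_edges`, `n_faces`, `n_boundary_edges`,
#'   `n_nonmanifold_edges`, `euler`, `closed`.
#' @export
mesh_topology <- function(mesh) {
  F <- mesh$faces
  nv <- nrow(mesh$vertices)
  ea <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- (as.numeric(pmin(ea[, 1], ea[, 2])) - 1) * nv +
    as.numeric(pmax(ea[, 1], ea[, 2]))
  cnt <- table(key)
  nb <- sum(cnt == 1L)
  nm <- sum(cnt > 2L)
  ne <- length(cnt)
  list(n_vertices = nv, n_edges = ne, n_faces = nrow(F),
       n_boundary_edges = nb, n_nonmanifold_edges = nm,
       euler = nv - ne + nrow(F), closed = nb == 0L && nm == 0L)
}

#' Extract the submesh carried by a face subset
#' @param mesh a [tooth_mesh].
#' @param faces integer vector of face indices to keep.
#' @param weld logical, re-weld the result (default FALSE: indices only).
#' @return a [tooth_mesh] with unreferenced vertices dropped.
#' @export
submesh <- function(mesh, faces, weld = FALSE) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  tooth_mesh(mesh$vertices, mesh$faces[faces, , drop = FALSE],
             weld = weld, orient = FALSE)
}
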