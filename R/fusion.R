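#' Delaunay candidate triangle set
#'
#' All triangular facets of the 3D Delaunay tetrahedralization of a point
#' set — the candidate pool from which the region-growing fusion surface is
#' assembled. A tiny deterministic symbolic perturbation (relative scale
#' `jitter`) resolves degenerate, cospherical configurations; returned facets
#' always reference the original, unperturbed points.
#'
#' @param points n x 3 matrix (n >= 4, not all coplanar).
#' @param jitter relative perturbation (default 1e-9 of the bounding box).
#' @return object of class `delaunay_facets`: integer m x 3 matrix of vertex
#'   triples (sorted within row), with attributes `points` and `n_tets`.
#' @export
delaunay_candidates <- function(points, jitter = 1e-9) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] < (1e-7)^2 * max(ev[1], 1e-300))
    stop("degenerate input: points are coplanar")
  res <- .delaunay3d_cpp(points, jitter)
  structure(res$facets, points = points, n_tets = nrow(res$tets),
            class = "delaunay_facets")
}

#' Starting triangle for the region-growing fusion
#'
#' Among candidate facets containing the globally largest-z vertex, the one
#' with minimum circumradius; ties broken by the lexicographically smallest
#' sorted vertex triple. z is the tooth long axis, crown up.
#'
#' @param facets a `delaunay_facets` object or plain m x 3 index matrix.
#' @param points n x 3 coordinates (taken from `facets` if absent).
#' @return integer length-3 vertex triple (sorted).
#' @export
select_start_triangle <- function(facets, points = attr(facets, "points")) {
  facets <- unclass(facets)
  attributes(facets) <- attributes(facets)["dim"]
  if (nrow(facets) == 0) stop("empty candidate set")
  vmax <- which.max(points[, 3])
  cand <- which(facets[, 1] == vmax | facets[, 2] == vmax |
                  facets[, 3] == vmax)
  if (!length(cand)) stop("no facet contains the max-z vertex")
  rad <- vapply(cand, function(f) {
    .circumradius(points[facets[f, 1], ], points[facets[f, 2], ],
                  points[facets[f, 3], ])
  }, numeric(1))
  best <- cand[rad <= min(rad) + 1e-12 * (1 + min(rad))]
  if (length(best) > 1) {
    keys <- t(apply(facets[best, , drop = FALSE], 1, sort))
    best <- best[do.call(order, as.data.frame(keys))[1]]
  }
  sort(facets[best, ])
}

.circumradius <- function(a, b, c) {
  e1 <- sqrt(sum((b - a)^2))
  e2 <- sqrt(sum((c - b)^2))
  e3 <- sqrt(sum((a - c)^2))
  s <- (e1 + e2 + e3) / 2
  ar2 <- s * (s - e1) * (s - e2) * (s - e3)
  if (ar2 <= 0) return(Inf)
  e1 * e2 * e3 / (4 * sqrt(ar2))
}

# boundary edges of an accepted oriented face set: edge -> single incident
# face, with its traversal direction
.boundary_edges <- function(faces) {
  if (is.null(dim(faces))) faces <- matrix(faces, ncol = 3)
  ea <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  fid <- rep.int(seq_len(nrow(faces)), 3L)
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  cnt <- table(key)
  single <- names(cnt)[cnt == 1L]
  sel <- key %in% single
  list(key = key[sel], from = ea[sel, 1], to = ea[sel, 2], face = fid[sel],
       all_keys = key, counts = cnt)
}

#' Local smooth degree of a candidate triangle
#'
#' Scores how smoothly a candidate triangle continues the accepted surface F
#' across its shared boundary edges: the cosine of the angle between the
#' consistently oriented normals of the candidate and its accepted neighbour,
#' averaged over shared boundary edges. 1 for a coplanar continuation, -1
#' for a fold-back, `cos(pi - dihedral)` in between.
#'
#' @param tri length-3 vertex triple of the candidate.
#' @param faces accepted oriented faces (k x 3 matrix).
#' @param points n x 3 coordinates.
#' @return LSD score in \[-1, 1\].
#' @export
local_smooth_degree <- function(tri, faces, points) {
  if (is.null(dim(faces))) faces <- matrix(faces, ncol = 3)
  be <- .boundary_edges(faces)
  nrm <- function(t) {
    u <- points[t[2], ] - points[t[1], ]
    v <- points[t[3], ] - points[t[1], ]
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    n / sqrt(sum(n^2))
  }
  scores <- numeric(0)
  o <- .orient_against(tri, be)
  if (is.null(o$tri)) stop("candidate shares no boundary edge with F")
  nt <- nrm(o$tri)
  ot <- o$tri
  tedges <- rbind(ot[c(1, 2)], ot[c(2, 3)], ot[c(3, 1)])
  for (e in 1:3) {
    k <- paste(min(tedges[e, ]), max(tedges[e, ]))
    hit <- which(be$key == k)
    if (!length(hit)) next
    nf <- nrm(faces[be$face[hit], ])
    scores <- c(scores, sum(nt * nf))
  }
  mean(scores)
}

# orient tri so that it traverses every shared boundary edge opposite to F.
# Returns list(tri = oriented triple or NULL when no shared edge,
#              conflict = TRUE when shared edges demand opposite flips;
#              tri is then oriented by the first shared edge alone).
.orient_against <- function(tri, be) {
  flip <- NA
  conflict <- FALSE
  for (e in 1:3) {
    a <- tri[e]; b <- tri[if (e == 3) 1 else e + 1]
    k <- paste(min(a, b), max(a, b))
    hit <- which(be$key == k)
    if (!length(hit)) next
    need <- if (be$from[hit] == b && be$to[hit] == a) 0 else 1
    if (is.na(flip)) flip <- need
    else if (flip != need) conflict <- TRUE
  }
  if (is.na(flip)) return(list(tri = NULL, conflict = FALSE))
  list(tri = if (flip == 1) tri[c(1, 3, 2)] else tri, conflict = conflict)
}

#' Admissibility of a candidate triangle for region growing
#'
#' TRUE iff adding the candidate to the accepted set F keeps the complex
#' 2-manifold-like: (i) no edge acquires a third incident triangle, (ii) no
#' vertex ends up with two disjoint triangle fans (exhaustive fan
#' enumeration over F plus the candidate), and (iii) the candidate can be
#' oriented consistently with all accepted neighbours across shared boundary
#' edges. This is the strict predicate applied during normal growth; when
#' growth stalls with open boundary left, [dbrg_fuse] bridges fronts with a
#' relaxed variant of (ii) that tolerates a transient pinch at an open
#' boundary vertex (such fans merge as growth continues).
#'
#' @param tri length-3 vertex triple of the candidate (from the Delaunay
#'   candidate set).
#' @param faces accepted oriented faces (k x 3 matrix).
#' @param points n x 3 coordinates (unused geometrically; kept for interface
#'   symmetry with [local_smooth_degree]).
#' @return logical.
#' @export
dbrg_admissible <- function(tri, faces, points = NULL) {
  if (is.null(dim(faces))) faces <- matrix(faces, ncol = 3)
  be <- .boundary_edges(faces)
  tedges_key <- c(paste(min(tri[1], tri[2]), max(tri[1], tri[2])),
                  paste(min(tri[2], tri[3]), max(tri[2], tri[3])),
                  paste(min(tri[3], tri[1]), max(tri[3], tri[1])))
  # (i) edge saturation
  for (k in tedges_key)
    if (!is.na(be$counts[k]) && be$counts[k] >= 2) return(FALSE)
  o <- .orient_against(tri, be)
  if (is.null(o$tri)) return(FALSE)       # no contact with the front
  if (o$conflict) return(FALSE)           # (iii) orientation conflict
  # (ii) vertex fans: components of faces-at-v (incl. tri) connected through
  # shared edges incident at v
  allf <- rbind(faces, tri)
  for (v in tri) {
    at <- which(allf[, 1] == v | allf[, 2] == v | allf[, 3] == v)
    if (length(at) < 2) next
    edges_at <- lapply(at, function(f) {
      t0 <- allf[f, ]
      ee <- rbind(t0[c(1, 2)], t0[c(2, 3)], t0[c(3, 1)])
      ee <- ee[ee[, 1] == v | ee[, 2] == v, , drop = FALSE]
      paste(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]))
    })
    comp <- seq_along(at)
    for (i in seq_along(at)) {
      for (j in seq_len(i - 1)) {
        if (length(intersect(edges_at[[i]], edges_at[[j]]))) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
        }
      }
    }
    if (length(unique(comp)) > 1) return(FALSE)
  }
  TRUE
}

#' Fuse a laser crown and a CT root into one tooth surface (DBRG)
#'
#' The Delaunay-based region-growing fusion: (1) compute the Delaunay
#' candidate facets of the combined crown + root vertex set; (2) seed the
#' accepted set F with the start triangle of [select_start_triangle]; (3-5)
#' repeatedly admit the frontier candidate with the largest local smooth
#' degree whose addition keeps F edge-manifold, until the queue empties.
#' Before triangulation, root vertices lying within `overlap_band` of the
#' crown surface are discarded so the double-walled overlap region does not
#' seed non-manifold shells.
#'
#' Both meshes must be in the same (laser) frame with z the tooth long axis,
#' crown up.
#'
#' @param crown laser crown [tooth_mesh] (post-registration frame).
#' @param root CT root [tooth_mesh], or NULL to resurface the crown alone.
#' @param overlap_band root-vertex pruning distance in mm (default 0.1).
#' @param jitter Delaunay symbolic perturbation (default 1e-7).
#' @param min_align minimum cosine between a candidate facet's oriented
#'   normal and the mean input-surface normal of its vertices (default 0.5,
#'   i.e. 60 degrees): candidate facets tilted away from the local surface
#'   orientation of the input meshes are never accepted.
#' @return a [tooth_mesh] of the fused tooth; attributes `report` (list:
#'   vertex/triangle/rejection counts, boundary edges) and `provenance`
#'   (per-vertex "laser"/"ct").
#' @export
dbrg_fuse <- function(crown, root = NULL, overlap_band = 0.1, jitter = 1e-7,
                      min_align = 0.5) {
  stopifnot(inherits(crown, "tooth_mesh"))
  # vertex normals flipped, per input, to point away from the part centroid
  # (outward for our star-shaped crowns/roots); consistent winding required
  out_normals <- function(m) {
    N <- vertex_normals(m)
    ctr <- colMeans(m$vertices)
    if (sum(N * sweep(m$vertices, 2, ctr)) < 0) N <- -N
    N
  }
  Vc <- crown$vertices
  Nc <- out_normals(crown)
  if (!is.null(root)) {
    stopifnot(inherits(root, "tooth_mesh"))
    Vr <- root$vertices
    Nr <- out_normals(root)
    d <- .point_mesh_distance_cpp(Vr, crown$vertices, crown$faces)$distance
    keep <- d > overlap_band
    Vr <- Vr[keep, , drop = FALSE]
    Nr <- Nr[keep, , drop = FALSE]
  } else {
    Vr <- matrix(numeric(0), 0, 3)
    Nr <- matrix(numeric(0), 0, 3)
  }
  P <- rbind(Vc, Vr)
  Nn <- rbind(Nc, Nr)
  prov <- rep(c("laser", "ct"), c(nrow(Vc), nrow(Vr)))
  cand <- delaunay_candidates(P, jitter = jitter)
  h <- .local_spacing(P)
  # input-mesh faces (with root vertices remapped past the pruning) serve as
  # the top-priority tier: growth reproduces the inputs verbatim wherever
  # they appear among the Delaunay facets
  inF <- crown$faces
  if (!is.null(root)) {
    rmap <- integer(nrow(root$vertices))
    rmap[keep] <- nrow(Vc) + seq_len(sum(keep))
    rf <- matrix(rmap[root$faces], ncol = 3)
    rf <- rf[rowSums(rf == 0L) == 0L, , drop = FALSE]
    inF <- rbind(inF, rf)
  }
  res <- .dbrg_cpp(P, unclass(cand), h,
                   vertex_normals = Nn, min_align = min_align,
                   input_faces = inF)
  faces <- res$faces
  # post-filter: drop accepted facets that stray far from both input
  # surfaces (junk chords admitted while bridging)
  cent <- (P[faces[, 1], , drop = FALSE] + P[faces[, 2], , drop = FALSE] +
             P[faces[, 3], , drop = FALSE]) / 3
  dc <- .point_mesh_distance_cpp(cent, crown$vertices, crown$faces)$distance
  if (!is.null(root)) {
    dr <- .point_mesh_distance_cpp(cent, root$vertices, root$faces)$distance
    dc <- pmin(dc, dr)
  }
  tol <- 2 * pmax(h[faces[, 1]], h[faces[, 2]], h[faces[, 3]])
  stray <- dc > tol
  if (any(stray)) faces <- faces[!stray, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(P))
  remap[used] <- seq_along(used)
  mesh <- structure(list(vertices = P[used, , drop = FALSE],
                         faces = matrix(remap[faces], ncol = 3)),
                    class = "tooth_mesh")
  top <- mesh_topology(mesh)
  if (top$n_nonmanifold_edges > 0)
    stop("fusion produced non-manifold edges")     # guarded by construction
  if (nrow(Vr) > 0) {
    # crown and root must end up connected in the fused surface
    comp <- .vertex_components(mesh)
    pv <- prov[used]
    joint <- any(vapply(seq_len(max(comp)), function(k) {
      s <- pv[comp == k]
      any(s == "laser") && any(s == "ct")
    }, logical(1)))
    if (!joint)
      stop("fusion gap: crown and root surfaces were never joined")
  }
  structure(mesh,
            report = list(n_vertices_in = nrow(P),
                          n_root_pruned = if (is.null(root)) 0L
                                          else nrow(root$vertices) - nrow(Vr),
                          n_candidates = nrow(cand),
                          n_accepted = nrow(faces),
                          n_rejected = res$rejected,
                          n_boundary_edges = res$boundary_edges,
                          start_facet = res$start_facet),
            provenance = prov[used])
}

#' Area-weighted per-vertex unit normals of a mesh
#' @param mesh a [tooth_mesh].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  F <- mesh$faces
  V <- mesh$vertices
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
  acc <- rowsum(rbind(fn, fn, fn), as.vector(F), reorder = TRUE)
  N <- matrix(0, nrow(V), 3)
  N[as.integer(rownames(acc)), ] <- acc
  N / pmax(sqrt(rowSums(N^2)), 1e-300)
}

# local sampling spacing per vertex: distance to the 6th nearest neighbour.
# Candidate facets whose circumradius exceeds ~1.4x this spacing skip over a
# sample point; the growth queue defers them to a second priority tier.
.local_spacing <- function(P) {
  k <- min(7L, nrow(P))
  RANN::nn2(P, P, k = k)$nn.dists[, k]
}

# connected components over vertices (edge graph of the faces)
.vertex_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  F <- mesh$faces
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (i in seq_len(nrow(F))) {
    link(F[i, 1], F[i, 2])
    link(F[i, 2], F[i, 3])
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  match(roots, sort(unique(roots)))
}
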