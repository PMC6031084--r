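#' Seed points for per-tooth segmentation
#'
#' One manually picked 3D point per tooth on the arch surface (or, for CT
#' slices, one 2D point per tooth on the starting slice). Tooth ids must be
#' unique positive integers.
#'
#' @param tooth_id integer vector of unique positive labels.
#' @param x,y,z coordinates in mm (z may be omitted for slice seeds).
#' @return a `seed_points` data frame.
#' @export
seed_points <- function(tooth_id, x, y, z = NULL) {
  tooth_id <- as.integer(tooth_id)
  if (anyDuplicated(tooth_id)) stop("tooth_ids must be unique")
  if (any(tooth_id < 1L)) stop("tooth_ids must be positive")
  df <- if (is.null(z)) data.frame(tooth_id = tooth_id, x = x, y = y)
        else data.frame(tooth_id = tooth_id, x = x, y = y, z = z)
  class(df) <- c("seed_points", "data.frame")
  df
}

#' Read seed points from JSON
#'
#' Expects a JSON array of objects `{tooth_id, x, y, z}` (z optional).
#' @param path JSON file path.
#' @return a [seed_points] data frame.
#' @export
read_seeds <- function(path) {
  d <- jsonlite::fromJSON(path)
  if (is.null(d$tooth_id)) stop("seeds JSON must contain tooth_id fields")
  seed_points(d$tooth_id, d$x, d$y, if ("z" %in% names(d)) d$z else NULL)
}

#' Edge height function for watershed crown segmentation
#'
#' For every pair of edge-sharing facets (t1, t2) the height is
#' `H(t1, t2) = w * (area(t1) + area(t2)) / max(area(ti)) + (1 - w) * C(t1, t2)`
#' where the max ranges over t1 and its first-order neighbours and C is the
#' normalized dihedral curvature score of [facet_pair_curvature]. H is
#' direction-dependent through the normalizer; the per-edge watershed barrier
#' is the conservative `max(H(t1,t2), H(t2,t1))`.
#'
#' @param mesh a [tooth_mesh] with at least two adjacent faces.
#' @param w area-term weight in \[0, 1\]; 0.16 works well for intraoral arch
#'   scans and is the default.
#' @param convex_frac convex attenuation passed to the curvature score.
#' @param adjacency optional precomputed [facet_adjacency].
#' @return an object of class `height_field`: list with `edges` (vertex
#'   pairs), `edge_faces` (face pairs, interior edges only), `H12`, `H21`
#'   (direction-resolved heights), `H` (per-edge barrier), `C` (curvature
#'   term) and `w`.
#' @export
compute_height_field <- function(mesh, w = 0.16, convex_frac = 0.2,
                                 adjacency = NULL) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (is.null(adjacency)) adjacency <- facet_adjacency(mesh)
  ef <- adjacency$edge_faces
  interior <- !is.na(ef[, 2])
  if (!any(interior)) stop("mesh has no adjacent face pairs")
  ef <- ef[interior, , drop = FALSE]
  edges <- adjacency$edges[interior, , drop = FALSE]
  areas <- facet_area(mesh)
  # max facet area over {t} U neighbors(t), per face
  maxnb <- vapply(seq_len(nrow(mesh$faces)), function(i) {
    max(areas[c(i, adjacency$neighbors[[i]])])
  }, numeric(1))
  C <- .pair_curvature(mesh, ef[, 1], ef[, 2], convex_frac)
  s <- areas[ef[, 1]] + areas[ef[, 2]]
  H12 <- w * s / maxnb[ef[, 1]] + (1 - w) * as.numeric(C)
  H21 <- w * s / maxnb[ef[, 2]] + (1 - w) * as.numeric(C)
  structure(list(edges = edges, edge_faces = ef, H12 = H12, H21 = H21,
                 H = pmax(H12, H21), C = as.numeric(C),
                 C_raw = attr(C, "raw"), concave = attr(C, "concave"),
                 w = w),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("height_field: %d interior edges, w = %.3f, H in [%.4f, %.4f]\n",
              nrow(x$edges), x$w, min(x$H), max(x$H)))
  invisible(x)
}

.seed_faces <- function(mesh, seeds) {
  stopifnot(inherits(seeds, "data.frame"))
  if (nrow(seeds) == 0) stop("empty seed list")
  if (anyDuplicated(seeds$tooth_id)) stop("tooth_ids must be unique")
  P <- as.matrix(seeds[, c("x", "y", "z")])
  bb <- apply(mesh$vertices, 2, range)
  pad <- 0.05 * max(bb[2, ] - bb[1, ]) + 1e-9
  if (any(t(P) < bb[1, ] - pad) || any(t(P) > bb[2, ] + pad))
    stop("seed point outside the mesh bounding box")
  hit <- .point_mesh_distance_cpp(P, mesh$vertices, mesh$faces)
  f <- hit$face
  if (anyDuplicated(f)) {
    clash <- seeds$tooth_id[f %in% f[duplicated(f)]]
    stop("seeds of tooth_ids ", paste(sort(clash), collapse = ", "),
         " resolve to the same face")
  }
  f
}

.flood <- function(mesh, hf, seed_faces, seed_labels, threshold,
                   init_labels = integer(0), admit = numeric(0),
                   admit_threshold = Inf) {
  .mesh_flood_cpp(nrow(mesh$faces), hf$edge_faces, hf$H,
                  as.integer(seed_faces), as.integer(seed_labels),
                  threshold, as.integer(init_labels), admit, admit_threshold)
}

.crown_labeling <- function(label, entry_h, seeds, seed_faces, params) {
  structure(label,
            entry_h = entry_h, seeds = seeds, seed_faces = seed_faces,
            params = params, class = "crown_labeling")
}

#' @export
print.crown_labeling <- function(x, ...) {
  tb <- table(factor(unclass(x)))
  cat("crown_labeling:", length(x), "faces;",
      sum(x != 0L), "labeled in", sum(names(tb) != "0"), "teeth\n")
  print(tb)
  invisible(x)
}

#' Pre-segment the occlusal cap of each crown by region growing
#'
#' From each seed's nearest face, neighbouring faces are admitted while the
#' crossing-edge height H stays below `growth_threshold`; growth fronts never
#' overwrite each other (priority-flood in ascending H, deterministic
#' tie-break by lower tooth id). This caps each crown's smooth occlusal area
#' and prevents the over-segmentation that a plain watershed of the height
#' field would produce.
#'
#' @param mesh a [tooth_mesh].
#' @param seeds a [seed_points] data frame with x/y/z in mm.
#' @param growth_threshold admission threshold on H; `NULL` (default) uses the
#'   60th percentile of the barrier distribution.
#' @param height_field optional precomputed [compute_height_field] result.
#' @param w,convex_frac height-field parameters when it is computed here.
#' @return a `crown_labeling`: integer vector, one label per face (0 =
#'   unassigned), with attributes `entry_h`, `seeds`, `seed_faces`, `params`.
#' @export
preseg_occlusal <- function(mesh, seeds, growth_threshold = NULL,
                            height_field = NULL, w = 0.16,
                            convex_frac = 0.2) {
  if (is.null(height_field))
    height_field <- compute_height_field(mesh, w = w,
                                         convex_frac = convex_frac)
  if (is.null(growth_threshold))
    growth_threshold <- stats::quantile(height_field$H, 0.60, names = FALSE)
  sf <- .seed_faces(mesh, seeds)
  res <- .flood(mesh, height_field, sf, seeds$tooth_id, growth_threshold)
  .crown_labeling(res$label, res$entry_h, seeds, sf,
                  list(growth_threshold = growth_threshold,
                       w = height_field$w))
}

#' Watershed segmentation of individual crowns from an arch mesh
#'
#' Marker-based watershed on the dual graph of the mesh: seeds are grown into
#' occlusal caps by [preseg_occlusal], then all remaining faces are flooded in
#' ascending barrier-height order from the labeled regions. Region boundaries
#' settle on the concave, high-H valleys between neighbouring crowns. The
#' flood never crosses a sharp concave crease: the gingival sulcus and the
#' inter-tooth grooves are such creases at any sampling pitch, while the
#' per-edge dihedral of smooth crown surface vanishes with the pitch. Because
#' grid sampling smears a crease over two consecutive edges, the blocking
#' score accumulates the edge's own concave turning with the strongest
#' concave turning of its immediate neighbour edges.
#'
#' @inheritParams preseg_occlusal
#' @param gingival_crease accumulated concave turning (fractions of pi) above
#'   which an edge is never flooded (default 0.3, i.e. a total fold beyond
#'   ~54 degrees across the two-edge band); `Inf` floods everything.
#' @param background_marker seed the mesh's open border faces as an explicit
#'   gingiva/background basin (default TRUE). The crown/gingiva boundary then
#'   settles where the tooth and background wavefronts meet — on the
#'   maximal-height margin ring — instead of relying on the crease threshold
#'   alone. Ignored on closed meshes.
#' @return a `crown_labeling` (see [preseg_occlusal]); every face carries
#'   exactly one label and each tooth's faces form one connected component
#'   containing its seed.
#' @export
watershed_segment <- function(mesh, seeds, w = 0.16, growth_threshold = NULL,
                              gingival_crease = 0.3, convex_frac = 0.2,
                              background_marker = TRUE,
                              height_field = NULL) {
  if (is.null(height_field))
    height_field <- compute_height_field(mesh, w = w,
                                         convex_frac = convex_frac)
  pre <- preseg_occlusal(mesh, seeds, growth_threshold = growth_threshold,
                         height_field = height_field)
  init <- unclass(pre)
  bg <- 0L
  if (background_marker) {
    border <- .border_faces(mesh, height_field)
    border <- setdiff(border, which(init != 0L))
    if (length(border)) {
      bg <- max(seeds$tooth_id) + 1L
      init[border] <- bg
    }
  }
  res <- .flood(mesh, height_field, attr(pre, "seed_faces"),
                pre[attr(pre, "seed_faces")], Inf,
                init_labels = init,
                admit = crease_score(height_field),
                admit_threshold = gingival_crease)
  lab <- res$label
  if (bg > 0L) lab[lab == bg] <- 0L
  entry <- ifelse(is.na(res$entry_h), attr(pre, "entry_h"), res$entry_h)
  .crown_labeling(lab, entry, seeds, attr(pre, "seed_faces"),
                  c(attr(pre, "params"),
                    list(gingival_crease = gingival_crease,
                         background_marker = background_marker)))
}

# faces incident to an open boundary edge of the mesh
.border_faces <- function(mesh, hf) {
  F <- mesh$faces
  nv <- nrow(mesh$vertices)
  ea <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  fid <- rep.int(seq_len(nrow(F)), 3L)
  key <- (as.numeric(pmin(ea[, 1], ea[, 2])) - 1) * nv +
    as.numeric(pmax(ea[, 1], ea[, 2]))
  cnt <- table(key)
  single <- names(cnt)[cnt == 1L]
  sort(unique(fid[key %in% single]))
}

#' Accumulated concave crease score per interior edge
#'
#' The edge\'s own concave turning (fraction of pi; 0 for convex folds) plus
#' the largest concave turning among the other edges of its two incident
#' faces. Grid-sampled meshes smear a geometric crease over two consecutive
#' edges; the accumulated score recovers the total fold while staying small
#' on smooth (even jittered) surface.
#'
#' @param height_field a [compute_height_field] result.
#' @return numeric vector, one score per interior edge.
#' @export
crease_score <- function(height_field) {
  cc <- ifelse(height_field$concave, height_field$C_raw, 0)
  ef <- height_field$edge_faces
  nf <- max(ef)
  # top two concave edge scores per face
  top1 <- numeric(nf); top2 <- numeric(nf)
  idx <- c(ef[, 1], ef[, 2])
  val <- c(cc, cc)
  o <- order(idx, -val)
  idx <- idx[o]; val <- val[o]
  first <- !duplicated(idx)
  top1[idx[first]] <- val[first]
  rest <- which(!first)
  second <- rest[!duplicated(idx[rest])]
  top2[idx[second]] <- val[second]
  nb_max <- function(col) {
    f <- ef[, col]
    ifelse(abs(cc - top1[f]) < 1e-15, top2[f], top1[f])
  }
  cc + pmax(nb_max(1), nb_max(2))
}

#' Split an arch mesh into per-tooth crown meshes
#' @param mesh the segmented [tooth_mesh].
#' @param labeling a `crown_labeling` from [watershed_segment].
#' @return named list of [tooth_mesh] objects, one per tooth id.
#' @export
split_crowns <- function(mesh, labeling) {
  ids <- sort(unique(unclass(labeling)[unclass(labeling) != 0L]))
  out <- lapply(ids, function(id) submesh(mesh, which(labeling == id)))
  names(out) <- as.character(ids)
  out
}

#' Write a per-face label CSV
#' @param labeling a `crown_labeling`.
#' @param path output CSV path (columns `face`, `tooth_id`).
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labeling, path) {
  utils::write.csv(data.frame(face = seq_along(labeling),
                              tooth_id = as.integer(labeling)),
                   path, row.names = FALSE)
  invisible(path)
}
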