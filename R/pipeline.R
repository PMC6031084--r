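#' Pipeline configuration
#'
#' Collects every tunable parameter of the reconstruction pipeline with its
#' default. Unknown names are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return a validated list of class `pipeline_config`.
#' @details Defaults: `w = 0.16` (height-function area weight),
#'   `growth_threshold = NULL` (60th H percentile), `gingival_crease = 0.3`, `convex_frac = 0.2`, `levelset = levelset_params()`,
#'   `min_area_vox = 4`, `E_th = 1e-4` mm^2, `max_iter = 100`, `trim = 0.2`
#'   (partial-overlap correspondence rejection), `max_points = 3000`, `overlap_band = 0.1` mm, `root_overlap_mm =
#'   0.5`, `delaunay_jitter = 1e-7`, `histogram_bins = 50`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(w = 0.16, growth_threshold = NULL, gingival_crease = 0.3,
              convex_frac = 0.2, levelset = levelset_params(),
              min_area_vox = 4, E_th = 1e-4, max_iter = 100, trim = 0.2,
              max_points = 3000, overlap_band = 0.1, root_overlap_mm = 0.5,
              delaunay_jitter = 1e-7, histogram_bins = 50)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$w < 0 || cfg$w > 1) stop("w must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

.stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full tooth-model reconstruction pipeline
#'
#' Executes the stages in order: watershed segmentation of the laser arch
#' mesh into crowns; slice-propagated level-set segmentation of the CT
#' volume and surface reconstruction per tooth; per-tooth PCA + ICP
#' registration of the CT tooth to its laser crown (matched by seed tooth
#' id); DBRG fusion of the laser crown with the CT root; directed
#' average-distance evaluation. Teeth present in only one modality are
#' reported in `unmatched`, never silently dropped.
#'
#' @param laser_mesh intraoral arch [tooth_mesh].
#' @param ct_volume a [voxel_volume] (transverse slices along axis 3, crown
#'   toward increasing slice index).
#' @param laser_seeds [seed_points] with x/y/z in mm on the arch surface.
#' @param ct_seeds [seed_points] with x/y in pixels on `start_slice`.
#' @param start_slice CT starting slice (inside the crowns).
#' @param config a [pipeline_config].
#' @param out_dir optional output directory; per-tooth STL, transform JSON
#'   and error reports are written there deterministically.
#' @param verbose log stage progress (default TRUE).
#' @return list of class `pipeline_result`: `labeling`, `laser_crowns`,
#'   `ct_teeth`, `registrations`, `fused`, `evaluation` (per-tooth
#'   registration/fusion AD), `unmatched`, `config`.
#' @export
run_pipeline <- function(laser_mesh, ct_volume, laser_seeds, ct_seeds,
                         start_slice, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(laser_mesh, "tooth_mesh"),
            inherits(ct_volume, "voxel_volume"))
  if (is.null(laser_seeds) || nrow(laser_seeds) == 0)
    stop("no laser seeds given")
  if (is.null(ct_seeds) || nrow(ct_seeds) == 0)
    stop("no CT seeds given")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[3]
  .stage_log(verbose, "segment-laser", "watershed on %d faces, %d seeds",
             nrow(laser_mesh$faces), nrow(laser_seeds))
  labeling <- watershed_segment(laser_mesh, laser_seeds, w = config$w,
                                growth_threshold = config$growth_threshold,
                                gingival_crease = config$gingival_crease,
                                convex_frac = config$convex_frac)
  laser_crowns <- split_crowns(laser_mesh, labeling)
  .stage_log(verbose, "segment-laser", "%d crowns in %.1f s",
             length(laser_crowns), proc.time()[3] - t0)

  t1 <- proc.time()[3]
  .stage_log(verbose, "segment-ct", "propagating from slice %d", start_slice)
  contours <- propagate_contours(ct_volume, start_slice, ct_seeds,
                                 params = config$levelset,
                                 min_area_vox = config$min_area_vox)
  ct_teeth <- list()
  for (id in names(contours)) {
    if (!length(contours[[id]])) next
    mask <- contours_to_mask(contours, id)
    ct_teeth[[id]] <- reconstruct_surface(mask, ct_volume$voxel_size,
                                          ct_volume$origin)
  }
  .stage_log(verbose, "segment-ct", "%d teeth reconstructed in %.1f s",
             length(ct_teeth), proc.time()[3] - t1)

  laser_ids <- names(laser_crowns)
  ct_ids <- names(ct_teeth)
  shared <- intersect(laser_ids, ct_ids)
  unmatched <- list(laser_only = setdiff(laser_ids, ct_ids),
                    ct_only = setdiff(ct_ids, laser_ids))
  if (length(unmatched$laser_only) || length(unmatched$ct_only))
    warning("unmatched teeth: laser-only [",
            paste(unmatched$laser_only, collapse = ","), "], CT-only [",
            paste(unmatched$ct_only, collapse = ","), "]")
  registrations <- list()
  fused <- list()
  evaluation <- list()
  for (id in shared) {
    t2 <- proc.time()[3]
    reg <- register_crowns(ct_teeth[[id]], laser_crowns[[id]],
                           E_th = config$E_th, max_iter = config$max_iter,
                           trim = config$trim,
                           max_points = config$max_points)
    registrations[[id]] <- reg
    ct_in_laser <- apply_transform(ct_teeth[[id]], reg$transform)
    reg_ad <- average_distance(laser_crowns[[id]],
                               apply_transform(reg$ct_crown, reg$transform),
                               bins = config$histogram_bins)
    .stage_log(verbose, "register", "tooth %s: AD %.4f mm, %d ICP iters (%.1f s)",
               id, reg_ad$mean, nrow(reg$trace), proc.time()[3] - t2)
    t3 <- proc.time()[3]
    # root part: everything below the crown plane (lifted by the overlap)
    pl <- crown_plane(ct_in_laser)
    root <- section_crown(ct_in_laser,
                          pl$point + config$root_overlap_mm * pl$normal,
                          -pl$normal)
    fus <- dbrg_fuse(laser_crowns[[id]], root,
                     overlap_band = config$overlap_band,
                     jitter = config$delaunay_jitter)
    fused[[id]] <- fus
    fus_ad <- average_distance(laser_crowns[[id]], fus,
                               bins = config$histogram_bins)
    .stage_log(verbose, "fuse", "tooth %s: %d triangles, AD %.5f mm (%.1f s)",
               id, nrow(fus$faces), fus_ad$mean, proc.time()[3] - t3)
    evaluation[[id]] <- list(registration = reg_ad, fusion = fus_ad)
  }
  res <- list(labeling = labeling, laser_crowns = laser_crowns,
              ct_teeth = ct_teeth, registrations = registrations,
              fused = fused, evaluation = evaluation,
              unmatched = unmatched, config = config)
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  write_labels_csv(res$labeling, file.path(out_dir, "laser_labels.csv"))
  for (id in names(res$fused)) {
    write_stl(res$laser_crowns[[id]],
              file.path(out_dir, sprintf("crown_laser_%s.stl", id)))
    write_stl(res$ct_teeth[[id]],
              file.path(out_dir, sprintf("tooth_ct_%s.stl", id)))
    write_stl(res$fused[[id]],
              file.path(out_dir, sprintf("tooth_fused_%s.stl", id)))
    write_transform_json(res$registrations[[id]]$transform,
                         file.path(out_dir, sprintf("transform_%s.json", id)))
    export_error_report(res$evaluation[[id]]$registration,
                        file.path(out_dir, sprintf("registration_%s", id)))
    export_error_report(res$evaluation[[id]]$fusion,
                        file.path(out_dir, sprintf("fusion_%s", id)))
  }
  summary <- lapply(res$evaluation, function(e)
    list(registration_ad_mm = e$registration$mean,
         fusion_ad_mm = e$fusion$mean))
  jsonlite::write_json(summary, file.path(out_dir, "evaluation.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d fused teeth\n", length(x$fused)))
  for (id in names(x$evaluation))
    cat(sprintf("  tooth %s: registration AD %.4f mm, fusion AD %.5f mm\n",
                id, x$evaluation[[id]]$registration$mean,
                x$evaluation[[id]]$fusion$mean))
  invisible(x)
}
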