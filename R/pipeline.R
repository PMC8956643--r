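# End-to-end canonical holistic morphometric analysis: canonical bone
# creation, per-specimen registration, canonical meshing, mesh morphing,
# BV/TV mapping on the original-resolution images, and element-wise group
# statistics.

#' Pipeline configuration
#'
#' Defaults follow the workflow's identified parameter set: 10x image
#' rescaling for registration (0.03 mm scans become 0.3 mm), 20 mm B-spline
#' control spacing, two model iterations, 1 mm characteristic mesh edge
#' length, a 2.5 mm background grid (hence 5 mm sampling spheres) and
#' alpha = 0.05 with permutation FWER control.
#'
#' @param rescale_factor integer voxel-size multiplier for registration.
#' @param bspline_grid_spacing requested control-point spacing, mm.
#' @param sdm_iterations number of canonical-model iterations.
#' @param mesh_edge_length characteristic tetrahedron edge length, mm.
#' @param hma_grid_spacing background grid spacing, mm (sphere diameter is
#'   twice this).
#' @param alpha significance level for FWER control.
#' @param n_perm number of label permutations.
#' @param seed seed for all stochastic steps (permutations).
#' @param closing_radius,shell_offset compartment-masking radii, mm
#'   (`NULL`: 5 and 2 voxels).
#' @param sphere_denominator `"mask"` or `"full"`, see [bvtv_sphere()].
#' @param start_index starting reference image for the canonical model.
#' @param registration extra [registration_options()].
#' @export
chma_config <- function(rescale_factor = 10, bspline_grid_spacing = 20,
                        sdm_iterations = 2, mesh_edge_length = 1,
                        hma_grid_spacing = 2.5, alpha = 0.05, n_perm = 10000,
                        seed = 1, closing_radius = NULL, shell_offset = NULL,
                        sphere_denominator = "mask", start_index = 1,
                        registration = registration_options()) {
  cfg <- list(rescale_factor = rescale_factor,
              bspline_grid_spacing = bspline_grid_spacing,
              sdm_iterations = sdm_iterations,
              mesh_edge_length = mesh_edge_length,
              hma_grid_spacing = hma_grid_spacing,
              alpha = alpha, n_perm = n_perm, seed = seed,
              closing_radius = closing_radius, shell_offset = shell_offset,
              sphere_denominator = sphere_denominator,
              start_index = start_index, registration = registration)
  class(cfg) <- "chma_config"
  cfg
}

log_stage <- function(log_path, stage, ...) {
  if (is.null(log_path)) return(invisible())
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE)
}

#' Run the full canonical HMA workflow
#'
#' Executes, in order: compartment masking (unless masks are supplied),
#' canonical bone creation, registration of every specimen onto the
#' canonical bone, averaging of the transformed trabecular masks in
#' canonical space, canonical meshing, mesh morphing onto each specimen,
#' BV/TV mapping on the original-resolution images with the morphed meshes
#' (morphometry is always measured in individual space — transforming the
#' images would distort the microstructure), rBVTV normalization, and
#' pairwise element-wise group comparison with permutation FWER control
#' plus PCA.
#'
#' @param images list of [masked_image]s (binary segmented bone + mask).
#' @param groups group label per image.
#' @param config a [chma_config()].
#' @param masks optional list of `compartment_masks` (bypasses
#'   [fill_masks()]).
#' @param out_dir if non-`NULL`, all intermediates are written there
#'   (canonical image, transforms, meshes with cell data, per-specimen
#'   fields, population matrix, statistics, config, JSONL log).
#' @param verbose print progress.
#' @return An object of class `chma_run`; see Details. Components:
#'   `sdm` (the canonical model state), `canonical_mesh`, `morphed_meshes`,
#'   `fields` (per-specimen rBVTV element fields), `population` (specimens x
#'   elements rBVTV matrix), `stats` (list of `chma_stats` per group pair),
#'   `pca`, `config`.
#' @export
run_chma <- function(images, groups, config = chma_config(), masks = NULL,
                     out_dir = NULL, verbose = FALSE) {
  stopifnot(length(images) >= 2, length(groups) == length(images))
  log_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(out_dir, "run_log.jsonl")
    jsonlite::write_json(config[setdiff(names(config), "registration")],
                         file.path(out_dir, "config.json"), auto_unbox = TRUE)
  }
  say <- function(...) if (verbose) message(...)

  say("stage 1/6: compartment masks")
  t0 <- proc.time()[3]
  if (is.null(masks)) {
    masks <- lapply(images, fill_masks, closing_radius = config$closing_radius,
                    shell_offset = config$shell_offset)
  }
  log_stage(log_path, "masking", seconds = round(proc.time()[3] - t0, 2))

  say("stage 2/6: canonical bone (SDM)")
  t0 <- proc.time()[3]
  sdm <- build_canonical(images, start_index = config$start_index,
                         n_iter = config$sdm_iterations,
                         rescale_factor = config$rescale_factor,
                         grid_spacing = config$bspline_grid_spacing,
                         opts = config$registration, verbose = verbose)
  canonical <- sdm$reference
  log_stage(log_path, "sdm", seconds = round(proc.time()[3] - t0, 2),
            dice = sdm$diagnostics$dice[nrow(sdm$diagnostics)])

  say("stage 3/6: registration onto the canonical bone")
  t0 <- proc.time()[3]
  low <- lapply(images, rescale_by_factor, factor = config$rescale_factor)
  transforms <- vector("list", length(images))
  reg_metrics <- data.frame()
  for (i in seq_along(images)) {
    sim <- register_similarity(canonical, low[[i]], config$registration)
    bsp <- register_bspline(canonical, low[[i]], config$bspline_grid_spacing,
                            sim, config$registration)
    transforms[[i]] <- compose_transforms(bsp, sim)
    warped <- apply_transform(low[[i]], transforms[[i]], canonical)
    sd <- surface_distances(canonical, warped)
    reg_metrics <- rbind(reg_metrics, data.frame(
      specimen = i, dice = dice(canonical, warped), msd = sd$msd,
      hausdorff = sd$hausdorff))
  }
  log_stage(log_path, "registration", seconds = round(proc.time()[3] - t0, 2),
            mean_dice = mean(reg_metrics$dice))

  say("stage 4/6: canonical trabecular mask and mesh")
  t0 <- proc.time()[3]
  geom <- image_geometry(canonical)
  acc <- array(0, geom$dim)
  for (i in seq_along(images)) {
    trab_img <- masked_image(array(as.numeric(masks[[i]]$trabecular),
                                   dim(masks[[i]]$trabecular)),
                             masks[[i]]$trabecular,
                             spacing = images[[i]]$spacing,
                             origin = images[[i]]$origin)
    warped <- apply_transform(trab_img, transforms[[i]], canonical)
    acc <- acc + (warped$mask > 0)
  }
  canon_trab <- acc >= length(images) / 2
  canonical_mesh <- mesh_from_mask(canon_trab, config$mesh_edge_length,
                                   spacing = geom$spacing, origin = geom$origin)
  log_stage(log_path, "meshing", seconds = round(proc.time()[3] - t0, 2),
            n_elements = nrow(canonical_mesh$elements))

  say("stage 5/6: mesh morphing and HMA (", nrow(canonical_mesh$elements),
      " elements)")
  t0 <- proc.time()[3]
  morphed <- vector("list", length(images))
  fields <- vector("list", length(images))
  for (i in seq_along(images)) {
    morphed[[i]] <- morph_mesh(canonical_mesh, transforms[[i]],
                               provenance = paste0("specimen_", i))
    grid <- evaluate_background_grid(images[[i]], masks[[i]]$trabecular,
                                     spacing_mm = config$hma_grid_spacing,
                                     denominator = config$sphere_denominator)
    bv <- interpolate_to_centroids(grid, morphed[[i]])
    fields[[i]] <- relative_bvtv(bv)
  }
  population <- do.call(rbind, lapply(fields, function(f) f$value))
  rownames(population) <- paste0("specimen_", seq_along(images))
  log_stage(log_path, "hma", seconds = round(proc.time()[3] - t0, 2))

  say("stage 6/6: statistics")
  t0 <- proc.time()[3]
  glev <- unique(groups)
  stats_list <- list()
  if (length(glev) >= 2) {
    pairs <- utils::combn(glev, 2, simplify = FALSE)
    for (p in pairs) {
      a <- population[groups == p[1], , drop = FALSE]
      b <- population[groups == p[2], , drop = FALSE]
      if (nrow(a) >= 2 && nrow(b) >= 2) {
        stats_list[[paste(p, collapse = "_vs_")]] <-
          compare_groups(a, b, n_perm = config$n_perm, alpha = config$alpha,
                         seed = config$seed)
      }
    }
  }
  pca <- if (nrow(population) >= 3) pca_elements(population) else NULL
  log_stage(log_path, "stats", seconds = round(proc.time()[3] - t0, 2))

  run <- structure(list(config = config, sdm = sdm, canonical = canonical,
                        transforms = transforms, reg_metrics = reg_metrics,
                        canonical_trabecular = canon_trab,
                        canonical_mesh = canonical_mesh,
                        morphed_meshes = morphed, fields = fields,
                        population = population, groups = groups,
                        stats = stats_list, pca = pca),
                   class = "chma_run")
  if (!is.null(out_dir)) save_chma_run(run, out_dir)
  run
}

#' @export
print.chma_run <- function(x, ...) {
  cat("chma_run:", length(x$fields), "specimens, groups:",
      paste(unique(x$groups), collapse = ", "), "\n")
  cat("  canonical mesh:", nrow(x$canonical_mesh$elements), "elements\n")
  cat("  mean registration Dice:", signif(mean(x$reg_metrics$dice), 4), "\n")
  for (nm in names(x$stats)) {
    cat("  ", nm, ":", sum(x$stats[[nm]]$significant), "significant elements\n")
  }
  invisible(x)
}

# Write every pipeline product into a run directory.
save_chma_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_masked_image(run$canonical, file.path(out_dir, "canonical.mha"),
                     file.path(out_dir, "canonical_mask.mha"))
  utils::write.csv(run$sdm$diagnostics, file.path(out_dir, "sdm_diagnostics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$reg_metrics, file.path(out_dir, "registration_metrics.csv"),
                   row.names = FALSE)
  for (i in seq_along(run$transforms)) {
    write_transform(run$transforms[[i]],
                    file.path(out_dir, sprintf("transform_%03d.tfm", i)))
  }
  write_mesh_vtk(run$canonical_mesh, file.path(out_dir, "canonical_mesh.vtk"))
  for (i in seq_along(run$morphed_meshes)) {
    write_mesh_vtk(run$morphed_meshes[[i]],
                   file.path(out_dir, sprintf("mesh_%03d.vtk", i)),
                   cell_data = list(rBVTV = run$fields[[i]]$value))
  }
  utils::write.csv(as.data.frame(run$population),
                   file.path(out_dir, "population_rbvtv.csv"))
  for (nm in names(run$stats)) {
    st <- run$stats[[nm]]
    utils::write.csv(data.frame(st), file.path(out_dir, paste0("stats_", nm, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(glance.chma_stats(st),
                         file.path(out_dir, paste0("stats_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    mean_diff_field <- st$mean_diff
    write_mesh_vtk(run$canonical_mesh,
                   file.path(out_dir, paste0("stats_", nm, ".vtk")),
                   cell_data = list(t = st$t, significant = as.numeric(st$significant),
                                    mean_diff = mean_diff_field))
  }
  if (!is.null(run$pca)) {
    utils::write.csv(data.frame(specimen = rownames(run$population),
                                group = run$groups, run$pca$scores),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Extract a sub-region of a mesh and its fields
#'
#' Keeps the listed elements (e.g. a femoral-head-style crop given as an
#' element-id list); vertex coordinates are untouched, so element ids can
#' be traced back through the `element_map` attribute.
#'
#' @param mesh a [tet_mesh].
#' @param element_ids integer ids of elements to keep.
#' @export
mesh_subset <- function(mesh, element_ids) {
  stopifnot(all(element_ids >= 1), all(element_ids <= nrow(mesh$elements)))
  out <- tet_mesh(mesh$vertices, mesh$elements[element_ids, , drop = FALSE],
                  provenance = mesh$provenance)
  attr(out, "element_map") <- as.integer(element_ids)
  out
}
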