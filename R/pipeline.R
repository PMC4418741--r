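#' Default pipeline configuration
#'
#' Parameters for an end-to-end desk-scale run: phantom generation,
#' segmentation and crack classification, trabecular fabric analysis,
#' material mapping and homogenisation, heterogeneous-versus-homogeneous
#' finite element comparison, fracture-regime search, and the fall-mechanics
#' chain. Stage toggles let expensive stages be skipped.
#'
#' @param seed global seed.
#' @param out_dir output directory (created if missing).
#' @param target_elements mesh size for the FE stages.
#' @param n_orientations,n_points fabric analysis settings.
#' @param stages character vector of stages to run, any of
#'   "phantom", "segment", "fabric", "materials", "fe", "fracture",
#'   "mechanics".
#' @param fe_magnitude applied force (N) for the comparison regimes.
#' @param search_target_elements mesh size for the fracture search.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("paleofract_run_"),
                            target_elements = 20000,
                            n_orientations = 256L, n_points = 300L,
                            stages = c("phantom", "segment", "fabric",
                                       "materials", "fe", "fracture",
                                       "mechanics"),
                            fe_magnitude = 56.1,
                            search_target_elements = 4000) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 target_elements = target_elements,
                 n_orientations = n_orientations, n_points = n_points,
                 stages = stages, fe_magnitude = fe_magnitude,
                 search_target_elements = search_target_elements),
            class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' Executes the configured stages in dependency order, writing each stage's
#' artifacts (volumes, meshes, CSV/JSON tables) and a manifest (config,
#' seeds, timing) to the output directory. Stage failures halt the run with
#' a stage-tagged error.
#'
#' @param config a [pipeline_config()].
#' @param spec optional [phantom_spec()]; default uses the config seed.
#' @return list of stage results (invisibly also written to disk).
#' @export
run_pipeline <- function(config = pipeline_config(), spec = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  t0 <- Sys.time()
  timing <- list()
  want <- function(s) s %in% config$stages
  step <- function(name, fun) {
    tryCatch({
      t1 <- Sys.time()
      out <- fun()
      timing[[name]] <<- as.numeric(difftime(Sys.time(), t1, units = "secs"))
      out
    }, error = function(e) stop(sprintf("stage '%s' failed: %s", name,
                                        conditionMessage(e)), call. = FALSE))
  }

  if (is.null(spec)) spec <- phantom_spec(seed = config$seed)
  res$spec <- spec

  if (want("phantom")) res$phantom <- step("phantom", function() {
    ph <- generate_phantom(spec)
    write_volume(ph$volume, file.path(config$out_dir, "phantom.nii"))
    ph
  })
  if (want("segment")) res$segment <- step("segment", function() {
    if (is.null(res$phantom)) stop("dependency error: needs stage 'phantom'")
    seg <- segment_materials(res$phantom$volume,
                             n_cancellous = length(spec$cancellous_class_densities),
                             thresholds = res$phantom$truth$thresholds)
    cracks <- classify_cracks(detect_cracks(res$phantom$volume, seg))
    utils::write.csv(crack_report(cracks),
                     file.path(config$out_dir, "crack_report.csv"),
                     row.names = FALSE)
    list(segmentation = seg, cracks = cracks)
  })
  if (want("fabric")) res$fabric <- step("fabric", function() {
    tv <- generate_trabecular_volume(axis = spec$trabecular_axis,
                                     anisotropy_ratio = spec$anisotropy_ratio,
                                     bvf = spec$bone_volume_fraction,
                                     seed = config$seed)
    fab <- fabric_analysis(tv, n_orientations = config$n_orientations,
                           n_points = config$n_points, seed = config$seed)
    ang <- alignment_angle(fab, spec$trabecular_axis)
    write_fabric_report(fab, file.path(config$out_dir, "fabric.json"),
                        extra = list(alignment_angle_deg = ang))
    list(fabric = fab, alignment_angle_deg = ang)
  })
  if (want("materials") || want("fe") || want("fracture"))
    res$mesh_stage <- step("mesh", function() {
      generate_tet_phantom(spec, target_elements = config$target_elements)
    })
  if (want("materials")) res$materials <- step("materials", function() {
    tp <- res$mesh_stage
    het <- material_card(tp$class_densities)
    cls_vol <- tapply(tet_volumes(tp$mesh), tp$mesh$material_id, sum)
    canc <- as.integer(names(cls_vol)) > 1
    rho_hom <- homogenize(tp$class_densities[as.integer(names(cls_vol))[canc]],
                          as.numeric(cls_vol[canc]))
    hom <- material_card(c(tp$class_densities[1], rho_hom))
    mass <- total_mass(tp$mesh, tp$density)
    utils::write.csv(het, file.path(config$out_dir, "materials_het.csv"),
                     row.names = FALSE)
    utils::write.csv(hom, file.path(config$out_dir, "materials_hom.csv"),
                     row.names = FALSE)
    list(het = het, hom = hom, rho_hom = rho_hom, total_mass_g = mass)
  })
  if (want("fe")) res$fe <- step("fe", function() {
    cmp <- compare_het_hom(res$mesh_stage$mesh, res$materials$het,
                           res$materials$hom, magnitude = config$fe_magnitude)
    utils::write.csv(cmp, file.path(config$out_dir, "het_hom_comparison.csv"),
                     row.names = FALSE)
    cmp
  })
  if (want("fracture")) res$fracture <- step("fracture", function() {
    tp <- generate_tet_phantom(spec,
                               target_elements = config$search_target_elements)
    surface <- fracture_surface_from_spec(tp$mesh, spec)
    card <- material_card(tp$class_densities)
    mats <- material_props(tp$mesh, card)
    scores <- search_loading(tp$mesh, mats, surface,
                             magnitude = config$fe_magnitude)
    utils::write.csv(scores, file.path(config$out_dir, "regime_scores.csv"),
                     row.names = FALSE)
    scores
  })
  if (want("mechanics")) res$mechanics <- step("mechanics", function() {
    ch <- fracture_scenario_chain()
    jsonlite::write_json(ch[setdiff(names(ch), "falls")],
                         file.path(config$out_dir, "mechanics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    ch
  })

  manifest <- list(seed = config$seed, stages = config$stages,
                   timing_s = timing,
                   total_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Human-readable pipeline report
#'
#' Summarises a completed [run_pipeline()] result: material card, mass
#' check, fabric anisotropy and alignment, crack classification,
#' heterogeneous/homogeneous comparison, ranked loading regimes, and the
#' mechanics chain. Missing stages are flagged as gaps rather than errors.
#'
#' @param run result of [run_pipeline()] (or a run directory containing its
#'   artifacts, in which case tables are re-read).
#' @return character vector of report lines, printed invisibly.
#' @export
pf_report <- function(run) {
  if (is.character(run)) {
    if (!dir.exists(run) || !file.exists(file.path(run, "manifest.json")))
      stop("not a completed run directory")
    run <- list(manifest = jsonlite::read_json(file.path(run, "manifest.json")))
  }
  ln <- c("== paleofract run report ==")
  gap <- function(x) ln <<- c(ln, paste0("  [missing stage: ", x, "]"))
  if (!is.null(run$materials)) {
    ln <- c(ln, "-- materials --",
            utils::capture.output(print(run$materials$het)),
            sprintf("homogenised cancellous density: %.4f g/cm3",
                    run$materials$rho_hom),
            sprintf("total mesh mass: %.3f g", run$materials$total_mass_g))
  } else gap("materials")
  if (!is.null(run$fabric)) {
    ln <- c(ln, "-- fabric --",
            sprintf("DA = %.3f, primary-axis alignment = %.2f deg",
                    degree_of_anisotropy(run$fabric$fabric),
                    run$fabric$alignment_angle_deg))
  } else gap("fabric")
  if (!is.null(run$segment)) {
    ln <- c(ln, "-- cracks --",
            utils::capture.output(print(crack_report(run$segment$cracks))))
  } else gap("segment")
  if (!is.null(run$fe)) {
    ln <- c(ln, "-- heterogeneous vs homogeneous (mean von Mises strain) --",
            utils::capture.output(print(run$fe)))
  } else gap("fe")
  if (!is.null(run$fracture)) {
    ln <- c(ln, "-- top loading regimes --",
            utils::capture.output(print(utils::head(run$fracture, 3))))
  } else gap("fracture")
  if (!is.null(run$mechanics)) {
    ln <- c(ln, "-- mechanics chain --",
            utils::capture.output(print(run$mechanics)))
  } else gap("mechanics")
  cat(ln, sep = "\n")
  invisible(ln)
}
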