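#' Default workflow configuration
#'
#' The full configuration of [run_workflow()] with every default filled
#' in; pass overrides as a nested list (or a YAML/JSON file) with the
#' same structure.
#'
#' @return nested list of defaults.
#' @export
default_workflow_config <- function() {
  list(
    seed = 1L,
    bone = list(
      # either `mesh` (a path) or `synth` (bone_phantom_spec overrides)
      mesh = NULL,
      synth = list()
    ),
    frame = list(
      posterior_hint = c(0, 1, 0),
      shaft_fraction = c(0.15, 0.70)
    ),
    plate = list(
      span_frac = c(0.40, 0.96),   # of the axial extent, proximal->distal
      n_sections = 9L,
      sector_angle_deg = 90,
      distal_bias = 0.3,
      thickness_mm = 2
    ),
    deviation = list(
      n_samples = 800L,
      gate_mm = 0.5
    ),
    mesh_res = list(nu = 80L, nv = 24L),
    material = list(
      material = "Ti-6Al-4V",
      process = "DMLS",
      layer_note = "0.1 mm layer; support on the bone-facing side"
    ),
    out_dir = NULL
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

read_workflow_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_pf("pf_parameter_error", "config must be a list")
  merge_config(default_workflow_config(), config)
}

#' Run the plate-modelling workflow
#'
#' Orchestrates the full chain: bone input (a mesh file or a synthetic
#' phantom), frame and parameter extraction, plate surface construction,
#' deviation analysis with a quality gate, solid generation, and a
#' material/manufacturing metadata stub, writing a reproducible artifact
#' bundle (STL + JSON + manifest with config hash and seed). Given the
#' same config and seed the parameter and deviation files are
#' byte-identical across runs.
#'
#' @param config nested list, or path to a YAML/JSON file; see
#'   [default_workflow_config()]. `out_dir` is required.
#' @return (invisibly) list with `params`, `surface`, `report`, `solid`,
#'   `manifest`, `paths`.
#' @export
run_workflow <- function(config) {
  cfg <- read_workflow_config(config)
  if (is.null(cfg$out_dir)) stop_pf("pf_parameter_error", "out_dir required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  timings <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), plateforge_error = function(e) {
      stop_pf(class(e)[1], "stage '%s' failed: %s", name,
              conditionMessage(e))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # P1 boundary: the bone surface (imaging itself is out of pipeline)
  bone_input <- stage("bone", {
    if (!is.null(cfg$bone$mesh)) {
      list(mesh = read_mesh(cfg$bone$mesh), ground_truth = NULL)
    } else {
      spec <- do.call(bone_phantom_spec,
                      merge_config(list(seed = cfg$seed), cfg$bone$synth))
      generate_humerus(spec)
    }
  })
  bone <- bone_input$mesh
  if (is.null(cfg$bone$mesh)) {
    paths$bone <- file.path(cfg$out_dir, "bone.stl")
    write_mesh(bone, paths$bone)
    paths$bone_ground_truth <- file.path(cfg$out_dir, "bone_ground_truth.json")
    jsonlite::write_json(ground_truth_sidecar(bone_input$ground_truth),
                         paths$bone_ground_truth, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }

  # P2: parameter extraction and application
  frame <- stage("frame", compute_anatomical_axis(
    bone, shaft_fraction = as.numeric(cfg$frame$shaft_fraction),
    posterior_hint = as.numeric(cfg$frame$posterior_hint)))
  params <- stage("params", {
    span <- as.numeric(cfg$plate$span_frac) * frame$extent
    stations <- place_stations(frame, span,
                               n_sections = as.integer(cfg$plate$n_sections),
                               distal_bias = cfg$plate$distal_bias)
    assemble_params(bone, frame, stations,
                    sector_angles = cfg$plate$sector_angle_deg * pi / 180,
                    thickness = cfg$plate$thickness_mm)
  })
  paths$params <- file.path(cfg$out_dir, "plate_params.json")
  save_params(params, paths$params)

  surface <- stage("surface", loft_surface(params))
  paths$surface <- file.path(cfg$out_dir, "plate_surface.stl")
  write_mesh(surface_to_mesh(surface, cfg$mesh_res$nu, cfg$mesh_res$nv),
             paths$surface)

  # P3: deviation analysis and quality gate
  report <- stage("deviation", surface_deviation(
    surface, bone, n_samples = as.integer(cfg$deviation$n_samples),
    footprint_only = TRUE, seed = cfg$seed,
    query_mesh_res = c(cfg$mesh_res$nu, cfg$mesh_res$nv)))
  paths$deviation <- file.path(cfg$out_dir, "deviation.json")
  jsonlite::write_json(deviation_report_json(report), paths$deviation,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (report$median_abs > cfg$deviation$gate_mm) {
    cond <- structure(
      class = c("pf_gate_error", "plateforge_error", "error", "condition"),
      list(message = sprintf(
        "deviation gate failed: median |d| = %.4f mm > gate %.4f mm",
        report$median_abs, cfg$deviation$gate_mm),
        call = NULL, report = report))
    stop(cond)
  }

  # plate solid
  solid <- stage("solid", thicken(surface, cfg$plate$thickness_mm,
                                  nu = cfg$mesh_res$nu,
                                  nv = cfg$mesh_res$nv))
  paths$solid <- file.path(cfg$out_dir, "plate.stl")
  write_mesh(solid, paths$solid)

  # P4: material / manufacturing metadata stub
  paths$material <- file.path(cfg$out_dir, "material.json")
  jsonlite::write_json(cfg$material, paths$material, auto_unbox = TRUE,
                       pretty = TRUE)

  # P5: manifest sealing the bundle
  cfg_canon <- file.path(cfg$out_dir, "config_resolved.json")
  jsonlite::write_json(cfg, cfg_canon, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_canon)),
    seed = cfg$seed,
    n_sections = params$n_sections,
    median_abs_deviation_mm = report$median_abs,
    files = {
      fl <- unlist(paths)
      stats::setNames(unname(tools::md5sum(fl)), basename(fl))
    },
    timings_s = timings
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(params = params, surface = surface, report = report,
                 solid = solid, manifest = manifest, paths = paths,
                 frame = frame, bone = bone))
}
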