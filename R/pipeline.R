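## Scenario orchestration: fixtures -> intact solve -> carve/relocate ->
## damaged solve -> submodel solves -> failure reports, under one validated
## configuration with provenance.

#' Scenario configuration
#'
#' Bundles every input of a full run: compartment and gait specifications,
#' material cards, defect specification with one or more target locations,
#' solver settings, failure thresholds and submodel parameters.
#'
#' @param compartment a [compartment_spec()]
#' @param gait a [gait_spec()]
#' @param materials named material list (see [fe_problem()]); entry "1" is
#'   the cartilage card
#' @param defect a [make_defect()] spec, or `NULL` for an intact-only run
#' @param locations list of defect centers (each length-2, mm)
#' @param solver a [solver_config()]
#' @param thresholds a [failure_thresholds()]
#' @param submodel `list(extent_mm =, element_size_mm =)` or `NULL` to skip
#'   submodeling and analyze the global mesh
#' @param roi_radius_mm rim ROI radius for the failure report (mm)
#' @param measure_steps steps at which measures are stored ("all" or indices)
#' @param damaged_global re-solve the carved global model to drive the
#'   damaged submodel boundaries; with the default `FALSE` both submodels
#'   are driven by the intact global solution (at global mesh resolution
#'   the small defect's far-field influence is negligible)
#' @param seed integer seed threaded to every stochastic component
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(compartment = compartment_spec(),
                            gait = gait_spec(n_time_points = 21L),
                            materials = list("1" = frpe_params()),
                            defect = make_defect(),
                            locations = list(c(0, 0)),
                            solver = solver_config(),
                            thresholds = failure_thresholds(),
                            submodel = list(extent_mm = 6, element_size_mm = 0.3),
                            roi_radius_mm = 1.0,
                            measure_steps = "all",
                            damaged_global = FALSE,
                            seed = 1L) {
  stopifnot(inherits(compartment, "compartment_spec"),
            inherits(gait, "gait_spec"))
  if (!is.null(defect) && !inherits(defect, "defect_spec"))
    stopf("defect must be a defect_spec or NULL")
  structure(list(compartment = compartment, gait = gait,
                 materials = materials, defect = defect,
                 locations = locations, solver = solver,
                 thresholds = thresholds, submodel = submodel,
                 roi_radius_mm = roi_radius_mm,
                 measure_steps = measure_steps,
                 damaged_global = isTRUE(damaged_global),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

## Intact global problem for a compartment: bone interface tied (fixed),
## side faces on rollers (no in-plane motion) approximating the lateral
## continuity of the surrounding plateau, articular surface in frictionless
## contact with the rigid indenter.
global_problem <- function(comp, materials, solver,
                           drained_nodes = integer()) {
  fe_problem(comp$mesh, materials,
             fixed_u = list(list(nodes = comp$mesh$node_sets$bone,
                                 dims = 1:3, value = 0),
                            list(nodes = comp$mesh$node_sets$sides,
                                 dims = 1:2, value = 0)),
             drained_nodes = drained_nodes,
             contact = list(center = comp$indenter$center,
                            radius = comp$indenter$radius,
                            faces = "surface", mode = "force"),
             config = solver)
}

## submodel compartment centered on a defect location
submodel_compartment <- function(config, center) {
  spec <- config$compartment
  spec$target_element_size_mm <- config$submodel$element_size_mm
  spec$plateau_extent_mm <- rep(config$submodel$extent_mm, 2)
  make_compartment(spec, patch_center = center)
}

#' Run a full defect scenario
#'
#' Executes the intact global solve, then for every defect location carves
#' the defect into the global and submodel meshes, re-solves, and evaluates
#' the failure criteria around the rim against the co-located intact
#' response. A failed stage aborts the downstream stages for that location
#' only; every stage outcome is recorded in the run manifest.
#'
#' @param config a [scenario_config()]
#' @return object of class `scenario_result` with elements `manifest`,
#'   `reports` (one `failure_report` per location), `intact` states and the
#'   generated fixtures
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  t_start <- Sys.time()
  cfg_hash <- object_hash(unclass(config))
  manifest <- list(config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("cartimech")),
                   seed = config$seed, stages = list(), warnings = character(0))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) e)
    manifest$stages[[name]] <<- list(
      status = if (inherits(out, "error")) "failed" else "ok",
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      message = if (inherits(out, "error")) conditionMessage(out) else NULL)
    out
  }

  comp <- stage("fixtures", make_compartment(config$compartment))
  if (inherits(comp, "error")) stopf("fixture generation failed: %s",
                                     conditionMessage(comp))
  protocol <- make_gait_protocol(config$gait)

  intact_global <- stage("intact_global_solve",
                         solve_protocol(global_problem(comp, config$materials,
                                                       config$solver),
                                        protocol,
                                        measure_steps = config$measure_steps))
  if (inherits(intact_global, "error"))
    stopf("intact global solve failed: %s", conditionMessage(intact_global))

  use_sub <- !is.null(config$submodel)
  reports <- list()
  intact_subs <- list()
  if (!is.null(config$defect)) {
    for (li in seq_along(config$locations)) {
      loc_name <- paste0("location_", li)
      centre <- config$locations[[li]]
      res <- stage(loc_name, {
        dspec <- config$defect
        dspec$center <- as.numeric(centre)
        dgeo_global <- carve_defect(comp, dspec)
        damaged_global <- intact_global
        if (isTRUE(config$damaged_global)) {
          drain_global <- defect_drainage_bcs(dgeo_global)
          dcomp <- comp
          dcomp$mesh <- dgeo_global$mesh
          damaged_global <- solve_protocol(
            global_problem(dcomp, config$materials, config$solver,
                           drained_nodes = drain_global$drained_nodes),
            protocol, measure_steps = config$measure_steps)
          if (!is.null(damaged_global$failure))
            stopf("damaged global solve failed at step %d",
                  damaged_global$failure$step)
        }
        if (use_sub) {
          sub_comp <- submodel_compartment(config, centre)
          bnodes <- submodel_boundary_nodes(sub_comp$mesh)
          bcs_i <- submodel_bcs(intact_global, sub_comp$mesh, bnodes)
          intact_sub <- solve_submodel(sub_comp$mesh, config$materials, bcs_i,
                                       protocol, comp$indenter,
                                       config = config$solver,
                                       measure_steps = config$measure_steps)
          dgeo_sub <- carve_defect(sub_comp, dspec)
          drain_sub <- defect_drainage_bcs(dgeo_sub)
          bcs_d <- submodel_bcs(damaged_global, dgeo_sub$mesh, bnodes)
          damaged_sub <- solve_submodel(
            dgeo_sub$mesh, config$materials, bcs_d, protocol, comp$indenter,
            drained_nodes = setdiff(drain_sub$drained_nodes, bnodes),
            config = config$solver, measure_steps = config$measure_steps)
          if (!is.null(damaged_sub$failure))
            stopf("damaged submodel solve failed at step %d",
                  damaged_sub$failure$step)
          rim_xyz <- dgeo_sub$mesh$nodes[dgeo_sub$rim_nodes, , drop = FALSE]
          rep1 <- failure_report(damaged_sub, rim_xyz, config$thresholds,
                                 intact = intact_sub,
                                 radius_mm = config$roi_radius_mm)
          list(report = rep1, intact_sub = intact_sub,
               damaged_sub = damaged_sub, geometry = dgeo_sub)
        } else {
          rim_xyz <- dgeo_global$mesh$nodes[dgeo_global$rim_nodes, , drop = FALSE]
          rep1 <- failure_report(damaged_global, rim_xyz, config$thresholds,
                                 intact = intact_global,
                                 radius_mm = config$roi_radius_mm)
          list(report = rep1, geometry = dgeo_global)
        }
      })
      if (!inherits(res, "error")) {
        reports[[li]] <- res$report
        attr(reports[[li]], "location") <- centre
        intact_subs[[li]] <- res$intact_sub
      }
    }
  }
  manifest$total_seconds <- round(as.numeric(Sys.time() - t_start,
                                             units = "secs"), 1)
  manifest$n_locations_failed <- sum(vapply(
    manifest$stages[grepl("^location_", names(manifest$stages))],
    function(s1) s1$status == "failed", logical(1)))
  structure(list(manifest = manifest, reports = reports,
                 intact = intact_global, compartment = comp,
                 protocol = protocol, config = config),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d defect location(s), config %s\n",
              length(x$reports), x$manifest$config_hash))
  for (nm in names(x$manifest$stages))
    cat(sprintf("  %-22s %-7s %8.1f s\n", nm, x$manifest$stages[[nm]]$status,
                x$manifest$stages[[nm]]$seconds))
  invisible(x)
}

#' Ranked summary over defect locations
#'
#' Table of peak minimum principal strain, peak shear strain, exceedance
#' fractions and criterion flags per location, sorted by descending
#' magnitude of the peak compressive strain (ties broken by shear strain).
#'
#' @param reports list of `failure_report` objects (e.g. from
#'   [run_scenario()])
#' @return data frame, one row per location
#' @export
summarize_locations <- function(reports) {
  if (!length(reports)) stopf("at least one report is required")
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    loc <- attr(r, "location") %||% c(NA, NA)
    exc_len <- vapply(r$exceedance, function(iv)
      if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0, numeric(1))
    data.frame(location = i, x = loc[1], y = loc[2],
               peak_min_principal = min(r$roi_series$e3),
               peak_shear = max(r$roi_series$shear),
               peak_tensile = max(r$roi_series$e1),
               peak_fibril = max(r$roi_series$fibril),
               peak_sig1_MPa = max(r$roi_series$sig1),
               exceedance_pct = sum(exc_len),
               flag_compressive = exc_len[["compressive_strain"]] > 0,
               flag_shear = exc_len[["shear_strain"]] > 0)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$peak_min_principal), -out$peak_shear), , drop = FALSE]
}

#' Write a scenario result to a run directory
#'
#' Emits the manifest (JSON), per-location failure reports (JSON), the
#' ranked location summary (CSV), and the carved meshes (legacy VTK).
#'
#' @param result a [run_scenario()] result
#' @param dir output directory (created if missing)
#' @export
write_scenario <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(result$reports))
    write_failure_report(result$reports[[i]],
                         file.path(dir, sprintf("failure_report_%d.json", i)))
  if (length(result$reports))
    write.csv(summarize_locations(result$reports),
              file.path(dir, "location_summary.csv"), row.names = FALSE)
  write_vtk(result$compartment$mesh, file.path(dir, "compartment.vtk"))
  invisible(dir)
}
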