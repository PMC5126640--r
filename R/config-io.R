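## YAML configuration interface: scenario configs and material cards as
## plain-text files with explicit units in the key names. Unknown keys are
## rejected so typos surface early.

check_fields <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stopf("unknown field(s) in %s: %s", where, paste(bad, collapse = ", "))
  invisible(x)
}

#' Read a material card from YAML
#'
#' @param path YAML file with a `frpe` block (cartilage constants) and
#'   optionally a `meniscus` block
#' @return named material list usable in [fe_problem()]
#' @export
read_material_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$frpe)) {
    check_fields(y$frpe, names(formals(frpe_params)), "frpe material card")
    out[["1"]] <- do.call(frpe_params, y$frpe)
  }
  if (!is.null(y$meniscus)) {
    check_fields(y$meniscus, names(formals(meniscus_params)), "meniscus card")
    out[["2"]] <- list(type = "meniscus",
                       params = do.call(meniscus_params, y$meniscus))
  }
  if (!length(out)) stopf("material card %s defines no materials", path)
  out
}

#' Read a scenario configuration from YAML
#'
#' Maps nested YAML blocks (`compartment`, `gait`, `defect`, `solver`,
#' `thresholds`, `submodel`, plus top-level `locations`, `seed`, ...) onto
#' the corresponding specification constructors, validating every field
#' name.
#'
#' @param path YAML file path
#' @return a [scenario_config()]
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  check_fields(y, c("compartment", "gait", "materials", "defect", "locations",
                    "solver", "thresholds", "submodel", "roi_radius_mm",
                    "measure_steps", "damaged_global", "seed"),
               "scenario config")
  args <- list()
  build <- function(block, fn, where) {
    check_fields(block, names(formals(fn)), where)
    block <- lapply(block, function(v) if (is.list(v)) unlist(v) else v)
    do.call(fn, block)
  }
  if (!is.null(y$compartment))
    args$compartment <- build(y$compartment, compartment_spec, "compartment")
  if (!is.null(y$gait)) args$gait <- build(y$gait, gait_spec, "gait")
  if (!is.null(y$defect)) args$defect <- build(y$defect, make_defect, "defect")
  if (!is.null(y$solver)) args$solver <- build(y$solver, solver_config, "solver")
  if (!is.null(y$thresholds))
    args$thresholds <- build(y$thresholds, failure_thresholds, "thresholds")
  if (!is.null(y$materials)) {
    if (is.character(y$materials)) {
      args$materials <- read_material_yaml(
        if (file.exists(y$materials)) y$materials
        else file.path(dirname(path), y$materials))
    } else {
      args$materials <- list("1" = build(y$materials, frpe_params, "materials"))
    }
  }
  if (!is.null(y$submodel)) {
    check_fields(y$submodel, c("extent_mm", "element_size_mm"), "submodel")
    args$submodel <- y$submodel
  }
  if (!is.null(y$locations))
    args$locations <- lapply(y$locations, unlist)
  for (nm in c("roi_radius_mm", "seed", "damaged_global", "measure_steps"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(scenario_config, args)
}
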