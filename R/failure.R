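## Five-criterion cartilage failure analysis: threshold classification of
## strain/stress fields, ROI maxima around the defect rim over the stance
## phase, exceedance intervals, and intact-vs-damaged comparisons.

#' Cartilage failure thresholds
#'
#' Literature limits for potential tissue failure: maximum principal
#' (tensile) stress 7 MPa for the collagen matrix, fibril strain 8% for
#' collagen network damage, maximum principal strain 30% for the matrix,
#' minimum principal strain -30% for chondrocyte apoptosis, and maximum
#' engineering shear strain 32% for collagen crosslink failure. Exceedance
#' is strict (boundary equality is not flagged).
#'
#' @param max_principal_stress_MPa tensile stress limit (MPa)
#' @param fibril_strain fibril strain limit (dimensionless)
#' @param max_principal_strain tensile (logarithmic) strain limit
#' @param min_principal_strain compressive strain limit (negative)
#' @param shear_strain maximum engineering shear strain limit
#' @return object of class `failure_thresholds`
#' @export
failure_thresholds <- function(max_principal_stress_MPa = 7,
                               fibril_strain = 0.08,
                               max_principal_strain = 0.30,
                               min_principal_strain = -0.30,
                               shear_strain = 0.32) {
  check_scalar(max_principal_stress_MPa, "max_principal_stress_MPa", 0, Inf,
               strict_lower = TRUE)
  check_scalar(min_principal_strain, "min_principal_strain", -Inf, 0,
               strict_upper = TRUE)
  check_scalar(fibril_strain, "fibril_strain", 0, Inf, strict_lower = TRUE)
  check_scalar(max_principal_strain, "max_principal_strain", 0, Inf,
               strict_lower = TRUE)
  check_scalar(shear_strain, "shear_strain", 0, Inf, strict_lower = TRUE)
  structure(list(max_principal_stress_MPa = max_principal_stress_MPa,
                 fibril_strain = fibril_strain,
                 max_principal_strain = max_principal_strain,
                 min_principal_strain = min_principal_strain,
                 shear_strain = shear_strain),
            class = "failure_thresholds")
}

#' @export
print.failure_thresholds <- function(x, ...) {
  cat(sprintf("<failure_thresholds> sig1 > %g MPa | fibril > %g | e1 > %g | e3 < %g | shear > %g\n",
              x$max_principal_stress_MPa, x$fibril_strain,
              x$max_principal_strain, x$min_principal_strain, x$shear_strain))
  invisible(x)
}

CRITERIA <- c("tensile_stress", "fibril_strain", "tensile_strain",
              "compressive_strain", "shear_strain")

## the measure column and direction each criterion reads
criterion_map <- function() {
  list(tensile_stress = list(col = "sig1", dir = +1, thr = "max_principal_stress_MPa"),
       fibril_strain = list(col = "fibril", dir = +1, thr = "fibril_strain"),
       tensile_strain = list(col = "e1", dir = +1, thr = "max_principal_strain"),
       compressive_strain = list(col = "e3", dir = -1, thr = "min_principal_strain"),
       shear_strain = list(col = "shear", dir = +1, thr = "shear_strain"))
}

#' Classify failure criteria over a measure field
#'
#' Per-criterion boolean masks over evaluation points: a point is flagged
#' iff its measure strictly exceeds the limit (strictly falls below it for
#' the compressive criterion).
#'
#' @param measures matrix of strain/stress measures with columns `e1`,
#'   `e3`, `shear`, `fibril`, `sig1` (one evaluation point per row), as
#'   produced per step in an `fe_states` object
#' @param thresholds a [failure_thresholds()]
#' @return logical matrix, one column per criterion
#' @export
classify_failure <- function(measures, thresholds = failure_thresholds()) {
  cm <- criterion_map()
  need <- unique(vapply(cm, `[[`, "", "col"))
  missing_cols <- setdiff(need, colnames(measures))
  if (length(missing_cols))
    stopf("measure field(s) missing: %s", paste(missing_cols, collapse = ", "))
  out <- vapply(names(cm), function(nm) {
    m <- cm[[nm]]
    thr <- thresholds[[m$thr]]
    if (m$dir > 0) measures[, m$col] > thr else measures[, m$col] < thr
  }, logical(nrow(measures)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(cm)))
  out
}

#' ROI extrema time series around the defect rim
#'
#' For each stored time step, the extremum of each measure over evaluation
#' points within `radius_mm` of the nearest rim node (minimum for the
#' minimum principal strain, maximum otherwise). ROI membership is computed
#' once from reference-configuration distances.
#'
#' @param states an `fe_states` with stored measures
#' @param rim_xyz matrix of rim node coordinates (reference configuration)
#' @param radius_mm ROI radius (mm); the literature choice is 1 mm
#' @return data frame with stance %, time, and one column per measure
#' @export
roi_max_series <- function(states, rim_xyz, radius_mm = 1.0) {
  check_scalar(radius_mm, "radius_mm", 0, Inf, strict_lower = TRUE)
  rim_xyz <- matrix(rim_xyz, ncol = 3)
  qp <- states$qp_coords
  d2min <- rep(Inf, nrow(qp))
  for (r in seq_len(nrow(rim_xyz)))
    d2min <- pmin(d2min, (qp[, 1] - rim_xyz[r, 1])^2 +
                    (qp[, 2] - rim_xyz[r, 2])^2 + (qp[, 3] - rim_xyz[r, 3])^2)
  roi <- d2min <= radius_mm^2
  if (!any(roi)) stopf("empty ROI: no evaluation point within %.2f mm of the rim",
                       radius_mm)
  steps <- which(!vapply(states$measures, is.null, logical(1)))
  if (!length(steps)) stopf("states carry no stored measures")
  rows <- lapply(steps, function(s) {
    m <- states$measures[[s]][roi, , drop = FALSE]
    data.frame(step = s, stance_pct = states$stance_pct[s],
               time_s = states$times[s],
               e1 = max(m[, "e1"]), e3 = min(m[, "e3"]),
               shear = max(m[, "shear"]), fibril = max(m[, "fibril"]),
               sig1 = max(m[, "sig1"]))
  })
  out <- do.call(rbind, rows)
  attr(out, "roi_points") <- sum(roi)
  out
}

#' Threshold exceedance intervals over the stance phase
#'
#' Maximal contiguous intervals (in % stance) where a series violates a
#' threshold; crossing times are linearly interpolated between samples.
#' For `direction = -1` (the compressive criterion) exceedance means
#' falling below the threshold.
#'
#' @param series numeric series sampled over the stance phase
#' @param threshold the limit
#' @param stance_pct sampling positions (%, strictly increasing)
#' @param direction +1 (exceed above) or -1 (exceed below)
#' @return matrix with columns `start`, `end` (% stance); zero rows if the
#'   threshold is never violated
#' @export
exceedance_intervals <- function(series, threshold, stance_pct,
                                 direction = +1) {
  if (length(series) != length(stance_pct))
    stopf("series and stance_pct must have equal length")
  if (is.unsorted(stance_pct, strictly = TRUE))
    stopf("stance_pct must be strictly increasing")
  g <- direction * (series - threshold)    # > 0 means exceeded
  n <- length(g)
  over <- g > 0
  if (!any(over)) return(matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("start", "end"))))
  cross <- function(i) {
    ## linear interpolation of the zero crossing in (i, i+1)
    stance_pct[i] + (stance_pct[i + 1] - stance_pct[i]) * (0 - g[i]) / (g[i + 1] - g[i])
  }
  starts <- ends <- numeric(0)
  inside <- FALSE
  for (i in seq_len(n)) {
    if (!inside && over[i]) {
      starts <- c(starts, if (i == 1) stance_pct[1] else cross(i - 1))
      inside <- TRUE
    }
    if (inside && !over[i]) {
      ends <- c(ends, cross(i - 1))
      inside <- FALSE
    }
  }
  if (inside) ends <- c(ends, stance_pct[n])
  cbind(start = starts, end = ends)
}

#' Compare intact and damaged state histories on a shared grid
#'
#' Evaluates the intact model's measures at the damaged model's evaluation
#' points (reference coordinates located in the intact mesh), forms
#' per-measure difference fields at each shared time step, and fold-change
#' series `|damaged| / |intact|` at co-located points; intact magnitudes
#' below `floor` are masked out of the fold change.
#'
#' @param intact,damaged `fe_states` objects on a shared time grid (the
#'   damaged states' measures must be stored at the compared steps)
#' @param steps steps to compare (default: all steps with stored measures
#'   in both)
#' @param floor minimum intact magnitude entering a fold change
#' @return object of class `scenario_comparison`: per-step difference
#'   matrices, fold-change matrices, and the location/stance % of the
#'   maximum absolute difference per measure
#' @export
compare_scenarios <- function(intact, damaged, steps = NULL, floor = 1e-4) {
  if (length(intact$times) != length(damaged$times) ||
      max(abs(intact$times - damaged$times)) > 1e-9)
    stopf("intact and damaged histories are on different time grids")
  have <- function(s, st) !vapply(s$measures[st], is.null, logical(1))
  if (is.null(steps)) {
    steps <- which(!vapply(intact$measures, is.null, logical(1)) &
                     !vapply(damaged$measures, is.null, logical(1)))
  }
  if (!length(steps)) stopf("no shared steps with stored measures")
  cols <- c("e1", "e3", "shear", "fibril", "sig1")
  ## identical meshes: co-located quadrature points, compare directly
  same_mesh <- isTRUE(all.equal(intact$mesh$nodes, damaged$mesh$nodes)) &&
    identical(intact$mesh$elems, damaged$mesh$elems)
  ## otherwise map damaged evaluation points into the intact mesh once
  loc <- if (!same_mesh)
    locate_points(intact$mesh, damaged$qp_coords, tol_out = 0.05)
  ## intact measures live at intact quadrature points; interpolate via
  ## volume-weighted nodal projection of the intact fields
  diffs <- folds <- vector("list", length(steps))
  names(diffs) <- names(folds) <- as.character(steps)
  maxdiff <- NULL
  for (si in seq_along(steps)) {
    s <- steps[si]
    mi <- intact$measures[[s]]
    md <- damaged$measures[[s]][, cols, drop = FALSE]
    mi_at_d <- if (same_mesh) mi[, cols, drop = FALSE] else {
      nod <- fe_qp_to_nodes(intact$mesh$elems, hex_shape_table(),
                            rep(1, nrow(mi)), mi[, cols, drop = FALSE],
                            nrow(intact$mesh$nodes))
      nodal <- nod$acc / pmax(nod$wt, 1e-30)
      out <- interp_at(intact$mesh, loc, nodal)
      colnames(out) <- cols
      out
    }
    dd <- md - mi_at_d
    ff <- abs(md) / pmax(abs(mi_at_d), floor)
    ff[abs(mi_at_d) < floor] <- NA
    diffs[[si]] <- dd
    folds[[si]] <- ff
    for (cn in cols) {
      k <- which.max(abs(dd[, cn]))
      maxdiff <- rbind(maxdiff,
                       data.frame(measure = cn, step = s,
                                  stance_pct = damaged$stance_pct[s],
                                  difference = dd[k, cn],
                                  fold_change = ff[k, cn],
                                  x = damaged$qp_coords[k, 1],
                                  y = damaged$qp_coords[k, 2],
                                  z = damaged$qp_coords[k, 3]))
    }
  }
  best <- do.call(rbind, lapply(split(maxdiff, maxdiff$measure), function(d) {
    d[which.max(abs(d$difference)), ]
  }))
  structure(list(steps = steps, differences = diffs, fold_changes = folds,
                 max_differences = best),
            class = "scenario_comparison")
}

## constant 8x8 trilinear shape table at the 2x2x2 Gauss points
hex_shape_table <- function() {
  gp <- 1 / sqrt(3)
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  out <- matrix(0, 8, 8)
  for (q in 1:8) {
    xi <- gp * s[q, ]
    out[, q] <- 0.125 * (1 + s[, 1] * xi[1]) * (1 + s[, 2] * xi[2]) *
      (1 + s[, 3] * xi[3])
  }
  out
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> %d steps compared\n", length(x$steps)))
  print(x$max_differences, row.names = FALSE)
  invisible(x)
}

#' Assemble a failure report for a damaged scenario
#'
#' Bundles per-criterion masks at each stored step, rim ROI extrema series,
#' exceedance intervals per criterion, and (when an intact history is
#' given) the intact-vs-damaged comparison.
#'
#' @param states damaged `fe_states`
#' @param rim_xyz rim node coordinates
#' @param thresholds a [failure_thresholds()]
#' @param intact optional intact `fe_states` for fold changes
#' @param radius_mm ROI radius (mm)
#' @return object of class `failure_report`
#' @export
failure_report <- function(states, rim_xyz, thresholds = failure_thresholds(),
                           intact = NULL, radius_mm = 1.0) {
  steps <- which(!vapply(states$measures, is.null, logical(1)))
  masks <- lapply(steps, function(s)
    classify_failure(states$measures[[s]], thresholds))
  names(masks) <- as.character(steps)
  roi <- roi_max_series(states, rim_xyz, radius_mm)
  cm <- criterion_map()
  intervals <- lapply(names(cm), function(nm) {
    m <- cm[[nm]]
    exceedance_intervals(roi[[m$col]], thresholds[[m$thr]], roi$stance_pct,
                         direction = m$dir)
  })
  names(intervals) <- names(cm)
  cmp <- if (!is.null(intact)) compare_scenarios(intact, states, steps = steps)
  else NULL
  structure(list(thresholds = thresholds, steps = steps, masks = masks,
                 roi_series = roi, exceedance = intervals,
                 comparison = cmp, radius_mm = radius_mm,
                 provenance = list(mesh_hash = object_hash(states$mesh$nodes))),
            class = "failure_report")
}

#' @export
print.failure_report <- function(x, ...) {
  cat(sprintf("<failure_report> %d steps, ROI radius %.1f mm (%d points)\n",
              length(x$steps), x$radius_mm,
              attr(x$roi_series, "roi_points") %||% NA))
  cat(sprintf("Peak ROI values: e3 = %.3f, shear = %.3f, e1 = %.3f, fibril = %.3f, sig1 = %.3f MPa\n",
              min(x$roi_series$e3), max(x$roi_series$shear),
              max(x$roi_series$e1), max(x$roi_series$fibril),
              max(x$roi_series$sig1)))
  for (nm in names(x$exceedance)) {
    iv <- x$exceedance[[nm]]
    if (nrow(iv))
      cat(sprintf("  %s exceeded over %s %% stance\n", nm,
                  paste(sprintf("[%.1f, %.1f]", iv[, 1], iv[, 2]),
                        collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a failure report to JSON
#' @param report a [failure_report()]
#' @param path output file
#' @export
write_failure_report <- function(report, path) {
  out <- list(
    thresholds = unclass(report$thresholds),
    roi_series = report$roi_series,
    exceedance = lapply(report$exceedance, function(m)
      if (nrow(m)) unname(apply(m, 1, function(r) list(start = r[1], end = r[2]),
                                simplify = FALSE)) else list()),
    max_differences = if (!is.null(report$comparison))
      report$comparison$max_differences else NULL,
    n_flagged = lapply(report$masks, colSums),
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
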