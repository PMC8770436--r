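#' Simulation case configurations
#'
#' The eight study cases: a stiff silicon Michigan-type probe at 1/10/20 um
#' tangential micromotion (cases 1-3), a polyimide probe (case 4), a
#' hypothetical probe with brain-matched modulus (case 5), and post-insertion
#' PVAc-NC compliant probes 63 um and 25 um thick (cases 6-8). An extra
#' config `"case8_thick63"` runs the 63 um compliant probe at 20 um, the
#' variant used for the strain-distribution profiles.
#'
#' @param id case id: integer 1..8 or one of the shipped config names
#'   (`"case1"` .. `"case8"`, `"case8_thick63"`).
#' @param mesh a [mesh_params()] (default [mesh_params()]).
#' @param brain_E brain-tissue modulus override, MPa (default 6).
#' @param solver `"direct"` or `"cg"`.
#' @param tol solver tolerance.
#' @param vm_nu_eff optional effective Poisson ratio override for the
#'   equivalent-strain formula (default: each element's material ratio).
#' @param symmetry `"quarter"` (default) solves the quarter domain with
#'   symmetry-plane constraints (exact for this centred geometry and
#'   tangential load, at a quarter of the cost); `"none"` solves the full
#'   domain.
#' @return object of class `"case_config"`.
#' @export
#' @examples
#' case_config(1)
case_config <- function(id, mesh = mesh_params(), brain_E = 6,
                        solver = "direct", tol = 1e-8, vm_nu_eff = NULL,
                        symmetry = c("quarter", "none")) {
  symmetry <- match.arg(symmetry)
  tab <- case_table()
  key <- as.character(id)
  if (grepl("^[0-9]+$", key)) key <- paste0("case", key)
  if (!key %in% names(tab))
    stop("unknown case '", id, "'; available: ",
         paste(names(tab), collapse = ", "))
  row <- tab[[key]]
  stopifnot(inherits(mesh, "mesh_params"), row$displacement > 0)
  structure(c(row, list(mesh = mesh, brain_E = brain_E, solver = solver,
                        tol = tol, vm_nu_eff = vm_nu_eff,
                        symmetry = symmetry)),
            class = "case_config")
}

# Table 1 case matrix (probe dims in um, displacement along x in um)
case_table <- function() {
  p25 <- c(length = 1125, width = 125, thickness = 25)
  p63 <- c(length = 1125, width = 125, thickness = 63)
  mk <- function(id, mat, dims, d)
    list(id = id, probe_material = mat,
         probe_length = dims[["length"]], probe_width = dims[["width"]],
         probe_thickness = dims[["thickness"]], displacement = d)
  list(case1 = mk("case1", "silicon", p25, 1),
       case2 = mk("case2", "silicon", p25, 10),
       case3 = mk("case3", "silicon", p25, 20),
       case4 = mk("case4", "polyimide", p25, 1),
       case5 = mk("case5", "hypothetical", p25, 1),
       case6 = mk("case6", "pvac_nc", p63, 1),
       case7 = mk("case7", "pvac_nc", p25, 1),
       case8 = mk("case8", "pvac_nc", p25, 20),
       case8_thick63 = mk("case8_thick63", "pvac_nc", p63, 20))
}

#' @export
print.case_config <- function(x, ...) {
  cat(sprintf("<case_config> %s: %s probe %g x %g x %g um, d = %g um (x), h_near = %g um\n",
              x$id, x$probe_material, x$probe_length, x$probe_width,
              x$probe_thickness, x$displacement, x$mesh$h_near))
  invisible(x)
}

#' Domain specification for a case
#'
#' @param case a [case_config()].
#' @return a [domain_spec()] with the case's probe dimensions in the default
#'   1500 x 1500 x 1500 um tissue block.
#' @export
build_domain_spec <- function(case) {
  stopifnot(inherits(case, "case_config"))
  domain_spec(probe_length = case$probe_length,
              probe_width = case$probe_width,
              probe_thickness = case$probe_thickness)
}

case_materials <- function(case) {
  cat_ <- material_catalog(brain_E = case$brain_E)
  if (!case$probe_material %in% names(cat_))
    stop("unknown probe material '", case$probe_material, "'")
  list(probe = cat_[[case$probe_material]], tissue = cat_$brain)
}

#' Run one simulation case end to end
#'
#' Full pipeline: mesh generation, assembly, boundary conditions, solve,
#' strain recovery, and extraction of the reported quantities.
#'
#' @param case a [case_config()].
#' @param mesh optional pre-built `"hex_mesh"` for the case geometry (reused
#'   across cases sharing a probe thickness).
#' @param system optional pre-assembled `"linear_system"` (must match `mesh`
#'   and the case materials); used to amortise assembly across displacement
#'   magnitudes.
#' @param keep_field keep the strain field and mesh on the result (default
#'   TRUE; set FALSE to save memory in batch runs).
#' @param out_dir optional directory: writes `<id>.vtu` (displacements +
#'   Von Mises) and `<id>_result.json` there.
#' @param verbose log element count, residual and timing to stderr.
#' @return object of class `"case_result"`: `id`, `max_strain`, `location`,
#'   `location_class`, `element_count`, `residual`, `elapsed` (s), and
#'   (optionally) `field`, `mesh`, `materials`.
#' @export
run_case <- function(case, mesh = NULL, system = NULL, keep_field = TRUE,
                     out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(case, "case_config"))
  t0 <- proc.time()[["elapsed"]]
  spec <- build_domain_spec(case)
  if (is.null(mesh)) mesh <- generate_hex_mesh(spec, case$mesh,
                                               symmetry = case$symmetry)
  mats <- case_materials(case)
  if (is.null(system)) system <- assemble(mesh, mats)
  system <- apply_boundary_conditions(system,
                                      fixed = mesh$node_sets$bottom_edges,
                                      prescribed = mesh$node_sets$probe_top_face,
                                      d = case$displacement, direction = "x")
  if (identical(mesh$symmetry, "quarter")) {
    # x = 0 is an antisymmetry plane (u_y = u_z = 0), z = 0 a symmetry
    # plane (u_z = 0); skip dofs already prescribed on the probe top face
    sx <- setdiff(mesh$node_sets$sym_x0, mesh$node_sets$bottom_edges)
    sz <- setdiff(mesh$node_sets$sym_z0, mesh$node_sets$bottom_edges)
    system <- constrain_dofs(system, node_dofs(sx, 2:3),
                             rep(0, 2L * length(sx)))
    system <- constrain_dofs(system, node_dofs(sz, 3),
                             rep(0, length(sz)))
  }
  u <- solve_system(system, method = case$solver, tol = case$tol)
  field <- compute_strain_field(mesh, u, materials = mats,
                                nu_eff = case$vm_nu_eff)
  mx <- max_tissue_strain(field, mesh)
  cls <- classify_max_location(mx$location, spec)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (verbose)
    message(sprintf("[%s] %d elements, residual %.2e, max tissue strain %.5g (%s), %.1f s",
                    case$id, nrow(mesh$elements), u$residual, mx$value, cls,
                    elapsed))
  res <- structure(list(id = case$id, max_strain = mx$value,
                        location = mx$location, location_class = cls,
                        element = mx$element,
                        element_count = nrow(mesh$elements),
                        residual = u$residual, elapsed = elapsed,
                        displacement = case$displacement,
                        probe_material = case$probe_material,
                        probe_thickness = case$probe_thickness),
                   class = "case_result")
  if (keep_field) {
    res$field <- field
    res$mesh <- mesh
    res$materials <- mats
    res$displacement_field <- u
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vtu(mesh, file.path(out_dir, paste0(case$id, ".vtu")),
              point_data = list(displacement = u$U),
              cell_data = list(von_mises = field$von_mises))
    jsonlite::write_json(res[c("id", "max_strain", "location",
                               "location_class", "element_count",
                               "residual", "displacement")],
                         file.path(out_dir, paste0(case$id, "_result.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> %s: max tissue Von Mises strain %.5g at (%.1f, %.1f, %.1f) um [%s], %d elements\n",
              x$id, x$max_strain, x$location[1], x$location[2], x$location[3],
              x$location_class, x$element_count))
  invisible(x)
}

#' Run a batch of cases and tabulate the comparisons
#'
#' Runs each config and derives the cross-case columns: strain normalized to
#' the case-1 baseline and percent reduction versus case 1 (when a case-1
#' config is present; otherwise versus the first case). Meshes and assembled
#' systems are shared between cases with identical geometry and materials.
#' Per-case failures are recorded and the run continues.
#'
#' @param configs list of [case_config()]s.
#' @param verbose log progress to stderr.
#' @return data.frame, one row per case: `id`, `max_strain`,
#'   `location_class`, `y_location`, `element_count`, `residual`,
#'   `normalized_to_case1`, `percent_reduction_vs_case1`, `error`.
#' @export
run_table <- function(configs, verbose = FALSE) {
  stopifnot(length(configs) >= 1)
  if (inherits(configs, "case_config")) configs <- list(configs)
  results <- vector("list", length(configs))
  mesh_cache <- list()
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    key <- paste(cf$probe_length, cf$probe_width, cf$probe_thickness,
                 cf$mesh$h_near, cf$mesh$ratio, cf$mesh$h_max,
                 cf$mesh$n_through_thickness, cf$symmetry, sep = "/")
    results[[i]] <- tryCatch({
      if (is.null(mesh_cache[[key]]))
        mesh_cache[[key]] <- generate_hex_mesh(build_domain_spec(cf), cf$mesh,
                                               symmetry = cf$symmetry)
      run_case(cf, mesh = mesh_cache[[key]], keep_field = FALSE,
               verbose = verbose)
    }, error = function(e) {
      structure(list(id = cf$id, error = conditionMessage(e)),
                class = "case_result")
    })
  }
  ids <- vapply(results, function(r) r$id, "")
  ok <- vapply(results, function(r) is.null(r$error), TRUE)
  out <- data.frame(
    id = ids,
    max_strain = vapply(results, function(r)
      if (is.null(r$error)) r$max_strain else NA_real_, 1.0),
    location_class = vapply(results, function(r)
      if (is.null(r$error)) r$location_class else NA_character_, ""),
    y_location = vapply(results, function(r)
      if (is.null(r$error)) r$location[2] else NA_real_, 1.0),
    element_count = vapply(results, function(r)
      if (is.null(r$error)) r$element_count else NA_integer_, 1L),
    residual = vapply(results, function(r)
      if (is.null(r$error)) r$residual else NA_real_, 1.0),
    error = vapply(results, function(r)
      if (is.null(r$error)) NA_character_ else r$error, ""),
    stringsAsFactors = FALSE)
  base_i <- if ("case1" %in% ids) match("case1", ids) else 1L
  base <- out$max_strain[base_i]
  if (isTRUE(is.finite(base)) && base > 0) {
    out$normalized_to_case1 <- out$max_strain / base
    out$percent_reduction_vs_case1 <- 100 * (1 - out$max_strain / base)
  } else {
    out$normalized_to_case1 <- NA_real_
    out$percent_reduction_vs_case1 <- NA_real_
  }
  attr(out, "results") <- results
  out
}

#' Read and write case configurations as YAML
#'
#' The YAML schema mirrors [case_config()]: per-case `probe_material`, probe
#' dims, `displacement`, and nested `mesh` (h_near, ratio, h_max,
#' n_through_thickness) and solver settings. The shipped configs live at
#' `system.file("extdata", "cases.yaml", package = "micromotionfem")`.
#'
#' @param path YAML file path.
#' @return for `read_case_yaml`, a named list of [case_config()]s.
#' @export
read_case_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    mp <- do.call(mesh_params, r$mesh)
    cc <- case_config(r$id, mesh = mp,
                      brain_E = r$brain_E %||% 6,
                      solver = r$solver %||% "direct",
                      tol = r$tol %||% 1e-8,
                      vm_nu_eff = r$vm_nu_eff,
                      symmetry = r$symmetry %||% "quarter")
    # allow explicit overrides of the tabulated values
    for (f in c("probe_material", "probe_length", "probe_width",
                "probe_thickness", "displacement"))
      if (!is.null(r[[f]])) cc[[f]] <- r[[f]]
    cc
  })
}

#' @rdname read_case_yaml
#' @param configs named list of [case_config()]s.
#' @export
write_case_yaml <- function(configs, path) {
  raw <- lapply(configs, function(cc) {
    list(id = cc$id, probe_material = cc$probe_material,
         probe_length = cc$probe_length, probe_width = cc$probe_width,
         probe_thickness = cc$probe_thickness,
         displacement = cc$displacement,
         mesh = cc$mesh[c("h_near", "ratio", "h_max", "n_through_thickness")],
         brain_E = cc$brain_E, solver = cc$solver, tol = cc$tol,
         vm_nu_eff = cc$vm_nu_eff, symmetry = cc$symmetry)
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
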