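#' Write / read a mesh snapshot as JSON
#'
#' Schema: `box` (L_DV, L_AP), `vertices` (N_v x 2), `cells` (list of
#' 1-based vertex-index loops), and optionally per-cell `state` columns.
#'
#' @param mesh a `vm_mesh`.
#' @param path output file.
#' @param state optional per-cell state tibble (as in `vm_sim$state`).
#' @export
write_mesh_json <- function(mesh, path, state = NULL) {
  obj <- list(box = mesh$box, vertices = mesh$v, cells = mesh$cells)
  if (!is.null(state)) obj$state <- state
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_mesh_json
#' @return `read_mesh_json` returns a `vm_mesh`; any stored state is
#'   attached as attribute `state`.
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$vertices
  if (!is.matrix(v)) v <- do.call(rbind, v)
  cells <- obj$cells
  # equal-length loops simplify to a matrix (one row per cell)
  if (is.matrix(cells)) cells <- lapply(seq_len(nrow(cells)),
                                        function(i) cells[i, ])
  m <- vm_mesh(matrix(as.numeric(v), ncol = 2, byrow = FALSE),
               lapply(cells, as.integer), as.numeric(obj$box))
  if (!is.null(obj$state)) attr(m, "state") <- tibble::as_tibble(obj$state)
  m
}

#' Export a simulation to flat files
#'
#' Writes `cells.csv` (per-cell geometry + state), `divisions.csv`,
#' `t1.csv`, `extrusions.csv`, `clones.csv`, `series.csv`, a final-mesh
#' `mesh.json`, and `run.json` (config echo) into `dir`.
#'
#' @param sim a `vm_sim`.
#' @param dir output directory (created if needed).
#' @export
export_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(geometry_table(sim$mesh, sim$state), "cells.csv")
  wcsv(sim$events$divisions, "divisions.csv")
  wcsv(sim$events$t1, "t1.csv")
  wcsv(sim$events$extrusions, "extrusions.csv")
  if (!is.null(sim$clones)) wcsv(sim$clones, "clones.csv")
  wcsv(sim$series, "series.csv")
  write_mesh_json(sim$mesh, file.path(dir, "mesh.json"), sim$state)
  cfg <- sim$config
  cfg$interp <- NULL                     # functions do not serialise
  cfg_flat <- list(
    lambda_bar = cfg$nd$lambda_bar, gamma_bar = cfg$nd$gamma_bar,
    A0_ref = cfg$nd$A0, dt = cfg$mech$dt, n_rows = cfg$n_rows,
    n_cols = cfg$n_cols, t_T_hours = cfg$phases$t_T_hours, A_c = cfg$rule$A_c,
    equilibrate_hours = cfg$equilibrate_hours, run_hours = cfg$run_hours,
    mu_dv = cfg$mu_dv, mu_ap = cfg$mu_ap, pmn_fraction = cfg$pmn_fraction,
    diff_rate_per_hour = cfg$diff_rate_per_hour, seed = cfg$seed,
    package_version = as.character(utils::packageVersion("neurovertex"))
  )
  jsonlite::write_json(cfg_flat, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Accepts the flat key set written by [export_simulation()] (`lambda_bar`,
#' `gamma_bar`, `n_rows`, ...) or a `preset` name, and returns a
#' [simulation_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a `vm_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  keep <- intersect(names(raw), names(formals(simulation_config)))
  do.call(simulation_config, raw[keep])
}
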