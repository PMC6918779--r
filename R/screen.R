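#' Screen mechanical parameter space against reference geometry
#'
#' Runs simulations on a grid of `(lambda_bar, gamma_bar)` points and scores
#' each against reference geometry tables with
#' [geometry_similarity_score()] and (optionally) against reference tissue
#' growth with [tissue_fit_score()]. Replicates differ only by seed.
#'
#' @param lambda_bars,gamma_bars grid coordinates (all combinations used).
#' @param ref reference geometry table or list of tables.
#' @param base_config a [simulation_config()] whose mechanics are overridden
#'   per grid point.
#' @param reps replicate simulations per point.
#' @param area_scale see [geometry_similarity_score()].
#' @param dv_change_ref,final_ratio_ref optional tissue-scale references.
#' @param seed base seed; replicate `r` of point `k` uses
#'   `seed + 1000 * k + r`.
#' @return a `vm_screen` tibble: `lambda_bar`, `gamma_bar`,
#'   `geometry_score`, `tissue_score`, `n_reps`.
#' @export
screen_parameters <- function(lambda_bars, gamma_bars, ref, base_config,
                              reps = 1, area_scale = NULL,
                              dv_change_ref = NULL, final_ratio_ref = NULL,
                              seed = 1) {
  grid <- expand.grid(lambda_bar = lambda_bars, gamma_bar = gamma_bars)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cfg <- base_config
    cfg$nd <- nondimensional_params(grid$lambda_bar[k], grid$gamma_bar[k],
                                    base_config$nd$A0)
    cfg$mech <- denormalise_parameters(cfg$nd, dt = base_config$mech$dt)
    sims <- lapply(seq_len(reps), function(r) {
      cfg$seed <- seed + 1000L * k + r
      run_simulation(cfg)
    })
    tabs <- lapply(sims, function(s) geometry_table(s$mesh, s$state))
    gs <- geometry_similarity_score(tabs, ref, area_scale = area_scale)
    ts <- NA_real_
    if (!is.null(dv_change_ref) && !is.null(final_ratio_ref)) {
      dvc <- vapply(sims, function(s) {
        s$series$L_DV[nrow(s$series)] - s$series$L_DV[1]
      }, 0)
      fr <- vapply(sims, function(s) tissue_aspect_ratio(s$mesh), 0)
      ts <- tissue_fit_score(dvc, fr, dv_change_ref, final_ratio_ref)
    }
    tibble::tibble(lambda_bar = grid$lambda_bar[k],
                   gamma_bar = grid$gamma_bar[k],
                   geometry_score = as.numeric(gs), tissue_score = ts,
                   n_reps = reps)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vm_screen", class(out))
  out
}
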