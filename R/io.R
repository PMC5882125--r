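#' Read and write run configurations
#'
#' Run configurations are declarative YAML documents with blocks `model`
#' (variant, x_diffusion, exponents or explicit regulatory specs),
#' `params`, `lattice` (`type: ring, N: ...` or `type: hex, nx:, ny:`),
#' and `control`. [config_to_run()] materializes the objects.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: the raw config list; `config_to_run()`: a
#'   list with `spec`, `params`, `lattice`, `control`.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config a config list as returned by [read_run_config()].
#' @export
config_to_run <- function(config) {
  m <- config$model %||% list()
  reg_args <- lapply(m$regulatory %||% list(), function(r)
    reg_fun(r$form %||% "power", r$exponent %||% 1,
            ref = r$ref %||% NA_real_, ceiling = r$ceiling %||% NA_real_))
  spec <- do.call(model_spec, c(
    list(variant = m$variant %||% "O",
         x_diffusion = if (is.null(m$x_diffusion) ||
                           identical(m$x_diffusion, "none")) "simple"
                       else m$x_diffusion,
         psi_form = m$psi_form %||% "hill",
         qss_pin = isTRUE(m$qss_pin)),
    m[intersect(names(m), c("n", "m", "r"))],
    reg_args))
  params <- do.call(model_params,
                    config$params %||% list())
  lt <- config$lattice %||% list(type = "ring", N = 40)
  lattice <- if (identical(lt$type, "hex")) hex_lattice(lt$nx, lt$ny)
             else ring_lattice(lt$N %||% 40)
  ctl <- do.call(sim_control, config$control %||% list())
  list(spec = spec, params = params, lattice = lattice, control = ctl)
}

#' Write a state or trajectory as CSV
#'
#' Long format: `field`, `id`, `value` for states; with a leading `time`
#' column for trajectories (cell auxin snapshots; apoplast auxin and X
#' included when present).
#'
#' @param state an `auxin_state`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(state, path) {
  rows <- list()
  for (f in names(state)) {
    v <- state[[f]]
    if (is.null(v)) next
    rows[[f]] <- data.frame(field = f, id = seq_along(v),
                            value = as.vector(v))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_csv
#' @param trajectory an `auxin_trajectory`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  blocks <- list()
  for (f in c("a", "a_apo", "x")) {
    m <- trajectory[[f]]
    if (is.null(m)) next
    blocks[[f]] <- data.frame(
      time = rep(trajectory$times, ncol(m)),
      field = f,
      id = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m))
  }
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records what a run was and how it ended: model variant, parameters,
#' lattice, control settings (including the seed), stop reason, final
#' conservation diagnostics, and pattern metrics where computed.
#'
#' @param trajectory an `auxin_trajectory` (from [simulate_model()]).
#' @param spec,params,lattice,control the run inputs.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(trajectory, spec, params, lattice, control,
                               path) {
  dg <- trajectory$diagnostics
  last <- dg[nrow(dg), ]
  obj <- list(
    model = list(variant = spec$variant, x_diffusion = spec$x_diffusion,
                 qss_pin = spec$qss_pin),
    params = unclass(as_params(params)),
    lattice = list(type = lattice$type, n_cells = lattice$n_cells,
                   K = lattice$K),
    control = unclass(control),
    stop_reason = trajectory$stop_reason,
    steps = trajectory$steps,
    final_time = trajectory$times[length(trajectory$times)],
    final_diagnostics = as.list(last),
    metrics = if (!is.null(trajectory$metrics))
      lapply(trajectory$metrics, function(m)
        if (is.null(m)) NULL else unclass(m)[c("k1", "L1", "L2",
                                               "n_spots", "n_clusters",
                                               "patterned")])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export a dispersion result
#'
#' Writes the (nu, lambda) curve as CSV and, when `json_path` is given,
#' the condition summary (nu*, L*, unstable, coefficients) as JSON.
#'
#' @param disp a `dispersion_result`.
#' @param csv_path,json_path output files (either may be `NULL`).
#' @export
write_dispersion <- function(disp, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(data.frame(k = disp$k, nu = disp$nu,
                                lambda = disp$lambda_k),
                     csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    keep <- intersect(names(disp),
                      c("model", "N", "c0", "c1", "c2", "alpha", "beta",
                        "gamma", "kappa", "Ra", "Rx", "nu_star", "L_star",
                        "unstable", "units_of_L"))
    jsonlite::write_json(disp[keep], json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(disp)
}
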