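#' Parameter-plane sweep of a model
#'
#' Runs the full pipeline (equilibrium, seeded perturbation, Euler
#' integration, pattern metrics) on every point of a one- or
#' two-parameter grid, and overlays the analytic instability condition
#' where a dispersion relation exists. Axis parameters may be rate
#' constants (names in [model_params()]) or the regulatory exponents
#' `"n"`, `"m"`, `"r"`.
#'
#' Each grid point gets its own seed derived from `master_seed` by a
#' counter, so any single cell can be reproduced in isolation. A blown-up
#' integration (step size too large for that corner of parameter space) is
#' recorded as a failed cell and the sweep continues.
#'
#' @param spec a [model_spec()].
#' @param params base [model_params()].
#' @param axis1,axis2 lists `list(par = <name>, values = <numeric>)`;
#'   `axis2` may be `NULL` for a 1D transect.
#' @param N ring size.
#' @param control a [sim_control()]; its `seed` is ignored in favor of the
#'   per-cell seeds.
#' @param master_seed integer master seed.
#' @return A data frame of class `"sweep_result"`, one row per grid point:
#'   axis values, `seed`, `patterned`, `L1_cells`, `L2_cells`, `L1_apo`,
#'   `L2_apo` (apoplast columns NA for Model O), `stop_reason`, `failed`,
#'   and where available the analytic `unstable`, `nu_star`, `L_star`.
#' @export
run_sweep <- function(spec, params, axis1, axis2 = NULL, N = 40,
                      control = sim_control(), master_seed = 1L) {
  stopifnot(is.list(axis1), !is.null(axis1$par), length(axis1$values) > 0)
  params <- as_params(params)
  grid <- if (is.null(axis2)) {
    data.frame(v1 = axis1$values)
  } else {
    expand.grid(v1 = axis1$values, v2 = axis2$values,
                KEEP.OUT.ATTRS = FALSE)
  }
  n_cells_budget <- nrow(grid) * (control$max_time / control$dt)
  if (n_cells_budget * N > 1e10)
    warning("sweep budget is large (", nrow(grid), " cells x ",
            format(control$max_time / control$dt), " steps); consider a ",
            "coarser grid or shorter horizon")
  lat <- ring_lattice(N)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- apply_axis(spec, params, axis1$par, grid$v1[i])
    if (!is.null(axis2))
      sp <- apply_axis(sp$spec, sp$params, axis2$par, grid$v2[i])
    seed_i <- cell_seed(master_seed, i)
    ctl <- control; ctl$seed <- seed_i
    ana <- analytic_condition_or_null(sp$spec, sp$params)
    res <- tryCatch(
      simulate_model(sp$spec, sp$params, lat, ctl),
      error = function(e) e)
    failed <- inherits(res, "error")
    mc <- if (!failed) res$metrics$cells else NULL
    ma <- if (!failed) res$metrics$apoplast else NULL
    rows[[i]] <- data.frame(
      v1 = grid$v1[i],
      v2 = if (is.null(axis2)) NA_real_ else grid$v2[i],
      seed = seed_i,
      failed = failed,
      stop_reason = if (failed) conditionMessage(res) else res$stop_reason,
      patterned = if (failed) NA else isTRUE(mc$patterned) ||
        isTRUE(ma$patterned),
      L1_cells = metric_or_na(mc, "L1"), L2_cells = metric_or_na(mc, "L2"),
      L1_apo = metric_or_na(ma, "L1"), L2_apo = metric_or_na(ma, "L2"),
      unstable = if (is.null(ana)) NA else ana$unstable,
      nu_star = if (is.null(ana)) NA_real_ else ana$nu_star,
      L_star = if (is.null(ana)) NA_real_ else ana$L_star
    )
  }
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c(axis1$par, if (is.null(axis2)) ".v2" else axis2$par)
  attr(out, "spec") <- spec
  attr(out, "N") <- N
  attr(out, "master_seed") <- master_seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

metric_or_na <- function(m, what) {
  if (is.null(m) || !isTRUE(m$patterned)) NA_real_ else m[[what]]
}

apply_axis <- function(spec, params, par, value) {
  if (par %in% names(params)) {
    params[[par]] <- value
  } else if (par %in% c("n", "m", "r")) {
    spec <- set_exponent(spec, par, value)
  } else {
    stop("unknown sweep parameter: ", par)
  }
  list(spec = spec, params = params)
}

set_exponent <- function(spec, which, value) {
  reg <- spec$reg0 %||% spec$reg
  if (which == "n") {
    f <- if (spec$family == "O") "phi0" else "phia"
    if (reg[[f]]$form == "one") reg[[f]] <- reg_fun("power", value)
    else reg[[f]]$exponent <- value
  } else if (which == "r") {
    reg$theta$exponent <- value
  } else {  # m: X feedback exponent
    reg$phix$exponent <- value
    reg$psi1$exponent <- value
    reg$psi2$exponent <- value
  }
  spec$reg <- reg
  spec$reg0 <- NULL
  spec$resolved <- FALSE
  spec
}

cell_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 7919 + i * 104729) %% 2147483647)
}

analytic_condition_or_null <- function(spec, params) {
  tryCatch(pattern_condition(spec, params), error = function(e) NULL)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep result: %d grid points, %d patterned, %d failed\n",
              nrow(x), sum(x$patterned, na.rm = TRUE), sum(x$failed)))
  NextMethod()
}

#' Heatmap of a sweep metric
#'
#' @param x a `sweep_result` from a two-axis sweep.
#' @param metric column to plot (default `"L1_cells"`).
#' @param ... passed to [graphics::image()].
#' @export
plot.sweep_result <- function(x, metric = "L1_cells", ...) {
  ax <- names(x)[1:2]
  v1 <- sort(unique(x[[1]])); v2 <- sort(unique(x[[2]]))
  z <- matrix(NA_real_, length(v1), length(v2))
  z[cbind(match(x[[1]], v1), match(x[[2]], v2))] <- x[[metric]]
  graphics::image(v1, v2, z, xlab = ax[1], ylab = ax[2],
                  main = metric, ...)
  invisible(x)
}

#' Figure-shaped sweep and simulation presets
#'
#' Emits ready-to-run configurations for the main computational
#' experiments: the Model O `p`-`Da` plane (`"fig2"`), the Model A
#' `p`-`Da` plane (`"fig4"`), its symplast/apoplast diffusion variants
#' (`"fig5"`), the Model B `n`-`m` feedback planes (`"fig6"`), the Model
#' B6 planes and `Dx` transect (`"fig8"`), and the 2D hexagonal triptych
#' of Models O/A/B6 (`"fig3-2d"`). `scale = "test"` uses reduced grids and
#' `N = 40`; `"full"` uses 32 x 32 grids on `N = 200` rings.
#'
#' @param name preset name.
#' @param scale `"test"` or `"full"`.
#' @return A list with elements `spec`, `params`, `axis1`, `axis2`, `N`
#'   (or a list of 2D run configs for `"fig3-2d"`), and `control`.
#' @export
sweep_preset <- function(name = c("fig2", "fig4", "fig5", "fig6", "fig8",
                                  "fig3-2d"),
                         scale = c("test", "full")) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  N <- if (scale == "test") 40L else 200L
  npts <- if (scale == "test") 8L else 32L
  gr <- function(lo, hi) exp(seq(log(lo), log(hi), length.out = npts))
  ctl <- sim_control(max_time = if (scale == "test") 400 else 1000)
  switch(name,
    fig2 = list(
      spec = model_spec("O", n = 2),
      params = model_params(A = 1, Ep = 1, Gp = 1, Ga = 0.2),
      axis1 = list(par = "p", values = gr(1, 100)),
      axis2 = list(par = "Da", values = gr(0.1, 100)),
      N = N, control = ctl),
    fig4 = list(
      spec = model_spec("A", n = 4),
      params = model_params(A = 1, Ep = 1, Eq = 1, Gp = 1, V = 1,
                            q = 10, Ga = 0.2),
      axis1 = list(par = "p", values = gr(1, 100)),
      axis2 = list(par = "Da", values = gr(0.1, 100)),
      N = N, control = ctl),
    fig5 = list(
      symplast = list(
        spec = model_spec("A_symplast", n = 4),
        params = model_params(A = 1, Ep = 1, Eq = 1, Gp = 1, V = 1,
                              q = 10, Ga = 0.2),
        axis1 = list(par = "p", values = gr(1, 100)),
        axis2 = list(par = "Da1", values = gr(0.1, 100)),
        N = N, control = ctl),
      apoplast = list(
        spec = model_spec("A_apoplast", n = 4),
        params = model_params(A = 1, Ep = 1, Eq = 1, Gp = 1, V = 1,
                              q = 10, Ga = 0.2),
        axis1 = list(par = "p", values = gr(1, 100)),
        axis2 = list(par = "Da2", values = gr(0.1, 100)),
        N = N, control = ctl)),
    fig6 = lapply(stats::setNames(nm = paste0("B", 1:6)), function(v) list(
      spec = model_spec(v, n = 1, r = 1,
                        x_diffusion = "simple"),
      params = model_params(A = 1, Ep = 1, Eq = 1, Gx = 1, Gp = 1,
                            Da = 1, V = 1, p = 10, q = 10, Dx = 10,
                            Ga = 0.2),
      axis1 = list(par = "n", values = seq(-4, 4, length.out = npts)),
      axis2 = list(par = "m", values = seq(-10, 10, length.out = npts)),
      N = N, control = ctl)),
    fig8 = list(
      dx_transect = list(
        spec = model_spec("B6", r = 2, m = 6),
        params = model_params(A = 1, Ep = 1, Eq = 1, Gp = 1, V = 1,
                              p = 10, q = 10, Ga = 0.2, Gx = 0.5,
                              Da = 1),
        axis1 = list(par = "Dx", values = c(0.2, 1, 5, 20)),
        axis2 = NULL, N = N, control = ctl),
      rm_plane = list(
        spec = model_spec("B6", r = 2, m = 6),
        params = model_params(A = 1, Ep = 1, Eq = 1, Gp = 1, V = 1,
                              p = 10, q = 10, Ga = 0.2, Gx = 1,
                              Da = 1, Dx = 20),
        axis1 = list(par = "r", values = seq(-4, 4, length.out = npts)),
        axis2 = list(par = "m", values = seq(-10, 10, length.out = npts)),
        N = N, control = ctl)),
    `fig3-2d` = {
      nn <- if (scale == "test") 14L else 20L
      list(
        O = list(spec = model_spec("O", n = 2),
                 params = model_params(A = 1, Ep = 1, Gp = 1, Da = 2,
                                       p = 2, Ga = 0.2),
                 lattice = c(nn, nn), control = ctl),
        A = list(spec = model_spec("A", n = 3),
                 params = model_params(A = 1, Ep = 1, Eq = 1, Gp = 1,
                                       Da = 1, V = 1, p = 5, q = 5,
                                       Ga = 0.2),
                 lattice = c(nn, nn), control = ctl),
        B6 = list(spec = model_spec("B6", r = 2, m = 3),
                  params = model_params(A = 1, Ep = 1, Eq = 1, Gp = 1,
                                        Gx = 1, Da = 1, Dx = 1, V = 1,
                                        p = 5, q = 5, Ga = 0.2),
                  lattice = c(nn, nn), control = ctl))
    })
}
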