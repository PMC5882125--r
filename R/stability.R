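#' Analytic dispersion relation on a 1D ring
#'
#' Linear growth rate of a spatially periodic perturbation of the uniform
#' equilibrium, as a function of the lattice wavenumber variable
#' `nu = cos(2*pi*k/N)`:
#'
#' * **Model O** (and its QSS form): `lambda(nu) = 4 c2 nu^2 + 2 c1 nu +
#'   c0 - 2 c2`, with `c1 = Ep*p + Da`, `c2 = -Ep*p*a_eq*phi0'(a_eq) /
#'   (2*phi0(a_eq))`, and `c0 = -(Ga + 2 c1 + 2 c2)`; consequently
#'   `lambda(1) = -Ga` exactly (the uniform mode relaxes at the auxin
#'   turnover rate).
#' * **Model A**: `lambda(nu) = 2 c1 nu + c0` is affine in `nu`, with
#'   `alpha = 2(Ep*p + Da)(Eq*q + Da) / (V (2 Ep*p + 2 Da + Ga))`,
#'   `beta = Ep*p (2 (Eq*q + Da) a'_eq + Ga*A) phia'(a'_eq) /
#'   (V (2 Ep*p + 2 Da + Ga) phia(a'_eq))`, `c0 = alpha + beta -
#'   (2 (Eq*q + Da)/V + Ga)`, `c1 = (alpha - beta)/2`. Its maximum over
#'   the grid is always attained at `nu = -1` (wavelength 2 apoplast
#'   spaces) whenever the equilibrium is unstable.
#' * **Model B6** (reduced, `phia = 1`): the same quadratic form as Model
#'   O with `gamma = (Eq*q + Da) / (2 Eq*q + 2 Da + V*Ga)`,
#'   `kappa = Dx*Gx / ((2 Dx + Gx)(2 Dx + V*Gx))`, `c1 = gamma (Ep*p +
#'   Da)`, `c2 = -gamma*kappa*Ep*p*a_eq*theta'(a_eq) * phix'(x'_eq) /
#'   (2 phix(x'_eq))`, `c0 = 2 c1 - 2 c2 - (2 Ep*p + 2 Da + Ga)`; this
#'   relation is approximate (it descends from a reduced linearization)
#'   and is validated against the numerical Jacobian spectrum in sign and
#'   argmax.
#'
#' @param model `"O"`, `"A"`, or `"B6"` — or a [model_spec()] whose
#'   variant belongs to one of those families.
#' @param params a [model_params()] list.
#' @param N ring size used for the wavenumber grid.
#' @param spec optional [model_spec()] carrying the regulatory functions;
#'   defaults to `model_spec(model)` defaults.
#' @return An object of class `"dispersion_result"`: coefficients (`c0`,
#'   `c1`, and `c2`, `alpha`, `beta`, `gamma`, `kappa` where defined),
#'   ratios `Ra = Da/(Ep p)` and `Rx = Dx/Gx`, the grid `k`, `nu`,
#'   `lambda_k`, the continuous maximizer `nu_star`, predicted wavelength
#'   `L_star` (`units_of_L`: cells, or apoplast spaces for Model A),
#'   and the `unstable` flag.
#' @seealso [pattern_condition()], [jacobian_spectrum()]
#' @export
dispersion <- function(model, params, N = 200, spec = NULL) {
  if (inherits(model, "auxin_model")) { spec <- model; model <- NULL }
  if (is.null(spec)) spec <- model_spec(model)
  model <- dispersion_model_of(spec)
  params <- as_params(params)
  spec <- resolve_model(spec, params, K = 2L)
  co <- dispersion_coefficients(model, spec, params)
  k <- 0:(N - 1)
  nu <- cos(2 * pi * k / N)
  lambda_k <- lambda_of_nu(model, co, nu)
  cond <- condition_from_coefficients(model, co)
  structure(c(list(model = model, N = N, k = k, nu = nu,
                   lambda_k = lambda_k,
                   units_of_L = if (model == "A") "apoplast spaces"
                                else "cells"),
              co, cond),
            class = "dispersion_result")
}

dispersion_model_of <- function(spec) {
  switch(spec$family,
    O = "O",
    A = if (spec$variant == "A") "A" else
      stop("dispersion relation is available for plain Model A only"),
    B = if (spec$variant == "B6" && spec$x_diffusion == "simple") "B6" else
      stop("dispersion relation is available for Model B6 with simple X ",
           "diffusion only"))
}

dispersion_coefficients <- function(model, spec, params) {
  pr <- params
  EpP <- pr$Ep * pr$p
  if (model == "O") {
    a_eq <- spec$eq$a
    c1 <- EpP + pr$Da
    c2 <- -EpP * a_eq * reg_logderiv(spec$reg$phi0, a_eq) / 2
    c0 <- -(pr$Ga + 2 * c1 + 2 * c2)
    return(list(c0 = c0, c1 = c1, c2 = c2, Ra = pr$Da / EpP))
  }
  if (model == "A") {
    aw_eq <- spec$eq$a_apo
    cq <- pr$Eq * pr$q + pr$Da
    den <- pr$V * (2 * EpP + 2 * pr$Da + pr$Ga)
    alpha <- 2 * (EpP + pr$Da) * cq / den
    beta <- EpP * (2 * cq * aw_eq + pr$Ga * pr$A) *
      reg_logderiv(spec$reg$phia, aw_eq) / den
    c0 <- alpha + beta - (2 * cq / pr$V + pr$Ga)
    c1 <- (alpha - beta) / 2
    return(list(c0 = c0, c1 = c1, alpha = alpha, beta = beta,
                Ra = pr$Da / EpP))
  }
  # B6 (reduced): requires the simple-diffusion X equilibrium
  a_eq <- spec$eq$a; xw_eq <- spec$eq$x_apo
  gamma <- (pr$Eq * pr$q + pr$Da) / (2 * pr$Eq * pr$q + 2 * pr$Da +
                                     pr$V * pr$Ga)
  kappa <- pr$Dx * pr$Gx / ((2 * pr$Dx + pr$Gx) * (2 * pr$Dx +
                                                   pr$V * pr$Gx))
  c1 <- gamma * (EpP + pr$Da)
  c2 <- -gamma * kappa * EpP * a_eq * reg_deriv(spec$reg$theta, a_eq) *
    reg_logderiv(spec$reg$phix, xw_eq) / 2
  c0 <- 2 * c1 - 2 * c2 - (2 * EpP + 2 * pr$Da + pr$Ga)
  list(c0 = c0, c1 = c1, c2 = c2, gamma = gamma, kappa = kappa,
       Ra = pr$Da / EpP, Rx = pr$Dx / pr$Gx)
}

lambda_of_nu <- function(model, co, nu) {
  if (model == "A") 2 * co$c1 * nu + co$c0
  else 4 * co$c2 * nu^2 + 2 * co$c1 * nu + co$c0 - 2 * co$c2
}

condition_from_coefficients <- function(model, co) {
  if (model == "A") {
    unstable <- lambda_of_nu(model, co, -1) > 0
    return(list(unstable = unstable, nu_star = -1,
                L_star = if (unstable) 2 else NA_real_))
  }
  if (co$c2 == 0)
    return(list(unstable = FALSE, nu_star = NA_real_, L_star = NA_real_))
  nu_star <- -co$c1 / (4 * co$c2)
  unstable <- abs(nu_star) < 1 &&
    lambda_of_nu(model, co, nu_star) > 0
  list(unstable = unstable, nu_star = nu_star,
       L_star = if (unstable) 2 * pi / acos(nu_star) else NA_real_)
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("dispersion (Model %s, N = %d): %s\n", x$model, x$N,
              if (x$unstable)
                sprintf("unstable, nu* = %.4g, L* = %.4g %s",
                        x$nu_star, x$L_star, x$units_of_L)
              else "stable (no pattern)"))
  invisible(x)
}

#' Pattern-formation condition and predicted wavelength
#'
#' For Models O and B6, the equilibrium is unstable to a periodic
#' perturbation iff `|nu*| < 1` and `lambda(nu*) > 0` with
#' `nu* = -c1 / (4 c2)`, and the fastest-growing wavelength is
#' `L* = 2*pi / acos(nu*)` cells. For Model A the condition is
#' `lambda(-1) > 0` and the wavelength is always 2 apoplast spaces.
#'
#' @inheritParams dispersion
#' @return list with `unstable`, `nu_star`, `L_star`.
#' @export
pattern_condition <- function(model, params, spec = NULL) {
  d <- dispersion(model, params, N = 4, spec = spec)
  list(unstable = d$unstable, nu_star = d$nu_star, L_star = d$L_star)
}

#' Numerical Jacobian spectrum per wavenumber (brute-force oracle)
#'
#' Independent check of the analytic dispersion relations: linearizes the
#' (QSS-PIN1) model around its analytic equilibrium on a ring of `N`
#' cells by central finite differences, exploits the circulant (shift-
#' invariant) structure by discrete-Fourier block-diagonalization, and
#' returns the leading eigenvalue for every wavenumber `k`. With
#' `eliminate = "a"` the cytosolic-auxin rows are removed by a Schur
#' complement at `lambda = 0` (adiabatic elimination), the reduction under
#' which the affine Model A relation is exact.
#'
#' @inheritParams dispersion
#' @param spec a [model_spec()]; PIN1 is always treated as quasi-steady
#'   here.
#' @param eliminate character vector of per-cell fields to eliminate
#'   adiabatically (currently `"a"` or empty).
#' @param h relative finite-difference step.
#' @param circulant_tol relative tolerance on the shift-invariance of the
#'   numerical Jacobian; a larger residual is an internal-consistency
#'   error.
#' @return list with `k`, `nu`, `lambda_k` (leading real part per
#'   wavenumber), and `fields`.
#' @export
jacobian_spectrum <- function(spec, params, N = 64, eliminate = character(),
                              h = 1e-5, circulant_tol = 1e-6) {
  params <- as_params(params)
  lat <- ring_lattice(N)
  spec$qss_pin <- TRUE
  if (spec$variant == "O") spec$variant <- "O_qss"
  spec <- resolve_model(spec, params, lat$K)
  eq <- model_equilibrium(spec, params, lat)

  fields <- c("a",
              if (spec$family != "O") "a_apo",
              if (spec$family == "B") c("x", "x_apo"))
  v <- length(fields)
  u0 <- unlist(lapply(fields, function(f) eq[[f]]), use.names = FALSE)
  nvar <- length(u0)  # v * N (edges count equals N on a ring)

  unpack <- function(u) {
    st <- list()
    for (i in seq_along(fields))
      st[[fields[i]]] <- u[((i - 1) * N + 1):(i * N)]
    st
  }
  f_of <- function(u) {
    st <- unpack(u)
    d <- rhs_core(spec, params, lat, st$a, NULL, st$a_apo, st$x, st$x_apo)
    out <- c(d$da, d$daw, d$dx, d$dxw)
    out[seq_len(nvar)]
  }

  J <- matrix(0, nvar, nvar)
  scale <- pmax(abs(u0), 1)
  for (j in seq_len(nvar)) {
    hj <- h * scale[j]
    up <- u0; up[j] <- up[j] + hj
    um <- u0; um[j] <- um[j] - hj
    J[, j] <- (f_of(up) - f_of(um)) / (2 * hj)
  }

  # shift-invariance check: J[row(f,2), col(g, 1+((s+1) mod N))] must equal
  # J[row(f,1), col(g, 1+s)]
  Jscale <- max(abs(J))
  for (fi in seq_len(v)) for (gi in seq_len(v)) {
    blk1 <- J[(fi - 1) * N + 1, (gi - 1) * N + seq_len(N)]
    blk2 <- J[(fi - 1) * N + 2, (gi - 1) * N + c(seq_len(N - 1) + 1L, 1L)]
    if (max(abs(blk1 - blk2)) > circulant_tol * max(Jscale, 1))
      stop("internal consistency error: Jacobian is not circulant ",
           "(residual above tolerance)")
  }

  elim_idx <- which(fields %in% eliminate)
  keep_idx <- setdiff(seq_len(v), elim_idx)
  if (length(keep_idx) == 0L) stop("cannot eliminate every field")

  k <- 0:(N - 1)
  lambda_k <- numeric(N)
  omega <- exp(-2i * pi / N)
  s <- 0:(N - 1)
  for (kk in k) {
    phase <- omega^(kk * s)
    M <- matrix(0i, v, v)
    for (fi in seq_len(v)) for (gi in seq_len(v)) {
      row <- J[(fi - 1) * N + 1, (gi - 1) * N + seq_len(N)]
      M[fi, gi] <- sum(row * phase)
    }
    if (length(elim_idx)) {
      Maa <- M[elim_idx, elim_idx, drop = FALSE]
      M <- M[keep_idx, keep_idx, drop = FALSE] -
        M[keep_idx, elim_idx, drop = FALSE] %*%
        solve(Maa, M[elim_idx, keep_idx, drop = FALSE])
    }
    ev <- if (nrow(M) == 1L) M[1, 1] else eigen(M, only.values = TRUE)$values
    lambda_k[kk + 1L] <- max(Re(ev))
  }
  list(k = k, nu = cos(2 * pi * k / N), lambda_k = lambda_k,
       fields = fields[keep_idx],
       eliminated = fields[elim_idx])
}

#' Empirical growth rate of a single Fourier mode
#'
#' Simulation-side validation of the dispersion relation: seeds a pure
#' cosine perturbation of wavenumber `k` on the cytosolic auxin field,
#' integrates briefly, and returns the slope of `log |F_k|` against time,
#' where `F_k` is the discrete Fourier amplitude of mode `k`. The
#' perturbation must stay in the linear regime (below 1% of the
#' equilibrium) while the slope is measured. Cleanest on QSS-PIN1 models,
#' where the Fourier modes are exact eigenvectors of the linearization.
#'
#' @inheritParams model_rhs
#' @param k integer wavenumber (0 to N-1).
#' @param amp relative cosine amplitude.
#' @param t_max measurement horizon.
#' @param dt Euler step.
#' @param n_records number of amplitude records over the window.
#' @return list with `rate` (fitted slope), `r_squared`, `records`.
#' @export
mode_growth_rate <- function(spec, params, lattice, k, amp = 1e-5,
                             t_max = 2, dt = 1e-3, n_records = 40) {
  stopifnot(lattice$type == "ring")
  params <- as_params(params)
  spec <- resolve_model(spec, params, lattice$K)
  N <- lattice$n_cells
  eq <- model_equilibrium(spec, params, lattice)
  st <- eq
  st$a <- eq$a * (1 + amp * cos(2 * pi * k * (0:(N - 1)) / N))

  a <- st$a; p <- st$p; aw <- st$a_apo; x <- st$x; xw <- st$x_apo
  rec_stride <- max(1L, round(t_max / dt / n_records))
  n_steps <- ceiling(t_max / dt)
  times <- c(); amps <- c()
  a_eq_scale <- max(abs(eq$a))
  for (step in 0:n_steps) {
    if (step %% rec_stride == 0L) {
      dev <- a - eq$a
      if (max(abs(dev)) > 0.01 * a_eq_scale) {
        if (length(times) < 5L)
          stop("perturbation left the linear regime before a growth ",
               "slope could be established (reduce amp)")
        break
      }
      Fk <- Mod(stats::fft(dev)[k + 1L] / N)
      if (Fk > 0) { times <- c(times, step * dt); amps <- c(amps, Fk) }
    }
    d <- rhs_core(spec, params, lattice, a, p, aw, x, xw)
    a <- a + dt * d$da
    if (!is.null(p)) p <- p + dt * d$dp
    if (!is.null(aw)) aw <- aw + dt * d$daw
    if (!is.null(x)) x <- x + dt * d$dx
    if (!is.null(xw)) xw <- xw + dt * d$dxw
  }
  if (length(times) < 5L)
    stop("too few usable amplitude records for a slope")
  fit <- stats::lm(log(amps) ~ times)
  list(rate = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       records = data.frame(time = times, amplitude = amps))
}
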