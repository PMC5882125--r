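#' Model variants of auxin-PIN1 patterning
#'
#' Constructs the specification of a model variant together with its
#' regulatory functions. Three families are available:
#'
#' * **Model O** (`"O"`, `"O_qss"`): no extracellular space; auxin moves
#'   directly between cells by PIN1 transport and diffusion, and PIN1
#'   polarizes toward neighboring cells with high auxin (`phi0`).
#'   `"O_qss"` replaces the PIN1 relaxation by its quasi-steady-state
#'   allocation (valid when PIN1 turnover is fast).
#' * **Model A** (`"A"`, `"A_symplast"`, `"A_apoplast"`): one well-mixed
#'   apoplast compartment per cell-cell interface; auxin is pumped
#'   cell-to-apoplast by PIN1, imported by influx carriers, and diffuses
#'   between cytoplasm and apoplast. PIN1 polarizes toward apoplast auxin
#'   (`phia`). The two suffixed variants add direct cell-cell (symplast)
#'   or apoplast-apoplast auxin diffusion; these are defined on 1D rings.
#' * **Model B** (`"B1"`..`"B6"`): Model A plus a diffusible molecule X,
#'   synthesized under auxin control (`theta`) and moving either between
#'   cytoplasm and apoplast (`x_diffusion = "simple"`), directly between
#'   cells (`"symplast"`), or between apoplast spaces (`"apoplast"`, 1D
#'   only). The variants differ in the feedback of X on the auxin-PIN1
#'   system: B1 scales influx-carrier amount by `psi1(x_i)`, B2 the PIN1
#'   amount by `psi1(x_i)`, B3 auxin synthesis by `psi1(x_i)`, B4 the
#'   influx efficiency by `psi2(x'_ij)`, B5 the efflux efficiency by
#'   `psi2(x'_ij)`, and B6 multiplies the PIN1-polarization weight by
#'   `phix(x'_ij)` so that PIN1 reads apoplast X rather than auxin.
#'
#' The default regulatory functions follow the published convention:
#' `phi0`/`phia` are powers with exponent `n`, `phix` a power with
#' exponent `m`, `theta` a normalized Hill with exponent `r` referenced at
#' the auxin equilibrium, and `psi1`/`psi2` normalized (Hill by default,
#' normalized power via `psi_form = "power_ref"`) at the corresponding X
#' equilibrium so that every feedback equals 1 at the uniform equilibrium
#' and the closed-form equilibria are preserved. For B6 the default
#' `phia` is the constant 1 (the reduced form in which the auxin feedback
#' on PIN1 is dropped); pass `n` to restore it.
#'
#' B4 and B5 with `x_diffusion = "symplast"` are rejected: the apoplast X
#' equilibrium is exactly 0 there, so no normalized `psi2` exists. For the
#' same reason, B6 under symplast X diffusion reads the polarization
#' signal from the neighboring cell's cytosolic X (`phix(x_j)`), the
#' direct symplast analogue of Model O's `phi0(a_j)`; with apoplast X
#' identically zero the literal apoplast reading would zero every
#' allocation weight.
#'
#' @param variant one of `"O"`, `"O_qss"`, `"A"`, `"A_symplast"`,
#'   `"A_apoplast"`, `"B1"`, ..., `"B6"`.
#' @param n exponent of the PIN1-polarization function of auxin
#'   (`phi0`/`phia`). Defaults: 2 (Model O family), 4 (Model A family and
#'   B1-B5); for B6, `NULL` means drop the auxin feedback (`phia` = 1).
#' @param m exponent of the X feedback (`phix` for B6, `psi1`/`psi2`
#'   otherwise); default 6.
#' @param r exponent of the auxin-to-X synthesis function `theta`;
#'   default 2.
#' @param x_diffusion X transport mode for B variants: `"simple"`,
#'   `"symplast"`, or `"apoplast"`.
#' @param psi_form form used for `psi1`/`psi2`: `"hill"` (default) or
#'   `"power_ref"`.
#' @param qss_pin replace PIN1 dynamics by the quasi-steady-state
#'   allocation (implied by `variant = "O_qss"`).
#' @param kappa_T optional saturation constant of the Model O flux by
#'   neighboring auxin (0 = off, the default); provided for equivalence
#'   checks with earlier model formulations only.
#' @param phi0,phia,phix,theta,psi1,psi2 optional [reg_fun()] overrides.
#' @return An object of class `"auxin_model"`.
#' @examples
#' model_spec("O", n = 2)
#' model_spec("A", n = 4)
#' model_spec("B6", r = 2, m = 6, x_diffusion = "simple")
#' @export
model_spec <- function(variant = c("O", "O_qss", "A", "A_symplast",
                                   "A_apoplast", "B1", "B2", "B3", "B4",
                                   "B5", "B6"),
                       n = NULL, m = NULL, r = NULL,
                       x_diffusion = c("simple", "symplast", "apoplast"),
                       psi_form = c("hill", "power_ref"),
                       qss_pin = FALSE, kappa_T = 0,
                       phi0 = NULL, phia = NULL, phix = NULL,
                       theta = NULL, psi1 = NULL, psi2 = NULL) {
  variant <- match.arg(variant)
  x_diffusion <- match.arg(x_diffusion)
  psi_form <- match.arg(psi_form)
  family <- variant_family(variant)
  if (variant == "O_qss") qss_pin <- TRUE
  if (family != "B") x_diffusion <- "none"
  if (variant %in% c("B4", "B5") && x_diffusion == "symplast")
    stop("Model ", variant, " with symplast X diffusion has apoplast X ",
         "equilibrium 0; no normalized psi2 exists (choose 'simple' or ",
         "'apoplast')")
  m <- m %||% 6
  r <- r %||% 2
  reg <- list(
    phi0 = phi0 %||% reg_fun("power", n %||% 2),
    phia = phia %||% (
      if (variant == "B6" && is.null(n)) reg_fun("one")
      else reg_fun("power", n %||% 4)),
    phix = phix %||% reg_fun("power", m),
    theta = theta %||% reg_fun("hill", r),
    psi1 = psi1 %||% reg_fun(psi_form, m),
    psi2 = psi2 %||% reg_fun(psi_form, m)
  )
  structure(list(variant = variant, family = family,
                 x_diffusion = x_diffusion, qss_pin = qss_pin,
                 kappa_T = kappa_T, reg = reg, resolved = FALSE),
            class = "auxin_model")
}

variant_family <- function(variant) {
  if (variant %in% c("O", "O_qss")) "O"
  else if (startsWith(variant, "A")) "A"
  else "B"
}

#' @export
print.auxin_model <- function(x, ...) {
  cat("auxin-PIN1 model ", x$variant,
      if (x$family == "B") paste0(" (X diffusion: ", x$x_diffusion, ")"),
      if (x$qss_pin) " [QSS PIN1]", "\n", sep = "")
  invisible(x)
}

#' Rate constants and coefficients
#'
#' All models share one parameter list; each variant reads the subset it
#' needs. Defaults are the values used throughout the published figure
#' legends (`A = Ep = Eq = Gp = V = 1`, `Ga = 0.2`, `p = q = 10`), with
#' the X-molecule rates of the B-family sweeps.
#'
#' @param A auxin synthesis level (equilibrium auxin in Model O).
#' @param Ga auxin turnover rate.
#' @param Da auxin diffusion coefficient: cell-cell in Model O,
#'   cytoplasm-apoplast in Models A/B.
#' @param Ep PIN1 efflux efficiency.
#' @param p PIN1 density scale (per cell side).
#' @param Gp PIN1 turnover rate.
#' @param Eq influx-carrier efficiency.
#' @param q influx-carrier density per cell side.
#' @param V apoplast/cytoplasm volume ratio.
#' @param Gx X turnover rate.
#' @param Dx X cytoplasm-apoplast diffusion coefficient.
#' @param Da1,Dx1 symplast (cell-cell) diffusion coefficients of auxin / X.
#' @param Da2,Dx2 apoplast-apoplast diffusion coefficients of auxin / X.
#' @param S X secretion coefficient (apoplast X diffusion mode).
#' @return A named list of class `"auxin_params"`.
#' @export
model_params <- function(A = 1, Ga = 0.2, Da = 1, Ep = 1, p = 10, Gp = 1,
                         Eq = 1, q = 10, V = 1, Gx = 1, Dx = 10,
                         Da1 = 1, Da2 = 1, Dx1 = 10, Dx2 = 10, S = 1) {
  prm <- list(A = A, Ga = Ga, Da = Da, Ep = Ep, p = p, Gp = Gp, Eq = Eq,
              q = q, V = V, Gx = Gx, Dx = Dx, Da1 = Da1, Da2 = Da2,
              Dx1 = Dx1, Dx2 = Dx2, S = S)
  bad <- names(prm)[!vapply(prm, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0, TRUE)]
  if (length(bad))
    stop("parameters must be finite non-negative scalars: ",
         paste(bad, collapse = ", "))
  if (prm$V <= 0) stop("V (apoplast/cytoplasm volume ratio) must be > 0")
  structure(prm, class = "auxin_params")
}

as_params <- function(params) {
  if (inherits(params, "auxin_params")) params
  else do.call(model_params, as.list(params))
}

#' Model state
#'
#' A state holds the per-cell auxin `a`, the directed PIN1 densities `p`
#' (an `n_cells x K` matrix, column `s` = membrane toward neighbor slot
#' `s`; absent under QSS PIN1), the per-edge apoplast auxin `a_apo`
#' (Models A/B), and the X fields `x`, `x_apo` (Model B). Apoplast
#' concentrations are stored once per undirected edge, which encodes the
#' symmetry a'_ij = a'_ji structurally.
#'
#' @param a numeric vector of cytosolic auxin.
#' @param p directed PIN1 matrix or `NULL`.
#' @param a_apo,x,x_apo optional field vectors.
#' @return An object of class `"auxin_state"`.
#' @export
model_state <- function(a, p = NULL, a_apo = NULL, x = NULL, x_apo = NULL) {
  structure(list(a = a, p = p, a_apo = a_apo, x = x, x_apo = x_apo),
            class = "auxin_state")
}

#' @export
print.auxin_state <- function(x, ...) {
  flds <- names(x)[!vapply(x, is.null, TRUE)]
  cat("auxin state:",
      paste(sprintf("%s[%d]", flds,
                    vapply(x[flds], length, 0L)), collapse = ", "), "\n")
  invisible(x)
}

# Resolve equilibrium-referenced regulatory functions and cache the scalar
# equilibrium values for a (model, params, K) triple.
resolve_model <- function(spec, params, K) {
  params <- as_params(params)
  if (isTRUE(spec$resolved) && identical(spec$K, K) &&
      identical(spec$params_used, unclass(params))) return(spec)
  spec$resolved <- FALSE
  if (is.null(spec$reg0)) spec$reg0 <- spec$reg  # user-supplied forms
  reg <- spec$reg0
  eq <- list()
  if (spec$family == "O") {
    eq$a <- params$A
    if (is.na(reg$phi0$ref)) reg$phi0$ref <- eq$a
  } else {
    cp <- params$Ep * params$p + params$Da
    cq <- params$Eq * params$q + params$Da
    a0 <- params$A / (K * params$V * cp + 2 * cq + params$V * params$Ga)
    eq$a <- (2 * cq + params$V * params$Ga) * a0
    eq$a_apo <- 2 * cp * a0
    if (is.na(reg$phia$ref)) reg$phia$ref <- eq$a_apo
    if (spec$family == "B") {
      if (is.na(reg$theta$ref)) reg$theta$ref <- eq$a
      th <- reg_eval(reg$theta, eq$a)
      eq <- c(eq, x_equilibrium(spec$x_diffusion, params, K, th))
      if (is.na(reg$phix$ref))
        reg$phix$ref <- if (spec$x_diffusion == "symplast") eq$x
                        else eq$x_apo
      if (is.na(reg$psi1$ref)) reg$psi1$ref <- eq$x
      if (is.na(reg$psi2$ref)) reg$psi2$ref <- eq$x_apo
    }
  }
  spec$reg <- reg
  spec$eq <- eq
  spec$K <- K
  spec$params_used <- unclass(params)
  spec$resolved <- TRUE
  spec
}

x_equilibrium <- function(mode, params, K, theta_eq) {
  with(params, switch(mode,
    simple = {
      x0 <- theta_eq / ((K * V + 2) * Dx + V * Gx)
      list(x = (2 * Dx + V * Gx) * x0, x_apo = 2 * Dx * x0)
    },
    symplast = list(x = theta_eq, x_apo = 0),
    apoplast = list(x = Gx * theta_eq / (Gx + K * S),
                    x_apo = 2 * S * theta_eq / (V * (Gx + K * S)))
  ))
}

#' Analytic uniform equilibrium of a model
#'
#' Returns the spatially uniform state that satisfies the closed-form
#' equilibria of the chosen variant: in Model O auxin equals the synthesis
#' level `A` and every PIN1 density equals `p`; in Models A/B the cytosolic
#' and apoplast auxin partition according to the carrier and diffusion
#' rates; the X fields follow the transport mode (in particular, apoplast X
#' is exactly 0 under symplast X diffusion).
#'
#' @param spec a [model_spec()].
#' @param params a [model_params()] list.
#' @param lattice an [ring_lattice()] / [hex_lattice()] object.
#' @return An `auxin_state` (see [model_state()]).
#' @export
model_equilibrium <- function(spec, params, lattice) {
  check_variant_lattice(spec, lattice)
  params <- as_params(params)
  spec <- resolve_model(spec, params, lattice$K)
  n <- lattice$n_cells; K <- lattice$K; E <- lattice$n_edges
  st <- model_state(
    a = rep(spec$eq$a, n),
    p = if (!spec$qss_pin) matrix(params$p, n, K),
    a_apo = if (spec$family != "O") rep(spec$eq$a_apo, E),
    x = if (spec$family == "B") rep(spec$eq$x, n),
    x_apo = if (spec$family == "B") rep(spec$eq$x_apo, E)
  )
  st
}

check_variant_lattice <- function(spec, lattice) {
  ring_only <- spec$variant %in% c("A_symplast", "A_apoplast") ||
    (spec$family == "B" && spec$x_diffusion == "apoplast")
  if (ring_only && lattice$type != "ring")
    stop("variant ", spec$variant,
         if (spec$family == "B") paste0(" (x_diffusion = ", spec$x_diffusion, ")"),
         " is defined on 1D rings only")
  invisible(TRUE)
}

check_state_dims <- function(spec, lattice, state) {
  n <- lattice$n_cells; K <- lattice$K; E <- lattice$n_edges
  if (length(state$a) != n) stop("state: length(a) != n_cells")
  if (spec$qss_pin) {
    if (!is.null(state$p)) stop("state: p present but PIN1 is quasi-steady")
  } else {
    if (is.null(state$p) || !all(dim(state$p) == c(n, K)))
      stop("state: p must be an n_cells x K matrix")
  }
  if (spec$family != "O" && length(state$a_apo) != E)
    stop("state: length(a_apo) != n_edges")
  if (spec$family == "B") {
    if (length(state$x) != n) stop("state: length(x) != n_cells")
    if (length(state$x_apo) != E) stop("state: length(x_apo) != n_edges")
  }
  invisible(TRUE)
}

# PIN1 allocation target K * pscale * w / rowSums(w); errors on degenerate
# weights (all-zero row) instead of patching 0/0.
pin_target <- function(K, pscale, w) {
  den <- .rowSums(w, nrow(w), ncol(w))
  if (any(!is.finite(den)) || any(den <= 0))
    stop("degenerate state: PIN1 allocation weights sum to zero (or are ",
         "non-finite) in at least one cell")
  (K * pscale) * w / den
}

#' Time derivatives of a model state
#'
#' Evaluates the full right-hand side of the chosen variant on the given
#' lattice: auxin synthesis/turnover, PIN1-mediated transport (flux toward
#' neighboring cells in Model O, cell-to-apoplast flux against the influx
#' carriers in Models A/B), passive diffusion with the apoplast volume
#' factor `1/V`, PIN1 relaxation toward its normalized allocation, and the
#' X dynamics of the B family. Under QSS PIN1 the PIN1 field is eliminated
#' algebraically and no `p` derivative is returned.
#'
#' @inheritParams model_equilibrium
#' @param state an `auxin_state` with dimensions matching `lattice`.
#' @return An `auxin_state` holding the time derivative of every dynamic
#'   field.
#' @export
model_rhs <- function(spec, params, lattice, state) {
  check_variant_lattice(spec, lattice)
  params <- as_params(params)
  spec <- resolve_model(spec, params, lattice$K)
  check_state_dims(spec, lattice, state)
  d <- rhs_core(spec, params, lattice, state$a, state$p, state$a_apo,
                state$x, state$x_apo)
  model_state(a = d$da, p = d$dp, a_apo = d$daw, x = d$dx, x_apo = d$dxw)
}

# Core RHS on raw fields; `spec` must be resolved. Returns list of
# derivatives (NULL for absent fields).
rhs_core <- function(spec, params, lat, a, p, aw, x, xw) {
  n <- lat$n_cells; K <- lat$K
  Ep <- params$Ep; Da <- params$Da; Ga <- params$Ga; A <- params$A
  reg <- spec$reg

  if (spec$family == "O") {
    anb <- a[lat$nb]; dim(anb) <- c(n, K)
    w <- reg_eval(reg$phi0, anb)
    ptarget <- pin_target(K, params$p, w)
    dp <- NULL
    if (spec$qss_pin) p <- ptarget
    else dp <- params$Gp * (ptarget - p)
    prev <- p[lat$opp]; dim(prev) <- c(n, K)
    if (spec$kappa_T > 0) {
      f <- Ep * (p * a / (1 + spec$kappa_T * anb) -
                 prev * anb / (1 + spec$kappa_T * a))
    } else {
      f <- Ep * (p * a - prev * anb)
    }
    da <- Ga * (A - a) - .rowSums(f, n, K) +
      Da * (.rowSums(anb, n, K) - K * a)
    return(list(da = da, dp = dp, daw = NULL, dx = NULL, dxw = NULL))
  }

  ## Models A / B: apoplast compartments
  V <- params$V
  awM <- aw[lat$edge_slot]; dim(awM) <- c(n, K)
  variant <- spec$variant

  # X-dependent rescalings (all equal 1 at equilibrium)
  psi1x <- if (variant %in% c("B1", "B2", "B3")) reg_eval(reg$psi1, x)
  xwM <- NULL
  if (variant %in% c("B4", "B5", "B6")) {
    xwM <- xw[lat$edge_slot]; dim(xwM) <- c(n, K)
  }

  # PIN1 allocation weights
  w <- reg_eval(reg$phia, awM)
  if (identical(dim(w), NULL)) { w <- matrix(w, n, K) }  # constant phia
  if (variant == "B6") {
    if (spec$x_diffusion == "symplast") {
      # apoplast X is identically 0 here; the polarization signal is the
      # symplastically transmitted cytosolic X of the neighboring cell
      xnb <- x[lat$nb]; dim(xnb) <- c(n, K)
      w <- w * reg_eval(reg$phix, xnb)
    } else {
      w <- w * reg_eval(reg$phix, xwM)
    }
  }
  pscale <- if (variant == "B2") psi1x * params$p else params$p
  ptarget <- pin_target(K, pscale, w)
  dp <- NULL
  if (spec$qss_pin) p <- ptarget else dp <- params$Gp * (ptarget - p)

  # cell -> apoplast flux, f_ij = Ep p_ij a_i - Eq q a'_ij (with feedbacks)
  EpM <- if (variant == "B5") Ep * reg_eval(reg$psi2, xwM) else Ep
  influx_coef <- params$Eq * params$q
  influx <- if (variant == "B1") (influx_coef * psi1x) * awM
            else if (variant == "B4")
              influx_coef * reg_eval(reg$psi2, xwM) * awM
            else influx_coef * awM
  f <- EpM * p * a - influx

  Aeff <- if (variant == "B3") psi1x * A else A
  da <- Ga * (Aeff - a) - .rowSums(f, n, K) +
    Da * (.rowSums(awM, n, K) - K * a)
  if (variant == "A_symplast") {
    anb <- a[lat$nb]; dim(anb) <- c(n, K)
    da <- da + params$Da1 * (.rowSums(anb, n, K) - K * a)
  }

  fsum <- f[lat$edge_dir1] + f[lat$edge_dir2]
  asum <- a[lat$edge_cells[, 1L]] + a[lat$edge_cells[, 2L]]
  daw <- -Ga * aw + fsum / V + (Da / V) * (asum - 2 * aw)
  if (variant == "A_apoplast") {
    daw <- daw + (params$Da2 / V) *
      (aw[lat$edge_adj[, 1L]] + aw[lat$edge_adj[, 2L]] - 2 * aw)
  }

  dx <- NULL; dxw <- NULL
  if (spec$family == "B") {
    Gx <- params$Gx
    synth <- Gx * (reg_eval(reg$theta, a) - x)
    if (spec$x_diffusion == "simple") {
      xwM2 <- xw[lat$edge_slot]; dim(xwM2) <- c(n, K)
      dx <- synth + params$Dx * (.rowSums(xwM2, n, K) - K * x)
      xsum <- x[lat$edge_cells[, 1L]] + x[lat$edge_cells[, 2L]]
      dxw <- -Gx * xw + (params$Dx / V) * (xsum - 2 * xw)
    } else if (spec$x_diffusion == "symplast") {
      xnb <- x[lat$nb]; dim(xnb) <- c(n, K)
      dx <- synth + params$Dx1 * (.rowSums(xnb, n, K) - K * x)
      dxw <- -Gx * xw
    } else {  # apoplast
      dx <- synth - K * params$S * x
      xsum <- x[lat$edge_cells[, 1L]] + x[lat$edge_cells[, 2L]]
      dxw <- -Gx * xw + (params$S / V) * xsum + (params$Dx2 / V) *
        (xw[lat$edge_adj[, 1L]] + xw[lat$edge_adj[, 2L]] - 2 * xw)
    }
  }
  list(da = da, dp = dp, daw = daw, dx = dx, dxw = dxw)
}

#' Auxin flux between a cell and one interface
#'
#' In Model O, the net PIN1-mediated flow from cell `i` to neighboring
#' cell `j` (antisymmetric: `f_ij = -f_ji`). In Models A/B, the directed
#' flow from cell `i` into the apoplast compartment between `i` and `j`:
#' PIN1 efflux minus influx-carrier import, with the variant-specific X
#' feedbacks applied.
#'
#' @inheritParams model_rhs
#' @param i,j adjacent cell ids.
#' @return a single flow rate.
#' @export
edge_flux <- function(spec, params, lattice, state, i, j) {
  params <- as_params(params)
  spec <- resolve_model(spec, params, lattice$K)
  s <- match(j, lattice$nb[i, ])
  if (is.na(s)) stop("cells ", i, " and ", j, " are not adjacent")
  p_dir <- function(ii, jj) {
    if (spec$qss_pin) qss_pin_value(spec, params, lattice, state, ii, jj)
    else state$p[ii, match(jj, lattice$nb[ii, ])]
  }
  if (spec$family == "O") {
    pij <- p_dir(i, j); pji <- p_dir(j, i)
    if (spec$kappa_T > 0)
      return(params$Ep * (pij * state$a[i] / (1 + spec$kappa_T * state$a[j]) -
                          pji * state$a[j] / (1 + spec$kappa_T * state$a[i])))
    return(params$Ep * (pij * state$a[i] - pji * state$a[j]))
  }
  e <- lattice$edge_slot[i, s]
  awv <- state$a_apo[e]
  Ep <- params$Ep; Eqq <- params$Eq * params$q
  variant <- spec$variant
  if (variant == "B5") Ep <- Ep * reg_eval(spec$reg$psi2, state$x_apo[e])
  if (variant == "B4") Eqq <- Eqq * reg_eval(spec$reg$psi2, state$x_apo[e])
  if (variant == "B1") Eqq <- Eqq * reg_eval(spec$reg$psi1, state$x[i])
  Ep * p_dir(i, j) * state$a[i] - Eqq * awv
}

# QSS PIN1 density of cell i toward neighbor j
qss_pin_value <- function(spec, params, lattice, state, i, j) {
  K <- lattice$K
  nbs <- lattice$nb[i, ]
  if (spec$family == "O") {
    w <- reg_eval(spec$reg$phi0, state$a[nbs])
  } else {
    e <- lattice$edge_slot[i, ]
    w <- reg_eval(spec$reg$phia, state$a_apo[e])
    if (length(w) == 1L) w <- rep(w, K)
    if (spec$variant == "B6") {
      xs <- if (spec$x_diffusion == "symplast") state$x[nbs]
            else state$x_apo[e]
      w <- w * reg_eval(spec$reg$phix, xs)
    }
  }
  den <- sum(w)
  if (!is.finite(den) || den <= 0)
    stop("degenerate state: PIN1 allocation weights sum to zero")
  pscale <- if (spec$variant == "B2")
    reg_eval(spec$reg$psi1, state$x[i]) * params$p else params$p
  s <- match(j, nbs)
  K * pscale * w[s] / den
}
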