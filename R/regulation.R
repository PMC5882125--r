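#' Regulatory function specifications
#'
#' The models couple fields through small monotone regulatory functions:
#' PIN1 polarization reads auxin of neighboring cells (`phi0`) or apoplast
#' spaces (`phia`), or apoplast X (`phix`); X synthesis reads cytosolic
#' auxin (`theta`); and the B-family feedbacks rescale carrier amounts or
#' efficiencies through `psi1` (cytosolic X) and `psi2` (apoplast X).
#' A specification is a form plus an exponent and, for normalized forms, a
#' reference concentration.
#'
#' Forms:
#' \describe{
#'   \item{`power`}{`f(c) = c^e`; any real exponent, `c > 0` required when
#'     `e` is negative or non-integer.}
#'   \item{`hill`}{normalized Hill, `f(c) = 2 c^e / (ref^e + c^e)`, so that
#'     `f(ref) = 1` exactly for every exponent.}
#'   \item{`power_ref`}{normalized power, `f(c) = (c/ref)^e`, also 1 at the
#'     reference; the alternative convention for the X feedbacks.}
#'   \item{`one`}{constantly 1 (used for `phia` in the reduced B6 model).}
#'   \item{`hill_ceiling`}{`f(c) = c^e / (1 + (c/ceiling)^e)`, a saturating
#'     variant used optionally in 2D runs; off unless requested.}
#' }
#'
#' A reference of `NA` means "the equilibrium concentration of the argument
#' field"; it is resolved when a model is prepared (see [model_spec()]).
#'
#' @param form one of `"power"`, `"hill"`, `"power_ref"`, `"one"`,
#'   `"hill_ceiling"`.
#' @param exponent real exponent `e` (ignored for `"one"`).
#' @param ref reference concentration for the normalized forms; `NA` to
#'   resolve at equilibrium.
#' @param ceiling saturation level for `"hill_ceiling"`.
#' @return An object of class `"reg_fun"`.
#' @examples
#' f <- reg_fun("power", 2)
#' reg_eval(f, 3)       # 9
#' reg_deriv(f, 3)      # 6
#' h <- reg_fun("hill", 4, ref = 1.5)
#' reg_eval(h, 1.5)     # exactly 1
#' @export
reg_fun <- function(form = c("power", "hill", "power_ref", "one",
                             "hill_ceiling"),
                    exponent = 1, ref = NA_real_, ceiling = NA_real_) {
  form <- match.arg(form)
  if (form == "hill_ceiling" && (is.na(ceiling) || ceiling <= 0))
    stop("hill_ceiling needs a positive ceiling")
  structure(list(form = form, exponent = as.numeric(exponent),
                 ref = as.numeric(ref), ceiling = as.numeric(ceiling)),
            class = "reg_fun")
}

#' @export
print.reg_fun <- function(x, ...) {
  cat(switch(x$form,
    one          = "f(c) = 1",
    power        = sprintf("f(c) = c^%g", x$exponent),
    power_ref    = sprintf("f(c) = (c/%g)^%g", x$ref, x$exponent),
    hill         = sprintf("f(c) = 2 c^%g / (%g^%g + c^%g)",
                           x$exponent, x$ref, x$exponent, x$exponent),
    hill_ceiling = sprintf("f(c) = c^%g / (1 + (c/%g)^%g)",
                           x$exponent, x$ceiling, x$exponent)), "\n")
  invisible(x)
}

check_reg_domain <- function(spec, c) {
  e <- spec$exponent
  if (spec$form == "one") return(invisible(TRUE))
  neg_ok <- e >= 0 && e == round(e)
  if (!neg_ok && any(c <= 0))
    stop("regulatory function with exponent ", e,
         " undefined at non-positive concentration")
  if (any(c < 0))
    stop("negative concentration passed to regulatory function")
  invisible(TRUE)
}

#' Evaluate a regulatory function or its derivative
#'
#' Vectorized over `c` (matrices keep their shape). `reg_deriv` returns the
#' analytic first derivative of the selected form; it is exercised against a
#' central finite difference in the test-suite.
#'
#' @param spec a [reg_fun()] specification with any `NA` reference resolved.
#' @param c concentration(s); must lie in the form's domain.
#' @return numeric of the same shape as `c`.
#' @export
reg_eval <- function(spec, c) {
  check_reg_domain(spec, c)
  e <- spec$exponent
  switch(spec$form,
    one = keep_shape(rep(1, length(c)), c),
    power = c^e,
    power_ref = (c / spec$ref)^e,
    hill = {
      re <- spec$ref^e
      2 * c^e / (re + c^e)
    },
    hill_ceiling = c^e / (1 + (c / spec$ceiling)^e)
  )
}

#' @rdname reg_eval
#' @export
reg_deriv <- function(spec, c) {
  check_reg_domain(spec, c)
  e <- spec$exponent
  switch(spec$form,
    one = keep_shape(rep(0, length(c)), c),
    power = e * c^(e - 1),
    power_ref = (e / spec$ref) * (c / spec$ref)^(e - 1),
    hill = {
      re <- spec$ref^e
      2 * e * c^(e - 1) * re / (re + c^e)^2
    },
    hill_ceiling = {
      s <- 1 + (c / spec$ceiling)^e
      e * c^(e - 1) / s^2
    }
  )
}

keep_shape <- function(v, template) {
  if (!is.null(dim(template))) dim(v) <- dim(template)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ratio f'(c)/f(c), used by the dispersion coefficients
reg_logderiv <- function(spec, c) reg_deriv(spec, c) / reg_eval(spec, c)
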