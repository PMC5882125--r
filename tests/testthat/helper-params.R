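# Parameter sets used across tests: the published figure-legend values.

fig2_params <- function(p = 1, Da = 0.2) {
  model_params(A = 1, Ep = 1, Gp = 1, Ga = 0.2, p = p, Da = Da)
}

fig4_params <- function(p = 50, Da = 1) {
  model_params(A = 1, Ep = 1, Eq = 1, Gp = 1, V = 1, q = 10, Ga = 0.2,
               p = p, Da = Da)
}

# Model B6 transect / quadrant parameters (1D examples)
fig8_params <- function(Dx, Gx = 0.5, Da = 1) {
  model_params(A = 1, Ep = 1, Eq = 1, Gp = 1, V = 1, p = 10, q = 10,
               Ga = 0.2, Gx = Gx, Da = Da, Dx = Dx)
}

# random Model O parameter set (used for oracle and identity checks)
random_O_params <- function() {
  model_params(A = runif(1, 0.5, 2), Ep = runif(1, 0.2, 3),
               Ga = runif(1, 0.05, 1), p = runif(1, 0.5, 5),
               Da = runif(1, 0.05, 5), Gp = 1)
}

random_A_params <- function() {
  model_params(A = runif(1, 0.5, 2), Ep = runif(1, 0.2, 2),
               Eq = runif(1, 0.2, 2), q = runif(1, 2, 15),
               Ga = runif(1, 0.05, 0.5), p = runif(1, 2, 20),
               Da = runif(1, 0.05, 5), V = runif(1, 0.3, 2), Gp = 1)
}

# B6 parameters in the fast-mediator regime, where the approximate
# dispersion relation is quantitatively reliable
random_B6_fast_params <- function() {
  model_params(A = 1, Ep = 1, Eq = 1, Gp = 1,
               p = runif(1, 2, 10), q = runif(1, 2, 10), Ga = 0.2,
               Gx = runif(1, 20, 100), Dx = runif(1, 2, 10),
               Da = runif(1, 0.1, 1), V = runif(1, 0.3, 1.5))
}

# random positive state on a lattice for a given variant
random_state <- function(spec, params, lattice, seed = 1) {
  eq <- model_equilibrium(spec, params, lattice)
  perturb_state(eq, fluctuation = 0.5, seed = seed)
}

max_abs_rhs <- function(d) {
  max(abs(unlist(d[!vapply(d, is.null, TRUE)])))
}
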