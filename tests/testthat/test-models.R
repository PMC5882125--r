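all_variant_specs <- function() {
  specs <- list(
    model_spec("O", n = 2),
    model_spec("O_qss", n = 2),
    model_spec("A", n = 4),
    model_spec("A_symplast", n = 4),
    model_spec("A_apoplast", n = 4))
  for (v in paste0("B", 1:6))
    for (mode in c("simple", "symplast", "apoplast")) {
      if (v %in% c("B4", "B5") && mode == "symplast") next
      specs <- c(specs, list(model_spec(v, n = 1, m = 6, r = 2,
                                        x_diffusion = mode)))
    }
  specs
}

test_that("closed-form equilibria match the printed expressions", {
  lat <- ring_lattice(6)
  # Model O: auxin = synthesis level, PIN1 = p everywhere
  eqO <- model_equilibrium(model_spec("O"), model_params(A = 1.5, p = 2),
                           lat)
  expect_equal(eqO$a, rep(1.5, 6))
  expect_equal(eqO$p, matrix(2, 6, 2))

  # Model A at K=2, A=Ep=Eq=V=1, q=10, Ga=0.2, p=50, Da=1:
  # a0 = 1/124.2, a_eq = 22.2/124.2, a'_eq = 102/124.2
  eqA <- model_equilibrium(model_spec("A", n = 4), fig4_params(), lat)
  expect_equal(eqA$a[1], 22.2 / 124.2, tolerance = 1e-12)
  expect_equal(eqA$a_apo[1], 102 / 124.2, tolerance = 1e-12)

  # Model B framework (simple X diffusion): x0-based partition
  prm <- model_params(Gx = 2, Dx = 3, V = 0.5)
  eqB <- model_equilibrium(model_spec("B6", r = 2, m = 6), prm, lat)
  x0 <- 1 / ((2 * 0.5 + 2) * 3 + 0.5 * 2)      # theta(a_eq) = 1 (Hill)
  expect_equal(eqB$x[1], (2 * 3 + 0.5 * 2) * x0, tolerance = 1e-12)
  expect_equal(eqB$x_apo[1], 2 * 3 * x0, tolerance = 1e-12)

  # symplast X: apoplast X is exactly zero
  eqS <- model_equilibrium(model_spec("B1", x_diffusion = "symplast"),
                           model_params(), lat)
  expect_identical(eqS$x_apo, rep(0, 6))
  expect_equal(eqS$x, rep(1, 6))                # theta(a_eq) = 1

  # apoplast X: secretion/turnover partition
  prm2 <- model_params(Gx = 2, S = 3, V = 0.5)
  eqP <- model_equilibrium(model_spec("B1", x_diffusion = "apoplast"),
                           prm2, lat)
  expect_equal(eqP$x[1], 2 / (2 + 2 * 3), tolerance = 1e-12)
  expect_equal(eqP$x_apo[1], 2 * 3 / (0.5 * (2 + 2 * 3)), tolerance = 1e-12)
})

test_that("every variant's rhs vanishes at its analytic equilibrium", {
  lat <- ring_lattice(6)
  hx <- hex_lattice(3, 3)
  for (spec in all_variant_specs()) {
    prm <- model_params(p = 7, q = 4, Da = 0.7, Dx = 2, Gx = 0.8, V = 0.6,
                        S = 1.3)
    eq <- model_equilibrium(spec, prm, lat)
    expect_lt(max_abs_rhs(model_rhs(spec, prm, lat, eq)), 1e-12)
    ring_only <- spec$variant %in% c("A_symplast", "A_apoplast") ||
      (spec$family == "B" && spec$x_diffusion == "apoplast")
    if (!ring_only) {
      eqh <- model_equilibrium(spec, prm, hx)
      expect_lt(max_abs_rhs(model_rhs(spec, prm, hx, eqh)), 1e-12)
    } else {
      expect_error(model_equilibrium(spec, prm, hx), "1D rings only")
    }
  }
})

test_that("Model O flux is antisymmetric and vanishes by symmetry", {
  lat <- ring_lattice(5)
  spec <- model_spec("O", n = 2)
  prm <- model_params()
  st <- model_equilibrium(spec, prm, lat)
  # uniform state: zero flux
  expect_equal(edge_flux(spec, prm, lat, st, 1, 2), 0)
  # random state: f_ij + f_ji = 0 on every adjacent pair
  set.seed(3)
  st$a <- runif(5, 0.5, 2); st$p <- matrix(runif(10), 5, 2)
  for (i in 1:5) for (j in lat$nb[i, ])
    expect_equal(edge_flux(spec, prm, lat, st, i, j),
                 -edge_flux(spec, prm, lat, st, j, i))
  expect_error(edge_flux(spec, prm, lat, st, 1, 3), "not adjacent")
})

test_that("Model A flux balances efflux against influx", {
  lat <- ring_lattice(5)
  spec <- model_spec("A", n = 4)
  prm <- model_params(Ep = 1, Eq = 1, q = 10)
  st <- model_equilibrium(spec, prm, lat)
  st$a[1] <- 0.5; st$p[1, 2] <- 2; st$a_apo[1] <- 0.1
  # Ep p a - Eq q a' = 1*2*0.5 - 1*10*0.1 = 0
  expect_equal(edge_flux(spec, prm, lat, st, 1, 2), 0)
})

test_that("uniform Model O states relax auxin at the turnover rate", {
  lat <- ring_lattice(8)
  spec <- model_spec("O", n = 2)
  prm <- model_params(A = 1, Ga = 0.7, p = 3, Da = 2)
  st <- model_equilibrium(spec, prm, lat)
  st$a <- rep(1.8, 8)           # uniform but off-equilibrium
  d <- model_rhs(spec, prm, lat, st)
  expect_equal(d$a, rep(0.7 * (1 - 1.8), 8), tolerance = 1e-14)
})

test_that("total auxin is conserved without turnover", {
  lat <- ring_lattice(7)
  # Model O with Ga = 0: sum_i da_i/dt = 0 on arbitrary states
  spec <- model_spec("O", n = 2)
  prm <- model_params(Ga = 0, p = 3, Da = 0.5)
  for (s in 1:5) {
    st <- random_state(spec, prm, lat, seed = s)
    d <- model_rhs(spec, prm, lat, st)
    expect_lt(abs(sum(d$a)), 1e-12)
  }
  # Models A/B with Ga = 0: sum a + V sum a' invariant (1/V bookkeeping)
  for (spec2 in list(model_spec("A", n = 4),
                     model_spec("B6", r = 2, m = 6))) {
    prm2 <- model_params(Ga = 0, V = 0.37, p = 5, q = 5)
    for (s in 1:5) {
      st <- random_state(spec2, prm2, lat, seed = s)
      d <- model_rhs(spec2, prm2, lat, st)
      expect_lt(abs(sum(d$a) + 0.37 * sum(d$a_apo)), 1e-12)
    }
  }
})

test_that("per-cell total PIN1 follows the closed-form relaxation", {
  # for every variant whose allocation numerator is not X-scaled,
  # d(sum_j p_ij)/dt = Gp (K p - sum_j p_ij) exactly
  lat <- ring_lattice(7)
  prm <- model_params(Gp = 1.7, p = 4, q = 5)
  for (spec in list(model_spec("O", n = 2), model_spec("A", n = 4),
                    model_spec("B1", n = 1), model_spec("B6", r = 2, m = 6))) {
    for (s in 1:3) {
      st <- random_state(spec, prm, lat, seed = s)
      d <- model_rhs(spec, prm, lat, st)
      expect_equal(rowSums(d$p),
                   1.7 * (2 * 4 - rowSums(st$p)), tolerance = 1e-12)
    }
  }
})

test_that("PIN1 allocation degenerates loudly on all-zero weights", {
  lat <- ring_lattice(5)
  spec <- model_spec("O", n = 2)
  prm <- model_params()
  st <- model_equilibrium(spec, prm, lat)
  st$a <- rep(0, 5)             # phi0(a) = a^2 = 0 everywhere
  expect_error(model_rhs(spec, prm, lat, st), "degenerate state")
})

test_that("B4/B5 with symplast X diffusion are rejected at construction", {
  expect_error(model_spec("B4", x_diffusion = "symplast"), "psi2")
  expect_error(model_spec("B5", x_diffusion = "symplast"), "psi2")
})

test_that("the optional flux-saturation flag damps transport as specified", {
  # with kappa_T > 0: f_ij = Ep (p_ij a_i/(1 + kT a_j) - p_ji a_j/(1 + kT a_i))
  lat <- ring_lattice(5)
  prm <- model_params(Ep = 0.9)
  base <- model_spec("O", n = 2)
  sat <- model_spec("O", n = 2, kappa_T = 0.7)
  st <- model_equilibrium(base, prm, lat)
  set.seed(8)
  st$a <- runif(5, 0.5, 2); st$p <- matrix(runif(10), 5, 2)
  f <- edge_flux(sat, prm, lat, st, 1, 2)
  expect_equal(f, 0.9 * (st$p[1, 2] * st$a[1] / (1 + 0.7 * st$a[2]) -
                         st$p[2, 1] * st$a[2] / (1 + 0.7 * st$a[1])),
               tolerance = 1e-14)
  # still antisymmetric, and off by default
  expect_equal(f, -edge_flux(sat, prm, lat, st, 2, 1))
  expect_false(isTRUE(all.equal(f, edge_flux(base, prm, lat, st, 1, 2))))
})

test_that("QSS Model O reproduces the bare up-the-gradient model", {
  # reference dynamics: da_i/dt = -sum_j T(p_ij a_i - p_ji a_j)
  #                              + sum_j D(a_j - a_i),  p_ij = P a_j/sum a_j
  # equals Model O with Ga = 0, Da = D, Ep = T, p = P/K, phi0(a) = a.
  N <- 10; TT <- 0.8; D <- 0.3; P <- 4
  ref_step <- function(a, dt) {
    nxt <- a
    for (i in seq_len(N)) {
      l <- if (i == 1) N else i - 1
      r <- if (i == N) 1 else i + 1
      dai <- 0
      for (j in c(l, r)) {
        lj <- if (j == 1) N else j - 1
        rj <- if (j == N) 1 else j + 1
        pij <- P * a[j] / (a[l] + a[r])
        pji <- P * a[i] / (a[lj] + a[rj])
        dai <- dai - TT * (pij * a[i] - pji * a[j]) + D * (a[j] - a[i])
      }
      nxt[i] <- a[i] + dt * dai
    }
    nxt
  }
  set.seed(20)
  a0 <- runif(N, 0.8, 1.2)
  lat <- ring_lattice(N)
  spec <- model_spec("O_qss", phi0 = reg_fun("power", 1))
  prm <- model_params(Ga = 0, Da = D, Ep = TT, p = P / 2)
  a_ref <- a0
  a_pkg <- a0
  dt <- 0.001
  for (step in 1:1000) {
    a_ref <- ref_step(a_ref, dt)
    d <- model_rhs(spec, prm, lat, model_state(a = a_pkg))
    a_pkg <- a_pkg + dt * d$a
  }
  expect_lt(max(abs(a_ref - a_pkg)), 1e-10)
})
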