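# Core reaction-transport model: binding, effective rates, and the two
# steady-state solvers, checked against closed-form transit oracles.

test_that("binding probability follows the distortion model", {
  expect_identical(binding_probability(5, 5, 3), 1)
  expect_identical(binding_probability(7, 2, 0), 1)
  expect_equal(binding_probability(3, 5, 1), exp(-2))
  # never underflows to exact zero, even at extreme mismatch energies
  expect_gt(binding_probability(1, 20000, 50), 0)
  expect_error(binding_probability(3, 5, -1), "nonnegative")
})

test_that("effective rates sum enzyme contributions and end the chain", {
  sys <- golgi_system(NC = 2, NE = 1, Ns = 10)
  par <- parameter_set(mu = c(1, 1), R = matrix(2, 1, 2),
                       L = matrix(1, 1, 2), sigma = 0)
  reff <- effective_rates(sys, par)
  expect_true(all(reff[, 1:9] == 2)) # promiscuous: P == 1 everywhere
  expect_true(all(reff[, 10] == 0)) # no reaction out of the last species

  # highly specific enzymes: only the matched one contributes
  sys2 <- golgi_system(NC = 1, NE = 2, Ns = 10)
  par2 <- parameter_set(mu = 1, R = matrix(1, 2, 1),
                        L = matrix(c(3, 6), 2, 1), sigma = 50)
  expect_equal(effective_rates(sys2, par2)[1, 3], 1, tolerance = 1e-12)

  # hand summation at sigma = 1
  par3 <- parameter_set(mu = 1, R = matrix(c(2, 3), 2, 1),
                        L = matrix(c(1, 4), 2, 1), sigma = 1)
  expect_equal(effective_rates(sys2, par3)[1, 2], 2 * exp(-1) + 3 * exp(-2))

  # activity mask zeroes an enzyme's contribution
  par4 <- parameter_set(mu = 1, R = matrix(c(2, 3), 2, 1),
                        L = matrix(c(1, 4), 2, 1), sigma = 1,
                        activity = matrix(c(0, 1), 2, 1))
  expect_equal(effective_rates(sys2, par4)[1, 2], 3 * exp(-2))
})

test_that("displayed distribution matches the geometric transit oracle", {
  sys <- golgi_system(NC = 1, NE = 1, Ns = 60)
  ss <- steady_state_linear(sys, uniform_params(1, R = 1, mu = 1, Ns = 60))
  k <- 1:59
  expect_lt(max(abs(ss$displayed$abundance[k] - 2^-k)), 1e-12)
  expect_equal(sum(ss$displayed$abundance), 1, tolerance = 1e-10)
})

test_that("displayed distribution matches the negative-binomial oracle", {
  # k - 1 completed reactions across NC cisternae, escape prob mu/(R + mu)
  for (NC in c(1, 2, 5)) {
    R <- 0.5; mu <- 0.8; Ns <- 80
    sys <- golgi_system(NC = NC, NE = 1, Ns = Ns)
    ss <- steady_state_linear(sys, uniform_params(NC, R, mu, Ns))
    p <- mu / (R + mu)
    nb <- dnbinom(0:(Ns - 2), size = NC, prob = p)
    expect_lt(pnbinom(Ns - 2, NC, p, lower.tail = FALSE), 1e-12)
    expect_lt(max(abs(ss$displayed$abundance[1:(Ns - 1)] - nb)), 1e-10)
    # NB mean: mean displayed index - 1 = NC * R / mu
    mean_idx <- sum(ss$displayed$index * ss$displayed$abundance)
    expect_equal(mean_idx - 1, NC * R / mu, tolerance = 1e-8)
  }
  # NC = 2, symmetric rates: k * 2^-(k+1)
  sys2 <- golgi_system(NC = 2, NE = 1, Ns = 60)
  ss2 <- steady_state_linear(sys2, uniform_params(2, 1, 1, 60))
  k <- 1:59
  expect_lt(max(abs(ss2$displayed$abundance[k] - k * 2^-(k + 1))), 1e-12)
})

test_that("both solvers conserve flux for random parameter draws", {
  n_draws <- 50
  for (i in seq_len(n_draws)) {
    sys <- tiny_system(NC = 1 + (i %% 4), NE = 1 + (i %% 3), Ns = 40)
    par <- random_params(sys, sigma = (i %% 5), seed = 1000 + i)
    ss <- steady_state_linear(sys, par)
    gl <- glance(ss)
    expect_lt(gl$flux_rel_error, 1e-8)
    expect_true(all(ss$conc >= 0))
    expect_equal(sum(ss$displayed$abundance), 1, tolerance = 1e-10)
  }
  # MM solver on a further set of draws
  for (i in seq_len(n_draws)) {
    set.seed(2000 + i)
    NC <- 1 + (i %% 3); NE <- 1 + (i %% 2); Ns <- 30
    sys <- golgi_system(NC = NC, NE = NE, Ns = Ns)
    par <- mm_parameter_set(
      mu = runif(NC, 0.01, 1),
      M = matrix(10^runif(NE * NC, -1, 3), NE, NC),
      V = matrix(10^runif(NE * NC, -1, 2), NE, NC),
      L = matrix(runif(NE * NC, 1, Ns), NE, NC),
      sigma = runif(1, 0, 3))
    ss <- steady_state_mm(sys, par)
    exit <- sum(par$mu[NC] * ss$conc[NC, ])
    expect_lt(abs(exit - sys$q) / sys$q, 1e-8)
    expect_true(all(ss$conc >= 0))
  }
})

test_that("MM solver reduces to the linear solver in the dilute limit", {
  sys <- golgi_system(NC = 2, NE = 2, Ns = 50)
  par <- random_params(sys, sigma = 1, seed = 42)
  ss_lin <- steady_state_linear(sys, par)
  par_mm <- mm_parameter_set(mu = par$mu, M = matrix(1e6, 2, 2),
                             V = 1e6 * par$R, L = par$L, sigma = par$sigma)
  ss_mm <- steady_state_mm(sys, par_mm)
  tv <- 0.5 * sum(abs(ss_mm$displayed$abundance - ss_lin$displayed$abundance))
  expect_lt(tv, 1e-4)
})

test_that("MM solver agrees with independent ODE time integration when saturated", {
  # strongly saturated single cisterna, solved to steady state with deSolve
  Ns <- 3; V <- 2; M <- 0.05; mu <- 0.7; q <- 1
  sys <- golgi_system(NC = 1, NE = 1, Ns = Ns, q = q)
  par <- mm_parameter_set(mu = mu, M = matrix(M), V = matrix(V),
                          L = matrix(1), sigma = 0)
  ss <- steady_state_mm(sys, par)
  deriv <- function(t, y, p) {
    S <- sum(y)
    rate <- V / (M + S)
    phi <- c(rate * y[1], rate * y[2], 0)
    list(c(q, 0, 0) + c(0, phi[1], phi[2]) - phi - mu * y)
  }
  ode <- deSolve::ode(y = rep(0, Ns), times = c(0, 1e5), func = deriv,
                      parms = NULL, rtol = 1e-12, atol = 1e-14)
  c_ode <- as.numeric(ode[nrow(ode), -1])
  disp_ode <- mu * c_ode / q
  expect_equal(ss$displayed$abundance, disp_ode, tolerance = 1e-7)
})

test_that("swapping cisternae exchanges enzyme complements only", {
  sys <- tiny_system(NC = 4, NE = 2, Ns = 40)
  par <- random_params(sys, sigma = 2, seed = 3)
  expect_identical(swap_cisternae(par, 2, 2), par)
  swapped <- swap_cisternae(par, 2, 4)
  expect_identical(swapped$R[, 2], par$R[, 4])
  expect_identical(swapped$L[, 4], par$L[, 2])
  expect_identical(swapped$mu, par$mu)
  expect_error(swap_cisternae(par, 2, 7), "out of range")

  # identical cisternae: swap is a symmetry of the displayed distribution
  par_sym <- par
  par_sym$R[, 4] <- par_sym$R[, 2]
  par_sym$L[, 4] <- par_sym$L[, 2]
  par_sym$mu[4] <- par_sym$mu[2]
  d0 <- displayed_profile(steady_state_linear(sys, par_sym))
  d1 <- displayed_profile(steady_state_linear(sys, swap_cisternae(par_sym, 2, 4)))
  expect_equal(d0$abundance, d1$abundance, tolerance = 1e-14)

  # generic cisternae: the displayed profile changes
  d2 <- displayed_profile(steady_state_linear(sys, swapped))
  dref <- displayed_profile(steady_state_linear(sys, par))
  expect_gt(kl_divergence(dref, d2), 0)
})

test_that("system and parameter constructors validate their invariants", {
  expect_error(golgi_system(NC = 0, NE = 1), ">= 1")
  expect_error(golgi_system(NC = 1, NE = 1, Ns = 1), ">= 2")
  expect_error(golgi_system(NC = 1, NE = 1, mu_bounds = c(1, 0.01)),
               "mu_min < mu_max")
  expect_error(parameter_set(mu = c(1, -1), R = matrix(1, 1, 2),
                             L = matrix(1, 1, 2), sigma = 0), "positive")
  expect_error(parameter_set(mu = 1, R = matrix(1), L = matrix(1), sigma = -2),
               "nonnegative")
  expect_error(steady_state_mm(golgi_system(1, 1, 10),
                               parameter_set(1, matrix(1), matrix(1), 0)))
  expect_identical(param_dim(golgi_system(NC = 4, NE = 4)), 37L)
})
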