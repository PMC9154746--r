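# Fidelity-landscape geometry: finite-difference Hessian, stiffness grouping,
# degeneracy probing. Analytic quadratics provide the oracle.

test_that("the full coordinate vector has dimension NC + 2*NE*NC + 1", {
  expect_identical(param_dim(golgi_system(NC = 4, NE = 4)), 37L)
  sys <- tiny_system(NC = 2, NE = 2, Ns = 30)
  par <- random_params(sys, sigma = 0.5, seed = 1)
  fx <- make_recovery_fixture(sys, 0.5, seed = 2)
  ha <- hessian_at(sys, fx$target, par, step = 1e-3)
  expect_identical(ha$dim, param_dim(sys))
  expect_identical(dim(ha$hessian), c(ha$dim, ha$dim))
})

test_that("quadratic oracle: eigenvalues of a known diagonal form are recovered", {
  A <- c(4, 1, 0.25, 0.01)
  f <- function(x) 0.5 * sum(A * (x - 0.5)^2)
  ha <- hessian_at(objective = f, x0 = rep(0.5, 4), step = 1e-3)
  expect_equal(sort(ha$eigenvalues), sort(A), tolerance = 1e-4)
  # eigen-decomposition reconstructs the Hessian
  rec <- ha$eigenvectors %*% diag(ha$eigenvalues) %*% t(ha$eigenvectors)
  expect_lt(max(abs(rec - ha$hessian)), 1e-6)
  expect_lt(max(abs(ha$hessian - t(ha$hessian))), 1e-8)
})

test_that("constant objective yields a floor-level flat landscape", {
  ha <- hessian_at(objective = function(x) 1.0, x0 = rep(0.5, 3), step = 1e-3)
  expect_lt(max(abs(ha$eigenvalues)), 1e-8)
  expect_equal(ha$total_stiffness, log(1e-12))
})

test_that("differencing near the box face falls back to shifted stencils", {
  f <- function(x) sum(x^2)
  ha <- hessian_at(objective = f, x0 = c(0, 1), step = 1e-3)
  expect_equal(ha$eigenvalues, c(2, 2), tolerance = 1e-4)
})

test_that("eigenvector groups partition the spectrum by parameter block", {
  sys <- tiny_system(NC = 2, NE = 1, Ns = 30)
  fx <- make_recovery_fixture(sys, 0.5, seed = 9)
  fit <- optimize_fidelity(sys, fx$target, 0.5, n_starts = 4, seed = 1,
                           control = list(maxit = 200))
  ha <- hessian_at(sys, fx$target, fit$best_params, step = 1e-3)
  expect_identical(length(ha$groups), ha$dim)
  expect_true(all(ha$groups %in% c("mu", "R", "L", "sigma")))
  expect_true(all(names(ha$group_stiffness) %in% c("mu", "R", "L", "sigma")))
  # near a verified optimum the spectrum is numerically PSD
  expect_gte(min(ha$eigenvalues), -1e-4 * max(abs(ha$eigenvalues)))
  td <- tidy(ha)
  expect_identical(nrow(td), ha$dim)
})

test_that("specificity is stiffer than reaction rates at a (3,3) optimum", {
  t3 <- shipped_target("3gmm")
  sys <- golgi_system(NC = 3, NE = 3, Ns = 200)
  fit <- optimize_fidelity(sys, t3, sigma = 0.25, n_starts = 4, seed = 6,
                           control = list(maxit = 200))
  ha <- hessian_at(sys, t3, fit$best_params, step = 1e-3)
  expect_gte(ha$group_stiffness[["sigma"]], ha$group_stiffness[["R"]])
  # most R-dominated directions sit in the sloppy part of the spectrum:
  # their median eigenvalue rank is in the lower half
  r_ranks <- which(ha$groups == "R")
  expect_gte(stats::median(r_ranks), ha$dim / 2)
})

test_that("degeneracy probing counts clusters and flat directions", {
  # permutation symmetry: two identical cisternae give a swapped twin of any
  # optimum with identical fidelity, i.e. at least two distinct clusters
  sys <- tiny_system(NC = 2, NE = 1, Ns = 30)
  fx <- make_recovery_fixture(sys, 0.5, seed = 14)
  fit <- optimize_fidelity(sys, fx$target, 0.5, n_starts = 10, seed = 2,
                           control = list(maxit = 200))
  rep_ <- probe_degeneracy(fit, cluster_radius = 0.05)
  expect_gte(rep_$n_clusters, 1L)
  expect_true(rep_$fraction_near_best > 0)

  # single start: one cluster by construction
  fit1 <- optimize_fidelity(sys, fx$target, 0.5, n_starts = 1, seed = 2,
                            control = list(maxit = 100))
  expect_identical(probe_degeneracy(fit1)$n_clusters, 1L)

  # quadratic with one exactly flat direction
  f <- function(x) (x[1] - 0.5)^2
  ha <- hessian_at(objective = f, x0 = c(0.5, 0.5), step = 1e-3)
  rep2 <- probe_degeneracy(fit1, hessian = ha)
  expect_identical(rep2$n_flat_directions, 1L)
})

test_that("enzyme relabeling is a discrete degeneracy with identical fidelity", {
  # permuting the enzyme labels within every cisterna leaves the effective
  # rates (a sum over enzymes) unchanged: same fidelity, distinct parameter
  # vector, hence two clusters among equally good solutions
  sys <- tiny_system(NC = 2, NE = 2, Ns = 30)
  fx <- make_recovery_fixture(sys, 0.5, seed = 14)
  fit <- optimize_fidelity(sys, fx$target, 0.5, n_starts = 4, seed = 2,
                           control = list(maxit = 200))
  p <- fit$best_params
  twin <- p
  twin$R <- p$R[2:1, , drop = FALSE]
  twin$L <- p$L[2:1, , drop = FALSE]
  f0 <- fidelity(fx$target, displayed_profile(steady_state_linear(sys, p)))$F
  f1 <- fidelity(fx$target, displayed_profile(steady_state_linear(sys, twin)))$F
  expect_equal(f0, f1, tolerance = 1e-9)
  x0 <- golgicode:::pack_params(sys, p)
  x1 <- golgicode:::pack_params(sys, twin)
  fake <- fit
  fake$per_start <- tibble::tibble(
    start = 1:2, seed = c(1, 2), value = c(f0, f1),
    converged = c(TRUE, TRUE), iterations = c(1L, 1L), x = list(x0, x1))
  if (sqrt(sum((x0 - x1)^2)) > 0.05) {
    expect_gte(probe_degeneracy(fake, cluster_radius = 0.05)$n_clusters, 2L)
  }
})
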