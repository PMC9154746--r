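# Multi-start constrained optimization of fidelity and diversity.
# Test-scale settings (few starts, reduced maxit, small Ns) keep each block
# fast while exercising the full optimization path.

test_that("optimizer recovers self-generated targets to near-zero fidelity", {
  # two seeds here; the full five-seed recovery check runs in the
  # acceptance suite
  sys <- tiny_system(NC = 3, NE = 2, Ns = 60)
  for (s in 1:2) {
    fx <- make_recovery_fixture(sys, sigma = 1, seed = 100 + s)
    fit <- optimize_fidelity(sys, fx$target, sigma = 1, n_starts = 16,
                             seed = s, control = list(maxit = 400))
    expect_lte(fit$best_value, 0.01)
  }
})

test_that("optimization is deterministic, feasible and sound", {
  sys <- tiny_system(NC = 2, NE = 2, Ns = 50)
  fx <- make_recovery_fixture(sys, sigma = 0.5, seed = 12)
  fit1 <- optimize_fidelity(sys, fx$target, sigma = 0.5, n_starts = 6,
                            seed = 4, control = list(maxit = 150))
  fit2 <- optimize_fidelity(sys, fx$target, sigma = 0.5, n_starts = 6,
                            seed = 4, control = list(maxit = 150))
  # bit-for-bit determinism given identical inputs and seed
  expect_identical(fit1$per_start$value, fit2$per_start$value)
  expect_identical(fit1$best_params$mu, fit2$best_params$mu)
  # feasibility: the optimum lies inside its box
  expect_true(validate_params_ok(sys, fit1$best_params))
  # soundness: reported best value re-evaluates identically from best_params
  ss <- steady_state_linear(sys, fit1$best_params)
  expect_equal(fit1$best_value, fidelity(fx$target, ss$displayed)$F,
               tolerance = 1e-10)
  # per-start table shape
  td <- tidy(fit1)
  expect_identical(nrow(td), 6L)
  expect_true(all(c("start", "seed", "value", "converged") %in% names(td)))
  expect_true(glance(fit1)$fraction_near_best >= 1 / 6)
})

test_that("a target displayed at the fixed sigma is matched nearly exactly", {
  sys <- tiny_system(NC = 2, NE = 1, Ns = 40)
  fx <- make_recovery_fixture(sys, sigma = 0.5, seed = 33)
  fit <- optimize_fidelity(sys, fx$target, sigma = 0.5, n_starts = 8,
                           seed = 2, control = list(maxit = 400))
  expect_lte(fit$best_value, 1e-4)
})

test_that("multiple cisternae beat one cisterna on a sharp target", {
  # near-delta target at k = 3 with 3 highly specific enzymes: a single
  # cisterna inevitably displays lower-index intermediates
  Ns <- 6
  target <- normalize_profile(glycan_profile(c(0.02, 0.03, 0.9, 0.03,
                                               0.01, 0.01)))
  sys1 <- golgi_system(NC = 1, NE = 3, Ns = Ns)
  sys3 <- golgi_system(NC = 3, NE = 3, Ns = Ns)
  f1 <- optimize_fidelity(sys1, target, sigma = 4, n_starts = 12, seed = 5,
                          control = list(maxit = 300))
  f3 <- optimize_fidelity(sys3, target, sigma = 4, n_starts = 12, seed = 5,
                          control = list(maxit = 300))
  expect_lt(f3$best_value, f1$best_value)
})

test_that("sigma scans record the grid argmin with smallest-sigma ties", {
  sys <- tiny_system(NC = 2, NE = 2, Ns = 50)
  fx <- make_recovery_fixture(sys, sigma = 0.5, seed = 19)
  one <- scan_sigma(sys, fx$target, sigma_grid = 0.5, n_starts = 4, seed = 1,
                    control = list(maxit = 100))
  expect_identical(attr(one, "sigma_min"), 0.5)
  expect_error(scan_sigma(sys, fx$target, numeric(0)), "nonempty")
  expect_error(scan_sigma(sys, fx$target, c(1, 0.5)), "increasing")
  sc <- scan_sigma(sys, fx$target, c(0, 0.5, 1), n_starts = 4, seed = 1,
                   control = list(maxit = 150))
  expect_identical(nrow(sc), 3L)
  expect_identical(attr(sc, "Dbar_min"), min(sc$Dbar))
  # the generating sigma wins on this self-generated target
  expect_identical(attr(sc, "sigma_min"), 0.5)
})

test_that("capacity nesting: (1,1) is strictly worse than (3,3)", {
  t3 <- shipped_target("3gmm")
  # desk-scale: shrink to Ns = 100 by rebinning the target
  t3s <- normalize_profile(glycan_profile(
    t3$abundance[seq(1, 199, by = 2)] + t3$abundance[seq(2, 200, by = 2)]))
  f11 <- scan_sigma(golgi_system(1, 1, 100), t3s, c(0, 0.5), n_starts = 4,
                    seed = 2, control = list(maxit = 150))
  f33 <- scan_sigma(golgi_system(3, 3, 100), t3s, c(0, 0.5), n_starts = 4,
                    seed = 2, control = list(maxit = 150))
  expect_lt(attr(f33, "Dbar_min"), attr(f11, "Dbar_min"))
})

test_that("diversity maximization respects its analytic bound", {
  sys <- tiny_system(NC = 2, NE = 2, Ns = 50)
  fit <- maximize_diversity(sys, sigma = 0, n_starts = 4, seed = 3,
                            control = list(maxit = 150))
  expect_lte(-fit$best_value, 50)
  expect_gte(-fit$best_value, 0)
  expect_true(validate_params_ok(sys, fit$best_params))
  expect_equal(glance(fit)$diversity, -fit$best_value)
})

test_that("the two optimization parametrizations agree on small instances", {
  Ns <- 6
  target <- normalize_profile(glycan_profile(c(0.1, 0.35, 0.1, 0.05,
                                               0.3, 0.1)))
  sys <- golgi_system(NC = 1, NE = 1, Ns = Ns)
  eq <- check_ab_equivalence(sys, target, sigma = 0.5, n_starts = 10,
                             seed = 7, control = list(maxit = 300))
  expect_lte(eq$gap, 0.01)
})

test_that("a B-achievable target is matched by both parametrizations", {
  sys <- golgi_system(NC = 1, NE = 1, Ns = 6)
  fx <- make_recovery_fixture(sys, sigma = 0.5, seed = 88)
  eq <- check_ab_equivalence(sys, fx$target, sigma = 0.5, n_starts = 10,
                             seed = 3, control = list(maxit = 400))
  expect_lte(eq$F_B, 1e-3)
  expect_lte(eq$F_A, 1e-3)
})

test_that("tradeoff surfaces report per-cell optima", {
  sys_target <- make_recovery_fixture(tiny_system(NC = 2, NE = 2, Ns = 40),
                                      sigma = 0.5, seed = 50)$target
  tr <- tradeoff_surface(sys_target, NE_range = 1:2, NC_range = 2,
                         sigma_grid = c(0, 0.5), n_starts = 3, seed = 4,
                         control = list(maxit = 100))
  expect_identical(nrow(tr), 2L)
  expect_true(all(c("NE", "NC", "Dbar_min", "sigma_min") %in% names(tr)))
  expect_true(all(is.finite(tr$Dbar_min)))
})
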