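# Multi-start local optimization over box-normalized coordinates.
# mu and R are optimized on log scale (their boxes span decades), L on linear
# scale; all coordinates are mapped to [0, 1] so finite-difference steps are
# comparable across blocks. Gradients are forward finite differences with
# step 1e-6, flipped to backward at the upper box face.

fd_gradient <- function(fn, x, f0, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x
    if (x[i] + h <= 1) {
      xi[i] <- x[i] + h
      g[i] <- (fn(xi) - f0) / h
    } else {
      xi[i] <- x[i] - h
      g[i] <- (f0 - fn(xi)) / h
    }
  }
  g
}

default_control <- function(control) {
  modifyList(list(maxit = 200, factr = 1e7, fd_step = 1e-6,
                  near_tol_abs = 0.01, near_tol_rel = 0.05), control)
}

run_multistart <- function(fn, dim, n_starts, seed, control, init_fn = NULL) {
  ctrl <- default_control(control)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_starts))
  starts <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    x0 <- with_seed(seeds[i],
                    if (is.null(init_fn)) runif(dim) else init_fn(i))
    res <- tryCatch(
      optim(x0, fn,
            gr = function(x) fd_gradient(fn, x, fn(x), ctrl$fd_step),
            method = "L-BFGS-B", lower = 0, upper = 1,
            control = list(maxit = ctrl$maxit, factr = ctrl$factr)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      starts[[i]] <- list(seed = seeds[i], value = NA_real_, converged = FALSE,
                          iterations = NA_integer_, x = NULL,
                          message = conditionMessage(res))
    } else {
      starts[[i]] <- list(seed = seeds[i], value = res$value,
                          converged = res$convergence == 0,
                          iterations = unname(res$counts[1]), x = res$par,
                          message = res$message %||% "")
    }
  }
  values <- vapply(starts, function(s) s$value, numeric(1))
  if (all(is.na(values))) {
    abort(paste0("all ", n_starts, " optimization starts failed: ",
                 starts[[1]]$message))
  }
  best <- which.min(values)
  near_tol <- max(ctrl$near_tol_abs, ctrl$near_tol_rel * values[best])
  per_start <- tibble::tibble(
    start = seq_len(n_starts),
    seed = vapply(starts, function(s) s$seed, numeric(1)),
    value = values,
    converged = vapply(starts, function(s) s$converged, logical(1)),
    iterations = vapply(starts, function(s) as.integer(s$iterations %||% NA),
                        integer(1)),
    x = lapply(starts, function(s) s$x)
  )
  list(best = best, per_start = per_start,
       fraction_near_best = mean(values <= values[best] + near_tol,
                                 na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_golgi_fit <- function(objective, system, sigma, best_params, best_value,
                          per_start, fraction_near_best, target = NULL,
                          extra = list()) {
  structure(
    c(list(objective = objective, system = system, sigma = sigma,
           best_params = best_params, best_value = best_value,
           per_start = per_start, fraction_near_best = fraction_near_best,
           target = target), extra),
    class = "golgi_fit"
  )
}

#' Optimize fidelity to a target distribution
#'
#' Minimizes the normalized-KL fidelity `F(target || displayed)` over the
#' transfer rates `mu`, effective reaction rates `R`, and enzyme shapes `L`
#' at a fixed specificity `sigma` (the effective-rate parametrization of the
#' synthesis model), subject to the system's box bounds. `n_starts`
#' independent local minimizations are run from in-box initial points
#' (log-uniform for `mu` and `R`), deterministically given `seed`. The
#' enzyme-placement landscape is rugged at moderate and high specificity,
#' so every second start seeds the shapes `L` from the target's own mass
#' distribution (an enzyme is useful just below an abundant product index);
#' the remaining starts are fully uniform.
#'
#' @param system A [golgi_system()].
#' @param target Normalized [glycan_profile()] of length `Ns` with positive
#'   entropy.
#' @param sigma Fixed specificity for this optimization.
#' @param n_starts Number of random multi-starts.
#' @param seed Integer seed controlling all initializations.
#' @param activity Optional binary `NE x NC` activity mask held fixed.
#' @param control Optional list: `maxit`, `factr`, `fd_step`,
#'   `near_tol_abs`, `near_tol_rel`.
#' @return A `golgi_fit` with fields `best_params`, `best_value` (the best
#'   fidelity), a `per_start` tibble, and `fraction_near_best`.
#' @export
optimize_fidelity <- function(system, target, sigma, n_starts = 32, seed = 1,
                              activity = NULL, control = list()) {
  tv <- profile_vec(target)
  assert_normalized(tv, "target")
  if (length(tv) != system$Ns) abort("target length must equal system Ns.")
  H <- profile_entropy(tv)
  if (H <= 0) abort("target has zero entropy; fidelity is undefined (use diversity or raw KL).")
  if (n_starts < 1) abort("`n_starts` must be at least 1.")
  dim <- system$NC + 2 * system$NE * system$NC
  fn <- function(x) {
    params <- unpack_params(system, x, sigma = sigma, activity = activity)
    ss <- steady_state_linear(system, params)
    fidelity_value(tv, ss$displayed$abundance, H)
  }
  NC <- system$NC; NE <- system$NE; Ns <- system$Ns
  n_rl <- NE * NC
  init_fn <- function(i) {
    x <- runif(dim)
    if (i %% 2 == 0) {
      # place enzyme shapes just below target-abundant indices
      kdraw <- sample.int(Ns, n_rl, replace = TRUE, prob = tv + 1e-9)
      x[NC + n_rl + seq_len(n_rl)] <-
        (pmax(kdraw - runif(n_rl, 0, 3), 1) - 1) / (Ns - 1)
    }
    x
  }
  ms <- run_multistart(fn, dim, n_starts, seed, control, init_fn = init_fn)
  best_x <- ms$per_start$x[[ms$best]]
  best_params <- unpack_params(system, best_x, sigma = sigma,
                               activity = activity)
  new_golgi_fit("fidelity", system, sigma, best_params,
                ms$per_start$value[ms$best], ms$per_start,
                ms$fraction_near_best, target = glycan_profile(tv))
}

#' Maximize glycan diversity
#'
#' Maximizes the sigmoid-smoothed [diversity()] of the displayed
#' distribution over `mu`, `R` and `L` at fixed `sigma`, subject to the box
#' bounds (internally a minimization of the negative diversity with the same
#' multi-start machinery as [optimize_fidelity()]).
#'
#' @inheritParams optimize_fidelity
#' @param c_th Abundance threshold; defaults to `1/Ns`.
#' @return A `golgi_fit` whose `best_value` is the negative achieved
#'   diversity; `glance()` reports `diversity = -best_value`.
#' @export
maximize_diversity <- function(system, sigma, n_starts = 32, seed = 1,
                               c_th = NULL, control = list()) {
  Ns <- system$Ns
  if (is.null(c_th)) c_th <- 1 / Ns
  dim <- system$NC + 2 * system$NE * system$NC
  fn <- function(x) {
    params <- unpack_params(system, x, sigma = sigma)
    ss <- steady_state_linear(system, params)
    -diversity_value(ss$displayed$abundance, c_th, Ns)
  }
  ms <- run_multistart(fn, dim, n_starts, seed, control)
  best_x <- ms$per_start$x[[ms$best]]
  best_params <- unpack_params(system, best_x, sigma = sigma)
  new_golgi_fit("diversity", system, sigma, best_params,
                ms$per_start$value[ms$best], ms$per_start,
                ms$fraction_near_best, extra = list(c_th = c_th))
}

#' @export
print.golgi_fit <- function(x, ...) {
  cat("<golgi_fit> objective:", x$objective, " sigma =", signif(x$sigma, 4),
      "\n  best value:", signif(x$best_value, 6),
      " (", nrow(x$per_start), "starts,",
      sprintf("%.0f%%", 100 * x$fraction_near_best), "near best )\n")
  invisible(x)
}

#' @method tidy golgi_fit
#' @export
tidy.golgi_fit <- function(x, ...) {
  dplyr::select(x$per_start, "start", "seed", "value", "converged",
                "iterations")
}

#' @method glance golgi_fit
#' @export
glance.golgi_fit <- function(x, ...) {
  out <- tibble::tibble(
    objective = x$objective, sigma = x$sigma,
    best_value = x$best_value,
    n_starts = nrow(x$per_start),
    fraction_near_best = x$fraction_near_best,
    NE = x$system$NE, NC = x$system$NC, Ns = x$system$Ns
  )
  if (x$objective == "diversity") out$diversity <- -x$best_value
  out
}

#' Scan the optimal fidelity over a grid of specificities
#'
#' Runs [optimize_fidelity()] at each `sigma` on the grid and records the
#' optimized fidelity `Dbar(sigma)`. The optimal specificity `sigma_min` is
#' the grid argmin (ties broken toward the smallest `sigma`). Failures at
#' individual grid points are recorded as `NA` rather than aborting the
#' scan.
#'
#' @inheritParams optimize_fidelity
#' @param sigma_grid Increasing vector of nonnegative specificities.
#' @param keep_fits Keep the per-sigma `golgi_fit` objects as an attribute.
#' @return A `sigma_scan` tibble with columns `sigma`, `Dbar`,
#'   `fraction_near_best`, and attributes `sigma_min`, `Dbar_min`.
#' @export
scan_sigma <- function(system, target, sigma_grid, n_starts = 32, seed = 1,
                       control = list(), keep_fits = FALSE) {
  if (length(sigma_grid) == 0) abort("`sigma_grid` must be nonempty.")
  if (is.unsorted(sigma_grid, strictly = TRUE)) {
    abort("`sigma_grid` must be strictly increasing.")
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                      length(sigma_grid)))
  fits <- vector("list", length(sigma_grid))
  Dbar <- frac <- rep(NA_real_, length(sigma_grid))
  err <- rep(NA_character_, length(sigma_grid))
  for (i in seq_along(sigma_grid)) {
    fit <- tryCatch(
      optimize_fidelity(system, target, sigma_grid[i], n_starts = n_starts,
                        seed = seeds[i], control = control),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      err[i] <- conditionMessage(fit)
    } else {
      Dbar[i] <- fit$best_value
      frac[i] <- fit$fraction_near_best
      if (keep_fits) fits[[i]] <- fit
    }
  }
  if (all(is.na(Dbar))) {
    abort(paste0("every grid point failed; first error: ", err[1]))
  }
  i_min <- which.min(Dbar) # first minimum = smallest sigma on ties
  out <- tibble::tibble(sigma = as.numeric(sigma_grid), Dbar = Dbar,
                        fraction_near_best = frac, error = err)
  class(out) <- c("sigma_scan", class(out))
  attr(out, "sigma_min") <- sigma_grid[i_min]
  attr(out, "Dbar_min") <- Dbar[i_min]
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' @method autoplot sigma_scan
#' @export
autoplot.sigma_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma, y = .data$Dbar)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = attr(object, "sigma_min"),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = expression(sigma), y = expression(bar(D)(sigma))) +
    ggplot2::theme_minimal()
}

#' Fidelity trade-off surface over enzyme and cisterna numbers
#'
#' For every `(NE, NC)` pair, scans `sigma` and reports the best achievable
#' fidelity `min_sigma Dbar` and the optimal specificity `sigma_min`. Cells
#' are computed independently with per-cell seeds derived from `seed`;
#' failed cells are reported as `NA`.
#'
#' @param target Normalized target profile (its length sets `Ns`).
#' @param NE_range,NC_range Integer vectors of enzyme/cisterna numbers.
#' @param sigma_grid Specificity grid passed to [scan_sigma()].
#' @param n_starts,seed,control As in [optimize_fidelity()].
#' @param q Injection rate for each constructed system.
#' @param mu_bounds,R_bounds Boxes for each constructed system.
#' @return A tibble with columns `NE`, `NC`, `Dbar_min`, `sigma_min`.
#' @export
tradeoff_surface <- function(target, NE_range, NC_range, sigma_grid,
                             n_starts = 32, seed = 1, control = list(),
                             q = 1, mu_bounds = c(0.01, 1),
                             R_bounds = c(0.018, 20)) {
  if (length(NE_range) == 0 || length(NC_range) == 0) {
    abort("`NE_range` and `NC_range` must be nonempty.")
  }
  tv <- profile_vec(target)
  grid <- tidyr::expand_grid(NE = as.integer(NE_range),
                             NC = as.integer(NC_range))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, nrow(grid)))
  res <- purrr::pmap(list(grid$NE, grid$NC, seeds), function(NE, NC, s) {
    sys <- golgi_system(NC = NC, NE = NE, Ns = length(tv), q = q,
                        mu_bounds = mu_bounds, R_bounds = R_bounds)
    scan <- tryCatch(
      scan_sigma(sys, tv, sigma_grid, n_starts = n_starts, seed = s,
                 control = control),
      error = function(e) NULL
    )
    if (is.null(scan)) {
      tibble::tibble(Dbar_min = NA_real_, sigma_min = NA_real_)
    } else {
      tibble::tibble(Dbar_min = attr(scan, "Dbar_min"),
                     sigma_min = attr(scan, "sigma_min"))
    }
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Numerical equivalence of the two optimization parametrizations
#'
#' The synthesis model can be optimized either in the effective-rate form
#' (over `mu`, `R`, `L`; steady state explicit by forward substitution) or
#' in the full Michaelis--Menten form (over `mu`, `M`, `V`, `L`; steady
#' state by fixed-point iteration). The two are equivalent: the dilute limit
#' of the MM kinetics is the linear model with `R = V/M`, and saturation
#' only rescales effective rates. This function optimizes both forms on the
#' same (small) instance and returns both optima; their gap should vanish
#' within optimizer noise. The MM form is parametrized by
#' `(mu, rho = V/M, M, L)` with `rho` in the `R` box and `M` log-uniform in
#' `M_bounds`, so the dilute limit reproduces exactly the effective-rate
#' feasible set.
#'
#' @inheritParams optimize_fidelity
#' @param M_bounds Box for the saturation constants in the MM form.
#' @return A one-row tibble with columns `F_B` (effective-rate optimum),
#'   `F_A` (MM optimum), and `gap = |F_B - F_A|`; the two fits are attached
#'   as attributes `fit_B` and `fit_A`.
#' @export
check_ab_equivalence <- function(system, target, sigma, n_starts = 16,
                                 seed = 1, control = list(),
                                 M_bounds = c(1, 1e6)) {
  tv <- profile_vec(target)
  assert_normalized(tv, "target")
  H <- profile_entropy(tv)
  fit_B <- optimize_fidelity(system, target, sigma, n_starts = n_starts,
                             seed = seed, control = control)
  NE <- system$NE; NC <- system$NC
  n_blk <- NE * NC
  unpack_mm <- function(x) {
    mu <- denorm_log(x[seq_len(NC)], system$mu_bounds[1], system$mu_bounds[2])
    rho <- matrix(denorm_log(x[NC + seq_len(n_blk)],
                             system$R_bounds[1], system$R_bounds[2]), NE, NC)
    M <- matrix(denorm_log(x[NC + n_blk + seq_len(n_blk)],
                           M_bounds[1], M_bounds[2]), NE, NC)
    L <- matrix(1 + x[NC + 2 * n_blk + seq_len(n_blk)] * (system$Ns - 1),
                NE, NC)
    mm_parameter_set(mu = mu, M = M, V = rho * M, L = L, sigma = sigma)
  }
  fn_A <- function(x) {
    ss <- steady_state_mm(system, unpack_mm(x))
    fidelity_value(tv, ss$displayed$abundance, H)
  }
  ms_A <- run_multistart(fn_A, NC + 3 * n_blk, n_starts, seed + 1,
                         control)
  best_A <- unpack_mm(ms_A$per_start$x[[ms_A$best]])
  fit_A <- new_golgi_fit("fidelity_mm", system, sigma, best_A,
                         ms_A$per_start$value[ms_A$best], ms_A$per_start,
                         ms_A$fraction_near_best, target = glycan_profile(tv))
  out <- tibble::tibble(F_B = fit_B$best_value, F_A = fit_A$best_value,
                        gap = abs(fit_B$best_value - fit_A$best_value))
  attr(out, "fit_B") <- fit_B
  attr(out, "fit_A") <- fit_A
  out
}
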