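#' Define a Golgi synthesis system
#'
#' A `golgi_system` fixes the static dimensions and kinetic boxes of the
#' cisternal reaction--transport model: the number of cisternae `NC`, the
#' number of enzyme species per cisterna `NE`, the number of glycan species
#' `Ns` (the reaction line graph has `Ns - 1` steps), the injection rate `q`
#' of unglycosylated protein into cisterna 1, and box bounds on the
#' inter-cisternal transfer rates `mu` and the effective catalytic capacities
#' `R`. The default boxes, `(0.01, 1)` per minute for `mu` and `(0.018, 20)`
#' per minute for `R`, are the physiological ranges used throughout.
#'
#' @param NC Number of cisternae (positive integer).
#' @param NE Number of enzyme species per cisterna (positive integer).
#' @param Ns Number of glycan species, i.e. chain length (integer, at least 2).
#' @param q Injection rate into cisterna 1, in concentration per minute.
#' @param mu_bounds Length-2 numeric, `(mu_min, mu_max)` in 1/min.
#' @param R_bounds Length-2 numeric, `(R_min, R_max)` in 1/min.
#'
#' @return An object of class `golgi_system`.
#' @examples
#' sys <- golgi_system(NC = 4, NE = 4, Ns = 100)
#' param_dim(sys)
#' @export
golgi_system <- function(NC, NE, Ns = 200, q = 1,
                         mu_bounds = c(0.01, 1),
                         R_bounds = c(0.018, 20)) {
  stopifnot(
    is.numeric(NC), length(NC) == 1, NC >= 1, NC == round(NC),
    is.numeric(NE), length(NE) == 1, NE >= 1, NE == round(NE),
    is.numeric(Ns), length(Ns) == 1, Ns >= 2, Ns == round(Ns),
    is.numeric(q), length(q) == 1, q > 0,
    length(mu_bounds) == 2, length(R_bounds) == 2
  )
  if (!(0 < mu_bounds[1] && mu_bounds[1] < mu_bounds[2])) {
    abort("`mu_bounds` must satisfy 0 < mu_min < mu_max.")
  }
  if (!(0 < R_bounds[1] && R_bounds[1] < R_bounds[2])) {
    abort("`R_bounds` must satisfy 0 < R_min < R_max.")
  }
  structure(
    list(NC = as.integer(NC), NE = as.integer(NE), Ns = as.integer(Ns),
         q = q, mu_bounds = as.numeric(mu_bounds),
         R_bounds = as.numeric(R_bounds)),
    class = "golgi_system"
  )
}

#' @export
print.golgi_system <- function(x, ...) {
  cat("<golgi_system> NC =", x$NC, " NE =", x$NE, " Ns =", x$Ns,
      " q =", x$q, "\n")
  cat("  mu in [", x$mu_bounds[1], ",", x$mu_bounds[2], "] /min;",
      " R in [", x$R_bounds[1], ",", x$R_bounds[2], "] /min\n")
  invisible(x)
}

#' Dimension of the full parameter vector
#'
#' The fidelity landscape lives on the coordinates `(mu, R, L, sigma)`:
#' `NC` transfer rates, `NE x NC` reaction rates, `NE x NC` enzyme shapes,
#' and the shared specificity, giving `NC + 2 * NE * NC + 1` dimensions.
#'
#' @param system A [golgi_system()].
#' @return Integer dimension.
#' @export
param_dim <- function(system) {
  stopifnot(inherits(system, "golgi_system"))
  system$NC + 2L * system$NE * system$NC + 1L
}

#' Construct a parameter set for the linear effective-rate model
#'
#' Holds the optimization variables of the effective-rate (linear flux)
#' parametrization: per-cisterna transfer rates `mu`, enzyme-by-cisterna
#' catalytic capacities `R`, continuous enzyme shapes `L` (the substrate
#' index each enzyme binds best), the shared specificity `sigma`, and an
#' optional binary `activity` mask restricting which enzymes are active in
#' which cisternae.
#'
#' @param mu Numeric vector, length `NC`, transfer rates in 1/min;
#'   `mu[NC]` is the exit rate to the plasma membrane.
#' @param R Numeric matrix `NE x NC`, effective catalytic capacities in 1/min.
#' @param L Numeric matrix `NE x NC`, ideal enzyme shapes (continuous reals,
#'   conventionally in `[1, Ns]`).
#' @param sigma Nonnegative scalar specificity; `sigma = 0` is a fully
#'   promiscuous enzyme.
#' @param activity Optional binary `NE x NC` matrix; defaults to all ones.
#'
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(mu, R, L, sigma, activity = NULL) {
  R <- as.matrix(R); L <- as.matrix(L)
  if (!all(dim(R) == dim(L))) abort("`R` and `L` must have identical dimensions.")
  if (length(sigma) != 1 || !is.finite(sigma) || sigma < 0) {
    abort("`sigma` must be a single nonnegative number.")
  }
  if (any(mu <= 0)) abort("all transfer rates `mu` must be positive.")
  if (is.null(activity)) {
    activity <- matrix(1, nrow(R), ncol(R))
  } else {
    activity <- as.matrix(activity)
    if (!all(dim(activity) == dim(R))) abort("`activity` must match dim(R).")
    if (!all(activity %in% c(0, 1))) abort("`activity` must be binary.")
    storage.mode(activity) <- "double"
  }
  if (length(mu) != ncol(R)) {
    abort("length(mu) must equal ncol(R) (one transfer rate per cisterna).")
  }
  structure(
    list(mu = as.numeric(mu), R = R, L = L, sigma = as.numeric(sigma),
         activity = activity),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> NC =", length(x$mu), " NE =", nrow(x$R),
      " sigma =", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' Construct a parameter set for the full Michaelis--Menten model
#'
#' Holds the variables of the saturable kinetics: saturation constants `M`
#' and maximal velocities `V` (both enzyme-by-cisterna, k-independent),
#' together with `mu`, `L` and `sigma` as in [parameter_set()]. In the dilute
#' limit (`M` much larger than total bound substrate) the model reduces to
#' the linear effective-rate model with `R = V / M`.
#'
#' @inheritParams parameter_set
#' @param M Numeric matrix `NE x NC` of positive saturation constants
#'   (concentration units).
#' @param V Numeric matrix `NE x NC` of positive maximal velocities
#'   (concentration/min).
#' @return An object of class `mm_parameter_set`.
#' @export
mm_parameter_set <- function(mu, M, V, L, sigma) {
  M <- as.matrix(M); V <- as.matrix(V); L <- as.matrix(L)
  if (!all(dim(M) == dim(V)) || !all(dim(M) == dim(L))) {
    abort("`M`, `V`, `L` must have identical dimensions.")
  }
  if (any(M <= 0) || any(V <= 0)) abort("`M` and `V` must be positive.")
  if (any(mu <= 0)) abort("all transfer rates `mu` must be positive.")
  if (length(sigma) != 1 || sigma < 0) abort("`sigma` must be nonnegative scalar.")
  if (length(mu) != ncol(M)) abort("length(mu) must equal ncol(M).")
  structure(
    list(mu = as.numeric(mu), M = M, V = V, L = L, sigma = as.numeric(sigma)),
    class = "mm_parameter_set"
  )
}

validate_params <- function(system, params, tol = 1e-9) {
  stopifnot(inherits(system, "golgi_system"), inherits(params, "parameter_set"))
  if (length(params$mu) != system$NC || nrow(params$R) != system$NE) {
    abort("parameter dimensions do not match the system (NC, NE).")
  }
  mb <- system$mu_bounds; rb <- system$R_bounds
  if (any(params$mu < mb[1] - tol) || any(params$mu > mb[2] + tol)) {
    abort("`mu` outside its box.")
  }
  if (any(params$R < rb[1] - tol) || any(params$R > rb[2] + tol)) {
    abort("`R` outside its box.")
  }
  if (any(params$L < 1 - tol) || any(params$L > system$Ns + tol)) {
    abort("`L` outside [1, Ns].")
  }
  invisible(TRUE)
}

#' Exchange the enzymes of two cisternae
#'
#' Swaps the columns of `R`, `L` and `activity` belonging to cisternae `j1`
#' and `j2`, leaving the transfer rates untouched. Repartitioning the
#' optimized enzymes this way generically alters the displayed glycan
#' distribution, which is how enzyme placement is probed in the model.
#'
#' @param params A [parameter_set()].
#' @param j1,j2 Cisterna indices to exchange.
#' @return A `parameter_set` with the two cisternal enzyme complements swapped.
#' @export
swap_cisternae <- function(params, j1, j2) {
  stopifnot(inherits(params, "parameter_set"))
  NC <- length(params$mu)
  if (!(j1 %in% seq_len(NC)) || !(j2 %in% seq_len(NC))) {
    abort("cisterna indices out of range.")
  }
  out <- params
  idx <- c(j1, j2)
  out$R[, idx] <- params$R[, rev(idx)]
  out$L[, idx] <- params$L[, rev(idx)]
  out$activity[, idx] <- params$activity[, rev(idx)]
  out
}

# ---- box-normalized coordinates -------------------------------------------
# mu and R live on log scale (their boxes span decades), L on linear scale,
# sigma linear on [0, sigma_max]. All packed coordinates lie in [0, 1].

norm_log <- function(v, lo, hi) (log(v) - log(lo)) / (log(hi) - log(lo))
# clamp to the box so rounding in exp(log(...)) can never step outside it
denorm_log <- function(x, lo, hi) {
  pmin(pmax(exp(log(lo) + x * (log(hi) - log(lo))), lo), hi)
}

pack_params <- function(system, params, include_sigma = FALSE,
                        sigma_max = 10) {
  x <- c(
    norm_log(params$mu, system$mu_bounds[1], system$mu_bounds[2]),
    norm_log(as.vector(params$R), system$R_bounds[1], system$R_bounds[2]),
    (as.vector(params$L) - 1) / (system$Ns - 1)
  )
  if (include_sigma) x <- c(x, params$sigma / sigma_max)
  pmin(pmax(x, 0), 1)
}

unpack_params <- function(system, x, sigma = NULL, activity = NULL,
                          sigma_max = 10) {
  NC <- system$NC; NE <- system$NE
  n_rl <- NE * NC
  mu <- denorm_log(x[seq_len(NC)], system$mu_bounds[1], system$mu_bounds[2])
  R <- matrix(denorm_log(x[NC + seq_len(n_rl)],
                         system$R_bounds[1], system$R_bounds[2]), NE, NC)
  L <- matrix(pmin(pmax(1 + x[NC + n_rl + seq_len(n_rl)] * (system$Ns - 1),
                        1), system$Ns), NE, NC)
  if (is.null(sigma)) {
    sigma <- x[NC + 2 * n_rl + 1] * sigma_max
  }
  parameter_set(mu, R, L, sigma, activity = activity)
}

# uniform draw in the box: log-uniform for mu and R, uniform for L
draw_params <- function(system, sigma) {
  NE <- system$NE; NC <- system$NC
  parameter_set(
    mu = denorm_log(runif(NC), system$mu_bounds[1], system$mu_bounds[2]),
    R = matrix(denorm_log(runif(NE * NC), system$R_bounds[1],
                          system$R_bounds[2]), NE, NC),
    L = matrix(1 + runif(NE * NC) * (system$Ns - 1), NE, NC),
    sigma = sigma
  )
}
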