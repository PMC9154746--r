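#' Enzyme-substrate binding probability from the distortion model
#'
#' An enzyme whose ideal shape is `l` binds substrate `k` (whose shape is the
#' index itself) with probability `exp(-sigma * |k - l|)`: the mismatch
#' penalty is linear in the shape difference and `sigma` sets how sharply
#' binding falls off. `sigma = 0` gives a fully promiscuous enzyme
#' (probability 1 for every substrate); large `sigma` a highly specific one.
#' The value is computed as the exponential of a clipped log and floored at
#' `1e-300`, so it never underflows to exactly zero.
#'
#' @param k Substrate index (vectorized).
#' @param l Ideal enzyme shape, a continuous real (vectorized).
#' @param sigma Nonnegative specificity.
#' @return Binding probabilities in `(0, 1]`.
#' @examples
#' binding_probability(3, 5, 1) # exp(-2)
#' @export
binding_probability <- function(k, l, sigma) {
  if (length(sigma) != 1 || !is.finite(sigma) || sigma < 0) {
    abort("`sigma` must be a single nonnegative number.")
  }
  exp(pmax(-sigma * abs(k - l), log(1e-300)))
}

#' Effective reaction rates per cisterna and species
#'
#' The rate of the reaction `k -> k + 1` in cisterna `j` is the sum of all
#' active enzymes' contributions, `R[a, j] * P(k, a)` with `P` the binding
#' probability of enzyme `a`'s shape `L[a, j]` at substrate `k`. The last
#' species `Ns` has no outgoing reaction, so its rate is zero (the chain
#' ends there).
#'
#' @param system A [golgi_system()].
#' @param params A [parameter_set()].
#' @return An `NC x Ns` matrix of rates in 1/min; column `Ns` is zero.
#' @export
effective_rates <- function(system, params) {
  stopifnot(inherits(system, "golgi_system"), inherits(params, "parameter_set"))
  if (length(params$mu) != system$NC || nrow(params$R) != system$NE) {
    abort("parameter dimensions do not match the system.")
  }
  Ns <- system$Ns
  k <- seq_len(Ns)
  reff <- matrix(0, system$NC, Ns)
  for (j in seq_len(system$NC)) {
    # P is NE x Ns: binding probability of each enzyme at each substrate
    P <- exp(pmax(-params$sigma * abs(outer(params$L[, j], k, "-")),
                  log(1e-300)))
    w <- params$activity[, j] * params$R[, j]
    reff[j, ] <- as.vector(crossprod(P, w))
  }
  reff[, Ns] <- 0
  reff
}

new_steady_state <- function(conc, system, params) {
  NC <- nrow(conc)
  displayed <- glycan_profile(params$mu[NC] * conc[NC, ] / system$q)
  structure(
    list(conc = conc, displayed = displayed, system = system, params = params),
    class = "golgi_steady_state"
  )
}

#' @export
print.golgi_steady_state <- function(x, ...) {
  cat("<golgi_steady_state> NC =", nrow(x$conc), " Ns =", ncol(x$conc), "\n")
  cat("  exit flux:", sum(x$params$mu[nrow(x$conc)] * x$conc[nrow(x$conc), ]),
      " (injection q =", x$system$q, ")\n")
  invisible(x)
}

#' Steady state of the linear effective-rate model
#'
#' Solves the cisternal balance equations exactly by forward substitution.
#' With reaction flux `phi(j, k) = Reff(j, k) * c_k^(j)`, species `k` in
#' cisterna `j` satisfies
#' `influx_k + phi(j, k - 1) - phi(j, k) - mu_j * c_k^(j) = 0`,
#' where the influx is the injection `q` (only species 1, cisterna 1) or the
#' transfer `mu_{j-1} * c_k^(j-1)` from the upstream cisterna. The system is
#' strictly lower triangular, so a single sweep over `j` and `k` is exact.
#' The displayed distribution is the normalized exit flux,
#' `cbar_k = mu_NC * c_k^(NC) / q`.
#'
#' @param system A [golgi_system()].
#' @param params A [parameter_set()].
#' @return A `golgi_steady_state` with fields `conc` (an `NC x Ns` matrix)
#'   and `displayed` (a normalized [glycan_profile()]).
#' @examples
#' sys <- golgi_system(NC = 1, NE = 1, Ns = 30)
#' par <- parameter_set(mu = 1, R = matrix(1), L = matrix(1), sigma = 0)
#' ss <- steady_state_linear(sys, par)
#' head(ss$displayed) # geometric: 1/2, 1/4, 1/8, ...
#' @export
steady_state_linear <- function(system, params) {
  if (any(params$mu <= 0)) abort("all transfer rates `mu` must be positive.")
  reff <- effective_rates(system, params)
  conc <- chain_steady_state_cpp(system$q, params$mu, reff)
  new_steady_state(conc, system, params)
}

# MM per-species rate vector given enzyme occupancies S (length NE):
#   rate_k = sum_a V_a P(k, a) / (M_a + S_a),  S_a = sum_k P(k, a) c_k
mm_rates <- function(P, V, M, S) {
  as.vector(crossprod(P, V / (M + S)))
}

solve_cisterna_mm <- function(influx, P, V, M, mu_j, damping = 0.5,
                              tol = 1e-10, max_iter = 1e5) {
  Ns <- length(influx)
  S <- rep(0, length(V))
  conc <- rep(0, Ns)
  for (it in seq_len(max_iter)) {
    rate <- mm_rates(P, V, M, S)
    rate[Ns] <- 0
    conc <- cisterna_steady_state_cpp(influx, rate, mu_j)
    S_new <- as.vector(P %*% conc)
    res <- max(abs(S_new - S) / (1 + abs(S_new)))
    S <- damping * S + (1 - damping) * S_new
    if (res < tol) {
      return(list(conc = conc, converged = TRUE, iterations = it, residual = res))
    }
  }
  list(conc = conc, converged = FALSE, iterations = max_iter, residual = res)
}

solve_cisterna_ode <- function(influx, P, V, M, mu_j, t_end = 1e6) {
  Ns <- length(influx)
  deriv <- function(t, conc, parms) {
    S <- as.vector(P %*% conc)
    rate <- mm_rates(P, V, M, S)
    rate[Ns] <- 0
    phi <- rate * conc
    list(influx + c(0, phi[-Ns]) - phi - mu_j * conc)
  }
  sol <- deSolve::ode(y = rep(0, Ns), times = c(0, t_end), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  as.numeric(sol[nrow(sol), -1])
}

#' Steady state of the full Michaelis--Menten model
#'
#' Computes the steady state of the saturable kinetics, where the flux
#' `k -> k + 1` in cisterna `j` is
#' `sum_a V[a,j] P(k,a) c_k / (M[a,j] + sum_k' P(k',a) c_k')`:
#' enzymes are shared across all substrates they bind, so each substrate
#' competes for enzyme through the occupancy term in the denominator.
#' Cisternae are solved in order (the chain is feed-forward); within a
#' cisterna the enzyme occupancies are found by damped fixed-point iteration
#' (damping 0.5, residual below `tol`), falling back to stiff ODE
#' integration if the iteration fails to converge.
#'
#' @param system A [golgi_system()].
#' @param params An [mm_parameter_set()].
#' @param tol Fixed-point residual tolerance.
#' @param max_iter Maximum fixed-point iterations per cisterna.
#' @return A `golgi_steady_state`.
#' @export
steady_state_mm <- function(system, params, tol = 1e-10, max_iter = 1e5) {
  stopifnot(inherits(system, "golgi_system"),
            inherits(params, "mm_parameter_set"))
  if (length(params$mu) != system$NC || nrow(params$M) != system$NE) {
    abort("parameter dimensions do not match the system.")
  }
  NC <- system$NC; Ns <- system$Ns
  k <- seq_len(Ns)
  conc <- matrix(0, NC, Ns)
  influx <- c(system$q, rep(0, Ns - 1))
  for (j in seq_len(NC)) {
    P <- exp(pmax(-params$sigma * abs(outer(params$L[, j], k, "-")),
                  log(1e-300)))
    fp <- solve_cisterna_mm(influx, P, params$V[, j], params$M[, j],
                            params$mu[j], tol = tol, max_iter = max_iter)
    if (!fp$converged) {
      cj <- solve_cisterna_ode(influx, P, params$V[, j], params$M[, j],
                               params$mu[j])
      # verify the ODE end state against the balance equations
      S <- as.vector(P %*% cj)
      rate <- mm_rates(P, params$V[, j], params$M[, j], S)
      rate[Ns] <- 0
      phi <- rate * cj
      res <- max(abs(influx + c(0, phi[-Ns]) - phi - params$mu[j] * cj)) /
        system$q
      if (res > 1e-6) {
        abort(sprintf(
          "MM steady state failed to converge in cisterna %d (residual %.3g).",
          j, res))
      }
      conc[j, ] <- cj
    } else {
      conc[j, ] <- fp$conc
    }
    influx <- params$mu[j] * conc[j, ]
  }
  displayed <- glycan_profile(params$mu[NC] * conc[NC, ] / system$q)
  structure(
    list(conc = conc, displayed = displayed, system = system, params = params),
    class = "golgi_steady_state"
  )
}

#' Displayed distribution of a steady state
#'
#' @param state A `golgi_steady_state`.
#' @return The normalized displayed [glycan_profile()].
#' @export
displayed_profile <- function(state) {
  stopifnot(inherits(state, "golgi_steady_state"))
  state$displayed
}

#' @method tidy golgi_steady_state
#' @export
tidy.golgi_steady_state <- function(x, ...) {
  tibble::tibble(
    cisterna = rep(seq_len(nrow(x$conc)), ncol(x$conc)),
    index = rep(seq_len(ncol(x$conc)), each = nrow(x$conc)),
    concentration = as.vector(x$conc)
  )
}

#' @method glance golgi_steady_state
#' @export
glance.golgi_steady_state <- function(x, ...) {
  NC <- nrow(x$conc)
  exit_flux <- sum(x$params$mu[NC] * x$conc[NC, ])
  tibble::tibble(
    NC = NC, Ns = ncol(x$conc), q = x$system$q,
    exit_flux = exit_flux,
    flux_rel_error = abs(exit_flux - x$system$q) / x$system$q,
    mean_displayed_index = sum(x$displayed$index * x$displayed$abundance)
  )
}

#' @method autoplot golgi_steady_state
#' @export
autoplot.golgi_steady_state <- function(object, ...) {
  autoplot(object$displayed) +
    ggplot2::labs(y = "displayed abundance")
}
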