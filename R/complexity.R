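# Weighted EM for Gaussian mixtures on the discrete glycan index grid.
# The data are the support points k = 1..Ns weighted by the profile
# abundances p_k (not resampled pseudo-counts), so the fit is deterministic
# given the seed and directly targets the divergence that is reported:
# D(profile || discretized mixture).

gmm_discretize <- function(weights, means, sds, Ns) {
  k <- seq_len(Ns)
  dens <- rep(0, Ns)
  for (i in seq_along(weights)) {
    dens <- dens + weights[i] * dnorm(k, means[i], sds[i])
  }
  dens <- pmax(dens, 1e-300)
  dens / sum(dens)
}

# uses the same probability floor as kl_divergence() so the value reported
# by a fit equals the generic divergence of its discretized profile
gmm_kl <- function(pv, weights, means, sds, floor = 1e-12) {
  q <- gmm_discretize(weights, means, sds, length(pv))
  q <- pmax(q, floor)
  q <- q / sum(q)
  pos <- pv > 0
  max(sum(pv[pos] * (log(pv[pos]) - log(q[pos]))), 0)
}

# one EM run from a given initialization; returns parameters and the
# discretized KL of the best iterate seen
gmm_em <- function(pv, weights, means, sds, sd_floor = 0.5,
                   max_iter = 500, tol = 1e-10) {
  Ns <- length(pv)
  k <- seq_len(Ns)
  m <- length(weights)
  best <- list(weights = weights, means = means, sds = sds,
               kl = gmm_kl(pv, weights, means, sds))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step: responsibilities at each support point
    dens <- vapply(seq_len(m), function(i) {
      weights[i] * dnorm(k, means[i], sds[i])
    }, numeric(Ns))
    dens <- as.matrix(dens)
    tot <- rowSums(dens)
    tot[tot <= 0] <- 1e-300
    resp <- dens / tot
    # M-step with abundance weights
    Nm <- as.vector(crossprod(resp, pv))
    Nm[Nm <= 0] <- 1e-300
    weights <- Nm / sum(Nm)
    means <- as.vector(crossprod(resp, pv * k)) / Nm
    for (i in seq_len(m)) {
      v <- sum(resp[, i] * pv * (k - means[i])^2) / Nm[i]
      sds[i] <- max(sqrt(v), sd_floor)
    }
    ll <- sum(pv[pv > 0] * log(tot[pv > 0]))
    kl <- gmm_kl(pv, weights, means, sds)
    if (kl < best$kl) {
      best <- list(weights = weights, means = means, sds = sds, kl = kl)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  best
}

gmm_init_quantile <- function(pv, m, jitter = 0) {
  Ns <- length(pv)
  cdf <- cumsum(pv)
  probs <- (seq_len(m) - 0.5) / m
  means <- vapply(probs, function(p) as.numeric(which(cdf >= p)[1]), numeric(1))
  means <- means + jitter
  means <- pmin(pmax(means, 1), Ns)
  sds <- rep(max(Ns / (2 * m), 0.5), m)
  list(weights = rep(1 / m, m), means = means, sds = sds)
}

new_glycan_gmm <- function(m, fit, pv) {
  structure(
    list(m = m, weights = fit$weights, means = fit$means, sds = fit$sds,
         discretized = glycan_profile(gmm_discretize(fit$weights, fit$means,
                                                     fit$sds, length(pv))),
         kl = fit$kl, profile = glycan_profile(pv)),
    class = "glycan_gmm"
  )
}

#' Fit an m-component Gaussian mixture to a glycan profile
#'
#' Denoises a discrete glycan profile by a weighted EM fit of an
#' m-component Gaussian mixture on the support points `k = 1..Ns`, the
#' point weights being the profile abundances. The reported divergence is
#' `D(profile || discretized mixture)` with the mixture density evaluated
#' at the integer indices and renormalized -- exactly the quantity whose
#' saturation defines profile complexity. The best of `restarts` seeded
#' initializations is returned (one quantile-spaced start plus random
#' starts with abundance-weighted or spatially uniform means); component
#' sds are floored at 0.5 index units so components cannot collapse onto
#' single indices.
#'
#' @param profile Normalized [glycan_profile()].
#' @param m Number of mixture components.
#' @param restarts Number of jittered EM restarts.
#' @param seed Integer seed.
#' @param sd_floor Lower bound on component sds, in index units.
#' @return A `glycan_gmm` with fields `m`, `weights`, `means`, `sds`,
#'   `discretized` (the fitted profile) and `kl`.
#' @export
fit_gmm <- function(profile, m, restarts = 10, seed = 1, sd_floor = 0.5) {
  pv <- profile_vec(profile)
  assert_normalized(pv, "profile")
  if (m < 1 || m != round(m)) abort("`m` must be a positive integer.")
  n_support <- sum(pv > 0)
  if (m > n_support) {
    abort(sprintf("m = %d exceeds the %d support points with positive mass.",
                  m, n_support))
  }
  Ns <- length(pv)
  inits <- with_seed(seed, {
    out <- list(gmm_init_quantile(pv, m))
    sd0 <- max(Ns / (2 * m), 0.5)
    for (r in seq_len(max(restarts - 1, 0))) {
      # alternate abundance-weighted and spatially uniform mean draws
      means <- if (r %% 2 == 0) {
        sort(sample(seq_len(Ns), m, prob = pv + 1e-12))
      } else {
        sort(runif(m, 1, Ns))
      }
      out[[r + 1]] <- list(weights = rep(1 / m, m), means = means,
                           sds = rep(sd0, m))
    }
    out
  })
  best <- NULL
  for (init in inits) {
    fit <- gmm_em(pv, init$weights, init$means, init$sds, sd_floor = sd_floor)
    if (is.null(best) || fit$kl < best$kl) best <- fit
  }
  new_glycan_gmm(m, best, pv)
}

#' @export
print.glycan_gmm <- function(x, ...) {
  cat("<glycan_gmm> m =", x$m, " KL =", signif(x$kl, 4), "\n")
  invisible(x)
}

#' @method tidy glycan_gmm
#' @export
tidy.glycan_gmm <- function(x, ...) {
  tibble::tibble(component = seq_len(x$m), weight = x$weights,
                 mean = x$means, sd = x$sds)
}

#' @method glance glycan_gmm
#' @export
glance.glycan_gmm <- function(x, ...) {
  tibble::tibble(m = x$m, kl = x$kl)
}

#' @method autoplot glycan_gmm
#' @export
autoplot.glycan_gmm <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$profile, what = "profile"),
    dplyr::mutate(object$discretized, what = "GMM fit")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$abundance,
                                   color = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "glycan index k", y = "abundance", color = NULL) +
    ggplot2::theme_minimal()
}

#' KL curve over the number of mixture components
#'
#' Fits mixtures with `m = 1..m_max` components and records the divergence
#' `D(profile || GMM(m))` at each `m`. Each `m` is additionally warm-started
#' from the previous solution: the previous mixture with the heaviest
#' component split in two, and the previous mixture itself padded with a
#' zero-weight component (whose divergence is exactly the previous value),
#' so the curve is nonincreasing by construction.
#'
#' @inheritParams fit_gmm
#' @param m_max Largest number of components to fit.
#' @return A `complexity_curve` tibble with columns `m`, `kl`.
#' @export
kl_curve <- function(profile, m_max, restarts = 10, seed = 1, sd_floor = 0.5) {
  pv <- profile_vec(profile)
  assert_normalized(pv, "profile")
  if (m_max < 1) abort("`m_max` must be at least 1.")
  Ns <- length(pv)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, m_max))
  fits <- vector("list", m_max)
  prev <- NULL
  for (m in seq_len(m_max)) {
    # candidate initializations: quantile-spaced, seeded random draws, and
    # greedy splits of each component of the previous solution
    inits <- with_seed(seeds[m], {
      out <- list(gmm_init_quantile(pv, m))
      sd0 <- max(Ns / (2 * m), 0.5)
      for (r in seq_len(max(restarts - 1, 0))) {
        means <- if (r %% 2 == 0) {
          sort(sample(seq_len(Ns), m, prob = pv + 1e-12))
        } else {
          sort(runif(m, 1, Ns))
        }
        out[[length(out) + 1]] <- list(weights = rep(1 / m, m),
                                       means = means, sds = rep(sd0, m))
      }
      out
    })
    if (!is.null(prev)) {
      # residual-guided splits: rank components by their share of the
      # remaining divergence and split the worst-fitting ones; also place a
      # fresh narrow component at the single worst-fit index
      q <- gmm_discretize(prev$weights, prev$means, prev$sds, Ns)
      resid <- ifelse(pv > 0, pv * pmax(log(pv) - log(q), 0), 0)
      k_idx <- seq_len(Ns)
      assign_comp <- vapply(k_idx, function(k) {
        which.max(vapply(seq_along(prev$weights), function(i) {
          prev$weights[i] * dnorm(k, prev$means[i], prev$sds[i])
        }, numeric(1)))
      }, integer(1))
      comp_resid <- vapply(seq_along(prev$weights), function(i) {
        sum(resid[assign_comp == i])
      }, numeric(1))
      for (i in utils::head(order(-comp_resid), 3)) {
        w <- prev$weights; mu <- prev$means; s <- prev$sds
        inits[[length(inits) + 1]] <- list(
          weights = c(w[-i], w[i] / 2, w[i] / 2),
          means = c(mu[-i], mu[i] - s[i] / 2, mu[i] + s[i] / 2),
          sds = c(s[-i], s[i], s[i]))
      }
      k_worst <- which.max(resid)
      inits[[length(inits) + 1]] <- list(
        weights = c(prev$weights * (1 - 0.05), 0.05),
        means = c(prev$means, k_worst),
        sds = c(prev$sds, max(1, sd_floor)))
    }
    cand <- NULL
    for (ini in inits) {
      full <- gmm_em(pv, ini$weights, ini$means, ini$sds,
                     sd_floor = sd_floor)
      if (is.null(cand) || full$kl < cand$kl) cand <- full
    }
    if (!is.null(prev)) {
      # zero-weight padding: identical density, hence identical divergence
      pad <- list(weights = c(prev$weights, 0),
                  means = c(prev$means, prev$means[1]),
                  sds = c(prev$sds, prev$sds[1]), kl = prev$kl)
      if (pad$kl < cand$kl) cand <- pad
    }
    fits[[m]] <- cand
    prev <- cand
  }
  out <- tibble::tibble(m = seq_len(m_max),
                        kl = vapply(fits, function(f) f$kl, numeric(1)))
  class(out) <- c("complexity_curve", class(out))
  attr(out, "fits") <- fits
  attr(out, "profile") <- glycan_profile(pv)
  out
}

#' Call the complexity of a glycan profile
#'
#' The complexity `m_star` of a profile is the number of mixture components
#' at which the KL curve saturates. Two clauses, in order of precedence:
#' the smallest `m` with `kl[m] <= abs_tol` (the mixture reproduces the
#' profile essentially exactly, the signature of a noise-free profile of
#' true complexity `m`); otherwise the smallest `m` such that
#' `kl[m] - kl[m + w] < tol * kl[1]` for all `w = 1..window` (the curve has
#' flattened onto its noise plateau). If the curve never saturates before
#' `m_max`, `m_max` is returned with `saturated = FALSE`.
#'
#' @param curve A `complexity_curve` from [kl_curve()], or a normalized
#'   profile (in which case the curve is computed first).
#' @param tol Relative flattening tolerance (fraction of `kl[1]`).
#' @param window Number of consecutive components the curve must stay flat.
#' @param abs_tol Divergence below which a fit counts as exact.
#' @param ... Passed to [kl_curve()] when `curve` is a profile
#'   (`m_max`, `restarts`, `seed`).
#' @return A `complexity_call` list with `m_star`, `saturated`, `curve`,
#'   `tol`, `window`.
#' @export
call_complexity <- function(curve, tol = 0.01, window = 2, abs_tol = 1e-3,
                            ...) {
  if (!inherits(curve, "complexity_curve")) {
    curve <- kl_curve(curve, ...)
  }
  kl <- curve$kl
  m_max <- length(kl)
  if (m_max < 1 + window) {
    abort("curve must extend at least `window` components past m = 1.")
  }
  thr <- tol * kl[1] + 1e-12 # absolute floor guards exactly-zero curves
  m_star <- NA_integer_
  exact <- which(kl <= abs_tol)
  if (length(exact) > 0 && exact[1] <= m_max - window) {
    m_star <- exact[1]
  } else {
    for (m in seq_len(m_max - window)) {
      if (all(kl[m] - kl[m + seq_len(window)] < thr)) {
        m_star <- m
        break
      }
    }
  }
  saturated <- !is.na(m_star)
  if (!saturated) m_star <- m_max
  structure(
    list(m_star = as.integer(m_star), saturated = saturated, curve = curve,
         tol = tol, window = window, abs_tol = abs_tol),
    class = "complexity_call"
  )
}

#' @export
print.complexity_call <- function(x, ...) {
  cat("<complexity_call> m* =", x$m_star,
      if (!x$saturated) "(no saturation before m_max)" else "", "\n")
  invisible(x)
}

#' @method glance complexity_call
#' @export
glance.complexity_call <- function(x, ...) {
  tibble::tibble(m_star = x$m_star, saturated = x$saturated,
                 tol = x$tol, window = x$window,
                 m_max = nrow(x$curve))
}

#' @method autoplot complexity_curve
#' @export
autoplot.complexity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$kl)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "GMM components m", y = "D(profile || GMM(m))") +
    ggplot2::theme_minimal()
}
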