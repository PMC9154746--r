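#' Discretized Gaussian-mixture target distribution
#'
#' Builds a target glycan profile by evaluating an m-component Gaussian
#' mixture density at the integer indices `k = 1..Ns` and renormalizing.
#' This is the synthetic stand-in for the coarse-grained (GMM-denoised)
#' MSMS targets used to drive the fidelity optimization.
#'
#' @param Ns Number of glycan indices.
#' @param components Data frame with columns `weight`, `mean`, `sd`
#'   (weights are renormalized to sum to 1; means should lie in `[1, Ns]`,
#'   sds be positive).
#' @return A normalized [glycan_profile()].
#' @examples
#' tgt <- make_gmm_target(100, data.frame(weight = 1, mean = 50, sd = 5))
#' which.max(tgt$abundance) # 50
#' @export
make_gmm_target <- function(Ns, components) {
  components <- tibble::as_tibble(components)
  if (nrow(components) == 0) abort("`components` must have at least one row.")
  if (!all(c("weight", "mean", "sd") %in% names(components))) {
    abort("`components` needs columns weight, mean, sd.")
  }
  if (any(components$sd <= 0)) abort("component sds must be positive.")
  if (any(components$weight < 0) || sum(components$weight) <= 0) {
    abort("component weights must be nonnegative with positive sum.")
  }
  w <- components$weight / sum(components$weight)
  k <- seq_len(Ns)
  dens <- vapply(seq_along(w), function(i) {
    w[i] * dnorm(k, components$mean[i], components$sd[i])
  }, numeric(Ns))
  glycan_profile(rowSums(as.matrix(dens)), normalize = TRUE)
}

#' Draw random mixture components for a synthetic target
#'
#' Emulates the denoised MSMS targets of a given complexity: `m` component
#' means quantile-spaced across the index range with jitter, sds drawn
#' uniformly in `sd_range`, and random weights mixing a Dirichlet(1) draw
#' with the uniform share so every component carries at least
#' `min_frac / m` of the mass -- a peak far lighter than that is not
#' resolvable and would make the component count ill-posed. Deterministic
#' given `seed`.
#'
#' @param Ns Number of glycan indices.
#' @param m Number of mixture components.
#' @param seed Integer seed.
#' @param sd_range Range the component sds are drawn from, in index units.
#' @param jitter_frac Jitter of the means as a fraction of the component
#'   spacing.
#' @param min_frac Guaranteed fraction of the equal share `1/m` per
#'   component.
#' @return A tibble with columns `weight`, `mean`, `sd`.
#' @export
sample_gmm_components <- function(Ns, m, seed, sd_range = c(2, 6),
                                  jitter_frac = 0.2, min_frac = 0.2) {
  stopifnot(m >= 1, Ns >= 2, min_frac >= 0, min_frac <= 1)
  with_seed(seed, {
    spacing <- Ns / (m + 1)
    means <- spacing * seq_len(m) +
      runif(m, -jitter_frac * spacing, jitter_frac * spacing)
    means <- pmin(pmax(means, 1), Ns)
    sds <- runif(m, sd_range[1], sd_range[2])
    w <- -log(runif(m)) # Dirichlet(1) via normalized exponentials
    w <- (1 - min_frac) * w / sum(w) + min_frac / m
    tibble::tibble(weight = w, mean = means, sd = sds)
  })
}

#' Delta-function target
#'
#' All probability mass on a single glycan index `M`; the classic target for
#' which high fidelity requires as many highly specific enzymes as reaction
#' steps and multiple cisternae.
#'
#' @param Ns Number of glycan indices.
#' @param M Index carrying all the mass.
#' @return A normalized [glycan_profile()] with zero entropy.
#' @export
make_delta_target <- function(Ns, M) {
  if (!(M %in% seq_len(Ns))) abort("`M` must be an index in 1..Ns.")
  v <- rep(0, Ns)
  v[M] <- 1
  glycan_profile(v)
}

#' MSMS-like noisy raw profile
#'
#' Emulates a raw mass-spectrometry profile: Poisson counting noise on top
#' of the target signal, plus a uniform chemical-noise baseline. Counts at
#' index `k` are `Poisson(total_counts * ((1 - baseline) * target_k +
#' baseline / Ns))`. The result is an unnormalized count profile.
#'
#' @param target A normalized [glycan_profile()].
#' @param total_counts Total expected ion count (Poisson intensity scale).
#' @param baseline Uniform chemical-noise fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `glycan_profile` of raw counts (unnormalized); if all counts
#'   are zero the attribute `unnormalizable` is set.
#' @export
make_msms_like <- function(target, total_counts, baseline = 0, seed = 1) {
  v <- profile_vec(target)
  assert_normalized(v, "target")
  if (baseline < 0 || baseline >= 1) abort("`baseline` must be in [0, 1).")
  if (total_counts < 0) abort("`total_counts` must be nonnegative.")
  Ns <- length(v)
  lambda <- total_counts * ((1 - baseline) * v + baseline / Ns)
  counts <- with_seed(seed, rpois(Ns, lambda))
  out <- glycan_profile(counts)
  if (sum(counts) == 0) attr(out, "unnormalizable") <- TRUE
  out
}

#' Parameter-recovery fixture
#'
#' Draws an in-bounds random parameter set (log-uniform `mu` and `R`,
#' uniform `L`, the given `sigma`) and returns it together with the
#' displayed distribution it produces, for use as a self-consistent
#' optimization target: the generating parameters attain fidelity zero by
#' construction.
#'
#' Degenerate draws whose displayed distribution is a near-delta (transfer
#' much faster than reaction, so virtually nothing reacts) are rejected and
#' redrawn: the entropy-normalized fidelity is undefined in the delta limit,
#' so such targets cannot serve as recovery fixtures.
#'
#' @param system A [golgi_system()].
#' @param sigma Specificity used for the draw.
#' @param seed Integer seed.
#' @param min_entropy Smallest acceptable target entropy in nats.
#' @return A list with elements `params` (a [parameter_set()]) and `target`
#'   (the displayed [glycan_profile()]).
#' @export
make_recovery_fixture <- function(system, sigma, seed, min_entropy = 0.5) {
  for (i in 0:99) {
    params <- with_seed(seed + i * 7919, draw_params(system, sigma))
    target <- displayed_profile(steady_state_linear(system, params))
    if (profile_entropy(target) >= min_entropy) {
      return(list(params = params, target = target))
    }
  }
  abort("could not draw a recovery fixture with non-degenerate target entropy.")
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single integer.")
  }
  had_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
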