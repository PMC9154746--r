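#' Shannon entropy of a glycan profile
#'
#' `H(p) = sum_k p_k ln(1 / p_k)` in nats, with `0 ln(1/0) := 0`. The
#' entropy of the target distribution is the denominator of the normalized
#' fidelity, which makes fidelities comparable across targets of different
#' complexity.
#'
#' @param p A normalized [glycan_profile()] (or numeric probability vector).
#' @return Entropy in nats.
#' @export
profile_entropy <- function(p) {
  v <- profile_vec(p)
  assert_normalized(v, "p")
  pos <- v > 0
  -sum(v[pos] * log(v[pos]))
}

#' Kullback--Leibler divergence between two profiles
#'
#' `D(p || q) = sum_{k: p_k > 0} p_k ln(p_k / q_k)` in nats, over aligned
#' indices `1..Ns`. The second argument is floored at `1e-12` and
#' renormalized before evaluation: with any finite specificity every species
#' has strictly positive displayed probability in exact arithmetic, so the
#' floor only guards floating-point underflow and keeps the divergence
#' finite.
#'
#' @param p,q Normalized profiles on the same index range.
#' @param floor Floor applied to `q` before renormalization.
#' @return Nonnegative divergence in nats; zero iff `p = q` on `p`'s support.
#' @export
kl_divergence <- function(p, q, floor = 1e-12) {
  pv <- profile_vec(p)
  qv <- profile_vec(q)
  if (length(pv) != length(qv)) abort("profiles must share the index range 1..Ns.")
  assert_normalized(pv, "p")
  assert_normalized(qv, "q")
  qv <- pmax(qv, floor)
  qv <- qv / sum(qv)
  pos <- pv > 0
  # clamp -1e-17-scale rounding when p = q; KL is nonnegative exactly
  max(sum(pv[pos] * (log(pv[pos]) - log(qv[pos]))), 0)
}

#' Normalized-KL fidelity of a displayed distribution
#'
#' The fidelity of the synthesis machinery is
#' `F(target || displayed) = D(target || displayed) / H(target)`:
#' the KL divergence from the target to the displayed distribution,
#' normalized by the target entropy. High fidelity corresponds to low `F`.
#' A delta (zero-entropy) target makes the ratio undefined; for such targets
#' work with the raw [kl_divergence()] instead.
#'
#' @param target,displayed Normalized profiles on the same index range.
#' @return A one-row tibble with columns `kl`, `entropy`, `F`.
#' @examples
#' target <- glycan_profile(rep(1 / 4, 4))
#' shown <- glycan_profile(c(1 / 2, 1 / 4, 1 / 8, 1 / 8))
#' fidelity(target, shown) # F = 1/8
#' @export
fidelity <- function(target, displayed) {
  H <- profile_entropy(target)
  if (H <= 0) {
    abort(paste0("target has zero entropy (delta distribution): the ",
                 "normalized fidelity is undefined; use kl_divergence()."))
  }
  kl <- kl_divergence(target, displayed)
  tibble::tibble(kl = kl, entropy = H, F = kl / H)
}

# scalar fast path used inside optimization loops
fidelity_value <- function(target_vec, displayed_vec, H, floor = 1e-12) {
  qv <- pmax(displayed_vec, floor)
  qv <- qv / sum(qv)
  pos <- target_vec > 0
  sum(target_vec[pos] * (log(target_vec[pos]) - log(qv[pos]))) / H
}

#' Sigmoid-smoothed glycan diversity
#'
#' Diversity is the number of glycan species displayed above a threshold
#' abundance `c_th`, smoothed with the sigmoid
#' `(1 + exp(-Ns * (c_i - c_th)))^(-1)` (a differentiable approximation of
#' the step function, sharpness `1/tau = Ns`) so it can be optimized by
#' gradient methods. The default threshold is `c_th = 1/Ns`; species below
#' it would not be distinguishable from noise.
#'
#' @param c A normalized profile.
#' @param c_th Positive abundance threshold (default `1/Ns`).
#' @return A one-row tibble with columns `value` (in `[0, Ns]`), `threshold`,
#'   `tau_inverse`.
#' @examples
#' diversity(glycan_profile(rep(1 / 50, 50))) # exactly Ns/2 = 25
#' @export
diversity <- function(c, c_th = NULL) {
  v <- profile_vec(c)
  assert_normalized(v, "c")
  Ns <- length(v)
  if (is.null(c_th)) c_th <- 1 / Ns
  if (!is.numeric(c_th) || length(c_th) != 1 || c_th <= 0) {
    abort("`c_th` must be a positive scalar.")
  }
  tibble::tibble(value = diversity_value(v, c_th, Ns),
                 threshold = c_th, tau_inverse = Ns)
}

diversity_value <- function(v, c_th, Ns) {
  sum(1 / (1 + exp(-Ns * (v - c_th))))
}
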