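# Geometry of the fidelity landscape around an optimum: finite-difference
# Hessian over the full coordinate vector (mu, R, L, sigma), eigenvalue
# spectrum, stiff/sloppy grouping, and degeneracy probing.

#' Hessian of the fidelity at a parameter set
#'
#' Computes the central finite-difference Hessian of the fidelity over the
#' full `NC + 2*NE*NC + 1` coordinate vector `(mu, R, L, sigma)`, in
#' box-normalized coordinates (log scale for `mu` and `R`, linear for `L`,
#' `sigma` scaled by `sigma_max`) so that eigenvalues are comparable across
#' parameter blocks whose physical scales span decades. The matrix is
#' symmetrized as `(H + t(H))/2` and eigen-decomposed; each eigenvector is
#' assigned to the block (`mu`, `R`, `L` or `sigma`) of its largest
#' absolute component, and the per-block stiffness is the log of the mean
#' (nonnegative-clipped) eigenvalue of the block. Stencil points that would
#' leave the unit box are handled by shifting the differencing center onto
#' the box face (a one-sided evaluation).
#'
#' @param system A [golgi_system()] (may be `NULL` when `objective` is given).
#' @param target Normalized target profile (ignored when `objective` given).
#' @param params A [parameter_set()] including `sigma`, normally an optimum
#'   from [optimize_fidelity()].
#' @param step Finite-difference step in normalized coordinates.
#' @param sigma_max Upper edge of the `sigma` coordinate box.
#' @param objective Optional test hook: a function of the normalized
#'   coordinate vector replacing the fidelity.
#' @param x0 Center point in normalized coordinates (required with
#'   `objective` when `params` is absent).
#' @return A `hessian_analysis` with fields `dim`, `hessian`, `eigenvalues`
#'   (nonincreasing), `eigenvectors` (orthonormal columns), `groups`,
#'   `group_stiffness`, `total_stiffness`.
#' @export
hessian_at <- function(system = NULL, target = NULL, params = NULL,
                       step = 1e-3, sigma_max = 10, objective = NULL,
                       x0 = NULL) {
  if (is.null(objective)) {
    stopifnot(inherits(system, "golgi_system"), inherits(params, "parameter_set"))
    tv <- profile_vec(target)
    assert_normalized(tv, "target")
    H_t <- profile_entropy(tv)
    if (H_t <= 0) abort("target has zero entropy; fidelity is undefined.")
    sigma_max <- max(sigma_max, 2 * params$sigma)
    activity <- params$activity
    objective <- function(x) {
      p <- unpack_params(system, x, sigma = NULL, activity = activity,
                         sigma_max = sigma_max)
      ss <- steady_state_linear(system, p)
      fidelity_value(tv, ss$displayed$abundance, H_t)
    }
    x0 <- pack_params(system, params, include_sigma = TRUE,
                      sigma_max = sigma_max)
  } else if (is.null(x0)) {
    abort("`x0` must be supplied together with `objective`.")
  }
  d <- length(x0)
  # keep every stencil point inside [0, 1]: shift centers on the box faces
  xc <- pmin(pmax(x0, step), 1 - step)
  f0 <- objective(xc)
  H <- matrix(0, d, d)
  fp <- fm <- numeric(d)
  for (i in seq_len(d)) {
    xp <- xc; xp[i] <- xc[i] + step
    xm <- xc; xm[i] <- xc[i] - step
    fp[i] <- objective(xp)
    fm[i] <- objective(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / step^2
  }
  if (d > 1) {
    for (i in seq_len(d - 1)) {
      for (j in (i + 1):d) {
        xpp <- xc; xpp[i] <- xc[i] + step; xpp[j] <- xc[j] + step
        xpm <- xc; xpm[i] <- xc[i] + step; xpm[j] <- xc[j] - step
        xmp <- xc; xmp[i] <- xc[i] - step; xmp[j] <- xc[j] + step
        xmm <- xc; xmm[i] <- xc[i] - step; xmm[j] <- xc[j] - step
        H[i, j] <- H[j, i] <-
          (objective(xpp) - objective(xpm) - objective(xmp) +
             objective(xmm)) / (4 * step^2)
      }
    }
  }
  H <- (H + t(H)) / 2
  eig <- eigen(H, symmetric = TRUE)
  groups <- if (!is.null(system)) {
    blocks <- c(rep("mu", system$NC), rep("R", system$NE * system$NC),
                rep("L", system$NE * system$NC), "sigma")
    apply(abs(eig$vectors), 2, function(v) blocks[which.max(v)])
  } else {
    rep("x", d)
  }
  lam_clip <- pmax(eig$values, 0)
  group_stiffness <- vapply(
    unique(groups),
    function(g) log(max(mean(lam_clip[groups == g]), 1e-12)),
    numeric(1)
  )
  structure(
    list(dim = d, hessian = H, eigenvalues = eig$values,
         eigenvectors = eig$vectors, groups = groups,
         group_stiffness = group_stiffness,
         total_stiffness = log(max(mean(lam_clip), 1e-12)),
         step = step, x0 = x0, sigma_max = sigma_max),
    class = "hessian_analysis"
  )
}

#' @export
print.hessian_analysis <- function(x, ...) {
  cat("<hessian_analysis> dim =", x$dim,
      " total stiffness =", signif(x$total_stiffness, 4), "\n")
  if (length(x$group_stiffness) > 1) {
    cat("  group stiffness:",
        paste(names(x$group_stiffness), signif(x$group_stiffness, 3),
              sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' @method tidy hessian_analysis
#' @export
tidy.hessian_analysis <- function(x, ...) {
  tibble::tibble(rank = seq_len(x$dim), eigenvalue = x$eigenvalues,
                 group = x$groups)
}

#' @method glance hessian_analysis
#' @export
glance.hessian_analysis <- function(x, ...) {
  tibble::tibble(dim = x$dim, total_stiffness = x$total_stiffness,
                 max_eigenvalue = max(x$eigenvalues),
                 min_eigenvalue = min(x$eigenvalues))
}

#' @method autoplot hessian_analysis
#' @export
autoplot.hessian_analysis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = pmax(.data$eigenvalue, 1e-12))) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dominant parameter block", y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' Probe discrete and continuous degeneracies of an optimization result
#'
#' The fidelity landscape is typically rugged and degenerate: distinct
#' parameter combinations can synthesize the same displayed distribution.
#' This clusters the near-optimal multi-start endpoints (single-linkage on
#' box-normalized Euclidean distance) to count discrete degeneracies, and
#' counts near-zero Hessian eigenvalues as continuous flat directions.
#'
#' @param fit A `golgi_fit` from [optimize_fidelity()] or
#'   [maximize_diversity()].
#' @param cluster_radius Single-linkage merge radius in normalized
#'   coordinates.
#' @param hessian Optional [hessian_at()] result at the optimum.
#' @param flat_threshold Eigenvalues below this count as flat; default
#'   `1e-6 * max(eigenvalue)`.
#' @return A `degeneracy_report` with `n_clusters`, `fraction_near_best`,
#'   `n_flat_directions` (`NA` without a Hessian).
#' @export
probe_degeneracy <- function(fit, cluster_radius = 0.05, hessian = NULL,
                             flat_threshold = NULL) {
  stopifnot(inherits(fit, "golgi_fit"))
  ps <- fit$per_start
  ok <- !is.na(ps$value) & !vapply(ps$x, is.null, logical(1))
  if (!any(ok)) abort("no converged starts to probe.")
  vals <- ps$value[ok]
  best <- min(vals)
  near <- vals <= best + max(0.01, 0.05 * abs(best))
  xs <- do.call(rbind, ps$x[ok][near])
  n_clusters <- if (nrow(xs) == 1) {
    1L
  } else {
    max(cutree(hclust(dist(xs), method = "single"), h = cluster_radius))
  }
  n_flat <- NA_integer_
  if (!is.null(hessian)) {
    stopifnot(inherits(hessian, "hessian_analysis"))
    if (is.null(flat_threshold)) {
      flat_threshold <- 1e-6 * max(hessian$eigenvalues)
    }
    n_flat <- sum(hessian$eigenvalues < flat_threshold)
  }
  structure(
    list(n_clusters = as.integer(n_clusters),
         fraction_near_best = fit$fraction_near_best,
         n_flat_directions = n_flat,
         cluster_radius = cluster_radius, n_near_best = sum(near)),
    class = "degeneracy_report"
  )
}

#' @export
print.degeneracy_report <- function(x, ...) {
  cat("<degeneracy_report>", x$n_clusters, "cluster(s) among", x$n_near_best,
      "near-optimal start(s);", x$n_flat_directions, "flat direction(s)\n")
  invisible(x)
}

#' @method glance degeneracy_report
#' @export
glance.degeneracy_report <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters,
                 fraction_near_best = x$fraction_near_best,
                 n_flat_directions = x$n_flat_directions,
                 cluster_radius = x$cluster_radius)
}
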