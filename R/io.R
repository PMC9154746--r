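# Readers/writers and the reproducible pipeline runner.

#' Write a parameter set as JSON
#'
#' Matrices are stored row-wise (one row per enzyme); the system's boxes
#' are echoed under `bounds` so a file is self-describing.
#'
#' @param params A [parameter_set()].
#' @param path Output path.
#' @param system Optional [golgi_system()] whose bounds are echoed.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path, system = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  obj <- list(
    mu = params$mu,
    R = apply(params$R, 1, identity, simplify = FALSE),
    L = apply(params$L, 1, identity, simplify = FALSE),
    activity = apply(params$activity, 1, identity, simplify = FALSE),
    sigma = params$sigma
  )
  if (!is.null(system)) {
    obj$bounds <- list(mu = system$mu_bounds, R = system$R_bounds,
                       L = c(1, system$Ns))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path Path to a file written by [write_parameter_set()].
#' @return A [parameter_set()].
#' @export
read_parameter_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_row_matrix <- function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    as.matrix(x)
  }
  parameter_set(mu = as.numeric(obj$mu), R = as_row_matrix(obj$R),
                L = as_row_matrix(obj$L), sigma = as.numeric(obj$sigma),
                activity = if (!is.null(obj$activity)) {
                  as_row_matrix(obj$activity)
                } else NULL)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.ya?ml$", config)) {
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) abort("`config` must be a list or a JSON/YAML path.")
  known <- c("system", "seed", "stages", "target", "sigma", "sigma_grid",
             "optimizer", "complexity", "diversity", "hessian", "swap",
             "tradeoff")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(
    seed = 1,
    stages = c("simulate"),
    sigma = 1,
    sigma_grid = c(0, 0.5, 1, 2, 4),
    optimizer = list(n_starts = 8, maxit = 200),
    complexity = list(m_max = 10, restarts = 5, tol = 0.01, window = 2),
    diversity = list(c_th = NULL),
    hessian = list(step = 1e-3),
    swap = list(j1 = 2, j2 = 4),
    tradeoff = list(NE_range = NULL, NC_range = NULL)
  )
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$system)) abort("config must contain a `system` block.")
  cfg
}

config_target <- function(cfg, system) {
  tg <- cfg$target
  if (is.null(tg)) abort("this stage needs a `target` block in the config.")
  if (!is.null(tg$file)) {
    return(normalize_profile(read_glycan_profile(tg$file)))
  }
  if (!is.null(tg$delta)) {
    return(make_delta_target(system$Ns, tg$delta))
  }
  if (!is.null(tg$components)) {
    comp <- tibble::as_tibble(as.data.frame(tg$components))
    return(make_gmm_target(system$Ns, comp))
  }
  if (!is.null(tg$m)) {
    comp <- sample_gmm_components(system$Ns, tg$m,
                                  seed = tg$seed %||% cfg$seed,
                                  sd_range = tg$sd_range %||% c(2, 6))
    return(make_gmm_target(system$Ns, comp))
  }
  abort("`target` block needs one of: file, delta, components, m.")
}

write_tsv_plain <- function(df, path) {
  readr::write_tsv(dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric), ~ formatC(.x, format = "g", digits = 17))), path)
  invisible(path)
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages against one configuration and writes all
#' outputs (TSV for vectors and tables, JSON for structured results) plus a
#' manifest and a log into `out_dir`. Reruns with an identical config and
#' seed produce byte-identical numerical outputs. Stage failures are
#' recorded in the log; stages depending on a failed stage are skipped.
#'
#' Supported stages: `simulate` (draw parameters, write the steady state),
#' `optimize`, `scan_sigma`, `tradeoff`, `complexity`, `diversity`,
#' `landscape` (Hessian at the optimize stage's optimum), `swap` (exchange
#' two cisternae of the optimum and report the KL shift of the displayed
#' distribution).
#'
#' @param config A list, or path to a JSON/YAML file, with blocks `system`
#'   (NC, NE, Ns, q, bounds), `stages`, `seed`, `target`, `sigma`,
#'   `sigma_grid`, `optimizer` (n_starts, maxit), `complexity`, `diversity`,
#'   `hessian`, `swap`, `tradeoff`. Unknown keys are rejected.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `manifest` (output files) and `status`
#'   (per-stage success flags).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sys_args <- cfg$system
  system <- golgi_system(
    NC = sys_args$NC, NE = sys_args$NE, Ns = sys_args$Ns %||% 200,
    q = sys_args$q %||% 1,
    mu_bounds = as.numeric(sys_args$mu_bounds %||% c(0.01, 1)),
    R_bounds = as.numeric(sys_args$R_bounds %||% c(0.018, 20))
  )
  manifest <- character(0)
  status <- list()
  log_lines <- c(
    paste0("golgicode ", as.character(utils::packageVersion("golgicode"))),
    paste0("seed ", cfg$seed)
  )
  emit <- function(name) {
    manifest <<- c(manifest, name)
  }
  log_stage <- function(stage, ok, note = "") {
    status[[stage]] <<- ok
    log_lines <<- c(log_lines, paste0(
      "stage ", stage, ": ", if (ok) "ok" else "FAILED",
      if (nzchar(note)) paste0(" (", note, ")") else ""))
  }
  run_stage <- function(stage, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      log_stage(stage, FALSE, conditionMessage(res))
      NULL
    } else {
      log_stage(stage, TRUE)
      res
    }
  }
  jsonw <- function(obj, name) {
    jsonlite::write_json(obj, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    emit(name)
  }
  n_starts <- cfg$optimizer$n_starts %||% 8
  ctrl <- list(maxit = cfg$optimizer$maxit %||% 200)
  stages <- cfg$stages
  opt_fit <- NULL

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      fx <- make_recovery_fixture(system, cfg$sigma, cfg$seed)
      write_parameter_set(fx$params, file.path(out_dir, "simulate_params.json"),
                          system)
      emit("simulate_params.json")
      write_glycan_profile(fx$target,
                           file.path(out_dir, "simulate_displayed.tsv"))
      emit("simulate_displayed.tsv")
      TRUE
    })
  }
  if ("optimize" %in% stages) {
    opt_fit <- run_stage("optimize", function() {
      target <- config_target(cfg, system)
      fit <- optimize_fidelity(system, target, cfg$sigma,
                               n_starts = n_starts, seed = cfg$seed,
                               control = ctrl)
      write_parameter_set(fit$best_params,
                          file.path(out_dir, "optimize_best_params.json"),
                          system)
      emit("optimize_best_params.json")
      write_tsv_plain(tidy(fit), file.path(out_dir, "optimize_starts.tsv"))
      emit("optimize_starts.tsv")
      jsonw(as.list(glance(fit)), "optimize_summary.json")
      fit
    })
  }
  if ("scan_sigma" %in% stages) {
    run_stage("scan_sigma", function() {
      target <- config_target(cfg, system)
      scan <- scan_sigma(system, target, cfg$sigma_grid, n_starts = n_starts,
                         seed = cfg$seed, control = ctrl)
      write_tsv_plain(dplyr::select(scan, "sigma", "Dbar",
                                    "fraction_near_best"),
                      file.path(out_dir, "sigma_scan.tsv"))
      emit("sigma_scan.tsv")
      jsonw(list(sigma_min = attr(scan, "sigma_min"),
                 Dbar_min = attr(scan, "Dbar_min")), "sigma_scan_summary.json")
      TRUE
    })
  }
  if ("tradeoff" %in% stages) {
    run_stage("tradeoff", function() {
      target <- config_target(cfg, system)
      tr <- tradeoff_surface(target,
                             NE_range = cfg$tradeoff$NE_range %||% system$NE,
                             NC_range = cfg$tradeoff$NC_range %||% system$NC,
                             sigma_grid = cfg$sigma_grid,
                             n_starts = n_starts, seed = cfg$seed,
                             control = ctrl, q = system$q,
                             mu_bounds = system$mu_bounds,
                             R_bounds = system$R_bounds)
      write_tsv_plain(tr, file.path(out_dir, "tradeoff_surface.tsv"))
      emit("tradeoff_surface.tsv")
      TRUE
    })
  }
  if ("complexity" %in% stages) {
    run_stage("complexity", function() {
      target <- config_target(cfg, system)
      curve <- kl_curve(target, m_max = cfg$complexity$m_max,
                        restarts = cfg$complexity$restarts, seed = cfg$seed)
      call <- call_complexity(curve, tol = cfg$complexity$tol,
                              window = cfg$complexity$window)
      write_tsv_plain(tibble::as_tibble(curve),
                      file.path(out_dir, "complexity_curve.tsv"))
      emit("complexity_curve.tsv")
      jsonw(list(m_star = call$m_star, saturated = call$saturated,
                 tol = call$tol, window = call$window, seed = cfg$seed),
            "complexity_call.json")
      TRUE
    })
  }
  if ("diversity" %in% stages) {
    run_stage("diversity", function() {
      fit <- maximize_diversity(system, cfg$sigma, n_starts = n_starts,
                                seed = cfg$seed, c_th = cfg$diversity$c_th,
                                control = ctrl)
      jsonw(list(diversity = -fit$best_value, sigma = cfg$sigma,
                 c_th = fit$c_th, n_starts = n_starts,
                 fraction_near_best = fit$fraction_near_best),
            "diversity.json")
      write_parameter_set(fit$best_params,
                          file.path(out_dir, "diversity_params.json"), system)
      emit("diversity_params.json")
      TRUE
    })
  }
  if ("landscape" %in% stages) {
    if (is.null(opt_fit)) {
      log_stage("landscape", FALSE, "requires a successful optimize stage")
    } else {
      run_stage("landscape", function() {
        ha <- hessian_at(system, opt_fit$target, opt_fit$best_params,
                         step = cfg$hessian$step)
        write_tsv_plain(tidy(ha), file.path(out_dir, "hessian_spectrum.tsv"))
        emit("hessian_spectrum.tsv")
        jsonw(list(dim = ha$dim, total_stiffness = ha$total_stiffness,
                   group_stiffness = as.list(ha$group_stiffness)),
              "hessian_summary.json")
        TRUE
      })
    }
  }
  if ("swap" %in% stages) {
    if (is.null(opt_fit)) {
      log_stage("swap", FALSE, "requires a successful optimize stage")
    } else {
      run_stage("swap", function() {
        j1 <- cfg$swap$j1; j2 <- cfg$swap$j2
        swapped <- swap_cisternae(opt_fit$best_params, j1, j2)
        orig <- displayed_profile(steady_state_linear(system,
                                                      opt_fit$best_params))
        after <- displayed_profile(steady_state_linear(system, swapped))
        write_glycan_profile(after, file.path(out_dir, "swap_displayed.tsv"))
        emit("swap_displayed.tsv")
        jsonw(list(j1 = j1, j2 = j2,
                   kl_original_vs_swapped = kl_divergence(orig, after)),
              "swap_summary.json")
        TRUE
      })
    }
  }

  jsonw(cfg, "config.json")
  jsonlite::write_json(list(outputs = sort(manifest)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(manifest = sort(manifest), status = status,
                 out_dir = out_dir))
}
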