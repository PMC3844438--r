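# Reproducible experiment harness: a flat config schema, dispatch to the
# analysis functions, and tidy CSV + JSON-sidecar output.

#' Experiment configuration
#'
#' A validated, serializable bundle of model parameters, distribution spec
#' and replay settings. Configs round-trip losslessly through JSON (and YAML
#' when the yaml package is available), and every output artifact embeds the
#' config hash, so results are traceable to their exact settings.
#'
#' @param experiment one of `"replay"`, `"success"`, `"phase"`,
#'   `"capacity"`, `"scatter"`, `"validate_network"`.
#' @param N,cm network size and morphological connectivity.
#' @param theta firing threshold (single value) or, where the experiment
#'   maximizes over thresholds, a grid.
#' @param family,phi0,sigma_phi,phi_max,skew coding-ratio distribution (see
#'   [coding_spec()]).
#' @param c_target,P exactly one: calibrated connectivity or fixed storage.
#' @param Q replay length; `n_real` ensemble size; `t_eval` evaluation step.
#' @param phi_grid,theta_grid grids for phase/capacity experiments.
#' @param inhibition `"linear"` or `"nonlinear"`; `b_override` optional
#'   inhibitory weight.
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, N, cm, theta = NULL,
                              family = "gamma", phi0 = NULL,
                              sigma_phi = NULL, phi_max = NULL,
                              skew = "symmetric",
                              c_target = NULL, P = NULL,
                              Q = 100, n_real = 100, t_eval = Q,
                              phi_grid = NULL, theta_grid = NULL,
                              inhibition = "linear", b_override = NULL,
                              seed = 1L) {
  experiment <- match.arg(experiment, c("replay", "success", "phase",
                                        "capacity", "scatter",
                                        "validate_network"))
  if (!is.null(c_target) && !is.null(P))
    stop("give at most one of `c_target` and `P`")
  if (!is.null(c_target) && c_target >= cm)
    stop("`c_target` must be smaller than `cm`")
  # build the spec now so invalid distribution settings fail fast
  spec <- coding_spec(family, phi0 = phi0, sigma_phi = sigma_phi,
                      phi_max = phi_max, skew = skew)
  cfg <- list(experiment = experiment, N = N, cm = cm, theta = theta,
              family = family, phi0 = phi0, sigma_phi = sigma_phi,
              phi_max = phi_max, skew = skew, c_target = c_target, P = P,
              Q = Q, n_real = n_real, t_eval = t_eval,
              phi_grid = phi_grid, theta_grid = theta_grid,
              inhibition = inhibition, b_override = b_override,
              seed = as.integer(seed))
  structure(cfg, class = "experiment_config", spec = spec)
}

#' Serialize / deserialize experiment configs
#'
#' @param cfg an [experiment_config()].
#' @param path file path; `.json` or `.yaml`/`.yml` (YAML needs the yaml
#'   package).
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the config.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  lst <- unclass(cfg)
  attr(lst, "spec") <- NULL
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML output needs the yaml package")
    writeLines(yaml::as.yaml(lst), path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML input needs the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lst <- lst[!vapply(lst, is.null, logical(1))]
  do.call(experiment_config, lst)
}

#' Short content hash of a config
#'
#' MD5 of the canonical JSON serialization, truncated to 12 hex digits;
#' embedded in every output artifact.
#'
#' @param cfg an [experiment_config()].
#' @return character scalar.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

cfg_spec <- function(cfg) attr(cfg, "spec")

#' Run a configured experiment and write its artifacts
#'
#' Dispatches to the analysis functions and writes a tidy CSV of the result
#' plus a JSON sidecar holding the full config, the seed and the config
#' hash. Identical (config, seed) pairs produce identical outputs.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @param spec_fun for the `"phase"` experiment: optional override of the
#'   mapping from grid value to [coding_spec()]; the default scales
#'   `sigma_phi` proportionally to the grid value.
#' @return named list of written file paths, invisibly; the result object
#'   is attached as attribute `"result"`.
#' @export
run_experiment <- function(cfg, out_dir = ".", spec_fun = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  spec <- cfg_spec(cfg)
  seed <- cfg$seed
  res <- switch(cfg$experiment,
    replay = {
      rs <- draw_realization(spec, cfg$N, cfg$cm, cfg$Q, seed = seed,
                             c_target = cfg$c_target, P = cfg$P)
      p <- mf_params(cfg$N, cfg$cm, cfg$theta, rs$varsigma, rs$V2,
                     b = cfg$b_override, inhibition = cfg$inhibition,
                     phi0 = spec$phi0)
      run_replay(rs$f_head, p, Q = cfg$Q)
    },
    success = success_rate(spec, cfg$theta, cfg$N, cfg$cm, cfg$Q,
                           cfg$n_real, seed = seed,
                           c_target = cfg$c_target, P = cfg$P,
                           inhibition = cfg$inhibition, b = cfg$b_override),
    phase = {
      if (is.null(spec_fun)) {
        rel <- spec$sigma_phi / spec$phi0
        fam <- cfg$family; skw <- cfg$skew
        spec_fun <- function(phi)
          coding_spec(fam, phi0 = phi, sigma_phi = rel * phi,
                      phi_max = phi, skew = skw)
      }
      phase_diagram(spec_fun, cfg$phi_grid, cfg$theta_grid, cfg$N, cfg$cm,
                    cfg$c_target, Q = cfg$Q, n_real = cfg$n_real,
                    t_eval = cfg$t_eval, seed = seed,
                    inhibition = cfg$inhibition)
    },
    capacity = {
      sw <- capacity_sweep(spec, cfg$N, cfg$cm, cfg$phi_grid %||% cfg$P,
                           theta_grid = cfg$theta_grid, Q = cfg$Q,
                           n_real = cfg$n_real, seed = seed,
                           inhibition = cfg$inhibition)
      attr(sw$curve, "fit") <- sw$fit
      sw$curve
    },
    scatter = {
      sc <- termination_scatter(spec, cfg$theta, cfg$N, cfg$cm,
                                cfg$c_target, Q = cfg$Q,
                                n_real = cfg$n_real, seed = seed,
                                inhibition = cfg$inhibition)
      attr(sc$pairs, "frac_above") <- sc$frac_above
      attr(sc$pairs, "n_completed") <- sc$n_completed
      sc$pairs
    },
    validate_network = {
      rs <- draw_realization(spec, cfg$N, cfg$cm, cfg$Q, seed = seed,
                             c_target = cfg$c_target, P = cfg$P)
      p <- mf_params(cfg$N, cfg$cm, cfg$theta, rs$varsigma, rs$V2,
                     b = cfg$b_override, inhibition = cfg$inhibition,
                     phi0 = spec$phi0)
      mf <- run_replay(rs$f_head, p, Q = cfg$Q)
      pats <- generate_patterns(pmax(1L, round(rs$f_head * cfg$N)), cfg$N,
                                seed = substream_seed(seed, 1L))
      net <- learn_willshaw(pats, cfg$N, cfg$cm,
                            seed = substream_seed(seed, 2L))
      bn <- simulate_network(net, cfg$theta, Q = cfg$Q, b = cfg$b_override,
                             inhibition = cfg$inhibition, phi0 = spec$phi0)
      data.frame(t = mf$t, M = mf$M, m_meanfield = mf$m, n_meanfield = mf$n,
                 gamma_meanfield = mf$gamma, m_network = bn$m,
                 n_network = bn$n, gamma_network = bn$gamma)
    })

  hash <- config_hash(cfg)
  stem <- file.path(out_dir, paste0(cfg$experiment, "-", hash))
  csv <- paste0(stem, ".csv")
  utils::write.csv(as.data.frame(res), csv, row.names = FALSE)
  sidecar <- paste0(stem, ".json")
  meta <- unclass(cfg)
  attr(meta, "spec") <- NULL
  jsonlite::write_json(list(config = meta, config_hash = hash,
                            package_version =
                              as.character(utils::packageVersion("seqreplay"))),
                       sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  out <- list(csv = csv, sidecar = sidecar)
  attr(out, "result") <- res
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
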