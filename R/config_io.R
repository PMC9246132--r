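#' Load and validate a run configuration
#'
#' Reads a YAML or JSON config describing one experiment.  Top-level keys:
#' `experiment` (one of `simulate`, `distribution`, `fixed_points`,
#' `scaling`, `state_diagram`, `residence`, `coexistence`, `flagella`,
#' `centrosome`, `nucleus`, `llps_map`), a `model` block (flat key-value
#' parameters for the chosen experiment), an `execution` block (`t_max` /
#' `max_events`, `seed`, `burn_in`, `record`), and an `output` block
#' (`dir`, `formats`).  Unknown keys are rejected; defaults are filled and
#' recorded.  A config with `beta < 0` is accepted with a warning (the
#' regime is analyzable but has no known biophysical realization).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` object.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(raw)
}

run_experiments <- c("simulate", "distribution", "fixed_points", "scaling",
                     "state_diagram", "residence", "coexistence",
                     "flagella", "centrosome", "nucleus", "llps_map")

#' Validate a raw config list
#'
#' @param raw A named list (already parsed from YAML/JSON).
#' @return A `run_config` object with defaults filled.
#' @export
validate_config <- function(raw) {
  allowed_top <- c("experiment", "model", "execution", "output")
  bad <- setdiff(names(raw), allowed_top)
  if (length(bad) > 0)
    stop("unknown top-level config keys: ", paste(bad, collapse = ", "))
  if (is.null(raw$experiment) || !(raw$experiment %in% run_experiments))
    stop("`experiment` must be one of: ", paste(run_experiments, collapse = ", "))
  model <- raw$model %||% list()
  allowed_model <- c("alpha", "beta", "k_plus", "k_minus", "N_total", "V",
                     "M", "mode", "rho", "alpha2", "beta2", "k_plus2",
                     "k_minus2", "tubulin_conc", "subunit_size",
                     "t0", "r_p", "n_c", "subunit_conc", "subunit_volume",
                     "V_cell", "growth_mode", "dsub", "num_filaments",
                     "mt_conc", "dL", "km_plus", "km_minus", "R_sys",
                     "Q", "k", "k_BA", "psi_minus", "dv", "N_tot",
                     "kappa_grid", "alpha_grid", "s_grid", "V_grid",
                     "model_tag", "rho0", "kappa", "kappa2",
                     "lo_frac", "hi_frac")
  bad <- setdiff(names(model), allowed_model)
  if (length(bad) > 0)
    stop("unknown model config keys: ", paste(bad, collapse = ", "))
  if (identical(model$mode, "constant_concentration") && is.null(model$rho))
    stop("constant_concentration mode requires `rho` in the model block")
  if (!is.null(model$beta) && model$beta < 0)
    warning("beta < 0: size-dependent positive feedback in disassembly is ",
            "analyzable but has no known biophysical realization; the ",
            "divergence at n = 0 is regularized by the boundary rule")
  execution <- modifyList(list(seed = 1, t_max = NULL, max_events = NULL,
                               burn_in = NULL, record = "every_event"),
                          raw$execution %||% list())
  output <- modifyList(list(dir = ".", formats = c("tsv", "json")),
                       raw$output %||% list())
  structure(list(experiment = raw$experiment, model = model,
                 execution = execution, output = output),
            class = "run_config")
}

#' Execute a validated run configuration
#'
#' Dispatches to the module behind `cfg$experiment` and writes the
#' outputs (trajectory TSV, distribution/scaling CSV, summary JSON) plus a
#' manifest recording the config, package version, seed, wall times, and
#' file digests.  Re-running the same config reproduces every stochastic
#' output byte for byte.
#'
#' @param cfg A `run_config` from [load_config()] / [validate_config()].
#' @param out_dir Output directory (created if missing); overrides the
#'   config's `output$dir`.
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- out_dir %||% cfg$output$dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", out_dir)
  unlink(probe)

  t_start <- Sys.time()
  ex <- cfg$execution
  m <- cfg$model
  files <- character(0)
  summary <- list()

  emit_traj <- function(tr, stem) {
    path <- file.path(out_dir, paste0(stem, ".tsv"))
    write_trajectory(tr, path)
    files <<- c(files, path)
    s <- trajectory_summary(tr)
    summary <<- c(summary, list(means = s$means, sds = s$sds, cvs = s$cvs,
                                correlation = s$correlation))
  }
  emit_csv <- function(df, stem) {
    path <- file.path(out_dir, paste0(stem, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  if (cfg$experiment == "simulate") {
    pl <- params_from_list(m)
    params <- rep(list(pl$params), pl$cfg$M)
    if (!is.null(m$alpha2))
      params[[2]] <- feedback_params(m$alpha2, m$beta2 %||% 0,
                                     m$k_plus2 %||% 1, m$k_minus2 %||% 1)
    spec <- simulation_spec(pl$cfg, params, t_max = ex$t_max,
                            max_events = ex$max_events, seed = ex$seed,
                            record = ex$record, burn_in = ex$burn_in)
    tr <- gillespie_run(spec)
    emit_traj(tr, "trajectory")
  } else if (cfg$experiment == "distribution") {
    pl <- params_from_list(m)
    d <- stationary_single(pl$params, pl$cfg$N_total, pl$cfg$V)
    emit_csv(as.data.frame(d), "distribution")
    summary <- list(mean = d$mean, sd = d$sd, cv = d$cv,
                    modes = count_modes(d), prob_sum = sum(d$probs))
  } else if (cfg$experiment == "fixed_points") {
    pl <- params_from_list(m)
    fps <- fixed_points(pl$params, pl$cfg)
    summary <- list(fixed_points = lapply(fps, function(fp)
      list(location = fp$location, eigenvalues_re = Re(fp$eigenvalues),
           eigenvalues_im = Im(fp$eigenvalues),
           classification = fp$classification)))
  } else if (cfg$experiment == "scaling") {
    sc <- scaling_sweep(m$model_tag %||% "01", m$kappa %||% 1,
                        m$rho0 %||% 50, m$V_grid, m$M %||% 1)
    emit_csv(sc, "scaling")
    summary <- list(n_points = nrow(sc))
  } else if (cfg$experiment == "state_diagram") {
    sd_ <- state_diagram(m$kappa_grid, m$alpha_grid, m$beta %||% 0,
                         m$N_total %||% 50, m$V %||% 1)
    emit_csv(sd_, "state_diagram")
    summary <- list(states = table(sd_$state))
  } else if (cfg$experiment == "residence") {
    pl <- params_from_list(m)
    spec <- simulation_spec(pl$cfg, pl$params, t_max = ex$t_max,
                            seed = ex$seed, record = ex$record,
                            burn_in = ex$burn_in)
    st <- residence_times(gillespie_run(spec),
                          lo_frac = m$lo_frac %||% 0.25,
                          hi_frac = m$hi_frac %||% 0.75)
    summary <- list(tau_R = st$tau_R, n_transitions = st$n_transitions,
                    censored = st$censored)
  } else if (cfg$experiment == "coexistence") {
    cp <- coexistence_phase(m$kappa_grid, m$s_grid, m$kappa2 %||% 2,
                            m$N_total %||% 50, m$V %||% 1)
    emit_csv(cp, "coexistence")
    summary <- list(coexist_fraction = mean(cp$coexist))
  } else if (cfg$experiment == "flagella") {
    sp <- flagella_spec(M = m$M %||% 2, tubulin_conc = m$tubulin_conc %||% 5,
                        subunit_size = m$subunit_size %||% 0.01,
                        k_plus = m$k_plus %||% 120,
                        k_minus = m$k_minus %||% 100, V = m$V %||% 1,
                        t0 = m$t0 %||% 1000, r_p = m$r_p %||% 0.0016)
    tr <- flagella_simulate(sp, t_max = ex$t_max, seed = ex$seed,
                            record = ex$record)
    emit_traj(tr, "flagella_trajectory")
  } else if (cfg$experiment == "centrosome") {
    sp <- centrosome_spec(n_c = m$n_c %||% 2,
                          subunit_conc = m$subunit_conc %||% 1.67,
                          subunit_volume = m$subunit_volume %||% 5.8e-7,
                          k_plus = m$k_plus %||% 1e3,
                          k_minus = m$k_minus %||% 1e-3,
                          V_cell = m$V_cell %||% 5000)
    tr <- centrosome_simulate(sp, t_max = ex$t_max, seed = ex$seed)
    emit_traj(tr, "centrosome_trajectory")
  } else if (cfg$experiment == "nucleus") {
    sp <- nucleus_spec(growth_mode = m$growth_mode %||% "NE_surface",
                       V = m$V %||% 100, R_sys = m$R_sys %||% Inf,
                       num_filaments = m$num_filaments %||% 10)
    tr <- nucleus_simulate(sp, t_max = ex$t_max, seed = ex$seed)
    df <- data.frame(time = tr$times, n = tr$n, R_n = tr$R_n, Lbar = tr$Lbar)
    emit_csv(df, "nucleus_trajectory")
    k <- length(tr$times)
    summary <- list(final_R_n = tr$R_n[k], final_Lbar = tr$Lbar[k])
  } else if (cfg$experiment == "llps_map") {
    lp <- llps_params(Q = m$Q, k = m$k, k_BA = m$k_BA,
                      psi_minus = m$psi_minus, dv = m$dv %||% 1,
                      N_tot = m$N_tot, V_cell = m$V_cell %||% 1)
    red <- llps_reduce(lp)
    summary <- list(C0 = red$C0, C1 = red$C1, C2 = red$C2,
                    ratio = red$ratio, effective_regime = red$effective_regime)
  }

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  files <- c(files, summary_path)

  manifest <- list(config = unclass(cfg),
                   package_version = as.character(packageVersion("poolgrowth")),
                   seed = ex$seed,
                   started = format(t_start, "%Y-%m-%dT%H:%M:%OS3"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                   files = as.list(setNames(unname(tools::md5sum(files)),
                                            basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
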