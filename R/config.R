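## Configuration-driven runner. One canonical config dialect (YAML) with a
## flat, versioned schema; every default equals the sweep's standard values,
## so an empty block reproduces the study conditions. All outputs are CSV
## plus a JSON manifest sufficient to re-run the artifact exactly.

config_schema <- function() {
  list(
    top = c("seed", "tasks", "model", "environment", "integration",
            "output", "synthetic", "paramspace", "compare", "simulate"),
    model = c("base", "grid"),
    grid = c("v_dot", "p_Am_max", "kappa"),
    base = c("p_Am_max", "kappa_X", "v_dot", "kappa", "p_M_vol", "k_J",
             "E_G_vol", "E_H_birth", "E_H_puberty", "E_0", "delta_M", "d_V",
             "w_E", "mu_E", "wet_factor"),
    environment = c("constant_f", "seasonal_f_mean", "f_amp", "phases",
                    "period_days"),
    integration = c("duration_days", "compare_duration_days",
                    "output_step_days", "rtol", "atol", "V_birth",
                    "window_years", "compare_window_years"),
    output = c("dir"),
    synthetic = c("n_species", "seed", "log_pAm_mean", "log_pAm_sd",
                  "log_v_mean", "log_v_sd", "log_cor", "kappa_default",
                  "kappa_default_weight", "kappa_shape1", "kappa_shape2",
                  "lifespan_meanlog", "lifespan_sdlog", "p_M_meanlog",
                  "p_M_sdlog", "completeness_mean", "completeness_sd",
                  "frac_std", "n_outliers", "outlier_factor"),
    paramspace = c("table", "column_map", "model_label", "max_lifespan",
                   "min_completeness", "iqr_columns", "iqr_k", "n_bins",
                   "representative", "min_frequency", "drop_edge_outliers"),
    compare = c("p_Am_max", "v_dot", "kappa", "p_M_vol", "f_mean", "f_amp"),
    simulate = c("params", "environment_kind", "f", "f_mean", "f_amp",
                 "phase_label", "duration_days")
  )
}

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible(NULL))
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0L)
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(NULL)
}

#' Run the simulation study from a configuration file
#'
#' Executes the tasks requested in a YAML configuration and writes CSV
#' outputs plus a machine-readable run manifest (resolved configuration,
#' package version, seed, per-run statuses) to the output directory. The
#' schema is validated before any computation; unknown keys are rejected
#' with the offending key named. Available tasks: `sweep` (constant and
#' seasonal grid sweeps), `validate` (reserve-density residual table; runs
#' the constant sweep if `sweep` is not also requested), `compare`
#' (two-environment comparison for one species), `paramspace` (curation
#' pipeline on a species table, bundled fixture by default), `synth`
#' (synthetic species table) and `simulate` (single trajectory).
#'
#' @param config_path path to the YAML configuration.
#' @param out_dir output directory; overrides `output: dir` in the file
#'   (default `"deb_outputs"`).
#' @param seed overrides the file's `seed`.
#' @param strict if `TRUE`, any failed run makes the call an error after
#'   the manifest is written.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the written file paths and the manifest.
#' @export
run_deb_config <- function(config_path, out_dir = NULL, seed = NULL,
                           strict = FALSE, quiet = FALSE) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  sch <- config_schema()
  check_keys(cfg, sch$top, "config")
  for (blk in c("model", "environment", "integration", "output", "synthetic",
                "paramspace", "compare", "simulate"))
    check_keys(cfg[[blk]], sch[[blk]], blk)
  check_keys(cfg$model$base, sch$base, "model$base")
  check_keys(cfg$model$grid, sch$grid, "model$grid")

  if (is.null(cfg$tasks) || length(cfg$tasks) == 0L)
    stop("config must list at least one task under 'tasks'", call. = FALSE)
  tasks <- match.arg(unlist(cfg$tasks),
                     c("sweep", "validate", "compare", "paramspace", "synth",
                       "simulate"), several.ok = TRUE)

  seed <- seed %||% cfg$seed %||% 1L
  set.seed(seed)
  out_dir <- out_dir %||% cfg$output$dir %||% "deb_outputs"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say <- function(...) if (!quiet) message(...)
  base <- do.call(deb_params, cfg$model$base %||% list())
  gridspec <- cfg$model$grid %||% list()
  grid <- build_parameter_grid(
    v_list = unlist(gridspec$v_dot) %||% c(0.2, 0.3, 0.4, 0.5),
    pAm_list = unlist(gridspec$p_Am_max) %||% c(2000, 4000, 6000, 8000),
    kappa_list = unlist(gridspec$kappa) %||% c(0.43, 0.51, 0.58),
    base = base)

  env <- cfg$environment %||% list()
  constant_f <- unlist(env$constant_f) %||% c(0.2, 0.4, 0.6, 0.8, 1)
  seasonal_f_mean <- unlist(env$seasonal_f_mean) %||% c(0.4, 0.6, 0.8)
  f_amp <- env$f_amp %||% 0.2
  period <- env$period_days %||% 365
  phases <- start_phases()
  if (!is.null(env$phases)) {
    sel <- unlist(env$phases)
    bad <- setdiff(sel, names(phases))
    if (length(bad) > 0L)
      stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    phases <- phases[sel]
  }

  intg <- cfg$integration %||% list()
  duration <- intg$duration_days %||% 1095
  output_step <- intg$output_step_days %||% 1
  rtol <- intg$rtol %||% 1e-8
  atol <- intg$atol %||% 1e-10
  V_birth <- intg$V_birth %||% "dmagna"
  window_years <- intg$window_years %||% 2

  files <- list(); statuses <- list()
  sweep_all <- NULL

  if ("sweep" %in% tasks || "validate" %in% tasks) {
    say("running constant sweep: ", length(grid), " species x ",
        length(constant_f), " food levels")
    cs <- constant_sweep(grid, constant_f, duration = duration,
                         window_years = window_years,
                         output_step = output_step, rtol = rtol, atol = atol,
                         V_birth = V_birth)
    statuses$constant_sweep <- table(cs$status)
    if ("sweep" %in% tasks) {
      say("running seasonal sweep: ", length(grid), " species x ",
          length(seasonal_f_mean), " means x ", length(phases), " phases")
      ss <- seasonal_sweep(grid, seasonal_f_mean, f_amp = f_amp,
                           phases = phases, period = period,
                           duration = duration, window_years = window_years,
                           output_step = output_step, rtol = rtol,
                           atol = atol, V_birth = V_birth)
      statuses$seasonal_sweep <- table(ss$status)
      sweep_all <- add_relative_differences(rbind(cs, ss))
      files$sweep <- file.path(out_dir, "sweep.csv")
      write_sweep_csv(sweep_all, files$sweep)
    }
    if ("validate" %in% tasks) {
      chk <- reserve_density_check(cs)
      files$validation <- file.path(out_dir, "validation.csv")
      utils::write.csv(chk, files$validation, row.names = FALSE, quote = FALSE)
      statuses$validation <- c(pass = sum(chk$pass), fail = sum(!chk$pass))
    }
  }

  if ("compare" %in% tasks) {
    cmp_cfg <- cfg$compare %||% list()
    cmp_params <- deb_params(p_Am_max = cmp_cfg$p_Am_max %||% 2000,
                             v_dot = cmp_cfg$v_dot %||% 0.3,
                             kappa = cmp_cfg$kappa %||% 0.3,
                             p_M_vol = cmp_cfg$p_M_vol %||% 1800,
                             species_id = "comparison")
    cmp <- compare_environments(cmp_params,
                                f_mean = cmp_cfg$f_mean %||% 0.8,
                                f_amp = cmp_cfg$f_amp %||% f_amp,
                                duration = intg$compare_duration_days %||% 2190,
                                window_years = intg$compare_window_years %||% 4,
                                output_step = output_step, rtol = rtol,
                                atol = atol, V_birth = V_birth)
    rec <- data.frame(
      f_mean = cmp$f_mean, f_amp = cmp$f_amp,
      constant_ss_biomass_g = cmp$summary_constant$ss_biomass,
      seasonal_mean_biomass_g = cmp$summary_seasonal$mean_biomass,
      constant_repro_mean_J = cmp$summary_constant$repro_mean,
      seasonal_repro_mean_J = cmp$summary_seasonal$repro_mean,
      assim_mean_dynamic_Jd = cmp$assim_mean_dynamic,
      assim_mean_fixed_volume_Jd = cmp$assim_mean_fixed_volume)
    files$comparison <- file.path(out_dir, "comparison.csv")
    utils::write.csv(rec, files$comparison, row.names = FALSE, quote = FALSE)
    statuses$compare <- c(constant = attr(cmp$constant, "status"),
                          seasonal = attr(cmp$seasonal, "status"))
  }

  if ("paramspace" %in% tasks) {
    ps <- cfg$paramspace %||% list()
    table <- if (is.null(ps$table)) bundled_fixture()
             else read_species_table(ps$table, column_map = unlist(ps$column_map))
    combos <- curate_parameter_space(
      table,
      model_label = ps$model_label %||% "std",
      max_lifespan = ps$max_lifespan %||% 100,
      min_completeness = ps$min_completeness %||% 2.5,
      iqr_columns = unlist(ps$iqr_columns) %||% c("p_Am_max", "v_dot", "kappa", "p_M_vol"),
      iqr_k = ps$iqr_k %||% 1.5,
      n_bins = ps$n_bins %||% 5,
      representative = ps$representative %||% "midpoint",
      min_frequency = ps$min_frequency %||% 2,
      drop_edge_outliers = ps$drop_edge_outliers %||% TRUE)
    files$paramspace <- file.path(out_dir, "paramspace_combos.csv")
    utils::write.csv(combos, files$paramspace, row.names = FALSE, quote = FALSE)
    statuses$paramspace <- c(n_combos = nrow(combos))
  }

  if ("synth" %in% tasks) {
    syn_cfg <- cfg$synthetic %||% list()
    if (is.null(syn_cfg$seed)) syn_cfg$seed <- seed
    spec <- do.call(synth_spec, syn_cfg)
    gen <- generate_species_table(spec)
    files$synthetic <- file.path(out_dir, "synthetic_species.csv")
    write_species_table(gen$table, files$synthetic)
    statuses$synth <- c(n_species = nrow(gen$table),
                        n_outliers = length(gen$ground_truth$outlier_ids))
  }

  if ("simulate" %in% tasks) {
    sim <- cfg$simulate %||% list()
    sp <- do.call(deb_params, sim$params %||% list())
    kind <- sim$environment_kind %||% "constant"
    forcing <- if (kind == "constant") constant_forcing(sim$f %||% 0.8)
    else seasonal_forcing(sim$f_mean %||% 0.8, sim$f_amp %||% f_amp,
                          phase = start_phases()[[sim$phase_label %||% "increasing-mid"]],
                          period = period)
    traj <- deb_simulate(sp, forcing, duration = sim$duration_days %||% duration,
                         output_step = output_step, rtol = rtol, atol = atol,
                         V_birth = V_birth)
    files$trajectory <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(traj, files$trajectory)
    statuses$simulate <- c(status = attr(traj, "status"))
  }

  manifest <- list(
    package = "debsim",
    version = as.character(utils::packageVersion("debsim")),
    seed = seed,
    tasks = tasks,
    config = cfg,
    outputs = lapply(files, basename),
    statuses = lapply(statuses, function(s) as.list(structure(as.character(s), names = names(s))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  files$manifest <- manifest_path

  n_failed <- sum(vapply(list(sweep_all), function(s)
    if (is.null(s)) 0L else sum(s$status != "ok"), integer(1)))
  if (strict && n_failed > 0L)
    stop(n_failed, " run(s) failed (see manifest statuses)", call. = FALSE)

  invisible(list(files = files, manifest = manifest))
}
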