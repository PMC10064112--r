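#' Build the interspecific parameter grid
#'
#' Full factorial combination of energy conductance, maximum assimilation
#' rate and somatic allocation fraction, each combination standing for one
#' species; all other constants are taken from `base`. The defaults
#' reproduce the 48-species grid of the sweep (4 conductances x 4
#' assimilation rates x 3 allocation fractions). Ordering is deterministic:
#' `v_dot` varies slowest, then `p_Am_max`, with `kappa` innermost.
#'
#' @param v_list energy conductances, cm/d.
#' @param pAm_list maximum assimilation rates, J/(d cm^2).
#' @param kappa_list somatic allocation fractions.
#' @param base a [deb_params()] object supplying the fixed constants.
#' @return A list of [deb_params()] objects with `species_id`s `"s01"`,
#'   `"s02"`, ...; the attribute `"grid"` holds the corresponding data frame
#'   of varied values.
#' @examples
#' length(build_parameter_grid())  # 48
#' @export
build_parameter_grid <- function(v_list = c(0.2, 0.3, 0.4, 0.5),
                                 pAm_list = c(2000, 4000, 6000, 8000),
                                 kappa_list = c(0.43, 0.51, 0.58),
                                 base = deb_params()) {
  for (nm in c("v_list", "pAm_list", "kappa_list")) {
    x <- get(nm)
    if (length(x) == 0L) stop("'", nm, "' must be non-empty", call. = FALSE)
    if (anyDuplicated(x)) stop("duplicate values in '", nm, "'", call. = FALSE)
  }
  gr <- expand.grid(kappa = kappa_list, p_Am_max = pAm_list, v_dot = v_list,
                    KEEP.OUT.ATTRS = FALSE)
  gr <- gr[, c("v_dot", "p_Am_max", "kappa")]
  gr$species_id <- sprintf("s%02d", seq_len(nrow(gr)))
  grid <- lapply(seq_len(nrow(gr)), function(i) {
    p <- base
    p$v_dot <- gr$v_dot[i]; p$p_Am_max <- gr$p_Am_max[i]; p$kappa <- gr$kappa[i]
    p$species_id <- gr$species_id[i]
    validate_deb_params(p)
    p
  })
  attr(grid, "grid") <- gr
  grid
}

empty_sweep_row <- function(p, env_kind, f_or_fmean, f_amp, phase_label) {
  data.frame(species_id = p$species_id %||% NA_character_,
             v_dot = p$v_dot, pAm = p$p_Am_max, kappa = p$kappa,
             env_kind = env_kind, f_or_fmean = f_or_fmean, f_amp = f_amp,
             phase_label = phase_label,
             ss_biomass_g = NA_real_, mean_biomass_g = NA_real_,
             biomass_min_g = NA_real_, biomass_max_g = NA_real_,
             repro_mean_J = NA_real_, repro_net_J = NA_real_,
             t_puberty_d = NA_real_, t_puberty_ceil_d = NA_real_,
             E_terminal_J = NA_real_, V_terminal_cm3 = NA_real_,
             status = "failed", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_one <- function(p, forcing, env_kind, f_or_fmean, f_amp, phase_label,
                    duration, window_years, ...) {
  row <- empty_sweep_row(p, env_kind, f_or_fmean, f_amp, phase_label)
  res <- try({
    traj <- deb_simulate(p, forcing, duration = duration, ...)
    sm <- summarize_run(traj, window_years = window_years)
    n <- nrow(traj)
    row$ss_biomass_g <- sm$ss_biomass
    row$mean_biomass_g <- sm$mean_biomass
    row$biomass_min_g <- sm$min_biomass
    row$biomass_max_g <- sm$max_biomass
    row$repro_mean_J <- sm$repro_mean
    row$repro_net_J <- sm$repro_net
    row$t_puberty_d <- sm$t_puberty
    row$t_puberty_ceil_d <- sm$t_puberty_ceil
    row$E_terminal_J <- traj$E[n]
    row$V_terminal_cm3 <- traj$V[n]
    row$status <- attr(traj, "status")
  }, silent = TRUE)
  if (inherits(res, "try-error")) row$status <- "failed"
  row
}

#' Sweep the parameter grid over constant food levels
#'
#' One integration and summary per (species, food level). Failed runs are
#' kept as rows with `status = "failed"` rather than dropped.
#'
#' @param grid a list of [deb_params()] from [build_parameter_grid()].
#' @param f_levels constant scaled functional responses to evaluate.
#' @param duration integration length in days.
#' @param window_years trailing analysis window in years.
#' @param ... further arguments passed to [deb_simulate()].
#' @return A data frame with one row per run: the varied parameters, the
#'   environment descriptor, the run summary columns (steady-state and
#'   window biomass in g, reproduction energy in J, time to puberty in d and
#'   ceiling days), the terminal reserve and volume (used by
#'   [reserve_density_check()]) and a status flag.
#' @export
constant_sweep <- function(grid, f_levels = c(0.2, 0.4, 0.6, 0.8, 1),
                           duration = 1095, window_years = 2, ...) {
  rows <- lapply(f_levels, function(f) {
    forcing <- constant_forcing(f)
    do.call(rbind, lapply(grid, run_one, forcing = forcing,
                          env_kind = "constant", f_or_fmean = f, f_amp = 0,
                          phase_label = NA_character_, duration = duration,
                          window_years = window_years, ...))
  })
  do.call(rbind, rows)
}

#' Sweep the parameter grid over seasonal environments
#'
#' One integration and summary per (species, annual mean food, start
#' phase).
#'
#' @inheritParams constant_sweep
#' @param f_mean_levels annual mean scaled functional responses.
#' @param f_amp seasonal amplitude.
#' @param phases named phase offsets, see [start_phases()].
#' @param period period of the seasonal cycle in days.
#' @return As [constant_sweep()], with `env_kind = "seasonal"` and one row
#'   per phase.
#' @export
seasonal_sweep <- function(grid, f_mean_levels = c(0.4, 0.6, 0.8),
                           f_amp = 0.2, phases = start_phases(),
                           period = 365, duration = 1095, window_years = 2,
                           ...) {
  if (is.null(names(phases)) || any(!nzchar(names(phases))))
    stop("'phases' must be a named vector of phase offsets", call. = FALSE)
  rows <- list()
  for (fb in f_mean_levels) {
    for (j in seq_along(phases)) {
      forcing <- seasonal_forcing(fb, f_amp, phase = phases[[j]], period = period)
      rows[[length(rows) + 1L]] <-
        do.call(rbind, lapply(grid, run_one, forcing = forcing,
                              env_kind = "seasonal", f_or_fmean = fb,
                              f_amp = f_amp, phase_label = names(phases)[j],
                              duration = duration,
                              window_years = window_years, ...))
    }
  }
  do.call(rbind, rows)
}

#' Relative differences across species at one resource level
#'
#' `d_r(x) = x / mean(x)`, where the mean is taken over all parameter sets
#' evaluated at the same resource level. The returned ratios average to 1
#' exactly.
#'
#' @param values numeric vector of one statistic, one entry per species, all
#'   at the same resource level.
#' @return Vector of ratios of the same length.
#' @export
relative_difference <- function(values) {
  if (length(values) < 1L || !any(is.finite(values)))
    stop("'values' must contain at least one finite value", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("relative differences are undefined for zero mean", call. = FALSE)
  values / m
}

#' Add relative-difference columns to a sweep table
#'
#' Computes `dr_biomass` (from `ss_biomass_g` for constant runs and
#' `mean_biomass_g` for seasonal runs) and `dr_repro` (from `repro_mean_J`)
#' within each environment group (kind, level and phase), over successful
#' runs.
#'
#' @param sweep a [constant_sweep()] or [seasonal_sweep()] result.
#' @return The sweep with `dr_biomass` and `dr_repro` columns appended.
#' @export
add_relative_differences <- function(sweep) {
  sweep$dr_biomass <- NA_real_
  sweep$dr_repro <- NA_real_
  key <- paste(sweep$env_kind, sweep$f_or_fmean, sweep$f_amp,
               ifelse(is.na(sweep$phase_label), "", sweep$phase_label))
  for (k in unique(key)) {
    i <- which(key == k & sweep$status == "ok")
    if (length(i) == 0L) next
    b <- if (sweep$env_kind[i[1L]] == "constant") sweep$ss_biomass_g[i] else sweep$mean_biomass_g[i]
    sweep$dr_biomass[i] <- relative_difference(b)
    sweep$dr_repro[i] <- relative_difference(sweep$repro_mean_J[i])
  }
  sweep
}

#' Reserve-density validation of constant-food runs
#'
#' At constant food the reserve density equilibrates at `f * [E_m]`, so
#' every converged run must end with `E / (V * f * [E_m])` equal to 1. This
#' recomputes that residual per run and flags passes at `|residual| < tol`.
#' Defined only at constant resource; seasonal input is an error.
#'
#' @param sweep a [constant_sweep()] result.
#' @param tol pass tolerance on the residual (default `1e-3`).
#' @return Data frame with `species_id`, `f`, `residual` and `pass`.
#' @export
reserve_density_check <- function(sweep, tol = 1e-3) {
  if (any(sweep$env_kind != "constant"))
    stop("reserve-density check is defined only at constant resource", call. = FALSE)
  Em <- sweep$pAm / sweep$v_dot
  residual <- sweep$E_terminal_J / (sweep$V_terminal_cm3 * sweep$f_or_fmean * Em) - 1
  data.frame(species_id = sweep$species_id, f = sweep$f_or_fmean,
             residual = residual, pass = abs(residual) < tol,
             stringsAsFactors = FALSE)
}

#' Constant versus seasonal environment for one species
#'
#' Runs the same parameter set under a constant resource at `f_mean` and
#' under a seasonal resource with the same annual mean, then contrasts the
#' trailing-window summaries and the assimilation fluxes. The seasonal
#' individual's realized assimilation over the final year is compared with
#' the fixed-volume reference `p_A_ref(t) = f(t) * {p_Am} * V_const^(2/3)`,
#' the flux a hypothetical individual would have if only food varied while
#' its structural volume stayed at the constant-environment steady state.
#' The default parameter set is the low-assimilation, low-allocation species
#' used for the temperate-versus-tropical illustration
#' (`{p_Am} = 2000`, `v = 0.3`, `kappa = 0.3`, `[p_M] = 1800`).
#'
#' @param params a [deb_params()] object; default as described above.
#' @param f_mean shared annual mean scaled functional response.
#' @param f_amp seasonal amplitude.
#' @param duration integration length in days (default 6 years).
#' @param window_years trailing analysis window in years (default 4).
#' @param ... further arguments passed to [deb_simulate()].
#' @return An object of class `deb_env_comparison`: list with the two
#'   trajectories (`constant`, `seasonal`), their summaries
#'   (`summary_constant`, `summary_seasonal`), the constant steady-state
#'   volume `V_const`, and the final-year cycle averages of the realized
#'   (`assim_mean_dynamic`) and fixed-volume reference
#'   (`assim_mean_fixed_volume`) assimilation fluxes in J/d.
#' @export
compare_environments <- function(params = NULL, f_mean = 0.8, f_amp = 0.2,
                                 duration = 2190, window_years = 4, ...) {
  if (is.null(params))
    params <- deb_params(p_Am_max = 2000, v_dot = 0.3, kappa = 0.3,
                         p_M_vol = 1800, species_id = "comparison")
  tr_const <- deb_simulate(params, constant_forcing(f_mean),
                           duration = duration, ...)
  forcing_s <- seasonal_forcing(f_mean, f_amp)
  tr_seas <- deb_simulate(params, forcing_s, duration = duration, ...)

  yr <- tr_seas$time >= duration - 365
  V_const <- tr_const$V[nrow(tr_const)]
  assim_dyn <- mean(tr_seas$p_A[yr])
  assim_ref <- mean(tr_seas$f[yr] * params$p_Am_max * V_const^(2 / 3))

  out <- list(constant = tr_const, seasonal = tr_seas,
              summary_constant = summarize_run(tr_const, window_years),
              summary_seasonal = summarize_run(tr_seas, window_years),
              V_const = V_const,
              assim_mean_dynamic = assim_dyn,
              assim_mean_fixed_volume = assim_ref,
              f_mean = f_mean, f_amp = f_amp, params = params)
  class(out) <- "deb_env_comparison"
  out
}

#' @export
print.deb_env_comparison <- function(x, ...) {
  cat("Constant vs seasonal environment (same annual mean f =", x$f_mean, ")\n")
  cat(sprintf("  constant : steady-state dry biomass %.4g g, window-mean E_R %.4g J\n",
              x$summary_constant$ss_biomass, x$summary_constant$repro_mean))
  cat(sprintf("  seasonal : window-mean dry biomass %.4g g, window-mean E_R %.4g J\n",
              x$summary_seasonal$mean_biomass, x$summary_seasonal$repro_mean))
  cat(sprintf("  final-year mean assimilation: dynamic %.4g J/d vs fixed-volume reference %.4g J/d\n",
              x$assim_mean_dynamic, x$assim_mean_fixed_volume))
  invisible(x)
}

#' Maturation statistics per resource level
#'
#' Aggregates time to puberty across species for each environment level:
#' minimum, maximum and range of the interpolated crossing times and of
#' their ceiling-day report, together with the species attaining the
#' slowest maturation. Runs where puberty is not reached are excluded and
#' counted.
#'
#' @param sweep a sweep result containing `t_puberty_d`.
#' @return One row per (environment kind, level): counts, raw and
#'   ceiling-day minima/maxima/ranges, and the `species_id` of the maximum.
#' @export
maturation_table <- function(sweep) {
  key <- paste(sweep$env_kind, sweep$f_or_fmean)
  out <- lapply(unique(key), function(k) {
    s <- sweep[key == k, ]
    reached <- s[!is.na(s$t_puberty_d) & s$status == "ok", ]
    data.frame(env_kind = s$env_kind[1L], f_or_fmean = s$f_or_fmean[1L],
               n_runs = nrow(s), n_reached = nrow(reached),
               n_not_reached = nrow(s) - nrow(reached),
               t_min_d = min(reached$t_puberty_d),
               t_max_d = max(reached$t_puberty_d),
               t_range_d = diff(range(reached$t_puberty_d)),
               ceil_min_d = min(reached$t_puberty_ceil_d),
               ceil_max_d = max(reached$t_puberty_ceil_d),
               ceil_range_d = diff(range(reached$t_puberty_ceil_d)),
               slowest_species = reached$species_id[which.max(reached$t_puberty_d)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a sweep table to CSV
#'
#' @param sweep a sweep result (optionally with relative-difference
#'   columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
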