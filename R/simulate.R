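#' Default structural volume at birth
#'
#' The integrations start at birth (the onset of feeding) rather than at egg
#' deposition: with the default thresholds the embryo's initial reserve
#' (`E_0 = 0.167` J) is smaller than the maturity required at birth
#' (`E_H^b = 0.55` J), so the embryonic stage cannot be simulated with the
#' same energy bookkeeping. The default birth volume is the structural
#' volume at birth of *Daphnia magna* (structural length at birth of about
#' 0.046 cm), the species that supplies every fixed constant of the sweep;
#' `1e-4` cm^3. An alternative rule, `"reserve-capacity"`, sets
#' `V_birth = E_0 / [E_m]` so that the neonate starts at full reserve
#' density. Maturation times over the first days of life are sensitive to
#' this choice; steady states and long-run seasonal summaries are not.
#'
#' @export
deb_default_birth_volume <- 1e-4

resolve_birth_volume <- function(params, V_birth) {
  if (is.character(V_birth)) {
    V_birth <- match.arg(V_birth, c("dmagna", "reserve-capacity"))
    if (V_birth == "reserve-capacity") return(params$E_0 / reserve_capacity(params))
    return(deb_default_birth_volume)
  }
  if (!is.numeric(V_birth) || length(V_birth) != 1L || !is.finite(V_birth) ||
      V_birth <= 0)
    stop("'V_birth' must be a positive volume or a named rule", call. = FALSE)
  V_birth
}

#' Initial state at birth
#'
#' Returns the organism state from which all integrations start: reserve
#' equal to the egg energy `E_0`, maturity exactly at the birth threshold
#' (so feeding is already switched on), no reproduction buffer, and the
#' birth volume given by `V_birth` (see [deb_default_birth_volume]).
#'
#' @param params a [deb_params()] object.
#' @param V_birth a positive volume in cm^3, or `"dmagna"` (default) or
#'   `"reserve-capacity"` (`E_0 / [E_m]`).
#' @return A [deb_state()] with `stage = "juvenile"`.
#' @export
initialize_at_birth <- function(params, V_birth = "dmagna") {
  deb_state(E = params$E_0, V = resolve_birth_volume(params, V_birth),
            E_H = params$E_H_birth, E_R = 0, stage = "juvenile")
}

## Right-hand side closures for the two latched modes. The stage is a
## discrete mode, not a state variable: threshold crossing is located by the
## solver's rootfinder and the integration restarted in the adult mode, so
## a later decline of E_H under starvation cannot demote the organism.
make_rhs <- function(params, forcing, adult) {
  kap <- params$kappa; v <- params$v_dot; pM <- params$p_M_vol
  EG <- params$E_G_vol; kJ <- params$k_J; pAm <- params$p_Am_max
  EHp <- params$E_H_puberty
  f_const <- if (inherits(forcing, "deb_forcing_constant")) forcing$f_const else NULL
  function(t, y, parms) {
    E <- y[1L]; V <- y[2L]; EH <- y[3L]
    f <- if (is.null(f_const)) evaluate_f(forcing, t) else f_const
    r <- (kap * v * E / V^(4 / 3) - pM) / (kap * E / V + EG)
    p_A <- f * pAm * V^(2 / 3)
    p_C <- E * (v * V^(-1 / 3) - r)
    p_J <- if (adult) kJ * EHp else kJ * EH
    branch <- (1 - kap) * p_C - p_J
    if (adult) {
      list(c(p_A - p_C, r * V, 0, branch))
    } else {
      list(c(p_A - p_C, r * V, branch, 0))
    }
  }
}

#' Integrate the standard DEB model
#'
#' Solves the four-state dynamics from [initialize_at_birth()] with the
#' stiff-capable adaptive solver [deSolve::lsoda()]. The puberty switch is a
#' latched event located by the solver's rootfinding on
#' `E_H - E_H_puberty`; the integration is split there and restarted in the
#' adult mode. Output is returned on a uniform grid (default 1-day spacing).
#'
#' @param params a [deb_params()] object.
#' @param forcing a [constant_forcing()] or [seasonal_forcing()] object.
#' @param duration integration length in days (> 0).
#' @param output_step spacing of the output grid in days (> 0).
#' @param rtol,atol relative and absolute solver tolerances.
#' @param V_birth birth volume rule, see [initialize_at_birth()].
#' @return An object of class `deb_trajectory`: a data frame with one row
#'   per output time and columns `time`, `f`, `E`, `V`, `E_H`, `E_R`,
#'   `stage`, `dry_biomass`, `wet_biomass`, `p_X`, `p_A`, `p_C`, `p_S`,
#'   `p_J`, `r`; attributes carry the parameters, the forcing, the exact
#'   puberty-crossing time (`t_puberty_exact`, `NA` if never crossed) and a
#'   `status` flag (`"ok"` or `"failed"`; failed runs return the partial
#'   trajectory up to the failure together with a diagnostic message).
#' @examples
#' tr <- deb_simulate(deb_params(), constant_forcing(0.8), duration = 30)
#' time_to_puberty(tr)
#' @export
deb_simulate <- function(params, forcing, duration = 1095, output_step = 1,
                         rtol = 1e-8, atol = 1e-10, V_birth = "dmagna") {
  stopifnot(inherits(params, "deb_params"), inherits(forcing, "deb_forcing"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a positive number of days", call. = FALSE)
  if (!is.numeric(output_step) || length(output_step) != 1L || output_step <= 0)
    stop("'output_step' must be a positive number of days", call. = FALSE)

  s0 <- initialize_at_birth(params, V_birth)
  y0 <- c(E = s0$E, V = s0$V, E_H = s0$E_H, E_R = s0$E_R)
  times <- seq(0, duration, by = output_step)
  if (times[length(times)] < duration) times <- c(times, duration)

  status <- "ok"; diagnostic <- NA_character_
  t_cross <- NA_real_

  solve_leg <- function(y, tt, adult, root = FALSE) {
    rhs <- make_rhs(params, forcing, adult)
    args <- list(y = y, times = tt, func = rhs, parms = NULL,
                 rtol = rtol, atol = atol)
    if (root) args$rootfunc <- function(t, y, parms) y[3L] - params$E_H_puberty
    out <- try(suppressWarnings(do.call(deSolve::lsoda, args)), silent = TRUE)
    out
  }

  if (s0$E_H >= params$E_H_puberty) {
    t_cross <- 0
    out <- solve_leg(y0, times, adult = TRUE)
    if (inherits(out, "try-error")) {
      status <- "failed"; diagnostic <- as.character(out)
      out <- matrix(c(0, y0), nrow = 1, dimnames = list(NULL, c("time", names(y0))))
    }
    stage <- rep("adult", nrow(out))
  } else {
    o1 <- solve_leg(y0, times, adult = FALSE, root = TRUE)
    if (inherits(o1, "try-error")) {
      status <- "failed"; diagnostic <- as.character(o1)
      out <- matrix(c(0, y0), nrow = 1, dimnames = list(NULL, c("time", names(y0))))
      stage <- "juvenile"
    } else {
      troot <- attr(o1, "troot")
      if (is.null(troot) || length(troot) == 0L) {
        out <- o1
        stage <- rep("juvenile", nrow(out))
      } else {
        t_cross <- troot[1L]
        y1 <- as.numeric(o1[nrow(o1), 2:5]); names(y1) <- names(y0)
        keep1 <- o1[, 1L] < t_cross
        t2 <- c(t_cross, times[times > t_cross])
        o2 <- solve_leg(y1, t2, adult = TRUE)
        if (inherits(o2, "try-error")) {
          status <- "failed"; diagnostic <- as.character(o2)
          out <- o1[keep1, , drop = FALSE]
          stage <- rep("juvenile", nrow(out))
        } else {
          on_grid <- abs(t_cross %% output_step) < 1e-12 ||
            abs(t_cross %% output_step - output_step) < 1e-12
          o2 <- o2[if (on_grid) TRUE else -1L, , drop = FALSE]
          out <- rbind(o1[keep1, , drop = FALSE], o2)
          stage <- c(rep("juvenile", sum(keep1)), rep("adult", nrow(o2)))
        }
      }
    }
  }

  out <- as.matrix(out)
  bad <- !is.finite(out[, "V"]) | out[, "V"] <= 0 |
    !is.finite(out[, "E"]) | !is.finite(out[, "E_H"]) | !is.finite(out[, "E_R"])
  if (any(bad)) {
    status <- "failed"
    if (is.na(diagnostic)) diagnostic <- "non-finite state or non-positive volume"
    first_bad <- which(bad)[1L]
    out <- out[seq_len(max(first_bad - 1L, 1L)), , drop = FALSE]
    stage <- stage[seq_len(nrow(out))]
  }

  tt <- out[, "time"]
  fvals <- evaluate_f(forcing, tt)
  E <- out[, "E"]; V <- out[, "V"]; EH <- out[, "E_H"]; ER <- out[, "E_R"]
  kap <- params$kappa; v <- params$v_dot
  r <- (kap * v * E / V^(4 / 3) - params$p_M_vol) / (kap * E / V + params$E_G_vol)
  p_X <- fvals * max_ingestion_rate(params) * V^(2 / 3)
  p_A <- params$kappa_X * p_X
  p_C <- E * (v * V^(-1 / 3) - r)
  p_S <- params$p_M_vol * V
  p_J <- ifelse(stage == "adult", params$k_J * params$E_H_puberty, params$k_J * EH)
  B <- params$d_V * V + (params$w_E / params$mu_E) * E

  traj <- data.frame(time = tt, f = fvals, E = E, V = V, E_H = EH, E_R = ER,
                     stage = stage, dry_biomass = B,
                     wet_biomass = params$wet_factor * B,
                     p_X = p_X, p_A = p_A, p_C = p_C, p_S = p_S, p_J = p_J,
                     r = r, row.names = NULL)
  attr(traj, "params") <- params
  attr(traj, "forcing") <- forcing
  attr(traj, "t_puberty_exact") <- t_cross
  attr(traj, "status") <- status
  attr(traj, "diagnostic") <- diagnostic
  attr(traj, "output_step") <- output_step
  class(traj) <- c("deb_trajectory", "data.frame")
  traj
}

#' @export
print.deb_trajectory <- function(x, ...) {
  p <- attr(x, "params"); f <- attr(x, "forcing")
  cat(sprintf("DEB trajectory: %d samples over %g d [%s]\n",
              nrow(x), x$time[nrow(x)], attr(x, "status")))
  print(f)
  cat(sprintf("  final: V = %.4g cm^3, E = %.4g J, dry biomass = %.4g g, E_R = %.4g J\n",
              x$V[nrow(x)], x$E[nrow(x)], x$dry_biomass[nrow(x)], x$E_R[nrow(x)]))
  invisible(x)
}

#' Time to reach the puberty threshold
#'
#' First time at which the cumulative maturity reaches `E_H_puberty`. For
#' trajectories produced by [deb_simulate()] this is the crossing located
#' by the solver's rootfinder. For trajectories lacking event information
#' (e.g. rebuilt from file) the crossing is located by linear interpolation
#' between the bracketing output samples; note that after the latched
#' puberty switch `E_H` plateaus exactly at the threshold, so the
#' interpolated time can sit up to one output step above the true crossing.
#'
#' @param traj a [deb_simulate()] trajectory.
#' @return Days from the start of the run (0 if already at or past the
#'   threshold at the first sample), or `NA` if the threshold is never
#'   reached.
#' @export
time_to_puberty <- function(traj) {
  stopifnot(inherits(traj, "deb_trajectory"))
  t_exact <- attr(traj, "t_puberty_exact")
  if (!is.null(t_exact) && !is.na(t_exact)) return(t_exact)
  EHp <- attr(traj, "params")$E_H_puberty
  EH <- traj$E_H; tt <- traj$time
  if (EH[1L] >= EHp) return(0)
  i <- which(EH >= EHp)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1L]
  tt[i - 1L] + (EHp - EH[i - 1L]) / (EH[i] - EH[i - 1L]) * (tt[i] - tt[i - 1L])
}

#' Summarize one run
#'
#' Reduces a trajectory to the study's per-run statistics. For constant
#' forcing the biomass summary is the terminal (steady-state) dry biomass;
#' for seasonal forcing it is the mean (with min and max) dry biomass over
#' the trailing window. Reproduction is summarized as the mean cumulative
#' reproduction energy over the same trailing window; `repro_net` is the
#' reproduction energy produced within the window (last minus first sample),
#' which unlike the cumulative mean carries no memory of the birth season.
#'
#' @param traj a [deb_simulate()] trajectory.
#' @param window_years length of the trailing analysis window in years
#'   (365-day years); the transient ontogenetic growth before the window is
#'   discarded. Default 2 (sweeps use the final 2 of 3 years; the
#'   two-environment species comparison uses the final 4 of 6).
#' @return An object of class `deb_run_summary`: list with `t_puberty`,
#'   `t_puberty_ceil`, `ss_biomass` (terminal dry biomass, g),
#'   `mean_biomass`, `min_biomass`, `max_biomass` (g, trailing window),
#'   `repro_mean`, `repro_net` (J), `final_state` and `status`.
#' @export
summarize_run <- function(traj, window_years = 2) {
  stopifnot(inherits(traj, "deb_trajectory"))
  t_end <- traj$time[nrow(traj)]
  w0 <- t_end - window_years * 365
  if (w0 < 0) stop("analysis window is longer than the trajectory", call. = FALSE)
  w <- traj$time >= w0
  tp <- time_to_puberty(traj)
  n <- nrow(traj)
  out <- list(
    t_puberty = tp,
    t_puberty_ceil = if (is.na(tp)) NA_real_ else ceiling(tp),
    ss_biomass = traj$dry_biomass[n],
    mean_biomass = mean(traj$dry_biomass[w]),
    min_biomass = min(traj$dry_biomass[w]),
    max_biomass = max(traj$dry_biomass[w]),
    repro_mean = mean(traj$E_R[w]),
    repro_net = traj$E_R[n] - traj$E_R[w][1L],
    final_state = deb_state(E = traj$E[n], V = traj$V[n], E_H = traj$E_H[n],
                            E_R = traj$E_R[n], stage = traj$stage[n]),
    status = attr(traj, "status"))
  class(out) <- "deb_run_summary"
  out
}

#' @export
print.deb_run_summary <- function(x, ...) {
  cat("DEB run summary [", x$status, "]\n", sep = "")
  cat(sprintf("  time to puberty: %.3f d (ceiling %g d)\n", x$t_puberty, x$t_puberty_ceil))
  cat(sprintf("  dry biomass: terminal %.4g g; window mean %.4g g [%.4g, %.4g]\n",
              x$ss_biomass, x$mean_biomass, x$min_biomass, x$max_biomass))
  cat(sprintf("  reproduction energy: window mean %.4g J, window net %.4g J\n",
              x$repro_mean, x$repro_net))
  invisible(x)
}

#' @export
summary.deb_trajectory <- function(object, window_years = 2, ...) {
  summarize_run(object, window_years = window_years)
}

#' @export
plot.deb_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$dry_biomass, type = "l", xlab = "time (d)",
                 ylab = "dry biomass (g)", main = "Biomass", ...)
  graphics::plot(x$time, x$E_R, type = "l", xlab = "time (d)",
                 ylab = "E_R (J)", main = "Cumulative reproduction", ...)
  graphics::plot(x$time, x$E_H, type = "l", xlab = "time (d)",
                 ylab = "E_H (J)", main = "Maturity", ...)
  graphics::abline(h = attr(x, "params")$E_H_puberty, lty = 3)
  graphics::plot(x$time, x$f, type = "l", xlab = "time (d)", ylab = "f",
                 ylim = c(0, 1), main = "Resource", ...)
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Writes the per-day trajectory with units embedded in the column names:
#' `t_days, f, E_J, V_cm3, EH_J, ER_J, stage, dry_biomass_g, wet_biomass_g,
#' pA, pC, pS, pJ, r`.
#'
#' @param traj a [deb_simulate()] trajectory.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "deb_trajectory"))
  out <- data.frame(t_days = traj$time, f = traj$f, E_J = traj$E,
                    V_cm3 = traj$V, EH_J = traj$E_H, ER_J = traj$E_R,
                    stage = traj$stage, dry_biomass_g = traj$dry_biomass,
                    wet_biomass_g = traj$wet_biomass, pA = traj$p_A,
                    pC = traj$p_C, pS = traj$p_S, pJ = traj$p_J, r = traj$r)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
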