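## Shared fixtures and cached heavy computations. The full-grid sweeps are
## computed once per test run and reused by the acceptance checks.

.debsim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .debsim_cache, inherits = FALSE))
    assign(key, force(expr), envir = .debsim_cache)
  get(key, envir = .debsim_cache, inherits = FALSE)
}

full_grid <- function() cached("grid", build_parameter_grid())

full_constant_sweep <- function() {
  cached("constant_sweep", constant_sweep(full_grid()))
}

full_seasonal_sweep <- function() {
  cached("seasonal_sweep", seasonal_sweep(full_grid()))
}

## A hand-built trajectory carrying only the columns and attributes that
## interpolation-based summaries need (no solver event information).
fake_trajectory <- function(times, E_H, params = deb_params()) {
  traj <- data.frame(time = times, f = 1, E = 1, V = 1, E_H = E_H, E_R = 0,
                     stage = "juvenile", dry_biomass = 1, wet_biomass = 5,
                     p_X = 0, p_A = 0, p_C = 0, p_S = 0, p_J = 0, r = 0)
  attr(traj, "params") <- params
  attr(traj, "status") <- "ok"
  class(traj) <- c("deb_trajectory", "data.frame")
  traj
}

random_feeding_state <- function(params) {
  V <- stats::runif(1, 1e-4, 10)
  e <- stats::runif(1, 0.05, 1.2)  # reserve density relative to capacity
  E <- e * V * reserve_capacity(params)
  E_H <- stats::runif(1, 0, 2 * params$E_H_puberty)
  stage <- if (E_H >= params$E_H_puberty) "adult" else "juvenile"
  deb_state(E = E, V = V, E_H = min(E_H, params$E_H_puberty), E_R = 0,
            stage = stage)
}
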