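#' Instantaneous organism state
#'
#' The four state variables of the standard DEB model plus the (latched)
#' life stage: reserve energy `E` (J), structural volume `V` (cm^3),
#' cumulative maturity energy `E_H` (J) and cumulative reproduction energy
#' `E_R` (J).
#'
#' @param E reserve energy, J (>= 0).
#' @param V structural volume, cm^3 (> 0).
#' @param E_H cumulative maturity energy, J (>= 0).
#' @param E_R cumulative reproduction energy, J.
#' @param stage one of `"embryo"`, `"juvenile"`, `"adult"`.
#' @return An object of class `deb_state`.
#' @export
deb_state <- function(E, V, E_H, E_R = 0, stage = "juvenile") {
  stage <- match.arg(stage, deb_stages())
  if (any(V <= 0)) stop("structural volume must be strictly positive", call. = FALSE)
  if (any(E < 0)) stop("reserve energy must be nonnegative", call. = FALSE)
  if (any(E_H < 0)) stop("maturity energy must be nonnegative", call. = FALSE)
  structure(list(E = E, V = V, E_H = E_H, E_R = E_R, stage = stage),
            class = "deb_state")
}

#' @export
print.deb_state <- function(x, ...) {
  cat(sprintf("DEB state (%s): E = %g J, V = %g cm^3, E_H = %g J, E_R = %g J\n",
              x$stage, x$E[1], x$V[1], x$E_H[1], x$E_R[1]))
  invisible(x)
}

deb_stages <- function() c("embryo", "juvenile", "adult")

#' Life stage from maturity level
#'
#' Determines the developmental stage from the cumulative maturity energy
#' relative to the birth and puberty thresholds. Stage switches are one-way
#' latches: once a threshold has been crossed the organism never reverts to
#' an earlier stage, even if `E_H` later declines under starvation.
#'
#' @param E_H cumulative maturity energy, J.
#' @param params a [deb_params()] object supplying the thresholds.
#' @param previous_stage the stage already attained (enforces the latch).
#' @return `"embryo"`, `"juvenile"` or `"adult"`.
#' @export
life_stage <- function(E_H, params, previous_stage = "embryo") {
  previous_stage <- match.arg(previous_stage, deb_stages())
  if (!is.numeric(E_H) || length(E_H) != 1L || is.na(E_H))
    stop("'E_H' must be a single number", call. = FALSE)
  if (E_H < 0) stop("invalid state: negative maturity energy", call. = FALSE)
  if (previous_stage == "adult" || E_H >= params$E_H_puberty) return("adult")
  if (previous_stage == "juvenile" || E_H > params$E_H_birth) return("juvenile")
  "embryo"
}

#' Specific growth rate of structural volume
#'
#' `r = (kappa * v * E / V^(4/3) - [p_M]) / (kappa * E / V + [E_G])`, 1/d.
#' The rate is negative when mobilized energy does not cover somatic
#' maintenance, in which case the organism shrinks (structure is degraded to
#' pay maintenance); no starvation clamping is applied.
#'
#' @param state a [deb_state()] object (only `E` and `V` are used).
#' @param params a [deb_params()] object.
#' @return Specific growth rate in 1/d.
#' @export
specific_growth_rate <- function(state, params) {
  E <- state$E; V <- state$V
  if (any(V <= 0)) stop("invalid state: structural volume must be positive", call. = FALSE)
  (params$kappa * params$v_dot * E / V^(4 / 3) - params$p_M_vol) /
    (params$kappa * E / V + params$E_G_vol)
}

#' Energy fluxes at a given state
#'
#' Computes the five fluxes of the standard DEB model (J/d) together with the
#' specific growth rate. Feeding scales with structural surface area,
#' `p_X = f * {p_Xm} * V^(2/3)`, and is zero for embryos; assimilation is
#' `kappa_X * p_X`. Mobilization is `p_C = E * (v * V^(-1/3) - r)`, the form
#' consistent with the growth-rate equation. Maturity maintenance is paid on
#' the current maturity for embryos and juveniles and on the puberty
#' threshold for adults.
#'
#' @inheritParams specific_growth_rate
#' @param f scaled functional response in \[0, 1\].
#' @return An object of class `deb_fluxes`: list with `p_X`, `p_A`, `p_C`,
#'   `p_S`, `p_J` (J/d) and `r` (1/d).
#' @export
compute_fluxes <- function(state, params, f) {
  if (any(f < 0) || any(f > 1))
    stop("scaled functional response 'f' must lie in [0, 1]", call. = FALSE)
  r <- specific_growth_rate(state, params)
  feeding <- state$stage != "embryo"
  p_X <- if (feeding) f * max_ingestion_rate(params) * state$V^(2 / 3) else 0 * f
  p_A <- params$kappa_X * p_X
  p_C <- state$E * (params$v_dot * state$V^(-1 / 3) - r)
  p_S <- params$p_M_vol * state$V
  E_H_paid <- if (state$stage == "adult") params$E_H_puberty else state$E_H
  p_J <- params$k_J * E_H_paid
  structure(list(p_X = p_X, p_A = p_A, p_C = p_C, p_S = p_S, p_J = p_J, r = r),
            class = "deb_fluxes")
}

#' @export
print.deb_fluxes <- function(x, ...) {
  cat(sprintf("DEB fluxes (J/d): p_X = %g, p_A = %g, p_C = %g, p_S = %g, p_J = %g; r = %g /d\n",
              x$p_X[1], x$p_A[1], x$p_C[1], x$p_S[1], x$p_J[1], x$r[1]))
  invisible(x)
}

#' Time derivatives of the state variables
#'
#' The kappa-rule dynamics: `dE/dt = p_A - p_C`; growth is paid from the
#' somatic share of mobilization after somatic maintenance,
#' `dV/dt = (kappa * p_C - p_S) / [E_G]` (identically `r * V`); before puberty the non-somatic branch feeds
#' maturation, `dE_H/dt = (1 - kappa) p_C - p_J` with `dE_R/dt = 0`; from
#' puberty onwards maturation stops and the branch feeds reproduction.
#' Negative allocation under starvation is passed through unclamped.
#'
#' @inheritParams compute_fluxes
#' @return Named numeric vector `c(dE, dV, dE_H, dE_R)` in J/d, cm^3/d, J/d,
#'   J/d.
#' @export
state_derivatives <- function(state, params, f) {
  fx <- compute_fluxes(state, params, f)
  dE <- fx$p_A - fx$p_C
  dV <- (params$kappa * fx$p_C - fx$p_S) / params$E_G_vol
  branch <- (1 - params$kappa) * fx$p_C - fx$p_J
  if (state$stage == "adult") {
    c(dE = dE, dV = dV, dE_H = 0, dE_R = branch)
  } else {
    c(dE = dE, dV = dV, dE_H = branch, dE_R = 0)
  }
}

#' Dry and wet biomass observables
#'
#' Dry biomass combines structure and reserve with the composition constants:
#' `B = d_V * V + (w_E / mu_E) * E` (g). The reproduction buffer is excluded
#' because reproduction energy is assumed to be released continually as
#' gametes. Wet biomass is `wet_factor * B`.
#'
#' @param state a [deb_state()] object, or any list with numeric `E` and `V`
#'   (vectors allowed).
#' @param params a [deb_params()] object.
#' @return Biomass in grams.
#' @export
dry_biomass <- function(state, params) {
  if (any(state$V < 0) || any(state$E < 0))
    stop("biomass is defined for nonnegative V and E", call. = FALSE)
  params$d_V * state$V + (params$w_E / params$mu_E) * state$E
}

#' @rdname dry_biomass
#' @param B_dry dry biomass in grams (vectorized).
#' @export
wet_biomass <- function(B_dry, params) {
  if (any(B_dry < 0)) stop("dry biomass must be nonnegative", call. = FALSE)
  params$wet_factor * B_dry
}
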