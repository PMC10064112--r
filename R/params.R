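#' Species-defining parameters of the standard DEB model
#'
#' Constructs the parameter set for one species. Defaults are the values used
#' throughout the interspecific sweep: the three life-history parameters
#' (`p_Am_max`, `v_dot`, `kappa`) take the first value of their respective
#' sweep lists, and all remaining constants are the *Daphnia magna*-derived
#' values that are held fixed across species, plus the standard composition
#' constants used to convert state variables into dry biomass.
#'
#' @param p_Am_max maximum surface-area-specific assimilation rate
#'   \{p_Am\}, J/(d cm^2).
#' @param kappa_X assimilation efficiency from food to reserve (0, 1].
#' @param v_dot energy conductance, cm/d.
#' @param kappa fraction of mobilized reserve allocated to soma (0, 1).
#' @param p_M_vol volume-specific somatic maintenance cost, J/(d cm^3).
#' @param k_J maturity maintenance rate coefficient, 1/d.
#' @param E_G_vol volume-specific cost of structure, J/cm^3.
#' @param E_H_birth cumulative maturity at birth (feeding switch), J.
#' @param E_H_puberty cumulative maturity at puberty (reproduction switch), J.
#' @param E_0 initial reserve energy in the embryo, J.
#' @param delta_M shape coefficient; only used to convert structural to
#'   physical length, never in the dynamics.
#' @param d_V density of structure, g/cm^3.
#' @param w_E molar weight of reserve, g/C-mol.
#' @param mu_E chemical potential of reserve, J/C-mol.
#' @param wet_factor wet:dry biomass ratio (>= 1).
#' @param species_id optional identifier carried through sweeps.
#'
#' @return An object of class `deb_params`.
#' @examples
#' p <- deb_params()
#' reserve_capacity(p)
#' @export
deb_params <- function(p_Am_max = 2000, kappa_X = 0.9, v_dot = 0.2,
                       kappa = 0.43, p_M_vol = 1800, k_J = 0.52,
                       E_G_vol = 4400, E_H_birth = 0.55, E_H_puberty = 1.09,
                       E_0 = 0.167, delta_M = 1, d_V = 0.28, w_E = 23.9,
                       mu_E = 550000, wet_factor = 5, species_id = NULL) {
  p <- list(p_Am_max = p_Am_max, kappa_X = kappa_X, v_dot = v_dot,
            kappa = kappa, p_M_vol = p_M_vol, k_J = k_J, E_G_vol = E_G_vol,
            E_H_birth = E_H_birth, E_H_puberty = E_H_puberty, E_0 = E_0,
            delta_M = delta_M, d_V = d_V, w_E = w_E, mu_E = mu_E,
            wet_factor = wet_factor, species_id = species_id)
  validate_deb_params(p)
  class(p) <- "deb_params"
  p
}

validate_deb_params <- function(p) {
  num <- c("p_Am_max", "kappa_X", "v_dot", "kappa", "p_M_vol", "k_J",
           "E_G_vol", "E_H_birth", "E_H_puberty", "E_0", "delta_M", "d_V",
           "w_E", "mu_E", "wet_factor")
  for (nm in num) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  pos <- c("p_Am_max", "v_dot", "p_M_vol", "k_J", "E_G_vol", "E_H_birth",
           "E_H_puberty", "E_0", "delta_M", "d_V", "w_E", "mu_E")
  for (nm in pos) {
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  }
  if (p$kappa <= 0 || p$kappa >= 1)
    stop("'kappa' must lie strictly between 0 and 1", call. = FALSE)
  if (p$kappa_X <= 0 || p$kappa_X > 1)
    stop("'kappa_X' must lie in (0, 1]", call. = FALSE)
  if (p$E_H_birth >= p$E_H_puberty)
    stop("'E_H_birth' must be smaller than 'E_H_puberty'", call. = FALSE)
  if (p$wet_factor < 1)
    stop("'wet_factor' must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("Standard DEB model parameters",
      if (!is.null(x$species_id)) paste0(" [", x$species_id, "]"), "\n", sep = "")
  cat(sprintf("  {p_Am} = %g J/(d cm^2), v = %g cm/d, kappa = %g\n",
              x$p_Am_max, x$v_dot, x$kappa))
  cat(sprintf("  [p_M] = %g J/(d cm^3), k_J = %g 1/d, [E_G] = %g J/cm^3\n",
              x$p_M_vol, x$k_J, x$E_G_vol))
  cat(sprintf("  E_H^b = %g J, E_H^p = %g J, E_0 = %g J\n",
              x$E_H_birth, x$E_H_puberty, x$E_0))
  cat(sprintf("  reserve capacity [E_m] = %g J/cm^3\n", reserve_capacity(x)))
  invisible(x)
}

#' Reserve capacity
#'
#' Maximum reserve density `[E_m] = {p_Am}/v`, the ratio of the maximum
#' surface-area-specific assimilation rate to the energy conductance. At
#' constant food the reserve density `E/V` equilibrates at `f * [E_m]`.
#'
#' @param params a [deb_params()] object.
#' @return Reserve capacity in J/cm^3.
#' @export
reserve_capacity <- function(params) {
  if (params$v_dot <= 0)
    stop("energy conductance must be strictly positive", call. = FALSE)
  params$p_Am_max / params$v_dot
}

#' Maximum surface-area-specific ingestion rate
#'
#' `{p_Xm} = {p_Am}/kappa_X`, J/(d cm^2).
#'
#' @inheritParams reserve_capacity
#' @return Ingestion rate in J/(d cm^2).
#' @export
max_ingestion_rate <- function(params) {
  params$p_Am_max / params$kappa_X
}

#' Ultimate structural length and volume at constant food
#'
#' Closed-form steady state of the growth equation at constant scaled
#' functional response `f`: `L_inf = kappa * f * {p_Am} / [p_M]` (cm), with
#' ultimate structural volume `L_inf^3` (cm^3). Used to validate long
#' integrations against the analytic solution.
#'
#' @inheritParams reserve_capacity
#' @param f constant scaled functional response in \[0, 1\].
#' @return For `ultimate_length`, length in cm; for `ultimate_volume`,
#'   volume in cm^3.
#' @export
ultimate_length <- function(params, f = 1) {
  if (f < 0 || f > 1) stop("'f' must lie in [0, 1]", call. = FALSE)
  params$kappa * f * params$p_Am_max / params$p_M_vol
}

#' @rdname ultimate_length
#' @export
ultimate_volume <- function(params, f = 1) {
  ultimate_length(params, f)^3
}

#' Physical length from structural volume
#'
#' `L_physical = V^(1/3) / delta_M`; the shape coefficient only enters this
#' observable conversion, never the dynamics.
#'
#' @param V structural volume, cm^3 (vectorized).
#' @inheritParams reserve_capacity
#' @return Physical length in cm.
#' @export
physical_length <- function(V, params) {
  V^(1 / 3) / params$delta_M
}
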