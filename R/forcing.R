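#' Resource forcing: constant or seasonal scaled functional response
#'
#' The environment enters the model only through the scaled functional
#' response `f(t)` in \[0, 1\]. `constant_forcing()` holds `f` fixed;
#' `seasonal_forcing()` oscillates sinusoidally around an annual mean,
#' `f(t) = f_mean + f_amp * sin(2 * pi * t / period + phase)`, giving one
#' season of high and one of low food per period. Forcings whose range
#' leaves \[0, 1\] are rejected at construction; values are never clipped.
#'
#' @param f constant level in \[0, 1\].
#' @param f_mean annual mean level.
#' @param f_amp oscillation amplitude (>= 0); `f_mean - f_amp >= 0` and
#'   `f_mean + f_amp <= 1` are required.
#' @param phase phase offset in radians; see [start_phases()] for the four
#'   labelled birth-season offsets.
#' @param period period in days (default one year of 365 days).
#' @return An object of class `deb_forcing`.
#' @examples
#' evaluate_f(seasonal_forcing(0.6, 0.2), 91.25)
#' @export
constant_forcing <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("constant forcing level must be a single value in [0, 1]", call. = FALSE)
  structure(list(kind = "constant", f_const = f),
            class = c("deb_forcing_constant", "deb_forcing"))
}

#' @rdname constant_forcing
#' @export
seasonal_forcing <- function(f_mean, f_amp = 0.2, phase = 0, period = 365) {
  for (nm in c("f_mean", "f_amp", "phase", "period")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (f_amp < 0) stop("amplitude 'f_amp' must be nonnegative", call. = FALSE)
  if (period <= 0) stop("'period' must be positive", call. = FALSE)
  if (f_mean - f_amp < 0 || f_mean + f_amp > 1)
    stop("seasonal forcing must keep f(t) within [0, 1]: require ",
         "f_mean - f_amp >= 0 and f_mean + f_amp <= 1", call. = FALSE)
  structure(list(kind = "seasonal", f_mean = f_mean, f_amp = f_amp,
                 phase = phase, period = period),
            class = c("deb_forcing_seasonal", "deb_forcing"))
}

#' Evaluate the scaled functional response at time t
#'
#' @param forcing a [constant_forcing()] or [seasonal_forcing()] object.
#' @param t time in days (vectorized, >= 0).
#' @return `f(t)` in \[0, 1\].
#' @export
evaluate_f <- function(forcing, t) UseMethod("evaluate_f")

#' @export
evaluate_f.deb_forcing_constant <- function(forcing, t) {
  rep_len(forcing$f_const, length(t))
}

#' @export
evaluate_f.deb_forcing_seasonal <- function(forcing, t) {
  forcing$f_mean + forcing$f_amp * sin(2 * pi * t / forcing$period + forcing$phase)
}

#' @export
print.deb_forcing <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("Constant resource forcing: f = %g\n", x$f_const))
  } else {
    cat(sprintf("Seasonal resource forcing: f_mean = %g, f_amp = %g, phase = %g rad, period = %g d\n",
                x$f_mean, x$f_amp, x$phase, x$period))
  }
  invisible(x)
}

#' The four seasonal start phases
#'
#' Phase offsets placing the start of the integration (the individual's
#' birth) at four labelled points of the seasonal cycle. With the sine
#' convention of [seasonal_forcing()], `t = 0` then sits at the annual mean
#' on the rising limb (`increasing-mid`, phase 0), the seasonal maximum
#' (`maximum`, pi/2), the mean on the falling limb (`decreasing-mid`, pi) or
#' the seasonal minimum (`minimum`, 3 pi/2). These correspond to individuals
#' born at different times of the year.
#'
#' @return Named numeric vector of four phase offsets in radians.
#' @export
start_phases <- function() {
  c("increasing-mid" = 0, "maximum" = pi / 2,
    "decreasing-mid" = pi, "minimum" = 3 * pi / 2)
}
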