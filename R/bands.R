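#' Frequency band specification
#'
#' A band is defined by its edges in Hz, a centre frequency at which the
#' Morlet wavelet is evaluated, and the number of wavelet cycles. Narrow
#' bands use fewer cycles (better temporal resolution), wide high-frequency
#' bands more.
#'
#' @param name band label, e.g. "high_alpha".
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @param n_cycles number of Morlet cycles (>= 3).
#' @param center wavelet centre frequency in Hz; defaults to the band
#'   midpoint.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("high_alpha", 10, 13, n_cycles = 5)
#' @export
band_spec <- function(name, f_lo, f_hi, n_cycles, center = (f_lo + f_hi) / 2) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(f_lo > 0 && f_hi > f_lo)) stopf("need 0 < f_lo < f_hi (got %g, %g)", f_lo, f_hi)
  if (n_cycles < 3) stopf("n_cycles must be >= 3 (got %g)", n_cycles)
  if (!(center >= f_lo && center <= f_hi)) stopf("center %g Hz outside band [%g, %g]", center, f_lo, f_hi)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 center = center, n_cycles = n_cycles),
            class = "band_spec")
}

#' Canonical analysis bands
#'
#' The five bands used throughout the pipeline: theta (4-8 Hz, 3 cycles),
#' low alpha (8-10 Hz, 5 cycles), high alpha (10-13 Hz, 5 cycles), beta
#' (13-30 Hz, 7 cycles) and gamma (31-48 Hz, 9 cycles). Both alpha sub-bands
#' share the 5-cycle wavelet as the two narrow neighbours of the set.
#'
#' @return Named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(
    theta      = band_spec("theta",       4,  8, n_cycles = 3),
    low_alpha  = band_spec("low_alpha",   8, 10, n_cycles = 5),
    high_alpha = band_spec("high_alpha", 10, 13, n_cycles = 5),
    beta       = band_spec("beta",       13, 30, n_cycles = 7),
    gamma      = band_spec("gamma",      31, 48, n_cycles = 9)
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz (center %g Hz, %g cycles)\n",
              x$name, x$f_lo, x$f_hi, x$center, x$n_cycles))
  invisible(x)
}
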