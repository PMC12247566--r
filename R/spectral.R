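#' Epoched parcel time series container
#'
#' @param data epochs x parcels x samples numeric array.
#' @param fs sampling rate in Hz.
#' @param participant,condition optional labels carried through the pipeline.
#' @return An object of class `parcel_epochs`.
#' @export
parcel_epochs <- function(data, fs, participant = NA, condition = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  if (!all(is.finite(data))) stopf("non-finite samples in epoch data")
  structure(list(data = data, fs = fs, participant = participant,
                 condition = condition),
            class = "parcel_epochs")
}

#' @export
print.parcel_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<parcel_epochs> %d epochs x %d parcels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

# complex Morlet kernel sampled at fs, exactly zero-mean so the transform is
# invariant to DC offsets; truncated at 3.5 temporal SDs
morlet_kernel <- function(fs, center, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * center)
  h <- ceiling(3.5 * sigma_t * fs)
  tau <- (-h:h) / fs
  g <- exp(-tau^2 / (2 * sigma_t^2))
  osc <- exp(2i * pi * center * tau)
  kappa <- sum(g * osc) / sum(g)
  w <- (osc - kappa) * g
  w <- w / sqrt(sum(Mod(w)^2))
  list(w = w, half = h)
}

# linear convolution of each column of mat (samples x series) with the
# analytic kernel; returns valid-sample coefficients ((n - 2h) x series)
morlet_convolve <- function(mat, kern) {
  n <- nrow(mat); h <- kern$half; p <- 2L * h + 1L
  if (n < p) stopf("epoch too short for wavelet support: need >= %d samples, got %d", p, n)
  # correlation with the kernel == convolution with its reverse
  kr <- rev(Conj(kern$w))
  L <- n + p - 1L
  K <- stats::fft(c(kr, rep(0, L - p)))
  pad <- rbind(mat, matrix(0, L - n, ncol(mat)))
  Y <- stats::mvfft(stats::mvfft(pad + 0i) * K, inverse = TRUE) / L
  Y[(p):(n), , drop = FALSE]
}

#' Instantaneous phase via complex Morlet wavelet
#'
#' Convolves every epoch and parcel with a zero-mean complex Morlet wavelet
#' at the band's centre frequency and returns the argument of the analytic
#' coefficient, wrapped to (-pi, pi]. Samples within half the wavelet
#' support of either epoch edge are marked invalid (NA) and excluded from
#' all downstream sample counts.
#'
#' @param series a [parcel_epochs()] object (or plain 3D array with `fs`).
#' @param band a [band_spec()].
#' @param fs sampling rate, only needed when `series` is a bare array.
#' @return An object of class `phase_tensor`: list with `phase`
#'   (epochs x parcels x samples, NA outside the valid window), `valid`
#'   (valid sample indices), `band`, `fs`.
#' @export
morlet_phase <- function(series, band, fs = NULL) {
  x <- as_epoch_array(series, fs)
  d <- dim(x$data)
  kern <- morlet_kernel(x$fs, band$center, band$n_cycles)
  coef <- epoch_coefficients(x$data, kern)
  ph <- Arg(coef)
  ph[ph <= -pi] <- pi # wrap (-pi, pi]
  n_valid <- d[3] - 2L * kern$half
  full <- array(NA_real_, d)
  full[, , (kern$half + 1L):(d[3] - kern$half)] <- aperm(
    array(ph, c(n_valid, d[1], d[2])), c(2, 3, 1))
  structure(list(phase = full,
                 valid = (kern$half + 1L):(d[3] - kern$half),
                 band = band, fs = x$fs),
            class = "phase_tensor")
}

#' Per-epoch band power
#'
#' Power is the mean squared magnitude of the Morlet coefficient over the
#' valid samples of each epoch and parcel, with a natural-log column for
#' statistics. Epochs with zero power (all-zero signal) are excluded with a
#' warning.
#'
#' @inheritParams morlet_phase
#' @return data.frame with columns epoch, parcel, power, log_power.
#' @export
band_power <- function(series, band, fs = NULL) {
  x <- as_epoch_array(series, fs)
  d <- dim(x$data)
  kern <- morlet_kernel(x$fs, band$center, band$n_cycles)
  coef <- epoch_coefficients(x$data, kern)
  pow <- colMeans(Mod(coef)^2)
  out <- data.frame(epoch = rep(seq_len(d[1]), times = d[2]),
                    parcel = rep(seq_len(d[2]), each = d[1]),
                    power = pow)
  bad <- out$power <= 0
  if (any(bad)) {
    warning(sprintf("%d epoch/parcel cells with zero band power excluded", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out$log_power <- log(out$power)
  out
}

# shared plumbing: accept parcel_epochs or bare array
as_epoch_array <- function(series, fs) {
  if (inherits(series, "parcel_epochs")) return(series)
  if (is.array(series) && length(dim(series)) == 3L) {
    if (is.null(fs)) stopf("fs required when passing a bare array")
    return(parcel_epochs(series, fs))
  }
  stopf("series must be a parcel_epochs object or epochs x parcels x samples array")
}

# run the convolution with epochs*parcels as columns;
# returns n_valid x (epochs*parcels), column-major in (epoch, parcel)
epoch_coefficients <- function(arr, kern) {
  d <- dim(arr)
  mat <- matrix(aperm(arr, c(3, 1, 2)), nrow = d[3])
  morlet_convolve(mat, kern)
}
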