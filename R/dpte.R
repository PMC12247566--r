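#' Analysis delay for phase transfer entropy
#'
#' The prediction delay (in samples) is set from the oscillatory content of
#' the band-limited signals themselves: `delay = round(N * S / X0)`, where N
#' is the number of valid samples per epoch, S the number of signals
#' (parcels), and X0 the number of sign changes of the real band-limited
#' signal (`cos(phase)`) counted across all S signals over those N samples.
#' With multiple epochs, X0 is the mean per-epoch count, so the delay is a
#' per-recording quantity. Rounding is half-away-from-zero, floored at 1.
#'
#' @param phase a `phase_tensor` from [morlet_phase()].
#' @return integer delay in samples.
#' @export
compute_delay <- function(phase) {
  stopifnot(inherits(phase, "phase_tensor"))
  v <- phase$valid
  d <- dim(phase$phase)
  N <- length(v); S <- d[2]
  x <- cos(phase$phase[, , v, drop = FALSE])
  sgn <- x >= 0
  changes <- sgn[, , -1L, drop = FALSE] != sgn[, , -length(v), drop = FALSE]
  x0_per_epoch <- apply(changes, 1, sum)
  x0 <- mean(x0_per_epoch)
  if (x0 == 0) stopf("no sign changes in any signal: delay undefined for constant phase")
  max(1L, as.integer(round_half_up(N * S / x0)))
}

#' Histogram bin count for phase discretization
#'
#' Number of uniform bins on (-pi, pi]: `round(exp(0.626 + 0.4 * ln(N - 1)))`
#' with N the number of valid samples per epoch, floored at 2.
#'
#' @param N valid sample count (>= 2).
#' @return integer bin count.
#' @examples
#' compute_n_bins(400) # 21
#' @export
compute_n_bins <- function(N) {
  if (N < 2) stopf("need N >= 2 samples to bin (got %g)", N)
  max(2L, as.integer(round_half_up(exp(0.626 + 0.4 * log(N - 1)))))
}

#' PTE estimator parameters
#'
#' @param delay prediction delay in samples (>= 1).
#' @param n_bins number of uniform phase bins (>= 2).
#' @param band optional [band_spec()] carried for bookkeeping.
#' @return object of class `pte_params`.
#' @export
pte_params <- function(delay, n_bins, band = NULL) {
  stopifnot(delay >= 1, delay == round(delay), n_bins >= 2, n_bins == round(n_bins))
  structure(list(delay = as.integer(delay), n_bins = as.integer(n_bins), band = band),
            class = "pte_params")
}

# discretize wrapped phase into 1..B uniform bins on (-pi, pi];
# left-open/right-closed, so exactly pi lands in the last bin
discretize_phase <- function(ph, n_bins) {
  b <- ceiling((ph + pi) / (2 * pi) * n_bins)
  b[b < 1L] <- 1L
  b[b > n_bins] <- n_bins
  as.integer(b)
}

# joint (target_now, target_past, source_past) counts -> the four plug-in
# entropies of the PTE decomposition, in bits
pte_from_bins <- function(bx, by, delay, n_bins) {
  n <- length(by)
  yt <- by[(delay + 1L):n]
  yp <- by[1L:(n - delay)]
  xp <- bx[1L:(n - delay)]
  B <- n_bins
  code <- yt + B * (yp - 1L) + B * B * (xp - 1L)
  c3 <- array(tabulate(code, nbins = B^3), c(B, B, B))
  m <- length(yt)
  ent <- function(cnt) {
    p <- cnt[cnt > 0] / m
    -sum(p * log2(p))
  }
  c_yt_yp <- rowSums(c3, dims = 2)            # sum over source dim
  c_yp_xp <- colSums(c3)                      # sum over target-now dim
  c_yp <- rowSums(c_yp_xp)
  ent(c_yt_yp) + ent(c_yp_xp) - ent(c_yp) - ent(c3)
}

#' Phase transfer entropy between two phase series
#'
#' Plug-in transfer entropy on discretized instantaneous phase: how much the
#' source's past phase improves prediction of the target's present phase
#' beyond the target's own past,
#' `PTE(x->y) = H(y_t, y_{t-d}) + H(y_{t-d}, x_{t-d}) - H(y_{t-d}) -
#' H(y_t, y_{t-d}, x_{t-d})`, entropies in bits from joint histograms over
#' within-epoch sample pairs. Non-negative by construction (a plug-in
#' conditional mutual information); empty bins contribute zero.
#'
#' @param phase_x,phase_y numeric phase vectors in (-pi, pi], equal length.
#' @param params a [pte_params()].
#' @return non-negative scalar PTE in bits.
#' @export
pte <- function(phase_x, phase_y, params) {
  n <- length(phase_y)
  if (length(phase_x) != n) stopf("phase series must have equal length")
  if (n <= params$delay) stopf("series length %d <= delay %d", n, params$delay)
  bx <- discretize_phase(phase_x, params$n_bins)
  by <- discretize_phase(phase_y, params$n_bins)
  max(0, pte_from_bins(bx, by, params$delay, params$n_bins))
}

#' Directed PTE matrix for one epoch
#'
#' For every ordered parcel pair, dPTE normalizes the two directed transfer
#' entropies: `dPTE(x->y) = PTE(x->y) / (PTE(x->y) + PTE(y->x))`, in [0, 1]
#' with 0.5 meaning no preferred direction. The diagonal is fixed at 0.5 and
#' degenerate pairs (both PTEs zero) are set to 0.5.
#'
#' @param phase a `phase_tensor`.
#' @param params a [pte_params()].
#' @param epoch epoch index.
#' @return parcels x parcels matrix of class `dpte_matrix`; entry (x, y) is
#'   the flow x -> y, and entry(x, y) + entry(y, x) == 1.
#' @export
dpte_epoch <- function(phase, params, epoch) {
  stopifnot(inherits(phase, "phase_tensor"))
  d <- dim(phase$phase)
  if (epoch < 1 || epoch > d[1]) stopf("epoch index %d out of range", epoch)
  P <- d[2]
  ph <- phase$phase[epoch, , phase$valid, drop = FALSE]
  bins <- matrix(discretize_phase(ph, params$n_bins), nrow = P)
  M <- matrix(0.5, P, P)
  for (x in seq_len(P - 1L)) {
    for (y in (x + 1L):P) {
      xy <- max(0, pte_from_bins(bins[x, ], bins[y, ], params$delay, params$n_bins))
      yx <- max(0, pte_from_bins(bins[y, ], bins[x, ], params$delay, params$n_bins))
      tot <- xy + yx
      M[x, y] <- if (tot > 0) xy / tot else 0.5
      M[y, x] <- 1 - M[x, y]
    }
  }
  class(M) <- c("dpte_matrix", class(M))
  M
}

#' Long-format connection table over all epochs
#'
#' One row per epoch per unordered parcel pair, with the dPTE oriented by
#' the pair convention (lower parcel index is the source side), so
#' re-orienting a pair maps dPTE to 1 - dPTE.
#'
#' @param matrices list of `dpte_matrix` (one per epoch, same parcellation).
#' @param participant,condition labels attached to every row.
#' @return data.frame (participant, condition, epoch, x, y, pair, dpte)
#'   with `epochs * P * (P - 1) / 2` rows.
#' @export
connection_table <- function(matrices, participant = NA, condition = NA_character_) {
  if (length(matrices) == 0L) stopf("no epochs")
  P <- nrow(matrices[[1]])
  if (!all(vapply(matrices, nrow, 1L) == P)) stopf("mixed parcellations across epochs")
  ut <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  vals <- vapply(matrices, function(m) m[ut], numeric(nrow(ut)))
  data.frame(
    participant = participant,
    condition = condition,
    epoch = rep(seq_along(matrices), each = nrow(ut)),
    x = rep(ut[, 1], times = length(matrices)),
    y = rep(ut[, 2], times = length(matrices)),
    pair = rep(paste0(ut[, 1], "-", ut[, 2]), times = length(matrices)),
    dpte = as.vector(vals)
  )
}

#' dPTE parameters and matrices for a whole recording
#'
#' Convenience wrapper: derives the delay and bin count from the phase
#' tensor itself (one delay/bin setting per band per recording, logged in
#' the result), then computes the per-epoch matrices.
#'
#' @param phase a `phase_tensor`.
#' @param params optional [pte_params()]; derived from the data when NULL.
#' @return list with `params` and `matrices` (list of per-epoch matrices).
#' @export
dpte_epochs <- function(phase, params = NULL) {
  if (is.null(params)) {
    params <- pte_params(compute_delay(phase),
                         compute_n_bins(length(phase$valid)),
                         band = phase$band)
  }
  n_epochs <- dim(phase$phase)[1]
  mats <- lapply(seq_len(n_epochs), function(e) dpte_epoch(phase, params, e))
  list(params = params, matrices = mats)
}
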