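# shared fixtures, all generated in code at test time

fixture_band <- function() band_spec("high_alpha", 10, 13, n_cycles = 5)

# tiny two-parcel coupled block: parcel 1 drives parcel 2
fixture_coupled_block <- function(epochs = 30, gain = 0.8, condition = "rest",
                                  seed = 11, n_parcels = 2) {
  net <- make_network(n_parcels,
                      data.frame(from = 1, to = 2, lag = 10, gain = gain),
                      condition_gains = list(rest = 1, task = 0))
  spec <- cohort_spec(n_participants = 1, conditions = c("rest", "task"),
                      epochs_per_condition = epochs, seed = seed)
  simulate_epochs(net, spec, 1, condition)
}

# wrap a bare phase array as a phase_tensor (all samples valid)
fixture_phase_tensor <- function(arr, fs = 200, band = fixture_band()) {
  structure(list(phase = arr, valid = seq_len(dim(arr)[3]), band = band, fs = fs),
            class = "phase_tensor")
}

# long connection table of independent dPTE rows for n_pairs connections
fixture_null_table <- function(n_pairs = 6, n_participants = 6,
                               epochs_per_condition = 20,
                               conditions = c("rest", "a", "b"),
                               sd = 0.05, seed = 1) {
  set.seed(seed)
  units <- expand.grid(epoch = seq_len(epochs_per_condition),
                       condition = conditions,
                       participant = seq_len(n_participants),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    cbind(units, pair = sprintf("%d-%d", 1, k + 1),
          x = 1L, y = k + 1L,
          dpte = 0.5 + rnorm(nrow(units), 0, sd))
  }))
}

# naive triple-loop PTE oracle: builds every histogram with explicit loops,
# independent of the package's tabulate/margin path
oracle_pte <- function(phase_x, phase_y, delay, n_bins) {
  bin_of <- function(p) {
    b <- ceiling((p + pi) / (2 * pi) * n_bins)
    min(max(b, 1), n_bins)
  }
  bx <- vapply(phase_x, bin_of, 1)
  by <- vapply(phase_y, bin_of, 1)
  n <- length(by)
  idx <- (delay + 1):n
  m <- length(idx)
  h3 <- array(0, c(n_bins, n_bins, n_bins))
  for (t in idx) h3[by[t], by[t - delay], bx[t - delay]] <-
    h3[by[t], by[t - delay], bx[t - delay]] + 1
  H <- function(p) { p <- p[p > 0] / m; -sum(p * log2(p)) }
  h_yt_yp <- matrix(0, n_bins, n_bins)
  h_yp_xp <- matrix(0, n_bins, n_bins)
  h_yp <- numeric(n_bins)
  for (a in 1:n_bins) for (b in 1:n_bins) for (cc in 1:n_bins) {
    h_yt_yp[a, b] <- h_yt_yp[a, b] + h3[a, b, cc]
    h_yp_xp[b, cc] <- h_yp_xp[b, cc] + h3[a, b, cc]
    h_yp[b] <- h_yp[b] + h3[a, b, cc]
  }
  H(h_yt_yp) + H(h_yp_xp) - H(h_yp) - H(h3)
}
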