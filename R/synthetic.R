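#' Ground-truth directed coupling network
#'
#' Defines the recovery target for synthetic cohorts: directed edges between
#' parcels with a transmission lag (samples), a base coupling gain, a
#' per-condition multiplicative gain factor, and a coefficient linking
#' realized inflow to target-parcel amplitude (so stronger inflow can lower
#' local band power, or vice versa).
#'
#' @param n_parcels number of parcels.
#' @param edges data.frame with columns `from`, `to`, `lag`, `gain`
#'   (1-based parcel indices; lag in samples >= 1; gain in [0, 1]).
#' @param condition_gains named list: condition label -> multiplicative gain
#'   factor (scalar, or one value per edge), all >= 0.
#' @param power_coupling coefficient linking an edge's realized gain to
#'   target-parcel amplitude scaling `1 - power_coupling * gain` (floored).
#' @param seed integer recorded with the network (construction is
#'   deterministic).
#' @return object of class `ground_truth_network`.
#' @examples
#' make_network(4, data.frame(from = 1, to = 2, lag = 10, gain = 0.8),
#'              condition_gains = list(rest = 1, task = 0.1))
#' @export
make_network <- function(n_parcels, edges, condition_gains,
                         power_coupling = 0, seed = 0L) {
  stopifnot(n_parcels >= 1)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "lag", "gain") %in% names(edges)))
    if (!all(edges$from %in% seq_len(n_parcels)) ||
        !all(edges$to %in% seq_len(n_parcels)))
      stopf("edge endpoints out of range 1..%d", n_parcels)
    if (any(edges$from == edges$to)) stopf("self-loop edges are not allowed")
    if (any(edges$lag < 1)) stopf("edge lags must be >= 1 sample")
    if (any(!is.finite(edges$gain)) || any(edges$gain < 0))
      stopf("edge gains must be finite and >= 0")
  }
  cg <- lapply(condition_gains, function(v) {
    v <- rep_len(as.numeric(v), max(1L, nrow(edges)))
    if (any(!is.finite(v)) || any(v < 0)) stopf("condition gains must be finite and >= 0")
    v
  })
  structure(list(n_parcels = as.integer(n_parcels), edges = edges,
                 condition_gains = cg, power_coupling = power_coupling,
                 seed = as.integer(seed)),
            class = "ground_truth_network")
}

#' Synthetic cohort specification
#'
#' The cohort structure emulated by the generator: 24 participants, five
#' condition labels with rest first, 2-second epochs at 200 Hz, band-limited
#' stochastic oscillators plus 1/f background noise, and a participant
#' random offset perturbing gains and amplitudes.
#'
#' @param n_participants number of participants.
#' @param conditions condition labels, "rest" first.
#' @param epochs_per_condition epochs per participant and condition.
#' @param fs sampling rate (Hz).
#' @param epoch_len epoch length (seconds); `epoch_len * fs` must be an
#'   integer >= 64.
#' @param band [band_spec()] of the oscillatory carrier.
#' @param participant_sd SD of the per-participant log-scale offset applied
#'   to edge gains and parcel amplitudes.
#' @param noise_exponent spectral slope of the 1/f background noise.
#' @param snr in-band oscillation-to-noise amplitude ratio. Phase-based
#'   connectivity is only meaningful when phase dynamics are dominated by
#'   the oscillation; below an in-band ratio of about 4 the direction of
#'   even a pure relay becomes unrecoverable, so the default (8) emulates a
#'   strong, reliably measurable alpha generator.
#' @param amp_floor positive floor for the power-coupled amplitude scaling.
#' @param seed master seed; per-(participant, condition) streams are derived
#'   from it so any block is independently reproducible.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 24,
                        conditions = c("rest", "audio", "visual",
                                       "visual_distraction", "counting"),
                        epochs_per_condition = 60,
                        fs = 200, epoch_len = 2,
                        band = band_spec("high_alpha", 10, 13, n_cycles = 5),
                        participant_sd = 0.1,
                        noise_exponent = 1,
                        snr = 8,
                        amp_floor = 0.1,
                        seed = 1L) {
  n <- epoch_len * fs
  if (abs(n - round(n)) > 1e-9 || n < 64) stopf("epoch_len * fs must be an integer >= 64")
  if (length(conditions) == 0 || anyDuplicated(conditions))
    stopf("conditions must be non-empty and unique")
  if (conditions[1] != "rest") stopf("'rest' must be the first condition")
  stopifnot(inherits(band, "band_spec"), participant_sd >= 0, snr > 0, amp_floor > 0)
  structure(list(n_participants = as.integer(n_participants),
                 conditions = conditions,
                 epochs_per_condition = as.integer(epochs_per_condition),
                 fs = fs, epoch_len = epoch_len, n_samples = as.integer(round(n)),
                 band = band, participant_sd = participant_sd,
                 noise_exponent = noise_exponent, snr = snr,
                 amp_floor = amp_floor, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Per-participant random offsets
#'
#' One log-scale offset per participant, drawn once from the cohort master
#' seed; `exp(offset)` multiplies edge gains and parcel amplitudes in every
#' block of that participant.
#'
#' @param spec a [cohort_spec()].
#' @return numeric vector of length `n_participants`.
#' @export
participant_offsets <- function(spec) {
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    stats::rnorm(spec$n_participants, 0, spec$participant_sd)
  })
  rng
}

# 1/f-shaped noise columns, length L, slope alpha (power ~ f^-alpha)
one_over_f_noise <- function(L, ncol, alpha) {
  f <- c(1, seq_len(L - 1))                       # avoid DC blow-up
  f <- pmin(f, L - f + 1)                         # two-sided spectrum
  shape <- f^(-alpha / 2)
  W <- stats::mvfft(matrix(stats::rnorm(L * ncol), L, ncol) + 0i)
  Re(stats::mvfft(W * shape, inverse = TRUE)) / L
}

#' Simulate one participant/condition block of parcel time series
#'
#' Each parcel carries a band-limited stochastic oscillator (band-pass
#' filtered Gaussian noise, Butterworth at the band edges) plus 1/f
#' background noise. For every network edge, the target parcel's
#' oscillatory component mixes in the source oscillation delayed by the
#' edge lag with weight `g = gain * condition_gain * exp(participant
#' offset)`, while the endogenous carrier is attenuated to `(1 - G)^2`
#' (G = total realized inflow gain, capped at 1): the gain is the source's
#' share of the target's oscillatory drive, so at full gain the target is
#' a pure delayed relay. The target's oscillation amplitude is further
#' scaled by `1 - power_coupling * G` (floored at `amp_floor`), so weaker
#' inflow means higher local band power. Reproducible from
#' (seed, participant, condition) alone.
#'
#' @param net a [make_network()] object.
#' @param spec a [cohort_spec()]; conditions must name entries of
#'   `net$condition_gains`.
#' @param participant participant index (1-based).
#' @param condition condition label in `spec$conditions`.
#' @return a [parcel_epochs()] object
#'   (`epochs_per_condition` x `n_parcels` x `n_samples`).
#' @export
simulate_epochs <- function(net, spec, participant, condition) {
  ci <- match(condition, spec$conditions)
  if (is.na(ci)) stopf("unknown condition '%s'", condition)
  if (!condition %in% names(net$condition_gains))
    stopf("network has no condition gains for '%s'", condition)
  stopifnot(participant >= 1, participant <= spec$n_participants)

  P <- net$n_parcels
  n <- spec$n_samples
  E <- spec$epochs_per_condition
  edges <- net$edges
  max_lag <- if (nrow(edges)) max(edges$lag) else 0L
  pad <- as.integer(spec$fs) + max_lag
  L <- n + pad
  win <- (pad + 1L):(pad + n)

  off <- participant_offsets(spec)[participant]
  gmult <- exp(off)
  eff_gain <- if (nrow(edges))
    edges$gain * net$condition_gains[[condition]] * gmult else numeric(0)
  inflow_gain <- if (nrow(edges))
    vapply(seq_len(P), function(t) sum(eff_gain[edges$to == t]), 0) else rep(0, P)
  amp <- gmult * pmax(spec$amp_floor, 1 - net$power_coupling * inflow_gain)

  bf <- signal::butter(2, c(spec$band$f_lo, spec$band$f_hi) / (spec$fs / 2), type = "pass")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(stream_seed(spec$seed, participant, ci))

  out <- array(NA_real_, c(E, P, n))
  for (e in seq_len(E)) {
    osc <- matrix(stats::rnorm(L * P), L, P)
    for (p in seq_len(P)) osc[, p] <- signal::filtfilt(bf, osc[, p])
    osc <- sweep(osc, 2, apply(osc[win, , drop = FALSE], 2, stats::sd), "/")

    own_w <- (1 - pmin(inflow_gain, 1))^2
    mixed <- sweep(osc, 2, own_w, "*")
    if (nrow(edges)) {
      for (k in seq_len(nrow(edges))) {
        lag <- edges$lag[k]
        mixed[, edges$to[k]] <- mixed[, edges$to[k]] +
          eff_gain[k] * c(rep(0, lag), osc[seq_len(L - lag), edges$from[k]])
      }
    }
    mixed <- sweep(mixed, 2, amp, "*")

    noi <- one_over_f_noise(L, P, spec$noise_exponent)
    for (p in seq_len(P)) {
      nb <- signal::filtfilt(bf, noi[, p])
      target_sd <- stats::sd(mixed[win, p]) / spec$snr
      noi[, p] <- noi[, p] * target_sd / stats::sd(nb[win])
    }
    sig <- mixed[win, , drop = FALSE] + noi[win, , drop = FALSE]
    out[e, , ] <- t(sweep(sig, 2, colMeans(sig), "-"))
  }
  parcel_epochs(out, spec$fs, participant = participant, condition = condition)
}

#' Generate a full synthetic cohort
#'
#' Every participant/condition block from [simulate_epochs()], plus the
#' network and spec as metadata. Fully reproducible from the spec seed.
#'
#' @inheritParams simulate_epochs
#' @return object of class `cohort`: `blocks[[participant]][[condition]]`,
#'   `net`, `spec`.
#' @export
generate_cohort <- function(net, spec) {
  blocks <- lapply(seq_len(spec$n_participants), function(pt) {
    bl <- lapply(spec$conditions, function(cd) simulate_epochs(net, spec, pt, cd))
    names(bl) <- spec$conditions
    bl
  })
  structure(list(blocks = blocks, net = net, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants x %d conditions x %d epochs (%d parcels, %g Hz)\n",
              x$spec$n_participants, length(x$spec$conditions),
              x$spec$epochs_per_condition, x$net$n_parcels, x$spec$fs))
  invisible(x)
}

#' Simulate per-epoch dPTE rows for one connection
#'
#' Direct simulation at the statistic level (no signal synthesis), for
#' parameter-recovery checks of the model ladder: dPTE = 0.5 + participant
#' offset + condition effect + residual noise.
#'
#' @param n_participants,epochs_per_condition design size.
#' @param conditions condition labels, rest first.
#' @param effects named condition effects in dPTE units (rest implicitly 0).
#' @param participant_sd SD of the participant random intercept.
#' @param resid_sd residual SD of per-epoch dPTE.
#' @param seed RNG seed.
#' @return data.frame (participant, condition, epoch, dpte).
#' @export
simulate_connection <- function(n_participants, epochs_per_condition,
                                conditions = c("rest", "task"),
                                effects = c(task = 0),
                                participant_sd = 0.01, resid_sd = 0.05,
                                seed = 1L) {
  set.seed(seed)
  b <- stats::rnorm(n_participants, 0, participant_sd)
  grid <- expand.grid(epoch = seq_len(epochs_per_condition),
                      condition = conditions,
                      participant = seq_len(n_participants),
                      stringsAsFactors = FALSE)
  eff <- ifelse(grid$condition == "rest", 0, effects[grid$condition])
  eff[is.na(eff)] <- 0
  grid$dpte <- 0.5 + b[grid$participant] + eff +
    stats::rnorm(nrow(grid), 0, resid_sd)
  grid[, c("participant", "condition", "epoch", "dpte")]
}

#' Simulate matched hub-flow and log-power records
#'
#' Statistic-level generator for the flow-power association models:
#' `log_power = intercept + condition shift + slope[condition] * flow +
#' participant offset + noise`, with flow drawn per epoch.
#'
#' @param n_participants,epochs_per_condition design size.
#' @param conditions condition labels, rest first.
#' @param slopes named per-condition slopes (log-power per unit dPTE sum);
#'   must include every condition.
#' @param cond_shift named per-condition intercept shifts (rest 0).
#' @param flow_sd SD of the per-epoch flow values (centred on flow_mean).
#' @param flow_mean mean flow.
#' @param participant_sd,resid_sd random-intercept and residual SDs.
#' @param seed RNG seed.
#' @return data.frame (participant, condition, epoch, flow, log_power).
#' @export
simulate_flow_power <- function(n_participants, epochs_per_condition,
                                conditions = c("rest", "audio", "visual"),
                                slopes = c(rest = 0, audio = -1, visual = -1),
                                cond_shift = NULL,
                                flow_sd = 0.1, flow_mean = 0.2,
                                participant_sd = 0.05, resid_sd = 0.3,
                                seed = 1L) {
  if (!all(conditions %in% names(slopes))) stopf("slopes must name every condition")
  set.seed(seed)
  b <- stats::rnorm(n_participants, 0, participant_sd)
  grid <- expand.grid(epoch = seq_len(epochs_per_condition),
                      condition = conditions,
                      participant = seq_len(n_participants),
                      stringsAsFactors = FALSE)
  shift <- if (is.null(cond_shift)) rep(0, nrow(grid)) else {
    s <- cond_shift[grid$condition]; s[is.na(s)] <- 0; s
  }
  grid$flow <- stats::rnorm(nrow(grid), flow_mean, flow_sd)
  grid$log_power <- b[grid$participant] + shift +
    slopes[grid$condition] * grid$flow + stats::rnorm(nrow(grid), 0, resid_sd)
  grid[, c("participant", "condition", "epoch", "flow", "log_power")]
}
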