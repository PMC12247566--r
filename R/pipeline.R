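#' Connection table for a whole cohort in one band
#'
#' Runs the spectral and dPTE stages over every participant/condition
#' block: Morlet phase, one delay and bin count derived per band for the
#' whole cohort (sign-change statistics pooled across blocks), per-epoch
#' dPTE matrices, and the stacked long-format connection table.
#'
#' @param cohort a [generate_cohort()] object (or one read back from disk).
#' @param band a [band_spec()].
#' @param params optional [pte_params()] override.
#' @return list with `params` and `table` (long connection table with
#'   participant/condition/epoch labels).
#' @export
cohort_connections <- function(cohort, band, params = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  phases <- list()
  i <- 0L
  for (pt in seq_along(cohort$blocks)) {
    for (cd in names(cohort$blocks[[pt]])) {
      i <- i + 1L
      phases[[i]] <- list(pt = pt, cd = cd,
                          phase = morlet_phase(cohort$blocks[[pt]][[cd]], band))
    }
  }
  if (is.null(params)) {
    # pooled delay: mean per-epoch sign-change count across all blocks
    N <- length(phases[[1]]$phase$valid)
    S <- dim(phases[[1]]$phase$phase)[2]
    x0 <- mean(vapply(phases, function(b) {
      x <- cos(b$phase$phase[, , b$phase$valid, drop = FALSE])
      sgn <- x >= 0
      nv <- dim(sgn)[3]
      mean(apply(sgn[, , -1L, drop = FALSE] != sgn[, , -nv, drop = FALSE], 1, sum))
    }, numeric(1)))
    if (x0 == 0) stopf("constant signals: delay undefined")
    params <- pte_params(max(1L, as.integer(round_half_up(N * S / x0))),
                         compute_n_bins(N), band = band)
  }
  tabs <- lapply(phases, function(b) {
    mats <- dpte_epochs(b$phase, params)$matrices
    connection_table(mats, participant = b$pt, condition = b$cd)
  })
  list(params = params, table = do.call(rbind, tabs))
}

#' Per-epoch band power table for a whole cohort
#'
#' @inheritParams cohort_connections
#' @return data.frame (participant, condition, epoch, parcel, power,
#'   log_power).
#' @export
cohort_band_power <- function(cohort, band) {
  stopifnot(inherits(cohort, "cohort"))
  out <- list(); i <- 0L
  for (pt in seq_along(cohort$blocks)) {
    for (cd in names(cohort$blocks[[pt]])) {
      i <- i + 1L
      bp <- band_power(cohort$blocks[[pt]][[cd]], band)
      bp <- cbind(participant = pt, condition = cd, bp)
      out[[i]] <- bp
    }
  }
  do.call(rbind, out)
}

#' Fit the model ladder for every connection
#'
#' @param tbl long connection table.
#' @param rest_label reference condition.
#' @return data.frame with one row per connection: AICs and deltas.
#' @export
fit_all_ladders <- function(tbl, rest_label = "rest") {
  pairs <- unique(tbl$pair)
  rows <- lapply(pairs, function(pr) {
    f <- fit_ladder(tbl[tbl$pair == pr, , drop = FALSE], rest_label)
    data.frame(pair = pr, aic_null = f$aic_null, aic_simple = f$aic_simple,
               aic_full = f$aic_full, delta_simple = f$delta_simple,
               delta_full = f$delta_full, converged = f$converged)
  })
  do.call(rbind, rows)
}
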