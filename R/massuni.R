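# fixed-effect design matrices for the three-model ladder; rest is always
# the reference level
ladder_designs <- function(condition, rest_label = "rest") {
  condition <- as.character(condition)
  if (!rest_label %in% condition) stopf("reference level '%s' absent from data", rest_label)
  lev <- c(rest_label, sort(setdiff(unique(condition), rest_label)))
  f <- factor(condition, levels = lev)
  X_null <- matrix(1, length(f), 1, dimnames = list(NULL, "(Intercept)"))
  X_simple <- cbind("(Intercept)" = 1, task = as.numeric(f != rest_label))
  X_full <- stats::model.matrix(~f)
  colnames(X_full) <- c("(Intercept)", paste0("condition", lev[-1]))
  list(null = X_null, simple = X_simple, full = X_full, levels = lev)
}

#' Fit the null / simple-task / full-task model ladder for one connection
#'
#' Each epoch is a data point and participant is a random intercept. The
#' three nested models share that random-effect structure and differ only
#' in fixed effects: intercept only (null), a rest-vs-task indicator
#' (simple), and the full condition factor with rest as reference (full).
#' All fits are maximum likelihood so the AICs are comparable.
#'
#' @param rows data.frame with columns `dpte` (or `value`), `condition`,
#'   `participant`; needs >= 2 participants, >= 2 conditions, >= 10 rows.
#' @param rest_label reference condition label.
#' @return object of class `ladder_fit`: AICs, AIC deltas
#'   (`delta_simple = aic_null - aic_simple`,
#'   `delta_full = aic_simple - aic_full`), and coefficient tables with 95%
#'   Wald intervals for the simple and full models.
#' @export
fit_ladder <- function(rows, rest_label = "rest") {
  y <- rows$dpte %||% rows$value
  if (is.null(y)) stopf("rows must have a 'dpte' or 'value' column")
  if (length(unique(rows$participant)) < 2) stopf("need >= 2 participants")
  if (length(unique(rows$condition)) < 2) stopf("need >= 2 conditions")
  if (nrow(rows) < 10) stopf("need >= 10 rows")
  dz <- ladder_designs(rows$condition, rest_label)
  g <- rows$participant
  f_null <- lmm_ml(dz$null, y, g)
  f_simple <- lmm_ml(dz$simple, y, g)
  f_full <- lmm_ml(dz$full, y, g)
  ok <- all(is.finite(c(f_null$aic, f_simple$aic, f_full$aic)))
  structure(list(
    aic_null = f_null$aic, aic_simple = f_simple$aic, aic_full = f_full$aic,
    delta_simple = f_null$aic - f_simple$aic,
    delta_full = f_simple$aic - f_full$aic,
    logLik = c(null = f_null$logLik, simple = f_simple$logLik, full = f_full$logLik),
    coef_simple = lmm_confint(f_simple),
    coef_full = lmm_confint(f_full),
    converged = ok, levels = dz$levels
  ), class = "ladder_fit")
}

#' @export
print.ladder_fit <- function(x, ...) {
  cat(sprintf("<ladder_fit> AIC null %.2f | simple %.2f | full %.2f  (d_simple %.2f, d_full %.2f)\n",
              x$aic_null, x$aic_simple, x$aic_full, x$delta_simple, x$delta_full))
  invisible(x)
}

#' Permutation-calibrated AIC-delta significance thresholds
#'
#' Condition labels are shuffled within each participant's epochs `n_perm`
#' times and the simple and full task models are refit to every connection
#' under each shuffle. For the simple-vs-null comparison, the AIC reduction
#' relative to each connection's (permutation-invariant) null model is
#' recorded; for the full-vs-simple comparison, the permuted full-model AIC
#' is subtracted from the connection's average permuted simple-model AIC.
#' For each connection the greatest reduction across permutations is kept,
#' and the threshold is the `1 - quantile` (upper-tail) point of those
#' per-connection maxima across all connections — a max-statistic control
#' of the mass-univariate multiplicity.
#'
#' Internally the label shuffle is applied as the equivalent inverse
#' permutation of the responses within participant, so the design-side
#' sufficient statistics are shared across all shuffles.
#'
#' @param tbl long connection table: columns `participant`, `condition`,
#'   `epoch`, `pair`, `dpte`; every connection must cover the same
#'   (participant, condition, epoch) units.
#' @param n_perm number of permutations (1024 at production scale).
#' @param quantile tail mass (default 0.025, i.e. 0.05/2).
#' @param seed RNG seed; thresholds are deterministic given the seed.
#' @param tail "upper" (default) or "lower" tail of the maxima.
#' @param rest_label reference condition label.
#' @return object of class `perm_thresholds` with `thr_simple`, `thr_full`,
#'   per-connection maxima, and the full permuted delta matrices.
#' @export
permutation_thresholds <- function(tbl, n_perm, quantile = 0.025, seed = 1L,
                                   tail = c("upper", "lower"),
                                   rest_label = "rest") {
  tail <- match.arg(tail)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (!(quantile > 0 && quantile < 1)) stopf("quantile must be in (0,1)")

  ord <- order(tbl$pair, tbl$participant, tbl$condition, tbl$epoch)
  tbl <- tbl[ord, , drop = FALSE]
  pairs <- unique(tbl$pair)
  C <- length(pairs)
  n <- nrow(tbl) / C
  if (n != round(n)) stopf("connections cover unequal numbers of epochs")
  units <- tbl[tbl$pair == pairs[1], c("participant", "condition", "epoch")]
  Y <- matrix(tbl$dpte, nrow = n, ncol = C)

  per_part <- split(seq_len(n), units$participant)
  n_cond <- vapply(per_part, function(i) length(unique(units$condition[i])), 1L)
  if (any(n_cond < 2))
    stopf("participant(s) with a single condition: labels are unpermutable")

  dz <- ladder_designs(units$condition, rest_label)
  g <- as.integer(factor(units$participant))
  G <- max(g)
  ni <- tabulate(g, G)
  SYg <- rowsum(Y, g)          # invariant under within-participant shuffles
  Syy <- colSums(Y^2)          # likewise
  pre <- lapply(dz[c("simple", "full")], function(X)
    list(X = X, p = ncol(X), Sxx = crossprod(X), sx = rowsum(X, g)))

  aic_for <- function(prep, Sxy_c, c_idx) {
    st <- list(ni = ni, sx = prep$sx, sy = SYg[, c_idx],
               Sxx = prep$Sxx, Sxy = Sxy_c, Syy = Syy[c_idx], G = G, p = prep$p)
    lmm_aic_from_stats(st, n, prep$p)
  }

  aic_null <- vapply(seq_len(C), function(c_idx) {
    prep <- list(X = dz$null, p = 1L, Sxx = crossprod(dz$null), sx = rowsum(dz$null, g))
    aic_for(prep, crossprod(dz$null, Y[, c_idx]), c_idx)
  }, numeric(1))

  set.seed(seed)
  aic_simple_perm <- matrix(NA_real_, n_perm, C)
  aic_full_perm <- matrix(NA_real_, n_perm, C)
  for (pm in seq_len(n_perm)) {
    idx <- seq_len(n)
    for (rows_p in per_part) idx[rows_p] <- rows_p[sample.int(length(rows_p))]
    Yp <- Y[idx, , drop = FALSE]
    Sxy_s <- crossprod(pre$simple$X, Yp)
    Sxy_f <- crossprod(pre$full$X, Yp)
    for (c_idx in seq_len(C)) {
      aic_simple_perm[pm, c_idx] <- aic_for(pre$simple, Sxy_s[, c_idx], c_idx)
      aic_full_perm[pm, c_idx] <- aic_for(pre$full, Sxy_f[, c_idx], c_idx)
    }
  }

  delta_simple_perm <- sweep(-aic_simple_perm, 2, aic_null, FUN = "+")
  mean_simple <- colMeans(aic_simple_perm)
  delta_full_perm <- sweep(-aic_full_perm, 2, mean_simple, FUN = "+")
  max_simple <- apply(delta_simple_perm, 2, max)
  max_full <- apply(delta_full_perm, 2, max)
  qpt <- if (tail == "upper") 1 - quantile else quantile
  structure(list(
    thr_simple = as.numeric(stats::quantile(max_simple, qpt)),
    thr_full = as.numeric(stats::quantile(max_full, qpt)),
    n_perm = n_perm, quantile = quantile, tail = tail, seed = seed,
    max_simple = max_simple, max_full = max_full,
    delta_simple_perm = delta_simple_perm,
    delta_full_perm = delta_full_perm,
    pairs = pairs
  ), class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf("<perm_thresholds> simple-vs-null %.2f | full-vs-simple %.2f (%d perms, %s %.3f quantile)\n",
              x$thr_simple, x$thr_full, x$n_perm, x$tail, x$quantile))
  invisible(x)
}

#' Classify connections against calibrated AIC-delta thresholds
#'
#' The three-way decision rule: a connection whose full-vs-simple AIC delta
#' reaches the full threshold is best explained by the full task model
#' (regardless of the simple-vs-null comparison); otherwise, if its
#' simple-vs-null delta reaches the simple threshold it is best explained
#' by the simple task model; otherwise it is left with the null model.
#'
#' @param fits data.frame with `delta_simple` and `delta_full` columns (one
#'   row per connection), or a list of `ladder_fit` objects.
#' @param thr a `perm_thresholds` object, or list with `thr_simple`,
#'   `thr_full`.
#' @return the input data.frame with a `class` column
#'   (null / simple_task / full_task).
#' @export
classify_connections <- function(fits, thr) {
  if (!is.data.frame(fits)) {
    fits <- data.frame(
      delta_simple = vapply(fits, `[[`, numeric(1), "delta_simple"),
      delta_full = vapply(fits, `[[`, numeric(1), "delta_full"))
  }
  stopifnot(is.finite(thr$thr_simple), is.finite(thr$thr_full))
  fits$class <- ifelse(fits$delta_full >= thr$thr_full, "full_task",
                ifelse(fits$delta_simple >= thr$thr_simple, "simple_task", "null"))
  fits
}

#' Total zero-centred outflow of a hub, by condition
#'
#' For every epoch, sums `dPTE(hub -> other) - 0.5` over all hub-to-nonhub
#' connections ("total dPTE"), then models that sum against condition with
#' a participant random intercept, reporting the rest-state mean and
#' per-condition changes with 95% intervals.
#'
#' @param tbl long connection table (`connection_table()` rows with
#'   `participant`, `condition`, `epoch`, `x`, `y`, `dpte`).
#' @param hub integer vector of hub parcel indices.
#' @param n_parcels total parcel count.
#' @param rest_label reference condition.
#' @return list with `flows` (per participant/condition/epoch totals) and
#'   `model` (coefficient table; intercept = rest mean).
#' @export
hub_summary <- function(tbl, hub, n_parcels, rest_label = "rest") {
  if (length(hub) == 0) stopf("hub is empty")
  if (length(unique(hub)) >= n_parcels) stopf("hub covers all parcels")
  flows <- hub_flow_sum(tbl, hub, setdiff(seq_len(n_parcels), hub))
  dz <- ladder_designs(flows$condition, rest_label)
  fit <- lmm_ml(dz$full, flows$flow, flows$participant)
  list(flows = flows, model = lmm_confint(fit), levels = dz$levels)
}

# per-(participant, condition, epoch) sum of zero-centred dPTE from a set
# of source parcels to a set of destination parcels
hub_flow_sum <- function(tbl, from, to) {
  fwd <- tbl$x %in% from & tbl$y %in% to
  rev_ <- tbl$y %in% from & tbl$x %in% to
  if (!any(fwd | rev_)) stopf("no connections between the given parcel sets")
  contrib <- c(tbl$dpte[fwd] - 0.5, (1 - tbl$dpte[rev_]) - 0.5)
  keys <- rbind(tbl[fwd, c("participant", "condition", "epoch")],
                tbl[rev_, c("participant", "condition", "epoch")])
  agg <- stats::aggregate(contrib,
                          by = list(participant = keys$participant,
                                    condition = keys$condition,
                                    epoch = keys$epoch),
                          FUN = sum)
  names(agg)[4] <- "flow"
  agg[order(agg$participant, agg$condition, agg$epoch), , drop = FALSE]
}
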