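#' Hub-to-destination flow records
#'
#' For each (participant, condition, epoch) and each named destination
#' region set, sums the zero-centred dPTE from the hub parcels to the
#' destination parcels (`dPTE(hub -> dest) - 0.5` over all hub x dest
#' connections). Positive values mean net outflow from the hub.
#'
#' @param tbl long connection table ([connection_table()] rows).
#' @param hub integer hub parcel indices.
#' @param destinations named list of integer parcel index vectors, e.g.
#'   `list(A = auditory, V = visual)`.
#' @return data.frame (participant, condition, epoch, destination, flow).
#' @export
hub_flow_records <- function(tbl, hub, destinations) {
  stopifnot(length(hub) > 0, length(destinations) > 0, !is.null(names(destinations)))
  if (any(vapply(destinations, function(d) length(intersect(d, hub)) > 0, TRUE)))
    stopf("destinations must be disjoint from the hub")
  out <- lapply(names(destinations), function(dn) {
    f <- hub_flow_sum(tbl, hub, destinations[[dn]])
    f$destination <- dn
    f
  })
  out <- do.call(rbind, out)
  out[, c("participant", "condition", "epoch", "destination", "flow")]
}

# Wald estimate/CI for linear combinations of the fixed effects of an
# lmm_ml fit
fixef_cells <- function(fit, Lmat, labels, level = 0.95) {
  b <- fit$beta
  V <- fit$cov_beta
  est <- drop(Lmat %*% b)
  se <- sqrt(diag(Lmat %*% V %*% t(Lmat)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- est / se
  data.frame(labels, estimate = est, se = se,
             lower = est - zq * se, upper = est + zq * se,
             z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
}

#' Hub outflow by condition and sensory destination
#'
#' Mixed model `flow ~ condition * destination + (1 | participant)`, ML
#' fit, with rest and the first destination as references. Reports the
#' coefficient table and the estimated per-(condition, destination) cell
#' means with 95% intervals (the interaction surface).
#'
#' @param records output of [hub_flow_records()]; both destinations and at
#'   least two conditions must be present.
#' @param rest_label reference condition.
#' @return list with `fit` ([lmm_ml()] result), `coefficients`, `cells`.
#' @export
hub_destination_model <- function(records, rest_label = "rest") {
  if (length(unique(records$destination)) < 2)
    stopf("need both destination levels, got: %s",
          paste(unique(records$destination), collapse = ", "))
  if (length(unique(records$condition)) < 2) stopf("need >= 2 conditions")
  records$condition <- stats::relevel(factor(records$condition), ref = rest_label)
  records$destination <- factor(records$destination)
  X <- stats::model.matrix(~ condition * destination, records)
  fit <- lmm_ml(X, records$flow, records$participant)
  grid <- expand.grid(condition = levels(records$condition),
                      destination = levels(records$destination))
  Xg <- stats::model.matrix(~ condition * destination, grid)
  cells <- fixef_cells(fit, Xg, grid)
  list(fit = fit, coefficients = lmm_confint(fit), cells = cells)
}

#' Trial-wise flow-power association model
#'
#' For one sensory destination, models the local log band power of each
#' epoch as a function of the hub's zero-centred dPTE outflow to it:
#' `log_power ~ flow * condition + (1 | participant)`, ML fit, rest as
#' reference. The per-condition slope (rest slope plus interaction) says
#' how strongly trial-wise power rises as inflow from the hub drops.
#'
#' @param flow [hub_flow_records()] rows, or any data.frame with
#'   participant, condition, epoch, flow (optionally filtered to one
#'   destination).
#' @param power data.frame with participant, condition, epoch, log_power
#'   (e.g. [band_power()] joined with block labels).
#' @param destination optional destination label to filter `flow` by.
#' @param rest_label reference condition.
#' @return object of class `flow_power_fit`: `fit`, `coefficients`, and
#'   `slopes` (per-condition slope and intercept with 95% intervals).
#' @export
flow_power_model <- function(flow, power, destination = NULL, rest_label = "rest") {
  if (!is.null(destination)) flow <- flow[flow$destination == destination, , drop = FALSE]
  keys <- c("participant", "condition", "epoch")
  m <- merge(flow[, c(keys, "flow")], power[, c(keys, "log_power")], by = keys)
  orphans <- nrow(flow) - nrow(m)
  if (nrow(m) == 0 || orphans > 0) {
    miss <- flow[!interaction(flow[keys]) %in% interaction(m[keys]), keys]
    stopf("flow/power key mismatch; %d orphan flow rows (first: %s)",
          orphans, paste(utils::head(apply(miss, 1, paste, collapse = "/"), 3), collapse = ", "))
  }
  m$condition <- stats::relevel(factor(m$condition), ref = rest_label)
  X <- stats::model.matrix(~ flow * condition, m)
  fit <- lmm_ml(X, m$log_power, m$participant)
  lev <- levels(m$condition)
  nm <- fit$coef_names
  # per-condition slope: flow main effect plus that condition's interaction
  Ls <- t(vapply(lev, function(cl) {
    L <- stats::setNames(numeric(length(nm)), nm)
    L["flow"] <- 1
    ia <- paste0("flow:condition", cl)
    if (ia %in% nm) L[ia] <- 1
    L
  }, numeric(length(nm))))
  slopes <- fixef_cells(fit, Ls, data.frame(condition = lev))
  Li <- t(vapply(lev, function(cl) {
    L <- stats::setNames(numeric(length(nm)), nm)
    L["(Intercept)"] <- 1
    mn <- paste0("condition", cl)
    if (mn %in% nm) L[mn] <- 1
    L
  }, numeric(length(nm))))
  intercepts <- fixef_cells(fit, Li, data.frame(condition = lev))
  structure(list(
    fit = fit, coefficients = lmm_confint(fit),
    slopes = slopes, intercepts = intercepts, n = nrow(m)
  ), class = "flow_power_fit")
}

#' @export
print.flow_power_fit <- function(x, ...) {
  cat(sprintf("<flow_power_fit> n = %d epochs\n", x$n))
  print(x$slopes)
  invisible(x)
}

#' SNR-confound model comparison
#'
#' Tests whether condition-related dPTE changes are explainable as a pure
#' by-product of band power (a proxy for SNR, which can bias phase
#' estimates). Three ML mixed models predict the hub's summed zero-centred
#' dPTE: condition only, log power only, and condition + log power, all on
#' identical rows. If the condition + power model beats the power-only
#' model by more than `meaningful_delta` AIC points, condition affects
#' dPTE independently of power.
#'
#' @param data data.frame with columns `flow` (hub dPTE summary),
#'   `log_power` (hub mean log power), `condition`, `participant`, matched
#'   row-wise.
#' @param meaningful_delta AIC-delta ruler (default 2).
#' @param rest_label reference condition.
#' @return list with `aic` (condition/power/both), `delta_both_vs_power`,
#'   `independent_of_power` (logical), `n`.
#' @export
snr_confound_comparison <- function(data, meaningful_delta = 2, rest_label = "rest") {
  need <- c("flow", "log_power", "condition", "participant")
  if (!all(need %in% names(data))) stopf("data must have columns: %s", paste(need, collapse = ", "))
  data <- data[stats::complete.cases(data[need]), , drop = FALSE]
  data$condition <- stats::relevel(factor(data$condition), ref = rest_label)
  g <- data$participant
  f_cond <- lmm_ml(stats::model.matrix(~condition, data), data$flow, g)
  f_pow <- lmm_ml(stats::model.matrix(~log_power, data), data$flow, g)
  f_both <- lmm_ml(stats::model.matrix(~ condition + log_power, data), data$flow, g)
  aic <- c(condition = f_cond$aic, power = f_pow$aic, both = f_both$aic)
  delta <- unname(aic["power"] - aic["both"])
  list(aic = aic, delta_both_vs_power = delta,
       independent_of_power = delta > meaningful_delta,
       n = nrow(data))
}
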