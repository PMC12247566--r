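# build a small connection table with known hub structure
hub_fixture_table <- function(val = 0.6) {
  P <- 5
  m <- matrix(0.5, P, P)
  for (j in 3:5) { m[1, j] <- val; m[j, 1] <- 1 - val }
  class(m) <- c("dpte_matrix", "matrix")
  connection_table(list(m), participant = 1, condition = "rest")
}

test_that("hub flow records equal the brute-force sum over hub connections", {
  tbl <- hub_fixture_table(0.6)
  rec <- hub_flow_records(tbl, hub = 1:2, destinations = list(A = 3L, V = c(4L, 5L)))
  # brute force: hub parcel 1 -> 3 carries 0.1; parcel 2 -> 3 carries 0
  expect_equal(rec$flow[rec$destination == "A"], 0.1)
  expect_equal(rec$flow[rec$destination == "V"], 0.2)
  expect_error(hub_flow_records(tbl, 1:2, list(A = 2L)), "disjoint")
})

test_that("hub_destination_model needs both destinations and reports cells", {
  set.seed(51)
  rec <- expand.grid(participant = 1:8, condition = c("rest", "audio", "visual"),
                     epoch = 1:10, destination = c("A", "V"),
                     stringsAsFactors = FALSE)
  drop_aud <- rec$condition == "audio" & rec$destination == "A"
  rec$flow <- 0.2 - 0.15 * drop_aud + rnorm(nrow(rec), 0, 0.05)
  fit <- hub_destination_model(rec)
  cells <- fit$cells
  # the audio x A cell shows the largest reduction from rest
  redA <- cells$estimate[cells$condition == "rest" & cells$destination == "A"] -
    cells$estimate[cells$condition == "audio" & cells$destination == "A"]
  expect_gt(redA, 0.1)
  expect_error(hub_destination_model(rec[rec$destination == "A", ]),
               "destination")
})

test_that("constant flow yields intercept c and zero effects", {
  rec <- expand.grid(participant = 1:4, condition = c("rest", "a"),
                     epoch = 1:6, destination = c("A", "V"),
                     stringsAsFactors = FALSE)
  rec$flow <- 0.25
  fit <- hub_destination_model(rec)
  expect_equal(fit$coefficients$estimate[1], 0.25, tolerance = 1e-8)
  expect_true(all(abs(fit$coefficients$estimate[-1]) < 1e-8))
})

test_that("flow_power_model recovers the exact deterministic slope", {
  rec <- expand.grid(participant = 1:6, condition = c("rest", "a"),
                     epoch = 1:10, destination = "A",
                     stringsAsFactors = FALSE)
  set.seed(52)
  rec$flow <- runif(nrow(rec), 0, 0.4)
  power <- rec[, c("participant", "condition", "epoch")]
  power$log_power <- -rec$flow          # log power = exp(-flow) exactly
  fit <- flow_power_model(rec, power, destination = "A")
  expect_equal(fit$slopes$estimate, c(-1, -1), tolerance = 1e-6)
})

test_that("flow_power slopes are invariant to constant log-power shifts", {
  set.seed(53)
  fp <- simulate_flow_power(10, 15, conditions = c("rest", "a"),
                            slopes = c(rest = -0.2, a = -1), seed = 6)
  power <- fp[, c("participant", "condition", "epoch", "log_power")]
  fp$destination <- "A"
  f1 <- flow_power_model(fp, power, destination = "A")
  power2 <- power; power2$log_power <- power2$log_power + 3.7
  f2 <- flow_power_model(fp, power2, destination = "A")
  expect_equal(f1$slopes$estimate, f2$slopes$estimate, tolerance = 1e-8)
})

test_that("key mismatches between flow and power are reported", {
  fp <- simulate_flow_power(4, 5, conditions = c("rest", "a"),
                            slopes = c(rest = 0, a = 0), seed = 7)
  power <- fp[fp$participant > 1, c("participant", "condition", "epoch", "log_power")]
  fp$destination <- "A"
  expect_error(flow_power_model(fp, power, destination = "A"),
               "orphan")
})

test_that("confound comparison separates condition-driven from power-driven flow", {
  set.seed(54)
  base <- expand.grid(participant = 1:10, condition = c("rest", "a", "b"),
                      epoch = 1:15, stringsAsFactors = FALSE)
  b <- rnorm(10, 0, 0.03)
  # condition modulates flow; power is unrelated noise
  d1 <- base
  d1$flow <- 0.2 - 0.1 * (d1$condition != "rest") + b[d1$participant] +
    rnorm(nrow(d1), 0, 0.05)
  d1$log_power <- rnorm(nrow(d1))
  r1 <- snr_confound_comparison(d1)
  expect_true(r1$independent_of_power)
  # flow is a pure function of power: adding condition should not help
  d2 <- base
  d2$log_power <- rnorm(nrow(d2))
  d2$flow <- 0.3 * d2$log_power + b[d2$participant] + rnorm(nrow(d2), 0, 0.05)
  r2 <- snr_confound_comparison(d2)
  expect_lte(r2$delta_both_vs_power, 2)
  expect_identical(names(r1$aic), c("condition", "power", "both"))
})

test_that("duplicating a predictor cannot improve the likelihood", {
  set.seed(55)
  d <- simulate_flow_power(8, 12, conditions = c("rest", "a"),
                           slopes = c(rest = 0, a = -0.5), seed = 8)
  X1 <- cbind(1, d$flow)
  X2 <- cbind(1, d$flow, d$flow)
  f1 <- lmm_ml(X1, d$log_power, d$participant)
  f2 <- lmm_ml(X2, d$log_power, d$participant)
  expect_lt(abs(f2$logLik - f1$logLik), 1e-3)
  expect_equal(f2$aic, f1$aic + 2, tolerance = 1e-3)
})
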