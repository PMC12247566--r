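test_that("network construction validates edges", {
  net <- make_network(4, data.frame(from = 1, to = 2, lag = 10, gain = 0.8),
                      condition_gains = list(rest = 1, task = 0.1))
  expect_s3_class(net, "ground_truth_network")
  expect_identical(nrow(net$edges), 1L)
  expect_error(make_network(4, data.frame(from = 2, to = 2, lag = 5, gain = 0.5),
                            list(rest = 1)), "self-loop")
  expect_error(make_network(4, data.frame(from = 1, to = 2, lag = 0, gain = 0.5),
                            list(rest = 1)), "lags")
  expect_error(make_network(4, data.frame(from = 1, to = 5, lag = 2, gain = 0.5),
                            list(rest = 1)), "out of range")
  expect_error(make_network(4, data.frame(from = 1, to = 2, lag = 2, gain = -1),
                            list(rest = 1)), "gains")
  n1 <- make_network(4, data.frame(from = 1, to = 2, lag = 10, gain = 0.8),
                     list(rest = 1), seed = 3)
  n2 <- make_network(4, data.frame(from = 1, to = 2, lag = 10, gain = 0.8),
                     list(rest = 1), seed = 3)
  expect_identical(n1, n2)
})

test_that("cohort_spec enforces its invariants", {
  expect_error(cohort_spec(epoch_len = 0.1, fs = 200), ">= 64")
  expect_error(cohort_spec(conditions = c("a", "rest")), "first")
  expect_error(cohort_spec(conditions = c("rest", "a", "a")), "unique")
})

test_that("blocks have the right shape, are centred, finite and reproducible", {
  net <- make_network(3, data.frame(from = 1, to = 2, lag = 8, gain = 0.5),
                      condition_gains = list(rest = 1, task = 0.5))
  spec <- cohort_spec(n_participants = 3, conditions = c("rest", "task"),
                      epochs_per_condition = 4, seed = 5)
  b1 <- simulate_epochs(net, spec, 2, "task")
  expect_identical(dim(b1$data), c(4L, 3L, 400L))
  expect_true(all(is.finite(b1$data)))
  expect_true(all(abs(apply(b1$data, c(1, 2), mean)) < 1e-10))
  b2 <- simulate_epochs(net, spec, 2, "task")
  expect_identical(b1$data, b2$data)
  b3 <- simulate_epochs(net, spec, 1, "task")
  expect_false(identical(b1$data, b3$data))
  expect_error(simulate_epochs(net, spec, 1, "nope"), "unknown condition")
})

test_that("cohorts are block-complete and seed-reproducible", {
  net <- make_network(2, data.frame(from = 1, to = 2, lag = 8, gain = 0.5),
                      condition_gains = list(rest = 1, task = 1))
  spec <- cohort_spec(n_participants = 3, conditions = c("rest", "task"),
                      epochs_per_condition = 5, seed = 9)
  c1 <- generate_cohort(net, spec)
  expect_length(c1$blocks, 3)
  expect_identical(names(c1$blocks[[1]]), c("rest", "task"))
  expect_identical(dim(c1$blocks[[2]]$rest$data), c(5L, 2L, 400L))
  c2 <- generate_cohort(net, spec)
  expect_identical(c1$blocks[[3]]$task$data, c2$blocks[[3]]$task$data)
  spec2 <- cohort_spec(n_participants = 3, conditions = c("rest", "task"),
                       epochs_per_condition = 5, seed = 10)
  c3 <- generate_cohort(net, spec2)
  expect_false(identical(c1$blocks[[1]]$rest$data, c3$blocks[[1]]$rest$data))
})

test_that("participant offsets have the configured scale", {
  spec <- cohort_spec(n_participants = 200, participant_sd = 0.1, seed = 2)
  off <- participant_offsets(spec)
  expect_length(off, 200)
  expect_lt(abs(stats::sd(off) - 0.1), 0.03)
  expect_identical(off, participant_offsets(spec))
})

test_that("power coupling lowers band power when inflow is strong", {
  # same seed, gain 0.9 vs 0: with power_coupling > 0 the coupled target's
  # oscillation is attenuated, so its band power must drop
  mk <- function(g) {
    net <- make_network(2, data.frame(from = 1, to = 2, lag = 8, gain = g),
                        condition_gains = list(rest = 1), power_coupling = 0.5)
    spec <- cohort_spec(n_participants = 1, conditions = "rest",
                        epochs_per_condition = 20, participant_sd = 0, seed = 33)
    simulate_epochs(net, spec, 1, "rest")
  }
  band <- fixture_band()
  p_hi <- band_power(mk(0.9), band)
  p_lo <- band_power(mk(0), band)
  lp_hi <- mean(p_hi$log_power[p_hi$parcel == 2])
  lp_lo <- mean(p_lo$log_power[p_lo$parcel == 2])
  expect_lt(lp_hi, lp_lo)
})

test_that("statistic-level simulators honour their effect parameters", {
  d <- simulate_connection(50, 10, conditions = c("rest", "task"),
                           effects = c(task = 0.1), participant_sd = 0.01,
                           resid_sd = 0.01, seed = 4)
  shift <- mean(d$dpte[d$condition == "task"]) - mean(d$dpte[d$condition == "rest"])
  expect_equal(shift, 0.1, tolerance = 0.01)
  fp <- simulate_flow_power(40, 10, conditions = c("rest", "a"),
                            slopes = c(rest = 0, a = -1), resid_sd = 0.01,
                            seed = 4)
  co <- stats::coef(stats::lm(log_power ~ flow, fp[fp$condition == "a", ]))
  expect_equal(unname(co[2]), -1, tolerance = 0.05)
})
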