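test_that("log-likelihoods are monotone along the nested ladder", {
  set.seed(41)
  for (k in 1:5) {
    d <- simulate_connection(6, 12, conditions = c("rest", "a", "b"),
                             effects = c(a = runif(1, -0.02, 0.02), b = 0),
                             seed = 100 + k)
    f <- fit_ladder(d)
    expect_true(f$logLik["simple"] >= f$logLik["null"] - 1e-6)
    expect_true(f$logLik["full"] >= f$logLik["simple"] - 1e-6)
  }
})

test_that("fit_ladder validates its inputs", {
  d <- simulate_connection(6, 12, seed = 1)
  expect_error(fit_ladder(d[d$participant == 1, ]), "participants")
  expect_error(fit_ladder(d[d$condition == "rest", ]), "conditions")
  expect_error(fit_ladder(d[d$participant <= 2 & d$epoch <= 2, ]), "rows")
})

test_that("simple-model task coefficient recovers an injected shift", {
  d <- simulate_connection(24, 25, conditions = c("rest", "task"),
                           effects = c(task = 0.03), participant_sd = 0.01,
                           resid_sd = 0.05, seed = 77)
  f <- fit_ladder(d)
  co <- f$coef_simple[f$coef_simple$term == "task", ]
  expect_gt(co$estimate, 0.01)
  expect_lt(co$estimate, 0.05)
  expect_true(co$lower < 0.03 && co$upper > 0.03)
})

test_that("permutation thresholds are deterministic and degenerate correctly", {
  tbl <- fixture_null_table(n_pairs = 4, n_participants = 5,
                            epochs_per_condition = 10, seed = 3)
  t1 <- permutation_thresholds(tbl, n_perm = 20, seed = 42)
  t2 <- permutation_thresholds(tbl, n_perm = 20, seed = 42)
  expect_identical(t1$thr_simple, t2$thr_simple)
  expect_identical(t1$thr_full, t2$thr_full)
  # n_perm = 1: thresholds are the cross-connection quantile of that
  # single permutation's deltas
  t3 <- permutation_thresholds(tbl, n_perm = 1, seed = 7)
  expect_equal(t3$thr_simple,
               as.numeric(stats::quantile(t3$delta_simple_perm[1, ], 0.975)))
})

test_that("thresholds grow with more permutations (prefix property)", {
  tbl <- fixture_null_table(n_pairs = 5, n_participants = 6,
                            epochs_per_condition = 12, seed = 4)
  t_small <- permutation_thresholds(tbl, n_perm = 25, seed = 11)
  t_big <- permutation_thresholds(tbl, n_perm = 100, seed = 11)
  # same seed: the first 25 shuffles are shared, so per-connection maxima
  # and hence the quantile can only grow
  expect_true(all(t_big$max_simple >= t_small$max_simple - 1e-9))
  expect_gte(t_big$thr_simple, t_small$thr_simple - 1e-9)
})

test_that("a participant with one condition is unpermutable", {
  tbl <- fixture_null_table(n_pairs = 2, n_participants = 3)
  tbl <- tbl[!(tbl$participant == 2 & tbl$condition != "rest"), ]
  expect_error(permutation_thresholds(tbl, n_perm = 5, seed = 1),
               "single condition")
})

test_that("observed null deltas are consistent with the permutation distribution", {
  tbl <- fixture_null_table(n_pairs = 8, n_participants = 8,
                            epochs_per_condition = 15, seed = 6)
  thr <- permutation_thresholds(tbl, n_perm = 60, seed = 13)
  obs <- vapply(unique(tbl$pair), function(pr)
    fit_ladder(tbl[tbl$pair == pr, ])$delta_simple, numeric(1))
  ks <- suppressWarnings(stats::ks.test(obs, as.vector(thr$delta_simple_perm)))
  expect_gt(ks$p.value, 0.01)
})

test_that("classification follows the three-way decision tree", {
  thr <- list(thr_simple = 14.97, thr_full = 19.88)
  fits <- data.frame(delta_simple = 20, delta_full = 1)
  expect_identical(classify_connections(fits, thr)$class, "simple_task")
  fits <- data.frame(delta_simple = 1, delta_full = 25)
  expect_identical(classify_connections(fits, thr)$class, "full_task")
  fits <- data.frame(delta_simple = 0, delta_full = 0)
  expect_identical(classify_connections(fits, thr)$class, "null")
})

test_that("classification is invariant to connection order and condition relabeling", {
  set.seed(44)
  tbl <- fixture_null_table(n_pairs = 5, n_participants = 6,
                            epochs_per_condition = 10, seed = 8)
  fits <- fit_all_ladders(tbl)
  thr <- list(thr_simple = 3, thr_full = 3)
  c1 <- classify_connections(fits, thr)
  c2 <- classify_connections(fits[sample(nrow(fits)), ], thr)
  expect_identical(c1$class[match(c2$pair, c1$pair)], c2$class)
  # swapping the two task labels (reference fixed) leaves deltas unchanged
  tbl2 <- tbl
  tbl2$condition <- c(rest = "rest", a = "b", b = "a")[tbl$condition]
  fits2 <- fit_all_ladders(tbl2)
  expect_equal(fits2$delta_simple, fits$delta_simple, tolerance = 1e-6)
  expect_equal(fits2$delta_full, fits$delta_full, tolerance = 1e-6)
})

test_that("hub summary sums zero-centred outflow correctly", {
  P <- 4
  m <- matrix(0.5, P, P)
  m[1, 2] <- 0.6; m[2, 1] <- 0.4
  m[1, 3] <- 0.6; m[3, 1] <- 0.4
  m[1, 4] <- 0.6; m[4, 1] <- 0.4
  class(m) <- c("dpte_matrix", "matrix")
  tbl <- connection_table(list(m), participant = 1, condition = "rest")
  flows <- dpteflow:::hub_flow_sum(tbl, 1L, 2:4)
  expect_equal(flows$flow, 0.3)
  # all-neutral matrix: total flow 0
  m0 <- matrix(0.5, P, P); class(m0) <- c("dpte_matrix", "matrix")
  tbl0 <- connection_table(list(m0), participant = 1, condition = "rest")
  expect_equal(dpteflow:::hub_flow_sum(tbl0, 1L, 2:4)$flow, 0)
})

test_that("hub_summary rejects empty or exhaustive hubs", {
  tbl <- fixture_null_table(n_pairs = 3)
  expect_error(hub_summary(tbl, integer(0), 4), "empty")
  expect_error(hub_summary(tbl, 1:4, 4), "all parcels")
})
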