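test_that("transition matrices are estimated by within-bout counting", {
  # deterministic cycle: 30 repeats of 1-2-3-4
  bouts <- rep(list(c(1L, 2L, 3L, 4L)), 30)
  tm <- estimate_transition_matrix(bouts, 4, bee_id = "c")
  expect_equal(tm$P[1, 2], 1)
  expect_equal(tm$P[2, 3], 1)
  expect_equal(tm$P[3, 4], 1)
  expect_equal(tm$P[4, ], rep(0.25, 4))  # arm 4 never a "from": uniform
  expect_equal(tm$start_dist, c(1, 0, 0, 0))
  # no transition crosses the bout boundary (no 4 -> 1 count)
  expect_equal(tm$counts[4, 1], 0)
})

test_that("additive smoothing follows the add-pseudo_count rule", {
  tm <- estimate_transition_matrix(list(c(1L, 2L)), 4, pseudo_count = 1)
  expect_equal(tm$P[1, ], c(1, 2, 1, 1) / 5)
  expect_equal(tm$P[2, ], rep(1, 4) / 4)
})

test_that("estimation recovers a known generating matrix", {
  set.seed(31)
  Q <- random_transition_matrix(4, forbid_self = TRUE, bee_id = "q")
  b <- simulate_markov_bouts(Q, 2500, return_sequences = TRUE)
  expect_gt(sum(b$n_visits) - nrow(b), 10000)  # >= 10k transitions
  est <- estimate_transition_matrix(b$arms, 4, bee_id = "q")
  expect_lt(max(abs(est$P - Q$P)), 0.03)
})

test_that("matrix estimation rejects degenerate inputs", {
  expect_error(estimate_transition_matrix(list(c(1L, 2L)), 1), ">= 2")
  expect_error(estimate_transition_matrix(list(1L, 2L), 4, bee_id = "zz"),
               "zz")
})

test_that("random matrices sit on the simplex with the requested support", {
  set.seed(41)
  tm <- random_transition_matrix(4, forbid_self = TRUE)
  expect_equal(diag(tm$P), rep(0, 4))
  expect_equal(rowSums(tm$P), rep(1, 4))
  # Dirichlet moment oracle: flat Dirichlet over 3 cells has mean 1/3
  off <- replicate(2000, {
    m <- random_transition_matrix(4, forbid_self = TRUE)
    m$P[1, 2]
  })
  se <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) - 1 / 3), 3 * se)
  # determinism under seed
  set.seed(99); a <- random_transition_matrix(5)
  set.seed(99); b <- random_transition_matrix(5)
  expect_identical(a, b)
})

test_that("every matrix constructor preserves row-stochasticity", {
  set.seed(51)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    tm1 <- random_transition_matrix(k, forbid_self = sample(c(TRUE, FALSE), 1))
    expect_equal(rowSums(tm1$P), rep(1, k))
    b <- simulate_markov_bouts(tm1, 5, return_sequences = TRUE)
    tm2 <- estimate_transition_matrix(b$arms, k,
                                      pseudo_count = sample(0:2, 1))
    expect_equal(rowSums(tm2$P), rep(1, k))
  }
})

test_that("simulant bouts follow the matrix and the stop rule", {
  set.seed(61)
  cyc <- cycle_matrix(4)
  b <- simulate_simulant_bout(cyc)
  expect_equal(length(b$arms), 4L)
  expect_equal(b$errors, 0L)
  expect_true(b$completed)
  expect_equal(diff(b$arms) %% 4, rep(1, 3))  # consecutive cycle steps
  # pathological 2-arm looping matrix hits the cap and is flagged
  P <- matrix(0, 4, 4); P[1, 2] <- P[2, 1] <- 1
  P[3, 4] <- P[4, 3] <- 1
  loop <- foragecog:::new_transition_matrix("loop", 4L, P,
                                            matrix(0L, 4, 4),
                                            c(.5, .5, 0, 0))
  b2 <- simulate_markov_bouts(loop, 10, cap = 5)
  expect_true(all(b2$truncated))
  expect_true(all(b2$n_visits == 5))
})

test_that("uniform no-self simulants match the absorbing-chain mean of 2.5", {
  # closed form on 4 arms: visits 1 + 3/3 + 3/2 + 3/1 = 6.5 -> 2.5 errors
  set.seed(71)
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  tm <- foragecog:::new_transition_matrix("u", 4L, P, matrix(0L, 4, 4),
                                          rep(0.25, 4))
  b <- simulate_markov_bouts(tm, 10000)
  bc <- b[b$completed, ]
  se <- sd(bc$errors) / sqrt(nrow(bc))
  expect_lt(abs(mean(bc$errors) - 2.5), 3 * se)
})

test_that("simulant datasets mirror cohort structure and are seed-stable", {
  set.seed(81)
  ms <- lapply(1:5, function(i)
    random_transition_matrix(4, bee_id = paste0("b", i)))
  covs <- data.frame(bee_id = paste0("b", 1:5), size_mm = 4:8,
                     age_days = 10:14)
  d <- generate_simulant_datasets(ms, covs, n_bouts_per_bee = 3,
                                  n_replicates = 3, seed = 5)
  expect_length(d, 3)
  expect_equal(nrow(d[[1]]), 15)  # 5 bees x 3 bouts
  expect_setequal(unique(d[[1]]$bee_id), paste0("b", 1:5))
  expect_true("size_mm" %in% names(d[[1]]))
  expect_length(generate_simulant_datasets(ms, covs, 3, n_replicates = 0), 0)
  d2 <- generate_simulant_datasets(ms, covs, n_bouts_per_bee = 3,
                                   n_replicates = 3, seed = 5)
  expect_identical(vapply(d, function(x) sum(x$errors), 0),
                   vapply(d2, function(x) sum(x$errors), 0))
  bad <- covs[1:3, ]
  expect_error(generate_simulant_datasets(ms, bad, 3, 1), "b4")
})

test_that("the batched null distribution matches the streaming path", {
  set.seed(91)
  ms <- lapply(1:4, function(i)
    random_transition_matrix(6, bee_id = paste0("b", i)))
  f <- simulant_null_mean_errors(ms, n_bouts_per_bee = 6,
                                 n_replicates = 400, seed = 1)
  slow <- generate_simulant_datasets(ms, n_bouts_per_bee = 6,
                                     n_replicates = 400, seed = 2)
  g <- vapply(slow, function(d) mean(d$errors), 0)
  expect_length(f, 400)
  # same generative process: equal means within Monte-Carlo error
  se <- sqrt(var(f) / 400 + var(g) / 400)
  expect_lt(abs(mean(f) - mean(g)), 4 * se)
})

test_that("dataset statistics behave on degenerate and toy inputs", {
  zero <- data.frame(bee_id = rep(c("a", "b"), each = 3), errors = 0)
  expect_equal(dataset_statistic(zero), 0)
  toy <- data.frame(bee_id = rep(c("a", "b"), each = 2),
                    errors = c(1, 3, 2, 2))
  expect_equal(dataset_statistic(toy), 2)
  # degenerate-model oracle: constant covariates, no between-bee variance
  # -> Poisson GLMM intercept ~ log of the grand mean
  set.seed(13)
  d <- data.frame(bee_id = rep(paste0("b", 1:12), each = 10),
                  errors = rpois(120, 3), size_mm = 4.4, age_days = 10)
  mi <- dataset_statistic(d, "model_intercept")
  expect_lt(abs(mi - log(mean(d$errors))), 0.08)
})

test_that("percentile p-values use the add-one rule on the right tail", {
  expect_equal(percentile_p_value(-5, 1:9999, "lower"), 1 / 10000)
  expect_equal(percentile_p_value(5, 1:9, "lower"), 6 / 10)
  expect_equal(percentile_p_value(5, 1:9, "upper"), 6 / 10)
  nul <- rnorm(20001)
  expect_lt(abs(percentile_p_value(0, nul, "lower") - 0.5), 0.02)
  expect_error(percentile_p_value(1, numeric(0)), "empty")
})

test_that("memory agents beat their own simulants (movement-rule null)", {
  set.seed(103)
  coh <- simulate_cohort(n_bees = 6, design = "validation",
                         memory_capacities = 2, lapse_rate = 0.1)
  d <- ram_design("validation")
  wins <- 0L
  reps <- 60L
  test_visits <- coh$visits[coh$visits$bout_type == "test", ]
  ms <- lapply(unique(test_visits$bee_id), function(id)
    estimate_transition_matrix(test_visits[test_visits$bee_id == id, ],
                               d$n_arms, bee_id = id))
  obs <- mean(score_bouts(test_visits, d$n_arms)$errors)
  nulls <- simulant_null_mean_errors(ms, n_bouts_per_bee = d$n_test_bouts,
                                     n_replicates = reps)
  expect_gt(mean(obs < nulls), 0.95)
})

test_that("ram_validation returns a calibrated lower-tail p-value object", {
  set.seed(113)
  coh <- simulate_cohort(n_bees = 6, design = "validation",
                         memory_capacities = 2, lapse_rate = 0.1)
  v <- ram_validation(coh$visits, coh$bees, n_replicates = 100, seed = 7)
  expect_s3_class(v, "ram_validation")
  expect_length(v$null_values, 100)
  expect_gt(v$p_value, 0)
  expect_lte(v$p_value, 1)
  expect_lt(v$observed, mean(v$null_values))  # memory helps
  expect_output(print(v), "percentile p")
})
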