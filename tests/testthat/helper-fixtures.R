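# Shared fixture builders; everything is generated in code under fixed seeds.

# a small hand-written visit log: 2 bees x 4 bouts on a 4-arm maze
toy_visit_log <- function() {
  mk <- function(bee, bout, type, arms)
    data.frame(bee_id = bee, bout_index = bout, bout_type = type,
               visit_index = seq_along(arms), arm_id = arms,
               timestamp_s = (seq_along(arms) - 1) * 30,
               stringsAsFactors = FALSE)
  rbind(
    mk("b1", 1, "training", c(1, 2, 1, 3, 4)),
    mk("b1", 2, "test", c(1, 2, 3, 4)),        # 0 errors
    mk("b1", 3, "test", c(2, 2, 3, 1, 4)),     # 1 error (immediate repeat)
    mk("b1", 4, "test", c(2, 3, 2, 3, 2)),     # 3 errors, incomplete
    mk("b2", 1, "training", c(4, 3, 2, 1)),
    mk("b2", 2, "test", c(1, 1, 1, 2, 3, 4)),  # 2 errors
    mk("b2", 3, "test", c(3, 4, 1, 2)),        # 0 errors
    mk("b2", 4, "test", c(1, 2, 3, 4)))        # 0 errors
}

# deterministic cycle transition matrix 1->2->3->4->1
cycle_matrix <- function(n_arms = 4L) {
  P <- matrix(0, n_arms, n_arms)
  for (a in seq_len(n_arms)) P[a, a %% n_arms + 1L] <- 1
  foragecog:::new_transition_matrix("cycle", n_arms, P,
                                    matrix(0L, n_arms, n_arms),
                                    rep(1 / n_arms, n_arms))
}

# small trip table with exact second-resolution times
toy_trips <- function(n = 6L, bee = "tagA", day = as.Date("2018-05-07")) {
  t0 <- as.POSIXct(paste(day, "09:00:00"), tz = "UTC")
  out <- t0 + (seq_len(n) - 1) * 3600
  data.frame(bee_id = bee, t_out = out, t_in = out + 1200,
             w_out_mg = 180 + seq_len(n), w_in_mg = 190 + 2 * seq_len(n),
             pollen_oneleg_mg = rep(c(0, 4), length.out = n),
             stringsAsFactors = FALSE)
}

# small season for pipeline-level tests
small_season <- function(seed = 1) {
  sp <- season_params(n_colonies = 4L, bees_per_colony = 6L)
  bees <- simulate_bee_table(sp, seed = seed)
  list(params = sp, bees = bees,
       season = simulate_season(bees, sp, seed = seed + 1))
}
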