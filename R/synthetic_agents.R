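# ---------------------------------------------------------------------------
# Synthetic maze bees.
#
# The generator operationalises the short-term-memory mechanism the maze is
# designed to probe: an agent holds a sliding window of the last `m`
# distinct arms it visited and avoids them when choosing the next arm.
# m = 0 reduces to a memoryless Markov walker (the movement-rule null);
# m = n_arms - 1 is a perfect win-shift forager that never revisits.
# ---------------------------------------------------------------------------

#' Maze-agent parameters
#'
#' @param memory_capacity `m`, the number of most-recent *distinct* arms the
#'   agent avoids (0 <= m <= n_arms; m = n_arms can exclude every arm and is
#'   rejected at simulation time when it does).
#' @param lapse_rate probability, per choice, of ignoring memory and falling
#'   back to the movement bias.
#' @param n_arms number of maze arms.
#' @param movement_bias optional `n_arms x n_arms` row-stochastic matrix used
#'   for memoryless choices (lapses, empty memory, m = 0); default uniform
#'   over the other arms (no self-transition).
#' @return list of class `agent_params`.
#' @export
agent_params <- function(memory_capacity, lapse_rate = 0, n_arms = 4L,
                         movement_bias = NULL) {
  stopifnot(memory_capacity >= 0, memory_capacity <= n_arms,
            lapse_rate >= 0, lapse_rate <= 1, n_arms >= 2)
  if (is.null(movement_bias)) {
    movement_bias <- matrix(1 / (n_arms - 1), n_arms, n_arms)
    diag(movement_bias) <- 0
  }
  stopifnot(nrow(movement_bias) == n_arms, ncol(movement_bias) == n_arms,
            all(abs(rowSums(movement_bias) - 1) < 1e-9))
  structure(list(memory_capacity = as.integer(memory_capacity),
                 lapse_rate = lapse_rate, n_arms = as.integer(n_arms),
                 movement_bias = movement_bias),
            class = "agent_params")
}

#' Simulate maze bouts for a memory-window agent
#'
#' Each choice: with probability `lapse_rate`, or when the memory window is
#' empty, the next arm is drawn from the movement-bias row of the current
#' arm; otherwise it is drawn uniformly among arms outside the window of the
#' last `m` distinct arms visited. A bout ends when all arms have been
#' visited (the agent is "fed to repletion") or at the visit cap. All bouts
#' advance in lock-step for speed.
#'
#' @param params an [agent_params()] object.
#' @param n_bouts number of bouts.
#' @param cap visit cap per bout (default `12 * n_arms`).
#' @param return_sequences also keep the visit sequences.
#' @return data frame as in [simulate_markov_bouts()].
#' @export
simulate_agent_bouts <- function(params, n_bouts, cap = 12L * params$n_arms,
                                 return_sequences = FALSE) {
  stopifnot(inherits(params, "agent_params"))
  k <- params$n_arms
  m <- params$memory_capacity
  n <- as.integer(n_bouts)
  if (n == 0L)
    return(data.frame(bout_index = integer(), n_visits = integer(),
                      distinct_arms_visited = integer(), errors = integer(),
                      completed = logical(), truncated = logical()))
  # first arm: uniform (the agent enters the maze with no within-bout memory)
  cur <- sample.int(k, n, replace = TRUE)
  first_arm <- cur
  visited <- matrix(FALSE, n, k)
  visited[cbind(seq_len(n), cur)] <- TRUE
  n_visits <- rep(1L, n)
  n_distinct <- rep(1L, n)
  mem <- matrix(0L, n, max(m, 1L))        # most recent distinct arms, col 1 newest
  if (m > 0L) mem[, 1L] <- cur
  steps <- list()                         # per-iteration (rows, arms) records
  t <- 0L
  active <- which(n_distinct < k & n_visits < cap)
  while (length(active)) {
    t <- t + 1L
    na <- length(active)
    use_bias <- if (m == 0L) rep(TRUE, na)
                else runif(na) < params$lapse_rate
    W <- matrix(0, na, k)
    if (any(use_bias))
      W[use_bias, ] <- params$movement_bias[cur[active][use_bias], ,
                                            drop = FALSE]
    if (any(!use_bias)) {
      rows <- which(!use_bias)
      allowed <- matrix(TRUE, length(rows), k)
      for (j in seq_len(m)) {
        mj <- mem[active[rows], j]
        nz <- which(mj > 0L)
        if (length(nz)) allowed[cbind(nz, mj[nz])] <- FALSE
      }
      nall <- rowSums(allowed)
      if (any(nall == 0L))
        stop("memory window excludes every arm; reduce `memory_capacity`",
             call. = FALSE)
      W[rows, ] <- allowed / nall
    }
    u <- runif(na)
    nxt <- pmin.int(rowSums(row_cumsum(W) < u) + 1L, k)
    if (m > 0L) {
      # slide the window: move `nxt` to the front, dropping its old position
      memx <- cbind(mem[active, , drop = FALSE], 0L)
      eq <- memx[, seq_len(m), drop = FALSE] == nxt
      appeared <- matrix(0L, na, m)        # nxt seen among first j-1 slots?
      if (m > 1L)
        appeared[, 2:m] <- t(apply(eq[, 1:(m - 1), drop = FALSE], 1L, cumsum))
      newmem <- matrix(0L, na, m)
      newmem[, 1L] <- nxt
      if (m > 1L)
        for (j in 2:m) {
          src <- (j - 1L) + appeared[, j]
          newmem[, j] <- memx[cbind(seq_len(na), src)]
        }
      mem[active, ] <- newmem
    }
    cur[active] <- nxt
    first <- !visited[cbind(active, nxt)]
    visited[cbind(active, nxt)] <- TRUE
    n_distinct[active] <- n_distinct[active] + first
    n_visits[active] <- n_visits[active] + 1L
    if (return_sequences) steps[[t]] <- list(rows = active, arms = nxt)
    active <- active[n_distinct[active] < k & n_visits[active] < cap]
  }
  out <- data.frame(bout_index = seq_len(n),
                    n_visits = n_visits,
                    distinct_arms_visited = n_distinct,
                    errors = n_visits - n_distinct,
                    completed = n_distinct == k,
                    truncated = n_distinct < k & n_visits >= cap)
  if (return_sequences) {
    rows <- c(seq_len(n), unlist(lapply(steps, `[[`, "rows")))
    arm_vec <- c(first_arm, unlist(lapply(steps, `[[`, "arms")))
    ord_idx <- c(rep(1L, n),
                 unlist(lapply(seq_along(steps),
                               function(i) rep(i + 1L,
                                               length(steps[[i]]$rows)))))
    o <- order(rows, ord_idx)
    seqs <- split(arm_vec[o], factor(rows[o], levels = seq_len(n)))
    names(seqs) <- NULL
    out$arms <- I(seqs)
  }
  out
}

#' Simulate a bee's maze bouts as a visit log
#'
#' Runs [simulate_agent_bouts()] and lays the result out in the visit-log
#' dialect used by [score_bouts()], with training/test bout labels from the
#' chosen design. Agents have no learning process, so training bouts are
#' statistically identical to test bouts; they exist to mirror the real
#' file layout.
#'
#' @param params an [agent_params()] object.
#' @param n_bouts total bouts; defaults from `design`.
#' @param design `"main"` (12 bouts / last 3 test) or `"validation"`
#'   (20 bouts / last 10 test).
#' @param bee_id identifier for the log.
#' @param mean_intervisit_s mean gap between landings, seconds; visit
#'   timestamps are cumulative exponential gaps (0 disables timestamps).
#' @return visit-log data frame: `bee_id`, `bout_index`, `bout_type`,
#'   `visit_index`, `arm_id`, `timestamp_s`.
#' @export
simulate_ram_bee <- function(params, n_bouts = NULL,
                             design = c("main", "validation"),
                             bee_id = "bee1", mean_intervisit_s = 30) {
  design <- match.arg(design)
  d <- ram_design(design)
  if (is.null(n_bouts)) n_bouts <- d$n_bouts
  b <- simulate_agent_bouts(params, n_bouts, return_sequences = TRUE)
  n_test <- min(d$n_test_bouts, n_bouts)
  types <- c(rep("training", n_bouts - n_test), rep("test", n_test))
  rows <- lapply(seq_len(n_bouts), function(i) {
    arms <- b$arms[[i]]
    nv <- length(arms)
    ts <- if (mean_intervisit_s > 0)
      cumsum(c(0, stats::rexp(nv - 1L, rate = 1 / mean_intervisit_s)))
    else rep(NA_real_, nv)
    data.frame(bee_id = bee_id, bout_index = i, bout_type = types[i],
               visit_index = seq_len(nv), arm_id = arms,
               timestamp_s = ts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cognitive-testing cohort
#'
#' Draws per-bee memory capacities, sizes and ages, simulates every bee's
#' maze bouts, and returns the visit log plus a bee table in the dialects
#' the scoring and validation stages consume.
#'
#' @param n_bees number of bees.
#' @param design maze design, see [ram_design()].
#' @param memory_capacities integer vector recycled over bees, or a function
#'   `function(n)` returning one capacity per bee.
#' @param lapse_rate shared lapse rate.
#' @param n_colonies colonies to spread bees over.
#' @param size_mean,size_sd intertegular-distance distribution (mm).
#' @param age_mean,age_sd age at testing (days).
#' @param seed integer seed.
#' @return list with `visits` (visit log) and `bees` (`bee_id`, `colony_id`,
#'   `size_mm`, `age_days`, `memory_capacity`).
#' @export
simulate_cohort <- function(n_bees = 20L, design = c("validation", "main"),
                            memory_capacities = 2L, lapse_rate = 0.1,
                            n_colonies = 4L, size_mean = 4.4, size_sd = 0.35,
                            age_mean = 10, age_sd = 3, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  d <- ram_design(design)
  m <- if (is.function(memory_capacities)) memory_capacities(n_bees)
       else rep_len(as.integer(memory_capacities), n_bees)
  bees <- data.frame(
    bee_id = sprintf("bee%03d", seq_len(n_bees)),
    colony_id = sprintf("col%02d", rep_len(seq_len(n_colonies), n_bees)),
    size_mm = round(rnorm(n_bees, size_mean, size_sd), 2),
    age_days = pmax(1, round(rnorm(n_bees, age_mean, age_sd))),
    memory_capacity = m,
    stringsAsFactors = FALSE)
  visits <- do.call(rbind, lapply(seq_len(n_bees), function(i) {
    p <- agent_params(memory_capacity = m[i], lapse_rate = lapse_rate,
                      n_arms = d$n_arms)
    simulate_ram_bee(p, n_bouts = d$n_bouts, design = design,
                     bee_id = bees$bee_id[i])
  }))
  rownames(visits) <- NULL
  list(visits = visits, bees = bees)
}
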