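# ---------------------------------------------------------------------------
# Movement-rule null models for RAM performance.
#
# Real bees may beat chance on the maze either through short-term memory or
# through stereotyped movement rules (e.g. always turning to an adjacent
# arm). The validation strips the memory component: each bee's test bouts
# yield a first-order arm-to-arm transition matrix; "simulant" bees moving
# under that matrix reproduce the movement stereotypy but not within-bout
# memory. Comparing real performance with the simulant null distribution
# (and with a random-matrix chance baseline) asks whether memory per se
# lowers the error count.
# ---------------------------------------------------------------------------

#' Construct a transition-matrix object
#' @keywords internal
new_transition_matrix <- function(bee_id, n_arms, P, counts, start_dist) {
  stopifnot(nrow(P) == n_arms, ncol(P) == n_arms)
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  if (any(P < 0) || any(P > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(start_dist) - 1) > 1e-9)
    stop("start distribution must sum to 1", call. = FALSE)
  structure(list(bee_id = bee_id, n_arms = as.integer(n_arms),
                 P = unname(P), counts = unname(counts),
                 start_dist = unname(start_dist)),
            class = "transition_matrix")
}

#' @export
#' @method print transition_matrix
#' @keywords internal
print.transition_matrix <- function(x, ...) {
  cat("Arm-to-arm transition matrix for bee", x$bee_id,
      sprintf("(%d arms, %d transitions observed)\n",
              x$n_arms, sum(x$counts)))
  print(round(x$P, 3))
  invisible(x)
}

#' Estimate a bee's empirical transition matrix
#'
#' Transitions are counted within bouts only (a bout boundary breaks the
#' chain), pooling the bee's test bouts. Row `a` of the matrix is the
#' probability of moving from arm `a` to each arm, with optional additive
#' smoothing. Rows with no observed transitions (and no smoothing) fall back
#' to uniform. The start distribution is the empirical frequency of
#' first-visited arms.
#'
#' @param bouts list of integer visit sequences (one per bout), or a visits
#'   data frame for a single bee (test bouts).
#' @param n_arms number of maze arms (>= 2).
#' @param pseudo_count additive smoothing constant (>= 0, default 0).
#' @param bee_id identifier carried on the result.
#' @return a `transition_matrix` object.
#' @export
estimate_transition_matrix <- function(bouts, n_arms, pseudo_count = 0,
                                       bee_id = NA_character_) {
  if (n_arms < 2) stop("`n_arms` must be >= 2", call. = FALSE)
  if (pseudo_count < 0) stop("`pseudo_count` must be >= 0", call. = FALSE)
  if (is.data.frame(bouts)) {
    if (is.na(bee_id) && "bee_id" %in% names(bouts)) {
      ids <- unique(bouts$bee_id)
      if (length(ids) != 1L)
        stop("visits contain multiple bees; estimate one matrix per bee",
             call. = FALSE)
      bee_id <- as.character(ids)
    }
    ord <- if ("visit_index" %in% names(bouts))
      order(bouts$bout_index, bouts$visit_index) else order(bouts$bout_index)
    bouts <- bouts[ord, , drop = FALSE]
    bouts <- split(as.integer(bouts$arm_id), bouts$bout_index)
  }
  counts <- matrix(0L, n_arms, n_arms)
  starts <- integer(n_arms)
  for (arms in bouts) {
    arms <- validate_arms(arms, n_arms, allow_empty = TRUE)
    if (length(arms) == 0L) next
    starts[arms[1L]] <- starts[arms[1L]] + 1L
    if (length(arms) > 1L) {
      from <- arms[-length(arms)]
      to <- arms[-1L]
      for (i in seq_along(from))
        counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    }
  }
  if (sum(counts) == 0L)
    stop("no transitions observed for bee ", bee_id, call. = FALSE)
  num <- counts + pseudo_count
  rs <- rowSums(num)
  P <- matrix(0, n_arms, n_arms)
  for (a in seq_len(n_arms)) {
    if (rs[a] > 0) P[a, ] <- num[a, ] / rs[a]
    else P[a, ] <- rep(1 / n_arms, n_arms)  # unvisited "from" arm: uniform
  }
  sd_ <- if (sum(starts) > 0) starts / sum(starts) else rep(1 / n_arms, n_arms)
  new_transition_matrix(bee_id, n_arms, P, counts, sd_)
}

#' Draw a random transition matrix
#'
#' Each row is drawn uniformly on the probability simplex (flat Dirichlet)
#' over the allowed destination arms; with `forbid_self` the diagonal is
#' fixed at zero. Used for the "chance alone" baseline.
#'
#' @param n_arms number of arms (>= 2).
#' @param forbid_self exclude self-transitions (default `FALSE`).
#' @param bee_id identifier carried on the result.
#' @return a `transition_matrix` with uniform start distribution.
#' @export
random_transition_matrix <- function(n_arms, forbid_self = FALSE,
                                     bee_id = NA_character_) {
  if (n_arms < 2) stop("`n_arms` must be >= 2", call. = FALSE)
  P <- matrix(0, n_arms, n_arms)
  for (a in seq_len(n_arms)) {
    allowed <- if (forbid_self) setdiff(seq_len(n_arms), a) else seq_len(n_arms)
    g <- rgamma(length(allowed), shape = 1)   # flat Dirichlet via Gamma(1)
    P[a, allowed] <- g / sum(g)
  }
  new_transition_matrix(bee_id, n_arms, P,
                        counts = matrix(0L, n_arms, n_arms),
                        start_dist = rep(1 / n_arms, n_arms))
}

# Row-wise cumulative sums via one matrix product (upper-triangular ones).
row_cumsum <- function(M) {
  k <- ncol(M)
  U <- matrix(0, k, k)
  U[upper.tri(U, diag = TRUE)] <- 1
  M %*% U
}

#' Simulate Markov-chain maze bouts
#'
#' Simulant bouts start at an arm drawn from the matrix's start
#' distribution, then move arm-to-arm under the transition matrix until all
#' arms have been visited or a visit cap is reached (default `12 * n_arms`),
#' mirroring the real task's end condition (the bee is fed to repletion at
#' the last undepleted arm). Bouts hitting the cap are flagged truncated.
#' All bouts are advanced in lock-step, so large batches are cheap.
#'
#' @param tm a `transition_matrix`.
#' @param n_bouts number of bouts to simulate.
#' @param cap maximum visits per bout.
#' @param return_sequences also return the visit sequences (list column).
#' @return data frame with one row per bout: `bout_index`, `n_visits`,
#'   `distinct_arms_visited`, `errors`, `completed`, `truncated`; with
#'   `return_sequences`, an extra list column `arms`.
#' @export
simulate_markov_bouts <- function(tm, n_bouts, cap = 12L * tm$n_arms,
                                  return_sequences = FALSE) {
  stopifnot(inherits(tm, "transition_matrix"))
  k <- tm$n_arms
  if (n_bouts == 0L)
    return(data.frame(bout_index = integer(), n_visits = integer(),
                      distinct_arms_visited = integer(), errors = integer(),
                      completed = logical(), truncated = logical()))
  if (any(rowSums(tm$P) <= 0))
    stop("transition matrix has an all-zero row", call. = FALSE)
  n <- as.integer(n_bouts)
  cumP <- row_cumsum(tm$P)
  cur <- sample.int(k, n, replace = TRUE, prob = tm$start_dist)
  visited <- matrix(FALSE, n, k)
  visited[cbind(seq_len(n), cur)] <- TRUE
  n_visits <- rep(1L, n)
  n_distinct <- rep(1L, n)
  seqs <- if (return_sequences) lapply(cur, function(a) a) else NULL
  active <- which(n_distinct < k & n_visits < cap)
  while (length(active)) {
    u <- runif(length(active))
    cm <- cumP[cur[active], , drop = FALSE]
    nxt <- pmin.int(rowSums(cm < u) + 1L, k)
    cur[active] <- nxt
    first <- !visited[cbind(active, nxt)]
    visited[cbind(active, nxt)] <- TRUE
    n_distinct[active] <- n_distinct[active] + first
    n_visits[active] <- n_visits[active] + 1L
    if (return_sequences)
      for (j in seq_along(active))
        seqs[[active[j]]] <- c(seqs[[active[j]]], nxt[j])
    active <- active[n_distinct[active] < k & n_visits[active] < cap]
  }
  out <- data.frame(bout_index = seq_len(n),
                    n_visits = n_visits,
                    distinct_arms_visited = n_distinct,
                    errors = n_visits - n_distinct,
                    completed = n_distinct == k,
                    truncated = n_distinct < k & n_visits >= cap)
  if (return_sequences) out$arms <- I(seqs)
  out
}

#' Simulate one simulant bout
#'
#' Convenience wrapper around [simulate_markov_bouts()] returning the visit
#' sequence of a single bout.
#'
#' @inheritParams simulate_markov_bouts
#' @return list with `arms` (integer sequence), `errors`, `completed`,
#'   `truncated`.
#' @export
simulate_simulant_bout <- function(tm, cap = 12L * tm$n_arms) {
  b <- simulate_markov_bouts(tm, 1L, cap = cap, return_sequences = TRUE)
  list(arms = b$arms[[1L]], errors = b$errors[1L],
       completed = b$completed[1L], truncated = b$truncated[1L])
}

#' Generate simulant datasets
#'
#' Builds replicate datasets in which each real bee is replaced by a
#' simulant moving under that bee's transition matrix, inheriting the bee's
#' covariates and bout count. Replicates are generated one at a time via a
#' callback so large replicate counts never hold all bouts in memory.
#'
#' @param matrices named list of `transition_matrix` objects (one per bee).
#' @param covariates optional data frame with `bee_id` plus covariate
#'   columns (e.g. `size_mm`, `age_days`); carried onto simulant bouts.
#' @param n_bouts_per_bee bouts per simulant; either a single number or a
#'   named vector keyed by bee id (the real bees' test-bout counts).
#' @param n_replicates number of simulant datasets.
#' @param cap per-bout visit cap.
#' @param seed integer seed; the stream is reproducible given the seed.
#' @param callback optional `function(replicate_id, bouts_df)` called per
#'   replicate; when supplied, per-replicate data are not accumulated.
#' @return invisibly, a list of per-replicate bout data frames (columns
#'   `bee_id`, `bout_index`, `errors`, `completed`, `truncated` plus
#'   covariates), or `NULL` when a callback is used.
#' @export
generate_simulant_datasets <- function(matrices, covariates = NULL,
                                       n_bouts_per_bee = 10L,
                                       n_replicates = 10000L,
                                       cap = NULL, seed = NULL,
                                       callback = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(matrices, function(m) as.character(m$bee_id), character(1))
  if (is.null(names(matrices))) names(matrices) <- ids
  if (!is.null(covariates)) {
    miss <- setdiff(ids, as.character(covariates$bee_id))
    if (length(miss))
      stop("covariates missing for bee(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  nb <- if (length(n_bouts_per_bee) == 1L)
    setNames(rep(as.integer(n_bouts_per_bee), length(ids)), ids)
  else {
    if (!all(ids %in% names(n_bouts_per_bee)))
      stop("`n_bouts_per_bee` must cover every bee id", call. = FALSE)
    setNames(as.integer(n_bouts_per_bee[ids]), ids)
  }
  keep <- is.null(callback)
  out <- if (keep) vector("list", n_replicates) else NULL
  if (n_replicates == 0L) return(invisible(out))
  for (r in seq_len(n_replicates)) {
    per_bee <- lapply(seq_along(ids), function(i) {
      tm <- matrices[[i]]
      b <- simulate_markov_bouts(
        tm, nb[[ids[i]]],
        cap = if (is.null(cap)) 12L * tm$n_arms else cap)
      b$bee_id <- ids[i]
      b
    })
    df <- do.call(rbind, per_bee)
    if (!is.null(covariates))
      df <- merge(df, covariates, by = "bee_id", sort = FALSE)
    if (keep) out[[r]] <- df else callback(r, df)
  }
  invisible(out)
}

#' Per-dataset performance statistic
#'
#' `mean_errors` is the grand mean of per-bout errors. `model_intercept`
#' refits the validation GLMM — per-bout errors as a Poisson count on body
#' size and age with a per-bee random intercept — and extracts the fixed
#' intercept; on non-convergence it falls back to `mean_errors` with a
#' warning and a `fallback` attribute.
#'
#' @param bouts data frame with `bee_id` and `errors`, plus `size_mm` and
#'   `age_days` for the model statistic.
#' @param statistic `"mean_errors"` or `"model_intercept"`.
#' @return a single number (with attribute `fallback = TRUE` if the model
#'   statistic fell back to the mean).
#' @export
dataset_statistic <- function(bouts, statistic = c("mean_errors",
                                                   "model_intercept")) {
  statistic <- match.arg(statistic)
  if (statistic == "mean_errors") return(mean(bouts$errors))
  need <- c("size_mm", "age_days", "bee_id", "errors")
  miss <- setdiff(need, names(bouts))
  if (length(miss))
    stop("model_intercept needs column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else rep(0, length(v))
  bouts$size_std <- std(bouts$size_mm)
  bouts$age_std <- std(bouts$age_days)
  fit <- tryCatch(
    suppressMessages(lme4::glmer(
      errors ~ size_std + age_std + (1 | bee_id),
      data = bouts, family = poisson,
      control = lme4::glmerControl(calc.derivs = FALSE))),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    warning("validation GLMM did not converge; using mean_errors fallback",
            call. = FALSE)
    return(structure(mean(bouts$errors), fallback = TRUE))
  }
  unname(lme4::fixef(fit)[1L])
}

#' Percentile (Monte-Carlo) p-value
#'
#' Position of the observed statistic within the simulated null
#' distribution, with the add-one correction `p = (1 + #{null <= obs}) /
#' (N + 1)` for the lower tail (mirrored for the upper tail), so p is never
#' exactly zero. The lower tail answers "did the real bees make fewer
#' errors than the null?".
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of simulated statistics.
#' @param tail `"lower"` or `"upper"`.
#' @return p-value in (0, 1].
#' @export
percentile_p_value <- function(observed, null_values,
                               tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (length(null_values) == 0L)
    stop("`null_values` is empty", call. = FALSE)
  n_le <- if (tail == "lower") sum(null_values <= observed)
          else sum(null_values >= observed)
  (1 + n_le) / (length(null_values) + 1)
}

#' Monte-Carlo validation of RAM performance
#'
#' Runs the full movement-rule validation: score the real cohort, estimate
#' one transition matrix per bee from its test bouts, simulate
#' `n_replicates` simulant datasets (empirical matrices, or random matrices
#' for the chance baseline), compute the performance statistic for every
#' dataset, and place the observed statistic in the null distribution.
#'
#' @param visits visit-log data frame for the cohort (test bouts are used
#'   for matrices; scoring uses the design's test bouts).
#' @param covariates optional per-bee covariates (needed for the model
#'   statistic).
#' @param design `"validation"` (default: 8 arms, last 10 of 20 bouts) or
#'   `"main"`.
#' @param n_replicates number of simulant datasets (study-scale default
#'   10000; reduce for quick checks).
#' @param statistic per-dataset statistic, see [dataset_statistic()].
#' @param null `"empirical"` (per-bee matrices) or `"random"` (random
#'   matrices, one per bee).
#' @param pseudo_count smoothing for matrix estimation.
#' @param forbid_self for random matrices, exclude self-transitions.
#' @param seed integer seed.
#' @return list of class `ram_validation`: `observed`, `null_values`,
#'   `p_value`, `tail`, `statistic`, `n_replicates`, `matrices`, `seed`.
#' @export
ram_validation <- function(visits, covariates = NULL,
                           design = c("validation", "main"),
                           n_replicates = 10000L,
                           statistic = c("mean_errors", "model_intercept"),
                           null = c("empirical", "random"),
                           pseudo_count = 0, forbid_self = FALSE,
                           seed = NULL) {
  design <- match.arg(design)
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  if (!is.null(seed)) set.seed(seed)
  d <- ram_design(design)
  bouts <- score_bouts(visits, d$n_arms)
  is_test <- !is.na(bouts$bout_type) & bouts$bout_type == "test"
  test_bouts <- if (any(is_test)) bouts[is_test, , drop = FALSE] else {
    do.call(rbind, lapply(split(bouts, bouts$bee_id),
                          function(b) tail(b[order(b$bout_index), ],
                                           d$n_test_bouts)))
  }
  if (!is.null(covariates))
    test_bouts <- merge(test_bouts, covariates, by = "bee_id", sort = FALSE)
  observed <- dataset_statistic(test_bouts, statistic)
  ids <- unique(as.character(test_bouts$bee_id))
  test_visits <- visits[
    (!is.na(visits$bout_type) & visits$bout_type == "test") |
      !"bout_type" %in% names(visits), , drop = FALSE]
  matrices <- lapply(ids, function(id) {
    if (null == "random")
      random_transition_matrix(d$n_arms, forbid_self = forbid_self,
                               bee_id = id)
    else
      estimate_transition_matrix(
        test_visits[test_visits$bee_id == id, , drop = FALSE],
        n_arms = d$n_arms, pseudo_count = pseudo_count, bee_id = id)
  })
  names(matrices) <- ids
  nb <- table(test_bouts$bee_id)[ids]
  null_values <- numeric(n_replicates)
  generate_simulant_datasets(
    matrices, covariates = covariates,
    n_bouts_per_bee = setNames(as.integer(nb), ids),
    n_replicates = n_replicates,
    callback = function(r, df) null_values[r] <<- dataset_statistic(df, statistic))
  p <- percentile_p_value(observed, null_values, tail = "lower")
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, tail = "lower", statistic = statistic,
                 n_replicates = as.integer(n_replicates),
                 null = null, matrices = matrices, seed = seed),
            class = "ram_validation")
}

#' @export
#' @method print ram_validation
#' @keywords internal
print.ram_validation <- function(x, ...) {
  cat(sprintf(
    "RAM validation (%s null, %d replicates)\n  statistic: %s\n  observed: %.4f\n  null mean: %.4f\n  percentile p (lower tail): %.4g\n",
    x$null, x$n_replicates, x$statistic, x$observed, mean(x$null_values),
    x$p_value))
  invisible(x)
}

#' Fast simulant null distribution of mean errors
#'
#' Equivalent to running [generate_simulant_datasets()] and taking the
#' `mean_errors` statistic per replicate, but batches all replicates of each
#' bee through one vectorised Markov simulation, which makes large replicate
#' counts fast. Only the `mean_errors` statistic is supported.
#'
#' @inheritParams generate_simulant_datasets
#' @return numeric vector of length `n_replicates`: per-replicate grand mean
#'   of per-bout errors.
#' @export
simulant_null_mean_errors <- function(matrices, n_bouts_per_bee = 10L,
                                      n_replicates = 10000L, cap = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(matrices, function(m) as.character(m$bee_id), character(1))
  nb <- if (length(n_bouts_per_bee) == 1L)
    setNames(rep(as.integer(n_bouts_per_bee), length(ids)), ids)
  else as.integer(n_bouts_per_bee[ids])
  total_err <- matrix(0, nrow = n_replicates, ncol = length(matrices))
  n_bouts_tot <- 0L
  for (i in seq_along(matrices)) {
    tm <- matrices[[i]]
    nbi <- nb[[i]]
    n_bouts_tot <- n_bouts_tot + nbi
    b <- simulate_markov_bouts(
      tm, n_replicates * nbi,
      cap = if (is.null(cap)) 12L * tm$n_arms else cap)
    # bouts laid out replicate-major: rep 1 gets bouts 1..nbi, etc.
    total_err[, i] <- rowSums(matrix(b$errors, nrow = n_replicates,
                                     byrow = TRUE))
  }
  rowSums(total_err) / n_bouts_tot
}
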