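#' foragecog: lab-to-field analysis of bumblebee memory and foraging
#'
#' See the package vignette `vignette("memory-foraging-pipeline")` for the
#' scientific background and an end-to-end worked example.
#'
#' @keywords internal
#' @importFrom stats aggregate as.formula coef complete.cases cor logLik
#'   median na.omit poisson pnorm predict prcomp qnorm quantile rbinom rgamma
#'   rlnorm rnorm rpois runif sd setNames vcov Gamma approx rank fitted
#'   resid lm poly
#' @importFrom utils head tail
"_PACKAGE"

# ---------------------------------------------------------------------------
# Radial-arm-maze (RAM) win-shift scoring.
#
# The maze is a win-shift paradigm: every arm holds a single reward per bout,
# so any return to an arm already visited within the same bout is an "error".
# Performance is summarised per bee as the mean error count over the final
# test bouts (the RAM score), analysed downstream on a log(n+1) scale.
# ---------------------------------------------------------------------------

#' Validate a single bout's visit sequence
#'
#' @param arms integer vector of visited arm ids, in visit order.
#' @param n_arms number of arms in the maze (>= 2).
#' @param allow_empty if `TRUE`, an empty sequence is tolerated (used when
#'   scanning unscored bouts); scored bouts must be non-empty.
#' @return the validated integer vector, invisibly.
#' @keywords internal
validate_arms <- function(arms, n_arms, allow_empty = FALSE) {
  if (length(n_arms) != 1L || is.na(n_arms) || n_arms < 2)
    stop("`n_arms` must be a single integer >= 2", call. = FALSE)
  arms <- as.integer(arms)
  if (length(arms) == 0L) {
    if (allow_empty) return(invisible(arms))
    stop("empty bout: no arm visits to score", call. = FALSE)
  }
  if (anyNA(arms) || any(arms < 1L) || any(arms > n_arms))
    stop("arm ids must lie in 1..", n_arms, call. = FALSE)
  invisible(arms)
}

#' Score one RAM bout
#'
#' Counts win-shift errors in a single foraging bout: every visit to an arm
#' already visited earlier in the same bout is an error, including an
#' immediate re-landing on the current arm (the reward platform is replaced
#' after every landing, so a re-landing is a revisit to a depleted arm). No
#' state carries across bouts; all arms are re-baited between bouts.
#'
#' @param arms integer vector of visited arm ids in visit order.
#' @param n_arms number of maze arms.
#' @param timestamps optional non-decreasing visit times in seconds, one per
#'   visit; used only for the bout duration.
#' @param count_immediate_repeats if `FALSE`, an immediate return to the arm
#'   just visited is not counted as an error (sensitivity-analysis variant;
#'   the default counts it).
#' @return a list of class `bout_score` with `errors`,
#'   `distinct_arms_visited`, `completed` (all arms visited) and
#'   `duration_min` (`NA` if no timestamps).
#' @examples
#' score_bout(c(1, 2, 1, 3, 4), n_arms = 4)  # one revisit -> 1 error
#' @export
score_bout <- function(arms, n_arms, timestamps = NULL,
                       count_immediate_repeats = TRUE) {
  arms <- as.integer(arms)
  validate_arms(arms, n_arms)
  if (!count_immediate_repeats && length(arms) > 1L) {
    keep <- c(TRUE, arms[-1L] != arms[-length(arms)])
    arms_eff <- arms[keep]
  } else {
    arms_eff <- arms
  }
  distinct <- length(unique(arms))
  errors <- length(arms_eff) - length(unique(arms_eff))
  dur <- NA_real_
  if (!is.null(timestamps)) {
    if (length(timestamps) != length(arms))
      stop("`timestamps` must have one entry per visit", call. = FALSE)
    if (is.unsorted(timestamps))
      stop("`timestamps` must be non-decreasing", call. = FALSE)
    dur <- (max(timestamps) - min(timestamps)) / 60
  }
  structure(
    list(errors = as.integer(errors),
         distinct_arms_visited = as.integer(distinct),
         completed = distinct == n_arms,
         duration_min = dur),
    class = "bout_score")
}

#' Score every bout in a visits table
#'
#' @param visits data frame in the visit-log dialect: columns `bee_id`,
#'   `bout_index`, `arm_id`, optionally `bout_type`, `visit_index`,
#'   `timestamp_s`. Rows are ordered within bout by `visit_index` (or by
#'   `timestamp_s` when present).
#' @param n_arms number of maze arms.
#' @inheritParams score_bout
#' @return data frame with one row per (bee, bout): `bee_id`, `bout_index`,
#'   `bout_type`, `errors`, `distinct_arms_visited`, `completed`,
#'   `n_visits`, `duration_min`.
#' @export
score_bouts <- function(visits, n_arms, count_immediate_repeats = TRUE) {
  req <- c("bee_id", "bout_index", "arm_id")
  miss <- setdiff(req, names(visits))
  if (length(miss))
    stop("visits table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"bout_type" %in% names(visits)) visits$bout_type <- NA_character_
  ord <- if ("visit_index" %in% names(visits)) {
    order(visits$bee_id, visits$bout_index, visits$visit_index)
  } else if ("timestamp_s" %in% names(visits)) {
    order(visits$bee_id, visits$bout_index, visits$timestamp_s)
  } else {
    order(visits$bee_id, visits$bout_index)
  }
  visits <- visits[ord, , drop = FALSE]
  key <- interaction(visits$bee_id, visits$bout_index, drop = TRUE,
                     lex.order = TRUE)
  idx <- split(seq_len(nrow(visits)), key)
  rows <- lapply(idx, function(i) {
    arms <- visits$arm_id[i]
    ts <- if ("timestamp_s" %in% names(visits)) visits$timestamp_s[i] else NULL
    bs <- score_bout(arms, n_arms, timestamps = ts)
    data.frame(bee_id = visits$bee_id[i[1L]],
               bout_index = visits$bout_index[i[1L]],
               bout_type = visits$bout_type[i[1L]],
               errors = bs$errors,
               distinct_arms_visited = bs$distinct_arms_visited,
               completed = bs$completed,
               n_visits = length(arms),
               duration_min = bs$duration_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$bee_id, out$bout_index), , drop = FALSE]
}

#' Bout designs
#'
#' The main study design is 12 bouts per bee with the last 3 scored as test
#' bouts; the maze-validation design is 20 bouts with the last 10 as test
#' bouts on an eight-arm maze.
#'
#' @param design `"main"` or `"validation"`.
#' @return list with `n_bouts`, `n_test_bouts`, `n_arms`.
#' @export
ram_design <- function(design = c("main", "validation")) {
  design <- match.arg(design)
  switch(design,
         main = list(n_bouts = 12L, n_test_bouts = 3L, n_arms = 4L),
         validation = list(n_bouts = 20L, n_test_bouts = 10L, n_arms = 8L))
}

#' Per-bee RAM scores
#'
#' The RAM score of a bee is the arithmetic mean of its win-shift error
#' counts over the final `test_bout_count` test bouts, with a natural-log
#' `log(score + 1)` companion used in downstream models. Bouts flagged
#' `"test"` in `bout_type` are used when that column is informative;
#' otherwise the last `test_bout_count` bouts by `bout_index` are taken.
#' Early-terminated bouts (not all arms visited) are scored by the same
#' error rule and included; nothing is imputed.
#'
#' @param visits visit-log data frame (see [score_bouts()]).
#' @param n_arms number of maze arms; defaults from `design`.
#' @param test_bout_count number of final test bouts to average; defaults
#'   from `design`.
#' @param design `"main"` (12 bouts, last 3 test) or `"validation"`
#'   (20 bouts, last 10 test).
#' @return data frame: `bee_id`, `ram_score`, `ram_score_log1p`,
#'   `n_test_bouts`, `n_bouts`.
#' @examples
#' v <- data.frame(bee_id = "b1", bout_index = rep(1:4, each = 4),
#'                 bout_type = rep(c("training", rep("test", 3)), each = 4),
#'                 visit_index = rep(1:4, 4),
#'                 arm_id = c(1, 2, 1, 3, 1, 2, 3, 4, 1, 1, 2, 3, 4, 3, 2, 1))
#' ram_scores(v, n_arms = 4, test_bout_count = 3)
#' @export
ram_scores <- function(visits, n_arms = NULL, test_bout_count = NULL,
                       design = c("main", "validation")) {
  design <- match.arg(design)
  d <- ram_design(design)
  if (is.null(n_arms)) n_arms <- d$n_arms
  if (is.null(test_bout_count)) test_bout_count <- d$n_test_bouts
  bouts <- score_bouts(visits, n_arms)
  per_bee <- split(bouts, bouts$bee_id)
  rows <- lapply(per_bee, function(b) {
    b <- b[order(b$bout_index), , drop = FALSE]
    is_test <- !is.na(b$bout_type) & b$bout_type == "test"
    cand <- if (any(is_test)) b[is_test, , drop = FALSE] else b
    if (nrow(cand) < test_bout_count)
      stop("bee ", b$bee_id[1L], ": only ", nrow(cand),
           " test bout(s), need ", test_bout_count, call. = FALSE)
    sel <- tail(cand, test_bout_count)
    s <- mean(sel$errors)
    data.frame(bee_id = b$bee_id[1L],
               ram_score = s,
               ram_score_log1p = log1p(s),
               n_test_bouts = as.integer(test_bout_count),
               n_bouts = nrow(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bout duration summary
#'
#' Durations are last-minus-first visit timestamp per bout, in minutes.
#'
#' @param visits visit-log data frame with a `timestamp_s` column.
#' @param n_arms number of maze arms.
#' @param bout_type optional filter, e.g. `"test"`.
#' @return list with `durations_min` (per-bout vector), `median`, `q1`, `q3`.
#' @export
bout_durations <- function(visits, n_arms, bout_type = NULL) {
  if (!"timestamp_s" %in% names(visits))
    stop("visit log has no `timestamp_s` column; durations unavailable",
         call. = FALSE)
  b <- score_bouts(visits, n_arms)
  if (!is.null(bout_type)) b <- b[!is.na(b$bout_type) & b$bout_type %in% bout_type, ]
  if (anyNA(b$duration_min))
    stop("some bouts are missing timestamps", call. = FALSE)
  q <- quantile(b$duration_min, c(0.25, 0.5, 0.75), names = FALSE)
  list(durations_min = b$duration_min, median = q[2L], q1 = q[1L], q3 = q[3L])
}
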