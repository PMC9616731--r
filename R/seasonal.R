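# ---------------------------------------------------------------------------
# Seasonal analysis scaffolding: ordered-quantile normalization, composite
# weather score, week-residualization, the four-spec candidate set and the
# delta-AIC/AICc selection protocol. Model fitting itself is delegated to
# lme4 (mixed models), mgcv (smooths) and survival (Cox frailty); this
# module owns the transforms, the candidate sets and the selection rule.
# ---------------------------------------------------------------------------

#' Ordered-quantile (ORQ) normalization
#'
#' Maps data to normal quantiles through their ranks:
#' `z_i = qnorm(rank(x_i) / (n + 1))`, with average ranks for ties. New
#' data are transformed by monotone linear interpolation of the fitted
#' rank-quantile mapping, with linear tail extrapolation; an inverse is
#' provided. The transform is strictly monotone, so orderings (and any
#' sign-reversal weeks derived from fitted models) are preserved.
#'
#' @param x numeric vector, length >= 3, finite, not constant.
#' @return list of class `orq_transform` with the fitted mapping, plus the
#'   transformed training sample in `$z`.
#' @examples
#' o <- orq_fit_transform(c(1, 2, 3))
#' o$z  # approx -0.674, 0, 0.674
#' @export
orq_fit_transform <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 values", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("values must be finite and non-missing", call. = FALSE)
  if (max(x) == min(x))
    stop("constant input: ORQ transform undefined", call. = FALSE)
  n <- length(x)
  z <- qnorm(rank(x, ties.method = "average") / (n + 1))
  ord <- order(x)
  xs <- x[ord]; zs <- z[ord]
  keep <- !duplicated(xs)
  obj <- structure(list(x = xs[keep], zq = zs[keep], n = n),
                   class = "orq_transform")
  obj$z <- z
  obj
}

#' @rdname orq_fit_transform
#' @param object a fitted `orq_transform`.
#' @param newdata values to transform.
#' @param ... unused.
#' @export
predict.orq_transform <- function(object, newdata, ...) {
  orq_interp(object$x, object$zq, as.numeric(newdata))
}

#' @rdname orq_fit_transform
#' @param z normal-scale values to map back to the data scale.
#' @export
orq_inverse <- function(object, z) {
  orq_interp(object$zq, object$x, as.numeric(z))
}

# monotone piecewise-linear map through (xs, ys) with linear tails
orq_interp <- function(xs, ys, xout) {
  k <- length(xs)
  out <- approx(xs, ys, xout = xout, rule = 2, ties = "ordered")$y
  lo <- xout < xs[1L]
  hi <- xout > xs[k]
  if (any(lo)) {
    s <- (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
    out[lo] <- ys[1L] + s * (xout[lo] - xs[1L])
  }
  if (any(hi)) {
    s <- (ys[k] - ys[k - 1L]) / (xs[k] - xs[k - 1L])
    out[hi] <- ys[k] + s * (xout[hi] - xs[k])
  }
  out
}

#' Composite weather score via PCA
#'
#' Standardizes daily temperature, humidity and wind speed and takes the
#' first principal component as a single weather axis; the sign is fixed so
#' the temperature loading is positive (higher score = hotter, drier days).
#' Constant columns are dropped; days with missing values are deleted
#' listwise with a message.
#'
#' @param weather data frame with `date`, `temp_C`, `humidity_pct`,
#'   `wind_ms`.
#' @return list of class `weather_composite`: `loadings` (unit norm),
#'   `variance_explained`, `scores` (data frame `date`, `score`).
#' @export
weather_composite <- function(weather) {
  check_columns(weather, c("date", "temp_C", "humidity_pct", "wind_ms"),
                "weather")
  vars <- c("temp_C", "humidity_pct", "wind_ms")
  cc <- complete.cases(weather[vars])
  if (!all(cc))
    message(sum(!cc), " day(s) dropped for missing weather values")
  w <- weather[cc, , drop = FALSE]
  if (nrow(w) < 3L) stop("need at least 3 complete days", call. = FALSE)
  keep <- vars[vapply(w[vars], function(v) sd(v) > 0, logical(1))]
  if (!length(keep)) stop("all weather variables constant", call. = FALSE)
  X <- scale(as.matrix(w[keep]))
  if (length(keep) == 1L) {
    loadings <- setNames(1, keep)
    scores <- as.numeric(X)
    ve <- 1
  } else {
    pc <- prcomp(X, center = FALSE, scale. = FALSE)
    loadings <- pc$rotation[, 1L]
    scores <- pc$x[, 1L]
    ve <- pc$sdev[1L]^2 / sum(pc$sdev^2)
    flip_on <- if ("temp_C" %in% keep) "temp_C" else keep[1L]
    if (loadings[flip_on] < 0) {
      loadings <- -loadings
      scores <- -scores
    }
  }
  structure(list(loadings = loadings, variance_explained = ve,
                 scores = data.frame(date = w$date, score = unname(scores))),
            class = "weather_composite")
}

#' Residualize a score on week of year
#'
#' Fits a penalized-spline smooth of the score on week (smoothing parameter
#' by GCV) and returns the residuals, so downstream "weather" effects are
#' those over and above the seasonal trend. With fewer than `min_weeks`
#' distinct weeks the smooth is replaced by a cubic polynomial, with a
#' warning.
#'
#' @param scores numeric scores (e.g. the weather composite).
#' @param week week of year per score.
#' @param min_weeks minimum distinct weeks for the spline (default 8).
#' @return numeric residuals, same length as `scores`.
#' @export
residualize_on_week <- function(scores, week, min_weeks = 8L) {
  nw <- length(unique(week))
  if (nw >= min_weeks) {
    k <- min(10L, nw)
    fit <- mgcv::gam(scores ~ s(week, k = k), method = "GCV.Cp",
                     data = data.frame(scores = scores, week = week))
    as.numeric(resid(fit))
  } else {
    warning("only ", nw, " distinct weeks; falling back to a cubic ",
            "polynomial", call. = FALSE)
    deg <- min(3L, nw - 1L)
    as.numeric(resid(lm(scores ~ poly(week, deg))))
  }
}

#' Candidate model sets
#'
#' Builds the four-model candidate set used for every analysis: a null
#' model (intercept + random terms), the full covariate model, the
#' covariate model plus RAM score (log(n+1)), and the covariate model plus
#' the RAM score x week interaction. Response, family and random-effect
#' structure follow the per-analysis conventions: nectar efficiency is a
#' Gaussian mixed model on the ORQ scale with correlated bee
#' intercept/experience slopes and a colony intercept; pollen efficiency a
#' log-link Gamma mixed model with linear experience and uncorrelated
#' slopes; survival a Cox model with a colony frailty; lifetime effort a
#' Poisson mixed model with an observation-level random intercept; the
#' control comparison swaps RAM score for the tested/control treatment
#' contrast.
#'
#' @param analysis one of `"nectar"`, `"pollen"`, `"survival"`, `"effort"`,
#'   `"control_comparison"`.
#' @return list of four `model_spec` lists (fields `name`, `response`,
#'   `transform`, `fixed`, `random`, `family`, `formula`, `k_order`).
#' @export
candidate_set <- function(analysis = c("nectar", "pollen", "survival",
                                       "effort", "control_comparison")) {
  analysis <- match.arg(analysis)
  mk <- function(name, response, transform, fixed, random, family) {
    rhs <- paste(c(fixed, random), collapse = " + ")
    if (!length(fixed)) rhs <- paste(c("1", random), collapse = " + ")
    list(name = name, analysis = analysis, response = response,
         transform = transform, fixed = fixed, random = random,
         family = family,
         formula = as.formula(paste(response, "~", rhs)))
  }
  key <- "ram_log1p"
  if (analysis == "control_comparison") key <- "tested"
  covs <- switch(analysis,
    nectar = c("week", "age_at_release_days", "size_mm", "year",
               "poly(experience_days, 2)", "weather_resid"),
    pollen = c("week", "age_at_release_days", "size_mm", "year",
               "experience_days", "weather_resid"),
    survival = c("week", "age_at_release_days", "size_mm", "year",
                 "weather_resid"),
    effort = c("week", "age_at_release_days", "size_mm", "year",
               "weather_resid"),
    control_comparison = c("week", "age_at_release_days", "size_mm", "year",
                           "poly(experience_days, 2)", "weather_resid"))
  random <- switch(analysis,
    nectar = c("(experience_days | bee_id)", "(1 | colony_id)"),
    pollen = c("(1 | bee_id)", "(0 + experience_days | bee_id)",
               "(1 | colony_id)"),
    survival = "frailty(colony_id)",
    effort = c("(1 | colony_id)", "(1 | bee_id)"),  # bee term is the OLRE
    control_comparison = c("(experience_days | bee_id)", "(1 | colony_id)"))
  response <- switch(analysis,
    nectar = "nectar_eff",
    pollen = "pollen_eff",
    survival = "Surv(survival_days, event)",
    effort = "n_trips_lifetime",
    control_comparison = "nectar_eff")
  transform <- if (analysis %in% c("nectar", "control_comparison")) "orq"
               else "none"
  family <- switch(analysis,
    nectar = "gaussian", pollen = "gamma_log", survival = "coxph_frailty",
    effort = "poisson", control_comparison = "gaussian")
  list(
    mk("null", response, transform, character(), random, family),
    mk("covariates", response, transform, covs, random, family),
    mk("covariates_ram", response, transform, c(covs, key), random, family),
    mk("covariates_ram_week", response, transform,
       c(covs, key, paste0(key, ":week")), random, family))
}

fit_one_spec <- function(spec, data) {
  orq <- NULL
  if (spec$transform == "orq") {
    y <- data[[spec$response]]
    orq <- orq_fit_transform(y)
    data[[spec$response]] <- orq$z
  }
  family <- spec$family
  fit <- NULL
  err <- NULL
  withCallingHandlers(
    tryCatch({
      if (family == "gaussian") {
        fit <- lme4::lmer(spec$formula, data = data, REML = FALSE,
                          control = lme4::lmerControl(calc.derivs = FALSE))
      } else if (family == "gamma_log") {
        fit <- lme4::glmer(spec$formula, data = data,
                           family = Gamma(link = "log"),
                           control = lme4::glmerControl(calc.derivs = FALSE))
      } else if (family == "poisson") {
        fit <- lme4::glmer(spec$formula, data = data, family = poisson,
                           control = lme4::glmerControl(calc.derivs = FALSE))
      } else if (family == "coxph_frailty") {
        env <- new.env(parent = environment())
        assign("Surv", survival::Surv, envir = env)
        assign("frailty", survival::frailty, envir = env)
        f <- spec$formula
        environment(f) <- env
        fit <- survival::coxph(f, data = data)
      } else stop("unknown family: ", family)
    }, error = function(e) err <<- conditionMessage(e)),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  if (!is.null(err))
    return(structure(list(name = spec$name, spec = spec, converged = FALSE,
                          error = err),
                     class = "fit_result"))
  if (inherits(fit, "coxph")) {
    ll <- fit$loglik[length(fit$loglik)]
    # penalized (frailty) fits report effective df; fall back to the
    # coefficient count when the frailty variance collapses to zero
    k <- if (!is.null(fit$df)) sum(fit$df) else length(coef(fit))
    if (!is.finite(k)) k <- length(coef(fit))
    n <- fit$n
    est <- coef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))[seq_along(est)]
  } else {
    llo <- logLik(fit)
    ll <- as.numeric(llo)
    k <- attr(llo, "df")
    n <- stats::nobs(fit)
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
  }
  converged <- TRUE
  if (inherits(fit, "merMod")) {
    cc <- fit@optinfo$conv$opt
    if (!is.null(cc) && cc != 0) converged <- FALSE
  }
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      ci_lo = unname(est) - 1.96 * unname(se),
                      ci_hi = unname(est) + 1.96 * unname(se),
                      stringsAsFactors = FALSE)
  structure(list(name = spec$name, spec = spec, fit = fit, orq = orq,
                 logLik = ll, k = as.numeric(k), n = as.integer(n),
                 AIC = aic, AICc = aicc, coefficients = coefs,
                 converged = converged),
            class = "fit_result")
}

#' Fit a candidate set and select by the delta-AIC rule
#'
#' Fits every candidate with the appropriate backend and compares them on
#' AIC, or AICc when the sample is small relative to the largest model
#' (`n / k_max < 40`). The best model is the one with the lowest criterion;
#' a cut-off of 2 identifies models of comparable fit, among which the
#' simplest (fewest parameters) is selected. Models that fail to fit are
#' excluded with a warning.
#'
#' @param specs list of model specs from [candidate_set()].
#' @param data analysis data frame (see [build_analysis_data()]).
#' @param criterion `"auto"` (the n/k rule), `"AIC"` or `"AICc"`.
#' @return list of class `model_selection`: `fits`, `table` (per-spec
#'   criterion values and deltas), `selected` (spec name), `best_fit`,
#'   `criterion_used`, `trace` (human-readable selection log).
#' @export
fit_and_select <- function(specs, data, criterion = c("auto", "AIC",
                                                      "AICc")) {
  criterion <- match.arg(criterion)
  fits <- lapply(specs, fit_one_spec, data = data)
  names(fits) <- vapply(specs, `[[`, "", "name")
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no candidate model converged", call. = FALSE)
  if (any(!ok))
    warning("excluded from selection (no fit): ",
            paste(names(fits)[!ok], collapse = ", "), call. = FALSE)
  fok <- fits[ok]
  kmax <- max(vapply(fok, `[[`, 0, "k"))
  n <- max(vapply(fok, function(f) as.numeric(f$n), 0))
  used <- if (criterion == "auto") {
    if (n / kmax >= 40) "AIC" else "AICc"
  } else criterion
  crit <- vapply(fok, `[[`, 0, used)
  ks <- vapply(fok, `[[`, 0, "k")
  delta <- crit - min(crit)
  comparable <- which(delta <= 2)
  sel_i <- comparable[order(ks[comparable], crit[comparable])][1L]
  selected <- names(fok)[sel_i]
  tab <- data.frame(name = names(fok), k = ks, n = vapply(fok, `[[`, 0L, "n"),
                    logLik = vapply(fok, `[[`, 0, "logLik"),
                    AIC = vapply(fok, `[[`, 0, "AIC"),
                    AICc = vapply(fok, `[[`, 0, "AICc"),
                    delta = delta, stringsAsFactors = FALSE)
  tab <- tab[order(tab[[if (used == "AIC") "AIC" else "AICc"]]), ]
  rownames(tab) <- NULL
  trace <- c(sprintf("criterion: %s (n = %d, k_max = %d, n/k = %.1f)",
                     used, as.integer(n), as.integer(kmax), n / kmax),
             sprintf("%-22s k=%-4.3g %s=%.2f delta=%.2f", tab$name, tab$k,
                     used, tab[[used]], tab$delta),
             sprintf("selected: %s (simplest within delta <= 2)", selected))
  structure(list(fits = fits, table = tab, selected = selected,
                 best_fit = fok[[sel_i]], criterion_used = used,
                 trace = trace),
            class = "model_selection")
}

#' @export
#' @method print model_selection
#' @keywords internal
print.model_selection <- function(x, ...) {
  cat(paste(x$trace, collapse = "\n"), "\n")
  invisible(x)
}

#' Per-week slope of efficiency on RAM score
#'
#' For a fit containing the RAM x week interaction, the slope of the
#' response on RAM score at week `w` is `beta_ram + beta_int * w`; its
#' standard error follows from the coefficient covariance (delta method,
#' here exact since the slope is linear in the coefficients). Reports the
#' sign-reversal week (the root of the slope) when it falls inside the
#' supplied week grid.
#'
#' @param fit a `fit_result` whose model contains `ram_term` and its
#'   interaction with `week_term`.
#' @param weeks numeric grid of weeks.
#' @param ram_term,week_term coefficient names.
#' @return list of class `interaction_profile`: `profile` (data frame
#'   `week`, `slope`, `se`, `lo`, `hi`), `reversal_week` (`NA` when the
#'   root lies outside the grid), `beta_ram`, `beta_int`.
#' @export
interaction_profile <- function(fit, weeks, ram_term = "ram_log1p",
                                week_term = "week") {
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  int_names <- c(paste0(ram_term, ":", week_term),
                 paste0(week_term, ":", ram_term))
  int_term <- int_names[int_names %in% names(est)]
  if (!length(int_term) || !ram_term %in% names(est))
    stop("fit does not contain the ", ram_term, " x ", week_term,
         " interaction", call. = FALSE)
  int_term <- int_term[1L]
  V <- as.matrix(vcov(fit$fit))
  rn <- rownames(V)
  b_r <- est[[ram_term]]
  b_i <- est[[int_term]]
  v_rr <- V[ram_term, ram_term]
  v_ii <- V[int_term, int_term]
  v_ri <- V[ram_term, int_term]
  slope <- b_r + b_i * weeks
  se <- sqrt(pmax(0, v_rr + weeks^2 * v_ii + 2 * weeks * v_ri))
  rev_w <- if (b_i != 0) -b_r / b_i else NA_real_
  if (!is.na(rev_w) && (rev_w < min(weeks) || rev_w > max(weeks)))
    rev_w <- NA_real_
  structure(list(
    profile = data.frame(week = weeks, slope = slope, se = se,
                         lo = slope - 1.96 * se, hi = slope + 1.96 * se),
    reversal_week = rev_w, beta_ram = b_r, beta_int = b_i),
    class = "interaction_profile")
}

#' Assemble the per-trip analysis table
#'
#' Joins the efficiency records with per-bee RAM scores and daily
#' residualized weather scores, and adds the derived model covariates
#' (`ram_log1p`, `week`, `year` as a factor).
#'
#' @param eff efficiency table from [efficiency_table()] (or the trips of a
#'   [simulate_season()] object).
#' @param scores per-bee scores (`bee_id`, `ram_score`, `ram_score_log1p`);
#'   omit if `eff` already carries them.
#' @param weather_scores optional `date` + `weather_resid` table; omit if
#'   already joined.
#' @return data frame covering the candidate-set covariate vocabulary.
#' @export
build_analysis_data <- function(eff, scores = NULL, weather_scores = NULL) {
  if (!is.null(scores))
    eff <- merge(eff, scores[c("bee_id", "ram_score", "ram_score_log1p")],
                 by = "bee_id", sort = FALSE)
  if (!is.null(weather_scores))
    eff <- merge(eff, weather_scores, by = "date", all.x = TRUE,
                 sort = FALSE)
  check_columns(eff, c("bee_id", "colony_id", "ram_score_log1p",
                       "week_of_year"), "analysis data")
  eff$ram_log1p <- eff$ram_score_log1p
  eff$week <- eff$week_of_year
  if ("year" %in% names(eff)) eff$year <- factor(eff$year)
  if (!"weather_resid" %in% names(eff)) eff$weather_resid <- 0
  eff
}
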