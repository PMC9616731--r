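test_that("ORQ matches the closed-form rank quantiles", {
  o <- orq_fit_transform(c(1, 2, 3))
  expect_equal(o$z, qnorm(c(1, 2, 3) / 4))
  set.seed(25)
  x <- rexp(500)  # tie-free skewed input
  o2 <- orq_fit_transform(x)
  expect_equal(o2$z, qnorm(rank(x) / (length(x) + 1)))
})

test_that("ORQ is strictly monotone with an exact inverse on training data", {
  set.seed(26)
  x <- sort(rlnorm(100))
  o <- orq_fit_transform(x)
  z <- predict(o, x)
  expect_true(all(diff(z) > 0))
  expect_lt(max(abs(orq_inverse(o, z) - x)), 1e-9)
  # new data transform is monotone and tails extrapolate linearly
  xn <- c(min(x) - 1, x[3] + 1e-4, max(x) + 1)
  zn <- predict(o, xn)
  expect_lt(zn[1], min(z))
  expect_gt(zn[3], max(z))
})

test_that("ORQ normalizes skewed samples", {
  set.seed(27)
  x <- rgamma(400, 0.8)
  o <- orq_fit_transform(x)
  expect_lt(abs(mean(o$z)), 0.05)
  expect_equal(median(o$z), 0, tolerance = 0.02)
  expect_gt(stats::shapiro.test(o$z)$p.value, 0.05)
})

test_that("ORQ averages ranks for ties and rejects degenerate input", {
  o <- orq_fit_transform(c(1, 2, 2, 3))
  expect_equal(o$z[2], o$z[3])
  expect_error(orq_fit_transform(rep(1, 10)), "constant")
  expect_error(orq_fit_transform(c(1, 2)), "at least 3")
  expect_error(orq_fit_transform(c(1, 2, NA)), "finite")
})

test_that("weather composite matches eigen-decomposition oracles", {
  set.seed(28)
  n <- 4000
  # two perfectly correlated variables + one independent: population
  # leading eigenvalue 2 of 3
  a <- rnorm(n)
  w <- data.frame(date = Sys.Date() + 1:n, temp_C = a,
                  humidity_pct = a, wind_ms = rnorm(n))
  ve <- weather_composite(w)$variance_explained
  expect_equal(ve, 2 / 3, tolerance = 0.02)
  # spherical covariance: leading share tends to 1/3
  w2 <- data.frame(date = Sys.Date() + 1:n, temp_C = rnorm(n),
                   humidity_pct = rnorm(n), wind_ms = rnorm(n))
  expect_equal(weather_composite(w2)$variance_explained, 1 / 3,
               tolerance = 0.03)
})

test_that("weather composite fixes sign and handles constant columns", {
  set.seed(29)
  w <- simulate_weather("2018-04-02", "2018-09-30")
  wc <- weather_composite(w)
  expect_gt(wc$loadings[["temp_C"]], 0)
  expect_equal(sum(wc$loadings^2), 1)
  # single informative variable: scores equal the standardized variable
  w3 <- data.frame(date = Sys.Date() + 1:50, temp_C = rnorm(50),
                   humidity_pct = 1, wind_ms = 2)
  wc3 <- weather_composite(w3)
  expect_equal(wc3$scores$score, as.numeric(scale(w3$temp_C)))
  expect_equal(wc3$variance_explained, 1)
})

test_that("week-residualization annihilates smooth trends", {
  week <- rep(14:38, each = 7)
  # linear trends lie in the spline's unpenalized null space: exact
  r_lin <- residualize_on_week(0.2 * week + 1, week)
  expect_lt(max(abs(r_lin)), 1e-6 * sd(0.2 * week))
  # curved noise-free trends are absorbed to numerical-GCV accuracy
  sc <- 0.2 * week + 0.01 * (week - 25)^3 / 50
  r <- residualize_on_week(sc, week)
  expect_lt(max(abs(r)), 1e-2 * sd(sc))
})

test_that("week-residualization recovers the noise component", {
  set.seed(30)
  week <- sample(14:38, 500, replace = TRUE)
  noise <- rnorm(500, 0, 0.7)
  sc <- sin(week / 6) + noise
  r <- residualize_on_week(sc, week)
  expect_lt(abs(var(r) / var(noise) - 1), 0.1)
  expect_lt(abs(cor(r, sc - r)), 0.05)
})

test_that("few-week inputs fall back to a polynomial with a warning", {
  week <- rep(1:5, each = 10)
  sc <- week + rnorm(50)
  expect_warning(r <- residualize_on_week(sc, week), "polynomial")
  expect_lt(abs(cor(r, sc - r)), 1e-8)  # exact OLS orthogonality
})

test_that("candidate sets contain the four protocol models", {
  cs <- candidate_set("nectar")
  expect_length(cs, 4)
  expect_equal(vapply(cs, `[[`, "", "name"),
               c("null", "covariates", "covariates_ram",
                 "covariates_ram_week"))
  expect_true(all(vapply(cs, `[[`, "", "family") == "gaussian"))
  expect_true(all(vapply(cs, `[[`, "", "transform") == "orq"))
  expect_false(any(grepl("ram", cs[[2]]$fixed)))
  expect_true("ram_log1p" %in% cs[[3]]$fixed)
  expect_true("ram_log1p:week" %in% cs[[4]]$fixed)
  expect_true(any(grepl("poly\\(experience_days, 2\\)", cs[[2]]$fixed)))
  expect_true(any(grepl("experience_days \\| bee_id", cs[[2]]$random)))
  # null model: intercept and random terms only
  expect_length(cs[[1]]$fixed, 0)
  # pollen: Gamma log link, linear experience, uncorrelated slopes
  cp <- candidate_set("pollen")
  expect_equal(cp[[2]]$family, "gamma_log")
  expect_true("experience_days" %in% cp[[2]]$fixed)
  expect_true("(0 + experience_days | bee_id)" %in% cp[[2]]$random)
  # survival: Cox frailty; effort: Poisson with OLRE
  expect_equal(candidate_set("survival")[[1]]$family, "coxph_frailty")
  expect_equal(candidate_set("effort")[[1]]$family, "poisson")
  expect_error(candidate_set("florivory"), "arg")
})

test_that("AIC and AICc identities hold for fitted models", {
  s <- small_season(seed = 31)
  dat <- build_analysis_data(s$season$trips)
  dat <- dat[dat$trip_type == "nectar", ]
  sel <- fit_and_select(candidate_set("nectar"), dat)
  for (f in sel$fits) {
    expect_equal(f$AIC, -2 * f$logLik + 2 * f$k)
    expect_equal(f$AICc,
                 f$AIC + 2 * f$k * (f$k + 1) / (f$n - f$k - 1))
  }
})

test_that("selection applies the delta-2 and simplest-on-tie rules", {
  pick <- function(tab) {
    # re-implement the documented rule on a bare table as an oracle
    delta <- tab$crit - min(tab$crit)
    cand <- which(delta <= 2)
    cand[order(tab$k[cand], tab$crit[cand])][1]
  }
  t1 <- data.frame(name = c("null", "full"), crit = c(104.7, 100),
                   k = c(2, 6))
  expect_equal(t1$name[pick(t1)], "full")      # delta 4.7 > 2: keep best
  t2 <- data.frame(name = c("A", "B"), crit = c(100, 101.5), k = c(6, 4))
  expect_equal(t2$name[pick(t2)], "B")         # comparable fit: simplest
})

test_that("fit_and_select prefers the simplest of comparable nested fits", {
  set.seed(32)
  # pure-noise RAM predictor: the covariates model should usually win over
  # the RAM models, never the reverse by more than chance
  s <- small_season(seed = 33)
  dat <- build_analysis_data(s$season$trips)
  dat <- dat[dat$trip_type == "nectar", ]
  dat$ram_log1p <- sample(dat$ram_log1p)   # break any real association
  sel <- fit_and_select(candidate_set("nectar"), dat)
  expect_s3_class(sel, "model_selection")
  expect_true(sel$criterion_used %in% c("AIC", "AICc"))
  expect_equal(sel$table$delta[1], 0)
  expect_output(print(sel), "selected")
})

test_that("interaction profiles report slopes, CIs and the reversal week", {
  s <- small_season(seed = 34)
  dat <- build_analysis_data(s$season$trips)
  dat <- dat[dat$trip_type == "nectar", ]
  sel <- fit_and_select(candidate_set("nectar"), dat)
  f <- sel$fits$covariates_ram_week
  pr <- interaction_profile(f, weeks = 14:38)
  expect_equal(nrow(pr$profile), 25)
  expect_true(all(pr$profile$se > 0))
  expect_equal(pr$profile$slope, pr$beta_ram + pr$beta_int * 14:38)
  # root arithmetic: slope crosses zero at -beta_ram / beta_int
  if (!is.na(pr$reversal_week))
    expect_equal(pr$beta_ram + pr$beta_int * pr$reversal_week, 0,
                 tolerance = 1e-10)
  expect_error(interaction_profile(sel$fits$covariates, weeks = 14:38),
               "interaction")
})

test_that("pollen, effort and survival candidate sets fit end to end", {
  set.seed(35)
  s <- small_season(seed = 36)
  dat <- build_analysis_data(s$season$trips)
  pol <- dat[dat$trip_type == "pollen" & dat$pollen_total_mg > 0, ]
  pol$pollen_eff <- pol$pollen_total_mg / pol$duration_min
  selp <- fit_and_select(candidate_set("pollen"), pol)
  expect_true(selp$selected %in% vapply(candidate_set("pollen"), `[[`, "",
                                        "name"))
  # per-bee table for survival / effort
  bees <- s$bees
  logs <- simulate_rfid_scale_logs(s$season$trips)
  surv <- survival_and_effort(bees, logs$rfid, trips = s$season$trips)
  surv <- surv[surv$forager & !surv$never_seen, ]
  surv$week <- surv$release_week
  surv$ram_log1p <- surv$ram_score_log1p
  surv$weather_resid <- 0
  surv$year <- factor(surv$year)
  sels <- fit_and_select(candidate_set("survival"), surv)
  expect_true(all(vapply(sels$fits, function(f) isTRUE(f$converged),
                         TRUE)))
  sele <- fit_and_select(candidate_set("effort"), surv)
  expect_true(sele$selected %in% names(sele$fits))
})
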