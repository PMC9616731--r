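# ---------------------------------------------------------------------------
# Synthetic field season.
#
# The generator inverts the seasonal efficiency model the analysis fits:
# latent nectar gain rate = seasonal baseline + RAM-score effect that
# changes sign across the season (score x week interaction) + size, age,
# year, quadratic-experience and weather effects + correlated bee
# intercept/experience-slope and colony random effects + residual. The
# observed mg/min passes through a configurable monotone warp so that the
# ordered-quantile normalization step is exercised non-trivially.
# ---------------------------------------------------------------------------

#' Season-generator parameters
#'
#' Defaults emulate the study layout: 25 colonies split over two field
#' seasons, released two weeks apart from mid-April (ISO week 14), about
#' nine cognition-tested bees per colony of which roughly 60% forage, eight
#' weigh-recording days in the two weeks after release, and a 2 mg scale
#' noise. Effect sizes are in latent mg/min.
#'
#' @param n_colonies,bees_per_colony,p_forager cohort layout.
#' @param years two calendar years of the staggered design.
#' @param start_week,stagger_weeks first release week and stagger.
#' @param recording_days weigh days per colony (within 14 days of release).
#' @param trips_per_day Poisson mean of trips per bee per recording day.
#' @param duration_meanlog,duration_sdlog log-normal trip duration (min).
#' @param p_pollen_trip probability a trip is a pollen trip.
#' @param baseline_b0,baseline_amp seasonal baseline
#'   `b0 + amp * cos((week - start_week) / 24 * pi)` mg/min.
#' @param beta_int RAM(log1p) x week interaction, mg/min per score unit per
#'   week.
#' @param reversal_week week at which the RAM-score slope crosses zero;
#'   sets the main effect `beta_ram = -beta_int * reversal_week` unless
#'   `beta_ram` is given explicitly.
#' @param beta_ram RAM(log1p) main effect at week 0 (see `reversal_week`).
#' @param beta_size,beta_age,beta_year covariate effects (size centred at
#'   4.4 mm, age at 10 days; year contrast is second year vs first).
#' @param b_exp1,b_exp2 linear and quadratic experience coefficients
#'   (days since first trip).
#' @param beta_weather effect of the week-residualized weather score.
#' @param sd_bee,sd_slope,cor_int_slope,sd_colony,sd_resid random-effect and
#'   residual SDs; bee intercepts and experience slopes are correlated.
#' @param scale_noise_sd balance accuracy (mg) applied when event logs are
#'   generated with noise on.
#' @param warp_cubic monotone warp `y = eta + warp_cubic * eta^3` applied to
#'   the latent rate (0 = identity).
#' @param base_mass_mg,mass_per_mm,mass_jitter_sd outbound body-mass model.
#' @return list of class `season_params`.
#' @export
season_params <- function(n_colonies = 25L, bees_per_colony = 9L,
                          p_forager = 0.6, years = c(2018L, 2019L),
                          start_week = 14L, stagger_weeks = 2L,
                          recording_days = 8L, trips_per_day = 1.55,
                          duration_meanlog = log(18), duration_sdlog = 0.55,
                          p_pollen_trip = 0.28,
                          baseline_b0 = 2.2, baseline_amp = 1.2,
                          beta_int = 0.18, reversal_week = 26,
                          beta_ram = NULL,
                          beta_size = 0.5, beta_age = -0.02,
                          beta_year = -0.15,
                          b_exp1 = 0.25, b_exp2 = -0.02,
                          beta_weather = 0.3,
                          sd_bee = 0.8, sd_slope = 0.05,
                          cor_int_slope = -0.3, sd_colony = 0.4,
                          sd_resid = 2.0, scale_noise_sd = 2,
                          warp_cubic = 0.001,
                          base_mass_mg = 180, mass_per_mm = 25,
                          mass_jitter_sd = 8) {
  if (is.null(beta_ram)) beta_ram <- -beta_int * reversal_week
  p <- as.list(environment())
  stopifnot(p$sd_bee >= 0, p$sd_slope >= 0, p$sd_colony >= 0,
            p$sd_resid >= 0, p$scale_noise_sd >= 0,
            p$start_week >= 1, p$start_week <= 52)
  structure(p, class = "season_params")
}

season_baseline <- function(week, params) {
  params$baseline_b0 +
    params$baseline_amp * cos((week - params$start_week) / 24 * pi)
}

#' Simulate daily weather records
#'
#' Temperature follows a seasonal sinusoid with day-to-day noise, humidity
#' is negatively correlated with temperature, and wind is independent
#' log-normal — enough structure for the first principal component to be a
#' meaningful hot-dry-vs-cool-humid axis correlated with week.
#'
#' @param start_date,end_date Date range (inclusive).
#' @param seed integer seed.
#' @return data frame `date`, `temp_C`, `humidity_pct`, `wind_ms`.
#' @export
simulate_weather <- function(start_date, end_date, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  temp <- 11 + 7.5 * sin(2 * pi * (doy - 105) / 365) + rnorm(length(dates), 0, 2.2)
  hum <- pmin(100, pmax(20, 92 - 1.6 * temp + rnorm(length(dates), 0, 6)))
  wind <- rlnorm(length(dates), log(3), 0.45)
  data.frame(date = dates, temp_C = round(temp, 2),
             humidity_pct = round(hum, 1), wind_ms = round(wind, 2))
}

#' Simulate a cognition-tested bee table for a field season
#'
#' Colonies are split across the two study years and staggered
#' `stagger_weeks` apart from `start_week`; each contributes
#' `bees_per_colony` tested bees, a share of which become foragers. RAM
#' scores are drawn from a right-skewed distribution over the observed 0-8
#' error range (use the maze-agent pipeline instead when score provenance
#' matters).
#'
#' @param params a [season_params()] object.
#' @param seed integer seed.
#' @return data frame: `bee_id`, `colony_id`, `year`, `release_week`,
#'   `release_date`, `end_date`, `size_mm`, `age_at_release_days`,
#'   `forager`, `ram_score`, `ram_score_log1p`.
#' @export
simulate_bee_table <- function(params = season_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- params$n_colonies
  per_year1 <- ceiling(nc / 2)
  rows <- lapply(seq_len(nc), function(i) {
    yr_i <- if (i <= per_year1) 1L else 2L
    pos <- if (yr_i == 1L) i else i - per_year1
    wk <- params$start_week + params$stagger_weeks * (pos - 1L)
    rel <- iso_week_monday(params$years[yr_i], wk)
    nb <- params$bees_per_colony
    data.frame(
      bee_id = sprintf("c%02db%02d", i, seq_len(nb)),
      colony_id = sprintf("col%02d", i),
      year = params$years[yr_i],
      release_week = wk,
      release_date = rel,
      end_date = rel + 28L,
      size_mm = round(rnorm(nb, 4.4, 0.35), 2),
      age_at_release_days = pmax(3L, round(rnorm(nb, 10, 3))),
      forager = runif(nb) < params$p_forager,
      stringsAsFactors = FALSE)
  })
  bees <- do.call(rbind, rows)
  s <- pmin(8, round(rgamma(nrow(bees), shape = 1.8, scale = 1.25), 1))
  bees$ram_score <- s
  bees$ram_score_log1p <- log1p(s)
  rownames(bees) <- NULL
  bees
}

#' Simulate a field season of foraging trips
#'
#' Generates per-trip records with the full generative structure (see
#' [season_params()]), including deliberately short trips and pollen-laden
#' trips so the 7-minute filter and 3-mg classifier are exercised. Stored
#' load fields are re-derived from the simulated weigh masses with the same
#' arithmetic the trip parser uses, so a round trip through
#' [simulate_rfid_scale_logs()] and [pair_events_to_trips()] is lossless.
#'
#' @param bees bee table (see [simulate_bee_table()]); must carry `bee_id`,
#'   `colony_id`, `year`, `release_date`, `size_mm`,
#'   `age_at_release_days`, `ram_score_log1p` and a logical `forager`.
#' @param params a [season_params()] object.
#' @param weather optional daily weather table covering the season;
#'   simulated when absent.
#' @param seed integer seed.
#' @return list of class `season_sim`: `trips`, `bees`, `weather`,
#'   `weather_scores` (date + residualized composite), and `truth`
#'   (generating coefficients, random effects, per-trip latent values,
#'   `sd_eta`, standardized coefficients, `reversal_week`).
#' @export
simulate_season <- function(bees, params = season_params(), weather = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("bee_id", "colony_id", "year", "release_date", "size_mm",
            "age_at_release_days", "ram_score_log1p")
  check_columns(bees, need, "bee table")
  if (!"forager" %in% names(bees)) bees$forager <- TRUE
  foragers <- bees[bees$forager, , drop = FALSE]
  if (!nrow(foragers)) stop("no foraging bees in the table", call. = FALSE)
  if (is.null(weather))
    weather <- simulate_weather(min(bees$release_date) - 7,
                                max(bees$release_date) + 28)
  wc <- weather_composite(weather)
  wres <- residualize_on_week(wc$scores$score, iso_week(wc$scores$date))
  weather_scores <- data.frame(date = wc$scores$date, weather_resid = wres)

  # random effects
  colonies <- unique(bees$colony_id)
  u_col <- setNames(rnorm(length(colonies), 0, params$sd_colony), colonies)
  nb <- nrow(foragers)
  z1 <- rnorm(nb); z2 <- rnorm(nb)
  u_bee <- params$sd_bee * z1
  v_slope <- params$sd_slope *
    (params$cor_int_slope * z1 + sqrt(1 - params$cor_int_slope^2) * z2)
  names(u_bee) <- names(v_slope) <- foragers$bee_id

  # trip skeleton: per bee, per recording day, sequential non-overlapping
  # trips laid out by cumulative (gap, duration) sums within each bee-day
  rd <- params$recording_days
  day_mat <- t(vapply(seq_len(nb),
                      function(i) sort(sample(0:13, rd)), integer(rd)))
  bd_bee <- rep(seq_len(nb), each = rd)
  bd_day <- as.vector(t(day_mat))
  nt <- rpois(length(bd_bee), params$trips_per_day)
  if (sum(nt) == 0L) stop("empty season: no trips generated", call. = FALSE)
  trip_bee <- rep(bd_bee, nt)
  trip_day <- rep(bd_day, nt)
  grp <- rep(seq_along(nt), nt)
  j <- sequence(nt)
  dur_s <- round(60 * pmax(2, rlnorm(length(j), params$duration_meanlog,
                                     params$duration_sdlog)))
  gap_s <- round(ifelse(j == 1L, runif(length(j), 0, 1800),
                        runif(length(j), 300, 2400)))
  cum_in <- stats::ave(gap_s + dur_s, grp, FUN = cumsum)
  off_out <- cum_in - dur_s
  keep <- cum_in <= 8 * 3600          # ~6-8 h recording window per day
  day0 <- as.POSIXct(paste(foragers$release_date[trip_bee] + trip_day,
                           "09:00:00"), tz = "UTC")
  trips <- data.frame(bee_id = foragers$bee_id[trip_bee],
                      t_out = day0 + off_out,
                      t_in = day0 + cum_in,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (!nrow(trips))
    stop("empty season: no trips generated", call. = FALSE)
  trips <- merge(trips, foragers, by = "bee_id", sort = FALSE)
  trips$date <- as.Date(trips$t_out)
  trips$duration_min <- as.numeric(difftime(trips$t_in, trips$t_out,
                                            units = "mins"))
  trips$week_of_year <- iso_week(trips$t_out)
  first_day <- tapply(trips$date, trips$bee_id, min)
  trips$experience_days <-
    as.integer(trips$date - as.Date(first_day[as.character(trips$bee_id)],
                                    origin = "1970-01-01"))
  trips <- merge(trips, weather_scores, by = "date", all.x = TRUE,
                 sort = FALSE)
  trips$weather_resid[is.na(trips$weather_resid)] <- 0

  p <- params
  eta <- season_baseline(trips$week_of_year, p) +
    p$beta_ram * trips$ram_score_log1p +
    p$beta_int * trips$ram_score_log1p * trips$week_of_year +
    p$beta_size * (trips$size_mm - 4.4) +
    p$beta_age * (trips$age_at_release_days - 10) +
    p$beta_year * (trips$year == p$years[2L]) +
    p$b_exp1 * trips$experience_days +
    p$b_exp2 * trips$experience_days^2 +
    p$beta_weather * trips$weather_resid +
    u_bee[trips$bee_id] + v_slope[trips$bee_id] * trips$experience_days +
    u_col[trips$colony_id] +
    rnorm(nrow(trips), 0, p$sd_resid)
  eff <- eta + p$warp_cubic * eta^3

  is_pollen <- runif(nrow(trips)) < p$p_pollen_trip
  pollen_total <- numeric(nrow(trips))
  pollen_total[is_pollen] <- rgamma(sum(is_pollen), shape = 4,
                                    scale = 0.11) * trips$duration_min[is_pollen]
  light <- !is_pollen & runif(nrow(trips)) < 0.1
  pollen_total[light] <- runif(sum(light), 0, 2.8)
  pollen_oneleg <- round(pollen_total / 2, 2)

  w_out <- round(p$base_mass_mg + p$mass_per_mm * (trips$size_mm - 4.4) +
                   rnorm(nrow(trips), 0, p$mass_jitter_sd), 2)
  nectar_target <- round(eff * trips$duration_min, 2)
  w_in <- w_out + nectar_target + 2 * pollen_oneleg

  # store exactly what the parser would derive from these masses
  trips$w_out_mg <- w_out
  trips$w_in_mg <- w_in
  trips$pollen_oneleg_mg <- pollen_oneleg
  trips$weight_incomplete <- FALSE
  trips$pollen_total_mg <- 2 * pollen_oneleg
  trips$nectar_mg <- w_in - w_out - trips$pollen_total_mg
  trips$nectar_eff <- trips$nectar_mg / trips$duration_min
  trips <- classify_and_filter(trips)
  o <- order(trips$bee_id, trips$t_out)
  trips <- trips[o, , drop = FALSE]
  eta <- eta[o]
  rownames(trips) <- NULL

  nectar_rows <- trips$trip_type == "nectar"
  sd_eta <- sd(eta[nectar_rows])
  truth <- list(
    params = p,
    bee_effects = data.frame(bee_id = foragers$bee_id,
                             intercept = unname(u_bee),
                             slope = unname(v_slope)),
    colony_effects = data.frame(colony_id = colonies,
                                intercept = unname(u_col)),
    eta = eta,
    sd_eta = sd_eta,
    beta_int = p$beta_int,
    beta_ram = p$beta_ram,
    beta_int_std = p$beta_int / sd_eta,
    beta_ram_std = p$beta_ram / sd_eta,
    reversal_week = if (p$beta_int != 0) -p$beta_ram / p$beta_int else NA_real_)
  structure(list(trips = trips, bees = bees, weather = weather,
                 weather_scores = weather_scores, truth = truth),
            class = "season_sim")
}

#' Emit RFID and scale event logs for a trip table
#'
#' Exact inverse of the trip-parsing stage: every trip becomes an out and an
#' in RFID read plus out/in weigh events at the same instants. Optional
#' duplicate reads (2 s echoes, absorbed by the default 5 s debounce) and
#' Gaussian scale noise exercise the parser's robustness; with both off the
#' round trip is lossless.
#'
#' @param trips trip table with `bee_id`, `t_out`, `t_in`, `w_out_mg`,
#'   `w_in_mg`, `pollen_oneleg_mg`.
#' @param duplicate_reads inject 2 s echo reads after ~half of all reads.
#' @param noise_sd scale noise SD in mg (0 = off).
#' @param seed integer seed.
#' @return list with `rfid` and `weighs` data frames.
#' @export
simulate_rfid_scale_logs <- function(trips, duplicate_reads = FALSE,
                                     noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_columns(trips, c("bee_id", "t_out", "t_in", "w_out_mg", "w_in_mg"),
                "trips")
  spl <- split(trips, trips$bee_id)
  for (b in spl) {
    b <- b[order(b$t_out), , drop = FALSE]
    if (nrow(b) > 1L && any(b$t_out[-1L] < b$t_in[-nrow(b)]))
      stop("overlapping trips for bee ", b$bee_id[1L], call. = FALSE)
  }
  pol <- if ("pollen_oneleg_mg" %in% names(trips))
    ifelse(is.na(trips$pollen_oneleg_mg), 0, trips$pollen_oneleg_mg) else 0
  n <- nrow(trips)
  rfid <- data.frame(
    tag_id = rep(trips$bee_id, 2L),
    timestamp = c(trips$t_out, trips$t_in),
    direction = rep(c("out", "in"), each = n),
    stringsAsFactors = FALSE)
  noise <- function(k) if (noise_sd > 0) rnorm(k, 0, noise_sd) else 0
  weighs <- data.frame(
    tag_id = rep(trips$bee_id, 2L),
    timestamp = c(trips$t_out, trips$t_in),
    direction = rep(c("out", "in"), each = n),
    mass_mg = c(trips$w_out_mg + noise(n), trips$w_in_mg + noise(n)),
    pollen_oneleg_mg = c(rep(0, n), pol),
    stringsAsFactors = FALSE)
  if (duplicate_reads) {
    echo <- rfid[runif(nrow(rfid)) < 0.5, , drop = FALSE]
    if (nrow(echo)) {
      echo$timestamp <- echo$timestamp + 2
      rfid <- rbind(rfid, echo)
    }
  }
  rfid <- rfid[order(rfid$tag_id, rfid$timestamp), , drop = FALSE]
  weighs <- weighs[order(weighs$tag_id, weighs$timestamp), , drop = FALSE]
  rownames(rfid) <- rownames(weighs) <- NULL
  list(rfid = rfid, weighs = weighs)
}
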