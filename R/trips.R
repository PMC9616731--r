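# ---------------------------------------------------------------------------
# RFID + nest-scale event processing.
#
# Bees pass through two directional RFID readers on exiting/entering the
# nest and are weighed on a motion-averaging balance (accuracy about 2 mg).
# A foraging trip is an out-read matched to the next in-read for the same
# tag; nectar load is the weight gain net of pollen, where the total pollen
# load is estimated as twice the mass stripped from one corbicula.
# ---------------------------------------------------------------------------

#' ISO week of year
#' @param x Date or POSIXct vector.
#' @return integer ISO-8601 week numbers.
#' @export
iso_week <- function(x) as.integer(strftime(x, "%V"))

#' Date of the Monday of an ISO week
#' @param year calendar year containing the week.
#' @param week ISO week number.
#' @return a `Date`.
#' @export
iso_week_monday <- function(year, week) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  wd <- as.integer(strftime(jan4, "%u"))   # 1 = Monday
  jan4 - (wd - 1L) + (week - 1L) * 7L
}

# collapse duplicate reads: drop an event if the previous *kept* event of
# the same tag has the same direction and is within `debounce_s` seconds
debounce_events <- function(ev, debounce_s) {
  if (nrow(ev) < 2L) return(ev)
  keep <- logical(nrow(ev))
  keep[1L] <- TRUE
  last_t <- as.numeric(ev$timestamp[1L])
  last_d <- ev$direction[1L]
  for (i in 2L:nrow(ev)) {
    ti <- as.numeric(ev$timestamp[i])
    if (ev$direction[i] == last_d && (ti - last_t) <= debounce_s) {
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE
      last_t <- ti
      last_d <- ev$direction[i]
    }
  }
  ev[keep, , drop = FALSE]
}

#' Pair RFID events into foraging trips
#'
#' Greedy chronological pairing per bee: every out-read is matched to the
#' next in-read before any other out-read. Duplicate reads (same direction
#' within the debounce window) are collapsed first. An in-read with no
#' pending out-read is logged and dropped; an out-read superseded by another
#' out-read, or left open at the end of the record, becomes a censored open
#' excursion, not a trip. Weigh events are attached to each trip end by
#' nearest-time match within `match_tol_s`.
#'
#' @param rfid data frame: `tag_id`, `timestamp` (POSIXct), `direction`
#'   (`"out"`/`"in"`).
#' @param weighs optional data frame: `tag_id`, `timestamp`, `direction`,
#'   `mass_mg`, `pollen_oneleg_mg` (inbound only).
#' @param debounce_s duplicate-read window, seconds (default 5).
#' @param match_tol_s weigh-to-RFID matching tolerance, seconds (default
#'   120).
#' @return data frame of trips: `bee_id`, `t_out`, `t_in`, `duration_min`,
#'   `w_out_mg`, `w_in_mg`, `pollen_oneleg_mg`; attributes `dropped`
#'   (data frame of discarded events with reasons) and `open_excursions`.
#' @export
pair_events_to_trips <- function(rfid, weighs = NULL, debounce_s = 5,
                                 match_tol_s = 120) {
  check_columns(rfid, c("tag_id", "timestamp", "direction"), "rfid")
  if (!all(rfid$direction %in% c("out", "in")))
    stop("rfid `direction` must be 'out' or 'in'", call. = FALSE)
  if (!is.null(weighs))
    check_columns(weighs, c("tag_id", "timestamp", "direction", "mass_mg"),
                  "weighs")
  rfid <- rfid[order(rfid$tag_id, rfid$timestamp), , drop = FALSE]
  dropped <- list()
  open <- list()
  trips <- list()
  for (tag in unique(rfid$tag_id)) {
    ev <- debounce_events(rfid[rfid$tag_id == tag, , drop = FALSE],
                          debounce_s)
    pending <- NULL
    for (i in seq_len(nrow(ev))) {
      if (ev$direction[i] == "out") {
        if (!is.null(pending))
          open[[length(open) + 1L]] <-
            data.frame(bee_id = tag, t_out = pending,
                       reason = "superseded_out")
        pending <- ev$timestamp[i]
      } else {
        if (is.null(pending)) {
          dropped[[length(dropped) + 1L]] <-
            data.frame(bee_id = tag, timestamp = ev$timestamp[i],
                       direction = "in", reason = "in_without_out")
        } else {
          trips[[length(trips) + 1L]] <-
            data.frame(bee_id = tag, t_out = pending, t_in = ev$timestamp[i])
          pending <- NULL
        }
      }
    }
    if (!is.null(pending))
      open[[length(open) + 1L]] <-
        data.frame(bee_id = tag, t_out = pending, reason = "open_at_end")
  }
  trips <- if (length(trips)) do.call(rbind, trips) else
    data.frame(bee_id = character(), t_out = as.POSIXct(character()),
               t_in = as.POSIXct(character()))
  trips$duration_min <- as.numeric(difftime(trips$t_in, trips$t_out,
                                            units = "mins"))
  trips$w_out_mg <- rep(NA_real_, nrow(trips))
  trips$w_in_mg <- rep(NA_real_, nrow(trips))
  trips$pollen_oneleg_mg <- rep(NA_real_, nrow(trips))
  if (!is.null(weighs) && nrow(trips)) {
    if (!"pollen_oneleg_mg" %in% names(weighs))
      weighs$pollen_oneleg_mg <- 0
    for (i in seq_len(nrow(trips))) {
      for (side in c("out", "in")) {
        tt <- if (side == "out") trips$t_out[i] else trips$t_in[i]
        cand <- weighs[weighs$tag_id == trips$bee_id[i] &
                         weighs$direction == side, , drop = FALSE]
        if (!nrow(cand)) next
        dt <- abs(as.numeric(difftime(cand$timestamp, tt, units = "secs")))
        j <- which.min(dt)
        if (dt[j] <= match_tol_s) {
          if (side == "out") {
            trips$w_out_mg[i] <- cand$mass_mg[j]
          } else {
            trips$w_in_mg[i] <- cand$mass_mg[j]
            trips$pollen_oneleg_mg[i] <- cand$pollen_oneleg_mg[j]
          }
        }
      }
    }
  }
  rownames(trips) <- NULL
  attr(trips, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
                            else NULL
  attr(trips, "open_excursions") <- if (length(open)) do.call(rbind, open)
                                    else NULL
  trips
}

#' Derive nectar and pollen loads
#'
#' Total pollen is twice the one-leg (single corbicula) mass; nectar is the
#' inbound-minus-outbound weight change net of pollen. Negative nectar
#' values (a bee returning lighter than it left) are retained. Trips
#' missing either weigh event are flagged `weight_incomplete`: they are
#' excluded from efficiency analyses but still count as foraging effort.
#'
#' @param trips data frame from [pair_events_to_trips()].
#' @return the trips with `pollen_total_mg`, `nectar_mg` and
#'   `weight_incomplete` columns added.
#' @export
derive_loads <- function(trips) {
  trips$weight_incomplete <- is.na(trips$w_out_mg) | is.na(trips$w_in_mg)
  pol <- ifelse(is.na(trips$pollen_oneleg_mg), 0, trips$pollen_oneleg_mg)
  trips$pollen_total_mg <- 2 * pol
  trips$nectar_mg <- trips$w_in_mg - trips$w_out_mg - trips$pollen_total_mg
  trips
}

#' Classify trips and apply the analysis filters
#'
#' Trips shorter than `min_duration` minutes are excluded (likely
#' orientation flights or waste disposal). Remaining trips are nectar trips
#' when less than `nectar_max_pollen` mg of pollen was collected and pollen
#' trips above it; a load exactly on the boundary goes to the class named by
#' `boundary` (default pollen).
#'
#' @param trips data frame with loads derived (see [derive_loads()]).
#' @param nectar_max_pollen pollen threshold in mg (default 3).
#' @param min_duration minimum trip duration in minutes (default 7).
#' @param boundary class for a pollen load exactly at the threshold.
#' @return trips with `trip_type` (`"nectar"`, `"pollen"`, `"excluded"`) and
#'   `exclude_reason` columns.
#' @export
classify_and_filter <- function(trips, nectar_max_pollen = 3,
                                min_duration = 7,
                                boundary = c("pollen", "nectar")) {
  boundary <- match.arg(boundary)
  if (!"pollen_total_mg" %in% names(trips))
    stop("derive loads before classifying (see `derive_loads()`)",
         call. = FALSE)
  type <- ifelse(trips$pollen_total_mg > nectar_max_pollen, "pollen",
                 "nectar")
  at <- !is.na(trips$pollen_total_mg) &
    trips$pollen_total_mg == nectar_max_pollen
  if (any(at)) type[at] <- boundary
  reason <- rep(NA_character_, nrow(trips))
  short <- trips$duration_min < min_duration
  type[short] <- "excluded"
  reason[short] <- "short_trip"
  trips$trip_type <- type
  trips$exclude_reason <- reason
  trips
}

#' Per-trip efficiency records
#'
#' Keeps classified nectar and pollen trips with complete weights, computes
#' the load rate in mg per minute, the ISO week of year, and foraging
#' experience (days since the bee's first recorded trip), and joins per-bee
#' covariates and daily weather scores when given.
#'
#' @param trips classified trips (see [classify_and_filter()]).
#' @param bees optional per-bee covariate table (keyed by `bee_id`).
#' @param weather_scores optional data frame `date`, `weather_resid` joined
#'   by trip date; trips on dates without weather keep `NA` (logged).
#' @return data frame with `nectar_eff` / `pollen_eff` (mg/min),
#'   `week_of_year`, `experience_days` and any joined covariates.
#' @export
efficiency_table <- function(trips, bees = NULL, weather_scores = NULL) {
  if (!"trip_type" %in% names(trips))
    stop("classify trips before tabulating efficiency", call. = FALSE)
  eff <- trips[trips$trip_type %in% c("nectar", "pollen") &
                 !trips$weight_incomplete, , drop = FALSE]
  eff$nectar_eff <- ifelse(eff$trip_type == "nectar",
                           eff$nectar_mg / eff$duration_min, NA_real_)
  eff$pollen_eff <- ifelse(eff$trip_type == "pollen",
                           eff$pollen_total_mg / eff$duration_min, NA_real_)
  eff$date <- as.Date(eff$t_out)
  eff$week_of_year <- iso_week(eff$t_out)
  first_day <- tapply(eff$date, eff$bee_id, min)
  eff$experience_days <-
    as.integer(eff$date - as.Date(first_day[as.character(eff$bee_id)],
                                  origin = "1970-01-01"))
  if (!is.null(bees))
    eff <- merge(eff, bees, by = "bee_id", all.x = TRUE, sort = FALSE)
  if (!is.null(weather_scores)) {
    eff <- merge(eff, weather_scores, by = "date", all.x = TRUE,
                 sort = FALSE)
    if (anyNA(eff$weather_resid))
      message(sum(is.na(eff$weather_resid)),
              " trip(s) on dates without weather records")
  }
  eff[order(eff$bee_id, eff$t_out), , drop = FALSE]
}

#' Per-bee survival time and lifetime foraging effort
#'
#' Survival is days from release to the last RFID read. Nearly all chipped
#' bees eventually fail to return and are presumed dead; a bee still active
#' on the colony's final day is administratively censored at euthanasia.
#' Lifetime effort counts all paired round trips regardless of weigh
#' completeness.
#'
#' @param bees data frame: `bee_id`, `release_date` (Date), `end_date`
#'   (colony euthanasia Date), plus covariates.
#' @param rfid RFID event data frame (for last-seen times).
#' @param trips paired trips (for lifetime trip counts).
#' @return data frame: `bee_id`, `survival_days`, `event` (1 = presumed
#'   dead, 0 = censored), `n_trips_lifetime`, `never_seen`, plus the input
#'   covariates.
#' @export
survival_and_effort <- function(bees, rfid, trips = NULL) {
  check_columns(bees, c("bee_id", "release_date", "end_date"), "bees")
  last_seen <- tapply(as.numeric(rfid$timestamp), rfid$tag_id, max)
  out <- bees
  ls <- last_seen[as.character(bees$bee_id)]
  ls_date <- as.Date(as.POSIXct(ls, origin = "1970-01-01", tz = "UTC"))
  out$never_seen <- is.na(ls)
  out$last_seen <- ls_date
  out$survival_days <- ifelse(out$never_seen, 0,
                              as.integer(ls_date - bees$release_date))
  out$event <- ifelse(out$never_seen, 1L,
                      ifelse(ls_date < bees$end_date, 1L, 0L))
  out$survival_days <- ifelse(out$event == 0L,
                              as.integer(bees$end_date - bees$release_date),
                              out$survival_days)
  nt <- if (!is.null(trips)) table(trips$bee_id) else NULL
  out$n_trips_lifetime <- if (is.null(nt)) NA_integer_ else {
    v <- as.integer(nt[as.character(bees$bee_id)])
    ifelse(is.na(v), 0L, v)
  }
  out
}
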