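ts <- function(x) as.POSIXct(x, tz = "UTC")

test_that("out/in reads pair chronologically into trips", {
  rfid <- data.frame(tag_id = "t1",
                     timestamp = ts(c("2018-05-07 10:00:00",
                                      "2018-05-07 10:20:00")),
                     direction = c("out", "in"))
  tr <- pair_events_to_trips(rfid)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$duration_min, 20)
})

test_that("double reads collapse within the debounce window", {
  rfid <- data.frame(tag_id = "t1",
                     timestamp = ts(c("2018-05-07 10:00:00",
                                      "2018-05-07 10:00:02",
                                      "2018-05-07 10:20:00")),
                     direction = c("out", "out", "in"))
  tr <- pair_events_to_trips(rfid, debounce_s = 5)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$duration_min, 20)
  # beyond the window the second out supersedes the first (open excursion)
  tr2 <- pair_events_to_trips(rfid, debounce_s = 1)
  expect_equal(nrow(tr2), 1)
  oe <- attr(tr2, "open_excursions")
  expect_equal(oe$reason, "superseded_out")
})

test_that("orphan reads are logged with reasons", {
  rfid <- data.frame(tag_id = "t1",
                     timestamp = ts(c("2018-05-07 09:00:00",
                                      "2018-05-07 10:00:00",
                                      "2018-05-07 18:00:00")),
                     direction = c("in", "out", "out"))
  tr <- pair_events_to_trips(rfid)
  expect_equal(nrow(tr), 0)
  expect_equal(attr(tr, "dropped")$reason, "in_without_out")
  expect_setequal(attr(tr, "open_excursions")$reason,
                  c("superseded_out", "open_at_end"))
})

test_that("load arithmetic doubles one-leg pollen and keeps negatives", {
  tr <- data.frame(bee_id = "b", t_out = ts("2018-05-07 10:00:00"),
                   t_in = ts("2018-05-07 10:20:00"), duration_min = 20,
                   w_out_mg = c(100, 110, 100), w_in_mg = c(120, 105, 100),
                   pollen_oneleg_mg = c(5, 0, 0))
  d <- derive_loads(tr)
  expect_equal(d$pollen_total_mg, c(10, 0, 0))
  expect_equal(d$nectar_mg, c(10, -5, 0))
  expect_false(any(d$weight_incomplete))
  # conservation: nectar + pollen == weight difference, exactly
  expect_identical(d$nectar_mg + d$pollen_total_mg, d$w_in_mg - d$w_out_mg)
})

test_that("missing weigh events flag the trip but keep it for effort", {
  tr <- data.frame(bee_id = "b", t_out = ts("2018-05-07 10:00:00"),
                   t_in = ts("2018-05-07 10:20:00"), duration_min = 20,
                   w_out_mg = NA_real_, w_in_mg = 150, pollen_oneleg_mg = 0)
  d <- classify_and_filter(derive_loads(tr))
  expect_true(d$weight_incomplete)
  expect_equal(nrow(efficiency_table(d)), 0)
})

test_that("classification respects the 3 mg and 7 min rules", {
  mk <- function(dur, pol) {
    t0 <- ts("2018-05-07 10:00:00")
    data.frame(bee_id = "b", t_out = t0, t_in = t0 + dur * 60,
               duration_min = dur, w_out_mg = 100, w_in_mg = 110,
               pollen_oneleg_mg = pol / 2)
  }
  durs <- c(5, 6, 6.9, 7, 8, 20, 20, 20, 20, 30)
  pols <- c(0, 4, 0, 0, 4, 0, 2.9, 3, 3.1, 12)
  tr <- classify_and_filter(derive_loads(
    do.call(rbind, Map(mk, durs, pols))))
  # brute-force enumeration: <7 min excluded; then pollen > 3 mg (or == 3,
  # inclusive boundary) -> pollen, else nectar
  expect_equal(tr$trip_type,
               c("excluded", "excluded", "excluded", "nectar", "pollen",
                 "nectar", "nectar", "pollen", "pollen", "pollen"))
  expect_equal(sum(tr$trip_type == "excluded"), 3)
  expect_true(all(tr$exclude_reason[tr$trip_type == "excluded"] ==
                    "short_trip"))
  # boundary is configurable
  tr2 <- classify_and_filter(derive_loads(mk(20, 3)), boundary = "nectar")
  expect_equal(tr2$trip_type, "nectar")
  # partition: classes cover all paired trips
  expect_equal(sum(table(tr$trip_type)), nrow(tr))
  # filter totality: no short trip ever reaches the efficiency table
  eff <- efficiency_table(tr)
  expect_true(all(eff$duration_min >= 7))
})

test_that("efficiency is load per minute with experience from first trip", {
  t0 <- ts("2018-05-07 10:00:00")
  tr <- data.frame(bee_id = "b",
                   t_out = c(t0, t0 + 86400 * 2),
                   t_in = c(t0 + 20 * 60, t0 + 86400 * 2 + 30 * 60),
                   duration_min = c(20, 30),
                   w_out_mg = 100, w_in_mg = c(110, 112),
                   pollen_oneleg_mg = c(0, 6))
  eff <- efficiency_table(classify_and_filter(derive_loads(tr)))
  expect_equal(eff$nectar_eff[1], 0.5)       # 10 mg / 20 min
  expect_equal(eff$pollen_eff[2], 0.4)       # 12 mg / 30 min
  expect_equal(eff$experience_days, c(0L, 2L))
  expect_equal(eff$week_of_year, rep(iso_week(t0), 2))
})

test_that("survival and effort follow the censoring conventions", {
  bees <- data.frame(bee_id = c("a", "b", "c"),
                     release_date = as.Date("2018-05-07"),
                     end_date = as.Date("2018-06-04"))
  rfid <- data.frame(tag_id = c("a", "a", "b"),
                     timestamp = ts(c("2018-05-07 10:00:00",
                                      "2018-05-20 12:00:00",
                                      "2018-06-04 09:00:00")),
                     direction = "in")
  s <- survival_and_effort(bees, rfid)
  expect_equal(s$survival_days[s$bee_id == "a"], 13)
  expect_equal(s$event[s$bee_id == "a"], 1L)       # presumed dead
  expect_equal(s$survival_days[s$bee_id == "b"], 28)
  expect_equal(s$event[s$bee_id == "b"], 0L)       # active at euthanasia
  expect_equal(s$survival_days[s$bee_id == "c"], 0)
  expect_true(s$never_seen[s$bee_id == "c"])
})

test_that("Kaplan-Meier median of exponential lifetimes matches ln2/lambda", {
  set.seed(19)
  lambda <- 1 / 10
  n <- 400
  life <- rexp(n, lambda)
  bees <- data.frame(bee_id = sprintf("b%03d", 1:n),
                     release_date = as.Date("2018-05-07"),
                     end_date = as.Date("2018-05-07") + 60)
  last <- as.POSIXct("2018-05-07 12:00:00", tz = "UTC") +
    pmin(life, 60) * 86400
  rfid <- data.frame(tag_id = bees$bee_id, timestamp = last,
                     direction = "in")
  s <- survival_and_effort(bees, rfid)
  km <- survival::survfit(survival::Surv(survival_days, event) ~ 1, data = s)
  med <- summary(km)$table[["median"]]
  expect_lt(abs(med - log(2) / lambda), 2.5)  # day-resolution + MC slack
})

test_that("a full synthetic log round-trips losslessly through the parser", {
  s <- small_season(seed = 23)
  tr <- s$season$trips
  logs <- simulate_rfid_scale_logs(tr, duplicate_reads = TRUE, seed = 24)
  rec <- pair_events_to_trips(logs$rfid, logs$weighs)
  rec <- classify_and_filter(derive_loads(rec))
  rec <- rec[order(rec$bee_id, rec$t_out), ]
  rownames(rec) <- NULL
  expect_equal(nrow(rec), nrow(tr))
  for (cn in c("t_out", "t_in", "duration_min", "w_out_mg", "w_in_mg",
               "pollen_oneleg_mg", "pollen_total_mg", "nectar_mg",
               "trip_type"))
    expect_identical(rec[[cn]], tr[[cn]])
})
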