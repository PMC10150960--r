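test_that("the canonical registry has exactly 83 uniquely named slots", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 83L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_false("tod" %in% reg$name)
  expect_true(all(c("cos_tod", "sin_tod", "is_bday", "bgi_mean", "ba_diff",
                    "neg_slopes_mean", "cnc_dist_std") %in% reg$name))
})

test_that("temporal features follow the clock-offset definitions", {
  t18 <- as.POSIXct("2024-03-06 18:00:00", tz = "UTC") # Wednesday
  d <- make_test_diary(t_event = t18, glucose_offsets = c(-10, -5), glucose_values = c(6, 7))
  bl <- subject_baselines(d, t18)
  f <- temporal_features(t18, d, bl)
  expect_equal(f$tod, 0.75)
  expect_equal(f$cos_tod, 6)
  expect_equal(f$sin_tod, 6)
  expect_equal(f$is_bday, 1)

  t12 <- as.POSIXct("2024-03-09 12:00:00", tz = "UTC") # Saturday noon
  d2 <- make_test_diary(t_event = t12, glucose_offsets = -5, glucose_values = 6)
  f2 <- temporal_features(t12, d2, subject_baselines(d2, t12))
  expect_equal(f2$cos_tod, 0)
  expect_equal(f2$is_bday, 0)

  t0 <- as.POSIXct("2024-03-06 00:00:00", tz = "UTC") # midnight
  d3 <- make_test_diary(t_event = t0, glucose_offsets = -5, glucose_values = 6)
  f3 <- temporal_features(t0, d3, subject_baselines(d3, t0))
  expect_equal(f3$sin_tod, 0)
})

test_that("wake_up_offset compares the episode day with the usual schedule", {
  t_ev <- as.POSIXct("2024-06-15 14:00:00", tz = "UTC")
  # 60 days of history with the first reading at 07:00, episode day at 08:30
  hist_off <- -24 * (1:60) - 7 # 07:00 on each of 60 previous days (event at 14:00)
  d <- make_test_diary(t_event = t_ev,
                       glucose_offsets = c(hist_off, -5.5),
                       glucose_values = rep(6, 61))
  bl <- subject_baselines(d, t_ev)
  expect_equal(bl$wake_median, 7)
  f <- temporal_features(t_ev, d, bl)
  expect_equal(f$wake_up_offset, 1.5)

  # no reading on the episode day before the event -> missing
  d2 <- make_test_diary(t_event = t_ev, glucose_offsets = hist_off,
                        glucose_values = rep(6, 60))
  f2 <- temporal_features(t_ev, d2, subject_baselines(d2, t_ev))
  expect_true(is.na(f2$wake_up_offset))
})

test_that("interpolated glucose summaries honour the PCHIP contract", {
  t_ev <- as.POSIXct("2024-03-06 14:00:00", tz = "UTC")
  # constant readings
  d <- make_test_diary(t_event = t_ev, glucose_offsets = c(-2, -1, 0, 1),
                       glucose_values = rep(5, 4))
  f <- interp_bg_features(d, t_ev)
  expect_equal(f$bgi_mean, 5)
  expect_equal(f$bgi_std, 0)
  expect_equal(f$bgi_range, 0)
  expect_equal(f$bgi_slope, 0)

  # collinear knots falling 8 -> 4 over 3 h: slope -4/3, knots reproduced
  d2 <- make_test_diary(t_event = t_ev, glucose_offsets = c(-1.5, 0, 1.5),
                        glucose_values = c(8, 6, 4))
  f2 <- interp_bg_features(d2, t_ev)
  expect_equal(f2$bgi_slope, -4 / 3, tolerance = 1e-9)
  expect_equal(f2$bgi_min, 4)
  expect_equal(f2$bgi_max, 8)

  # interpolant reproduces arbitrary knots and stays within their hull
  # (monotonicity-preserving), cross-checked against base R's monotone
  # Hermite spline at the knots
  off <- c(-2.5, -1.25, -0.5, 0, 0.75, 2)
  val <- c(9.1, 7.4, 5.2, 3.1, 4.4, 6.0)
  expect_equal(hypocause:::pchip_eval(off, val, off), val, tolerance = 1e-9)
  mono <- splinefun(off, val, method = "monoH.FC")
  expect_equal(mono(off), hypocause:::pchip_eval(off, val, off), tolerance = 1e-9)
  grid <- seq(min(off), max(off), by = 1 / 60)
  yv <- hypocause:::pchip_eval(off, val, grid)
  expect_true(all(yv <= max(val) + 1e-9 & yv >= min(val) - 1e-9))

  # degenerate windows
  d3 <- make_test_diary(t_event = t_ev, glucose_offsets = 0, glucose_values = 3.5)
  f3 <- interp_bg_features(d3, t_ev)
  expect_equal(f3$bgi_mean, 3.5)
  expect_equal(f3$bgi_std, 0)
  expect_true(is.na(f3$bgi_skew))
  d4 <- make_test_diary(t_event = t_ev, glucose_offsets = c(-20, 20),
                        glucose_values = c(5, 6)) # nothing inside +/-3 h
  expect_true(all(is.na(unlist(interp_bg_features(d4, t_ev)))))
  # two knots: linear
  d5 <- make_test_diary(t_event = t_ev, glucose_offsets = c(-1, 1),
                        glucose_values = c(4, 8))
  f5 <- interp_bg_features(d5, t_ev)
  expect_equal(f5$bgi_slope, 2, tolerance = 1e-9)
  expect_equal(f5$bgi_mean, 6, tolerance = 1e-9)
})

test_that("neighbouring readings follow the nearest-prior/next rules", {
  t_ev <- as.POSIXct("2024-03-06 14:00:00", tz = "UTC")
  d <- make_test_diary(
    t_event = t_ev,
    glucose_offsets = c(-2, -0.5, 0, 1.5, 4),
    glucose_values = c(5.2, 6.0, 3.2, 9.8, 11.2)
  )
  f <- neighbor_bg_features(d, t_ev)
  expect_equal(f$pre_g_val, 6.0)
  expect_equal(f$pre_g_offset, 0.5)
  expect_equal(f$post_g_val, 9.8)
  expect_equal(f$post_g_offset, 1.5)
  expect_equal(f$post_H_offset, 4.0) # first reading above 10 mmol/L
  expect_equal(f$pre_t_offset, 0.5)  # 6.0 is in [4, 10]
  expect_true(is.na(f$pre_h_offset)) # no prior hypo reading anywhere
  expect_true(is.na(f$pre_H_offset))
})

test_that("intake context is subject-centred with hour offsets", {
  t_ev <- as.POSIXct("2024-06-15 13:00:00", tz = "UTC")
  # QA history mean of 6 U over the window, last dose 8 U at -1.25 h
  d <- make_test_diary(
    t_event = t_ev,
    glucose_offsets = -1, glucose_values = 3.0,
    qa = list(off = c(-200, -150, -100, -1.25), units = c(5, 6, 5, 8)),
    carbs = list(off = c(-30, 0.5), grams = c(45, 60))
  )
  bl <- subject_baselines(d, t_ev)
  expect_equal(bl$qa_mean, 6)
  expect_equal(bl$carb_mean, 45) # only the pre-event carb is history
  f <- intake_context_features(d, t_ev, bl)
  expect_equal(f$pre_ins_dosage, 2.0)
  expect_equal(f$pre_ins_offset, 1.25)
  expect_equal(f$post_car_dosage, 15.0)
  expect_equal(f$post_car_offset, 0.5)
  # no basal records at all -> everything missing
  expect_true(is.na(f$pre_bas_dosage) && is.na(f$post_bas_offset))
})

test_that("advisor features read the most recent record in the lookback", {
  t_ev <- as.POSIXct("2024-03-06 14:00:00", tz = "UTC")
  adv <- data.frame(
    timestamp = t_ev - c(2, 1) * 3600,
    food_ins = c(3, 4), corr_ins = c(0.5, 1), total_ins = c(3.5, 5),
    logged_intake = c(3.5, 4), iob = c(1, 2), allowed_bgv = c(6, 6),
    carb_cu = c(1, 1), meal_rise = c(2, 2), exercise_tag = c(TRUE, FALSE)
  )
  d <- make_test_diary(t_event = t_ev, glucose_offsets = -1, glucose_values = 3,
                       advisor = adv)
  f <- advisor_features(d, t_ev)
  expect_equal(f$ba_total_ins, 5)
  expect_equal(f$ba_diff, 1.0) # advised 5 minus logged 4
  expect_equal(f$ba_has_excercise, 1) # tag anywhere in the lookback counts
  # outside the lookback -> all missing
  f2 <- advisor_features(d, t_ev + 10 * 3600)
  expect_true(all(is.na(unlist(f2))))
})

test_that("long-horizon statistics match their stated definitions", {
  t_ev <- as.POSIXct("2024-06-15 13:00:00", tz = "UTC")
  times <- t_ev - (6:1) * 3600
  vals <- c(4, 6, 4, 6, 4, 6)
  s <- longterm_signal_stats(times, vals, t_ev)
  expect_equal(s$mean, 5)
  expect_equal(s$mean_x, 5 / 6) # five sign changes over six samples
  expect_equal(s$range, 2)
  expect_equal(s$skew, 0) # symmetric sample

  # two-segment slopes: 10 -> 6 over 2 h, then 6 -> 8 over 1 h
  times2 <- t_ev - c(4, 2, 1) * 3600
  s2 <- longterm_signal_stats(times2, c(10, 6, 8), t_ev, slopes = TRUE)
  expect_equal(s2$neg_slopes_mean, -2)
  expect_equal(s2$pos_slopes_mean, 2)

  # consecutive pairs further than 6 h apart are excluded from slope means
  times3 <- t_ev - c(20, 2, 1) * 3600
  s3 <- longterm_signal_stats(times3, c(10, 6, 8), t_ev, slopes = TRUE)
  expect_true(is.na(s3$neg_slopes_mean)) # the only negative pair spans 18 h
  expect_equal(s3$pos_slopes_mean, 2)

  s4 <- longterm_signal_stats(times[1], vals[1], t_ev)
  expect_equal(s4$mean, 4)
  expect_true(is.na(s4$std) && is.na(s4$mean_x) && is.na(s4$kurt))
  s5 <- longterm_signal_stats(times[0], vals[0], t_ev)
  expect_true(all(is.na(unlist(s5))))
})

test_that("quiz engagement counts answers, days and sessions", {
  t_ev <- as.POSIXct("2024-06-15 13:00:00", tz = "UTC")
  quiz <- data.frame(
    timestamp = t_ev - c(49:46, 25:20) * 3600,
    points = c(2, 2, 2, 2, 3, 3, 3, 3, 3, 3),
    session_id = rep(c("q1", "q2"), c(4, 6))
  )
  f <- quiz_engagement_features(quiz, t_ev)
  expect_equal(f$cnc_ansnum, 10)
  expect_equal(f$cnc_dist_avg, 5)  # sessions of sizes 4 and 6
  expect_equal(f$cnc_daysnum, 2)
  f0 <- quiz_engagement_features(quiz[0, ], t_ev)
  expect_equal(f0$cnc_ansnum, 0)
  expect_true(is.na(f0$cnc_points_avg))
  fc <- quiz_engagement_features(quiz[1:3, ], t_ev)
  expect_equal(fc$cnc_points_avg, 2)
  expect_equal(fc$cnc_points_std, 0)
})

test_that("moment helpers agree with longhand textbook formulas", {
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(5:60, 1), sd = runif(1, 0.5, 5))
    expect_equal(hypocause:::sample_skewness(x), oracle_skewness(x), tolerance = 1e-9)
    expect_equal(hypocause:::excess_kurtosis(x), oracle_kurtosis(x), tolerance = 1e-9)
    expect_equal(hypocause:::population_sd(x), sqrt(mean((x - mean(x))^2)),
                 tolerance = 1e-12)
  }
})

test_that("event representation is complete, deterministic and leak-free", {
  cfg <- cohort_config(n_subjects = 4, days = 120, episodes_per_subject = 6,
                       advisor_availability = 1, seed = 13)
  res <- generate_cohort(cfg)
  d <- res$diaries[[1]]
  ep <- filter_label_episodes(d$episodes)[1, , drop = FALSE]
  v <- represent_event(ep, d)
  reg <- feature_registry()
  expect_true(all(reg$name %in% names(v)))
  expect_equal(sum(names(v) %in% reg$name), 83L)
  expect_true(all(extra_feature_names() %in% names(v)))
  # determinism
  expect_identical(represent_event(ep, d), v)

  # an episode without advisor context keeps all 83 slots, advisor ones missing
  d_na <- d
  d_na$advisor <- d_na$advisor[0, , drop = FALSE]
  v_na <- represent_event(ep, d_na)
  expect_equal(sum(names(v_na) %in% reg$name), 83L)
  adv_cols <- reg$name[reg$group == "advisor"]
  expect_true(all(is.na(v_na[adv_cols])))

  # invariants across a whole cohort
  ft <- featurize_cohort(res$diaries)
  off_cols <- grep("_offset$", reg$name, value = TRUE)
  off_cols <- setdiff(off_cols, "wake_up_offset") # signed by definition
  expect_true(all(as.matrix(ft[off_cols]) >= 0, na.rm = TRUE))
  expect_true(all(ft$cos_tod >= 0 & ft$cos_tod <= 12))
  expect_true(all(ft$sin_tod >= 0 & ft$sin_tod <= 12))
  expect_true(all(ft$tod >= 0 & ft$tod <= 1))
  for (p in c("bgi", "glu", "ins", "bas", "car")) {
    r <- ft[[paste0(p, "_range")]]
    expect_equal(r, ft[[paste0(p, "_max")]] - ft[[paste0(p, "_min")]],
                 tolerance = 1e-9, info = p)
  }

  # no look-ahead: truncating the diary at the episode leaves history-window
  # and baseline-driven features unchanged
  t_ev <- ep$timestamp
  d_tr <- d
  for (part in c("glucose", "qa_doses", "basal_doses", "carbs", "advisor", "quiz")) {
    d_tr[[part]] <- d_tr[[part]][d_tr[[part]]$timestamp <= t_ev, , drop = FALSE]
  }
  v_tr <- represent_event(ep, d_tr)
  hist_cols <- setdiff(reg$name, c(grep("^(post_|bgi_)", reg$name, value = TRUE)))
  expect_equal(v_tr[hist_cols], v[hist_cols])
})
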