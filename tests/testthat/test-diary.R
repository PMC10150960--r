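test_that("diary construction sorts, validates and assigns episode ids", {
  prof <- subject_profile("A", 40, "male", 10)
  t0 <- as.POSIXct("2024-02-01 12:00:00", tz = "UTC")
  d <- diary(
    profile = prof,
    glucose = data.frame(timestamp = t0 + c(3600, 0, 7200), value = c(5, 6, 7)),
    episodes = data.frame(timestamp = t0 + c(7200, 0), smbg_value = c(3.1, 3.9),
                          raw_reason = "planned exercise", confidence = c(5L, 4L),
                          category = "ACTIVITY")
  )
  expect_false(is.unsorted(d$glucose$timestamp))
  expect_equal(d$glucose$value, c(6, 5, 7))
  expect_equal(d$episodes$episode_id, c("A_E001", "A_E002"))

  expect_error(subject_profile("A", -1, 0, 0), "age")
  expect_error(subject_profile("A", 30, 0, 40), "years_with_diabetes")
  expect_error(subject_profile("A", 30, 2, 5), "gender")
  expect_error(
    diary(prof, episodes = data.frame(timestamp = t0, smbg_value = 4.5,
                                      raw_reason = "other", confidence = 5L,
                                      category = "OTHER")),
    "smbg_value"
  )
  expect_error(
    diary(prof, glucose = data.frame(timestamp = t0, value = -1)),
    "glucose"
  )
})

test_that("episode filtering keeps high-confidence analysed categories only", {
  eps <- data.frame(
    timestamp = as.POSIXct("2024-02-01 12:00:00", tz = "UTC") + 1:5 * 3600,
    smbg_value = 3.5,
    raw_reason = "x",
    confidence = c(3L, 5L, 4L, 5L, 2L),
    category = c("ACTIVITY", "OTHER", "FOOD", "MEDICATION", "FOOD")
  )
  kept <- filter_label_episodes(eps)
  # confidence 3 excluded, OTHER excluded regardless of confidence 5,
  # confidence 4 FOOD and confidence 5 MEDICATION included
  expect_equal(kept$category, c("FOOD", "MEDICATION"))
  expect_true(all(kept$confidence >= 4))
  # idempotent and never grows
  expect_identical(filter_label_episodes(kept), kept)
  expect_lte(nrow(kept), nrow(eps))
  # order preserved
  expect_true(!is.unsorted(match(kept$timestamp, eps$timestamp)))
  # empty result allowed
  expect_equal(nrow(filter_label_episodes(eps, min_confidence = 6)), 0)
})

test_that("reason labels map to categories with configurable fallback", {
  expect_equal(map_reason_to_category("Planned Exercise"), "ACTIVITY")
  expect_equal(map_reason_to_category("carbohydrate overestimated"), "FOOD")
  expect_equal(map_reason_to_category("Don't know"), "UNKNOWN")
  expect_equal(map_reason_to_category("basal dose too high"), "MEDICATION")
  expect_error(map_reason_to_category("went skydiving"), "went skydiving")
  expect_equal(map_reason_to_category("went skydiving", default = "OTHER"), "OTHER")
  custom <- c("skydiving" = "ACTIVITY")
  expect_equal(map_reason_to_category("skydiving", mapping = custom), "ACTIVITY")
})

test_that("CSV round trip is the identity on a simulated cohort", {
  cfg <- cohort_config(n_subjects = 3, days = 100, episodes_per_subject = 4, seed = 5)
  res <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_diary_tables(res$diaries, dir)
  back <- read_diary_tables(dir)
  expect_identical(names(back), names(res$diaries))
  for (id in names(back)) {
    for (part in c("profile", "glucose", "qa_doses", "basal_doses", "carbs",
                   "advisor", "quiz", "episodes")) {
      expect_equal(back[[id]][[part]], res$diaries[[id]][[part]],
                   info = paste(id, part))
    }
  }
})

test_that("writing an empty cohort yields headers-only files", {
  dir <- withr::local_tempdir()
  write_diary_tables(list(), dir)
  for (f in hypocause:::diary_csv_files()) {
    lines <- readLines(file.path(dir, f))
    expect_length(lines, 1L) # header only
  }
  prof <- subject_profile("B", 50, 1, 30)
  t0 <- as.POSIXct("2024-02-01 08:00:00", tz = "UTC")
  d <- diary(prof, glucose = data.frame(timestamp = t0 + 0:2 * 3600,
                                        value = c(5, 6, 7)))
  write_diary_tables(list(B = d), dir)
  expect_equal(nrow(read.csv(file.path(dir, "glucose.csv"))), 3L)
})

test_that("malformed CSV inputs are rejected loudly", {
  cfg <- cohort_config(n_subjects = 2, days = 95, episodes_per_subject = 2, seed = 9)
  res <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_diary_tables(res$diaries, dir)

  # corrupt a glucose value
  g <- read.csv(file.path(dir, "glucose.csv"), colClasses = "character")
  g$value_mmol_l[3] <- "abc"
  write.csv(g, file.path(dir, "glucose.csv"), row.names = FALSE, na = "")
  expect_error(read_diary_tables(dir), "row 3")

  write_diary_tables(res$diaries, dir)
  # drop a required column
  s <- read.csv(file.path(dir, "subjects.csv"))
  write.csv(s[setdiff(names(s), "age")], file.path(dir, "subjects.csv"),
            row.names = FALSE)
  expect_error(read_diary_tables(dir), "age")

  write_diary_tables(res$diaries, dir)
  # duplicate a subject row
  s <- read.csv(file.path(dir, "subjects.csv"), colClasses = "character")
  write.csv(rbind(s, s[1, ]), file.path(dir, "subjects.csv"), row.names = FALSE)
  expect_error(read_diary_tables(dir), "duplicated subject_id")
})
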