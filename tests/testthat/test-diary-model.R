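# Diary parsing, recoding, validity filtering and analytic-sample assembly.

mapping <- default_activity_mapping()

test_that("parse_diary_table builds one diary per person-day", {
  d <- make_counted_diary(c(sleep = 54, physical_activity = 8, media = 20,
                            school = 26, hobbies = 14, domestic = 22))
  long <- data.frame(participant_id = "P1", day_type = "weekday",
                     slot_index = 0:143, activity_code = d$slots,
                     stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  got <- parse_diary_table(path, mapping)
  expect_length(got, 1)
  expect_identical(got[[1]]$slots, d$slots)
  expect_false(anyNA(got[[1]]$slots))

  # one absent slot row becomes MISSING
  got143 <- parse_diary_table(long[-10, ], mapping)
  expect_length(got143, 1)
  expect_identical(sum(is.na(got143[[1]]$slots)), 1L)
  expect_true(is.na(got143[[1]]$slots[10]))
})

test_that("parse_diary_table enforces the slot and code contracts", {
  long <- data.frame(participant_id = "P1", day_type = "weekday",
                     slot_index = 0:143, activity_code = "sleeping",
                     stringsAsFactors = FALSE)
  expect_error(parse_diary_table(rbind(long, long[1, ]), mapping),
               "duplicate")
  bad_idx <- long; bad_idx$slot_index[1] <- 144
  expect_error(parse_diary_table(bad_idx, mapping), "slot_index")
  bad_code <- long; bad_code$activity_code[5] <- "levitating"
  expect_error(parse_diary_table(bad_code, mapping), "levitating")
})

test_that("recoding counts slots into minutes per behaviour set", {
  counts <- c(sleep = 54, physical_activity = 8, media = 20, school = 26,
              hobbies = 14, domestic = 22)
  d <- make_counted_diary(counts)
  got <- recode_diary(d, mapping)
  expect_equal(got, 10 * counts[behaviour_sets("weekday")])
  expect_equal(sum(got), 1440)

  all_sleep <- time_use_diary("P2", "weekday", rep("sleeping", 144))
  got2 <- recode_diary(all_sleep, mapping)
  expect_equal(unname(got2), c(1440, 0, 0, 0, 0, 0))

  d$slots[3] <- NA
  expect_error(recode_diary(d, mapping), "missing")
})

test_that("diary validation applies reasons in fixed priority order", {
  ok <- make_counted_diary(c(sleep = 60, physical_activity = 10,
                             media = 20, school = 20, hobbies = 14,
                             domestic = 20))
  expect_identical(validate_diary(ok, mapping),
                   list(valid = TRUE, reason = "none"))

  missing <- ok; missing$slots[100] <- NA
  expect_identical(validate_diary(missing, mapping)$reason, "missing_data")

  no_sleep <- make_counted_diary(c(media = 80, school = 30, hobbies = 14,
                                   domestic = 20))
  expect_identical(validate_diary(no_sleep, mapping)$reason, "no_sleep")

  no_dom <- make_counted_diary(c(sleep = 80, media = 40, school = 14,
                                 hobbies = 10))
  expect_identical(validate_diary(no_dom, mapping)$reason, "no_domestic")

  # missing data outranks no_sleep, which outranks no_domestic
  both <- no_sleep; both$slots[1] <- NA
  expect_identical(validate_diary(both, mapping)$reason, "missing_data")
  no_sleep_no_dom <- make_counted_diary(c(media = 100, school = 30,
                                          hobbies = 14))
  expect_identical(validate_diary(no_sleep_no_dom, mapping)$reason,
                   "no_sleep")
})

test_that("analytic sample filters in order and logs removals exactly", {
  counts <- c(sleep = 54, physical_activity = 8, media = 20, school = 26,
              hobbies = 14, domestic = 22)
  diaries <- lapply(sprintf("P%02d", 1:10), function(id) {
    make_counted_diary(counts, participant_id = id)
  })
  # corrupt two diaries with a missing slot
  diaries[[4]]$slots[7] <- NA
  diaries[[9]]$slots[70] <- NA
  covs <- data.frame(participant_id = sprintf("P%02d", 1:10),
                     sex = rep(c("female", "male"), 5),
                     ethnicity = "white_british", fsm = "no",
                     maternal_education = "nvq4_5",
                     stringsAsFactors = FALSE)
  outs <- data.frame(participant_id = sprintf("P%02d", 1:10),
                     attainment8 = 50 + 1:10, stringsAsFactors = FALSE)
  s <- build_analytic_sample(diaries, covs, outs, mapping, "weekday")
  expect_equal(nrow(s$data), 8)
  expect_equal(s$removal_log$removed, c(0, 2, 0))
  expect_equal(s$removal_log$remaining, c(10, 8, 8))

  # now also a missing covariate and a missing outcome
  covs$sex[2] <- NA
  outs$attainment8[6] <- NA
  s2 <- build_analytic_sample(diaries, covs, outs, mapping, "weekday")
  expect_equal(s2$removal_log$removed, c(1, 2, 1))
  expect_equal(nrow(s2$data), 6)
  # identical inputs give identical logs
  s3 <- build_analytic_sample(diaries, covs, outs, mapping, "weekday")
  expect_identical(s2$removal_log, s3$removal_log)
})

test_that("weekend samples are four-part subcompositions closed to 1440", {
  counts <- c(sleep = 60, physical_activity = 6, media = 30, school = 6,
              hobbies = 20, domestic = 22)
  diaries <- lapply(sprintf("W%02d", 1:5), function(id) {
    make_counted_diary(counts, participant_id = id, day_type = "weekend")
  })
  covs <- data.frame(participant_id = sprintf("W%02d", 1:5),
                     sex = "female", ethnicity = "white_british",
                     fsm = "no", maternal_education = "nvq4_5",
                     stringsAsFactors = FALSE)
  outs <- data.frame(participant_id = sprintf("W%02d", 1:5),
                     attainment8 = 55, stringsAsFactors = FALSE)
  s <- build_analytic_sample(diaries, covs, outs, mapping, "weekend")
  expect_equal(s$parts, c("sleep", "media", "hobbies", "domestic"))
  comp <- sample_compositions(s)
  expect_equal(unname(rowSums(comp)), rep(1440, 5))
  # re-closure of the kept weekday minutes
  kept <- 10 * counts[c("sleep", "media", "hobbies", "domestic")]
  expect_equal(comp[1, ], kept * 1440 / sum(kept))
})

test_that("duplicate person-day diaries are a format error", {
  counts <- c(sleep = 60, physical_activity = 6, media = 30, school = 6,
              hobbies = 20, domestic = 22)
  d1 <- make_counted_diary(counts, participant_id = "P1")
  covs <- data.frame(participant_id = "P1", sex = "female",
                     ethnicity = "white_british", fsm = "no",
                     maternal_education = "nvq4_5", stringsAsFactors = FALSE)
  outs <- data.frame(participant_id = "P1", attainment8 = 60,
                     stringsAsFactors = FALSE)
  expect_error(build_analytic_sample(list(d1, d1), covs, outs, mapping,
                                     "weekday"),
               "more than one")
})
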