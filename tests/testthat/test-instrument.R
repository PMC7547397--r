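test_that("well-formed records validate and malformed ones are rejected with named reasons", {
  resp <- validate_response(valid_record())
  expect_s3_class(resp, "mirror_response")
  expect_identical(resp$ptsd_items, c(4L, 5L, 3L, 4L))
  expect_identical(resp$resilience_items, c(4L, 3L, 3L))

  expect_error(validate_response(valid_record(mirror_q2 = 6)),
               "range violation.*mirror_q2")
  expect_error(validate_response(valid_record(mirror_functioning = NULL)),
               "incomplete record.*mirror_functioning")
  expect_error(validate_response(valid_record(event_type = "alien abduction")),
               "vocabulary violation")
  expect_error(validate_response(valid_record(weeks_since_event = -2)),
               "range violation")
  # a record with several problems reports all of them
  v <- response_violations(valid_record(mirror_q1 = 0, mirror_q8 = NULL,
                                        relation = "nope"))
  expect_length(v, 3)
})

test_that("scale scoring is the arithmetic sum over the full item lattice", {
  lo <- validate_response(valid_record(
    mirror_q1 = 1, mirror_q2 = 1, mirror_q3 = 1, mirror_q4 = 1,
    mirror_functioning = 1, mirror_q6 = 1, mirror_q7 = 1, mirror_q8 = 1))
  expect_equal(unclass(score_mirror_scales(lo))[1:3],
               list(ptsd_total = 4, functioning = 1, resilience_total = 3))
  hi <- validate_response(valid_record(
    mirror_q1 = 5, mirror_q2 = 5, mirror_q3 = 5, mirror_q4 = 5,
    mirror_functioning = 10, mirror_q6 = 5, mirror_q7 = 5, mirror_q8 = 5))
  expect_equal(unclass(score_mirror_scales(hi))[1:3],
               list(ptsd_total = 20, functioning = 10, resilience_total = 15))
  mid <- score_mirror_scales(validate_response(valid_record()))
  expect_equal(mid$ptsd_total, 16)
  expect_equal(mid$functioning, 5)
  expect_equal(mid$resilience_total, 10)

  # sampled grid: totals always equal sums and stay inside scale ranges
  set.seed(41)
  grid <- data.frame(mirror_q1 = sample(1:5, 300, TRUE),
                     mirror_q2 = sample(1:5, 300, TRUE),
                     mirror_q3 = sample(1:5, 300, TRUE),
                     mirror_q4 = sample(1:5, 300, TRUE),
                     mirror_functioning = sample(1:10, 300, TRUE),
                     mirror_q6 = sample(1:5, 300, TRUE),
                     mirror_q7 = sample(1:5, 300, TRUE),
                     mirror_q8 = sample(1:5, 300, TRUE))
  s <- score_mirror_scales(grid)
  expect_equal(s$ptsd_total, rowSums(grid[, 1:4]), ignore_attr = TRUE)
  expect_equal(s$resilience_total, rowSums(grid[, 6:8]), ignore_attr = TRUE)
  expect_true(all(s$ptsd_total >= 4 & s$ptsd_total <= 20))
  expect_true(all(s$resilience_total >= 3 & s$resilience_total <= 15))
})

test_that("time phases partition the week axis with recurrence dominating", {
  expect_equal(as.character(time_phase(0)), "under_1_week")
  expect_equal(as.character(time_phase(2)), "one_to_4_weeks")
  expect_equal(as.character(time_phase(2, recurring = TRUE)), "recurring")
  # boundary convention: 'between 1 and 4 weeks' is the closed interval [1, 4]
  expect_equal(as.character(time_phase(c(0.99, 1, 4, 4.01))),
               c("under_1_week", "one_to_4_weeks", "one_to_4_weeks",
                 "over_4_weeks"))
  expect_error(time_phase(-1), "range violation")

  set.seed(7)
  wk <- c(runif(300, 0, 100), 0, 1, 4)
  rec <- sample(c(TRUE, FALSE), length(wk), TRUE)
  ph <- time_phase(wk, rec)
  expect_false(anyNA(ph))                       # no gaps
  expect_true(all(as.character(ph[rec]) == "recurring"))
  manual <- ifelse(wk < 1, "under_1_week",
            ifelse(wk <= 4, "one_to_4_weeks", "over_4_weeks"))
  expect_equal(as.character(ph[!rec]), manual[!rec])  # no overlaps
})
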