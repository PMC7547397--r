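test_that("level classification respects cutoffs with closed upper bounds", {
  cfg <- default_triage_config()
  lv <- classify_levels(data.frame(
    ptsd_total = c(4, 9, 10, 14, 15, 20),
    functioning = c(1, 4, 5, 6, 7, 10),
    resilience_total = c(3, 9, 10, 15, 8, 12)), cfg)
  expect_equal(as.character(lv$ptsd_level),
               c("low", "low", "moderate", "moderate", "high", "high"))
  expect_equal(as.character(lv$functioning_level),
               c("low", "low", "moderate", "moderate", "high", "high"))
  expect_equal(as.character(lv$resilience_level),
               c("low", "low", "high", "high", "low", "high"))
  expect_error(classify_levels(lv, cfg = list()), "configuration error")
})

test_that("the color outcome follows the published verbal rules", {
  cfg <- default_triage_config()
  # few complaints and/or sufficient functioning -> green, any phase
  for (ph in time_phase_levels())
    expect_equal(as.character(triage_color("low", "high", ph, cfg)), "green")
  # complaints with moderate functioning, recent event -> orange
  expect_equal(as.character(
    triage_color("high", "moderate", "one_to_4_weeks", cfg)), "orange")
  # same complaints persisting past a month -> red
  expect_equal(as.character(
    triage_color("high", "moderate", "over_4_weeks", cfg)), "red")
  # recurring event dominates recency
  expect_equal(as.character(
    triage_color("high", "moderate", "recurring", cfg)), "red")
  # low functioning overrides low complaints, even immediately after the event
  expect_equal(as.character(
    triage_color("low", "low", "under_1_week", cfg)), "red")
})

test_that("the enumerated decision table is total, deterministic and monotone", {
  cfg <- default_triage_config()
  dt <- enumerate_decision_table(cfg)
  expect_equal(nrow(dt), 36)
  key <- paste(dt$ptsd_level, dt$functioning_level, dt$phase)
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(dt$color %in% c("green", "orange", "red")))
  # determinism: a second enumeration is identical
  expect_identical(dt, enumerate_decision_table(cfg))

  sev <- function(col) match(col, c("green", "orange", "red"))
  look <- function(p, f, ph) dt$color[dt$ptsd_level == p &
                                      dt$functioning_level == f & dt$phase == ph]
  l3 <- c("low", "moderate", "high")
  # severity non-decreasing in complaints, non-increasing in functioning
  for (ph in time_phase_levels()) {
    for (f in l3)
      expect_true(all(diff(sev(vapply(l3, look, "", f = f, ph = ph))) >= 0))
    for (p in l3)
      expect_true(all(diff(sev(vapply(rev(l3), look, "", p = p, ph = ph))) >= 0))
  }
  # every low-functioning cell refers to care
  expect_true(all(dt$color[dt$functioning_level == "low"] == "red"))
  # orange cannot persist past 4 weeks when complaints meet low-to-moderate functioning
  for (p in c("moderate", "high")) for (f in c("low", "moderate")) {
    along <- sev(vapply(c("under_1_week", "one_to_4_weeks", "over_4_weeks"),
                        look, "", p = p, f = f))
    expect_true(all(diff(along) >= 0))
    expect_equal(look(p, f, "over_4_weeks"), "red")
  }
})

test_that("resilience shapes the advice but never the color", {
  co <- simulate_cohort(simulation_config(n = 120, seed = 3))
  flipped <- co
  flipped[paste0("mirror_q", 6:8)] <- 6 - co[paste0("mirror_q", 6:8)]
  t1 <- triage_cohort(co)
  t2 <- triage_cohort(flipped)
  expect_identical(as.character(t1$color), as.character(t2$color))
  # where the flip crosses the resilience cutoff, the advice changes
  crossed <- t1$resilience_level != t2$resilience_level
  expect_true(any(crossed))
  expect_true(all(t1$advice[crossed] != t2$advice[crossed]))
})

test_that("advice bundles carry the mandated components", {
  g <- compose_advice("green", "high")
  expect_identical(g$components, "no_action")
  o <- compose_advice("orange", "high")
  expect_true(all(c("normalize_complaints", "watchful_waiting_reminder")
                  %in% o$components))
  expect_equal(o$highlight, "set_reminder")
  r <- compose_advice("red", "low")
  expect_true("seek_consultation" %in% r$components)
  # support encouragement tracks low resilience exactly
  for (col in c("green", "orange", "red")) {
    expect_true("social_support_encouragement" %in%
                  compose_advice(col, "low")$components)
    expect_false("social_support_encouragement" %in%
                   compose_advice(col, "high")$components)
  }
  expect_length(g$followup_options, 5)
})

test_that("malformed configurations are rejected before classification", {
  dt <- default_triage_config()$decision_table
  expect_error(triage_config(c(14, 9), c(4, 6), 9, dt), "configuration error")
  expect_error(triage_config(c(9, 14), c(4, 6), 20, dt), "configuration error")
  expect_error(triage_config(c(9, 14), c(4, 6), 9, dt[-1, ]),
               "missing cells")
  expect_error(triage_config(c(9, 14), c(4, 6), 9, rbind(dt, dt[1, ])),
               "duplicated")
})

test_that("triage configurations survive a JSON round trip", {
  cfg <- default_triage_config()
  path <- withr::local_tempfile(fileext = ".json")
  write_triage_config(cfg, path)
  cfg2 <- read_triage_config(path)
  expect_equal(cfg2$ptsd_cutoffs, cfg$ptsd_cutoffs)
  expect_identical(enumerate_decision_table(cfg2),
                   enumerate_decision_table(cfg))
})
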