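test_that("the generator is deterministic with full schema at any size", {
  empty <- simulate_cohort(simulation_config(n = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_true(all(c(mirror_columns(), "pcl5_q1", "dass_q21", "res_q9",
                    "mhc_q14") %in% names(empty)))
  a <- simulate_cohort(simulation_config(n = 200, seed = 5))
  b <- simulate_cohort(simulation_config(n = 200, seed = 5))
  expect_identical(a, b)
  c2 <- simulate_cohort(simulation_config(n = 200, seed = 6))
  expect_false(identical(a, c2))
})

test_that("ordinal thresholding reproduces designed category margins", {
  # loading 0, equal-probability thresholds: ~20% per category
  set.seed(51)
  items <- simulate_ordinal_items(rnorm(10000), 0, qnorm(c(.2, .4, .6, .8)))
  freq <- tabulate(items, 5) / 10000
  expect_true(all(abs(freq - 0.2) < 0.02))
  # loading 1, no noise: category fully determined by the latent
  det <- simulate_ordinal_items(c(-10, 0, 10), 1, c(-1, 1))
  expect_equal(as.integer(det), c(1L, 2L, 3L))
  expect_error(simulate_ordinal_items(rnorm(5), 1, c(1, -1)),
               "non-monotone")
})

test_that("two items sharing a latent factor carry its product of loadings", {
  set.seed(52)
  f <- rnorm(5000)
  m <- simulate_ordinal_items(f, c(0.7, 0.7),
                              list(qnorm(c(.2, .4, .6, .8)),
                                   qnorm(c(.1, .3, .6, .85))))
  expect_equal(polychoric_cor(m[, 1], m[, 2])$rho, 0.49, tolerance = 0.05)
})

test_that("event contexts follow the designed frequency weights", {
  ctx <- simulate_event_context(10000, seed = 53)
  phase <- as.character(time_phase(ctx$weeks_since_event, ctx$recurring))
  expect_equal(mean(phase == "under_1_week"), 0.363, tolerance = 0.02 / 0.363)
  # recurring share within 3 binomial standard errors of its design weight
  p <- 0.097
  expect_lt(abs(mean(ctx$recurring) - p), 3 * sqrt(p * (1 - p) / 10000))
  expect_true(all(ctx$event_type %in% lec5_event_types()))
  # degenerate distribution pins every draw
  f1 <- mirrorscreen:::default_context_frequencies()
  f1$event_type[] <- 0
  f1$event_type["captivity"] <- 1
  ctx2 <- simulate_event_context(50, f1, seed = 54)
  expect_true(all(ctx2$event_type == "captivity"))
})

test_that("scale-level correlations land on their design targets", {
  co <- default_cohort_5000()
  s <- score_mirror_scales(co)
  v <- score_reference_battery(co)
  expect_equal(cor(s$ptsd_total, v$pcl5_total), 0.665, tolerance = 0.08 / 0.665)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(100, 1, factor_correlation = -1.2),
               "configuration error")
  bad_thr <- mirrorscreen:::default_mirror_thresholds()
  bad_thr$mirror_q1 <- c(0, -1, 1, 2)
  expect_error(simulation_config(100, 1, mirror_thresholds = bad_thr),
               "non-monotone")
  bad_f <- mirrorscreen:::default_context_frequencies()
  bad_f$time_phase <- c(under_1_week = 0.9, one_to_4_weeks = 0.9,
                        over_4_weeks = 0, recurring = 0)
  expect_error(simulation_config(100, 1, context_frequencies = bad_f),
               "sum to 1")
  expect_error(simulation_config(100, 1, reference_weights = list(
    pcl5 = c(0.9, -0.9), dass = c(0.36, -0.60), res = c(0.04, 0.87),
    mhc = c(0.04, 0.86))), "variance > 1")
})
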