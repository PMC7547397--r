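# helper: a sample with exact mean and sd
fix_moments <- function(n, m, s) {
  x <- rnorm(n)
  as.numeric(m + s * scale(x))
}

test_that("equal group means give a zero F statistic", {
  for (v in c("classic", "welch")) {
    a <- oneway_anova(means = c(5, 5, 5), sds = c(1, 2, 3), ns = c(10, 20, 30),
                      variant = v)
    expect_equal(a$F, 0)
    expect_equal(a$p_value, 1)
  }
})

test_that("classic ANOVA agrees with aov and is identical from raw or summaries", {
  set.seed(21)
  g <- rep(c("a", "b", "c"), c(12, 15, 20))
  y <- rnorm(length(g), mean = rep(c(0, 0.5, 1), c(12, 15, 20)))
  mine <- oneway_anova(y, g, variant = "classic")
  ref <- summary(aov(y ~ g))[[1]]
  expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$df_within, ref$Df[2])
  expect_equal(mine$eta_squared,
               ref[["Sum Sq"]][1] / sum(ref[["Sum Sq"]]), tolerance = 1e-10)
  summ <- oneway_anova(means = tapply(y, g, mean), sds = tapply(y, g, sd),
                       ns = tapply(y, g, length), variant = "classic")
  expect_equal(summ$F, mine$F, tolerance = 1e-12)
  expect_equal(summ$eta_squared, mine$eta_squared, tolerance = 1e-12)
})

test_that("Welch ANOVA agrees with oneway.test", {
  set.seed(22)
  g <- rep(c("a", "b", "c"), c(10, 25, 40))
  y <- rnorm(length(g), rep(c(0, 1, 2), c(10, 25, 40)),
             rep(c(1, 2, 4), c(10, 25, 40)))
  mine <- oneway_anova(y, g, variant = "welch")
  ref <- oneway.test(y ~ g)
  expect_equal(mine$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df_within, unname(ref$parameter[2]), tolerance = 1e-8)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("published group summaries reproduce the printed F statistics", {
  stress <- oneway_anova(means = c(10.42, 17.60, 22.49),
                         sds = c(7.32, 9.20, 9.37),
                         ns = c(24, 200, 439), variant = "classic")
  expect_equal(stress$F, 34.15, tolerance = 0.5 / 34.15)
  expect_equal(stress$df_between, 2)
  expect_equal(stress$df_within, 660)
  expect_equal(stress$eta_squared, 0.094, tolerance = 0.01)
  pmh <- oneway_anova(means = c(50.0, 43.11, 31.42),
                      sds = c(12.05, 14.89, 14.28),
                      ns = c(24, 200, 439), variant = "classic")
  expect_equal(pmh$F, 57.79, tolerance = 0.5 / 57.79)
  expect_equal(pmh$df_within, 660)
})

test_that("Games-Howell flags exactly the separated group and reduces to Welch t", {
  x <- c(1, 2, 3, 4, 5)
  gh0 <- games_howell(c(x, x), rep(c("a", "b"), each = 5))
  expect_equal(gh0$diff, 0)
  expect_gt(gh0$p_value, 0.999)

  set.seed(23)
  y <- c(rnorm(100), rnorm(100), rnorm(100, 3))
  g <- rep(c("g1", "g2", "g3"), each = 100)
  gh <- games_howell(y, g)
  hit <- gh$p_value < 0.05
  involves3 <- gh$group1 == "g3" | gh$group2 == "g3"
  expect_identical(hit, involves3)

  # two-group case: studentized range with k = 2 equals the Welch t test
  a <- rnorm(40); b <- rnorm(35, 0.5, 2)
  gh2 <- games_howell(c(a, b), rep(c("a", "b"), c(40, 35)))
  tw <- t.test(a, b)
  expect_equal(gh2$p_value, tw$p.value, tolerance = 1e-6)
  expect_equal(abs(gh2$t), abs(unname(tw$statistic)), tolerance = 1e-10)
})

test_that("chi-square equals the brute-force O/E sum and handles edge tables", {
  tab <- matrix(c(409, 224, 230, 214, 24, 11), nrow = 3, byrow = TRUE)
  cs <- chi_square_independence(tab)
  expect_equal(round(cs$chi_square, 2), 18.99)
  expect_equal(cs$df, 2)
  set.seed(24)
  for (i in 1:10) {
    t2 <- matrix(rpois(6, 20) + 1, 2)
    expect_equal(chi_square_independence(t2)$chi_square, chisq_brute(t2),
                 tolerance = 1e-10)
  }
  prop <- outer(c(1, 2), c(3, 5)) * 4   # proportional rows
  expect_equal(chi_square_independence(prop)$chi_square, 0, tolerance = 1e-10)
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)),
               "degenerate-table")
  expect_error(chi_square_independence(matrix(c(1.5, 1, 1, 1), 2)),
               "integer")
})

test_that("two-sample t statistics match t.test for both variants", {
  set.seed(25)
  a <- rnorm(30); b <- rnorm(25, 0.4, 1.7)
  expect_equal(two_sample_t(a, a)$t, 0)
  for (v in c("pooled", "welch")) {
    mine <- two_sample_t(a, b, variant = v)
    ref <- t.test(a, b, var.equal = v == "pooled")
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    # summary interface is the identical statistic
    summ <- two_sample_t(means = c(mean(a), mean(b)), sds = c(sd(a), sd(b)),
                         ns = c(30, 25), variant = v)
    expect_equal(summ$t, mine$t, tolerance = 1e-12)
  }
})
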