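test_that("PCL-5 totals and cluster scores sum correctly", {
  z <- score_pcl5(rep(0, 20))
  expect_equal(unlist(z), c(pcl5_total = 0, pcl5_B = 0, pcl5_C = 0,
                            pcl5_D = 0, pcl5_E = 0))
  m <- score_pcl5(rep(4, 20))
  expect_equal(unlist(m), c(pcl5_total = 80, pcl5_B = 20, pcl5_C = 8,
                            pcl5_D = 28, pcl5_E = 24))
  o <- score_pcl5(rep(1, 20))
  expect_equal(unlist(o), c(pcl5_total = 20, pcl5_B = 5, pcl5_C = 2,
                            pcl5_D = 7, pcl5_E = 6))
  expect_error(score_pcl5(rep(1, 19)), "schema error")
  expect_error(score_pcl5(c(rep(1, 19), 5)), "range violation")

  # permutation invariance within a cluster, strict monotonicity per item
  set.seed(5)
  x <- sample(0:4, 20, TRUE)
  perm <- x
  perm[1:5] <- x[c(3, 1, 5, 2, 4)]
  expect_equal(score_pcl5(perm), score_pcl5(x))
  for (i in sample(1:20, 5)) if (x[i] < 4) {
    y <- x; y[i] <- y[i] + 1
    expect_equal(score_pcl5(y)$pcl5_total, score_pcl5(x)$pcl5_total + 1)
  }
})

test_that("the provisional diagnosis rule counts endorsed symptoms per cluster", {
  expect_false(pcl5_provisional_diagnosis(rep(0, 20)))
  expect_true(pcl5_provisional_diagnosis(rep(4, 20)))
  minimal <- rep(0, 20)
  minimal[c(1, 6, 8, 9, 15, 16)] <- 2    # 1 B, 1 C, 2 D, 2 E
  expect_true(pcl5_provisional_diagnosis(minimal))
  sub <- minimal
  sub[1] <- 1                            # a 1 is not an endorsed symptom
  expect_false(pcl5_provisional_diagnosis(sub))

  # monotone: raising any item never revokes a diagnosis
  set.seed(9)
  for (rep_i in 1:50) {
    x <- sample(0:4, 20, TRUE, prob = c(.4, .2, .2, .1, .1))
    d0 <- pcl5_provisional_diagnosis(x)
    i <- sample(1:20, 1)
    if (x[i] < 4) {
      y <- x; y[i] <- y[i] + 1
      expect_true(pcl5_provisional_diagnosis(y) >= d0)
    }
  }
})

test_that("DASS-21 doubling and severity bands follow the manual cutoffs", {
  sm <- mirrorscreen:::dass_scale_map()
  items <- rep(0L, 21)
  items[sm$depression] <- c(1, 1, 1, 1, 1, 1, 1)  # raw 7 -> doubled 14
  s <- score_dass21(items)
  expect_equal(s$dass_depression, 14)
  expect_equal(as.character(s$dass_depression_band), "moderate")
  expect_equal(s$dass_stress, 0)
  expect_equal(as.character(s$dass_stress_band), "normal")
  items2 <- rep(0L, 21)
  items2[sm$anxiety] <- c(2, 2, 2, 2, 1, 1, 1)    # raw 11 -> doubled 22
  s2 <- score_dass21(items2)
  expect_equal(s2$dass_anxiety, 22)
  expect_equal(as.character(s2$dass_anxiety_band), "extremely_severe")
  expect_error(score_dass21(rep(0, 20)), "schema error")

  b <- classify_dass_band("stress", 18)
  expect_equal(as.character(b$band), "mild")
  expect_equal(as.character(b$clinical_group), "subclinical")
  b2 <- classify_dass_band("depression", 27)
  expect_equal(as.character(b2$band), "severe")
  expect_equal(as.character(b2$clinical_group), "clinical")
  expect_equal(as.character(classify_dass_band("anxiety", 0)$band), "normal")

  # the banding partitions every attainable doubled score, and the
  # clinical split is exactly normal+mild vs the rest
  for (sc in c("depression", "anxiety", "stress")) {
    cls <- classify_dass_band(sc, seq(0, 42, by = 2))
    expect_false(anyNA(cls$band))
    expect_identical(cls$clinical_group == "subclinical",
                     cls$band %in% c("normal", "mild"))
    expect_false(is.unsorted(as.integer(cls$band)))   # monotone in the score
  }
})

test_that("RES and MHC-SF totals and fixed tertile cutpoints", {
  expect_equal(score_summative_scale("RES", rep(0, 9)), 0)
  expect_equal(score_summative_scale("RES", rep(4, 9)), 36)
  expect_equal(score_summative_scale("MHC-SF", rep(5, 14)), 70)
  expect_error(score_summative_scale("RES", rep(0, 14)), "schema error")

  expect_equal(as.character(tertile_classify("RES", c(17, 18, 24, 25))),
               c("low", "moderate", "moderate", "high"))
  expect_equal(as.character(tertile_classify("MHC-SF", c(23, 24, 47, 48))),
               c("low", "moderate", "moderate", "high"))
  expect_error(tertile_classify("RES", 40), "range violation")
})
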