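# shared fixtures, built in code and memoized across test files

valid_record <- function(...) {
  rec <- list(mirror_q1 = 4, mirror_q2 = 5, mirror_q3 = 3, mirror_q4 = 4,
              mirror_functioning = 5, mirror_q6 = 4, mirror_q7 = 3,
              mirror_q8 = 3, event_type = "physical_assault",
              relation = "happened_to_me", weeks_since_event = 2,
              recurring = FALSE, respondent_id = "T1", is_repeat = FALSE)
  utils::modifyList(rec, list(...))
}

# default synthetic cohort at the reference size, computed once per run
default_cohort_5000 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(simulation_config(n = 5000, seed = 20260921))
    cache
  }
})

mirror_item_cols <- c(paste0("mirror_q", 1:4), "mirror_functioning",
                      paste0("mirror_q", 6:8))

# polychoric matrix of the default cohort, computed once per run
default_polychoric <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- correlation_matrix(default_cohort_5000(), mirror_item_cols,
                                   method = "polychoric")
    cache
  }
})

# cohort reproducing the study's published exclusion accounting:
# 1314 rows of which 51 proxy, 37 repeats, 95 incomplete, 19 flagged;
# among the 1112 accepted, 663 carry a complete reference battery
exclusion_fixture <- function(seed = 99) {
  co <- simulate_cohort(simulation_config(n = 1314, seed = seed))
  co$is_proxy[1:51] <- TRUE
  co$is_repeat[52:88] <- TRUE
  co$pcl5_q1[89:183] <- NA            # partial battery -> incomplete
  co$flagged_invalid[184:202] <- TRUE
  bat <- c(paste0("pcl5_q", 1:20), paste0("dass_q", 1:21),
           paste0("res_q", 1:9), paste0("mhc_q", 1:14))
  accepted_rows <- 203:1314           # the 1112 retained
  no_battery <- accepted_rows[664:1112]
  co[no_battery, bat] <- NA
  co
}

# independent brute-force chi-square oracle
chisq_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# independent covariance-form alpha oracle
alpha_brute <- function(m) {
  C <- stats::cov(as.matrix(m))
  k <- ncol(C)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}
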