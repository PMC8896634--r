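test_that("extract_windows enumerates tenure episodes with the documented conventions", {
  ## hand-built trajectory at one site: D (states 0-4), E (5-30), D (31-40)
  n <- 40L
  res_aa <- matrix(aa_index("K"), n + 1, 2)
  res_aa[, 1] <- aa_index(c(rep("D", 5), rep("E", 26), rep("D", 10)))
  prop <- matrix(0.5, n + 1, 2)
  prop[, 1] <- seq(0.2, 0.6, length.out = n + 1)
  traj <- structure(list(resident_aa = res_aa, resident_prop = prop,
                         n = n, L = 2L,
                         steps = data.frame(synonymous = rep(FALSE, n))),
                    class = "trajectory")
  w <- extract_windows(traj, min_residency = 10, complete_only = TRUE)
  expect_length(w, 1)
  expect_equal(w[[1]]$aa, "E")
  expect_equal(w[[1]]$T_res, 26)
  expect_equal(w[[1]]$i, 5)
  expect_equal(w[[1]]$j, 31)
  expect_equal(w[[1]]$series, prop[6:31, 1])

  ## no filtering: every tenure episode at both sites is returned
  w_all <- extract_windows(traj, min_residency = 1, complete_only = FALSE)
  expect_length(w_all, 4)   # D, E, D at site 1; K at site 2
  ## window count is non-increasing in min_residency
  counts <- vapply(c(1, 5, 10, 27, 50), function(m) {
    length(extract_windows(traj, min_residency = m, complete_only = FALSE))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("m_slr and m_ami match naive-formula oracles on random series", {
  withr::with_seed(71, {
    for (trial in 1:20) {
      y <- stats::runif(sample(2:40, 1))
      ## independent oracles: lm() for the slope, explicit mean-minus-first
      slope_oracle <- unname(stats::coef(stats::lm(y ~ seq_along(y)))[2])
      expect_equal(m_slr(y), slope_oracle, tolerance = 1e-12)
      expect_equal(m_ami(y), mean(y) - y[1], tolerance = 1e-12)
    }
  })
  expect_equal(m_slr(c(0.1, 0.2, 0.3)), 0.1)
  expect_equal(m_slr(rep(0.4, 7)), 0)
  expect_equal(m_ami(c(0.2, 0.4, 0.6)), 0.2)
  expect_error(m_slr(0.5), "at least 2")
})

test_that("metric symmetries: reversal and shift invariance", {
  withr::with_seed(72, {
    for (trial in 1:10) {
      y <- stats::runif(sample(4:30, 1))
      ## time reversal negates the slope
      expect_equal(m_slr(rev(y)), -m_slr(y), tolerance = 1e-12)
      ## reversed M_AMI equals mean minus final of the original
      expect_equal(m_ami(rev(y)), mean(y) - y[length(y)], tolerance = 1e-12)
      ## adding a constant leaves both unchanged
      expect_equal(m_ami(y + 0.3), m_ami(y), tolerance = 1e-12)
      expect_equal(m_slr(y + 0.3), m_slr(y), tolerance = 1e-12)
    }
  })
})

test_that("half_window_rate detects late versus early change", {
  ## perfectly linear: equal half-slopes, rate ~ 0
  expect_equal(half_window_rate(seq(0.1, 0.8, length.out = 10)), 0,
               tolerance = 1e-12)
  ## flat then rising: change concentrates late, rate > 0
  flat_rise <- c(rep(0.2, 4), c(0.3, 0.4, 0.5, 0.6))
  expect_gt(half_window_rate(flat_rise), 0)
  ## mirror case: rising then flat, rate < 0
  expect_lt(half_window_rate(rev(flat_rise)), 0)
  ## hand computation on the 8-point series (halves of 4)
  expected <- (abs(m_slr(flat_rise[5:8])) - abs(m_slr(flat_rise[1:4]))) / 8
  expect_equal(half_window_rate(flat_rise), expected)
  ## odd length: first half gets the extra point
  y9 <- c(rep(0.2, 5), 0.3, 0.4, 0.5, 0.6)
  expected9 <- (abs(m_slr(y9[6:9])) - abs(m_slr(y9[1:5]))) / 9
  expect_equal(half_window_rate(y9), expected9)
  ## undefined below 4 points
  expect_true(is.na(half_window_rate(c(0.1, 0.2, 0.3))))
})

test_that("autocorrelation of series and changes behaves as constructed", {
  expect_gt(propensity_autocorrelation(seq(0, 1, length.out = 50)), 0.999)
  expect_lt(propensity_autocorrelation(rep(c(0.1, 0.9), 25)), -0.9)
  expect_true(is.na(propensity_autocorrelation(rep(0.5, 30))))
  ## independent random series: near zero
  z <- withr::with_seed(73, stats::runif(5000))
  expect_lt(abs(propensity_autocorrelation(z)), 0.05)
  ## changes: linear series has constant differences -> NA
  expect_true(is.na(change_autocorrelation(seq(0, 1, length.out = 30))))
  ## random walk has independent increments -> near zero
  w <- cumsum(withr::with_seed(74, stats::rnorm(5000)))
  expect_lt(abs(change_autocorrelation(w)), 0.05)
  ## mean-reverting AR(1) with negative coefficient: negative change
  ## autocorrelation matching the closed form rho_dx = (phi - 1) / 2
  phi <- 0.5
  x <- numeric(20000)
  withr::with_seed(75, {
    for (t in 2:20000) x[t] <- phi * x[t - 1] + stats::rnorm(1)
  })
  expect_equal(change_autocorrelation(x), (phi - 1) / 2, tolerance = 0.05)
})

test_that("summarize_shifts counts ties as non-negative and reports them", {
  mk <- function(series) residency_window(1, "A", 0, length(series), series)
  wins <- list(mk(c(0.1, 0.2, 0.3)),          # positive slope
               mk(c(0.3, 0.2, 0.1)),          # negative slope
               mk(rep(0.4, 5)))               # exactly zero
  s <- summarize_shifts(wins)
  expect_equal(s$n_windows, 3)
  expect_equal(s$pct_neg_slr, 100 / 3)
  expect_equal(s$pct_zero_slr, 100 / 3)
  expect_equal(s$pct_neg_ami, 100 / 3)
  expect_error(summarize_shifts(list()), "no windows")
})

test_that("symmetric propensity distributions give about 50% negative under both metrics", {
  ## iid series from symmetric distributions: by symmetry either sign of
  ## each metric is equally likely
  sizes <- withr::with_seed(76, sample(10:60, 4000, replace = TRUE))
  dists <- structure(list(propensity_values = stats::runif(1000),
                          window_sizes = sizes, lag1_target = 0),
                     class = "empirical_distributions")
  for (dist in c("uniform", "truncated_normal")) {
    s <- symmetric_distribution_check(dist, dists, n_windows = 4000,
                                      rng_seed = 77)$summary
    expect_lt(abs(s$pct_neg_slr - 50), 3)
    expect_lt(abs(s$pct_neg_ami - 50), 3)
  }
  ## a right-skewed source biases M_AMI below 50% negative
  s <- symmetric_distribution_check("exponential", dists, n_windows = 4000,
                                    rng_seed = 78)$summary
  expect_lt(s$pct_neg_ami, 45)
  expect_lt(abs(s$pct_neg_slr - 50), 3)
})

test_that("windows extracted from a real trajectory have consistent metrics", {
  traj <- small_trajectory()
  w <- extract_windows(traj, min_residency = 5, complete_only = FALSE)
  expect_gt(length(w), 10)
  met <- window_metrics(w)
  expect_equal(nrow(met), length(w))
  ## metric columns agree with per-window recomputation
  i <- which.max(met$T_res)
  expect_equal(met$m_slr[i], m_slr(w[[i]]))
  expect_equal(met$m_ami[i], m_ami(w[[i]]))
  ## series values are propensities
  expect_true(all(unlist(lapply(w, `[[`, "series")) >= 0))
  expect_true(all(unlist(lapply(w, `[[`, "series")) <= 1))
})
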