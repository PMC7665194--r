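test_that("prediction error is the Euclidean distance in the percent plane", {
  expect_equal(prediction_error(c(70, 80), c(70, 80)), 0)
  expect_equal(prediction_error(c(3, 4), c(0, 0)), 5)
  expect_equal(prediction_error(c(1.5, -2), c(0, 0)), 2.5)
  expect_error(prediction_error(c(NA, 1), c(0, 0)))
  expect_error(prediction_error(1, c(0, 0)))
  # symmetry and the triangle inequality on random triples
  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(2); b <- rnorm(2); ch <- rnorm(2)
    expect_equal(prediction_error(a, b), prediction_error(b, a))
    expect_lte(prediction_error(a, ch),
               prediction_error(a, b) + prediction_error(b, ch) + 1e-12)
  }
})

test_that("run_experiment walks visits 4-7 with the expected cardinality", {
  one <- noiseless_cohort(1)
  rows <- run_experiment(one)
  expect_equal(nrow(rows), 8)  # 1 eye x 4 visits x 2 models
  expect_setequal(rows$target_visit, 4:7)

  ten <- noiseless_cohort(10)
  rows <- run_experiment(ten)
  expect_equal(nrow(rows), 80)
  expect_true(all(rows$pe < 1e-9))
  expect_true(all(rows$velocity_rule == "mean"))

  short <- list(linear_eye("shorty", times = seq(0, 2.5, by = 0.5)))
  expect_equal(length(short[[1]]$series$t), 6)
  expect_error(run_experiment(short), "QC should have removed")
})

test_that("prediction error grows with injected measurement noise", {
  noisy_cohort <- function(sigma, n = 40, seed = 77) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      t <- seq(0, 3, by = 0.5)
      structure(list(eye_id = sprintf("e%03d", i), subgroup = "both",
                     series = data.frame(
                       t = t,
                       f_pct = 90 - 1.5 * t + rnorm(7, 0, sigma),
                       s_pct = 85 - 1.5 * t + rnorm(7, 0, sigma))),
                class = "eye_series")
    })
  }
  med <- vapply(c(1, 2, 4), function(sig) {
    median(run_experiment(noisy_cohort(sig))$pe)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("model comparison handles ties, dominance and pairing violations", {
  mk_rows <- function(pe_a, pe_b, visit = 4) {
    n <- length(pe_a)
    structure(data.frame(
      eye_id = rep(sprintf("e%02d", 1:n), 2),
      subgroup = "all", target_visit = visit,
      model = rep(c("DSF", "OLSLR"), each = n),
      f_pred = 0, s_pred = 0, f_obs = 0, s_obs = 0,
      pe = c(pe_a, pe_b), velocity_rule = "mean",
      prediction_rule = "centroid_anchored", stringsAsFactors = FALSE),
      class = c("prediction_rows", "data.frame"))
  }
  # identical PE arrays: zero median difference, nothing significant
  pe <- runif(20, 2, 8)
  cmp <- suppressWarnings(compare_models(mk_rows(pe, pe)))
  expect_equal(cmp$median_pe_a, cmp$median_pe_b)
  expect_equal(cmp$pct_eyes_a_lower, 0)
  expect_false(cmp$significant)

  # DSF uniformly better by 1: all ranks one-sided
  set.seed(13)
  pe_b <- runif(50, 3, 9)
  cmp <- compare_models(mk_rows(pe_b - 1, pe_b))
  expect_equal(cmp$pct_eyes_a_lower, 100)
  expect_lt(cmp$wilcoxon_p, 0.05)
  expect_true(cmp$significant)

  # antisymmetry under model swap: medians exchange, p unchanged
  set.seed(17)
  pe_a <- runif(30, 2, 8); pe_b2 <- runif(30, 2, 8)
  fwd <- compare_models(mk_rows(pe_a, pe_b2), models = c("DSF", "OLSLR"))
  rev <- compare_models(mk_rows(pe_a, pe_b2), models = c("OLSLR", "DSF"))
  expect_equal(fwd$median_pe_a, rev$median_pe_b)
  expect_equal(fwd$wilcoxon_p, rev$wilcoxon_p)

  # unpaired rows are rejected
  bad <- mk_rows(pe_a, pe_b2)
  bad <- bad[-3, ]
  expect_error(compare_models(bad), "unpaired")

  # n < 6 non-zero pairs: warning, p unavailable
  expect_warning(cmp_small <- compare_models(mk_rows(c(1, 2, 3, 4),
                                                     c(2, 3, 4, 5))),
                 "fewer than 6")
  expect_true(is.na(cmp_small$wilcoxon_p))
})

test_that("Wilcoxon p matches full sign enumeration on 8 untied pairs", {
  set.seed(29)
  for (rep in 1:5) {
    d <- round(runif(8, 0.5, 10), 3) * sample(c(-1, 1), 8, replace = TRUE)
    while (any(duplicated(abs(d)))) d <- d + runif(8, 0, 1e-3)
    pe_b <- runif(8, 5, 15)
    pe_a <- pe_b + d
    rows <- structure(data.frame(
      eye_id = rep(sprintf("e%d", 1:8), 2), subgroup = "all",
      target_visit = 4, model = rep(c("DSF", "OLSLR"), each = 8),
      f_pred = 0, s_pred = 0, f_obs = 0, s_obs = 0,
      pe = c(pe_a, pe_b), velocity_rule = "mean",
      prediction_rule = "centroid_anchored", stringsAsFactors = FALSE),
      class = c("prediction_rows", "data.frame"))
    cmp <- compare_models(rows)
    expect_equal(cmp$wilcoxon_p, wilcoxon_enumeration_p(d))
  }
})

test_that("noiseless cohorts tie both models exactly", {
  cmp <- suppressWarnings(compare_models(run_experiment(noiseless_cohort(12))))
  expect_true(all(cmp$median_pe_a < 1e-9))
  expect_true(all(cmp$median_pe_b < 1e-9))
  expect_equal(nrow(cmp), 4)
  expect_true(all(cmp$n_eyes == 12))  # no eye silently dropped
})

test_that("median CI brackets the median with order-statistic bounds", {
  x <- 1:25
  ci <- median_ci(x)
  expect_lte(ci["lower"], median(x))
  expect_gte(ci["upper"], median(x))
  # binomial coverage check by simulation
  set.seed(41)
  hits <- replicate(400, {
    x <- rnorm(25)
    ci <- median_ci(x)
    ci["lower"] <= 0 && 0 <= ci["upper"]
  })
  expect_gte(mean(hits), 0.93)
})

test_that("Bland-Altman recovers mean difference and limits of agreement", {
  x <- c(4, 5, 6, 7)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$mean_difference, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  ba2 <- bland_altman(x + 2, x)
  expect_equal(ba2$mean_difference, 2)
  expect_equal(ba2$loa_high - ba2$loa_low, 0)

  set.seed(53)
  d <- rnorm(1e4)
  ba <- bland_altman(d + 10, rep(10, 1e4))
  expect_equal(ba$loa_low, -1.96, tolerance = 0.1 / 1.96)
  expect_equal(ba$loa_high, 1.96, tolerance = 0.1 / 1.96)
  expect_lte(ba$loa_low, ba$mean_difference)
  expect_gte(ba$loa_high, ba$mean_difference)

  expect_error(bland_altman(1:3, 1:4))
  expect_error(bland_altman(1, 1))
})
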