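test_that("DSF fit recovers centroid and velocity on hand-computed cases", {
  s <- data.frame(t = 0:3, f_pct = c(100, 90, 80, 70),
                  s_pct = c(100, 90, 80, 70))
  st <- dsf_fit(s)
  expect_equal(st$centroid, c(f = 85, s = 85))
  expect_equal(st$velocity, c(f = -10, s = -10))
  expect_equal(st$centroid_time, 1.5)
  expect_equal(st$n_used, 4)

  const <- data.frame(t = c(0, 0.5, 1.2), f_pct = rep(80, 3),
                      s_pct = rep(60, 3))
  stc <- dsf_fit(const)
  expect_equal(stc$velocity, c(f = 0, s = 0))
  expect_equal(stc$centroid, c(f = 80, s = 60))

  # unequal spacing: quotients f = (-6, -3) -> mean -4.5; s = (-2, -2) -> -2
  u <- data.frame(t = c(0, 0.5, 1.5), f_pct = c(100, 97, 94),
                  s_pct = c(100, 99, 97))
  expect_equal(dsf_fit(u, "mean")$velocity, c(f = -4.5, s = -2))
  expect_equal(dsf_fit(u, "sum")$velocity, c(f = -9, s = -4))

  expect_error(dsf_fit(s[1, , drop = FALSE]))
  expect_error(dsf_fit(data.frame(t = c(0, 0, 1), f_pct = 1:3, s_pct = 1:3)))
})

test_that("velocity under equal spacing telescopes to the endpoint slope", {
  set.seed(11)
  for (k in c(3, 5, 8)) {
    t <- seq(0, by = 0.5, length.out = k)
    f <- cumsum(rnorm(k))
    s <- cumsum(rnorm(k))
    st <- dsf_fit(data.frame(t = t, f_pct = f, s_pct = s), "mean")
    expect_equal(st$velocity[["f"]], (f[k] - f[1]) / (t[k] - t[1]))
    expect_equal(st$velocity[["s"]], (s[k] - s[1]) / (t[k] - t[1]))
  }
})

test_that("centroid-anchored DSF prediction extrapolates along the velocity", {
  st <- structure(list(centroid = c(f = 85, s = 85),
                       velocity = c(f = -10, s = -10),
                       centroid_time = 1.5, t_last = 3, n_used = 4,
                       velocity_rule = "mean"), class = "dsf_state")
  p <- dsf_predict(st, 4, "centroid_anchored")
  expect_equal(c(p$f_pct, p$s_pct), c(60, 60))

  # zero velocity: prediction equals the centroid under both rules
  st0 <- dsf_fit(data.frame(t = 0:3, f_pct = rep(70, 4), s_pct = rep(50, 4)))
  for (rule in c("centroid_anchored", "printed")) {
    p0 <- dsf_predict(st0, 5, rule)
    expect_equal(c(p0$f_pct, p0$s_pct), c(70, 50))
  }

  # the printed rule reproduces the typeset formula verbatim
  pp <- dsf_predict(st, 4, "printed")
  expect_equal(pp$f_pct, 85 + (-10) / (4 - 3))
  expect_error(dsf_predict(st, 2.5))
})

test_that("both predictors are exact on noiseless lines at arbitrary spacing", {
  set.seed(23)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    t <- cumsum(c(0, runif(k - 1, 0.25, 1.5)))
    f0 <- runif(1, 60, 110); s0 <- runif(1, 60, 110)
    rf <- runif(1, -5, 1); rs <- runif(1, -5, 1)
    series <- linear_series(t, f0, s0, rf, rs)
    target <- max(t) + runif(1, 0.3, 2)
    truth <- c(f0 + rf * target, s0 + rs * target)
    pd <- dsf_predict(dsf_fit(series), target)
    po <- olslr_predict(series, target)
    expect_equal(prediction_error(c(pd$f_pct, pd$s_pct), truth), 0,
                 tolerance = 1e-9)
    expect_equal(prediction_error(c(po$f_pct, po$s_pct), truth), 0,
                 tolerance = 1e-9)
  }
})

test_that("predictions are time-shift and scale equivariant", {
  set.seed(31)
  t <- c(0, 0.4, 1.1, 1.9)
  series <- data.frame(t = t, f_pct = 90 + rnorm(4, 0, 3),
                       s_pct = 80 + rnorm(4, 0, 3))
  target <- 2.8
  base_d <- dsf_predict(dsf_fit(series), target)
  base_o <- olslr_predict(series, target)

  delta <- 4.25
  shifted <- transform(series, t = t + delta)
  shift_d <- dsf_predict(dsf_fit(shifted), target + delta)
  shift_o <- olslr_predict(shifted, target + delta)
  expect_equal(c(shift_d$f_pct, shift_d$s_pct), c(base_d$f_pct, base_d$s_pct))
  expect_equal(c(shift_o$f_pct, shift_o$s_pct), c(base_o$f_pct, base_o$s_pct))

  a <- 1.7
  scaled <- transform(series, f_pct = a * f_pct, s_pct = a * s_pct)
  scale_d <- dsf_predict(dsf_fit(scaled), target)
  scale_o <- olslr_predict(scaled, target)
  expect_equal(c(scale_d$f_pct, scale_d$s_pct),
               a * c(base_d$f_pct, base_d$s_pct))
  expect_equal(c(scale_o$f_pct, scale_o$s_pct),
               a * c(base_o$f_pct, base_o$s_pct))
})

test_that("OLSLR agrees with the brute-force least-squares oracle", {
  f <- c(10, 12, 11, 15)
  t <- 0:3
  p <- olslr_predict(data.frame(t = t, f_pct = f, s_pct = f), 4)
  expect_equal(p$f_pct, ols_oracle_predict(t, f, 4), tolerance = 1e-6)

  set.seed(47)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    t <- cumsum(c(0, runif(k - 1, 0.3, 1)))
    f <- 90 + rnorm(k, 0, 4)
    s <- 80 + rnorm(k, 0, 4)
    target <- max(t) + 1
    p <- olslr_predict(data.frame(t = t, f_pct = f, s_pct = s), target)
    expect_equal(p$f_pct, ols_oracle_predict(t, f, target), tolerance = 1e-6)
    expect_equal(p$s_pct, ols_oracle_predict(t, s, target), tolerance = 1e-6)
  }
  expect_error(olslr_predict(data.frame(t = 0, f_pct = 1, s_pct = 1), 1))
})

test_that("mean velocity is recovered without material bias from noisy series", {
  set.seed(101)
  n_eyes <- 500
  sd_noise <- 2
  true_rate <- -1.5
  est <- replicate(n_eyes, {
    t <- seq(0, 3, by = 0.5)
    s <- data.frame(t = t,
                    f_pct = 90 + true_rate * t + rnorm(7, 0, sd_noise),
                    s_pct = 85 + true_rate * t + rnorm(7, 0, sd_noise))
    dsf_fit(s)$velocity
  })
  expect_lt(abs(mean(est["f", ]) - true_rate), 0.3)
  expect_lt(abs(mean(est["s", ]) - true_rate), 0.3)
})
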