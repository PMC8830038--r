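test_that("survival function matches exhaustive window counting", {
  # events of 4 and 2 frames in a 6-frame trajectory
  ev <- tibble::tibble(start_frame = c(1L, 1L), end_frame = c(4L, 2L))
  sc <- survival_function(ev, T_total = 6, dt = 1)
  oracle <- survival_oracle(c(4L, 2L), t_frames = 6L, lags = 0:5)
  expect_equal(sc$sigma, oracle)
  expect_equal(sc$sigma[1], 1)

  set.seed(17)
  durs <- sample(1:15, 30, replace = TRUE)
  ev2 <- tibble::tibble(start_frame = rep(1L, 30), end_frame = durs)
  sc2 <- survival_function(ev2, T_total = 40, dt = 1)
  expect_equal(sc2$sigma, survival_oracle(durs, 40L, 0:39))
})

test_that("survival curve is 1 for a full-span contact and always monotone in [0,1]", {
  sc <- survival_function(
    tibble::tibble(start_frame = 1L, end_frame = 500L),
    T_total = 500, dt = 1
  )
  expect_true(all(sc$sigma == 1))

  set.seed(4)
  for (rep in 1:5) {
    durs <- rexp(200, runif(1, 0.1, 2))
    sc <- survival_function(durs, T_total = 100, dt = 0.5)
    expect_equal(sc$sigma[1], 1)
    expect_true(all(sc$sigma >= 0 & sc$sigma <= 1))
    expect_true(all(diff(sc$sigma) <= 1e-12))
  }

  expect_error(survival_function(numeric(), 10, 1), "no contacts sampled")
})

test_that("biexponential fit recovers closed-form curves", {
  t <- seq(0, 5, by = 0.01)
  f1 <- fit_biexponential(tibble::tibble(t = t, sigma = exp(-2 * t)))
  expect_lt(abs(f1$koff - 2) / 2, 0.001)
  expect_gte(f1$r_squared, 0.999)
  expect_equal(f1$residence_time * f1$koff, 1)

  f2 <- fit_biexponential(
    tibble::tibble(t = t, sigma = 0.5 * exp(-0.1 * t) + 0.5 * exp(-10 * t))
  )
  expect_lt(abs(f2$koff - 0.1) / 0.1, 0.02)
  expect_lte(f2$k1, f2$k2)

  # no decay: flagged, infinite residence time
  f3 <- fit_biexponential(tibble::tibble(t = t, sigma = rep(1, length(t))))
  expect_true(f3$no_decay)
  expect_equal(f3$residence_time, Inf)
})

test_that("tidy and glance expose the fit in broom style", {
  t <- seq(0, 5, by = 0.01)
  f <- fit_biexponential(
    tibble::tibble(t = t, sigma = 0.4 * exp(-0.2 * t) + 0.6 * exp(-5 * t))
  )
  td <- tidy(f)
  expect_equal(td$term, c("slow", "fast"))
  expect_lte(td$rate[1], td$rate[2])
  g <- glance(f)
  expect_named(g, c(
    "koff", "residence_time", "r_squared", "n_events", "converged",
    "boot_koff_mean", "boot_koff_sd"
  ))
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("rate fitting is covariant under time rescaling", {
  set.seed(23)
  durs <- rexp(800, 0.5)
  f_a <- fit_biexponential(survival_function(durs, 200, 0.1))
  f_b <- fit_biexponential(survival_function(durs * 2, 400, 0.2))
  expect_equal(f_b$koff, f_a$koff / 2, tolerance = 0.02)
})

test_that("exponential dwell times are recovered near the 1/mean oracle", {
  set.seed(7)
  durs <- rexp(2000, 0.5)
  sc <- survival_function(durs, T_total = 500, dt = 0.1)
  fit <- fit_biexponential(sc)
  oracle <- 1 / mean(pmax(round(durs / 0.1), 1) * 0.1)
  expect_lt(abs(fit$koff - 0.5) / 0.5, 0.15)
  expect_lt(abs(fit$koff - oracle) / oracle, 0.10)
})

test_that("two-exponential mixtures yield the slow rate", {
  set.seed(11)
  durs <- c(rexp(1500, 0.05), rexp(3500, 5))
  fit <- fit_biexponential(survival_function(durs, 1000, 0.1))
  expect_lt(abs(fit$koff - 0.05) / 0.05, 0.2)
})

test_that("bootstrap is seed-deterministic and degenerate on identical events", {
  durs <- rep(5, 50)
  bk <- bootstrap_koff(durs, 100, 0.5, n_boot = 5, seed = 2)
  expect_equal(length(unique(round(bk, 10))), 1)

  set.seed(7)
  durs2 <- rexp(300, 0.5)
  b1 <- bootstrap_koff(durs2, 200, 0.1, n_boot = 10, seed = 3)
  b2 <- bootstrap_koff(durs2, 200, 0.1, n_boot = 10, seed = 3)
  expect_identical(b1, b2)
  expect_lt(abs(median(b1, na.rm = TRUE) - 0.5) / 0.5, 0.15)
})

test_that("compute_koff pools events and attaches bootstraps", {
  set.seed(13)
  ev <- tibble::tibble(
    residue = 1L, molecule_id = 1L, traj_id = rep(1:2, each = 100),
    start_frame = 1L, end_frame = pmax(1L, as.integer(rexp(200, 0.5) / 0.5))
  )
  ev$duration <- (ev$end_frame - ev$start_frame + 1L) * 0.5
  fit <- residue_koff(ev, 1L, T_total = 300, dt = 0.5, n_boot = 4, seed = 9)
  expect_length(fit$bootstrap_koffs, 4)
  expect_equal(fit$n_events, 200)
  expect_error(residue_koff(ev, 99L, 300, 0.5), "no contacts sampled")
})
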