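test_that("init_censor_interval applies the rounded ratio with box clamp", {
  expect_equal(init_censor_interval(100, 1, 0.8, 70), 10)
  expect_equal(init_censor_interval(100, 1, 0.7, 70), 0)
  expect_equal(init_censor_interval(100, 1, 0.6, 70), 0)   # clamped, not -10
  expect_equal(init_censor_interval(100, 0.5, 0.4, 70), 10)
  expect_error(init_censor_interval(100, 0, 0.4, 70), "degenerate")
})

test_that("censor times are evenly spaced interior points", {
  expect_equal(censor_times_for_interval(10, 20, 3), c(12.5, 15, 17.5))
  expect_equal(censor_times_for_interval(0, 10, 4), c(2, 4, 6, 8))
  expect_length(censor_times_for_interval(0, 10, 0), 0)
})

test_that("sweep arithmetic matches the product-limit update", {
  sw <- survrecon:::sweep_interval(times = c(0, 1), survs = c(1, 0.9),
                                   n_start = 50, tcensor = numeric(0),
                                   t_next = 2, S_last_in = 1)
  expect_equal(sw$d, c(0, 5))           # round(50 * (1 - 0.9)) = 5
  expect_equal(sw$n_end, 45)
  expect_equal(sw$S_last_end, 1 - 5 / 50)

  # flat segment: no events, at-risk falls only by censoring
  sw2 <- survrecon:::sweep_interval(times = c(0, 1, 2),
                                    survs = c(0.8, 0.8, 0.8),
                                    n_start = 40, tcensor = c(0.5, 1.5),
                                    t_next = 3, S_last_in = 0.8)
  expect_equal(sw2$d, c(0, 0, 0))
  expect_equal(sw2$cens, c(1, 1, 0))
  expect_equal(sw2$n_end, 38)
})

test_that("a digitized drop produces one rounding of its event count", {
  # one drop from 1 to 0.905 out of n = 21: exact events 1.995 -> 2 after a
  # single rounding; split into interior sub-points it would round to 0
  pts <- data.frame(time = c(0, 3, 3), surv = c(1, 1, 0.905))
  prep <- partition_intervals(pts, total_n = 21)
  rec <- reconstruct_ipd(prep)
  expect_equal(sum(rec$ipd$status), 2)
})

test_that("fit_interval recovers known censoring and honours fixed points", {
  ipd <- toy_trial20()
  trisk <- c(0, 10)
  nrisk <- c(20L, 10L)
  pts <- km_step_points(ipd, trisk)
  prep <- preprocess_curve(pts, trisk = trisk, nrisk = nrisk)
  rec <- reconstruct_ipd(prep)
  expect_equal(rec$audit$ncensor_hat[1], 4)     # true interior censorings
  expect_equal(rec$audit$nrisk_hat, nrisk)
  expect_equal(sum(rec$ipd$status), 6)
  expect_equal(nrow(rec$ipd), 20)
})

test_that("downward pressure stops at zero censoring (modified boundary)", {
  # events alone already overshoot the reported drop: the unconstrained
  # update would drive the censor total negative; the box keeps it at 0
  pts <- data.frame(time = c(0, 1, 1, 2), surv = c(1, 1, 0.95, 0.95))
  prep <- partition_intervals(pts, trisk = c(0, 2), nrisk = c(100, 97))
  rec <- reconstruct_ipd(prep)
  expect_equal(rec$audit$ncensor_hat[1], 0)
  expect_gte(min(rec$estimates$cens_hat), 0)

  # an emulation of the original unconstrained update goes negative here
  unconstrained <- function(n_start, S_lo, S_next, target, d_fixed) {
    nc <- round(n_start * S_next / S_lo) - target
    for (it in 1:50) {
      n_end <- n_start - d_fixed - max(0, nc)
      if (n_end == target) break
      nc_new <- nc + n_end - target
      if (nc_new == nc) break
      nc <- nc_new
    }
    nc
  }
  expect_lt(unconstrained(100, 1, 0.95, 97, d_fixed = 5), 0)
})

test_that("perfect no-censoring step curve round-trips exactly", {
  true_t <- c(2, 5, 8, 11)
  n <- 8L
  ipd0 <- data.frame(time = rep(true_t, each = 2), status = 1L)
  pts <- km_step_points(ipd0)
  prep <- partition_intervals(normalize_points(pts), total_n = n)
  rec <- reconstruct_ipd(prep)
  expect_equal(sort(rec$ipd$time), sort(ipd0$time))
  expect_true(all(rec$ipd$status == 1))
})

test_that("counts are non-negative and conserve the starting cohort", {
  for (s in 1:8) {
    arm <- random_arm(seed = s)
    pts <- km_step_points(arm$ipd, arm$trisk)
    prep <- suppressWarnings(
      preprocess_curve(pts, trisk = arm$trisk, nrisk = arm$nrisk))
    rec <- reconstruct_ipd(prep)
    est <- rec$estimates
    expect_true(all(est$d_hat >= 0))
    expect_true(all(est$cens_hat >= 0))
    expect_true(all(est$n_hat >= 0))
    expect_true(all(rec$audit$ncensor_hat >= 0))
    expect_equal(sum(est$d_hat) + sum(est$cens_hat) + rec$n_final,
                 prep$nrisk[1])
    expect_equal(nrow(rec$ipd), prep$nrisk[1])
  }
})

test_that("the KM curve of the reconstructed IPD matches the internal one", {
  arm <- random_arm(seed = 21, n = 80)
  pts <- km_step_points(arm$ipd, arm$trisk)
  prep <- suppressWarnings(
    preprocess_curve(pts, trisk = arm$trisk, nrisk = arm$nrisk))
  rec <- reconstruct_ipd(prep)
  fit <- km_fit(rec$ipd)
  est <- rec$estimates
  last_of_time <- !duplicated(est$time, fromLast = TRUE)
  expect_equal(surv_at(fit, est$time[last_of_time]),
               est$S_km[last_of_time], tolerance = 1e-10)
})

test_that("supplied total events is respected on clean curves", {
  sim <- simulate_km_arm(n = 150, seed = 5, dropout_rate = 0.02)
  prep <- suppressWarnings(
    preprocess_curve(sim$points, trisk = sim$trisk, nrisk = sim$nrisk))
  d_true <- sum(sim$ipd$status)
  rec <- reconstruct_ipd(prep, tot_events = d_true)
  expect_lte(abs(sum(rec$ipd$status) - d_true), 2)
})

test_that("inconsistent inputs are rejected", {
  pts <- data.frame(time = c(0, 1, 1, 2, 2, 3, 3),
                    surv = c(1, 1, 0.75, 0.75, 0.5, 0.5, 0.25))
  prep <- partition_intervals(pts, total_n = 2)
  expect_error(reconstruct_ipd(prep), "inconsistent")
  expect_error(reconstruct_ipd(data.frame()), "preprocess_curve")
})

test_that("iterated censor total matches brute-force enumeration", {
  # small intervals (<= 30 at risk): enumerate every admissible censor
  # total and compare the end-of-interval discrepancy with fit_interval's
  for (s in 1:12) {
    set.seed(300 + s)
    n0 <- sample(8:30, 1)
    arm <- random_arm(seed = 600 + s, n = n0, risk_every = 6)
    if (length(arm$trisk) < 2) next
    pts <- km_step_points(arm$ipd, arm$trisk)
    prep <- suppressWarnings(
      preprocess_curve(pts, trisk = arm$trisk, nrisk = arm$nrisk))
    if (length(prep$trisk) < 2) next
    idx <- prep$lower[1]:prep$upper[1]
    target <- prep$nrisk[2]
    n_start <- prep$nrisk[1]
    cap <- max(0, n_start - target)
    t_lo <- prep$points$time[prep$lower[1]]
    t_hi <- prep$points$time[prep$lower[2]]
    gaps <- vapply(0:cap, function(nc) {
      tc <- censor_times_for_interval(t_lo, t_hi, nc)
      sw <- survrecon:::sweep_interval(prep$points$time[idx],
                                       prep$points$surv[idx],
                                       n_start, tc, t_hi, 1)
      abs(sw$n_end - target)
    }, numeric(1))
    fit <- survrecon:::fit_interval(prep$points$time[idx],
                                    prep$points$surv[idx], n_start,
                                    t_lo, t_hi, t_hi,
                                    ncensor_init = 0, cap = cap,
                                    target = target, S_last_in = 1)
    expect_equal(abs(fit$n_end - target), min(gaps))
  }
})
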