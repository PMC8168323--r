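test_that("normalize_points sorts, rescales percent axes and anchors", {
  out <- normalize_points(data.frame(time = c(5, 2), surv = c(80, 95)),
                          t0 = 0)
  expect_equal(out$time, c(0, 2, 5))
  expect_equal(out$surv, c(1, 0.95, 0.80))
  expect_equal(attr(out, "scale_factor"), 100)

  clean <- data.frame(time = c(0, 3), surv = c(1, 0.7))
  out2 <- normalize_points(clean)
  expect_equal(out2$time, clean$time)
  expect_equal(out2$surv, clean$surv)
  expect_equal(attr(out2, "scale_factor"), 1)

  # stable at tied times: top-of-drop digitized first stays first
  tied <- data.frame(time = c(0, 4, 4), surv = c(1, 0.8, 0.6))
  expect_equal(normalize_points(tied)$surv, c(1, 0.8, 0.6))

  expect_error(normalize_points(data.frame(time = 1, surv = 1)),
               "at least 2")
  expect_error(normalize_points(data.frame(time = c(0, -1),
                                           surv = c(1, 0.9))), "negative")
  expect_error(normalize_points(data.frame(time = c(0, 1),
                                           surv = c(1, -0.1))), "negative")
})

test_that("Tukey fence removes anomalous jumps and only those", {
  # 21 increments: 20 of -0.01 and a single +0.30 at position 11.
  # Q1 = Q3 = -0.01, IQR = 0, so the fence collapses to {-0.01} and the
  # jumped point (input index 12) is the only removal.
  inc <- c(rep(-0.01, 10), 0.30, rep(-0.01, 10))
  pts <- data.frame(time = 0:21, surv = 1 + cumsum(c(0, inc)))
  out <- fence_outliers(pts, k = 3)
  expect_equal(attr(out, "removed"), 12L)
  expect_equal(nrow(out), 21L)

  # a clean monotone curve passes unchanged
  clean <- data.frame(time = 0:10, surv = seq(1, 0.5, by = -0.05))
  expect_equal(fence_outliers(clean)$surv, clean$surv)
  expect_length(attr(fence_outliers(clean), "removed"), 0)

  # fewer than 4 points pass through
  tiny <- data.frame(time = 0:2, surv = c(1, 0.5, 0.4))
  expect_equal(nrow(fence_outliers(tiny)), 3L)
  expect_error(fence_outliers(clean, k = 0), "positive")
})

test_that("force_monotone is the running minimum and deletes nothing", {
  pts <- data.frame(time = 1:4, surv = c(1.0, 0.8, 0.85, 0.7))
  out <- force_monotone(pts)
  expect_equal(out$surv, c(1.0, 0.8, 0.8, 0.7))
  expect_equal(out$time, pts$time)

  mono <- data.frame(time = 1:3, surv = c(1, 0.6, 0.3))
  expect_equal(force_monotone(mono)$surv, mono$surv)
})

test_that("step_control keeps only top and bottom of each vertical run", {
  pts <- data.frame(time = c(0, 4, 4, 4), surv = c(1, 0.8, 0.7, 0.6))
  out <- step_control(pts)
  expect_equal(out$time, c(0, 4, 4))
  expect_equal(out$surv, c(1, 0.8, 0.6))

  nodup <- data.frame(time = 0:3, surv = c(1, 0.9, 0.8, 0.7))
  expect_equal(step_control(nodup), nodup)
})

test_that("step_control preserves distinct times and minimum survival", {
  set.seed(42)
  for (r in 1:20) {
    t <- sort(sample(0:8, 15, replace = TRUE))
    s <- cummin(runif(15))
    pts <- data.frame(time = t, surv = s)
    out <- step_control(pts)
    expect_equal(unique(out$time), unique(pts$time))
    expect_equal(tapply(out$surv, out$time, min),
                 tapply(pts$surv, pts$time, min))
  }
})

test_that("partition_intervals assigns half-open windows and merges empties", {
  pts <- data.frame(time = 0:19, surv = seq(1, 0.05, by = -0.05))
  expect_warning(
    prep <- partition_intervals(pts, trisk = c(0, 10, 20),
                                nrisk = c(100, 60, 30)),
    "merged")
  expect_equal(length(prep$trisk), 2L)   # third window holds no point
  expect_equal(prep$lower, c(1L, 11L))
  expect_equal(prep$upper, c(10L, 20L))

  # boundary point goes to the later interval
  pts2 <- data.frame(time = c(0, 5, 10, 15), surv = c(1, 0.8, 0.6, 0.4))
  prep2 <- partition_intervals(pts2, trisk = c(0, 10), nrisk = c(50, 20))
  expect_equal(prep2$lower, c(1L, 3L))

  # degenerate: no risk table
  prep3 <- partition_intervals(pts2, total_n = 100)
  expect_equal(prep3$lower, 1L)
  expect_equal(prep3$upper, 4L)
  expect_equal(prep3$nrisk, 100L)

  expect_error(partition_intervals(pts2, trisk = c(0, 0), nrisk = c(5, 5)),
               "increasing")
  expect_error(partition_intervals(pts2, trisk = c(0, 10), nrisk = c(5, 6)),
               "non-increasing")
  expect_error(partition_intervals(pts2, trisk = c(0, 10), nrisk = c(5)),
               "length")
  expect_error(partition_intervals(pts2), "total_n")
})

test_that("preprocess pipeline repairs noisy curves and is idempotent", {
  sim <- simulate_km_arm(n = 100, seed = 11, dropout_rate = 0.02)
  noisy <- digitization_noise(sim$points, sd_s = 0.005, seed = 3)
  # inject one gross outlier jump
  noisy$surv[40] <- min(1, noisy$surv[40] + 0.3)
  prep <- preprocess_curve(noisy, trisk = sim$trisk, nrisk = sim$nrisk)
  expect_monotone_unit(prep$points$surv)
  expect_true(40L %in% prep$removed || length(prep$removed) > 0)

  # partition indices disjointly cover 1..N
  N <- nrow(prep$points)
  covered <- unlist(mapply(seq, prep$lower, prep$upper, SIMPLIFY = FALSE))
  expect_equal(covered, seq_len(N))

  # idempotence on the point set
  prep2 <- preprocess_curve(prep$points, trisk = prep$trisk,
                            nrisk = prep$nrisk)
  expect_equal(prep2$points, prep$points, ignore_attr = TRUE)
})

test_that("preprocess keeps survival monotone in [0,1] on random noise", {
  for (s in 1:5) {
    sim <- simulate_km_arm(n = 50, seed = s, dropout_rate = 0.03,
                           risk_every = 10)
    noisy <- digitization_noise(sim$points, sd_t = 0.05, sd_s = 0.01,
                                seed = s + 100)
    noisy$time <- pmax(noisy$time, 0)
    prep <- suppressWarnings(
      preprocess_curve(noisy, trisk = sim$trisk, nrisk = sim$nrisk))
    expect_monotone_unit(prep$points$surv)
  }
})
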