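# Shared fixtures: small hand-checkable survival data sets and generators.

# Four subjects: events at 1 and 2, censored at 1.5 and 3.
# Hand product-limit: S(1) = 3/4; at t = 2 two remain, S = 0.75 * 1/2.
toy_ipd4 <- function() {
  data.frame(time = c(1, 1.5, 2, 3), status = c(1, 0, 1, 0))
}

# A small trial with known censoring structure inside [0, 10):
# 20 patients, single events at 1..6, censored at 2.5/4.5/6.5/8.5,
# the remaining 10 all censored at 12.
toy_trial20 <- function() {
  data.frame(
    time = c(1:6, 2.5, 4.5, 6.5, 8.5, rep(12, 10)),
    status = c(rep(1, 6), rep(0, 4), rep(0, 10))
  )
}

# Random one-arm trial for property tests: exponential events, uniform
# censoring, exact digitized coordinates and a risk table.
random_arm <- function(seed, n = 60, risk_every = 5) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    tev <- rexp(n, 1 / 8)
    tcn <- runif(n, 0, 25)
    ipd <- data.frame(time = pmin(tev, tcn),
                      status = as.integer(tev <= tcn))
    trisk <- seq(0, max(ipd$time), by = risk_every)
    nrisk <- vapply(trisk, function(t) sum(ipd$time >= t), 1L)
    keep <- nrisk > 0
    list(ipd = ipd, trisk = trisk[keep], nrisk = as.integer(nrisk[keep]))
  })
}

expect_monotone_unit <- function(surv) {
  expect_true(all(diff(surv) <= 1e-12))
  expect_true(all(surv >= 0 & surv <= 1))
}
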