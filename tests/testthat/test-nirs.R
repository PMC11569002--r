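make_cycles <- function(n = 60) {
  tibble::tibble(
    cycle = seq_len(n),
    t_on = (seq_len(n) - 1) * 5,
    t_off = (seq_len(n) - 1) * 5 + 3
  )
}

test_that("per-cycle oxygenation means honour the contraction windows", {
  cycles <- make_cycles()
  t <- seq(-30, 300, by = 0.1)
  nirs <- tibble::tibble(t = t, tsi = 60, hhb = 5)
  out <- per_cycle_oxygenation(nirs, cycles)
  expect_true(all(out$mean_tsi == 60))
  expect_true(all(out$mean_hhb == 5))

  # linear TSI decline: cycle means are linear in the window midpoint
  nirs2 <- tibble::tibble(t = t, tsi = 70 - 0.1 * t, hhb = 5)
  out2 <- per_cycle_oxygenation(nirs2, cycles)
  mid <- (cycles$t_on + cycles$t_off) / 2
  expect_equal(out2$mean_tsi, 70 - 0.1 * mid, tolerance = 1e-6)

  # a 3-s window at 10 Hz contains 30-31 samples
  nirs3 <- tibble::tibble(t = seq(0, 300, by = 0.1), tsi = 1, hhb = 1)
  w <- nirs3$t >= 0 & nirs3$t <= 3
  expect_true(sum(w) %in% c(30L, 31L))

  short <- tibble::tibble(t = seq(0, 100, 0.1), tsi = 60, hhb = 5)
  expect_error(per_cycle_oxygenation(short, cycles), "cycle 21")
})

test_that("percent-of-maximum normalization is exact and scale-invariant", {
  expect_equal(normalize_percent_of_max(c(50, 100, 75)), c(50, 100, 75))
  expect_equal(normalize_percent_of_max(rep(3, 10)), rep(100, 10))
  set.seed(2)
  x <- runif(60, 10, 90)
  expect_equal(max(normalize_percent_of_max(x)), 100)
  expect_equal(
    normalize_percent_of_max(x * 7.3),
    normalize_percent_of_max(x)
  )
  expect_error(normalize_percent_of_max(c(-3, -1)), "positive")
})

test_that("ratio construction divides elementwise and drops zero denominators", {
  r <- build_ratio(80, 100, 1.5, "tsi")
  expect_equal(r$ratio, 0.8)
  x <- c(100, 90, 80)
  r2 <- build_ratio(x, x, c(1, 2, 3), "hhb")
  expect_true(all(r2$ratio == 1))
  # halving the torque halves the ratio
  r3 <- build_ratio(x / 2, x, c(1, 2, 3), "tsi")
  expect_equal(r3$ratio, r2$ratio / 2)

  r4 <- build_ratio(c(1, 2), c(0, 4), c(1, 2), "tsi")
  expect_identical(nrow(r4), 1L)
  expect_identical(attr(r4, "dropped"), 1L)
})

test_that("the decay fit recovers noiseless parameters and model identities", {
  x <- seq(2.5, 297.5, by = 5)
  series <- tibble::tibble(time = x, ratio = ratio_decay_model(x, 0.40, 1.00, 60))
  fit <- fit_ratio_decay(series)
  expect_true(fit$converged)
  expect_lt(abs(fit$cr - 0.40) / 0.40, 0.005)
  expect_lt(abs(fit$r0 - 1.00) / 1.00, 0.005)
  expect_lt(abs(fit$tau - 60) / 60, 0.005)
  # half-life definition and model value one time constant in
  expect_equal(fit$tau_half, fit$tau * log(2))
  expect_equal(
    ratio_decay_model(60, 0.4, 1, 60), 0.4 + (1 - 0.4) / exp(1)
  )
  # for a decaying series the fitted asymptote sits at or below the
  # series minimum (the asymptote is only approached), and above zero
  expect_lte(fit$cr, min(series$ratio) + 1e-6)
  expect_gt(fit$cr, 0)
})

test_that("flat and rising ratio series are flagged", {
  flat <- tibble::tibble(time = seq(0, 295, 5), ratio = 0.7)
  ffit <- fit_ratio_decay(flat)
  expect_false(ffit$converged)
  expect_equal(ffit$cr, 0.7)
  expect_true("flat_series" %in% ffit$flags)

  x <- seq(2.5, 297.5, 5)
  rising <- tibble::tibble(time = x, ratio = ratio_decay_model(x, 1.0, 0.4, 80))
  rfit <- fit_ratio_decay(rising)
  expect_true("rising" %in% rfit$flags)
  expect_lt(rfit$r0, rfit$cr)
})

test_that("critical-ratio recovery stays within 5% under 5% multiplicative noise", {
  x <- seq(2.5, 297.5, by = 5)
  truth <- list(cr = 0.45, r0 = 1.0, tau = 80)
  mu <- ratio_decay_model(x, truth$cr, truth$r0, truth$tau)
  crs <- sapply(1:100, function(i) {
    set.seed(600 + i)
    fit <- fit_ratio_decay(tibble::tibble(time = x, ratio = mu * (1 + rnorm(length(x), 0, 0.05))))
    fit$cr
  })
  expect_lt(abs(mean(crs) - truth$cr) / truth$cr, 0.05)
  expect_lt(median(abs(crs - truth$cr)) / truth$cr, 0.05)
})

test_that("the full oxygenation chain reproduces generator truth", {
  gt <- gen_torque_test(noise_sd = 0, seed = 5)
  cycles <- cycle_metrics(gt$trace, segment_cycles(gt$trace))
  gn <- gen_nirs_trace(cycles, noise_tsi = 0, noise_hhb = 0, seed = 5)
  ox <- analyze_oxygenation(gn$nirs, cycles)
  truth <- gn$truth$params
  expect_lt(abs(ox$tsi$cr - truth$tsi$cr) / truth$tsi$cr, 0.005)
  expect_lt(abs(ox$tsi$tau - truth$tsi$tau) / truth$tsi$tau, 0.005)
  expect_lt(abs(ox$hhb$cr - truth$hhb$cr) / truth$hhb$cr, 0.005)
  expect_lt(abs(ox$hhb$tau - truth$hhb$tau) / truth$hhb$tau, 0.01)
  expect_s3_class(ggplot2::autoplot(ox$tsi), "ggplot")
  td <- generics::tidy(ox$hhb)
  expect_setequal(td$term, c("r0", "cr", "tau", "tau_half"))
})
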