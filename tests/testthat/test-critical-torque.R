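torque_tbl <- function(duration, fs = 100, torque = 0) {
  n <- duration * fs
  tibble::tibble(t = (seq_len(n) - 1) / fs, torque = rep_len(torque, n))
}

test_that("protocol segmentation yields exactly 60 cycles on a full trace", {
  trace <- torque_tbl(300)
  cycles <- segment_cycles(trace)
  expect_identical(nrow(cycles), 60L)
  expect_equal(cycles$t_on[1], 0)
  expect_equal(cycles$t_off[1], 3)
  expect_equal(cycles$t_on[60], 295)
  expect_true(all(cycles$t_off - cycles$t_on == 3))
  # schedule arithmetic: 60 cycles x 5 s = 300 s
  expect_equal(nrow(cycles) * 5, 300)

  err <- tryCatch(segment_cycles(torque_tbl(299)), error = conditionMessage)
  expect_match(err, "59 complete cycles")
})

test_that("cycle metrics match rectangle, triangle and quadratic closed forms", {
  fs <- 100
  # rectangle: constant 80 N.m over 3 s
  tr <- torque_tbl(5, fs, 0)
  tr$torque[tr$t <= 3] <- 80
  cyc <- cycle_metrics(tr, segment_cycles(tr, n_cycles = 1L))
  expect_equal(cyc$mean_torque, 80)
  expect_equal(cyc$impulse, 240)

  # triangle: linear 0 -> 90 over the contraction
  tr2 <- torque_tbl(5, fs, 0)
  w <- tr2$t <= 3
  tr2$torque[w] <- 30 * tr2$t[w]
  cyc2 <- cycle_metrics(tr2, segment_cycles(tr2, n_cycles = 1L))
  expect_equal(cyc2$mean_torque, 45, tolerance = 1e-3)
  expect_equal(cyc2$impulse, 135, tolerance = 1e-6)

  # quadratic T(u) = 80 - 5 u^2: closed-form integral 240 - 45 = 195
  tr3 <- torque_tbl(5, fs, 0)
  tr3$torque[w] <- 80 - 5 * tr3$t[w]^2
  cyc3 <- cycle_metrics(tr3, segment_cycles(tr3, n_cycles = 1L))
  expect_equal(cyc3$impulse, 195, tolerance = 195 * 0.001)
})

test_that("per-cycle impulses add up to the integral over all contraction windows", {
  g <- gen_torque_test(seed = 31)
  cycles <- cycle_metrics(g$trace, segment_cycles(g$trace))
  total_by_window <- sum(purrr::map2_dbl(cycles$t_on, cycles$t_off, function(a, b) {
    w <- g$trace$t >= a & g$trace$t <= b
    pracma::trapz(g$trace$t[w], g$trace$torque[w])
  }))
  expect_equal(sum(cycles$impulse), total_by_window)
})

test_that("critical torque is the mean of the final six contractions only", {
  cyc <- tibble::tibble(mean_torque = c(rep(100, 54), 65:70))
  expect_equal(compute_ct(cyc), 67.5)
  expect_equal(compute_ct(tibble::tibble(mean_torque = rep(70, 6))), 70)

  # invariant to torque outside the last six cycles
  cyc2 <- dplyr::mutate(cyc, mean_torque = replace(mean_torque, 1:54, 999))
  expect_equal(compute_ct(cyc2), compute_ct(cyc))

  expect_error(compute_ct(tibble::tibble(mean_torque = 1:5)), "at least 6")
})

test_that("ct recovery on the exponential-plateau generator is unbiased", {
  # noiseless: the generator's own expectation over cycles 55-60
  g <- gen_torque_test(t0 = 110, ct = 70, tau_f = 60, noise_sd = 0, seed = 1)
  cycles <- cycle_metrics(g$trace, segment_cycles(g$trace))
  expect_lt(abs(compute_ct(cycles) - 70), 1)

  # noisy, many seeds: bias below 2% of truth
  cts <- sapply(1:40, function(i) {
    gi <- gen_torque_test(t0 = 160, ct = 70, tau_f = 60, seed = 400 + i)
    compute_ct(cycle_metrics(gi$trace, segment_cycles(gi$trace)))
  })
  expect_lt(abs(mean(cts) - 70) / 70, 0.02)
})

test_that("impulse-prime follows the two-parameter model arithmetic", {
  expect_equal(compute_i_prime(25000, 70, 300), 4000)
  expect_equal(compute_i_prime(70 * 300, 70, 300), 0)
  # constant-torque test at exactly CT: I = 180 CT, I' = -120 CT, flagged
  ct <- 70
  expect_warning(ip <- compute_i_prime(180 * ct, ct, 300), "Negative")
  expect_equal(ip, -120 * ct)
})

test_that("baseline MVC is the peak across the three efforts", {
  eff <- function(peak) {
    tibble::tibble(t = seq(0, 3, by = 0.01), torque = peak * sin(seq(0, pi, length.out = 301)))
  }
  expect_equal(mvc_baseline(list(eff(110), eff(120), eff(115))), 120)
  expect_equal(mvc_baseline(list(eff(100), eff(100), eff(100))), 100)
  expect_warning(m <- mvc_baseline(list(eff(90), eff(95))), "Expected 3")
  expect_equal(m, 95)
})

test_that("analyze_ct composes the full critical-torque summary", {
  g <- gen_torque_test(seed = 12)
  res <- analyze_ct(g$trace, mvc_pre = 150)
  expect_s3_class(res, "ct_result")
  expect_lte(res$ct, res$mvc_test)
  expect_equal(res$tlim, 300)
  expect_equal(res$i_prime, res$total_impulse - res$ct * 300)
  expect_identical(nrow(ct_cycles(res)), 60L)
  # alternative convention: Tlim as total contraction time
  res180 <- analyze_ct(g$trace, tlim = 180)
  expect_equal(res180$i_prime, res$total_impulse - res$ct * 180)
  expect_false(res180$negative_i_prime)
})
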