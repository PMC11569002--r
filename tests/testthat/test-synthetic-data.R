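test_that("generators are bit-identical for identical seeds", {
  a <- gen_breath_transitions(seed = 7)
  b <- gen_breath_transitions(seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, gen_breath_transitions(seed = 8)))

  expect_identical(gen_torque_test(seed = 7), gen_torque_test(seed = 7))
  cyc <- cycle_metrics(
    gen_torque_test(seed = 1)$trace,
    segment_cycles(gen_torque_test(seed = 1)$trace)
  )
  expect_identical(gen_nirs_trace(cyc, seed = 7), gen_nirs_trace(cyc, seed = 7))
  expect_identical(gen_fmd_recording(seed = 7), gen_fmd_recording(seed = 7))
  expect_identical(gen_ramp_recording(seed = 7), gen_ramp_recording(seed = 7))
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_breath_transitions(seed = 99))
  invisible(gen_torque_test(seed = 99))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("breath generator marks protocol phases and injects errant breaths", {
  g <- gen_breath_transitions(n_transitions = 3, errant_rate = 0.02, seed = 17)
  expect_length(g$transitions, 3L)
  tr <- g$transitions[[1]]
  expect_equal(unname(tr$markers), c(0, 180, 360))
  expect_true(all(diff(tr$breaths$t) > 0))
  # ~660 s at ~2.5 s per breath: about 264 breaths
  expect_gt(nrow(tr$breaths), 200)
  # errant count near the binomial expectation across transitions
  n_err <- sum(lengths(g$truth$errant_indices))
  n_breaths <- sum(vapply(g$transitions, function(x) nrow(x$breaths), 1L))
  expect_gt(n_err, 0)
  expect_lt(abs(n_err - 0.02 * n_breaths), 4 * sqrt(0.02 * n_breaths))
  # injected breaths are far enough out for the screen to catch most
  cleaned <- remove_errant_breaths(tr$breaths)
  hit <- mean(g$truth$errant_indices[[1]] %in% attr(cleaned, "removed"))
  expect_gt(hit, 0.7)
})

test_that("noise-free breath transitions round-trip through the kinetics chain", {
  g <- gen_breath_transitions(noise_sd = 0, errant_rate = 0, seed = 3)
  k <- analyze_kinetics(g$transitions)
  p <- g$truth$params
  expect_lt(abs(k$fit$vo2_amp - p$vo2_amp) / p$vo2_amp, 0.01)
  expect_lt(abs(k$fit$tau - p$tau) / p$tau, 0.01)
  expect_lt(abs(k$fit$td - p$td), 0.5)
  expect_lt(abs(k$vo2_base - p$vo2_base) / p$vo2_base, 0.01)
})

test_that("torque generator matches its own closed-form impulse and plateau", {
  g <- gen_torque_test(t0 = 110, ct = 70, tau_f = 60, noise_sd = 0, seed = 2)
  expect_identical(nrow(g$trace), 30000L)
  cycles <- cycle_metrics(g$trace, segment_cycles(g$trace))
  # per-cycle means equal the programmed expectations
  expect_equal(cycles$mean_torque, g$truth$cycle_torque, tolerance = 0.004)
  # total impulse against the closed-form trapezoid-profile sum
  expect_lt(
    abs(sum(cycles$impulse) - g$truth$total_impulse) / g$truth$total_impulse,
    0.002
  )
  # rest intervals are silent
  rest <- g$trace$t %% 5 > 3.01
  expect_true(all(g$trace$torque[rest] == 0))
  expect_error(gen_torque_test(t0 = 50, ct = 70), "t0 > ct")
})

test_that("nirs generator back-solves ratios consistent with its truth", {
  gt <- gen_torque_test(noise_sd = 0, seed = 4)
  cycles <- cycle_metrics(gt$trace, segment_cycles(gt$trace))
  gn <- gen_nirs_trace(cycles, noise_tsi = 0, noise_hhb = 0, seed = 4)
  expect_true(all(gn$nirs$tsi > 0 & gn$nirs$tsi <= 100))
  # flat target (cr = r0) propagates a flat flag downstream
  flatg <- gen_nirs_trace(cycles,
    r0_tsi = 0.6, cr_tsi = 0.6,
    noise_tsi = 0, noise_hhb = 0, seed = 4
  )
  ox <- analyze_oxygenation(flatg$nirs, cycles)
  # ratio inherits the torque decay only through normalization; the
  # fitted tsi curve must be (numerically) flat in its asymptote
  expect_equal(ox$tsi$cr, ox$tsi$r0, tolerance = 0.02)
})

test_that("fmd generator programs its peak exactly", {
  g <- gen_fmd_recording(
    d_baseline = 4.00, d_peak = 4.24, t_peak = 35,
    noise_sd = 0, noise_v = 0, seed = 6
  )
  expect_equal(max(g$rec$diameter), 4.24)
  expect_equal(
    g$rec$t[which.max(g$rec$diameter)] - g$markers$deflation, 35
  )
  expect_equal(g$truth$params$fmd_pct, 6.00)
  expect_error(gen_fmd_recording(d_peak = 3), "d_peak")
  expect_error(gen_fmd_recording(t_peak = 400), "t_peak")
})
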