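test_that("errant-breath screen removes only breaths beyond the local SD band", {
  # constant series: zero local SD everywhere, nothing removed
  b <- breath_tbl(seq(0, 47.5, by = 2.5), rep(1000, 20))
  out <- remove_errant_breaths(b)
  expect_identical(nrow(out), 20L)
  expect_identical(attr(out, "removed"), integer(0))

  # one injected 6-SD breath in Gaussian noise: exactly that breath goes,
  # matching the brute-force oracle
  set.seed(11)
  vo2 <- rnorm(20, 1000, 50)
  vo2[12] <- 1000 + 6 * 50
  b <- breath_tbl(seq_len(20) * 2.5, vo2)
  out <- remove_errant_breaths(b)
  expect_identical(attr(out, "removed"), oracle_errant(vo2))
  expect_true(12L %in% attr(out, "removed"))
})

test_that("a breath exactly at 3 local SDs is retained (strict inequality)", {
  # neighbours of breath 3 are c(100, 140, 140, 100): mean 120, sd ~23.09
  nb <- c(100, 140, 140, 100)
  m <- mean(nb)
  s <- sd(nb)
  vo2 <- c(100, 140, m + 3 * s, 140, 100)
  b <- breath_tbl(1:5, vo2)
  out <- remove_errant_breaths(b)
  expect_identical(attr(out, "removed"), integer(0))
  # nudge it past the boundary and it is removed
  vo2[3] <- m + 3 * s + 1e-6
  out2 <- remove_errant_breaths(breath_tbl(1:5, vo2))
  expect_identical(attr(out2, "removed"), 3L)
})

test_that("screening preserves order, never inserts, and warns on short series", {
  set.seed(4)
  vo2 <- rnorm(40, 1500, 100)
  b <- breath_tbl(cumsum(runif(40, 1, 4)), vo2)
  out <- remove_errant_breaths(b)
  expect_lte(nrow(out), nrow(b))
  expect_false(is.unsorted(out$t, strictly = TRUE))
  expect_true(all(out$vo2 %in% vo2))

  short <- breath_tbl(1:3, c(1, 2, 3))
  expect_warning(res <- remove_errant_breaths(short), "shorter")
  expect_identical(nrow(res), 3L)
  expect_true(attr(res, "short_series"))
})

test_that("1-s interpolation is exact on lines and respects the observed span", {
  b <- breath_tbl(c(0, 2), c(1000, 1200))
  out <- interpolate_1s(b)
  expect_equal(out$vo2, c(1000, 1100, 1200))
  expect_equal(out$t, 0:2)

  # constant function between fractional breath times
  out2 <- interpolate_1s(breath_tbl(c(0.5, 1.5), c(900, 900)))
  expect_equal(out2$t, 1)
  expect_equal(out2$vo2, 900)

  # affine vo2(t) = 2 t reproduced exactly at every grid point
  set.seed(21)
  t <- sort(runif(30, 0, 60))
  out3 <- interpolate_1s(breath_tbl(t, 2 * t))
  expect_equal(out3$vo2, 2 * out3$t, tolerance = 1e-12)
  expect_gte(min(out3$t), min(t))
  expect_lte(max(out3$t), max(t))

  expect_error(interpolate_1s(breath_tbl(1, 100)), "at least 2")
})

test_that("ensemble averaging is idempotent, linear, and reduces noise", {
  s <- tibble::tibble(t = 0:100, vo2 = sin(0:100 / 10))
  expect_equal(ensemble_average(list(s, s, s)), s)

  s2 <- dplyr::mutate(s, vo2 = -vo2)
  expect_true(all(ensemble_average(list(s, s2))$vo2 == 0))

  # three noisy realizations of one mono-exponential: the ensemble is
  # closer to the truth than a single realization
  set.seed(33)
  truth <- vo2_onset_model(0:240, 900, 1100, 11, 25)
  reals <- lapply(1:3, function(i) {
    tibble::tibble(t = 0:240, vo2 = truth + rnorm(241, 0, 80))
  })
  rms <- function(x) sqrt(mean(x^2))
  ens <- ensemble_average(reals)
  expect_lt(rms(ens$vo2 - truth), rms(reals[[1]]$vo2 - truth))

  expect_error(ensemble_average(list()), "non-empty")
  d1 <- tibble::tibble(t = 0:10, vo2 = 1)
  d2 <- tibble::tibble(t = 50:60, vo2 = 1)
  expect_error(ensemble_average(list(d1, d2)), "disjoint")
})

test_that("5-s binning averages complete blocks at midpoint timestamps", {
  s <- tibble::tibble(t = 0:9, vo2 = 1:10)
  out <- bin_5s(s)
  expect_equal(out$vo2, c(3, 8))
  expect_equal(out$t, c(2, 7))

  # constant stays constant; 23 samples give 4 bins (3 discarded)
  s23 <- tibble::tibble(t = 0:22, vo2 = rep(7, 23))
  out23 <- bin_5s(s23)
  expect_identical(nrow(out23), 4L)
  expect_true(all(out23$vo2 == 7))

  # mean conservation over retained samples
  set.seed(5)
  s2 <- tibble::tibble(t = 0:99, vo2 = rnorm(100))
  expect_equal(mean(bin_5s(s2)$vo2), mean(s2$vo2))

  expect_error(bin_5s(tibble::tibble(t = 0:2, vo2 = 1:3)), "at least 5")
})

test_that("the full cleaning chain recovers a noiseless mono-exponential", {
  # three identical noiseless transitions through the whole chain:
  # binned values match the model at bin midpoints to < 0.5%
  t <- seq(-180, 300, by = 0.8)
  vo2 <- vo2_onset_model(pmax(t, -1e9), 900, 1100, 11, 25)
  vo2[t < 0] <- 900
  tr <- lapply(1:3, function(i) breath_tbl(t, vo2))
  ens <- ensemble_average(lapply(tr, interpolate_1s))
  binned <- bin_5s(ens)
  # compare over the phase-II region the fit consumes (the kink at the
  # time delay itself is not representable by any 5-s bin mean)
  phase2 <- dplyr::filter(binned, t > 20)
  model_at_mid <- vo2_onset_model(phase2$t, 900, 1100, 11, 25)
  rel <- abs(phase2$vo2 - model_at_mid) / model_at_mid
  expect_lt(max(rel), 0.005)
})
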