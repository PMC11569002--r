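#' Peak oxygen uptake from a ramp test
#'
#' Highest mean V̇O2 over any contiguous 30-s window of the 1-s
#' interpolated ramp recording.
#'
#' @param series Data frame with columns `t` (1-s grid) and `vo2`.
#' @param window_s Window length in seconds (default 30).
#' @return V̇O2peak in the units of `vo2`.
#' @export
compute_vo2peak <- function(series, window_s = 30L) {
  check_series(series, c("t", "vo2"))
  if (nrow(series) < window_s) {
    abort(sprintf("Need at least %d s of data.", window_s))
  }
  max(zoo::rollmean(series$vo2, k = window_s, align = "center"))
}

#' Peak power output with ramp-rate correction
#'
#' Power at test cessation minus two thirds of the ramp rate, the standard
#' correction for the lag between work rate and V̇O2 on a fast ramp
#' (for a 25 W/min ramp the correction is 16.67 W).
#'
#' @param power_at_cessation Power at volitional exhaustion (W).
#' @param ramp_rate Ramp rate (W/min), default 25.
#' @return Peak power output (W).
#' @export
compute_ppo <- function(power_at_cessation, ramp_rate = 25) {
  if (ramp_rate < 0) {
    abort("`ramp_rate` must be >= 0.")
  }
  power_at_cessation - (2 / 3) * ramp_rate
}

#' Gas-exchange threshold by v-slope breakpoint regression
#'
#' Algorithmic version of the simplified v-slope method: after binning the
#' ramp-phase gas-exchange channels (default 10-s bins to suppress breath
#' noise), a continuous two-segment piecewise-linear regression of V̇CO2
#' on V̇O2 is fitted at every candidate breakpoint; the breakpoint
#' minimising the pooled residual sum of squares is the GET, accepted only
#' when the upper segment is steeper than the lower and the two-segment
#' model improves on a single line by more than `min_improvement`
#' (fractional RSS reduction, default 5%).
#'
#' The ventilatory-equivalent criterion is computed as quality control: in
#' the 60 s following the breakpoint the slope of V̇E/V̇O2 against time
#' should turn positive while the slope of V̇E/V̇CO2 stays non-positive.
#' When the two criteria disagree a `review` flag is raised rather than
#' silently trusting either, mirroring the dual-assessor practice the
#' method replaces.
#'
#' @param series Data frame with columns `t`, `vo2`, `vco2`, `ve` on a 1-s
#'   grid, restricted to the ramp phase (onset to cessation). `vo2`/`vco2`
#'   in L/min, `ve` in L/min.
#' @param bin_s Bin width in seconds before breakpoint detection
#'   (default 10).
#' @param min_improvement Minimum fractional RSS improvement of the
#'   two-segment model over a single line for the GET to count as
#'   detected (default 0.05).
#' @return A one-row tibble of class `get_result` with columns `get_vo2`,
#'   `detected`, `slope1`, `slope2`, `rss_single`, `rss_two`,
#'   `improvement`, `vent_equiv_ok`, `review`. The binned data are
#'   attached as attribute `binned` for plotting.
#' @export
detect_get <- function(series, bin_s = 10L, min_improvement = 0.05) {
  check_series(series, c("t", "vo2", "vco2", "ve"))
  binned <- bin_gas_channels(series, bin_s)
  if (nrow(binned) < 20L) {
    abort("Need at least 20 bins of ramp data for GET detection.")
  }

  x <- binned$vo2
  y <- binned$vco2
  fit1 <- lm(y ~ x)
  rss_single <- sum(stats::resid(fit1)^2)

  # candidate knots: interior points, >= 3 bins in each segment
  ord <- order(x)
  xs <- x[ord]
  cand <- unique(xs[3:(length(xs) - 3L)])
  scan <- purrr::map(cand, function(c0) {
    h <- pmax(x - c0, 0)
    f <- lm(y ~ x + h)
    b <- coef(f)
    tibble(
      knot = c0, rss = sum(stats::resid(f)^2),
      slope1 = unname(b[["x"]]),
      slope2 = unname(b[["x"]] + b[["h"]])
    )
  }) %>% bind_rows()

  best <- scan[which.min(scan$rss), ]
  improvement <- (rss_single - best$rss) / rss_single
  # a single line already fitting to numerical precision leaves no knee
  # to detect, whatever the relative RSS ratio of two near-zero numbers
  tss <- sum((y - mean(y))^2)
  single_line_perfect <- rss_single <= 1e-12 * tss
  detected <- !single_line_perfect && is.finite(improvement) &&
    improvement > min_improvement && best$slope2 > best$slope1

  # ventilatory-equivalent QC around the breakpoint
  vent_ok <- NA
  if (detected) {
    t_break <- binned$t[which(binned$vo2 >= best$knot)[1]]
    post <- filter(binned, .data$t >= t_break, .data$t <= t_break + 60)
    if (nrow(post) >= 3L) {
      f_o2 <- lm(I(ve / vo2) ~ t, data = post)
      f_co2 <- lm(I(ve / vco2) ~ t, data = post)
      s_o2 <- coef(f_o2)[["t"]]
      s_co2 <- coef(f_co2)[["t"]]
      # the CO2 equivalent must not rise: reject only a slope that is both
      # statistically and materially positive (> 0.1% relative rise over
      # the window), so neither breath noise nor floating-point residue
      # can veto a true GET
      co2_t <- suppressWarnings(summary(f_co2)$coefficients["t", "t value"])
      rel_rise <- s_co2 * 60 / mean(post$ve / post$vco2)
      co2_rising <- rel_rise > 1e-3 && is.finite(co2_t) &&
        co2_t > stats::qt(0.95, df = nrow(post) - 2)
      vent_ok <- s_o2 > 0 && !co2_rising
    }
  }

  out <- tibble(
    get_vo2 = if (detected) best$knot else NA_real_,
    detected = detected,
    slope1 = best$slope1,
    slope2 = best$slope2,
    rss_single = rss_single,
    rss_two = best$rss,
    improvement = improvement,
    vent_equiv_ok = vent_ok,
    review = detected && isFALSE(vent_ok)
  )
  attr(out, "binned") <- binned
  class(out) <- c("get_result", class(out))
  out
}

bin_gas_channels <- function(series, bin_s) {
  n_bins <- nrow(series) %/% bin_s
  if (n_bins < 1L) {
    abort("Series shorter than one bin.")
  }
  keep <- seq_len(n_bins * bin_s)
  series[keep, ] %>%
    mutate(.bin = rep(seq_len(n_bins), each = bin_s)) %>%
    group_by(.data$.bin) %>%
    summarise(across(c("t", "vo2", "vco2", "ve"), mean), .groups = "drop") %>%
    dplyr::select(!".bin")
}

#' V-slope plot with the detected breakpoint
#'
#' @param object A `get_result` from [detect_get()].
#' @param ... Unused.
#' @return A ggplot of binned V̇CO2 against V̇O2 with the GET marked.
#' @exportS3Method ggplot2::autoplot
autoplot.get_result <- function(object, ...) {
  binned <- attr(object, "binned")
  p <- ggplot2::ggplot(binned, ggplot2::aes(x = .data$vo2, y = .data$vco2)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(
      x = expression(dot(V) * O[2] ~ "(L/min)"),
      y = expression(dot(V) * CO[2] ~ "(L/min)")
    )
  if (isTRUE(object$detected)) {
    p <- p + ggplot2::geom_vline(xintercept = object$get_vo2, linetype = 2)
  }
  p
}

#' Power output at the gas-exchange threshold
#'
#' Power at the first time the 30-s smoothed V̇O2 reaches the GET,
#' corrected by the same two-thirds ramp-rate lag term as [compute_ppo()]
#' and floored at zero.
#'
#' @param get_vo2 V̇O2 at the GET (same units as `series$vo2`).
#' @param series Ramp-phase data frame with `t` (s since ramp onset) and
#'   `vo2`, on a 1-s grid.
#' @param ramp_rate Ramp rate (W/min), default 25.
#' @param start_power Power at ramp onset (W), default 10.
#' @param smooth_s Width of the centred smoothing window (s), default 30.
#' @return Power at GET (W).
#' @export
power_at_get <- function(get_vo2, series, ramp_rate = 25, start_power = 10,
                         smooth_s = 30L) {
  check_series(series, c("t", "vo2"))
  smoothed <- moving_average(series$vo2, smooth_s)
  idx <- which(smoothed >= get_vo2)[1]
  if (is.na(idx)) {
    abort("`get_vo2` is never reached by the smoothed ramp response.")
  }
  t_cross <- series$t[idx]
  max(start_power + ramp_rate * t_cross / 60 - (2 / 3) * ramp_rate, 0)
}

#' Analyse an incremental ramp test
#'
#' Convenience wrapper chaining [compute_vo2peak()], [compute_ppo()],
#' [detect_get()] and [power_at_get()] for a 1-s interpolated ramp
#' recording.
#'
#' @param series Data frame with `t` (s since ramp onset), `vo2`, `vco2`,
#'   `ve`; V̇O2/V̇CO2 in L/min.
#' @param power_at_cessation Power at test cessation (W).
#' @param ramp_rate Ramp rate (W/min), default 25.
#' @param start_power Power at ramp onset (W), default 10.
#' @param ... Passed to [detect_get()].
#' @return A one-row tibble: `vo2peak`, `ppo`, `get_vo2`, `get_pct`
#'   (GET as % of V̇O2peak), `get_power`, `get_detected`, `review`.
#' @export
analyze_ramp <- function(series, power_at_cessation, ramp_rate = 25,
                         start_power = 10, ...) {
  vo2peak <- compute_vo2peak(series)
  ppo <- compute_ppo(power_at_cessation, ramp_rate)
  get <- detect_get(series, ...)
  get_power <- if (isTRUE(get$detected)) {
    power_at_get(get$get_vo2, series, ramp_rate, start_power)
  } else {
    NA_real_
  }
  tibble(
    vo2peak = vo2peak,
    ppo = ppo,
    get_vo2 = get$get_vo2,
    get_pct = 100 * get$get_vo2 / vo2peak,
    get_power = get_power,
    get_detected = get$detected,
    review = get$review
  )
}
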