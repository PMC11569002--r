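#' Per-contraction muscle-oxygenation means
#'
#' Means of the tissue saturation index and the deoxyhaemoglobin signal
#' over each 3-s contraction window of a paired all-out torque test. The
#' NIRS trace must share the torque test's clock and cover every
#' contraction window.
#'
#' @param nirs Data frame with columns `t` (s), `tsi` (%) and `hhb`
#'   (a.u.); `o2hb` optional and unused here.
#' @param cycles Cycle table from [segment_cycles()] (columns `cycle`,
#'   `t_on`, `t_off`).
#' @return `cycles` with `mean_tsi` and `mean_hhb` added.
#' @export
per_cycle_oxygenation <- function(nirs, cycles) {
  check_series(nirs, c("t", "tsi", "hhb"))
  check_series(cycles, c("cycle", "t_on", "t_off"))
  res <- purrr::pmap(cycles[c("cycle", "t_on", "t_off")], function(cycle, t_on, t_off) {
    w <- nirs$t >= t_on - 1e-9 & nirs$t <= t_off + 1e-9
    if (!any(w) || min(nirs$t) > t_on + 1e-9 || max(nirs$t) < t_off - 1e-9) {
      abort(sprintf("NIRS trace does not cover contraction cycle %d.", cycle))
    }
    c(mean_tsi = mean(nirs$tsi[w]), mean_hhb = mean(nirs$hhb[w]))
  })
  cycles$mean_tsi <- purrr::map_dbl(res, "mean_tsi")
  cycles$mean_hhb <- purrr::map_dbl(res, "mean_hhb")
  cycles
}

#' Express a per-cycle series as a percentage of its maximum
#'
#' Each value is scaled by 100 over the series maximum, so the maximum
#' element maps to exactly 100%. Used to put torque, TSI and
#' deoxyhaemoglobin per-cycle means on a common relative scale before
#' forming ratios.
#'
#' @param x Numeric vector of per-cycle values; `max(x)` must be > 0.
#' @return `x * 100 / max(x)`.
#' @export
normalize_percent_of_max <- function(x) {
  m <- max(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    abort("Series maximum must be positive to normalize.")
  }
  x * 100 / m
}

#' Mean resting NIRS baseline before the test
#'
#' Mean of a channel over a pre-test window, used to zero the (relative)
#' deoxyhaemoglobin signal before normalization. TSI, already an absolute
#' percentage, needs no baseline subtraction.
#'
#' @param nirs Data frame with `t` and the channel column.
#' @param channel Column name, default `"hhb"`.
#' @param window Length-2 numeric `[start, end)` in test-local seconds,
#'   default the 30 s before test start.
#' @return Baseline mean of the channel.
#' @export
nirs_baseline <- function(nirs, channel = "hhb", window = c(-30, 0)) {
  check_series(nirs, c("t", channel))
  sel <- nirs$t >= window[1] & nirs$t < window[2]
  if (!any(sel)) {
    abort("No NIRS samples in the baseline window.")
  }
  mean(nirs[[channel]][sel])
}

#' Torque-to-oxygenation ratio series
#'
#' Elementwise ratio of percent-of-maximum torque to percent-of-maximum
#' oxygenation (TSI for O2 availability, deoxyhaemoglobin for O2
#' extraction), one value per contraction cycle. Cycles with a zero
#' denominator are dropped and recorded in the `dropped` attribute.
#'
#' @param t_pct Per-cycle torque, % of maximum.
#' @param oxy_pct Per-cycle oxygenation, % of maximum (same length).
#' @param times Time point X of each ratio (s), by convention the
#'   contraction-window midpoint with X = 0 at test start.
#' @param kind `"tsi"` or `"hhb"`.
#' @return A tibble of class `ratio_series` with columns `time`, `ratio`
#'   and `kind`; dropped cycle indices in attribute `dropped`.
#' @export
build_ratio <- function(t_pct, oxy_pct, times, kind = c("tsi", "hhb")) {
  kind <- match.arg(kind)
  if (length(t_pct) != length(oxy_pct) || length(t_pct) != length(times)) {
    abort("`t_pct`, `oxy_pct` and `times` must have equal length.")
  }
  bad <- !is.finite(oxy_pct) | oxy_pct == 0
  out <- tibble(
    time = times[!bad],
    ratio = t_pct[!bad] / oxy_pct[!bad],
    kind = kind
  )
  attr(out, "dropped") <- which(bad)
  class(out) <- c("ratio_series", class(out))
  out
}

#' Exponential-decay model of the critical ratio
#'
#' Evaluates \deqn{R(X) = CR + (0R - CR)\,e^{-X/\tau},} the decay of the
#' torque/oxygenation ratio across an all-out test towards its critical
#' ratio (asymptote) CR from its initial value 0R.
#'
#' @param x Time points X (s).
#' @param cr Critical ratio (asymptote).
#' @param r0 Ratio at X = 0.
#' @param tau Time constant (s), > 0.
#' @return Model ratio values.
#' @export
ratio_decay_model <- function(x, cr, r0, tau) {
  stopifnot(tau > 0)
  cr + (r0 - cr) * exp(-x / tau)
}

#' Fit the critical-ratio exponential decay
#'
#' Nonlinear least-squares fit of [ratio_decay_model()] to a per-cycle
#' torque/oxygenation ratio series, returning the initial ratio, the
#' model-predicted critical ratio (asymptote), the time constant and its
#' half-life `tau * ln 2`. Levenberg–Marquardt with box constraints
#' (`cr >= 0`, `r0 >= 0`, `tau` in (0, 600] s) and three deterministic
#' starts (`tau` = 30, 60, 120 s); the lowest-RSS solution is kept. A
#' series that rises rather than decays is fitted all the same and
#' flagged `"rising"`; a flat series is returned unconverged with `cr`
#' set to the series mean.
#'
#' @param series Data frame with columns `time` and `ratio` (>= 10 valid
#'   cycles), e.g. from [build_ratio()].
#' @return An object of class `ratiofit`: list with `cr`, `r0`, `tau`,
#'   `tau_half`, `rss`, `n_points`, `converged`, `flags`, `kind`, and the
#'   fitted `data`. Methods: [predict.ratiofit()], [tidy()], [glance()],
#'   [autoplot.ratiofit()].
#' @export
fit_ratio_decay <- function(series) {
  check_series(series, c("time", "ratio"))
  dat <- as_tibble(series)[c("time", "ratio")]
  dat <- filter(dat, is.finite(.data$ratio))
  if (nrow(dat) < 10L) {
    abort("Need at least 10 valid ratio points to fit the decay model.")
  }
  kind <- if ("kind" %in% names(series)) series$kind[1] else NA_character_

  out <- list(
    cr = NA_real_, r0 = NA_real_, tau = NA_real_, tau_half = NA_real_,
    rss = NA_real_, n_points = nrow(dat), converged = FALSE,
    flags = character(0), kind = kind, data = dat
  )
  class(out) <- "ratiofit"

  if (sd(dat$ratio) == 0) {
    out$cr <- mean(dat$ratio)
    out$r0 <- out$cr
    out$rss <- 0
    out$flags <- "flat_series"
    return(out)
  }

  resid_fn <- function(par) {
    dat$ratio - ratio_decay_model(dat$time, par[["cr"]], par[["r0"]], par[["tau"]])
  }
  r0_0 <- dat$ratio[which.min(dat$time)]
  cr_0 <- mean(utils::tail(dat$ratio[order(dat$time)], 6L))
  lower <- c(cr = 0, r0 = 0, tau = 1e-3)
  upper <- c(cr = Inf, r0 = Inf, tau = 600)

  best <- NULL
  for (tau0 in c(30, 60, 120)) {
    start <- c(cr = max(cr_0, 1e-6), r0 = max(r0_0, 1e-6), tau = tau0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    out$flags <- "optimizer_failed"
    return(out)
  }

  out$cr <- unname(best$par[["cr"]])
  out$r0 <- unname(best$par[["r0"]])
  out$tau <- unname(best$par[["tau"]])
  out$tau_half <- out$tau * log(2)
  out$rss <- best$rss
  out$converged <- best$info %in% 1:4
  if (out$r0 < out$cr) {
    out$flags <- c(out$flags, "rising")
  }
  if (abs(out$tau - upper[["tau"]]) < 1e-6) {
    out$flags <- c(out$flags, "tau_at_bound")
    out$converged <- FALSE
  }
  out
}

#' @export
print.ratiofit <- function(x, ...) {
  cat(sprintf("Critical-ratio decay fit (%s)\n", x$kind))
  cat(sprintf(
    "  0R %.3f -> CR %.3f | tau %.1f s (tau_half %.1f s)\n",
    x$r0, x$cr, x$tau, x$tau_half
  ))
  cat(sprintf(
    "  RSS %.4g over %d points; converged: %s\n",
    x$rss, x$n_points, x$converged
  ))
  invisible(x)
}

#' Predict ratio values from a fitted decay model
#'
#' @param object A `ratiofit` from [fit_ratio_decay()].
#' @param x Time points X (s).
#' @param ... Unused.
#' @return Model ratio values.
#' @export
predict.ratiofit <- function(object, x, ...) {
  ratio_decay_model(x, object$cr, object$r0, object$tau)
}

#' @exportS3Method generics::tidy
tidy.ratiofit <- function(x, ...) {
  tibble(
    term = c("r0", "cr", "tau", "tau_half"),
    estimate = c(x$r0, x$cr, x$tau, x$tau_half)
  )
}

#' @exportS3Method generics::glance
glance.ratiofit <- function(x, ...) {
  tibble(
    rss = x$rss, n_points = x$n_points, converged = x$converged,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Ratio-series plot with fitted decay and critical-ratio asymptote
#'
#' @param object A `ratiofit`.
#' @param ... Unused.
#' @return A ggplot of the per-cycle ratios, fitted curve and asymptote.
#' @exportS3Method ggplot2::autoplot
autoplot.ratiofit <- function(object, ...) {
  curve <- tibble(time = seq(min(object$data$time), max(object$data$time),
    length.out = 200
  ))
  curve$ratio <- predict(object, curve$time)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$ratio)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::geom_hline(yintercept = object$cr, linetype = 3) +
    ggplot2::labs(x = "Time (s)", y = "Torque % / oxygenation %")
}

#' Critical-ratio analysis of a paired torque and NIRS test
#'
#' Full chain for one all-out test: per-cycle oxygenation means, percent-
#' of-maximum normalization (with resting-baseline subtraction for the
#' relative deoxyhaemoglobin signal), ratio construction at contraction-
#' window midpoints, and the exponential-decay fit for both signals.
#'
#' @param nirs Data frame with `t`, `tsi`, `hhb` (10 Hz typical), aligned
#'   to the torque-test clock (test start at `t = 0`).
#' @param cycles Cycle table with `mean_torque` from [cycle_metrics()].
#' @param hhb_baseline_window Pre-test window for the deoxyhaemoglobin
#'   baseline, default `c(-30, 0)`; `NULL` skips subtraction.
#' @return A list with elements `tsi` and `hhb`, each a `ratiofit`, plus
#'   `cycles` (the augmented per-cycle table).
#' @export
analyze_oxygenation <- function(nirs, cycles, hhb_baseline_window = c(-30, 0)) {
  check_series(cycles, c("cycle", "t_on", "t_off", "mean_torque"))
  cyc <- per_cycle_oxygenation(nirs, cycles)
  hhb0 <- if (is.null(hhb_baseline_window)) {
    0
  } else {
    nirs_baseline(nirs, "hhb", hhb_baseline_window)
  }
  t_pct <- normalize_percent_of_max(cyc$mean_torque)
  tsi_pct <- normalize_percent_of_max(cyc$mean_tsi)
  hhb_pct <- normalize_percent_of_max(cyc$mean_hhb - hhb0)
  x_mid <- (cyc$t_on + cyc$t_off) / 2
  list(
    tsi = fit_ratio_decay(build_ratio(t_pct, tsi_pct, x_mid, "tsi")),
    hhb = fit_ratio_decay(build_ratio(t_pct, hhb_pct, x_mid, "hhb")),
    cycles = mutate(cyc,
      t_pct = t_pct, tsi_pct = tsi_pct, hhb_pct = hhb_pct
    )
  )
}
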