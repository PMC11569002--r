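#' Phase-II mono-exponential oxygen-uptake model
#'
#' Evaluates the rest-to-exercise on-kinetics model
#' \deqn{\dot VO_2(t) = \dot VO_{2BASE} + \dot VO_{2AMP}\,[1 - e^{-(t - TD)/\tau}]}
#' for `t >= td`, and the unloaded baseline `vo2_base` for `t < td`.
#' The time delay is treated as a pure delay: before it the model sits flat
#' at baseline, which keeps pre-delay samples from biasing the time
#' constant. The time constant `tau` is the time needed to reach 63% of
#' the amplitude after the delay.
#'
#' @param t Time since load onset (s).
#' @param vo2_base Baseline V̇O2 during unloaded pedalling (mL/min).
#' @param vo2_amp Steady-state rise above baseline (mL/min).
#' @param td Time delay (s).
#' @param tau Time constant (s), > 0.
#' @return Model V̇O2 (mL/min), vectorised over `t`.
#' @export
#' @examples
#' vo2_onset_model(11 + 25, 900, 1100, td = 11, tau = 25) # ~ 900 + 0.63 * 1100
vo2_onset_model <- function(t, vo2_base, vo2_amp, td, tau) {
  stopifnot(tau > 0)
  ifelse(t < td, vo2_base, vo2_base + vo2_amp * (1 - exp(-(t - td) / tau)))
}

#' Baseline oxygen uptake during unloaded pedalling
#'
#' Arithmetic mean of V̇O2 over a window of the unloaded phase, by default
#' the final 60 s before the load onset (transition-local `t` in
#' `[-60, 0)`).
#'
#' @param series Data frame with columns `t` (transition-local s) and `vo2`.
#' @param window Length-2 numeric, `[start, end)` of the averaging window.
#' @return Baseline V̇O2 (mL/min), a single number.
#' @export
compute_baseline <- function(series, window = c(-60, 0)) {
  check_series(series, c("t", "vo2"))
  sel <- series$t >= window[1] & series$t < window[2]
  if (!any(sel)) {
    abort("No samples fall inside the baseline window.")
  }
  mean(series$vo2[sel])
}

#' Fit the phase-II mono-exponential to a binned transition
#'
#' Nonlinear least-squares fit of [vo2_onset_model()] to the 5-s binned
#' ensemble response, over samples with bin midpoint in
#' `(fit_window[1], fit_window[2]]` seconds after load onset. The first
#' 20 s are excluded by default as the cardiodynamic phase-I response, and
#' the window ends at 240 s. The baseline is fixed from the unloaded phase
#' (see [compute_baseline()]); free parameters are the amplitude, time
#' delay and time constant, bounded to `vo2_amp >= 0`, `td` in `[0, 40]` s
#' and `tau` in `(0, 120]` s.
#'
#' The optimiser is Levenberg–Marquardt with box constraints
#' ([minpack.lm::nls.lm()]), started from three deterministic initial
#' guesses (`tau` = 15, 25, 40 s; `td` = 10 s; amplitude = mean of the
#' final 60 s of the window minus baseline); the lowest-RSS solution is
#' returned.
#'
#' @param series Data frame with columns `t` (s post-onset, typically 5-s
#'   bin midpoints) and `vo2` (mL/min).
#' @param vo2_base Fixed baseline V̇O2 (mL/min).
#' @param fit_window Length-2 numeric; samples with
#'   `t > fit_window[1]` and `t <= fit_window[2]` are fitted.
#' @return An object of class `vo2fit`: a list with elements
#'   `vo2_base`, `vo2_amp`, `td`, `tau`, `rss`, `n_points`, `converged`,
#'   the fitted `data`, and `fit_window`. Methods: [predict.vo2fit()],
#'   [tidy()], [glance()], [autoplot.vo2fit()].
#' @export
fit_vo2_kinetics <- function(series, vo2_base, fit_window = c(20, 240)) {
  check_series(series, c("t", "vo2"))
  dat <- filter(as_tibble(series), .data$t > fit_window[1], .data$t <= fit_window[2])
  if (nrow(dat) < 8L) {
    abort("Fewer than 8 samples in the fitting window; cannot fit.")
  }

  out <- list(
    vo2_base = vo2_base, vo2_amp = NA_real_, td = NA_real_, tau = NA_real_,
    rss = NA_real_, n_points = nrow(dat), converged = FALSE,
    data = dat, fit_window = fit_window, flags = character(0)
  )
  class(out) <- "vo2fit"

  if (sd(dat$vo2) == 0) {
    # flat input: amplitude zero, tau unidentifiable
    out$vo2_amp <- 0
    out$td <- 0
    out$tau <- NA_real_
    out$rss <- sum((dat$vo2 - vo2_base)^2)
    out$flags <- "flat_input"
    return(out)
  }

  resid_fn <- function(par) {
    dat$vo2 - vo2_onset_model(dat$t, vo2_base, par[["vo2_amp"]], par[["td"]], par[["tau"]])
  }
  tail_sel <- dat$t > fit_window[2] - 60
  amp0 <- max(mean(dat$vo2[tail_sel]) - vo2_base, 0)
  lower <- c(vo2_amp = 0, td = 0, tau = 1e-3)
  upper <- c(vo2_amp = Inf, td = 40, tau = 120)

  best <- NULL
  for (tau0 in c(15, 25, 40)) {
    start <- c(vo2_amp = amp0, td = 10, tau = tau0)
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

  out$vo2_amp <- unname(best$par[["vo2_amp"]])
  out$td <- unname(best$par[["td"]])
  out$tau <- unname(best$par[["tau"]])
  out$rss <- best$rss
  out$converged <- best$info %in% 1:4
  if (abs(out$tau - upper[["tau"]]) < 1e-6 || out$vo2_amp == 0) {
    out$flags <- c(out$flags, "parameter_at_bound")
    out$converged <- FALSE
  }
  out
}

#' @export
print.vo2fit <- function(x, ...) {
  cat("Phase-II V̇O2 on-kinetics fit\n")
  cat(sprintf(
    "  vo2_base %.1f  vo2_amp %.1f mL/min | TD %.2f s | tau %.2f s\n",
    x$vo2_base, x$vo2_amp, x$td, x$tau
  ))
  cat(sprintf(
    "  RSS %.1f over %d points; converged: %s\n",
    x$rss, x$n_points, x$converged
  ))
  invisible(x)
}

#' Predict oxygen uptake from a fitted on-kinetics model
#'
#' @param object A `vo2fit` from [fit_vo2_kinetics()].
#' @param t Times since load onset (s).
#' @param ... Unused.
#' @return Predicted V̇O2 (mL/min).
#' @export
predict.vo2fit <- function(object, t, ...) {
  vo2_onset_model(t, object$vo2_base, object$vo2_amp, object$td, object$tau)
}

#' @exportS3Method generics::tidy
tidy.vo2fit <- function(x, ...) {
  tibble(
    term = c("vo2_base", "vo2_amp", "td", "tau"),
    estimate = c(x$vo2_base, x$vo2_amp, x$td, x$tau),
    fixed = c(TRUE, FALSE, FALSE, FALSE)
  )
}

#' @exportS3Method generics::glance
glance.vo2fit <- function(x, ...) {
  tibble(
    rss = x$rss, n_points = x$n_points, converged = x$converged,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Diagnostic plot for an on-kinetics fit
#'
#' @param object A `vo2fit`.
#' @param ... Unused.
#' @return A ggplot of the binned data and fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.vo2fit <- function(object, ...) {
  curve <- tibble(
    t = seq(min(object$data$t), max(object$data$t), length.out = 200)
  )
  curve$vo2 <- predict(object, curve$t)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$vo2)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(
      x = "Time after load onset (s)",
      y = expression(dot(V) * O[2] ~ "(mL/min)"),
      title = sprintf("tau = %.1f s, TD = %.1f s", object$tau, object$td)
    )
}
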