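#' Baseline arterial diameter
#'
#' Mean diameter over the 60 s immediately preceding cuff inflation.
#'
#' @param rec Data frame with columns `t` (1-s timestamps), `diameter`
#'   (mm) and optionally `velocity` (mm/s).
#' @param t_inflation Cuff-inflation time (s).
#' @param window_s Baseline window length (s), default 60.
#' @return Baseline diameter (mm).
#' @export
baseline_diameter <- function(rec, t_inflation, window_s = 60) {
  check_series(rec, c("t", "diameter"))
  sel <- rec$t >= t_inflation - window_s & rec$t < t_inflation
  if (!any(sel) || min(rec$t) > t_inflation - window_s) {
    abort(sprintf("Fewer than %g s of pre-inflation data.", window_s))
  }
  mean(rec$diameter[sel])
}

#' Post-occlusion peak diameter and time-to-peak
#'
#' Maximum of the (optionally smoothed) diameter trace after cuff
#' deflation. A centred moving average of `smoothing_s` seconds guards
#' the peak pick against single-frame noise (`smoothing_s = 0` disables
#' it); ties are broken by the earliest time. A trace that never rises
#' above its deflation value is flagged `no_dilation`.
#'
#' @param rec Data frame with `t` and `diameter`.
#' @param t_deflation Cuff-deflation time (s).
#' @param smoothing_s Smoothing window (s), default 3.
#' @return A one-row tibble: `d_max` (mm), `t_to_max` (s after
#'   deflation), `no_dilation`.
#' @export
find_dmax <- function(rec, t_deflation, smoothing_s = 3) {
  check_series(rec, c("t", "diameter"))
  post <- filter(as_tibble(rec), .data$t >= t_deflation)
  if (nrow(post) < 2L || max(post$t) - t_deflation < 30) {
    abort("Post-deflation segment missing or shorter than 30 s.")
  }
  k <- max(1L, round(smoothing_s))
  smoothed <- moving_average(post$diameter, k)
  if (smoothing_s == 0) smoothed <- post$diameter
  i <- which.max(smoothed) # which.max returns the first maximum: earliest tie wins
  tibble(
    d_max = smoothed[i],
    t_to_max = post$t[i] - t_deflation,
    no_dilation = post$t[i] == t_deflation
  )
}

#' Flow-mediated dilation percentage
#'
#' \deqn{FMD\% = 100\,(D_{MAX} - D_{BASELINE})/D_{BASELINE}.}
#'
#' @param d_baseline Baseline diameter (mm), > 0.
#' @param d_max Post-occlusion maximum diameter (mm).
#' @return FMD (%); negative when the artery constricted.
#' @export
fmd_percent <- function(d_baseline, d_max) {
  if (any(d_baseline <= 0)) {
    abort("`d_baseline` must be positive.")
  }
  100 * (d_max - d_baseline) / d_baseline
}

#' Shear rate from velocity and diameter
#'
#' \deqn{SR = 4V/D} per time frame, with V the mean blood velocity (mm/s)
#' and D the arterial diameter (mm). Frames with non-positive diameter
#' are returned as `NA` and their indices recorded in the `flagged`
#' attribute.
#'
#' @param velocity Mean velocity (mm/s).
#' @param diameter Diameter (mm), same length.
#' @return Shear rate (1/s) with attribute `flagged`.
#' @export
shear_rate <- function(velocity, diameter) {
  if (length(velocity) != length(diameter)) {
    abort("`velocity` and `diameter` must have equal length.")
  }
  bad <- !is.finite(diameter) | diameter <= 0
  sr <- ifelse(bad, NA_real_, 4 * velocity / diameter)
  attr(sr, "flagged") <- which(bad)
  sr
}

#' Shear-rate area under the curve
#'
#' Trapezoidal integral of the shear-rate series from cuff deflation (the
#' beginning of vasodilation) to the time of peak diameter. An empty
#' interval returns 0 with a warning.
#'
#' @param sr_series Data frame with columns `t` (s) and `sr` (1/s).
#' @param t_deflation Cuff-deflation time (s).
#' @param t_dmax Time of peak diameter (s, absolute).
#' @return SR_AUC (dimensionless).
#' @export
sr_auc <- function(sr_series, t_deflation, t_dmax) {
  check_series(sr_series, c("t", "sr"))
  sel <- sr_series$t >= t_deflation & sr_series$t <= t_dmax &
    is.finite(sr_series$sr)
  if (sum(sel) < 2L) {
    warn("Empty shear-rate interval; SR_AUC set to 0.")
    return(0)
  }
  pracma::trapz(sr_series$t[sel], sr_series$sr[sel])
}

#' Analyse a flow-mediated dilation recording
#'
#' Full chain: baseline diameter over the minute before inflation, peak
#' diameter and time-to-peak after deflation, FMD %, per-frame shear rate
#' and its area under the curve from deflation to peak. Occlusion-period
#' samples never enter any computation.
#'
#' @param rec Data frame with `t` (1-s timestamps), `diameter` (mm) and
#'   `velocity` (mm/s).
#' @param markers Named list or vector with `inflation` and `deflation`
#'   times (s); `baseline_start` optional.
#' @param smoothing_s Peak-pick smoothing (s), default 3; 0 disables.
#' @return A one-row tibble of class `fmd_result`: `d_baseline`, `d_max`,
#'   `t_to_max`, `fmd_pct`, `sr_auc`, `no_dilation`. The shear-rate
#'   series is attached as attribute `sr_series`.
#' @export
analyze_fmd <- function(rec, markers, smoothing_s = 3) {
  check_series(rec, c("t", "diameter", "velocity"))
  m <- as.list(markers)
  if (is.null(m$inflation) || is.null(m$deflation)) {
    abort("`markers` must provide `inflation` and `deflation` times.")
  }
  d_base <- baseline_diameter(rec, m$inflation)
  peak <- find_dmax(rec, m$deflation, smoothing_s)
  sr <- shear_rate(rec$velocity, rec$diameter)
  sr_series <- tibble(t = rec$t, sr = as.numeric(sr))
  auc <- sr_auc(sr_series, m$deflation, m$deflation + peak$t_to_max)
  out <- tibble(
    d_baseline = d_base,
    d_max = peak$d_max,
    t_to_max = peak$t_to_max,
    fmd_pct = fmd_percent(d_base, peak$d_max),
    sr_auc = auc,
    no_dilation = peak$no_dilation
  )
  attr(out, "sr_series") <- sr_series
  attr(out, "markers") <- m
  attr(out, "rec") <- as_tibble(rec)
  class(out) <- c("fmd_result", class(out))
  out
}

#' Diameter-trace plot with baseline and peak annotated
#'
#' @param object An `fmd_result` from [analyze_fmd()].
#' @param ... Unused.
#' @return A ggplot of the diameter trace with D_BASELINE and D_MAX.
#' @exportS3Method ggplot2::autoplot
autoplot.fmd_result <- function(object, ...) {
  rec <- attr(object, "rec")
  m <- attr(object, "markers")
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$t, y = .data$diameter)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$d_baseline, linetype = 3) +
    ggplot2::geom_hline(yintercept = object$d_max, linetype = 2) +
    ggplot2::geom_vline(
      xintercept = c(m$inflation, m$deflation),
      linetype = 1, colour = "grey70"
    ) +
    ggplot2::labs(x = "Time (s)", y = "Arterial diameter (mm)")
}
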