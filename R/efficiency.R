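#' Steady-state gas exchange over the final constant-load window
#'
#' Means of V̇O2 and RER over the last `window_s` seconds of the loaded
#' phase (default 120 s), the steady state used for gross-efficiency
#' calculation.
#'
#' @param breaths Data frame with columns `t` (s), `vo2` and `rer`.
#' @param t_end End of the constant-load phase (s, same clock as `t`).
#' @param window_s Averaging window (s), default 120.
#' @return A one-row tibble with `vo2_ss` and `rer_ss`.
#' @export
steady_state_window <- function(breaths, t_end = max(breaths$t), window_s = 120) {
  check_series(breaths, c("t", "vo2", "rer"))
  sel <- breaths$t >= t_end - window_s & breaths$t <= t_end
  if (!any(sel) || (max(breaths$t[sel]) - min(breaths$t[sel])) < window_s * 0.9) {
    abort(sprintf("Constant-load phase shorter than %g s.", window_s))
  }
  tibble(vo2_ss = mean(breaths$vo2[sel]), rer_ss = mean(breaths$rer[sel]))
}

#' Gross efficiency from steady-state gas exchange
#'
#' Gross efficiency is mechanical power output divided by metabolic power
#' input, expressed as a percentage. The metabolic input (W) is derived
#' from steady-state V̇O2 and RER using the energy-equivalent expression
#' \deqn{P_{met} = \dot VO_2 \times (4940\,RER + 16040)/60,}
#' with V̇O2 in L/min; the bracket term is the energy equivalent of oxygen
#' in J/L (about 20.5 kJ/L at RER 0.9) and division by 60 converts J/min
#' to W. The expression assumes purely aerobic metabolism and is valid for
#' RER at or below 1.0; above that a validity flag is set but the value is
#' still computed.
#'
#' @param power_w Mechanical power output (W).
#' @param vo2_ss Steady-state V̇O2 (L/min), > 0.
#' @param rer_ss Steady-state RER (dimensionless).
#' @return A one-row tibble: `power_w`, `vo2_ss`, `rer_ss`,
#'   `metabolic_input_w`, `gross_efficiency_pct`, `rer_valid`.
#' @export
#' @examples
#' gross_efficiency(power_w = 150, vo2_ss = 3.0, rer_ss = 0.9)
gross_efficiency <- function(power_w, vo2_ss, rer_ss) {
  if (vo2_ss <= 0) {
    abort("`vo2_ss` must be positive.")
  }
  metabolic_input_w <- vo2_ss * (4940 * rer_ss + 16040) / 60
  tibble(
    power_w = power_w,
    vo2_ss = vo2_ss,
    rer_ss = rer_ss,
    metabolic_input_w = metabolic_input_w,
    gross_efficiency_pct = 100 * power_w / metabolic_input_w,
    rer_valid = rer_ss <= 1.0
  )
}
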