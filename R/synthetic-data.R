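#' Synthetic breath-by-breath square-wave transitions
#'
#' Generates a series of rest/unloaded/loaded square-wave cycling bouts
#' with breath-stamped gas exchange. The protocol is 3 min rest, 3 min of
#' unloaded pedalling, then 5 min at a constant load; the loaded-phase
#' mean follows the phase-II mono-exponential [vo2_onset_model()]. Breath
#' times come from a gamma renewal process (mean interval
#' `breath_interval` s, shape `breath_shape`), breath noise is Gaussian,
#' and errant breaths are injected at rate `errant_rate` with offsets of
#' at least `errant_min_sd` noise SDs. V̇CO2, V̇E and RER are produced as
#' plausible companions of the V̇O2 channel.
#'
#' Default parameters match a recreationally trained adult cycling in the
#' moderate domain: baseline ~900 mL/min, amplitude ~1100 mL/min, time
#' delay ~11 s and time constant ~25 s, with 80 mL/min breath noise.
#'
#' @param n_transitions Number of bouts (default 3).
#' @param vo2_base,vo2_amp,td,tau Truth for the on-kinetics model
#'   (mL/min, mL/min, s, s).
#' @param rest_vo2 Mean V̇O2 while seated at rest (mL/min).
#' @param noise_sd Breath-to-breath Gaussian noise SD (mL/min).
#' @param errant_rate Probability a breath is errant (default 0.02).
#' @param errant_min_sd Minimum errant offset in units of `noise_sd`.
#' @param breath_interval Mean breath interval (s).
#' @param breath_shape Gamma shape of the renewal process.
#' @param rer Target steady-state respiratory exchange ratio.
#' @param load_w Imposed power in the loaded phase (W), metadata only.
#' @param seed Integer RNG seed; identical seeds give identical data.
#' @return A list with elements:
#'   * `transitions`: list of recordings, each a list with `breaths`
#'     (tibble `t`, `vo2`, `vco2`, `ve`, `rer`), `markers`
#'     (`rest`, `unloaded`, `load` onsets, s) and `load_w`;
#'   * `truth`: generating parameters, seed and per-transition errant
#'     breath indices.
#' @export
gen_breath_transitions <- function(n_transitions = 3L, vo2_base = 900,
                                   vo2_amp = 1100, td = 11, tau = 25,
                                   rest_vo2 = 350, noise_sd = 80,
                                   errant_rate = 0.02, errant_min_sd = 5,
                                   breath_interval = 2.5, breath_shape = 8,
                                   rer = 0.90, load_w = 150, seed = 1L) {
  if (tau <= 0 || td < 0 || vo2_amp < 0 || vo2_base <= 0) {
    abort("Invalid kinetics parameters.")
  }
  markers <- c(rest = 0, unloaded = 180, load = 360)
  t_total <- 660
  withr::with_seed(seed, {
    transitions <- vector("list", n_transitions)
    errant_idx <- vector("list", n_transitions)
    for (k in seq_len(n_transitions)) {
      gaps <- rgamma(
        ceiling(1.6 * t_total / breath_interval),
        shape = breath_shape, rate = breath_shape / breath_interval
      )
      t <- cumsum(gaps)
      t <- t[t < t_total]
      mu <- ifelse(
        t < markers[["unloaded"]], rest_vo2,
        ifelse(
          t < markers[["load"]], vo2_base,
          vo2_onset_model(t - markers[["load"]], vo2_base, vo2_amp, td, tau)
        )
      )
      vo2 <- mu + rnorm(length(t), 0, noise_sd)
      errant <- which(runif(length(t)) < errant_rate)
      if (length(errant) > 0) {
        offs <- sample(c(-1, 1), length(errant), replace = TRUE) *
          (errant_min_sd + abs(rnorm(length(errant)))) * noise_sd
        vo2[errant] <- vo2[errant] + offs
      }
      vco2 <- rer * mu + rnorm(length(t), 0, noise_sd * 0.8)
      ve <- 0.028 * vco2 + rnorm(length(t), 0, 1.5)
      transitions[[k]] <- list(
        breaths = tibble(
          t = t, vo2 = vo2, vco2 = vco2, ve = ve,
          rer = vco2 / pmax(vo2, 1)
        ),
        markers = markers,
        load_w = load_w
      )
      errant_idx[[k]] <- errant
    }
  })
  list(
    transitions = transitions,
    truth = list(
      family = "breath", seed = seed,
      params = list(
        vo2_base = vo2_base, vo2_amp = vo2_amp, td = td, tau = tau,
        rest_vo2 = rest_vo2, rer = rer, load_w = load_w
      ),
      noise = list(
        sd = noise_sd, errant_rate = errant_rate,
        errant_min_sd = errant_min_sd
      ),
      errant_indices = errant_idx
    )
  )
}

#' Synthetic incremental ramp recording
#'
#' Generates a 1-s gas-exchange recording of a ramp test with a
#' programmed gas-exchange threshold: V̇O2 rises linearly with the work
#' rate; V̇CO2 follows V̇O2 with slope `slope1` below the knee and
#' `slope2` above it (the v-slope breakpoint); V̇E tracks V̇CO2 so the
#' ventilatory equivalent of O2 rises after the knee while that of CO2
#' does not.
#'
#' @param duration_s Ramp duration (s), default 600.
#' @param vo2_start,vo2_end V̇O2 at ramp onset and cessation (L/min).
#' @param get_vo2 Programmed knee position (L/min).
#' @param slope1,slope2 V-slope segment slopes below/above the knee.
#' @param noise Multiplicative noise SD applied to each channel
#'   (default 0, noiseless).
#' @param seed Integer RNG seed.
#' @return A list with `series` (tibble `t`, `vo2`, `vco2`, `ve`) and
#'   `truth` (programmed parameters).
#' @export
gen_ramp_recording <- function(duration_s = 600, vo2_start = 0.9,
                               vo2_end = 4.0, get_vo2 = 2.4,
                               slope1 = 0.9, slope2 = 1.3,
                               noise = 0, seed = 1L) {
  if (get_vo2 <= vo2_start || get_vo2 >= vo2_end) {
    abort("`get_vo2` must lie strictly between `vo2_start` and `vo2_end`.")
  }
  withr::with_seed(seed, {
    t <- seq(0, duration_s - 1)
    vo2 <- vo2_start + (vo2_end - vo2_start) * t / (duration_s - 1)
    vco2 <- slope1 * vo2 + pmax(vo2 - get_vo2, 0) * (slope2 - slope1)
    # ventilation proportional to VCO2 keeps VE/VCO2 flat while VE/VO2
    # rises beyond the knee
    ve <- 25 * vco2
    if (noise > 0) {
      vo2 <- vo2 * (1 + rnorm(length(t), 0, noise))
      vco2 <- vco2 * (1 + rnorm(length(t), 0, noise))
      ve <- ve * (1 + rnorm(length(t), 0, noise))
    }
    series <- tibble(t = t, vo2 = vo2, vco2 = vco2, ve = ve)
  })
  list(
    series = series,
    truth = list(
      family = "ramp", seed = seed,
      params = list(
        duration_s = duration_s, vo2_start = vo2_start, vo2_end = vo2_end,
        get_vo2 = get_vo2, slope1 = slope1, slope2 = slope2
      ),
      noise = list(multiplicative_sd = noise)
    )
  )
}

#' Synthetic 5-min all-out torque test
#'
#' Generates a 100-Hz torque trace of the 60 x (3 s contraction + 2 s
#' rest) all-out protocol. The expected mean torque of cycle k decays
#' from `t0` towards the critical torque `ct` as
#' `ct + (t0 - ct) exp(-X_k / tau_f)` with `X_k` the contraction-window
#' midpoint. Within each contraction the profile is a trapezoidal ramp
#' (`rise_s` rise and fall) whose plateau is scaled so that the mean over
#' the 3-s window equals the cycle's expected torque; rest intervals sit
#' at zero. White noise (SD `noise_sd`, default 3% of `t0`) is added to
#' the whole trace.
#'
#' @param t0 Initial all-out torque (N·m), > `ct`; the default end-test
#'   plateau sits at ~44% of the starting torque, the fatigue depth
#'   typical of the 5-min all-out protocol.
#' @param ct Critical torque (N·m), > 0.
#' @param tau_f Fatigue time constant (s), typically 30–90.
#' @param noise_sd Additive noise SD (N·m), default `0.03 * t0`.
#' @param fs Sampling frequency (Hz), default 100.
#' @param n_cycles,cycle_s,contraction_s Protocol schedule (60, 5 s, 3 s).
#' @param rise_s Ramp rise/fall time within a contraction (s).
#' @param seed Integer RNG seed.
#' @return A list with `trace` (tibble `t`, `torque`) and `truth`
#'   (parameters, per-cycle expected mean torque `cycle_torque`, and the
#'   closed-form `total_impulse` of the noiseless profile).
#' @export
gen_torque_test <- function(t0 = 160, ct = 70, tau_f = 60,
                            noise_sd = 0.03 * t0, fs = 100,
                            n_cycles = 60L, cycle_s = 5, contraction_s = 3,
                            rise_s = 0.3, seed = 1L) {
  if (!(t0 > ct && ct > 0) || tau_f <= 0) {
    abort("Require t0 > ct > 0 and tau_f > 0.")
  }
  n <- n_cycles * cycle_s * fs
  t <- (seq_len(n) - 1) / fs
  x_mid <- (seq_len(n_cycles) - 1) * cycle_s + contraction_s / 2
  expected <- ct + (t0 - ct) * exp(-x_mid / tau_f)
  # plateau scaled so the window mean equals the expected per-cycle torque
  plateau <- expected * contraction_s / (contraction_s - rise_s)

  cyc_idx <- pmin(floor(t / cycle_s) + 1, n_cycles)
  u <- t - (cyc_idx - 1) * cycle_s
  shape <- ifelse(
    u < rise_s, u / rise_s,
    ifelse(
      u < contraction_s - rise_s, 1,
      ifelse(u < contraction_s, (contraction_s - u) / rise_s, 0)
    )
  )
  torque_clean <- plateau[cyc_idx] * shape
  withr::with_seed(seed, {
    torque <- torque_clean + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  })
  list(
    trace = tibble(t = t, torque = torque),
    truth = list(
      family = "torque", seed = seed,
      params = list(
        t0 = t0, ct = ct, tau_f = tau_f, fs = fs, n_cycles = n_cycles,
        cycle_s = cycle_s, contraction_s = contraction_s, rise_s = rise_s
      ),
      noise = list(sd = noise_sd),
      cycle_torque = expected,
      total_impulse = sum(plateau * (contraction_s - rise_s))
    )
  )
}

#' Synthetic NIRS trace paired with an all-out torque test
#'
#' Constructs a 10-Hz tissue-saturation / deoxyhaemoglobin trace such
#' that the per-cycle torque-%/oxygenation-% ratio series derived by the
#' analysis chain follows the exponential-decay critical-ratio model with
#' known parameters. Per-cycle oxygenation means are back-solved from the
#' target ratio series and the paired per-cycle torque percentages, then
#' placed across the contraction windows (linearly bridged across rests)
#' and overlaid with Gaussian noise. A 30-s resting baseline precedes the
#' test for the deoxyhaemoglobin zeroing.
#'
#' Percent-of-maximum normalization only identifies the ratio curve up to
#' a positive scale, so the requested `(r0, cr)` are rescaled once such
#' that the back-solved oxygenation series peaks at exactly 100%; the
#' effective parameters the analysis chain should recover are returned in
#' `truth` (`tau` is scale-invariant and unchanged).
#'
#' @param cycles Per-cycle table of the paired torque test with columns
#'   `cycle`, `t_on`, `t_off`, `mean_torque` (see [cycle_metrics()]).
#' @param r0_tsi,cr_tsi,tau_tsi Target ratio-decay parameters for the
#'   torque/TSI ratio (initial ratio, critical ratio, time constant s).
#' @param r0_hhb,cr_hhb,tau_hhb Same for the torque/deoxyhaemoglobin
#'   ratio.
#' @param tsi_max Absolute TSI (%) assigned to the 100% cycle.
#' @param tsi_rest Resting TSI (%) before the test.
#' @param hhb_base,hhb_amp Resting level and full-scale amplitude of the
#'   relative deoxyhaemoglobin signal (a.u.).
#' @param fs Sampling frequency (Hz), default 10.
#' @param noise_tsi Within-cycle Gaussian noise SD on TSI (percentage
#'   points, default 1).
#' @param noise_hhb Noise SD on deoxyhaemoglobin (a.u.).
#' @param seed Integer RNG seed.
#' @return A list with `nirs` (tibble `t`, `tsi`, `hhb`) spanning 30 s of
#'   rest plus the test, and `truth` carrying the effective
#'   (normalization-consistent) `r0`, `cr`, `tau`, `tau_half` per signal.
#' @export
gen_nirs_trace <- function(cycles,
                           r0_tsi = 1.05, cr_tsi = 0.45, tau_tsi = 79,
                           r0_hhb = 8, cr_hhb = 2.9, tau_hhb = 96,
                           tsi_max = 65, tsi_rest = 70,
                           hhb_base = 2, hhb_amp = 10,
                           fs = 10, noise_tsi = 1, noise_hhb = 0.15,
                           seed = 1L) {
  check_series(cycles, c("cycle", "t_on", "t_off", "mean_torque"))
  if (min(r0_tsi, cr_tsi, tau_tsi, r0_hhb, cr_hhb, tau_hhb) <= 0) {
    abort("Ratio parameters must be positive.")
  }
  t_pct <- normalize_percent_of_max(cycles$mean_torque)
  x_mid <- (cycles$t_on + cycles$t_off) / 2

  backsolve <- function(r0, cr, tau) {
    r <- ratio_decay_model(x_mid, cr, r0, tau)
    o <- t_pct / r
    s <- max(o) / 100 # one-shot rescale of (r0, cr) so max(o) = 100
    list(oxy_pct = o / s, r0 = r0 * s, cr = cr * s, tau = tau)
  }
  tsi_t <- backsolve(r0_tsi, cr_tsi, tau_tsi)
  hhb_t <- backsolve(r0_hhb, cr_hhb, tau_hhb)

  tsi_cycle <- tsi_t$oxy_pct * tsi_max / 100
  if (any(tsi_cycle <= 0 | tsi_cycle > 100)) {
    abort("Target ratios require TSI outside (0, 100]; adjust parameters.")
  }
  hhb_cycle <- hhb_base + hhb_t$oxy_pct * hhb_amp / 100

  t_end <- max(cycles$t_off) + 2
  t <- seq(-30, t_end, by = 1 / fs)
  fill_trace <- function(cycle_vals, rest_val) {
    # piecewise: constant at the cycle value inside each contraction,
    # linear bridges elsewhere
    knots_t <- c(-30, min(cycles$t_on) - 1)
    knots_v <- c(rest_val, rest_val)
    for (k in seq_len(nrow(cycles))) {
      knots_t <- c(knots_t, cycles$t_on[k], cycles$t_off[k])
      knots_v <- c(knots_v, cycle_vals[k], cycle_vals[k])
    }
    knots_t <- c(knots_t, t_end)
    knots_v <- c(knots_v, cycle_vals[nrow(cycles)])
    approx(knots_t, knots_v, xout = t, rule = 2)$y
  }
  withr::with_seed(seed, {
    tsi <- fill_trace(tsi_cycle, tsi_rest) + rnorm(length(t), 0, noise_tsi)
    hhb <- fill_trace(hhb_cycle, hhb_base) + rnorm(length(t), 0, noise_hhb)
  })
  list(
    nirs = tibble(t = t, tsi = pmin(pmax(tsi, 0), 100), hhb = hhb),
    truth = list(
      family = "nirs", seed = seed,
      params = list(
        tsi = list(
          r0 = tsi_t$r0, cr = tsi_t$cr, tau = tsi_t$tau,
          tau_half = tsi_t$tau * log(2)
        ),
        hhb = list(
          r0 = hhb_t$r0, cr = hhb_t$cr, tau = hhb_t$tau,
          tau_half = hhb_t$tau * log(2)
        ),
        tsi_max = tsi_max, tsi_rest = tsi_rest,
        hhb_base = hhb_base, hhb_amp = hhb_amp, fs = fs
      ),
      noise = list(tsi = noise_tsi, hhb = noise_hhb)
    )
  )
}

#' Synthetic flow-mediated dilation recording
#'
#' Generates a 1-s arterial diameter and velocity recording with 60 s of
#' baseline, a 5-min occlusion, and a post-deflation hyperaemic response:
#' the diameter rises along a log-normal-shaped pulse to `d_peak` exactly
#' `t_peak` seconds after cuff release and then relaxes; velocity shows a
#' hyperaemic surge decaying back to baseline.
#'
#' @param d_baseline Baseline diameter (mm).
#' @param d_peak Peak post-occlusion diameter (mm), >= `d_baseline`.
#' @param t_peak Time of peak after deflation (s), typically 20–120.
#' @param sigma Log-normal shape width (dimensionless), default 0.5.
#' @param v_base Baseline mean velocity (mm/s).
#' @param v_peak Peak hyperaemic velocity (mm/s).
#' @param v_tau Decay constant of the hyperaemic surge (s).
#' @param baseline_s,occlusion_s,post_s Phase durations (s).
#' @param noise_sd Gaussian diameter noise SD (mm), default 0.02.
#' @param noise_v Velocity noise SD (mm/s).
#' @param seed Integer RNG seed.
#' @return A list with `rec` (tibble `t`, `diameter`, `velocity`),
#'   `markers` (`baseline_start`, `inflation`, `deflation`) and `truth`.
#' @export
gen_fmd_recording <- function(d_baseline = 3.80, d_peak = 4.03, t_peak = 35,
                              sigma = 0.5, v_base = 100, v_peak = 700,
                              v_tau = 40, baseline_s = 60, occlusion_s = 300,
                              post_s = 240, noise_sd = 0.02, noise_v = 5,
                              seed = 1L) {
  if (d_baseline <= 0 || d_peak < d_baseline) {
    abort("Require d_peak >= d_baseline > 0.")
  }
  if (t_peak <= 0 || t_peak >= post_s) {
    abort("`t_peak` must lie inside the post-deflation window.")
  }
  markers <- list(
    baseline_start = 0, inflation = baseline_s,
    deflation = baseline_s + occlusion_s
  )
  t <- seq(0, baseline_s + occlusion_s + post_s - 1)
  u <- t - markers$deflation
  pulse <- ifelse(u > 0, exp(-(log(pmax(u, 1e-9) / t_peak))^2 / (2 * sigma^2)), 0)
  diameter <- ifelse(
    t < markers$inflation, d_baseline,
    ifelse(
      t < markers$deflation, d_baseline * 0.97,
      d_baseline + (d_peak - d_baseline) * pulse
    )
  )
  velocity <- ifelse(
    t < markers$inflation, v_base,
    ifelse(
      t < markers$deflation, 0,
      v_base + (v_peak - v_base) * exp(-pmax(u, 0) / v_tau)
    )
  )
  withr::with_seed(seed, {
    if (noise_sd > 0) diameter <- diameter + rnorm(length(t), 0, noise_sd)
    if (noise_v > 0) velocity <- velocity + rnorm(length(t), 0, noise_v)
  })
  list(
    rec = tibble(t = t, diameter = diameter, velocity = velocity),
    markers = markers,
    truth = list(
      family = "fmd", seed = seed,
      params = list(
        d_baseline = d_baseline, d_peak = d_peak, t_peak = t_peak,
        sigma = sigma, v_base = v_base, v_peak = v_peak, v_tau = v_tau,
        fmd_pct = 100 * (d_peak - d_baseline) / d_baseline
      ),
      noise = list(diameter = noise_sd, velocity = noise_v)
    )
  )
}
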