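#' Default pipeline configuration
#'
#' Collects every tunable stage parameter in one list, preset to the
#' standard protocol values: errant-breath screening at 3 SD over a
#' 5-breath window, a 20-s phase-I exclusion with a 240-s fitting window,
#' a 60-s unloaded baseline, 25 W/min ramp from 10 W, 60 x 5 s all-out
#' cycles with a 300-s Tlim, 10-s v-slope bins and 3-s FMD smoothing.
#'
#' @param ... Named overrides of any default.
#' @return A named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sd_mult = 3, window_breaths = 5L,
    t_load = 360, baseline_window = c(-60, 0), fit_window = c(20, 240),
    efficiency_window_s = 120, loaded_end = 300,
    ramp_rate = 25, start_power = 10, get_bin_s = 10L,
    n_cycles = 60L, cycle_s = 5, contraction_s = 3, tlim = 300,
    hhb_baseline_window = c(-30, 0),
    fmd_smoothing_s = 3, t_inflation = 60, t_deflation = 360
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Full oxygen-uptake on-kinetics chain for one visit
#'
#' Runs the complete breath-to-parameters chain on a set of square-wave
#' transitions: errant-breath removal, alignment to load onset, 1-s
#' interpolation, ensemble averaging, 5-s binning, unloaded baseline, and
#' the phase-II mono-exponential fit. Optionally computes gross
#' efficiency from the pooled cleaned breaths over the final 120 s of the
#' loaded phase.
#'
#' @param transitions List of recordings as produced by
#'   [gen_breath_transitions()] (each a list with `breaths`, `markers`,
#'   `load_w`), or bare breath data frames (then `t_load` supplies the
#'   load-onset marker).
#' @param t_load Load-onset time (s, recording clock) used for bare data
#'   frames; ignored when recordings carry markers.
#' @param load_w Power of the loaded phase (W) for gross efficiency;
#'   taken from the recordings when present, `NA` disables the
#'   efficiency step.
#' @param config List from [pipeline_config()].
#' @return A list: `fit` (a `vo2fit`), `vo2_base`, `ensemble` (1-s
#'   tibble), `binned` (5-s tibble), `n_removed` (errant breaths per
#'   transition), and `efficiency` (one-row tibble or `NULL`).
#' @export
analyze_kinetics <- function(transitions, t_load = NULL, load_w = NA_real_,
                             config = pipeline_config()) {
  if (!is.list(transitions) || length(transitions) == 0L) {
    abort("`transitions` must be a non-empty list.")
  }
  recs <- purrr::map(transitions, function(tr) {
    if (is.data.frame(tr)) {
      if (is.null(t_load)) {
        abort("`t_load` is required when transitions are bare data frames.")
      }
      list(breaths = tr, t_load = t_load, load_w = load_w)
    } else {
      list(
        breaths = tr$breaths,
        t_load = unname(tr$markers[["load"]]),
        load_w = tr$load_w %||% load_w
      )
    }
  })

  screened <- purrr::map(recs, ~ remove_errant_breaths(.x$breaths,
    window_breaths = config$window_breaths, sd_mult = config$sd_mult
  ))
  n_removed <- purrr::map_int(screened, ~ length(attr(.x, "removed")))
  cleaned <- purrr::map2(screened, recs, ~ align_to_onset(.x, .y$t_load))

  ensemble <- ensemble_average(purrr::map(cleaned, interpolate_1s))
  binned <- bin_5s(ensemble)
  vo2_base <- compute_baseline(ensemble, config$baseline_window)
  fit <- fit_vo2_kinetics(binned, vo2_base, config$fit_window)

  power <- recs[[1]]$load_w
  efficiency <- NULL
  if (is.finite(power)) {
    pooled <- bind_rows(cleaned)
    ss <- steady_state_window(
      filter(pooled, .data$t <= config$loaded_end),
      t_end = config$loaded_end, window_s = config$efficiency_window_s
    )
    efficiency <- gross_efficiency(power, ss$vo2_ss / 1000, ss$rer_ss)
  }

  list(
    fit = fit, vo2_base = vo2_base, ensemble = ensemble, binned = binned,
    n_removed = n_removed, efficiency = efficiency
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline over a file manifest
#'
#' Maps files to subjects, timepoints and tests, dispatches each test to
#' its analysis module, and gathers every derived parameter into one tidy
#' long table. A file that fails to read or analyse produces an error
#' record and the pipeline continues; NIRS tests require the same
#' subject/timepoint to also carry a torque test (for the shared cycle
#' schedule).
#'
#' Manifest columns: `subject`, `timepoint`, `test`
#' (`"kinetics"`, `"ramp"`, `"ct"`, `"nirs"`, `"fmd"`), `path`. Optional
#' columns supply per-row metadata: `load_w` (kinetics), `power_at_cessation`
#' (ramp), `t_inflation`/`t_deflation` (fmd). Kinetics transitions span
#' multiple rows (one file per bout).
#'
#' @param manifest Data frame as described above; zero rows are allowed
#'   (returns empty tables with a warning).
#' @param config List from [pipeline_config()].
#' @return A list with `results` (tibble `subject`, `timepoint`, `test`,
#'   `parameter`, `value`), and `errors` (tibble `subject`, `timepoint`,
#'   `test`, `message`).
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  if (nrow(manifest) == 0L) {
    warn("Empty manifest; nothing to analyse.")
    return(list(
      results = tibble(
        subject = character(), timepoint = character(), test = character(),
        parameter = character(), value = numeric()
      ),
      errors = tibble(
        subject = character(), timepoint = character(), test = character(),
        message = character()
      )
    ))
  }
  check_series(manifest, c("subject", "timepoint", "test", "path"))

  groups <- manifest %>%
    group_by(.data$subject, .data$timepoint, .data$test) %>%
    tidyr::nest() %>%
    ungroup()

  results <- list()
  errors <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    rows <- g$data[[1]]
    res <- tryCatch(
      analyze_manifest_entry(
        g$test, rows, config,
        manifest = manifest, subject = g$subject, timepoint = g$timepoint
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble(
        subject = g$subject, timepoint = g$timepoint, test = g$test,
        message = conditionMessage(res)
      )
    } else {
      results[[length(results) + 1L]] <- mutate(res,
        subject = g$subject, timepoint = g$timepoint, test = g$test,
        .before = 1
      )
    }
  }
  list(
    results = bind_rows(results),
    errors = bind_rows(errors)
  )
}

analyze_manifest_entry <- function(test, rows, config, manifest, subject,
                                   timepoint) {
  as_long <- function(...) {
    vals <- c(...)
    tibble(parameter = names(vals), value = unname(vals))
  }
  switch(test,
    kinetics = {
      transitions <- purrr::map(rows$path, read_breath_file)
      load_w <- if ("load_w" %in% names(rows)) rows$load_w[1] else NA_real_
      k <- analyze_kinetics(transitions,
        t_load = config$t_load,
        load_w = load_w, config = config
      )
      out <- as_long(
        vo2_base = k$fit$vo2_base, vo2_amp = k$fit$vo2_amp,
        td = k$fit$td, tau = k$fit$tau
      )
      if (!is.null(k$efficiency)) {
        out <- bind_rows(out, as_long(
          gross_efficiency_pct = k$efficiency$gross_efficiency_pct
        ))
      }
      out
    },
    ramp = {
      br <- read_breath_file(rows$path[1])
      series <- interp_channels(br, c("vo2", "vco2", "ve"))
      pc <- if ("power_at_cessation" %in% names(rows)) {
        rows$power_at_cessation[1]
      } else {
        abort("Ramp rows need a `power_at_cessation` column.")
      }
      r <- analyze_ramp(series, pc,
        ramp_rate = config$ramp_rate,
        start_power = config$start_power, bin_s = config$get_bin_s
      )
      as_long(
        vo2peak = r$vo2peak, ppo = r$ppo, get_vo2 = r$get_vo2,
        get_pct = r$get_pct, get_power = r$get_power
      )
    },
    ct = {
      trace <- read_torque_file(rows$path[1])
      r <- analyze_ct(trace,
        n_cycles = config$n_cycles, cycle_s = config$cycle_s,
        contraction_s = config$contraction_s, tlim = config$tlim
      )
      as_long(
        mvc_test = r$mvc_test, ct = r$ct,
        total_impulse = r$total_impulse, i_prime = r$i_prime
      )
    },
    nirs = {
      ct_rows <- filter(
        manifest, .data$subject == !!subject,
        .data$timepoint == !!timepoint, .data$test == "ct"
      )
      if (nrow(ct_rows) == 0L) {
        abort("NIRS analysis needs a paired `ct` test for the cycle schedule.")
      }
      trace <- read_torque_file(ct_rows$path[1])
      cycles <- cycle_metrics(trace, segment_cycles(
        trace,
        n_cycles = config$n_cycles, cycle_s = config$cycle_s,
        contraction_s = config$contraction_s
      ))
      nirs <- read_nirs_file(rows$path[1])
      r <- analyze_oxygenation(nirs, cycles, config$hhb_baseline_window)
      as_long(
        cr_tsi = r$tsi$cr, tau_half_tsi = r$tsi$tau_half,
        cr_hhb = r$hhb$cr, tau_half_hhb = r$hhb$tau_half
      )
    },
    fmd = {
      rec <- read_fmd_file(rows$path[1])
      markers <- list(
        inflation = if ("t_inflation" %in% names(rows)) {
          rows$t_inflation[1]
        } else {
          config$t_inflation
        },
        deflation = if ("t_deflation" %in% names(rows)) {
          rows$t_deflation[1]
        } else {
          config$t_deflation
        }
      )
      r <- analyze_fmd(rec, markers, config$fmd_smoothing_s)
      as_long(
        d_baseline = r$d_baseline, d_max = r$d_max,
        t_to_max = r$t_to_max, fmd_pct = r$fmd_pct, sr_auc = r$sr_auc
      )
    },
    abort(sprintf("Unknown test type '%s'.", test))
  )
}

interp_channels <- function(breaths, channels) {
  t_grid <- seq(ceiling(min(breaths$t)), floor(max(breaths$t)), by = 1)
  out <- tibble(t = t_grid)
  for (ch in channels) {
    out[[ch]] <- approx(breaths$t, breaths[[ch]], xout = t_grid)$y
  }
  out
}

#' Descriptive group-by-timepoint summaries and within-subject deltas
#'
#' Companion to [run_pipeline()]: per-parameter mean and SD for every
#' group and timepoint, and within-subject changes from the first
#' timepoint (e.g. MID − PRE, POST − PRE) averaged by group. Purely
#' descriptive — no inferential statistics are computed; the long table
#' is structured for external statistics tools.
#'
#' @param results Long results tibble from [run_pipeline()] (`subject`,
#'   `timepoint`, `parameter`, `value`).
#' @param groups Data frame mapping `subject` to `group`.
#' @param ref_timepoint Baseline timepoint label, default `"PRE"`.
#' @return A list with `by_timepoint` (group x timepoint x parameter mean,
#'   sd, n) and `deltas` (group x timepoint x parameter mean and sd of
#'   within-subject change from `ref_timepoint`).
#' @export
group_change_table <- function(results, groups, ref_timepoint = "PRE") {
  check_series(results, c("subject", "timepoint", "parameter", "value"))
  check_series(groups, c("subject", "group"))
  dat <- left_join(results, groups, by = "subject")

  by_timepoint <- dat %>%
    group_by(.data$group, .data$timepoint, .data$parameter) %>%
    summarise(
      mean = mean(.data$value), sd = sd(.data$value), n = n(),
      .groups = "drop"
    )

  ref <- dat %>%
    filter(.data$timepoint == ref_timepoint) %>%
    dplyr::select("subject", "parameter", ref_value = "value")
  deltas <- dat %>%
    filter(.data$timepoint != ref_timepoint) %>%
    left_join(ref, by = c("subject", "parameter")) %>%
    mutate(delta = .data$value - .data$ref_value) %>%
    group_by(.data$group, .data$timepoint, .data$parameter) %>%
    summarise(
      mean_delta = mean(.data$delta), sd_delta = sd(.data$delta), n = n(),
      .groups = "drop"
    )

  list(by_timepoint = by_timepoint, deltas = deltas)
}
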