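#' Remove errant breaths from a breath-by-breath series
#'
#' Screens a breath-by-breath oxygen-uptake series for errant breaths
#' (coughs, swallows, sighs) by comparing each breath against its local
#' neighbourhood: a breath is removed when its V̇O2 deviates from the mean
#' of the surrounding breaths by strictly more than `sd_mult` local
#' standard deviations. The filter makes a single pass over the original
#' series — survivors are never re-filtered — so it is idempotent on clean
#' data.
#'
#' The local neighbourhood is a centred window of `window_breaths` breaths
#' that excludes the candidate breath itself; at the ends of the series the
#' window is truncated to the available neighbours. A breath lying exactly
#' at `sd_mult` standard deviations is retained (strict inequality), and a
#' breath whose neighbourhood has zero spread is always retained.
#'
#' @param breaths Data frame with columns `t` (s, strictly increasing) and
#'   `vo2` (mL/min). Additional columns (`vco2`, `ve`, `rer`, ...) are
#'   carried through untouched; only `vo2` is screened.
#' @param window_breaths Odd integer, width of the centred window
#'   (including the candidate breath position). Default 5, i.e. two
#'   neighbours on each side.
#' @param sd_mult Positive multiplier on the local standard deviation.
#'   Default 3.
#'
#' @return A tibble of retained breaths with attributes:
#'   * `removed`: integer indices (into the input) of removed breaths;
#'   * `short_series`: `TRUE` when the series was shorter than
#'     `window_breaths` and returned unchanged (with a warning).
#' @seealso [interpolate_1s()], [ensemble_average()], [bin_5s()]
#' @export
#' @examples
#' b <- tibble::tibble(t = 1:20 * 2.5, vo2 = c(rep(1000, 10), 2000, rep(1000, 9)))
#' cleaned <- remove_errant_breaths(b)
#' attr(cleaned, "removed")
remove_errant_breaths <- function(breaths, window_breaths = 5L, sd_mult = 3) {
  check_series(breaths, c("t", "vo2"))
  if (window_breaths < 3L || window_breaths %% 2L == 0L) {
    abort("`window_breaths` must be an odd integer >= 3.")
  }
  if (sd_mult <= 0) {
    abort("`sd_mult` must be positive.")
  }
  if (is.unsorted(breaths$t, strictly = TRUE)) {
    abort("`breaths$t` must be strictly increasing.")
  }

  out <- as_tibble(breaths)
  n <- nrow(out)
  if (n < window_breaths) {
    warn("Series shorter than `window_breaths`; returned unchanged.")
    attr(out, "removed") <- integer(0)
    attr(out, "short_series") <- TRUE
    return(out)
  }

  half <- window_breaths %/% 2L
  vo2 <- out$vo2
  errant <- vapply(seq_len(n), function(i) {
    idx <- setdiff(max(1L, i - half):min(n, i + half), i)
    m <- mean(vo2[idx])
    s <- sd(vo2[idx])
    if (!is.finite(s) || s == 0) {
      return(FALSE)
    }
    # strict inequality with a relative guard so a breath sitting exactly
    # on the boundary is retained despite floating-point rounding
    abs(vo2[i] - m) > sd_mult * s * (1 + 1e-9)
  }, logical(1))

  res <- out[!errant, , drop = FALSE]
  attr(res, "removed") <- which(errant)
  attr(res, "short_series") <- FALSE
  res
}

#' Linearly interpolate breaths onto a 1-s grid
#'
#' Interpolates the V̇O2 channel of an (irregular) breath-stamped series
#' onto integer seconds spanning `[ceiling(first t), floor(last t)]`.
#' No extrapolation is performed beyond the observed breaths.
#'
#' @param breaths Data frame with columns `t` (s, strictly increasing) and
#'   `vo2` (mL/min); at least 2 rows.
#' @return A tibble with columns `t` (integer seconds) and `vo2`.
#' @export
interpolate_1s <- function(breaths) {
  check_series(breaths, c("t", "vo2"))
  if (nrow(breaths) < 2L) {
    abort("Need at least 2 breaths to interpolate.")
  }
  if (is.unsorted(breaths$t, strictly = TRUE)) {
    abort("`breaths$t` must be strictly increasing.")
  }
  t_grid <- seq(ceiling(min(breaths$t)), floor(max(breaths$t)), by = 1)
  if (length(t_grid) < 1L) {
    abort("Breath series spans less than one integer second.")
  }
  y <- approx(breaths$t, breaths$vo2, xout = t_grid, method = "linear")$y
  tibble(t = t_grid, vo2 = y)
}

#' Ensemble-average time-aligned transitions
#'
#' Averages several 1-s interpolated rest-to-exercise transitions, each
#' expressed in transition-local time (zero at load onset), second by
#' second over the time range common to all transitions, producing the
#' single V̇O2 response used for kinetics modelling.
#'
#' @param transitions List of data frames, each with columns `t`
#'   (1-s grid, transition-local seconds) and `vo2`.
#' @return A tibble with columns `t` and `vo2` on the intersection of the
#'   input time ranges.
#' @export
ensemble_average <- function(transitions) {
  if (!is.list(transitions) || length(transitions) == 0L) {
    abort("`transitions` must be a non-empty list of series.")
  }
  purrr::walk(transitions, check_series, cols = c("t", "vo2"))
  t_lo <- max(purrr::map_dbl(transitions, ~ min(.x$t)))
  t_hi <- min(purrr::map_dbl(transitions, ~ max(.x$t)))
  if (t_lo > t_hi) {
    abort("Transitions have disjoint time ranges; nothing to average.")
  }
  t_grid <- seq(t_lo, t_hi, by = 1)
  vals <- purrr::map(transitions, function(tr) {
    idx <- match(t_grid, tr$t)
    if (anyNA(idx)) {
      abort("All transitions must be on a common 1-s grid.")
    }
    tr$vo2[idx]
  })
  tibble(t = t_grid, vo2 = rowMeans(do.call(cbind, vals)))
}

#' Average a 1-s series into 5-s bins
#'
#' Collapses consecutive, non-overlapping blocks of `width` 1-s samples
#' into their arithmetic mean. The bin timestamp is the bin midpoint
#' (mean of the member timestamps), which keeps the time-sensitive
#' kinetics fit free of binning-induced delay bias. A trailing partial bin
#' is dropped.
#'
#' @param series Data frame with columns `t` (1-s spacing) and `vo2`.
#' @param width Samples per bin (default 5).
#' @return A tibble with columns `t` (bin midpoints) and `vo2` (bin means).
#' @export
bin_5s <- function(series, width = 5L) {
  check_series(series, c("t", "vo2"))
  if (nrow(series) < width) {
    abort(sprintf("Need at least %d samples to form one bin.", width))
  }
  dt <- diff(series$t)
  if (any(abs(dt - 1) > 1e-8)) {
    abort("`series` must be on a 1-s grid; run interpolate_1s() first.")
  }
  n_bins <- nrow(series) %/% width
  keep <- seq_len(n_bins * width)
  grp <- rep(seq_len(n_bins), each = width)
  series[keep, ] %>%
    mutate(.bin = grp) %>%
    group_by(.data$.bin) %>%
    summarise(t = mean(.data$t), vo2 = mean(.data$vo2), .groups = "drop") %>%
    dplyr::select("t", "vo2")
}

#' Shift a recording to transition-local time
#'
#' Re-expresses breath timestamps relative to the load-onset marker so that
#' `t = 0` is the unloaded-to-loaded transition, the time origin used by
#' all downstream kinetics functions.
#'
#' @param breaths Data frame with a `t` column (recording seconds).
#' @param t_load Load-onset marker (s, recording clock).
#' @return The input with `t` shifted by `-t_load`.
#' @export
align_to_onset <- function(breaths, t_load) {
  check_series(breaths, "t")
  mutate(as_tibble(breaths), t = .data$t - t_load)
}
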