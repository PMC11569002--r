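# Independent brute-force oracles used to freeze expected values.

# errant-breath screen: direct loop over every breath, recomputing the
# local mean/SD from the +/- half window excluding the candidate
oracle_errant <- function(vo2, window = 5L, sd_mult = 3) {
  n <- length(vo2)
  half <- window %/% 2L
  which(vapply(seq_len(n), function(i) {
    idx <- setdiff(max(1L, i - half):min(n, i + half), i)
    m <- mean(vo2[idx])
    s <- stats::sd(vo2[idx])
    is.finite(s) && s > 0 && abs(vo2[i] - m) > sd_mult * s
  }, logical(1)))
}

# exhaustive two-segment breakpoint search over every candidate knot,
# written independently of the package's scan
oracle_breakpoint <- function(vo2, vco2) {
  cands <- sort(unique(vo2))
  cands <- cands[cands > stats::quantile(vo2, 0.05) & cands < stats::quantile(vo2, 0.95)]
  best <- NULL
  for (c0 in cands) {
    lo <- vo2 <= c0
    hi <- !lo
    if (sum(lo) < 3 || sum(hi) < 3) next
    f <- stats::lm(vco2 ~ vo2 + pmax(vo2 - c0, 0))
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(knot = c0, rss = rss)
  }
  best$knot
}

# simple synthetic transition tibble on an arbitrary time base
breath_tbl <- function(t, vo2) tibble::tibble(t = t, vo2 = vo2)
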