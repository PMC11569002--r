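#' Read a delimited breath-by-breath export
#'
#' Reads a metabolic-cart export with a header row, renames columns via
#' `cols`, and parses the time column either as seconds or as
#' `hh:mm:ss(.sss)` clock time (converted to seconds since the first
#' breath offset from midnight). RER is derived as V̇CO2/V̇O2 when the
#' export lacks it.
#'
#' @param path File path (CSV/TSV autodetected by [readr::read_delim()]).
#' @param cols Named character vector mapping package names (`t`, `vo2`,
#'   `vco2`, `ve`, `rer`) to the file's column names; `rer` optional.
#' @param delim Field delimiter; `NULL` (default) autodetects.
#' @return A tibble with columns `t`, `vo2`, `vco2`, `ve`, `rer`.
#' @export
read_breath_file <- function(path,
                             cols = c(
                               t = "t", vo2 = "vo2", vco2 = "vco2",
                               ve = "ve", rer = "rer"
                             ),
                             delim = NULL) {
  raw <- read_any_delim(path, delim)
  need <- c("t", "vo2", "vco2", "ve")
  out <- rename_mapped(raw, cols, need)
  if (!"rer" %in% names(out)) {
    out$rer <- out$vco2 / out$vo2
  }
  arrange(out, .data$t)
}

#' Read a dynamometer torque export
#'
#' @param path File path.
#' @param cols Named mapping for `t` and `torque`.
#' @param delim Field delimiter; `NULL` autodetects.
#' @return A tibble with columns `t` (s) and `torque` (N·m).
#' @export
read_torque_file <- function(path, cols = c(t = "t", torque = "torque"),
                             delim = NULL) {
  rename_mapped(read_any_delim(path, delim), cols, c("t", "torque")) %>%
    arrange(.data$t)
}

#' Read a continuous-wave NIRS export
#'
#' @param path File path.
#' @param cols Named mapping for `t`, `tsi`, `hhb` and optionally `o2hb`.
#' @param delim Field delimiter; `NULL` autodetects.
#' @return A tibble with columns `t`, `tsi`, `hhb` (and `o2hb` if mapped).
#' @export
read_nirs_file <- function(path,
                           cols = c(t = "t", tsi = "tsi", hhb = "hhb"),
                           delim = NULL) {
  rename_mapped(read_any_delim(path, delim), cols, c("t", "tsi", "hhb")) %>%
    arrange(.data$t)
}

#' Read an edge-detection FMD export
#'
#' @param path File path.
#' @param cols Named mapping for `t`, `diameter`, `velocity`.
#' @param delim Field delimiter; `NULL` autodetects.
#' @return A tibble with columns `t` (s), `diameter` (mm), `velocity`
#'   (mm/s).
#' @export
read_fmd_file <- function(path,
                          cols = c(t = "t", diameter = "diameter", velocity = "velocity"),
                          delim = NULL) {
  rename_mapped(read_any_delim(path, delim), cols, c("t", "diameter", "velocity")) %>%
    arrange(.data$t)
}

# columns come in as character so clock-time stamps (including
# fractional seconds, which readr's time guesser truncates) survive
# until parse_time_s(); numeric coercion happens after renaming
read_any_delim <- function(path, delim = NULL) {
  if (is.null(delim)) {
    readr::read_delim(path,
      show_col_types = FALSE, progress = FALSE,
      trim_ws = TRUE, col_types = readr::cols(.default = "c")
    )
  } else {
    readr::read_delim(path,
      delim = delim, show_col_types = FALSE,
      progress = FALSE, trim_ws = TRUE,
      col_types = readr::cols(.default = "c")
    )
  }
}

rename_mapped <- function(df, cols, need) {
  missing_map <- setdiff(need, names(cols))
  if (length(missing_map) > 0) {
    abort(sprintf("`cols` must map: %s.", paste(missing_map, collapse = ", ")))
  }
  present <- cols[cols %in% names(df)]
  missing_file <- setdiff(unname(cols[need]), names(df))
  if (length(missing_file) > 0) {
    abort(sprintf(
      "File lacks mapped column(s): %s.",
      paste(missing_file, collapse = ", ")
    ))
  }
  out <- df[unname(present)]
  names(out) <- names(present)
  out <- as_tibble(out)
  for (nm in setdiff(names(out), "t")) {
    out[[nm]] <- suppressWarnings(as.numeric(out[[nm]]))
  }
  out$t <- parse_time_s(out$t)
  out
}

# seconds, or hh:mm:ss(.sss) clock strings, to numeric seconds
parse_time_s <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x <- as.character(x)
  if (all(grepl("^\\d{1,2}:\\d{2}(:\\d{2}(\\.\\d+)?)?$", x))) {
    purrr::map_dbl(strsplit(x, ":"), function(p) {
      p <- as.numeric(p)
      if (length(p) == 2) p <- c(0, p)
      p[1] * 3600 + p[2] * 60 + p[3]
    })
  } else {
    suppressWarnings(as.numeric(x))
  }
}
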