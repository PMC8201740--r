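#' Sociability index (interaction ratio)
#'
#' The sociability index (SI) of a mouse is the time it spends in the
#' interaction zone with a social target present divided by the time spent
#' there with the target absent. SI > 1 indicates social preference, SI < 1
#' social avoidance.
#'
#' @param time_with_target,time_no_target Zone times in seconds, >= 0.
#'   Vectorized.
#' @return Numeric SI ratio(s).
#' @examples
#' compute_si(75, 50)   # 1.5
#' compute_si(25, 50)   # 0.5, social avoidance
#' @export
compute_si <- function(time_with_target, time_no_target) {
  if (any(time_with_target < 0, na.rm = TRUE) ||
      any(time_no_target < 0, na.rm = TRUE))
    stopf("zone times must be non-negative")
  if (any(time_no_target == 0, na.rm = TRUE))
    stopf("undefined sociability index: time without target is zero")
  time_with_target / time_no_target
}

#' Classify a mouse into a stress cohort from its sociability index
#'
#' Non-stressed mice are controls. Stressed mice with SI above the exclusion
#' band are resilient, below it susceptible; mice inside the band (default
#' closed interval \[0.9, 1.1\]) have ambiguous susceptible/resilient traits
#' and are excluded from cohorts.
#'
#' @param si Sociability index, >= 0. Vectorized.
#' @param stressed Logical: did the mouse undergo the defeat paradigm?
#' @param band Length-2 exclusion band; values equal to an endpoint are
#'   excluded (closed band).
#' @return Character vector over \code{"control"}, \code{"resilient"},
#'   \code{"susceptible"}, \code{"excluded"}.
#' @examples
#' classify_mouse(c(1.61, 0.5, 1.0), stressed = TRUE)
#' @export
classify_mouse <- function(si, stressed, band = c(0.9, 1.1)) {
  if (length(band) != 2L || band[1] > band[2])
    stopf("invalid exclusion band: lower bound exceeds upper bound")
  if (any(si < 0, na.rm = TRUE)) stopf("sociability index must be >= 0")
  n <- max(length(si), length(stressed))
  si <- rep_len(si, n); stressed <- rep_len(stressed, n)
  out <- rep("control", n)
  out[stressed & si > band[2]] <- "resilient"
  out[stressed & si < band[1]] <- "susceptible"
  out[stressed & si >= band[1] & si <= band[2]] <- "excluded"
  out
}

#' Sucrose preference
#'
#' Anhedonia readout: sucrose intake as a percentage of total fluid intake,
#' \code{100 * sucrose / (sucrose + water)}.
#'
#' @param sucrose_intake,water_intake Intakes (g or mL), >= 0, not both zero.
#'   Vectorized.
#' @return Preference in percent, in \[0, 100\].
#' @export
sucrose_preference <- function(sucrose_intake, water_intake) {
  if (any(sucrose_intake < 0, na.rm = TRUE) ||
      any(water_intake < 0, na.rm = TRUE))
    stopf("intakes must be non-negative")
  total <- sucrose_intake + water_intake
  if (any(total == 0, na.rm = TRUE))
    stopf("undefined sucrose preference: total intake is zero")
  100 * sucrose_intake / total
}

#' Forced-swim immobility metrics
#'
#' From a mouse's immobility intervals in a forced swim assay, computes the
#' latency to first immobility (onset, measured from the start of the assay)
#' and the total immobility duration inside the scored window — by default the
#' last 4 min of a 6 min assay.
#'
#' @param intervals Two-column matrix (or data.frame, or list of length-2
#'   vectors) of immobility (start, end) times in seconds, sorted, within the
#'   assay, non-overlapping.
#' @param assay_duration Assay length in seconds (default 360).
#' @param window_start Start of the scored window in seconds (default 120,
#'   i.e. the last 240 s).
#' @return list with \code{latency} (seconds; \code{NA} if the mouse was never
#'   immobile) and \code{duration} (seconds of immobility inside the window).
#' @examples
#' immobility_metrics(rbind(c(200, 360)))  # latency 200, duration 160
#' @export
immobility_metrics <- function(intervals, assay_duration = 360,
                               window_start = 120) {
  if (window_start >= assay_duration)
    stopf("window_start must precede the end of the assay")
  iv <- normalize_intervals(intervals)
  if (nrow(iv) == 0L) return(list(latency = NA_real_, duration = 0))
  if (any(iv[, 1] < 0) || any(iv[, 2] > assay_duration))
    stopf("immobility intervals must lie within [0, assay_duration]")
  if (any(iv[, 2] < iv[, 1])) stopf("interval end precedes its start")
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2]))
    stopf("overlapping immobility intervals")
  overlap <- pmax(0, pmin(iv[, 2], assay_duration) -
                       pmax(iv[, 1], window_start))
  list(latency = iv[1, 1], duration = sum(overlap))
}

normalize_intervals <- function(intervals) {
  if (is.null(intervals) || length(intervals) == 0L)
    return(matrix(numeric(0), 0, 2))
  if (is.list(intervals) && !is.data.frame(intervals))
    intervals <- do.call(rbind, intervals)
  iv <- as.matrix(intervals)
  if (ncol(iv) != 2L) stopf("intervals must have two columns (start, end)")
  storage.mode(iv) <- "double"
  iv
}

#' Read / write behavior tables
#'
#' CSV with columns \code{mouse_id, group, time_no_target_s, time_target_s,
#' sucrose, water, immobility} where \code{immobility} holds
#' semicolon-separated \code{start-end} second pairs (may be empty). Reading
#' recomputes \code{si} and \code{cohort_label} with [compute_si()] and
#' [classify_mouse()].
#'
#' @param path File path.
#' @param band Exclusion band passed to [classify_mouse()].
#' @return \code{read_behavior_csv}: data.frame with a list-column
#'   \code{immobility_intervals} of two-column matrices.
#' @export
read_behavior_csv <- function(path, band = c(0.9, 1.1)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "group", "time_no_target_s", "time_target_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("behavior CSV lacks column(s): %s", paste(missing, collapse = ", "))
  df$si <- compute_si(df$time_target_s, df$time_no_target_s)
  df$cohort_label <- classify_mouse(df$si, df$group != "control", band)
  if ("immobility" %in% names(df)) {
    df$immobility_intervals <- lapply(df$immobility, parse_intervals)
    df$immobility <- NULL
  }
  df
}

parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(matrix(numeric(0), 0, 2))
  parts <- strsplit(trimws(strsplit(s, ";", fixed = TRUE)[[1]]), "-",
                    fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stopf("malformed immobility interval: '%s'", s)
  iv <- t(vapply(parts, as.numeric, numeric(2)))
  colnames(iv) <- c("start", "end")
  iv
}

#' @rdname read_behavior_csv
#' @param df Behavior data.frame, e.g. from [simulate_behavior_cohort()] or
#'   [read_behavior_csv()].
#' @export
write_behavior_csv <- function(df, path) {
  out <- df
  if ("immobility_intervals" %in% names(out)) {
    out$immobility <- vapply(out$immobility_intervals, function(iv) {
      if (nrow(iv) == 0L) return("")
      paste(sprintf("%g-%g", iv[, 1], iv[, 2]), collapse = ";")
    }, character(1))
    out$immobility_intervals <- NULL
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
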