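#' Segment a recording into cardiac cycles
#'
#' Summarises one velocity channel per inter-onset interval: `mean_v` is
#' the time-average of the channel on `[onset_i, onset_(i+1))` and
#' `peak_v` its maximum on that interval.
#'
#' @param rec A `cvr_recording`.
#' @param hemisphere `"stroke_affected"` or `"non_affected"`.
#' @return An object of class `cycle_series`: a data frame with one row
#'   per cycle and columns `onset` (s), `rr` (s), `mean_v`, `peak_v`
#'   (cm/s).
#' @export
extract_cycles <- function(rec, hemisphere = c("stroke_affected",
                                               "non_affected")) {
  hemisphere <- match.arg(hemisphere)
  onsets <- attr(rec, "beat_onsets")
  if (is.null(onsets) || length(onsets) < 2) {
    stop("need at least 2 beat onsets to form a cycle")
  }
  col <- if (hemisphere == "stroke_affected") "mcav_affected" else "mcav_nonaffected"
  v <- rec[[col]]
  t <- rec$time_s
  # assign each sample to the cycle whose [onset_i, onset_{i+1}) contains it
  cyc <- findInterval(t, onsets)
  keep <- cyc >= 1 & cyc < length(onsets)
  cyc <- cyc[keep]; v <- v[keep]
  mean_v <- as.numeric(rowsum(v, cyc)) / tabulate(cyc, length(onsets) - 1L)[sort(unique(cyc))]
  # cycles can be empty when an injected RR is shorter than one sample
  present <- sort(unique(cyc))
  means <- rep(NA_real_, length(onsets) - 1L)
  peaks <- rep(NA_real_, length(onsets) - 1L)
  means[present] <- mean_v
  peaks[present] <- as.numeric(tapply(v, cyc, max))
  out <- data.frame(onset = onsets[-length(onsets)],
                    rr = diff(onsets),
                    mean_v = means,
                    peak_v = peaks)
  # an empty cycle inherits its neighbour's summaries so downstream rules
  # still see one entry per interval
  if (anyNA(out$mean_v)) {
    filled <- stats::approx(which(!is.na(out$mean_v)),
                            out$mean_v[!is.na(out$mean_v)],
                            xout = seq_len(nrow(out)), rule = 2)$y
    out$mean_v[is.na(out$mean_v)] <- filled[is.na(out$mean_v)]
    filledp <- stats::approx(which(!is.na(out$peak_v)),
                             out$peak_v[!is.na(out$peak_v)],
                             xout = seq_len(nrow(out)), rule = 2)$y
    out$peak_v[is.na(out$peak_v)] <- filledp[is.na(out$peak_v)]
  }
  structure(out, class = c("cycle_series", "data.frame"))
}

#' Censor artifact cardiac cycles
#'
#' Flags cycles whose instantaneous cardiac frequency `1/rr` exceeds
#' `rate_max_hz`, or whose peak velocity changes by more than `jump_max`
#' from the most recent accepted (non-censored) cycle's peak. Referencing
#' the last accepted peak rather than the immediate predecessor is
#' equivalent whenever the predecessor is clean, and prevents one
#' spike-contaminated cycle from dragging its clean successor into the
#' censored set. Both thresholds are strict inequalities; the first cycle
#' (and any cycle with no accepted predecessor) is exempt from the jump
#' test.
#'
#' @param cycles A `cycle_series`.
#' @param rate_max_hz Maximum plausible instantaneous cardiac frequency
#'   (Hz). Default 5.
#' @param jump_max Maximum plausible cycle-to-cycle change in peak
#'   velocity (cm/s). Default 10.
#' @return An object of class `censor_mask`: a list with `censored`
#'   (logical per cycle), `reason` (`NA`, `"rr_implausible"` or
#'   `"velocity_jump"`; RR takes precedence when both fire),
#'   `censored_fraction`, and `discard` (`TRUE` when the fraction exceeds
#'   0.15).
#' @export
censor_cycles <- function(cycles, rate_max_hz = 5.0, jump_max = 10.0) {
  if (nrow(cycles) == 0) stop("empty cycle series")
  n <- nrow(cycles)
  rr_bad <- (1 / cycles$rr) > rate_max_hz
  jump_bad <- logical(n)
  ref <- NA_real_                     # peak of the last accepted cycle
  for (i in seq_len(n)) {
    if (!rr_bad[i] && !is.na(ref) && abs(cycles$peak_v[i] - ref) > jump_max) {
      jump_bad[i] <- TRUE
    }
    if (!rr_bad[i] && !jump_bad[i]) ref <- cycles$peak_v[i]
  }
  censored <- rr_bad | jump_bad
  reason <- rep(NA_character_, n)
  reason[jump_bad] <- "velocity_jump"
  reason[rr_bad] <- "rr_implausible"
  frac <- mean(censored)
  structure(list(censored = censored, reason = reason,
                 censored_fraction = frac,
                 discard = frac > 0.15),
            class = "censor_mask")
}

#' Whole-acquisition discard rule
#'
#' An acquisition is discarded when strictly more than `threshold` of its
#' cardiac cycles were censored.
#'
#' @param mask A `censor_mask`.
#' @param threshold Censored-fraction threshold. Default 0.15.
#' @return `TRUE` if the bout should be discarded.
#' @export
apply_discard_rule <- function(mask, threshold = 0.15) {
  mask$censored_fraction > threshold
}

#' Resample surviving cycle means onto a uniform 2 Hz grid
#'
#' Removes censored cycles, places each surviving cycle's mean velocity at
#' its temporal midpoint (`onset + rr/2`), and linearly interpolates onto
#' a 0.5-s grid over `[0, duration]`. Grid points outside the convex hull
#' of surviving beats are `NA`.
#'
#' @param cycles A `cycle_series`.
#' @param mask The corresponding `censor_mask`.
#' @param duration Recording duration (s).
#' @return An object of class `smoothed_series`: a data frame with
#'   columns `time_s` (0.5-s grid) and `value` (cm/s), attribute
#'   `provenance`.
#' @export
resample_to_2hz <- function(cycles, mask, duration) {
  if (apply_discard_rule(mask)) {
    stop("acquisition was discarded; refusing to resample")
  }
  keep <- !mask$censored
  if (!any(keep)) stop("all cycles censored")
  x <- cycles$onset[keep] + cycles$rr[keep] / 2
  y <- cycles$mean_v[keep]
  grid <- seq(0, duration, by = 0.5)
  val <- stats::approx(x, y, xout = grid, method = "linear", rule = 1)$y
  structure(data.frame(time_s = grid, value = val),
            provenance = "single bout",
            class = c("smoothed_series", "data.frame"))
}

#' 3-s block averaging with a 9-s sliding-window smooth
#'
#' Stage 1 collapses the 2 Hz series into non-overlapping 3-s block means
#' (6 samples per block, blocks anchored at t = 0; a final partial block
#' is dropped). Stage 2 applies a centred moving average over 3
#' consecutive blocks (a 9-s window); the first and last blocks average
#' the 2 available blocks. The result is reported at block centres.
#'
#' @param series A `smoothed_series` on the 0.5-s grid.
#' @return A `smoothed_series` with `time_s` at block centres (1.5, 4.5,
#'   ... s) and smoothed `value`.
#' @export
smooth_3s_9s <- function(series) {
  dt <- diff(series$time_s)
  if (length(dt) == 0 || any(abs(dt - 0.5) > 1e-9)) {
    stop("series must be on a uniform 0.5-s grid")
  }
  n_blocks <- floor(nrow(series) / 6)
  if (n_blocks < 1) stop("series shorter than one 3-s block")
  idx <- rep(seq_len(n_blocks), each = 6)
  v <- series$value[seq_len(n_blocks * 6)]
  block <- as.numeric(tapply(v, idx, function(z) {
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  }))
  centers <- (seq_len(n_blocks) - 0.5) * 3
  sm <- vapply(seq_len(n_blocks), function(i) {
    win <- block[max(1, i - 1):min(n_blocks, i + 1)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  structure(data.frame(time_s = centers, value = sm),
            provenance = attr(series, "provenance"),
            class = c("smoothed_series", "data.frame"))
}

#' Average smoothed series across exercise bouts
#'
#' Pointwise mean across bouts aligned by recording time; at each grid
#' point only the bouts with a non-missing value contribute. Averaging
#' repeated bouts improves the signal-to-noise ratio of the exercise
#' response.
#'
#' @param series_list Nonempty list of `smoothed_series` on a common grid.
#' @return A `smoothed_series`; attribute `provenance` lists contributing
#'   bouts.
#' @export
average_bouts <- function(series_list) {
  if (length(series_list) == 0) {
    stop("subject unmodelable: no surviving bouts to average")
  }
  grids <- lapply(series_list, `[[`, "time_s")
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("bouts must share a common time grid")
  }
  vals <- sapply(series_list, `[[`, "value")
  vals <- matrix(vals, ncol = length(series_list))
  avg <- rowMeans(vals, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  structure(data.frame(time_s = grids[[1]], value = avg),
            provenance = sprintf("mean of %d bouts", length(series_list)),
            class = c("smoothed_series", "data.frame"))
}

#' Full preprocessing chain for one bout and hemisphere
#'
#' Convenience wrapper: cycle extraction, censoring, the discard rule,
#' 2 Hz resampling and 3-s/9-s smoothing. Returns `NULL` when the bout is
#' discarded.
#'
#' @param rec A `cvr_recording`.
#' @param hemisphere Channel to process.
#' @param rate_max_hz,jump_max,discard_threshold Censoring thresholds.
#' @return A list with `series` (a `smoothed_series`, or `NULL` if
#'   discarded), `mask`, and `discarded`.
#' @export
preprocess_recording <- function(rec, hemisphere = "stroke_affected",
                                 rate_max_hz = 5.0, jump_max = 10.0,
                                 discard_threshold = 0.15) {
  cycles <- extract_cycles(rec, hemisphere)
  mask <- censor_cycles(cycles, rate_max_hz, jump_max)
  discarded <- apply_discard_rule(mask, discard_threshold)
  if (discarded) {
    return(list(series = NULL, mask = mask, discarded = TRUE))
  }
  duration <- nrow(rec) / attr(rec, "sample_rate")
  series <- resample_to_2hz(cycles, mask, duration)
  list(series = smooth_3s_9s(series), mask = mask, discarded = FALSE)
}
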