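#' Resting MCAv
#'
#' Mean of the non-missing smoothed MCAv values in the resting window
#' `[0, 90)` s (the first 90 s of the recording, before exercise onset).
#'
#' @param series A `smoothed_series`.
#' @param rest_window Half-open window `[a, b)` in seconds.
#' @return Resting MCAv (cm/s).
#' @export
resting_mcav <- function(series, rest_window = c(0, 90)) {
  window_mean(series, rest_window, "resting")
}

#' Steady-state exercise MCAv
#'
#' Mean of the non-missing smoothed MCAv values between recording minute
#' 3 and 4.5 (`[180, 270)` s on the continuous recording clock, i.e.
#' 90-180 s into exercise), the steady-state portion of the bout.
#'
#' @param series A `smoothed_series`.
#' @param ss_window Half-open window `[a, b)` in seconds.
#' @return Steady-state exercise MCAv (cm/s).
#' @export
steady_state_mcav <- function(series, ss_window = c(180, 270)) {
  window_mean(series, ss_window, "steady-state")
}

window_mean <- function(series, window, label) {
  sel <- series$time_s >= window[1] & series$time_s < window[2]
  vals <- series$value[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop(sprintf("no samples in the %s window [%g, %g)", label,
                 window[1], window[2]))
  }
  mean(vals)
}

#' Cerebrovascular response to exercise
#'
#' `CVR = steady-state exercising MCAv - resting MCAv` (cm/s).
#'
#' @param mcav_rest Resting MCAv (cm/s), must be positive.
#' @param mcav_ss Steady-state exercising MCAv (cm/s).
#' @return CVR (cm/s).
#' @export
compute_cvr <- function(mcav_rest, mcav_ss) {
  if (any(mcav_rest <= 0)) stop("resting MCAv must be positive")
  mcav_ss - mcav_rest
}

#' Percent change in MCAv from rest to exercise
#'
#' `%dMCAv = 100 * CVR / resting MCAv`, removing the dependence on the
#' resting baseline.
#'
#' @param cvr CVR (cm/s).
#' @param mcav_rest Resting MCAv (cm/s), must be positive.
#' @return Percent change.
#' @export
compute_pct_change <- function(cvr, mcav_rest) {
  if (any(mcav_rest <= 0)) stop("resting MCAv must be positive")
  100 * cvr / mcav_rest
}

#' Age-predicted maximal heart rate
#'
#' `220 - age` off beta-blockade, `164 - 0.72 * age` on beta-blockade;
#' the value is not rounded.
#'
#' @param age Age in years (> 0).
#' @param beta_blocker Logical: is the subject taking a beta-blocker?
#' @return Predicted HRmax (beats/min).
#' @examples
#' hr_max(50, FALSE)  # 170
#' hr_max(50, TRUE)   # 128
#' @export
hr_max <- function(age, beta_blocker) {
  if (any(age <= 0)) stop("age must be positive")
  ifelse(beta_blocker, 164 - 0.72 * age, 220 - age)
}

#' Karvonen moderate-intensity heart-rate prescription
#'
#' Target HR = intensity * (HRmax - resting HR) + resting HR, evaluated
#' at the lower and upper intensity bounds (default 45% and 55% of
#' heart-rate reserve, the moderate-intensity band).
#'
#' @param hr_max Maximal HR (beats/min).
#' @param hr_rest Resting HR (beats/min), must be below `hr_max`.
#' @param lo,hi Intensity fractions of heart-rate reserve.
#' @return A list `hr_prescription` with `hr_max`, `hr_low`, `hr_high`.
#' @examples
#' karvonen_range(170, 70)  # 115 to 125 bpm
#' @export
karvonen_range <- function(hr_max, hr_rest, lo = 0.45, hi = 0.55) {
  if (any(hr_rest >= hr_max)) stop("resting HR must be below HRmax")
  structure(list(hr_max = hr_max,
                 hr_low = lo * (hr_max - hr_rest) + hr_rest,
                 hr_high = hi * (hr_max - hr_rest) + hr_rest),
            class = "hr_prescription")
}

#' Per-subject CVR outcomes for one hemisphere
#'
#' Computes resting MCAv, steady-state exercising MCAv, CVR and percent
#' change from a bout-averaged smoothed series.
#'
#' @param series A `smoothed_series` (typically the average across
#'   surviving bouts).
#' @param subject_id,visit,hemisphere Metadata carried into the result.
#' @param rest_window,ss_window Analysis windows (s).
#' @return A one-row data frame (`cvr_result`): `subject_id`, `visit`,
#'   `hemisphere`, `mcav_rest`, `mcav_ss`, `cvr`, `pct_change`.
#' @export
cvr_metrics <- function(series, subject_id = NA_character_, visit = "3mo",
                        hemisphere = "stroke_affected",
                        rest_window = c(0, 90), ss_window = c(180, 270)) {
  rest <- resting_mcav(series, rest_window)
  ss <- steady_state_mcav(series, ss_window)
  cvr <- compute_cvr(rest, ss)
  structure(data.frame(subject_id = subject_id, visit = visit,
                       hemisphere = hemisphere,
                       mcav_rest = rest, mcav_ss = ss, cvr = cvr,
                       pct_change = compute_pct_change(cvr, rest),
                       stringsAsFactors = FALSE),
            class = c("cvr_result", "data.frame"))
}
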