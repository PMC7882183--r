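#' Parameters for the synthetic stroke cohort generator
#'
#' Bundles every knob of the synthetic-cohort and waveform simulator. The
#' defaults encode the study conditions the pipeline is validated against:
#' group sizes 13 (HbA1c < 7%) vs 6 (HbA1c > 7%), stroke-affected CVR
#' effect sizes 6.8 +/- 5.0 vs 0.9 +/- 3.7 cm/s, resting MCAv around
#' 55 +/- 15 cm/s, mono-exponential exercise onset kinetics, and two bouts
#' per visit.
#'
#' @param n_low,n_high Cohort sizes for the HbA1c < 7% and > 7% groups.
#' @param rest_mcav_mean,rest_mcav_sd Resting MCAv distribution (cm/s),
#'   shared by both hemispheres.
#' @param cvr_mean_low,cvr_sd_low,cvr_mean_high,cvr_sd_high Group CVR
#'   distributions (cm/s).
#' @param tau Exponential time constant of the exercise-onset rise (s).
#' @param time_delay Delay between exercise onset and the start of the
#'   MCAv rise (s).
#' @param pulsatility_amp Amplitude of the intra-cycle pulsatile waveform
#'   (cm/s).
#' @param noise_sd SD of additive white measurement noise (cm/s).
#' @param artifact_spike_rate Velocity-spike artifacts per minute.
#' @param artifact_spike_mag Spike magnitude (cm/s); must exceed 10 so the
#'   peak-jump censoring rule is triggered.
#' @param short_rr_rate Implausibly short RR-interval artifacts per minute.
#' @param hemi_correlation Subject-level correlation between hemispheres
#'   for both resting MCAv and CVR.
#' @param n_bouts Exercise bouts recorded per subject-visit.
#' @param duration Recording length (s): 90 s rest + 360 s exercise.
#' @param sample_rate Sampling rate (Hz).
#' @param seed Root seed; per-subject/bout substreams are derived from it.
#' @return An object of class `synth_params` (a validated list).
#' @export
synth_params <- function(n_low = 13, n_high = 6,
                         rest_mcav_mean = 55, rest_mcav_sd = 15,
                         cvr_mean_low = 6.8, cvr_sd_low = 5.0,
                         cvr_mean_high = 0.9, cvr_sd_high = 3.7,
                         tau = 30, time_delay = 5,
                         pulsatility_amp = 15, noise_sd = 2,
                         artifact_spike_rate = 0, artifact_spike_mag = 15,
                         short_rr_rate = 0,
                         hemi_correlation = 0.7,
                         n_bouts = 2, duration = 450, sample_rate = 500,
                         seed = 1L) {
  p <- list(n_low = n_low, n_high = n_high,
            rest_mcav_mean = rest_mcav_mean, rest_mcav_sd = rest_mcav_sd,
            cvr_mean_low = cvr_mean_low, cvr_sd_low = cvr_sd_low,
            cvr_mean_high = cvr_mean_high, cvr_sd_high = cvr_sd_high,
            tau = tau, time_delay = time_delay,
            pulsatility_amp = pulsatility_amp, noise_sd = noise_sd,
            artifact_spike_rate = artifact_spike_rate,
            artifact_spike_mag = artifact_spike_mag,
            short_rr_rate = short_rr_rate,
            hemi_correlation = hemi_correlation,
            n_bouts = n_bouts, duration = duration,
            sample_rate = sample_rate, seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  if (p$n_low < 1 || p$n_high < 1) {
    stop("configuration error: group sizes must be positive")
  }
  sds <- c(p$rest_mcav_sd, p$cvr_sd_low, p$cvr_sd_high, p$noise_sd)
  if (any(sds < 0)) stop("configuration error: SDs must be >= 0")
  if (p$artifact_spike_mag <= 10) {
    stop("configuration error: artifact_spike_mag must exceed 10 cm/s ",
         "(the peak-jump censoring threshold)")
  }
  if (p$tau <= 0) stop("configuration error: tau must be positive")
  if (p$artifact_spike_rate < 0 || p$short_rr_rate < 0) {
    stop("configuration error: artifact rates must be >= 0")
  }
  if (p$hemi_correlation < 0 || p$hemi_correlation > 1) {
    stop("configuration error: hemi_correlation must be in [0, 1]")
  }
  if (p$n_bouts < 1) stop("configuration error: n_bouts must be >= 1")
  if (p$duration < 270) {
    stop("configuration error: duration < 270 s leaves the steady-state ",
         "window undefined")
  }
  invisible(p)
}

# Deterministic substream seed from (root seed, labels...): a 32-bit
# djb2-style fold so editing one subject never reshuffles another.
derive_seed <- function(root, ...) {
  key <- paste(c(format(root), ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

#' Simulate a stroke cohort with known ground truth
#'
#' Draws subject profiles (demographics, HbA1c, beta-blocker use, resting
#' HR) and the per-subject, per-hemisphere ground truth the recording
#' simulator reproduces: resting MCAv and the true CVR, defined as the
#' noise-free mean MCAv increment over the steady-state analysis window.
#' HbA1c is uniform on 5.0-6.8% in the low group and 7.2-11.0% in the
#' high group. Hemispheres share a subject-level effect (correlation
#' `hemi_correlation`) for both baseline and CVR.
#'
#' @param params A [synth_params()] object.
#' @return An object of class `cvr_cohort`: a list with `profiles` (one
#'   row per subject) and `truth` (one row per subject x hemisphere with
#'   `true_rest_mcav` and `true_cvr`), plus the generating `params`.
#' @examples
#' cohort <- simulate_cohort(synth_params(n_low = 3, n_high = 2, seed = 7))
#' cohort$profiles$hba1c
#' @export
simulate_cohort <- function(params) {
  validate_synth_params(params)
  n <- params$n_low + params$n_high
  ids <- sprintf("S%02d", seq_len(n))
  group <- rep(c("low", "high"), c(params$n_low, params$n_high))

  profiles <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- derive_seed(params$seed, ids[i], "profile")
    set.seed(s)
    g <- group[i]
    hba1c <- if (g == "low") stats::runif(1, 5.0, 6.8) else stats::runif(1, 7.2, 11.0)
    age <- sample(40:85, 1)
    data.frame(
      subject_id = ids[i],
      age = age,
      sex = sample(c("male", "female"), 1, prob = c(0.63, 0.37)),
      hba1c = hba1c,
      beta_blocker = stats::runif(1) < 0.3,
      resting_hr = sample(55:85, 1),
      t2dm = if (g == "high") TRUE else stats::runif(1) < 0.31,
      stroke_side = sample(c("left", "right"), 1),
      bmi = stats::rnorm(1, if (g == "low") 30.6 else 27.1,
                         if (g == "low") 6.2 else 2.0),
      smoker = stats::runif(1) < if (g == "low") 5 / 13 else 1 / 6,
      hypertension = stats::runif(1) < if (g == "low") 10 / 13 else 0.95,
      hba1c_group = g,
      stringsAsFactors = FALSE)
  }))

  rho <- params$hemi_correlation
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- derive_seed(params$seed, ids[i], "truth")
    set.seed(s)
    g <- group[i]
    cvr_mean <- if (g == "low") params$cvr_mean_low else params$cvr_mean_high
    cvr_sd <- if (g == "low") params$cvr_sd_low else params$cvr_sd_high
    # shared subject effect + hemisphere-specific effect, correlation rho
    z_subj <- stats::rnorm(2)          # [rest, cvr] shared components
    z_hemi <- matrix(stats::rnorm(4), nrow = 2)
    mix <- function(shared, own) sqrt(rho) * shared + sqrt(1 - rho) * own
    data.frame(
      subject_id = ids[i],
      hemisphere = c("stroke_affected", "non_affected"),
      true_rest_mcav = params$rest_mcav_mean +
        params$rest_mcav_sd * mix(z_subj[1], z_hemi[1, ]),
      true_cvr = cvr_mean + cvr_sd * mix(z_subj[2], z_hemi[2, ]),
      stringsAsFactors = FALSE)
  }))
  # keep baselines physiological
  truth$true_rest_mcav <- pmax(truth$true_rest_mcav, 25)

  structure(list(profiles = profiles, truth = truth, params = params),
            class = "cvr_cohort")
}

# fraction of the exercise-onset rise completed, at time t (s); t0 is
# exercise onset, the rise starts at t0 + time_delay
onset_fraction <- function(t, tau, time_delay, t0 = 90) {
  tt <- pmax(0, t - t0 - time_delay)
  1 - exp(-tt / tau)
}

# closed-form mean of onset_fraction over [a, b)
onset_fraction_window_mean <- function(tau, time_delay, a = 180, b = 270,
                                       t0 = 90) {
  s <- t0 + time_delay
  stopifnot(a >= s)
  1 - (tau / (b - a)) * (exp(-(a - s) / tau) - exp(-(b - s) / tau))
}

# intra-cycle pulse shape on phase [0, 1): raised-cosine systolic bump in
# the first 30% of the cycle, mean-centred so it leaves cycle means intact
pulse_shape <- function(phase) {
  s <- ifelse(phase < 0.3, 0.5 * (1 - cos(2 * pi * phase / 0.3)), 0)
  s - 0.15
}

#' Simulate one exercise-bout recording for a subject
#'
#' Generates a multichannel recording (bilateral MCAv, MAP, end-tidal CO2,
#' beat-onset markers) for one 7.5-min bout: 90 s rest then 6 min of
#' moderate-intensity exercise. Cycle-mean MCAv follows
#' `rest + A * (1 - exp(-(t - t0 - TD)/tau))` after exercise onset, with
#' the amplitude `A` scaled so the noise-free mean over the steady-state
#' window \[180, 270) s equals the subject's `true_cvr` exactly. Heart rate
#' rises with the same kinetics from resting HR to the Karvonen
#' moderate-intensity midpoint. A mean-centred pulsatile waveform and
#' white noise are superimposed.
#'
#' @param profile One row of a cohort's `profiles` data frame.
#' @param truth The subject's rows of the cohort `truth` data frame (both
#'   hemispheres).
#' @param params The generating [synth_params()].
#' @param bout Bout index (used to derive the noise substream).
#' @param visit Visit label, `"3mo"` or `"6mo"`.
#' @return An object of class `cvr_recording`: a data frame with columns
#'   `time_s`, `mcav_affected`, `mcav_nonaffected`, `map_mmhg`,
#'   `petco2_mmhg`, `beat_onset`, with attributes `beat_onsets` (times, s),
#'   `sample_rate`, `bout_index`, `visit`, `subject_id`, `artifact_log`.
#' @export
simulate_recording <- function(profile, truth, params, bout = 1L,
                               visit = "3mo") {
  validate_synth_params(params)
  if (!all(truth$subject_id == profile$subject_id)) {
    stop("ground truth does not belong to this profile")
  }
  if (params$duration < 270) stop("steady-state window undefined")
  fs <- params$sample_rate
  dur <- params$duration
  t <- seq(0, dur - 1 / fs, by = 1 / fs)

  set.seed(derive_seed(params$seed, profile$subject_id, "bout", bout, visit))

  # beat onsets: RR = 60/HR(t), HR rising to the Karvonen midpoint
  presc <- karvonen_range(hr_max(profile$age, profile$beta_blocker),
                          profile$resting_hr)
  hr_target <- (presc$hr_low + presc$hr_high) / 2
  hr_fun <- function(tt) {
    profile$resting_hr + (hr_target - profile$resting_hr) *
      onset_fraction(tt, params$tau, params$time_delay)
  }
  onsets <- numeric(ceiling(dur * hr_target / 60) + 10)
  k <- 1L; tk <- 0
  while (tk < dur) {
    onsets[k] <- tk
    tk <- tk + 60 / hr_fun(tk)
    k <- k + 1L
  }
  onsets <- onsets[seq_len(k - 1L)]

  wmean <- onset_fraction_window_mean(params$tau, params$time_delay)
  frac <- onset_fraction(t, params$tau, params$time_delay)
  # cycle phase at each sample
  cyc <- findInterval(t, onsets)
  phase <- (t - onsets[cyc]) /
    (c(diff(onsets), 60 / hr_fun(onsets[length(onsets)]))[cyc])
  pulse <- params$pulsatility_amp * pulse_shape(pmin(phase, 0.999))

  channel <- function(hemi) {
    tr <- truth[truth$hemisphere == hemi, ]
    A <- tr$true_cvr / wmean
    tr$true_rest_mcav + A * frac + pulse +
      stats::rnorm(length(t), sd = params$noise_sd)
  }
  mcav_aff <- channel("stroke_affected")
  mcav_non <- channel("non_affected")

  map <- 80 + 18 * frac + stats::rnorm(length(t), sd = params$noise_sd)
  petco2 <- 35 + 4 * frac + stats::rnorm(length(t), sd = 0.5 * params$noise_sd)

  beat_flag <- integer(length(t))
  beat_flag[pmin(length(t), round(onsets * fs) + 1L)] <- 1L

  rec <- data.frame(time_s = t,
                    mcav_affected = mcav_aff,
                    mcav_nonaffected = mcav_non,
                    map_mmhg = map,
                    petco2_mmhg = petco2,
                    beat_onset = beat_flag)
  structure(rec,
            beat_onsets = onsets,
            sample_rate = fs,
            bout_index = as.integer(bout),
            visit = visit,
            subject_id = profile$subject_id,
            artifact_log = data.frame(time_s = numeric(0),
                                      kind = character(0),
                                      stringsAsFactors = FALSE),
            class = c("cvr_recording", "data.frame"))
}

#' Inject artifacts into a simulated recording
#'
#' Adds the two artifact classes the censoring rules are designed to
#' catch: velocity spikes that change a cycle's peak velocity by more than
#' 10 cm/s, and spurious extra beat markers that create instantaneous
#' cardiac frequencies above 5 Hz. Every injection is recorded in the
#' artifact log. Zero rates return the recording unchanged.
#'
#' @param recording A `cvr_recording`.
#' @param params The generating [synth_params()] (`artifact_spike_rate`,
#'   `artifact_spike_mag`, `short_rr_rate` are used).
#' @param cycles Optional integer vector of cycle indices to spike
#'   deterministically (overrides the Poisson draw; used for trace tests).
#' @return The recording with artifacts applied and an updated
#'   `artifact_log` attribute (`time_s`, `kind`).
#' @export
inject_artifacts <- function(recording, params, cycles = NULL) {
  stopifnot(inherits(recording, "cvr_recording"))
  onsets <- attr(recording, "beat_onsets")
  fs <- attr(recording, "sample_rate")
  dur <- nrow(recording) / fs
  minutes <- dur / 60
  log <- attr(recording, "artifact_log")

  set.seed(derive_seed(params$seed, attr(recording, "subject_id"),
                       "artifacts", attr(recording, "bout_index")))

  n_cycles <- length(onsets) - 1L
  if (is.null(cycles)) {
    n_spikes <- stats::rpois(1, params$artifact_spike_rate * minutes)
    cycles <- if (n_spikes > 0 && n_cycles > 0) {
      sample(n_cycles, min(n_spikes, n_cycles))
    } else integer(0)
  }
  for (cyc in cycles) {
    # raise a short run of samples centred on the systolic peak (phase
    # 0.15), so the cycle peak velocity changes by exactly the magnitude
    a <- onsets[cyc]; b <- onsets[cyc + 1L]
    peak_t <- a + 0.15 * (b - a)
    idx <- which(recording$time_s >= peak_t - 0.03 &
                   recording$time_s <= peak_t + 0.03)
    recording$mcav_affected[idx] <- recording$mcav_affected[idx] +
      params$artifact_spike_mag
    recording$mcav_nonaffected[idx] <- recording$mcav_nonaffected[idx] +
      params$artifact_spike_mag
    log <- rbind(log, data.frame(time_s = peak_t, kind = "velocity_spike",
                                 stringsAsFactors = FALSE))
  }

  n_short <- stats::rpois(1, params$short_rr_rate * minutes)
  if (n_short > 0 && n_cycles > 0) {
    host <- sample(n_cycles, min(n_short, n_cycles))
    for (cyc in host) {
      extra <- onsets[cyc] + 0.1      # 0.1 s after onset: 10 Hz instantaneous
      onsets <- sort(c(onsets, extra))
      i <- min(nrow(recording), round(extra * fs) + 1L)
      recording$beat_onset[i] <- 1L
      log <- rbind(log, data.frame(time_s = extra, kind = "short_rr",
                                   stringsAsFactors = FALSE))
    }
    attr(recording, "beat_onsets") <- onsets
  }

  log <- log[order(log$time_s), , drop = FALSE]
  rownames(log) <- NULL
  attr(recording, "artifact_log") <- log
  recording
}

#' Write a cohort's recordings and metadata to disk
#'
#' Writes each bout as a CSV (`<subject>_<visit>_bout<k>.csv` with columns
#' `time_s, mcav_affected, mcav_nonaffected, map_mmhg, petco2_mmhg,
#' beat_onset`), the subject table as `subjects.csv`, and ground truth
#' plus artifact logs as a JSON sidecar `ground_truth.json`.
#'
#' @param cohort A `cvr_cohort`.
#' @param recordings A list of `cvr_recording` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "subjects.csv")
  utils::write.csv(cohort$profiles, p, row.names = FALSE)
  paths <- c(paths, p)
  logs <- list()
  for (rec in recordings) {
    id <- attr(rec, "subject_id")
    fn <- sprintf("%s_%s_bout%d.csv", id, attr(rec, "visit"),
                  attr(rec, "bout_index"))
    fp <- file.path(dir, fn)
    utils::write.csv(as.data.frame(rec), fp, row.names = FALSE)
    paths <- c(paths, fp)
    logs[[fn]] <- attr(rec, "artifact_log")
  }
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(truth = cohort$truth, artifact_logs = logs),
                       gt, dataframe = "rows", digits = NA)
  paths <- c(paths, gt)
  invisible(paths)
}

#' Read a recording CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @param sample_rate Sampling rate (Hz); inferred from the time column
#'   when `NULL`.
#' @param subject_id,bout,visit Metadata to attach.
#' @return A `cvr_recording`.
#' @export
read_recording <- function(path, sample_rate = NULL, subject_id = NA_character_,
                           bout = 1L, visit = "3mo") {
  rec <- utils::read.csv(path)
  need <- c("time_s", "mcav_affected", "mcav_nonaffected", "beat_onset")
  if (!all(need %in% names(rec))) {
    stop("recording CSV missing columns: ",
         paste(setdiff(need, names(rec)), collapse = ", "))
  }
  if (is.null(sample_rate)) {
    sample_rate <- round(1 / stats::median(diff(rec$time_s)))
  }
  structure(rec,
            beat_onsets = rec$time_s[rec$beat_onset == 1],
            sample_rate = sample_rate,
            bout_index = as.integer(bout),
            visit = visit,
            subject_id = subject_id,
            artifact_log = data.frame(time_s = numeric(0),
                                      kind = character(0)),
            class = c("cvr_recording", "data.frame"))
}
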