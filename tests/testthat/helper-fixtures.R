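# Shared fixtures built in code.

# A minimal recording: velocity channel sampled at `fs` Hz with given
# beat-onset times; both hemispheres carry the same signal.
make_recording <- function(v, fs = 500, onsets, duration = length(v) / fs) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  stopifnot(length(t) == length(v))
  beat_flag <- integer(length(t))
  beat_flag[pmin(length(t), round(onsets * fs) + 1L)] <- 1L
  structure(data.frame(time_s = t, mcav_affected = v, mcav_nonaffected = v,
                       map_mmhg = 80, petco2_mmhg = 35,
                       beat_onset = beat_flag),
            beat_onsets = onsets, sample_rate = fs, bout_index = 1L,
            visit = "3mo", subject_id = "T01",
            artifact_log = data.frame(time_s = numeric(0),
                                      kind = character(0)),
            class = c("cvr_recording", "data.frame"))
}

# A cycle series straight from per-cycle summaries.
make_cycles <- function(onset, rr, mean_v, peak_v = mean_v) {
  structure(data.frame(onset = onset, rr = rr, mean_v = mean_v,
                       peak_v = peak_v),
            class = c("cycle_series", "data.frame"))
}

# A smoothed series on the uniform 0.5-s grid.
make_series <- function(value, t0 = 0) {
  structure(data.frame(time_s = t0 + 0.5 * (seq_along(value) - 1),
                       value = value),
            provenance = "fixture",
            class = c("smoothed_series", "data.frame"))
}

# A censor mask with a given number of censored cycles.
make_mask <- function(n_censored, n_total) {
  censored <- rep(c(TRUE, FALSE), c(n_censored, n_total - n_censored))
  structure(list(censored = censored,
                 reason = ifelse(censored, "velocity_jump", NA_character_),
                 censored_fraction = n_censored / n_total,
                 discard = n_censored / n_total > 0.15),
            class = "censor_mask")
}

# Two groups of tie-free values realising a prescribed U statistic for
# the first group: `wins[i]` lows are beaten by high i (lows are 1..n_low).
groups_with_u <- function(wins, n_low = 13) {
  low <- as.numeric(seq_len(n_low))
  high <- ifelse(wins == 0, -seq_along(wins) / 10, wins + 0.5)
  list(high = high, low = low)
}

# Brute-force U null distribution by enumerating all rank assignments.
brute_force_u_distribution <- function(n1, n2) {
  N <- n1 + n2
  combs <- utils::combn(N, n1)
  us <- colSums(matrix(seq_len(N)[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  counts <- tabulate(us + 1, nbins = n1 * n2 + 1)
  counts / sum(counts)
}
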