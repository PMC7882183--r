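test_that("cycle extraction summarises constant and pulsatile signals", {
  # constant 50 cm/s, onsets every second
  rec <- make_recording(rep(50, 1500), fs = 500, onsets = c(0, 1, 2))
  cyc <- extract_cycles(rec, "stroke_affected")
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$rr, c(1, 1))
  expect_equal(cyc$mean_v, c(50, 50))
  expect_equal(cyc$peak_v, c(50, 50))

  # sinusoidal intra-cycle waveform: mean matches the analytic integral
  fs <- 500
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  v <- 60 + 10 * sin(2 * pi * t)          # period 1 s = the cycle length
  rec2 <- make_recording(v, fs = fs, onsets = 0:3)
  cyc2 <- extract_cycles(rec2, "stroke_affected")
  # analytic: mean of 60 + 10 sin over a full period is 60; peak 70
  expect_equal(cyc2$mean_v, rep(60, 3), tolerance = 1e-10)
  expect_equal(cyc2$peak_v, rep(70, 3), tolerance = 1e-4)

  expect_error(extract_cycles(make_recording(rep(1, 10), onsets = 0.0)),
               "at least 2")
})

test_that("censoring applies the RR and peak-jump rules with strict bounds", {
  # 0.15 s RR interval: instantaneous frequency 6.67 Hz
  cyc <- make_cycles(onset = c(0, 1, 1.15), rr = c(1, 0.15, 1),
                     mean_v = c(50, 50, 50))
  mask <- censor_cycles(cyc)
  expect_equal(mask$censored, c(FALSE, TRUE, FALSE))
  expect_equal(mask$reason[2], "rr_implausible")

  # peak jump 60 -> 72: the second cycle is censored
  cyc2 <- make_cycles(onset = 0:1, rr = c(1, 1), mean_v = c(55, 67),
                      peak_v = c(60, 72))
  mask2 <- censor_cycles(cyc2)
  expect_equal(mask2$censored, c(FALSE, TRUE))
  expect_equal(mask2$reason[2], "velocity_jump")

  # jump of exactly 10.0 cm/s is NOT censored (strict inequality)
  cyc3 <- make_cycles(onset = 0:1, rr = c(1, 1), mean_v = c(55, 65),
                      peak_v = c(60, 70))
  expect_false(any(censor_cycles(cyc3)$censored))

  # one spiked cycle censors only itself: the successor is compared to
  # the last accepted peak
  cyc4 <- make_cycles(onset = 0:3, rr = rep(1, 4), mean_v = rep(55, 4),
                      peak_v = c(60, 72, 60, 60))
  mask4 <- censor_cycles(cyc4)
  expect_equal(which(mask4$censored), 2L)
})

test_that("censoring is order-preserving under added artifacts", {
  set.seed(71)
  for (i in 1:10) {
    n <- 40
    peaks <- 60 + cumsum(rnorm(n, sd = 1.5))
    cyc <- make_cycles(onset = seq_len(n) - 1, rr = rep(1, n),
                       mean_v = peaks - 5, peak_v = peaks)
    before <- censor_cycles(cyc)$censored
    k <- sample(which(!before), 1)
    cyc$peak_v[k] <- cyc$peak_v[k] + 15        # inject a spike
    after <- censor_cycles(cyc)$censored
    expect_true(all(after[before]), label = "previously censored stay censored")
    expect_true(after[k])
  }
})

test_that("the discard rule fires strictly above 15% censored cycles", {
  expect_true(apply_discard_rule(make_mask(16, 100)))
  expect_false(apply_discard_rule(make_mask(15, 100)))
  expect_false(apply_discard_rule(make_mask(0, 100)))
  # verdict depends only on the censored fraction
  set.seed(81)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    k <- sample(0:n, 1)
    expect_equal(apply_discard_rule(make_mask(k, n)), k / n > 0.15)
  }
})

test_that("2 Hz resampling interpolates linearly and bridges censored gaps", {
  # constant signal: grid identically 50 inside the hull
  cyc <- make_cycles(onset = 0:9, rr = rep(1, 10), mean_v = rep(50, 10))
  s <- resample_to_2hz(cyc, censor_cycles(cyc), duration = 10)
  expect_equal(diff(s$time_s), rep(0.5, length(s$time_s) - 1))
  inside <- s$time_s >= 0.5 & s$time_s <= 9.5
  expect_equal(s$value[inside], rep(50, sum(inside)))
  expect_true(all(is.na(s$value[!inside])))

  # linear ramp of cycle means stays on the same line
  cyc2 <- make_cycles(onset = 0:9, rr = rep(1, 10), mean_v = 40 + 2 * (0:9))
  s2 <- resample_to_2hz(cyc2, censor_cycles(cyc2), duration = 10)
  mids <- 0:9 + 0.5
  line <- approx(mids, 40 + 2 * (0:9), xout = s2$time_s, rule = 1)$y
  expect_equal(s2$value, line)

  # an interior censored cycle is bridged linearly by its neighbours
  # (1 of 10 censored keeps the bout below the 15% discard threshold)
  cyc3 <- make_cycles(onset = 0:9, rr = rep(1, 10),
                      mean_v = c(50, 50, 90, rep(50, 7)),
                      peak_v = c(55, 55, 95, rep(55, 7)))
  mask3 <- censor_cycles(cyc3)
  expect_equal(which(mask3$censored), 3L)
  s3 <- resample_to_2hz(cyc3, mask3, duration = 5)
  # midpoints 1.5 and 3.5 both 50: the bridged point at 2.5 must be 50
  expect_equal(s3$value[s3$time_s == 2.5], 50)

  all_bad <- make_cycles(onset = 0:1, rr = c(0.1, 0.1), mean_v = c(1, 1))
  expect_error(resample_to_2hz(all_bad, censor_cycles(all_bad), 2),
               "all cycles censored|discarded")
})

test_that("3-s/9-s smoothing matches hand-computed block averages", {
  # constant series is unchanged
  s <- make_series(rep(42, 36))
  expect_equal(smooth_3s_9s(s)$value, rep(42, 6))

  # three blocks of 10, 20, 30 smooth to 15, 20, 25 (shrunken edges)
  s2 <- make_series(rep(c(10, 20, 30), each = 6))
  sm2 <- smooth_3s_9s(s2)
  expect_equal(sm2$value, c(15, 20, 25))
  expect_equal(sm2$time_s, c(1.5, 4.5, 7.5))

  # a +6 single-sample spike spreads 6/(6*3) over the three blocks whose
  # 9-s windows contain it, by linearity of both averaging stages
  base <- rep(0, 54)                  # 9 blocks
  base[25] <- 6                       # inside block 5 (interior)
  sm3 <- smooth_3s_9s(make_series(base))
  expect_equal(sm3$value[4:6], rep(6 / 18, 3), tolerance = 1e-12)
  expect_equal(sm3$value[-(4:6)], rep(0, 6))

  # partial final block is dropped
  sm4 <- smooth_3s_9s(make_series(rep(1, 9)))
  expect_equal(nrow(sm4), 1)

  expect_error(smooth_3s_9s(make_series(rep(1, 3))), "shorter")
})

test_that("smoothing commutes with affine rescaling", {
  set.seed(91)
  v <- rnorm(60, 55, 8)
  a <- 2.5; b <- -7
  lhs <- smooth_3s_9s(make_series(a * v + b))$value
  rhs <- a * smooth_3s_9s(make_series(v))$value + b
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("bout averaging is pointwise with pairwise missing handling", {
  s1 <- make_series(rep(50, 36))
  expect_equal(average_bouts(list(s1, s1))$value, s1$value)  # idempotent

  set.seed(101)
  v <- rnorm(36); c0 <- 3
  sa <- make_series(v); sb <- make_series(-v + 2 * c0)
  expect_equal(average_bouts(list(sa, sb))$value, rep(c0, 36))

  # one bout with a missing stretch: average falls back to the survivor
  v2 <- v; v2[10:12] <- NA
  avg <- average_bouts(list(make_series(v), make_series(v2)))
  expect_equal(avg$value[10:12], v[10:12])

  # a discarded bout contributes nothing: averaging the one survivor
  expect_equal(average_bouts(list(sa))$value, sa$value)
  expect_error(average_bouts(list()), "unmodelable")
})

test_that("the noise-free pipeline reproduces the generator's cycle means", {
  p <- synth_params(n_low = 1, n_high = 1, noise_sd = 0,
                    pulsatility_amp = 0, n_bouts = 1, seed = 5)
  cohort <- simulate_cohort(p)
  prof <- cohort$profiles[1, ]
  truth <- cohort$truth[cohort$truth$subject_id == prof$subject_id, ]
  rec <- simulate_recording(prof, truth, p)
  cyc <- extract_cycles(rec, "stroke_affected")
  # recompute the expected discrete cycle means from the construction:
  # rest + A * onset fraction, averaged over each cycle's samples
  tr <- truth[truth$hemisphere == "stroke_affected", ]
  A <- tr$true_cvr / cvrpipe:::onset_fraction_window_mean(p$tau, p$time_delay)
  onsets <- attr(rec, "beat_onsets")
  t <- rec$time_s
  base <- tr$true_rest_mcav +
    A * cvrpipe:::onset_fraction(t, p$tau, p$time_delay)
  idx <- findInterval(t, onsets)
  keep <- idx >= 1 & idx < length(onsets)
  expected <- as.numeric(tapply(base[keep], idx[keep], mean))
  expect_equal(cyc$mean_v, expected, tolerance = 1e-9)
})
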