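test_that("resampling preserves length ratio, spectrum and original samples", {
  set.seed(4)
  spec <- session_spec()
  tr <- generate_trial(spec, "Silk")
  up <- resample_eeg(tr, 4000)
  expect_identical(ncol(up$eeg), 40000L)
  expect_identical(up$fs_eeg, 4000)

  # pure 10 Hz sine keeps its dominant PSD peak after 500 -> 4000 Hz
  t5 <- (seq_len(5000) - 1) / 500
  sine <- matrix(sin(2 * pi * 10 * t5), 1, dimnames = list("C3", NULL))
  tr_s <- mk_trial(rbind(C3 = sine[1, ], Cz = sine[1, ]), tr$emg,
                   fs_eeg = 500)
  up_s <- resample_eeg(tr_s, 4000)
  p <- welch_psd(up_s$eeg["C3", ], 4000)
  expect_equal(p$freqs[which.max(p$psd)], 10)

  # round trip: decimating the upsampled signal recovers the original
  back <- up$eeg[1, seq(1, 40000, by = 8)]
  i <- 100:4900
  err <- sqrt(mean((back[i] - tr$eeg[1, i])^2)) / sd(tr$eeg[1, i])
  expect_lt(err, 1e-6)

  expect_error(resample_eeg(tr, 250), "below the original")
  expect_error(resample_eeg(tr, 1250), "integer")
})

test_that("common average reference zeroes the cross-channel mean", {
  x <- matrix(rnorm(3000), 3)
  y <- apply_car(x)
  expect_lt(max(abs(colMeans(y))), 1e-12)
  expect_equal(y, sweep(x, 2, colMeans(x)))

  two <- matrix(rnorm(100), 2)
  same <- rbind(two[1, ], two[1, ])
  expect_equal(apply_car(same), matrix(0, 2, 50), ignore_attr = TRUE)

  opp <- rbind(two[1, ], -two[1, ])
  expect_equal(apply_car(opp), opp)

  expect_error(apply_car(matrix(rnorm(10), 1)), "single channel")
})

test_that("band-pass and notch filters meet their attenuation contracts", {
  fs <- 4000
  bp <- function(x) filter_signal(x, fs, band = c(6, 50))
  expect_gt(sine_ratio(bp, 10, fs), 0.9)   # passband
  expect_lt(sine_ratio(bp, 2, fs), 0.1)    # stopband, > 1 octave out
  expect_lt(sine_ratio(bp, 200, fs), 0.1)

  nt <- function(x) filter_signal(x, fs, kind = "notch")
  expect_lt(sine_ratio(nt, 50, fs), 0.1)           # > 20 dB at 50 Hz
  expect_gt(sine_ratio(nt, 40, fs), 10^(-1 / 20))  # within 1 dB at 40 Hz

  expect_error(filter_signal(rnorm(100), 100, band = c(6, 50)), "Nyquist")
})

test_that("double application changes the passband by less than 2 dB", {
  fs <- 4000
  once <- function(x) filter_signal(x, fs, band = c(6, 50))
  twice <- function(x) once(once(x))
  r1 <- sine_ratio(once, 20, fs)
  r2 <- sine_ratio(twice, 20, fs)
  expect_lt(abs(20 * log10(r2 / r1)), 2)
})

test_that("trial rejection follows the amplitude threshold and budget", {
  set.seed(5)
  spec <- tiny_spec()
  trials <- lapply(1:10, function(i)
    generate_trial(spec, "Suede", trial_id = i))
  # inject one outlier sample
  trials[[4]]$eeg[2, 100] <- 400
  rr <- reject_trials(trials, threshold_uv = 350, max_fraction = 0.10)
  expect_length(rr$trials, 9)
  expect_identical(rr$rejected_trial_ids, 4L)
  expect_false(all(!rr$report$rejected))

  clean <- reject_trials(trials[-4], 350, 0.10)
  expect_length(clean$rejected_trial_ids, 0)
  expect_false(clean$subject_flag)

  # 2 of 10 rejected -> fraction 0.2 exceeds the 10% budget
  trials[[9]]$eeg[1, 1] <- -400
  rr2 <- reject_trials(trials, 350, 0.10)
  expect_true(rr2$subject_flag)

  # channel symmetry: permuting channels does not change rejections
  perm <- lapply(trials, function(tr) {
    tr$eeg <- tr$eeg[c(3, 1, 2), ]
    tr
  })
  expect_identical(reject_trials(perm, 350, 0.10)$rejected_trial_ids,
                   rr2$rejected_trial_ids)

  expect_error(reject_trials(list(), 350, 0.1), "empty")
})

test_that("epoch split partitions samples at the cue without overlap", {
  set.seed(6)
  tr <- preprocess_trial(generate_trial(session_spec(), "Suede"))
  sp <- split_epochs(tr)
  expect_identical(ncol(sp$baseline$eeg), 8000L)
  expect_identical(ncol(sp$task$eeg), 32000L)
  expect_identical(ncol(sp$baseline$emg) + ncol(sp$task$emg), 40000L)

  short <- tr
  short$eeg <- short$eeg[, 1:6000]
  short$emg <- short$emg[, 1:6000]
  expect_error(split_epochs(short), "shorter")
})

test_that("session preprocessing keeps rates aligned and reports rejections", {
  spec <- tiny_spec(seed = 8)
  sess <- generate_session(spec)
  ep <- preprocess_session(sess)
  expect_s3_class(ep, "cmc_epochs")
  expect_length(ep$trials, length(sess$trials))
  expect_true(all(vapply(ep$trials, function(tr)
    tr$fs_eeg == tr$fs_emg, TRUE)))
  expect_identical(nrow(ep$rejection), length(sess$trials))
  expect_false(any(ep$subject_flags))
})
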