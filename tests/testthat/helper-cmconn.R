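# Shared fixtures and independent oracles for the test suite.

# Small, fast session spec: 4 s trials (cue at 1 s, replace at 3 s).
tiny_spec <- function(...) {
  session_spec(n_subjects = 1, n_trials_per_surface = 2,
               trial_duration_s = 4, cue_time_s = 1, replace_time_s = 3,
               ...)
}

# Wrap a list of preprocessed trials as a cmc_epochs object.
mk_epochs <- function(trials) {
  structure(list(trials = trials, rejection = NULL,
                 subject_flags = c(S01 = FALSE),
                 config = preprocess_config()),
            class = "cmc_epochs")
}

# Build a bare cmc_trial from matrices (for estimator-level tests).
mk_trial <- function(eeg, emg, fs_eeg = 4000, fs_emg = 4000,
                     cue = 2, replace = 8, surface = "Suede") {
  structure(list(eeg = eeg, emg = emg, fs_eeg = fs_eeg, fs_emg = fs_emg,
                 cue_time_s = cue, replace_time_s = replace,
                 surface = surface, subject_id = "S01", trial_id = 1L),
            class = "cmc_trial")
}

# Brute-force Spearman oracle: rank both vectors, then the explicit
# Pearson product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exhaustive-counting entropy oracle on given bin edges.
oracle_entropy <- function(idx, n_levels) {
  p <- numeric(n_levels)
  for (v in idx) p[v] <- p[v] + 1
  p <- p / length(idx)
  h <- 0
  for (q in p) if (q > 0) h <- h - q * log2(q)
  h
}

# Oracle bin assignment mirroring equal-width edges with right-closed top.
oracle_bins <- function(x, n_bins) {
  if (n_bins <= 1 || min(x) == max(x)) return(rep(1L, length(x)))
  e <- seq(min(x), max(x), length.out = n_bins + 1)
  sapply(x, function(v) {
    for (b in seq_len(n_bins)) {
      hi_ok <- if (b == n_bins) v <= e[b + 1] else v < e[b + 1]
      if (v >= e[b] && hi_ok) return(b)
    }
    n_bins
  })
}

oracle_mi <- function(x, y, bx, by) {
  ix <- oracle_bins(x, bx); iy <- oracle_bins(y, by)
  hx <- oracle_entropy(ix, bx)
  hy <- oracle_entropy(iy, by)
  hxy <- oracle_entropy((ix - 1L) * by + iy, bx * by)
  hx + hy - hxy
}

# Amplitude ratio of a sine after filtering (interior samples only).
sine_ratio <- function(filter_fun, f0, fs, dur = 10) {
  t <- (seq_len(dur * fs) - 1) / fs
  x <- sin(2 * pi * f0 * t)
  y <- filter_fun(x)
  i <- seq(round(0.2 * length(x)), round(0.8 * length(x)))
  sd(y[i]) / sd(x[i])
}
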