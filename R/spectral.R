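#' Frequency-band definitions
#'
#' Standard sensorimotor bands: mu 8-13 Hz, beta 14-30 Hz, gamma 30-50 Hz,
#' and the combined "all" band 8-50 Hz. Beta and gamma share the 30 Hz bin
#' by default; `gamma_disjoint = TRUE` moves gamma to 31-50 Hz.
#'
#' @param mu,beta,gamma,all two-element numeric band edges (Hz).
#' @param gamma_disjoint make gamma start one bin above the beta edge.
#' @return Named list of `band_definition` objects.
#' @export
cmc_bands <- function(mu = c(8, 13), beta = c(14, 30), gamma = c(30, 50),
                      all = c(8, 50), gamma_disjoint = FALSE) {
  if (gamma_disjoint) gamma[1] <- gamma[1] + 1
  list(mu = band_definition("mu", mu[1], mu[2]),
       beta = band_definition("beta", beta[1], beta[2]),
       gamma = band_definition("gamma", gamma[1], gamma[2]),
       all = band_definition("all", all[1], all[2]))
}

#' @rdname cmc_bands
#' @param name band label.
#' @param f_lo,f_hi band edges in Hz, `f_lo < f_hi`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  .assert(f_lo < f_hi, "band edges must satisfy f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("band %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi)); invisible(x)
}

# ---- Welch-style averaged periodograms ------------------------------------

.window_fn <- function(name, n) {
  k <- seq_len(n) - 1
  switch(name,
         hanning = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         stop("unknown window: ", name))
}

# Averaged modified periodogram; one-sided density so that
# sum(psd) * df ~ var(x).
.welch <- function(x, fs, window_s, overlap, window) {
  nwin <- round(window_s * fs)
  n <- length(x)
  if (n < nwin)
    stop("segment shorter than one analysis window", call. = FALSE)
  hop <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, n - nwin + 1, by = hop)
  w <- .window_fn(window, nwin)
  segs <- matrix(x[outer(seq_len(nwin) - 1L, as.integer(starts), `+`)], nwin)
  segs <- segs - rep(colMeans(segs), each = nwin)
  X <- mvfft(segs * w)
  nf <- floor(nwin / 2) + 1
  p <- rowMeans(Mod(X[seq_len(nf), , drop = FALSE])^2) / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nwin is even)
  dbl <- seq(2, nf - if (nwin %% 2 == 0) 1 else 0)
  p[dbl] <- 2 * p[dbl]
  list(freqs = (seq_len(nf) - 1) * fs / nwin, psd = p)
}

#' PSD by averaged 1 s Hanning-windowed periodograms
#'
#' FFT-based power spectral density with 1 s Hanning windows at 50% overlap,
#' giving a 1 Hz native frequency step. Used for the relative-power
#' (rest-vs-task) analysis.
#'
#' @param x numeric signal (at least one window long).
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return List with `freqs` (Hz) and non-negative `psd` (power per Hz).
#' @examples
#' fs <- 500; x <- sin(2*pi*10*seq(0, 4, by = 1/fs))
#' p <- psd_hanning(x, fs)
#' p$freqs[which.max(p$psd)]
#' @export
psd_hanning <- function(x, fs, window_s = 1, overlap = 0.5) {
  .welch(x, fs, window_s, overlap, "hanning")
}

#' Welch PSD with Hamming windows
#'
#' Averaged modified periodogram: the signal is split into overlapping
#' segments, each Hamming-windowed, and segment periodograms are averaged.
#' Defaults (1 s segments, 50% overlap) give a 1 Hz native resolution.
#'
#' @inheritParams psd_hanning
#' @param window taper name, `"hamming"` (default) or `"hanning"`.
#' @return List with `freqs` (Hz) and non-negative `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5,
                      window = "hamming") {
  .welch(x, fs, window_s, overlap, window)
}

#' Relative power between task and baseline
#'
#' `(A - B) / B * 100`: the percentage change of task power `A` relative to
#' baseline power `B`. Negative values are event-related desynchronization.
#'
#' @param A task (movement) power, non-negative.
#' @param B baseline power, strictly positive.
#' @return Percent change (vectorised).
#' @examples
#' relative_power(0.5, 1)  # -50
#' @export
relative_power <- function(A, B) {
  if (any(B <= 0)) stop("baseline power must be positive", call. = FALSE)
  (A - B) / B * 100
}

# ---- Morlet time-frequency ERD -------------------------------------------

# Analytic Morlet power via FFT convolution; returns freqs x times matrix of
# power averaged within stride bins.
.morlet_power <- function(x, fs, freqs, n_cycles, stride_s) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- fft(c(x, numeric(nfft - n)))
  f_axis <- (seq_len(nfft) - 1) * fs / nfft
  n_bins <- floor(n / round(stride_s * fs))
  bin <- rep(seq_len(n_bins), each = round(stride_s * fs))
  keep <- seq_along(bin)
  out <- matrix(0, length(freqs), n_bins)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sigma_t <- n_cycles / (2 * pi * f0)
    # analytic wavelet: Gaussian in frequency, zero on negative frequencies
    W <- exp(-0.5 * ((f_axis - f0) * 2 * pi * sigma_t)^2)
    W[f_axis > fs / 2] <- 0
    y <- fft(X * W, inverse = TRUE) / nfft
    p <- Mod(y[seq_len(n)])^2
    out[i, ] <- as.numeric(rowsum(p[keep], bin)) / round(stride_s * fs)
  }
  out
}

#' Event-related desynchronization time-frequency map
#'
#' Morlet-wavelet (fixed cycle count) relative-power map: for every
#' (time, frequency) cell the percentage power change against that trial's
#' mean baseline power at the same frequency, averaged over trials. Negative
#' values are desynchronization. Signals whose band of interest lies far
#' below Nyquist may be decimated first (`decimate_to`), which leaves the
#' map unchanged and speeds the transform up considerably.
#'
#' The per-frequency baseline mean excludes the wavelet cone of influence at
#' the trial start (`3 * sigma_t`), where edge attenuation would bias the
#' baseline low.
#'
#' @param trials list of numeric vectors (one EEG channel per trial, full
#'   trial from `t = 0`), or a `cmc_epochs` object together with `channel`.
#' @param fs sampling rate (Hz) of the supplied vectors (taken from the
#'   epochs object if one is given).
#' @param channel channel label, when `trials` is a `cmc_epochs`.
#' @param freqs analysis frequencies (Hz), default 8-50 in 1 Hz steps.
#' @param stride_s time stride (s) of the map, default 50 ms.
#' @param n_cycles Morlet cycles (default 5).
#' @param baseline_s baseline interval (s).
#' @param per_trial_baseline divide by each trial's own baseline power
#'   (default) or by the trial-average baseline.
#' @param decimate_to target rate (Hz) for pre-decimation; use `NULL` to
#'   disable. Requires `max(freqs) < decimate_to / 2`.
#' @return An `erd_map`: list with `times`, `freqs`, `values`
#'   (freqs x times, percent), `per_trial` (trials x freqs x times array),
#'   `sig_mask` (`NULL` until [erd_significance()] is run), `alpha`.
#' @seealso [bootstrap_significance()], [erd_significance()]
#' @export
erd_time_frequency <- function(trials, fs = NULL, channel = NULL,
                               freqs = 8:50, stride_s = 0.05, n_cycles = 5,
                               baseline_s = c(0, 2),
                               per_trial_baseline = TRUE,
                               decimate_to = 500) {
  if (inherits(trials, "cmc_epochs")) {
    .assert(!is.null(channel), "channel is required with a cmc_epochs input")
    fs <- trials$trials[[1]]$fs_eeg
    trials <- lapply(trials$trials, function(tr) tr$eeg[channel, ])
  }
  .assert(length(trials) >= 1, "at least one trial is required")
  .assert(!is.null(fs), "fs is required")
  n <- length(trials[[1]])
  .assert(all(vapply(trials, length, 1L) == n),
          "all trials must have equal length")
  if (n / fs <= baseline_s[2])
    stop("trials shorter than the baseline window", call. = FALSE)
  if (!is.null(decimate_to) && fs > decimate_to &&
      fs %% decimate_to == 0 && max(freqs) < decimate_to / 2) {
    dec <- fs / decimate_to
    trials <- lapply(trials, function(x) x[seq(1, length(x), by = dec)])
    fs <- decimate_to
    n <- length(trials[[1]])
  }
  stride_n <- round(stride_s * fs)
  n_bins <- floor(n / stride_n)
  times <- (seq_len(n_bins) - 0.5) * stride_s
  n_tr <- length(trials)
  per_trial <- array(NA_real_, c(n_tr, length(freqs), n_bins))
  base_pow <- matrix(NA_real_, n_tr, length(freqs))
  sigma_t <- n_cycles / (2 * pi * freqs)
  for (k in seq_len(n_tr)) {
    P <- .morlet_power(trials[[k]], fs, freqs, n_cycles, stride_s)
    for (i in seq_along(freqs)) {
      in_base <- times >= max(baseline_s[1], 3 * sigma_t[i]) &
        times < baseline_s[2]
      base_pow[k, i] <- mean(P[i, in_base])
    }
    per_trial[k, , ] <- P
  }
  B <- if (per_trial_baseline) base_pow
       else matrix(colMeans(base_pow), n_tr, length(freqs), byrow = TRUE)
  for (k in seq_len(n_tr))
    per_trial[k, , ] <- relative_power(per_trial[k, , , drop = FALSE][1, , ],
                                       B[k, ])
  values <- apply(per_trial, c(2, 3), mean)
  structure(list(times = times, freqs = freqs, values = values,
                 per_trial = per_trial, sig_mask = NULL, alpha = 0.05,
                 baseline_s = baseline_s, stride_s = stride_s,
                 n_cycles = n_cycles),
            class = "erd_map")
}

#' @export
print.erd_map <- function(x, ...) {
  cat(sprintf("ERD map: %d frequencies (%g-%g Hz) x %d time bins (stride %g ms), %d trial(s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              1000 * x$stride_s, dim(x$per_trial)[1]))
  task <- x$times >= x$baseline_s[2]
  cat(sprintf("  mean task-cell ERD: %.1f%%", mean(x$values[, task])))
  if (!is.null(x$sig_mask))
    cat(sprintf("; significant cells: %.1f%% (alpha = %g)",
                100 * mean(x$sig_mask), x$alpha))
  cat("\n")
  invisible(x)
}

#' @export
plot.erd_map <- function(x, ...) {
  image(x$times, x$freqs, t(x$values), xlab = "time (s)",
        ylab = "frequency (Hz)", col = hcl.colors(64, "Blue-Red 3"),
        main = "Relative power (%)", ...)
  invisible(x)
}

#' Bootstrap-t significance of per-trial means
#'
#' Marks a cell significant when the two-sided bootstrap-t (t-percentile)
#' confidence interval for the across-trial mean excludes zero. Trials are
#' resampled with replacement as whole units, so spatial correlation across
#' cells is preserved.
#'
#' @param values trials-by-cells numeric matrix (e.g. per-trial ERD values).
#' @param alpha significance level (CI level `1 - alpha`).
#' @param n_boot bootstrap replicates (>= 200).
#' @param seed optional seed for the resampling.
#' @return List with `mask` (logical, per cell), `ci_lo`, `ci_hi`, `mean`.
#' @export
bootstrap_significance <- function(values, alpha = 0.05, n_boot = 1000,
                                   seed = NULL) {
  .assert(is.matrix(values), "values must be a trials x cells matrix")
  n <- nrow(values)
  .assert(n >= 5, "bootstrap needs at least 5 trials")
  .assert(n_boot >= 200, "use at least 200 bootstrap replicates")
  .with_seed(seed, {
    m0 <- colMeans(values)
    v0 <- apply(values, 2, var)
    se0 <- sqrt(v0 / n)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    # resampled means / sds via one counts-matrix product per moment
    W <- matrix(0, n_boot, n)
    for (b in seq_len(n_boot)) {
      tb <- tabulate(idx[b, ], n)
      W[b, ] <- tb
    }
    W <- W / n
    M1 <- W %*% values
    M2 <- W %*% (values^2)
    Vb <- (M2 - M1^2) * n / (n - 1)
    Vb[Vb < 0] <- 0
    SE <- sqrt(Vb / n)
    Tstar <- sweep(M1, 2, m0) / SE
    Tstar[!is.finite(Tstar)] <- 0
    qs <- apply(Tstar, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                na.rm = TRUE)
    ci_lo <- m0 - qs[2, ] * se0
    ci_hi <- m0 - qs[1, ] * se0
    mask <- ci_lo > 0 | ci_hi < 0
    degen <- se0 == 0
    if (any(degen)) mask[degen] <- m0[degen] != 0
    list(mask = mask, ci_lo = ci_lo, ci_hi = ci_hi, mean = m0)
  })
}

#' Attach a bootstrap significance mask to an ERD map
#'
#' @param map an `erd_map` from [erd_time_frequency()].
#' @param alpha significance level.
#' @param n_boot bootstrap replicates.
#' @param seed optional resampling seed.
#' @return The map with `sig_mask` (freqs x times logical) and `alpha` set.
#' @export
erd_significance <- function(map, alpha = 0.05, n_boot = 1000, seed = NULL) {
  .assert(inherits(map, "erd_map"), "map must be an erd_map")
  d <- dim(map$per_trial)
  flat <- matrix(map$per_trial, d[1], d[2] * d[3])
  bs <- bootstrap_significance(flat, alpha, n_boot, seed)
  map$sig_mask <- matrix(bs$mask, d[2], d[3])
  map$alpha <- alpha
  map
}

#' Convenience ERD fit: map plus significance mask
#'
#' @inheritParams erd_time_frequency
#' @inheritParams erd_significance
#' @param ... passed to [erd_time_frequency()].
#' @return An `erd_map` with its significance mask filled in.
#' @export
erd <- function(trials, fs = NULL, channel = NULL, alpha = 0.05,
                n_boot = 1000, seed = NULL, ...) {
  map <- erd_time_frequency(trials, fs = fs, channel = channel, ...)
  erd_significance(map, alpha = alpha, n_boot = n_boot, seed = seed)
}
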