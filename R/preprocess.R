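#' Preprocessing configuration
#'
#' Parameters of the signal-conditioning stage: resampling target, band-pass
#' edges per modality, line-noise notch, amplitude-based trial rejection and
#' the subject-level rejection budget.
#'
#' `filter_order` is the effective zero-phase order: the default 8 is
#' realised as a 4th-order Butterworth applied forward-backward, which
#' squares the magnitude response (an 8th-order zero-phase magnitude).
#' `filter_mode = "double"` instead applies an 8th-order design
#' forward-backward (16th-order effective magnitude).
#'
#' @param target_fs common sampling rate (Hz) after EEG resampling.
#' @param eeg_band,emg_band band-pass edges (Hz).
#' @param notch_freq,notch_q line-noise notch centre (Hz) and quality factor
#'   (centre / -3 dB width; 25 gives about a 2 Hz notch at 50 Hz).
#' @param reject_threshold_uv absolute EEG amplitude bound (uV); any sample
#'   beyond it rejects the whole trial across modalities.
#' @param max_reject_fraction per-subject budget of rejected trials; above it
#'   the subject is flagged.
#' @param filter_order effective zero-phase order (even).
#' @param filter_mode `"effective"` (default, order/2 design run
#'   forward-backward) or `"double"` (full-order design run twice).
#' @param reject_on `"filtered"` (default; rejection inspects the filtered,
#'   re-referenced EEG) or `"raw"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_fs = 4000,
                              eeg_band = c(6, 50),
                              emg_band = c(20, 150),
                              notch_freq = 50,
                              notch_q = 25,
                              reject_threshold_uv = 350,
                              max_reject_fraction = 0.10,
                              filter_order = 8,
                              filter_mode = c("effective", "double"),
                              reject_on = c("filtered", "raw")) {
  filter_mode <- match.arg(filter_mode)
  reject_on <- match.arg(reject_on)
  for (band in list(eeg_band, emg_band))
    .assert(band[1] > 0 && band[1] < band[2] && band[2] < target_fs / 2,
            "band edges must satisfy 0 < lower < upper < target_fs/2")
  .assert(reject_threshold_uv > 0, "rejection threshold must be positive")
  .assert(filter_order %% 2 == 0 && filter_order >= 2,
          "filter_order must be an even positive integer")
  structure(list(target_fs = target_fs, eeg_band = eeg_band,
                 emg_band = emg_band, notch_freq = notch_freq,
                 notch_q = notch_q,
                 reject_threshold_uv = reject_threshold_uv,
                 max_reject_fraction = max_reject_fraction,
                 filter_order = filter_order, filter_mode = filter_mode,
                 reject_on = reject_on),
            class = "preprocess_config")
}

# ---- zero-phase filtering -------------------------------------------------

# Forward-backward application of an ARMA filter with reflective padding to
# suppress edge transients (compiled kernel).
.zerophase <- function(b, a, x) {
  zerophase_filter(b, a, x, min(length(x) - 1L, 3000L))
}

.design_bandpass <- function(band, fs, order) {
  # signal::butter doubles the order for band-pass designs
  signal::butter(order / 2, band / (fs / 2), type = "pass")
}

.design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase Butterworth band-pass or notch filtering
#'
#' Applies the filter forward and backward (zero phase). For
#' `kind = "bandpass"`, `order` is the single-pass Butterworth order; the
#' two-pass magnitude response has twice that order. For `kind = "notch"` a
#' second-order IIR notch of quality `notch_q` at `notch_freq` is used.
#'
#' @param x numeric vector, or a channels-by-samples matrix (filtered
#'   row-wise).
#' @param fs sampling rate (Hz).
#' @param band band edges (Hz) for `kind = "bandpass"`.
#' @param kind `"bandpass"` or `"notch"`.
#' @param order single-pass band-pass order (default 4, i.e. 8th-order
#'   zero-phase magnitude).
#' @param notch_freq,notch_q notch centre (Hz) and quality factor.
#' @return Filtered signal with the shape of `x`.
#' @examples
#' fs <- 500; t <- seq(0, 2, by = 1/fs)
#' y <- filter_signal(sin(2*pi*10*t), fs, band = c(6, 50))
#' @export
filter_signal <- function(x, fs, band = NULL,
                          kind = c("bandpass", "notch"),
                          order = 4, notch_freq = 50, notch_q = 25) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    .assert(!is.null(band) && band[1] > 0 && band[1] < band[2],
            "band must be increasing positive edges")
    if (band[2] >= fs / 2)
      stop("band edge at or above Nyquist frequency", call. = FALSE)
    .assert(order %% 2 == 0, "band-pass order must be even")
    flt <- .design_bandpass(band, fs, order)
    b <- flt$b; a <- flt$a
  } else {
    if (notch_freq >= fs / 2)
      stop("notch frequency at or above Nyquist", call. = FALSE)
    flt <- .design_notch(notch_freq, fs, notch_q)
    b <- flt$b; a <- flt$a
  }
  if (is.matrix(x)) {
    t(apply(x, 1, function(r) .zerophase(b, a, r)))
  } else .zerophase(b, a, x)
}

# ---- resampling -----------------------------------------------------------

# Interpolating windowed-sinc kernel (Kaiser window): h[0] = 1 and
# h[kL] = 0, so original samples are reproduced exactly at their positions.
.interp_kernel <- function(L, taps_per_side = 16, beta = 10) {
  K <- taps_per_side
  k <- seq(-K * L, K * L)
  h <- ifelse(k == 0, 1, sin(pi * k / L) / (pi * k / L))
  w <- besselI(beta * sqrt(pmax(0, 1 - (k / (K * L))^2)), 0) / besselI(beta, 0)
  h * w
}

#' Resample a trial's EEG to a higher rate
#'
#' Polyphase interpolation by an integer factor with an anti-imaging
#' windowed-sinc low-pass, so EEG and sEMG share one sampling rate. Original
#' samples are preserved exactly at their positions (the kernel is an
#' interpolating Nyquist filter), spectral content below the original
#' Nyquist is untouched, and duration is preserved.
#'
#' @param trial a `cmc_trial`.
#' @param target_fs target rate (Hz); must be an integer multiple of the
#'   trial's EEG rate.
#' @return The trial with `eeg` resampled and `fs_eeg = target_fs`.
#' @export
resample_eeg <- function(trial, target_fs) {
  .assert(inherits(trial, "cmc_trial"), "trial must be a cmc_trial")
  if (target_fs < trial$fs_eeg)
    stop("target rate below the original EEG rate", call. = FALSE)
  if (target_fs == trial$fs_eeg) return(trial)
  L <- target_fs / trial$fs_eeg
  if (abs(L - round(L)) > 1e-9)
    stop("only integer resampling ratios are supported", call. = FALSE)
  L <- as.integer(round(L))
  K <- 16L
  h <- .interp_kernel(L, K)
  up <- t(apply(trial$eeg, 1, function(r) polyphase_upsample(r, L, h, K)))
  dimnames(up) <- list(rownames(trial$eeg), NULL)
  trial$eeg <- up
  trial$fs_eeg <- target_fs
  trial
}

# ---- CAR, rejection, epoch split -----------------------------------------

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each sample's cross-channel mean becomes zero.
#'
#' @param eeg channels-by-samples numeric matrix (at least two channels).
#' @return Re-referenced matrix of the same shape.
#' @export
apply_car <- function(eeg) {
  .assert(is.matrix(eeg), "eeg must be a channels x samples matrix")
  if (nrow(eeg) < 2)
    stop("CAR is undefined for a single channel", call. = FALSE)
  sweep(eeg, 2, colMeans(eeg))
}

#' Amplitude-based trial rejection
#'
#' A trial is rejected iff any EEG sample in any channel exceeds the
#' threshold in absolute value; rejection removes the trial for EEG and sEMG
#' alike. A subject flag is raised when the rejected fraction exceeds
#' `max_fraction`.
#'
#' @param trials list of `cmc_trial`.
#' @param threshold_uv absolute amplitude bound (uV).
#' @param max_fraction subject rejection budget.
#' @return List with `trials` (retained), `rejected_trial_ids`,
#'   `subject_flag`, and `report` (data.frame: trial id, max |amplitude|,
#'   rejected flag).
#' @export
reject_trials <- function(trials, threshold_uv = 350, max_fraction = 0.10) {
  .assert(length(trials) > 0, "empty trial list")
  .assert(threshold_uv > 0, "threshold must be positive")
  mx <- vapply(trials, function(tr) max(abs(tr$eeg)), 0)
  rej <- mx > threshold_uv
  report <- data.frame(
    subject_id = vapply(trials, `[[`, "", "subject_id"),
    trial_id = vapply(trials, function(tr) tr$trial_id, 1L),
    max_abs_uv = mx, rejected = rej, stringsAsFactors = FALSE)
  list(trials = trials[!rej],
       rejected_trial_ids = report$trial_id[rej],
       subject_flag = mean(rej) > max_fraction,
       report = report)
}

#' Split a trial into baseline and task epochs
#'
#' Baseline is `[0, cue)` seconds, task is `[cue, end]`; the cut is half-open
#' so no sample belongs to both.
#'
#' @param trial a `cmc_trial`.
#' @param cue_time_s cut point (s); defaults to the trial's cue time.
#' @return List of two `cmc_trial`-like segments `baseline` and `task`.
#' @export
split_epochs <- function(trial, cue_time_s = trial$cue_time_s) {
  .assert(inherits(trial, "cmc_trial"), "trial must be a cmc_trial")
  dur <- ncol(trial$emg) / trial$fs_emg
  if (dur <= cue_time_s)
    stop("trial shorter than the cue time", call. = FALSE)
  cut_e <- floor(cue_time_s * trial$fs_eeg)   # samples with t < cue
  cut_m <- floor(cue_time_s * trial$fs_emg)
  seg <- function(ei, mi) {
    out <- trial
    out$eeg <- trial$eeg[, ei, drop = FALSE]
    out$emg <- trial$emg[, mi, drop = FALSE]
    out
  }
  list(baseline = seg(seq_len(cut_e), seq_len(cut_m)),
       task = seg(seq(cut_e + 1, ncol(trial$eeg)),
                  seq(cut_m + 1, ncol(trial$emg))))
}

.conv_poly <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1)
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' Preprocess one trial
#'
#' Fixed conditioning order: resample EEG to the target rate, common average
#' reference, band-pass (EEG and sEMG in their own bands), 50 Hz notch. The
#' band-pass and notch sections are applied as one zero-phase cascade, which
#' is algebraically identical to applying them in sequence.
#'
#' @param trial a `cmc_trial`.
#' @param config a [preprocess_config()].
#' @return The conditioned trial (class `cmc_trial`), with attribute
#'   `"raw_max_uv"` carrying the pre-filter peak amplitude.
#' @export
preprocess_trial <- function(trial, config = preprocess_config()) {
  raw_max <- max(abs(trial$eeg))
  trial <- resample_eeg(trial, config$target_fs)
  trial$eeg <- apply_car(trial$eeg)
  ord <- if (config$filter_mode == "effective") config$filter_order / 2
         else config$filter_order
  notch <- .design_notch(config$notch_freq, config$target_fs, config$notch_q)
  for (sig in c("eeg", "emg")) {
    band <- if (sig == "eeg") config$eeg_band else config$emg_band
    bp <- .design_bandpass(band, config$target_fs, ord)
    b <- .conv_poly(bp$b, notch$b)
    a <- .conv_poly(bp$a, notch$a)
    trial[[sig]] <- t(apply(trial[[sig]], 1,
                            function(r) .zerophase(b, a, r)))
  }
  attr(trial, "raw_max_uv") <- raw_max
  trial
}

#' Preprocess a session into analysis-ready epochs
#'
#' Runs the fixed pipeline resample -> CAR -> band-pass -> notch -> trial
#' rejection per subject. Rejection inspects the filtered EEG by default
#' (`config$reject_on`), and removes rejected trials from both modalities.
#'
#' @param session a `cmc_session` (or plain list of `cmc_trial`).
#' @param config a [preprocess_config()].
#' @return A `cmc_epochs`: list with `trials` (retained, conditioned),
#'   `rejection` (report data.frame), `subject_flags` (named logical), and
#'   `config`.
#' @export
preprocess_session <- function(session, config = preprocess_config()) {
  trials <- if (inherits(session, "cmc_session")) session$trials else session
  .assert(length(trials) > 0, "no trials to preprocess")
  proc <- lapply(trials, preprocess_trial, config = config)
  subj <- vapply(proc, `[[`, "", "subject_id")
  keep <- logical(length(proc))
  reports <- list()
  flags <- logical(0)
  for (s in unique(subj)) {
    i <- which(subj == s)
    if (config$reject_on == "filtered") {
      rr <- reject_trials(proc[i], config$reject_threshold_uv,
                          config$max_reject_fraction)
    } else {
      mx <- vapply(trials[i], function(tr) max(abs(tr$eeg)), 0)
      rej <- mx > config$reject_threshold_uv
      rr <- list(report = data.frame(
        subject_id = s,
        trial_id = vapply(trials[i], function(tr) tr$trial_id, 1L),
        max_abs_uv = mx, rejected = rej, stringsAsFactors = FALSE),
        subject_flag = mean(rej) > config$max_reject_fraction)
    }
    keep[i] <- !rr$report$rejected
    reports[[s]] <- rr$report
    flags[s] <- rr$subject_flag
  }
  structure(list(trials = proc[keep],
                 rejection = do.call(rbind, c(reports, make.row.names = FALSE)),
                 subject_flags = flags,
                 config = config),
            class = "cmc_epochs")
}

#' @export
print.cmc_epochs <- function(x, ...) {
  cat(sprintf("Preprocessed epochs: %d retained trial(s), %d rejected; %d flagged subject(s)\n",
              length(x$trials), sum(x$rejection$rejected),
              sum(x$subject_flags)))
  invisible(x)
}
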