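#' Specify a synthetic EEG/sEMG recording session
#'
#' Describes a trial-structured reach-grasp-lift-replace session: each trial
#' starts with a 2 s rest baseline, a visual cue, object manipulation, and an
#' object-replacement event, recorded with a small sensorimotor EEG montage
#' (500 Hz) and five upper-limb muscles (4 kHz). The generator embeds two
#' known effects so downstream estimators can be validated against ground
#' truth: a post-cue attenuation of the mu-band cortical rhythm
#' (`erd_amplitude_factor`, event-related desynchronization) and a shared
#' band-limited latent drive mixed into both modalities with a per-surface
#' gain (`coupling_gain_per_surface`, corticomuscular coupling).
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_surface trials generated per subject and surface.
#' @param surfaces contact-surface labels (experimental factor).
#' @param coupling_gain_per_surface named non-negative gains `kappa`, one per
#'   surface, scaling the shared EEG-EMG latent drive.
#' @param erd_amplitude_factor factor in (0, 1] applied to the mu-rhythm
#'   amplitude from the cue onward; 0.5 halves the amplitude, i.e. a -75%
#'   relative power change of the oscillatory component.
#' @param trial_duration_s,cue_time_s,replace_time_s trial timing in seconds;
#'   must satisfy `cue < replace < duration`.
#' @param fs_eeg,fs_emg sampling rates in Hz; `fs_emg` must be an integer
#'   multiple of `fs_eeg`.
#' @param eeg_channels,muscles channel labels.
#' @param noise_sd standard deviation (uV) of the 1/f EEG background noise.
#' @param seed integer seed making the whole session reproducible.
#' @param mu_freq,mu_amp,beta_freq,beta_amp frequency (Hz) and amplitude (uV)
#'   of the two sensorimotor rhythms.
#' @param drive_band band (Hz) of the latent coupling drive. The drive has a
#'   1/f-tilted spectrum inside the band.
#' @param drive_scale_eeg,drive_scale_emg amplitude (uV / EMG units) of the
#'   unit-variance drive as mixed into EEG and sEMG at `kappa = 1`.
#' @param muscle_gains named per-muscle multipliers on the drive; the default
#'   makes the anterior deltoid (AD) the dominant coupled muscle.
#' @param emg_activation_gain multiplicative rise of the sEMG noise envelope
#'   during the movement interval `[cue, replace]`.
#' @param subject_gain_jitter half-width of the uniform per-subject relative
#'   jitter applied to `kappa` (between-subject variance for group stats).
#'
#' @return An object of class `session_spec` (a validated list).
#' @seealso [generate_session()], [generate_trial()]
#' @examples
#' spec <- session_spec(n_subjects = 1, n_trials_per_surface = 2)
#' spec$coupling_gain_per_surface
#' @export
session_spec <- function(n_subjects = 12,
                         n_trials_per_surface = 11,
                         surfaces = c("Sandpaper", "Suede", "Silk"),
                         coupling_gain_per_surface = c(Sandpaper = 0.6,
                                                       Suede = 1.0,
                                                       Silk = 0.3),
                         erd_amplitude_factor = 0.5,
                         trial_duration_s = 10,
                         cue_time_s = 2,
                         replace_time_s = 8,
                         fs_eeg = 500,
                         fs_emg = 4000,
                         eeg_channels = c("C3", "Cz", "C4"),
                         muscles = c("AD", "B", "FD", "CED", "FDI"),
                         noise_sd = 4,
                         seed = 1L,
                         mu_freq = 10, mu_amp = 10,
                         beta_freq = 20, beta_amp = 5,
                         drive_band = c(14, 48),
                         drive_scale_eeg = 2,
                         drive_scale_emg = 1.0,
                         muscle_gains = c(AD = 2, B = 1, FD = 1,
                                          CED = 1, FDI = 1),
                         emg_activation_gain = 2,
                         subject_gain_jitter = 0.1) {
  .assert(n_subjects >= 1, "n_subjects must be >= 1")
  .assert(n_trials_per_surface >= 1, "n_trials_per_surface must be >= 1")
  .assert(length(surfaces) >= 1 && !anyDuplicated(surfaces),
          "surfaces must be distinct labels")
  .assert(all(surfaces %in% names(coupling_gain_per_surface)),
          "coupling_gain_per_surface must name every surface")
  kappa <- coupling_gain_per_surface[surfaces]
  .assert(all(kappa >= 0), "all coupling gains must be >= 0")
  .assert(erd_amplitude_factor > 0 && erd_amplitude_factor <= 1,
          "erd_amplitude_factor must be in (0, 1]")
  .assert(trial_duration_s > 0, "trial duration must be positive")
  .assert(cue_time_s < replace_time_s && replace_time_s < trial_duration_s,
          "need cue_time_s < replace_time_s < trial_duration_s")
  .assert(fs_emg %% fs_eeg == 0,
          "fs_emg must be an integer multiple of fs_eeg")
  .assert(all(muscles %in% names(muscle_gains)),
          "muscle_gains must name every muscle")
  spec <- list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_surface = as.integer(n_trials_per_surface),
    surfaces = surfaces,
    coupling_gain_per_surface = kappa,
    erd_amplitude_factor = erd_amplitude_factor,
    trial_duration_s = trial_duration_s,
    cue_time_s = cue_time_s,
    replace_time_s = replace_time_s,
    fs_eeg = fs_eeg, fs_emg = fs_emg,
    eeg_channels = eeg_channels, muscles = muscles,
    noise_sd = noise_sd, seed = as.integer(seed),
    mu_freq = mu_freq, mu_amp = mu_amp,
    beta_freq = beta_freq, beta_amp = beta_amp,
    drive_band = drive_band,
    drive_scale_eeg = drive_scale_eeg,
    drive_scale_emg = drive_scale_emg,
    muscle_gains = muscle_gains[muscles],
    emg_activation_gain = emg_activation_gain,
    subject_gain_jitter = subject_gain_jitter)
  class(spec) <- "session_spec"
  spec
}

#' @export
print.session_spec <- function(x, ...) {
  cat("Synthetic session specification\n")
  cat(sprintf("  %d subject(s) x %d surface(s) x %d trial(s) = %d trials\n",
              x$n_subjects, length(x$surfaces), x$n_trials_per_surface,
              x$n_subjects * length(x$surfaces) * x$n_trials_per_surface))
  cat(sprintf("  trial: %.1f s (cue %.1f s, replace %.1f s); EEG %g Hz, sEMG %g Hz\n",
              x$trial_duration_s, x$cue_time_s, x$replace_time_s,
              x$fs_eeg, x$fs_emg))
  cat("  coupling gains:",
      paste(sprintf("%s=%.2f", names(x$coupling_gain_per_surface),
                    x$coupling_gain_per_surface), collapse = ", "), "\n")
  invisible(x)
}

# Band-shaped Gaussian noise via spectral shaping. `gain_fn` maps frequency
# (Hz, >= 0) to an amplitude gain; output is rescaled to unit variance.
.shaped_noise <- function(n, fs, gain_fn) {
  z <- fft(rnorm(n))
  f <- c(seq(0, floor(n / 2)), seq(floor((n - 1) / 2), 1)) * fs / n
  g <- gain_fn(f)
  x <- Re(fft(z * g, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

# Smooth 0 -> 1 -> 0 gate over [t_on, t_off] with raised-cosine ramps.
.gate <- function(t, t_on, t_off, ramp = 0.25) {
  g <- numeric(length(t))
  g[t >= t_on + ramp & t <= t_off - ramp] <- 1
  i <- t >= t_on & t < t_on + ramp
  g[i] <- 0.5 * (1 - cos(pi * (t[i] - t_on) / ramp))
  i <- t > t_off - ramp & t <= t_off
  g[i] <- 0.5 * (1 - cos(pi * (t_off - t[i]) / ramp))
  g
}

# Exact bandlimited upsampling by zero-padding the spectrum (used for the
# latent drive, whose content is far below the original Nyquist).
.fft_upsample <- function(x, L) {
  n <- length(x)
  X <- fft(x)
  half <- floor(n / 2)
  XL <- complex(real = numeric(n * L))
  XL[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) XL[(n * L - half + 1):(n * L)] <- X[(n - half + 1):n]
  Re(fft(XL, inverse = TRUE)) / n   # scale by L/(n*L) = 1/n
}

#' Generate one synthetic trial
#'
#' Draws a single trial from the generative model of [session_spec()] using
#' the current RNG stream (seed it with `set.seed()` for standalone
#' reproducibility; [generate_session()] does this for you). Per channel the
#' EEG is 1/f background noise plus mu and beta oscillations - with the mu
#' amplitude multiplied by `erd_amplitude_factor` after the cue - plus
#' `kappa` times a band-limited latent drive gated to the movement interval.
#' Each muscle is band-limited (20-150 Hz) noise whose envelope ramps up
#' during the movement plus the same drive scaled by `kappa` and the
#' per-muscle gain.
#'
#' @param spec a [session_spec()].
#' @param surface one of `spec$surfaces`.
#' @param subject_id,trial_id identifiers stored in the trial.
#' @param kappa optional coupling-gain override (e.g. subject-jittered);
#'   defaults to the spec's gain for `surface`.
#' @return A `cmc_trial`: list with `eeg` (channels x samples, uV), `emg`
#'   (muscles x samples), sampling rates, cue/replace times, labels.
#' @examples
#' set.seed(1)
#' tr <- generate_trial(session_spec(), "Suede")
#' dim(tr$eeg); dim(tr$emg)
#' @export
generate_trial <- function(spec, surface, subject_id = "S01", trial_id = 1L,
                           kappa = NULL) {
  .assert(inherits(spec, "session_spec"), "spec must be a session_spec")
  if (!surface %in% spec$surfaces)
    stop("unknown surface label: ", surface, call. = FALSE)
  kappa <- kappa %||% unname(spec$coupling_gain_per_surface[surface])
  fs_e <- spec$fs_eeg; fs_m <- spec$fs_emg
  L <- fs_m / fs_e
  n_e <- round(spec$trial_duration_s * fs_e)
  n_m <- n_e * L
  t_e <- (seq_len(n_e) - 1) / fs_e
  t_m <- (seq_len(n_m) - 1) / fs_m

  # mu-rhythm amplitude envelope: 1 during baseline, erd factor after cue
  # (100 ms cosine transition)
  erd_env <- 1 + (spec$erd_amplitude_factor - 1) *
    .gate(t_e, spec$cue_time_s, spec$trial_duration_s + 1, ramp = 0.1)

  # shared latent drive at EEG rate, then exact upsample to the EMG rate
  lo <- spec$drive_band[1]; hi <- spec$drive_band[2]
  d_e <- .shaped_noise(n_e, fs_e, function(f)
    ifelse(f >= lo & f <= hi, lo / pmax(f, lo), 0))
  d_m <- .fft_upsample(d_e, L)
  gate_e <- .gate(t_e, spec$cue_time_s, spec$replace_time_s)
  gate_m <- .gate(t_m, spec$cue_time_s, spec$replace_time_s)

  eeg <- matrix(0, length(spec$eeg_channels), n_e,
                dimnames = list(spec$eeg_channels, NULL))
  for (ch in seq_len(nrow(eeg))) {
    bg <- spec$noise_sd * .shaped_noise(n_e, fs_e, function(f)
      1 / sqrt(pmax(f, 1)))
    mu <- spec$mu_amp * erd_env * sin(2 * pi * spec$mu_freq * t_e +
                                        runif(1, 0, 2 * pi))
    be <- spec$beta_amp * sin(2 * pi * spec$beta_freq * t_e +
                                runif(1, 0, 2 * pi))
    eeg[ch, ] <- bg + mu + be + kappa * spec$drive_scale_eeg * gate_e * d_e
  }

  act_env <- 1 + (spec$emg_activation_gain - 1) * gate_m
  emg <- matrix(0, length(spec$muscles), n_m,
                dimnames = list(spec$muscles, NULL))
  for (m in seq_len(nrow(emg))) {
    base <- .shaped_noise(n_e, fs_e, function(f)
      ifelse(f >= 20 & f <= 150, 1, 0))
    base <- .fft_upsample(base, L)  # bandlimited interpolation keeps unit sd
    g_m <- unname(spec$muscle_gains[spec$muscles[m]])
    emg[m, ] <- act_env * base +
      kappa * g_m * spec$drive_scale_emg * gate_m * d_m
  }

  structure(list(eeg = eeg, emg = emg, fs_eeg = fs_e, fs_emg = fs_m,
                 cue_time_s = spec$cue_time_s,
                 replace_time_s = spec$replace_time_s,
                 surface = surface, subject_id = subject_id,
                 trial_id = as.integer(trial_id)),
            class = "cmc_trial")
}

#' @export
print.cmc_trial <- function(x, ...) {
  cat(sprintf("Trial %s/%d on %s: EEG %d x %d @ %g Hz, sEMG %d x %d @ %g Hz\n",
              x$subject_id, x$trial_id, x$surface,
              nrow(x$eeg), ncol(x$eeg), x$fs_eeg,
              nrow(x$emg), ncol(x$emg), x$fs_emg))
  invisible(x)
}

#' Generate a full synthetic session with ground truth
#'
#' Generates `n_subjects x length(surfaces) x n_trials_per_surface` trials.
#' Coupling gains receive a per-subject uniform jitter
#' (`subject_gain_jitter`) so group statistics see between-subject variance.
#' Output is bit-identical for identical specs (including the seed).
#'
#' @param spec a [session_spec()].
#' @return A `cmc_session`: list with `trials` (list of `cmc_trial`),
#'   `ground_truth` (one data.frame row per trial: subject, trial, surface,
#'   kappa actually used, erd factor, coupling gate interval), and `spec`.
#' @examples
#' s <- generate_session(session_spec(n_subjects = 1, n_trials_per_surface = 2,
#'                                    trial_duration_s = 4, replace_time_s = 3))
#' length(s$trials); head(s$ground_truth)
#' @export
generate_session <- function(spec) {
  .assert(inherits(spec, "session_spec"), "spec must be a session_spec")
  .with_seed(spec$seed, {
    trials <- vector("list",
                     spec$n_subjects * length(spec$surfaces) *
                       spec$n_trials_per_surface)
    gt <- vector("list", length(trials))
    k <- 0L
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%02d", s)
      jit <- runif(length(spec$surfaces),
                   1 - spec$subject_gain_jitter,
                   1 + spec$subject_gain_jitter)
      names(jit) <- spec$surfaces
      tid <- 0L
      for (surf in spec$surfaces) {
        kap <- unname(spec$coupling_gain_per_surface[surf] * jit[surf])
        for (r in seq_len(spec$n_trials_per_surface)) {
          k <- k + 1L; tid <- tid + 1L
          trials[[k]] <- generate_trial(spec, surf, sid, tid, kappa = kap)
          gt[[k]] <- data.frame(subject_id = sid, trial_id = tid,
                                surface = surf, kappa = kap,
                                erd_amplitude_factor = spec$erd_amplitude_factor,
                                gate_start_s = spec$cue_time_s,
                                gate_end_s = spec$replace_time_s,
                                stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(trials = trials, ground_truth = do.call(rbind, gt),
                   spec = spec),
              class = "cmc_session")
  })
}

#' @export
print.cmc_session <- function(x, ...) {
  cat(sprintf("Synthetic session: %d trials, %d subject(s), surfaces: %s\n",
              length(x$trials), x$spec$n_subjects,
              paste(x$spec$surfaces, collapse = ", ")))
  invisible(x)
}

#' Export the per-trial ground-truth table
#'
#' Writes one delimited row per generated trial (subject, trial, surface,
#' coupling gain used, ERD amplitude factor, coupling gate interval).
#'
#' @param records ground-truth data.frame (`session$ground_truth`).
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
export_ground_truth <- function(records, path) {
  .assert(is.data.frame(records) && nrow(records) > 0,
          "records must be a non-empty data.frame")
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write a session to delimited text files
#'
#' One long-format CSV per subject (trial, channel, sample index, value, with
#' sampling rates and event times repeated as columns) plus the ground-truth
#' table. Intended for small sessions and interchange, not bulk storage.
#'
#' @param session a `cmc_session`.
#' @param dir output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_session <- function(session, dir) {
  .assert(inherits(session, "cmc_session"), "session must be a cmc_session")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- unique(vapply(session$trials, `[[`, "", "subject_id"))
  files <- character(0)
  for (s in subj) {
    rows <- list()
    for (tr in session$trials) {
      if (tr$subject_id != s) next
      for (sig in c("eeg", "emg")) {
        m <- tr[[sig]]
        fs <- if (sig == "eeg") tr$fs_eeg else tr$fs_emg
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = tr$trial_id, surface = tr$surface, signal = sig,
          channel = rep(rownames(m), each = ncol(m)), fs = fs,
          cue_time_s = tr$cue_time_s, replace_time_s = tr$replace_time_s,
          sample = rep(seq_len(ncol(m)), times = nrow(m)),
          value = as.vector(t(m)), stringsAsFactors = FALSE)
      }
    }
    f <- file.path(dir, paste0("session_", s, ".csv"))
    write.csv(do.call(rbind, rows), f, row.names = FALSE)
    files <- c(files, f)
  }
  gt <- file.path(dir, "ground_truth.csv")
  export_ground_truth(session$ground_truth, gt)
  invisible(c(files, gt))
}
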