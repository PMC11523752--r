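#' RMS envelope of a signal
#'
#' Root-mean-square amplitude in a sliding window (default 300 ms, 50%
#' overlap). The trailing incomplete window is dropped, so the number of
#' values depends only on signal length, window and overlap.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return An `envelope_series`: list with `times` (window centres, s) and
#'   `rms` (non-negative amplitudes).
#' @examples
#' env <- rms_envelope(sin(2*pi*50*seq(0, 1.2, by = 1/4000)), 4000)
#' length(env$rms)
#' @export
rms_envelope <- function(x, fs, window_s = 0.3, overlap = 0.5) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin)
    stop("signal shorter than one window", call. = FALSE)
  hop <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  rms <- vapply(starts, function(s) sqrt(mean(x[s:(s + nwin - 1)]^2)), 0)
  structure(list(times = (starts - 1 + nwin / 2) / fs, rms = rms,
                 window_s = window_s, overlap = overlap),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("RMS envelope: %d windows of %g ms (%.0f%% overlap), mean %.3g\n",
              length(x$rms), 1000 * x$window_s, 100 * x$overlap,
              mean(x$rms)))
  invisible(x)
}

#' @export
plot.envelope_series <- function(x, ...) {
  plot(x$times, x$rms, type = "l", xlab = "time (s)", ylab = "RMS", ...)
  invisible(x)
}

#' Muscle-activation summary with surface comparison
#'
#' Computes the task-segment RMS envelope per trial and muscle (mean over
#' windows), tabulates mean activation per muscle and surface, and compares
#' surfaces within each muscle with [compare_groups()] (two-sample t-test
#' for two surfaces, one-way ANOVA with Bonferroni post-hoc otherwise).
#'
#' @param epochs a `cmc_epochs` from [preprocess_session()].
#' @param window_s,overlap RMS envelope parameters.
#' @param normality normality check handed to the group test
#'   (Kolmogorov-Smirnov here, matching the activation analysis).
#' @return An `activation_summary`: list with `table` (subject, trial,
#'   surface, muscle, rms), `means` (muscle x surface), and `tests` (one
#'   `cmc_group_test` per muscle).
#' @export
summarize_activation <- function(epochs, window_s = 0.3, overlap = 0.5,
                                 normality = "ks") {
  .assert(inherits(epochs, "cmc_epochs"), "epochs must be a cmc_epochs")
  rows <- lapply(epochs$trials, function(tr) {
    task <- split_epochs(tr)$task
    data.frame(subject = tr$subject_id, trial = tr$trial_id,
               surface = tr$surface,
               muscle = rownames(task$emg),
               rms = apply(task$emg, 1, function(x)
                 mean(rms_envelope(x, tr$fs_emg, window_s, overlap)$rms)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  surfaces <- unique(tab$surface)
  .assert(length(surfaces) >= 2, "need at least two surfaces")
  .assert(all(table(tab$surface, tab$muscle) >= 2),
          "need at least two trials per surface")
  means <- tapply(tab$rms, list(tab$muscle, tab$surface), mean)
  tests <- lapply(split(tab, tab$muscle), function(d)
    compare_groups(d$rms, d$surface, normality = normality))
  structure(list(table = tab, means = means, tests = tests),
            class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat("Muscle activation (mean task RMS):\n")
  print(round(x$means, 3))
  p <- vapply(x$tests, function(t) t$omnibus$p, 0)
  cat("Surface-effect p per muscle:\n")
  print(round(p, 4))
  invisible(x)
}
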