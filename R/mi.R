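#' Optimal histogram bin count for one analysis window
#'
#' Bin count from the window's range, standard deviation and sample count:
#' `bins = (max - min) / (3.5 * sd * n^(-1/3))`, rounded to the nearest
#' integer and clamped to `[1, 256]`. A constant window (zero range or SD)
#' yields a single bin. With `rule = "fd"` the denominator uses twice the
#' interquartile range instead of `3.5 * sd` (the Freedman-Diaconis width).
#'
#' @param x numeric samples of one window (n >= 2).
#' @param rule `"scott"` (default, SD-based width) or `"fd"` (IQR-based).
#' @return Integer bin count.
#' @examples
#' optimal_bins(seq(0, 7, length.out = 1000) * 1)  # range/sd fixed by data
#' @export
optimal_bins <- function(x, rule = c("scott", "fd")) {
  rule <- match.arg(rule)
  n <- length(x)
  if (n == 0) stop("empty window", call. = FALSE)
  if (n < 2) return(1L)
  rng <- max(x) - min(x)
  width <- switch(rule,
                  scott = 3.5 * sd(x) * n^(-1 / 3),
                  fd = 2 * stats::IQR(x) * n^(-1 / 3))
  if (rng == 0 || width == 0 || !is.finite(width)) return(1L)
  as.integer(min(256, max(1, round(rng / width))))
}

# Bin index per sample on equal-width edges over [min, max]; last bin is
# right-closed so every sample lands in exactly one bin.
.bin_index <- function(x, n_bins) {
  if (n_bins <= 1) return(rep(1L, length(x)))
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  i <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1
  i[i > n_bins] <- n_bins
  as.integer(i)
}

.entropy_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Histogram entropy in bits
#'
#' Shannon entropy of the equal-width histogram of `x` with `n_bins` bins
#' spanning the sample range; probabilities are bin counts over the total
#' count, and `0 * log2(0)` is taken as 0. Bounded by `log2(n_bins)`.
#'
#' @param x numeric samples.
#' @param n_bins number of bins (defaults to [optimal_bins()]).
#' @return Entropy in bits.
#' @export
entropy_hist <- function(x, n_bins = optimal_bins(x)) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  .assert(n_bins >= 1, "n_bins must be >= 1")
  .entropy_counts(tabulate(.bin_index(x, n_bins), n_bins))
}

#' Joint histogram entropy in bits
#'
#' Entropy of the 2-D histogram of `(x, y)` on each signal's own equal-width
#' edges (`m_bins` for `x`, `n_bins` for `y`).
#'
#' @param x,y equal-length numeric samples.
#' @param m_bins,n_bins bin counts per signal.
#' @return Joint entropy in bits.
#' @export
joint_entropy_hist <- function(x, y, m_bins = optimal_bins(x),
                               n_bins = optimal_bins(y)) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ix <- .bin_index(x, m_bins)
  iy <- .bin_index(y, n_bins)
  .entropy_counts(tabulate((ix - 1L) * n_bins + iy, m_bins * n_bins))
}

#' Histogram mutual information in bits
#'
#' `MI = H(X) + H(Y) - H(X, Y)` with all three entropies computed from one
#' joint histogram (marginals are the joint's margins), which guarantees
#' `MI >= 0` and `MI(x, x) = H(x)` exactly. Windows are compared at zero
#' lag.
#'
#' @param x,y equal-length numeric samples.
#' @param bins_x,bins_y bin counts (default [optimal_bins()] per signal).
#' @return Mutual information in bits.
#' @examples
#' x <- rnorm(1000)
#' mutual_information(x, x) == entropy_hist(x)
#' @export
mutual_information <- function(x, y, bins_x = optimal_bins(x),
                               bins_y = optimal_bins(y)) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ix <- .bin_index(x, bins_x)
  iy <- .bin_index(y, bins_y)
  joint <- tabulate((ix - 1L) * bins_y + iy, bins_x * bins_y)
  jm <- matrix(joint, bins_x, bins_y, byrow = TRUE)
  hx <- .entropy_counts(rowSums(jm))
  hy <- .entropy_counts(colSums(jm))
  hxy <- .entropy_counts(joint)
  max(0, hx + hy - hxy)
}

#' Windowed mutual-information time course for one channel-muscle pair
#'
#' Splits the trial into adjacent (non-overlapping) windows from `t = 0`,
#' selects a bin count per signal and window, and computes the histogram
#' mutual information in each window. Both signals must share one sampling
#' rate (run [preprocess_session()] first).
#'
#' @param trial a preprocessed `cmc_trial` with `fs_eeg == fs_emg`.
#' @param eeg_channel,muscle labels selecting the pair.
#' @param window_s window length (s), default 100 ms.
#' @return An `mi_timecourse`: list with `times` (window centres), `mi`
#'   (bits), pair labels and trial identifiers.
#' @export
mi_timecourse <- function(trial, eeg_channel, muscle, window_s = 0.1) {
  .assert(inherits(trial, "cmc_trial"), "trial must be a cmc_trial")
  if (trial$fs_eeg != trial$fs_emg)
    stop("signals must share one sampling rate; preprocess first",
         call. = FALSE)
  x <- trial$eeg[eeg_channel, ]
  y <- trial$emg[muscle, ]
  fs <- trial$fs_emg
  nwin <- round(window_s * fs)
  if (length(y) < nwin)
    stop("trial shorter than one window", call. = FALSE)
  n_windows <- floor(length(y) / nwin)
  mi <- numeric(n_windows)
  for (k in seq_len(n_windows)) {
    i <- ((k - 1) * nwin + 1):(k * nwin)
    mi[k] <- mutual_information(x[i], y[i])
  }
  structure(list(times = (seq_len(n_windows) - 0.5) * window_s, mi = mi,
                 eeg_channel = eeg_channel, muscle = muscle,
                 surface = trial$surface, subject_id = trial$subject_id,
                 trial_id = trial$trial_id, window_s = window_s),
            class = "mi_timecourse")
}

#' @export
print.mi_timecourse <- function(x, ...) {
  cat(sprintf("MI time course %s-%s (%s): %d windows of %g ms, mean %.3f bits\n",
              x$eeg_channel, x$muscle, x$surface, length(x$mi),
              1000 * x$window_s, mean(x$mi)))
  invisible(x)
}

#' @export
plot.mi_timecourse <- function(x, ...) {
  plot(x$times, x$mi, type = "l", xlab = "time (s)", ylab = "MI (bits)",
       main = paste(x$eeg_channel, x$muscle, sep = "-"), ...)
  invisible(x)
}

#' Session-level mutual-information table
#'
#' Computes the windowed MI for every (channel, muscle) pair of every
#' retained trial, averages across trials and then across EEG channels, and
#' returns the tidy time course per subject, surface and muscle together
#' with the across-trial standard deviation. Bin indices per signal and
#' window are computed once and shared across pairs.
#'
#' @param epochs a `cmc_epochs`.
#' @param channels,muscles label subsets (default: all present).
#' @param window_s window length (s).
#' @return A `cmc_mi` data.frame: subject, surface, muscle, time, mi, sd.
#' @export
mi_session <- function(epochs, channels = NULL, muscles = NULL,
                       window_s = 0.1) {
  .assert(inherits(epochs, "cmc_epochs"), "epochs must be a cmc_epochs")
  .assert(length(epochs$trials) > 0, "no retained trials")
  tr1 <- epochs$trials[[1]]
  channels <- channels %||% rownames(tr1$eeg)
  muscles <- muscles %||% rownames(tr1$emg)
  per_trial <- lapply(epochs$trials, function(tr) {
    fs <- tr$fs_emg
    nwin <- round(window_s * fs)
    n_windows <- floor(ncol(tr$emg) / nwin)
    # cache bin indices and counts per signal and window
    idx_of <- function(x) {
      lapply(seq_len(n_windows), function(k) {
        xi <- x[((k - 1) * nwin + 1):(k * nwin)]
        nb <- optimal_bins(xi)
        list(i = .bin_index(xi, nb), nb = nb)
      })
    }
    eeg_idx <- lapply(channels, function(ch) idx_of(tr$eeg[ch, ]))
    emg_idx <- lapply(muscles, function(m) idx_of(tr$emg[m, ]))
    mi <- array(0, c(length(channels), length(muscles), n_windows))
    for (a in seq_along(channels)) for (b in seq_along(muscles)) {
      for (k in seq_len(n_windows)) {
        ex <- eeg_idx[[a]][[k]]; my <- emg_idx[[b]][[k]]
        joint <- tabulate((ex$i - 1L) * my$nb + my$i, ex$nb * my$nb)
        jm <- matrix(joint, ex$nb, my$nb, byrow = TRUE)
        mi[a, b, k] <- max(0, .entropy_counts(rowSums(jm)) +
                             .entropy_counts(colSums(jm)) -
                             .entropy_counts(joint))
      }
    }
    list(subject = tr$subject_id, surface = tr$surface, mi = mi,
         times = (seq_len(n_windows) - 0.5) * window_s)
  })
  keys <- data.frame(subject = vapply(per_trial, `[[`, "", "subject"),
                     surface = vapply(per_trial, `[[`, "", "surface"),
                     stringsAsFactors = FALSE)
  out <- list()
  for (g in unique(paste(keys$subject, keys$surface, sep = "\r"))) {
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    sel <- which(keys$subject == parts[1] & keys$surface == parts[2])
    arrs <- lapply(per_trial[sel], `[[`, "mi")
    times <- per_trial[[sel[1]]]$times
    # trial average, then channel average (means commute on complete data)
    tr_mean <- Reduce(`+`, arrs) / length(arrs)
    ch_mean <- apply(tr_mean, c(2, 3), mean)
    # across-trial SD of the channel-averaged series
    ch_series <- vapply(arrs, function(a) apply(a, c(2, 3), mean),
                        matrix(0, length(muscles), length(times)))
    sd_mat <- apply(ch_series, c(1, 2), sd)
    for (m in seq_along(muscles)) {
      out[[length(out) + 1L]] <- data.frame(
        subject = parts[1], surface = parts[2], muscle = muscles[m],
        time = times, mi = ch_mean[m, ], sd = sd_mat[m, ],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("cmc_mi", "data.frame")
  res
}

#' @export
print.cmc_mi <- function(x, ...) {
  cat(sprintf("MI time courses: %d rows (%d muscle(s), %d surface(s))\n",
              nrow(x), length(unique(x$muscle)),
              length(unique(x$surface))))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' @export
plot.cmc_mi <- function(x, surface = NULL, ...) {
  surface <- surface %||% x$surface[1]
  d <- x[x$surface == surface, ]
  agg <- aggregate(mi ~ muscle + time, data = d, FUN = mean)
  wide <- stats::reshape(agg, idvar = "time", timevar = "muscle",
                         direction = "wide")
  wide <- wide[order(wide$time), ]
  matplot(wide$time, as.matrix(wide[, -1]), type = "l", lty = 1,
          xlab = "time (s)", ylab = "MI (bits)", main = surface, ...)
  legend("topright", legend = sub("^mi\\.", "", names(wide)[-1]),
         col = seq_len(ncol(wide) - 1), lty = 1, cex = 0.8)
  invisible(x)
}
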