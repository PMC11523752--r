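#' Matched EEG frequency grid for power-based connectivity
#'
#' The sEMG spectral feature vector is fixed at 20-150 Hz in 3 Hz steps
#' (points 20, 23, ..., 149; MBL = 44). To correlate an EEG band's spectrum
#' against it, the EEG feature vector must have the same length, so the EEG
#' band (native 1 Hz resolution, EBL integer frequencies) is re-gridded to
#' the matched resolution `FR = (EBL - 1) / (MBL - 1)`: MBL evenly spaced
#' frequencies spanning the band. For the beta band (14-30 Hz, EBL = 17)
#' this gives FR = 16/43 = 0.372..., displayed as 0.37 Hz.
#'
#' @param band a [band_definition()] within the filtered EEG range.
#' @param emg_range,emg_res sEMG grid span (Hz) and step (Hz).
#' @return A `frequency_grid`: list with `band`, `EBL`, `MBL`, `FR`,
#'   `FR_display` (2-decimal rounding), `points` (EEG grid, Hz) and
#'   `emg_points` (sEMG grid, Hz).
#' @examples
#' matched_resolution(band_definition("beta", 14, 30))$FR_display  # 0.37
#' @export
matched_resolution <- function(band, emg_range = c(20, 150), emg_res = 3) {
  .assert(inherits(band, "band_definition"),
          "band must be a band_definition")
  emg_points <- seq(emg_range[1], emg_range[2], by = emg_res)
  MBL <- length(emg_points)
  EBL <- floor(band$f_hi) - ceiling(band$f_lo) + 1
  if (EBL < 2)
    stop("degenerate band: fewer than two native frequencies", call. = FALSE)
  FR <- (EBL - 1) / (MBL - 1)
  structure(list(band = band, EBL = EBL, MBL = MBL, FR = FR,
                 FR_display = round(FR, 2),
                 points = band$f_lo + (seq_len(MBL) - 1) * FR,
                 emg_points = emg_points),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("matched grid for %s (%g-%g Hz): EBL = %d, MBL = %d, FR = %.4f Hz (%.2f)\n",
              x$band$name, x$band$f_lo, x$band$f_hi, x$EBL, x$MBL, x$FR,
              x$FR_display))
  invisible(x)
}

#' Interpolate a PSD onto a frequency grid
#'
#' Linear interpolation of a natively sampled PSD onto `points`; exact for
#' affine spectra and non-negativity preserving.
#'
#' @param freqs native frequency axis (Hz).
#' @param psd native PSD values.
#' @param grid a `frequency_grid` or a numeric vector of target frequencies.
#' @return Interpolated values, one per grid point.
#' @export
regrid_psd <- function(freqs, psd, grid) {
  pts <- if (inherits(grid, "frequency_grid")) grid$points else grid
  if (min(pts) < min(freqs) || max(pts) > max(freqs))
    stop("grid extends outside the native frequency support", call. = FALSE)
  approx(freqs, psd, xout = pts)$y
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`. A constant vector cannot be scaled; it maps to
#' all zeros with a warning.
#'
#' @param x numeric vector, length >= 2.
#' @return Values in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(x) {
  .assert(length(x) >= 2, "need at least two values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant vector: min-max normalization undefined, returning zeros")
    return(numeric(length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Spearman correlation between two spectral feature vectors
#'
#' Rank correlation of the two equal-length feature vectors, with a
#' one-sided p-value for the hypothesis that the connectivity is greater
#' than zero (t approximation on the rank correlation). Vectors with all
#' values tied have undefined rank correlation and come back flagged.
#'
#' @param eeg_features,emg_features equal-length numeric vectors.
#' @return List with `rho`, `p` (one-sided, rho > 0), `n`, and `flag`
#'   (`NA_character_` or `"constant"`).
#' @examples
#' pbc_spearman(1:5, c(3, 1, 2, 5, 4))$rho  # 0.6
#' @export
pbc_spearman <- function(eeg_features, emg_features) {
  n <- length(eeg_features)
  if (n != length(emg_features))
    stop("feature vectors must have equal length", call. = FALSE)
  if (sd(eeg_features) == 0 || sd(emg_features) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "constant"))
  rho <- cor(eeg_features, emg_features, method = "spearman")
  p <- if (abs(rho) >= 1) {
    if (rho > 0) 0 else 1
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    pt(tstat, n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n, flag = NA_character_)
}

#' Normality check of spectral features
#'
#' One-sample Kolmogorov-Smirnov test of each feature set against a normal
#' distribution (standardised by the sample mean and SD). When any set
#' rejects normality, the report recommends rank (Spearman) correlation for
#' the connectivity estimate.
#'
#' @param features numeric vector, matrix (columns are feature sets) or list
#'   of numeric vectors; each set needs >= 20 samples.
#' @param alpha rejection level.
#' @return List with `report` (set, n, statistic, p, flag) and
#'   `recommendation` (`"spearman"` or `"pearson"`).
#' @export
normality_check <- function(features, alpha = 0.05) {
  sets <- if (is.list(features)) features
          else if (is.matrix(features)) asplit(features, 2)
          else list(features)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  rows <- lapply(names(sets), function(nm) {
    x <- as.numeric(sets[[nm]])
    .assert(length(x) >= 20, "each feature set needs at least 20 samples")
    if (sd(x) == 0)
      return(data.frame(set = nm, n = length(x), statistic = NA_real_,
                        p = NA_real_, flag = "degenerate",
                        stringsAsFactors = FALSE))
    kt <- suppressWarnings(ks.test((x - mean(x)) / sd(x), "pnorm"))
    data.frame(set = nm, n = length(x), statistic = unname(kt$statistic),
               p = kt$p.value, flag = NA_character_,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  reject <- any(report$p < alpha, na.rm = TRUE) | any(!is.na(report$flag))
  list(report = report,
       recommendation = if (reject) "spearman" else "pearson")
}

#' Power-based connectivity estimate
#'
#' For every retained trial, the task-segment Welch PSD (1 s Hamming
#' windows, 50% overlap) of each EEG channel is re-gridded per band onto the
#' matched-resolution grid of [matched_resolution()], min-max normalised,
#' and rank-correlated against the equally normalised sEMG feature vector
#' (20-150 Hz at 3 Hz) of each muscle. One record per (trial, channel,
#' muscle, band) with the Spearman coefficient and its one-sided p-value.
#'
#' @param epochs a `cmc_epochs` from [preprocess_session()].
#' @param bands named list of [band_definition()]s (default [cmc_bands()]).
#' @param emg_range,emg_res sEMG feature grid parameters.
#' @param window_s,overlap Welch parameters.
#' @param analysis_fs rate (Hz) at which the Welch features are computed.
#'   Both conditioned signals are band-limited well below 250 Hz, so they
#'   are first decimated to this rate (when it divides the sampling rate),
#'   which leaves the PSD features unchanged and saves most of the FFT
#'   work. Use `NULL` to stay at the native rate.
#' @return A `cmc_pbc`: data.frame with columns subject, trial, surface,
#'   eeg_channel, muscle, band, rho, p, flag.
#' @export
pbc <- function(epochs, bands = cmc_bands(), emg_range = c(20, 150),
                emg_res = 3, window_s = 1, overlap = 0.5,
                analysis_fs = 500) {
  .assert(inherits(epochs, "cmc_epochs"), "epochs must be a cmc_epochs")
  .assert(length(epochs$trials) > 0, "no retained trials")
  grids <- lapply(bands, matched_resolution, emg_range = emg_range,
                  emg_res = emg_res)
  maybe_decimate <- function(x, fs) {
    if (!is.null(analysis_fs) && fs > analysis_fs &&
        fs %% analysis_fs == 0 && analysis_fs > 2 * emg_range[2]) {
      list(x = x[seq(1, length(x), by = fs / analysis_fs)],
           fs = analysis_fs)
    } else list(x = x, fs = fs)
  }
  recs <- vector("list", length(epochs$trials))
  for (k in seq_along(epochs$trials)) {
    tr <- epochs$trials[[k]]
    task <- split_epochs(tr)$task
    emg_feat <- apply(task$emg, 1, function(x) {
      d <- maybe_decimate(x, tr$fs_emg)
      w <- welch_psd(d$x, d$fs, window_s, overlap)
      suppressWarnings(minmax_normalize(regrid_psd(w$freqs, w$psd,
                                                   grids[[1]]$emg_points)))
    })  # MBL x muscles
    eeg_w <- lapply(seq_len(nrow(task$eeg)), function(ch) {
      d <- maybe_decimate(task$eeg[ch, ], tr$fs_eeg)
      welch_psd(d$x, d$fs, window_s, overlap)
    })
    chn <- rownames(task$eeg); mus <- rownames(task$emg)
    nrec <- length(bands) * length(chn) * length(mus)
    rho <- p <- numeric(nrec)
    flag <- character(nrec)
    bnd <- chv <- muv <- character(nrec)
    j <- 0L
    for (b in names(bands)) {
      for (ch in seq_along(chn)) {
        ef <- suppressWarnings(minmax_normalize(
          regrid_psd(eeg_w[[ch]]$freqs, eeg_w[[ch]]$psd, grids[[b]])))
        for (m in seq_along(mus)) {
          sp <- pbc_spearman(ef, emg_feat[, m])
          j <- j + 1L
          rho[j] <- sp$rho; p[j] <- sp$p; flag[j] <- sp$flag
          bnd[j] <- b; chv[j] <- chn[ch]; muv[j] <- mus[m]
        }
      }
    }
    recs[[k]] <- data.frame(
      subject = tr$subject_id, trial = tr$trial_id, surface = tr$surface,
      eeg_channel = chv, muscle = muv, band = bnd, rho = rho, p = p,
      flag = flag, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(recs, make.row.names = FALSE))
  class(res) <- c("cmc_pbc", "data.frame")
  attr(res, "bands") <- bands
  res
}

#' @export
print.cmc_pbc <- function(x, ...) {
  cat(sprintf("Power-based connectivity: %d records (%d trial(s), bands: %s)\n",
              nrow(x), length(unique(paste(x$subject, x$trial))),
              paste(unique(x$band), collapse = ", ")))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' @export
summary.cmc_pbc <- function(object, ...) {
  agg <- aggregate(rho ~ surface + band, data = object, FUN = mean,
                   na.rm = TRUE)
  names(agg)[3] <- "mean_rho"
  agg
}

#' Aggregate connectivity records
#'
#' Subject-level aggregation modes used by the group studies:
#' `per_channel` averages over muscles (and trials) per EEG channel, band,
#' surface and subject; `per_muscle` averages over EEG channels per muscle;
#' `per_pair` keeps each (channel, muscle) pair in the broadband ("all")
#' band, averaged over trials.
#'
#' @param records a `cmc_pbc` (or compatible data.frame).
#' @param mode aggregation mode.
#' @return Data.frame with a `rho` column of aggregated coefficients.
#' @export
pbc_aggregate <- function(records,
                          mode = c("per_channel", "per_muscle", "per_pair")) {
  mode <- match.arg(mode)
  .assert(nrow(records) > 0, "no records to aggregate")
  df <- as.data.frame(records)
  df <- df[!is.na(df$rho), ]
  switch(mode,
    per_channel = aggregate(rho ~ subject + surface + band + eeg_channel,
                            data = df, FUN = mean),
    per_muscle = aggregate(rho ~ subject + surface + band + muscle,
                           data = df, FUN = mean),
    per_pair = {
      d <- df[df$band == "all", ]
      .assert(nrow(d) > 0, "per_pair mode needs broadband ('all') records")
      aggregate(rho ~ subject + surface + eeg_channel + muscle,
                data = d, FUN = mean)
    })
}
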