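#' Standard 16-channel montage labels
#'
#' The 16 scalp positions of the international 10-20 system used throughout:
#' Fp1, Fp2, F3, F4, C3, C4, P3, P4, O1, O2, F7, F8, Fz, Pz, T5, T6.
#' @return character vector of length 16.
#' @export
montage_16 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "Fz", "Pz", "T5", "T6")
}

#' Canonical EEG frequency bands
#'
#' delta 2-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-60 Hz.
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low = c(2, 4, 8, 13, 30),
    high = c(4, 8, 13, 30, 60),
    stringsAsFactors = FALSE
  )
}

#' Construct a multichannel recording
#'
#' @param samples channels x time numeric matrix (rows are channels).
#' @param sampling_rate Hz (> 0).
#' @param channel_labels one label per row; default [montage_16()].
#' @param group `"younger"` or `"older"` (or `NA` for unlabeled data).
#' @param subject_id identifier string.
#' @return object of class `eeg_recording`.
#' @export
new_recording <- function(samples, sampling_rate,
                          channel_labels = montage_16(),
                          group = NA_character_, subject_id = "subject") {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channel_labels)) {
    stop("row count (", nrow(samples), ") must equal number of channel labels (",
         length(channel_labels), ")")
  }
  if (!all(is.finite(samples))) stop("samples must all be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0")
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels, group = group,
         subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @exportS3Method base::print
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id,
      if (!is.na(x$group)) paste0(" (", x$group, ")"), "\n",
      "  ", nrow(x$samples), " channels x ", ncol(x$samples), " samples @ ",
      x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

new_epoch <- function(samples, sampling_rate, origin, purpose) {
  structure(
    list(samples = as.matrix(samples), sampling_rate = sampling_rate,
         origin = origin, purpose = purpose),
    class = "analysis_epoch"
  )
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`)
#' per channel, so the passband phase is preserved — a prerequisite for
#' meaningful Hilbert phase differences downstream. Length is unchanged.
#'
#' @param recording an `eeg_recording` (or plain matrix with attribute-free
#'   rows = channels together with `sampling_rate`).
#' @param low,high band edges in Hz, `0 < low < high < sampling_rate / 2`.
#' @param order filter order (default 4).
#' @param sampling_rate required if `recording` is a bare matrix.
#' @return same type as the input, filtered.
#' @export
bandpass <- function(recording, low, high, order = 4L, sampling_rate = NULL) {
  is_rec <- inherits(recording, "eeg_recording") ||
    inherits(recording, "analysis_epoch")
  samples <- if (is_rec) recording$samples else as.matrix(recording)
  fs <- if (is_rec) recording$sampling_rate else sampling_rate
  if (is.null(fs)) stop("`sampling_rate` required for a bare matrix")
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("`high` (", high, " Hz) must be below Nyquist (",
                           fs / 2, " Hz)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(samples, 1, function(ch) signal::filtfilt(bf, ch)))
  if (is_rec) {
    recording$samples <- out
    rownames(recording$samples) <- rownames(samples)
    recording
  } else {
    out
  }
}

#' Select the central complexity epoch of a 60-s recording
#'
#' The analysis epoch is the first 60 s (12,000 samples at 200 Hz) of the
#' recording; the first and last 5 s (1,000 samples each) are removed to
#' discard filter transients, leaving the central 50 s (10,000 samples) on
#' which multifractal and entropy analyses run.
#'
#' @param recording an `eeg_recording`, already bandpass filtered.
#' @return an `analysis_epoch` with exactly `50 * sampling_rate` samples and
#'   purpose `"complexity"`.
#' @export
trim_select <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  n_epoch <- round(60 * fs)
  n_trim <- round(5 * fs)
  if (ncol(recording$samples) < n_epoch) {
    stop("recording has ", ncol(recording$samples),
         " samples; need at least ", n_epoch, " (60 s at ", fs, " Hz)")
  }
  idx <- (n_trim + 1):(n_epoch - n_trim) # 0-based [n_trim, n_epoch - n_trim)
  new_epoch(recording$samples[, idx, drop = FALSE], fs,
            origin = list(subject_id = recording$subject_id,
                          start_sample = n_trim),
            purpose = "complexity")
}

#' Partition the complexity epoch into connectivity epochs
#'
#' The 50-s epoch is split into 10 contiguous non-overlapping 5-s epochs
#' (1,000 samples each at 200 Hz); phase-lag index is computed per epoch and
#' averaged, balancing epoch-length bias against slow-band coverage.
#'
#' @param epoch a `"complexity"` `analysis_epoch`.
#' @param n_segments number of segments (default 10).
#' @return list of `analysis_epoch` objects with purpose `"pli"`.
#' @export
segment_for_pli <- function(epoch, n_segments = 10L) {
  stopifnot(inherits(epoch, "analysis_epoch"))
  n <- ncol(epoch$samples)
  if (n %% n_segments != 0) {
    stop("epoch length ", n, " not divisible into ", n_segments, " segments")
  }
  expected <- round(50 * epoch$sampling_rate)
  if (n != expected) {
    stop("expected a ", expected, "-sample complexity epoch, got ", n)
  }
  len <- n %/% n_segments
  lapply(seq_len(n_segments) - 1L, function(k) {
    new_epoch(epoch$samples[, (k * len + 1):((k + 1) * len), drop = FALSE],
              epoch$sampling_rate,
              origin = list(subject_id = epoch$origin$subject_id,
                            start_sample = epoch$origin$start_sample + k * len),
              purpose = "pli")
  })
}

#' Decompose an epoch into canonical frequency bands
#'
#' Zero-phase Butterworth bandpass per band applied to the (already
#' broadband-filtered) epoch; one same-length band-limited copy per band.
#'
#' @param epoch an `analysis_epoch`.
#' @param bands data.frame as from [eeg_bands()].
#' @return named list of `analysis_epoch`, one per band.
#' @export
band_decompose <- function(epoch, bands = eeg_bands()) {
  stopifnot(inherits(epoch, "analysis_epoch"))
  if (any(bands$high >= epoch$sampling_rate / 2)) {
    stop("band upper edge at or above Nyquist")
  }
  out <- lapply(seq_len(nrow(bands)), function(i) {
    bandpass(epoch, bands$low[i], bands$high[i])
  })
  names(out) <- bands$name
  out
}

#' Standardize a series to zero mean and unit SD
#'
#' @param x numeric series with non-zero variance.
#' @return standardized series.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant (or degenerate) series")
  }
  (x - mean(x)) / s
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed segments of `window_sec`
#' seconds with 50% overlap.
#'
#' @param x numeric series.
#' @param sampling_rate Hz.
#' @param window_sec segment length in seconds (default 2).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, sampling_rate, window_sec = 2) {
  nw <- round(window_sec * sampling_rate)
  if (length(x) < nw) stop("series shorter than one Welch window")
  step <- nw %/% 2
  starts <- seq(1, length(x) - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1)) # Hann
  norm <- sum(w^2) * sampling_rate
  nf <- nw %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 / norm
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and (for even nw) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1; if (nw %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * sampling_rate / nw, psd = psd * dbl)
}

#' Relative band power per channel
#'
#' Band power as a fraction of the total broadband (2-60 Hz) power, from the
#' Welch PSD integrated with the trapezoid rule. Used as the ANCOVA
#' covariate (gamma relative power averaged over electrodes).
#'
#' @param epoch an `analysis_epoch` (>= 2 s of data).
#' @param band single-row data.frame with `low`, `high` (Hz), e.g. one row of
#'   [eeg_bands()].
#' @param total_range broadband reference range, default `c(2, 60)` Hz.
#' @return named numeric vector in `[0, 1]`, one fraction per channel.
#' @export
relative_band_power <- function(epoch, band, total_range = c(2, 60)) {
  stopifnot(inherits(epoch, "analysis_epoch"))
  fs <- epoch$sampling_rate
  if (ncol(epoch$samples) < 2 * fs) stop("epoch must cover at least 2 s")
  trapz_band <- function(freq, psd, lo, hi) {
    sel <- freq >= lo & freq <= hi
    f <- freq[sel]; p <- psd[sel]
    if (length(f) < 2) return(0)
    sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  }
  out <- apply(epoch$samples, 1, function(ch) {
    sp <- welch_psd(ch, fs)
    total <- trapz_band(sp$freq, sp$psd, total_range[1], total_range[2])
    if (total <= 0) stop("zero total power in reference range")
    trapz_band(sp$freq, sp$psd, band$low[1], band$high[1]) / total
  })
  stats::setNames(pmin(pmax(out, 0), 1), rownames(epoch$samples))
}
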