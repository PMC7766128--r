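## Triple eye-blink (TEB) brain switch: prefrontal preprocessing (FP1/FP2
## average, 2-15 Hz zero-phase IIR, undecimated biorthogonal-wavelet
## enhancement of the blink scales, Hilbert amplitude envelope), threshold
## calibration, peak counting, and sliding-window detection (1.6 s window,
## 0.4 s shift, event on exactly three supra-threshold peaks).

## bior1.5 analysis filter pair (standard published coefficients;
## decomposition lowpass is the 10-tap symmetric spline filter, highpass
## the 2-tap Haar-like filter).
.bior15_dec_lo <- c(0.01657281518405971, -0.01657281518405971,
                    -0.12153397801643787, 0.12153397801643787,
                    0.7071067811865476, 0.7071067811865476,
                    0.12153397801643787, -0.12153397801643787,
                    -0.01657281518405971, 0.01657281518405971)
.bior15_dec_hi <- c(0, 0, 0, 0, -0.7071067811865476, 0.7071067811865476,
                    0, 0, 0, 0)

#' TEB detector configuration
#'
#' @param bandpass prefrontal IIR bandpass edges (Hz), default 2-15.
#' @param order Butterworth order of that filter.
#' @param wavelet_range frequency range (Hz) whose undecimated wavelet
#'   detail levels are reconstructed to enlarge the blink pulse.
#' @param window_s,shift_s detection window geometry (1.6 s / 0.4 s).
#' @param min_gap_s minimum inter-peak separation inside a window.
#' @param rel_prominence fraction of the strongest peak in a window that
#'   any counted peak must reach; suppresses the small ringing satellites
#'   of a large blink, which scale with its amplitude and can otherwise
#'   clear an absolute threshold.
#' @param refractory_s suppression after a detection, so one physical
#'   triple blink is reported once.
#' @param threshold_mult robust-sigma multiplier of the calibration rule
#'   (threshold = median + mult * MAD of the baseline envelope).
#' @param smooth_s moving-average length of the rectified envelope.
#' @return object of class \code{blink_detector_config}.
#' @export
blink_detector_config <- function(bandpass = c(2, 15), order = 4,
                                  wavelet_range = c(2, 8),
                                  window_s = 1.6, shift_s = 0.4,
                                  min_gap_s = 0.15, rel_prominence = 0.4,
                                  refractory_s = 2,
                                  threshold_mult = 4, smooth_s = 0.05) {
  if (window_s <= 3 * min_gap_s)
    stop("window must exceed 3x the minimum inter-peak gap")
  structure(list(bandpass = bandpass, order = order,
                 wavelet_range = wavelet_range, window_s = window_s,
                 shift_s = shift_s, min_gap_s = min_gap_s,
                 rel_prominence = rel_prominence,
                 refractory_s = refractory_s,
                 threshold_mult = threshold_mult, smooth_s = smooth_s),
            class = "blink_detector_config")
}

## which undecimated-transform levels have pseudo-bands
## [fs/2^(j+1), fs/2^j] centred inside `range`
.wavelet_levels <- function(fs, range) {
  j <- 1:12
  ctr <- sqrt((fs / 2^(j + 1)) * (fs / 2^j))
  out <- j[ctr >= range[1] & ctr <= range[2]]
  if (!length(out)) stop("no wavelet level falls in the requested range")
  out
}

#' Undecimated wavelet detail reconstruction (zero phase)
#'
#' A-trous cascade with the bior1.5 analysis pair, evaluated in the
#' frequency domain; each level's detail is reconstructed with the
#' time-reversed cascade so the net response is zero phase (squared
#' magnitude of the level's transfer function).  The selected levels'
#' details are summed.
#'
#' @param x numeric signal; @param fs sampling rate; @param levels which
#'   decomposition levels to keep.
#' @return filtered signal, same length as x.
#' @export
swt_detail <- function(x, fs, levels) {
  n <- length(x)
  h <- .bior15_dec_lo / sqrt(2)     # DC gain 1
  g <- .bior15_dec_hi / sqrt(2)
  dft_up <- function(f, m) {        # DFT of the filter upsampled by m
    Hf <- stats::fft(c(f, rep(0, n - length(f))))
    Hf[(((0:(n - 1)) * m) %% n) + 1]
  }
  X <- stats::fft(x)
  resp <- rep(0 + 0i, n)
  for (j in levels) {
    C <- dft_up(g, 2^(j - 1))
    if (j > 1)
      for (l in 1:(j - 1)) C <- C * dft_up(h, 2^(l - 1))
    resp <- resp + Mod(C)^2
  }
  Re(stats::fft(X * resp, inverse = TRUE)) / n
}

#' Prefrontal blink-enhancement preprocessing
#'
#' Averages FP1 and FP2, applies the 2-15 Hz zero-phase IIR bandpass,
#' reconstructs the undecimated-wavelet detail scales covering the blink
#' frequencies, and returns the lightly smoothed analytic-signal
#' (Hilbert) amplitude envelope.
#'
#' @param rec an \code{eeg_recording} containing FP1 and FP2.
#' @param config a \code{blink_detector_config}.
#' @return numeric envelope (one value per sample).
#' @export
frontal_preprocess <- function(rec, config = blink_detector_config()) {
  if (!all(c("FP1", "FP2") %in% rec$channels))
    stop("recording lacks FP1/FP2")
  s <- colMeans(rec$data[c("FP1", "FP2"), , drop = FALSE])
  flt <- butter_bandpass(config$bandpass[1], config$bandpass[2], rec$fs,
                         config$order)
  s <- filtfilt(s, flt)
  lv <- .wavelet_levels(rec$fs, config$wavelet_range)
  s <- swt_detail(s, rec$fs, lv)
  env <- hilbert_envelope(s)
  k <- max(1L, round(config$smooth_s * rec$fs))
  if (k > 1)
    env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  env
}

#' Calibrate the detection threshold from a blink-free baseline
#'
#' Robust rule: median + \code{threshold_mult} * MAD (scaled, i.e.
#' 1.4826 * median absolute deviation) of the baseline envelope.
#'
#' @param baseline an \code{eeg_recording} (>= 30 s) without deliberate
#'   blinks; @param config detector configuration.
#' @return positive scalar threshold.
#' @export
calibrate_threshold <- function(baseline, config = blink_detector_config()) {
  if (recording_duration(baseline) < 30)
    stop("baseline must be at least 30 s (got ",
         round(recording_duration(baseline), 1), " s)")
  env <- frontal_preprocess(baseline, config)
  stats::median(env) + config$threshold_mult * stats::mad(env)
}

#' Count supra-threshold peaks in a window
#'
#' Counts local maxima of the envelope that exceed the threshold and
#' dominate their neighborhood: a peak is suppressed when any stronger
#' local maximum (supra-threshold or not) lies within the minimum
#' inter-peak gap.  Neighborhood dominance -- rather than greedy removal --
#' keeps the filter-ringing satellites of one physical blink from being
#' counted as separate peaks, while blinks a natural inter-blink interval
#' apart remain distinct.
#'
#' @param x envelope window; @param threshold detection threshold;
#' @param fs sampling rate; @param min_gap_s minimum separation (s);
#' @param rel_prominence relative floor vs the strongest window peak.
#' @return integer peak count (attribute \code{"peaks"}: sample indices).
#' @export
count_peaks <- function(x, threshold, fs, min_gap_s = 0.15,
                        rel_prominence = 0.4) {
  n <- length(x)
  if (n < 3) return(structure(0L, peaks = integer(0)))
  i <- 2:(n - 1)
  pk <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]      # all local maxima
  if (!length(pk)) return(structure(0L, peaks = integer(0)))
  gap <- round(min_gap_s * fs)
  dominant <- vapply(seq_along(pk), function(j) {
    nb <- pk[abs(pk - pk[j]) < gap & pk != pk[j]]
    all(x[nb] < x[pk[j]] | (x[nb] == x[pk[j]] & nb > pk[j]))
  }, TRUE)
  floor_ <- max(threshold, rel_prominence * max(x[pk]))
  keep <- pk[dominant & x[pk] > floor_]
  structure(length(keep), peaks = keep)
}

#' Detect deliberate triple eye-blinks
#'
#' Slides a 1.6 s window by 0.4 s over the preprocessed envelope and emits
#' a TEB event whenever exactly three supra-threshold peaks fall inside a
#' window; further detections are suppressed for the refractory period.
#'
#' @param x an \code{eeg_recording}, or a numeric envelope already produced
#'   by [frontal_preprocess()] (then \code{fs} must be given).
#' @param threshold calibrated threshold from [calibrate_threshold()].
#' @param config detector configuration; @param fs sampling rate when
#'   \code{x} is an envelope.
#' @return data frame: \code{time_s} (window end), \code{n_peaks},
#'   \code{peak1_s}, \code{peak2_s}, \code{peak3_s}, \code{amplitude}.
#' @export
detect_teb <- function(x, threshold, config = blink_detector_config(),
                       fs = NULL) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    env <- frontal_preprocess(x, config)
  } else {
    if (is.null(fs)) stop("fs required when passing a raw envelope")
    env <- x
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("detect_teb needs a calibrated positive threshold")
  w <- round(config$window_s * fs); s <- round(config$shift_s * fs)
  n <- length(env)
  ends <- if (n >= w) seq(w, n, by = s) else integer(0)
  out <- list()
  last <- -Inf
  for (e in ends) {
    t_end <- e / fs
    if (t_end < last + config$refractory_s) next
    win <- env[(e - w + 1):e]
    cnt <- count_peaks(win, threshold, fs, config$min_gap_s,
                       config$rel_prominence)
    if (as.integer(cnt) == 3L) {
      pk <- (attr(cnt, "peaks") + e - w) / fs
      out[[length(out) + 1]] <-
        data.frame(time_s = t_end, n_peaks = 3L,
                   peak1_s = pk[1], peak2_s = pk[2], peak3_s = pk[3],
                   amplitude = max(win))
      last <- t_end
    }
  }
  if (!length(out))
    return(data.frame(time_s = numeric(0), n_peaks = integer(0),
                      peak1_s = numeric(0), peak2_s = numeric(0),
                      peak3_s = numeric(0), amplitude = numeric(0)))
  do.call(rbind, out)
}
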