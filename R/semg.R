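# Surface-EMG processing: zero-phase Butterworth band-pass (20-500 Hz) with
# a 50 Hz mains notch, moving-RMS envelope (66.7 ms window), normalisation
# to %MVC against maximal-voluntary-contraction recordings, and rank
# correlation of measured vs predicted activity.

#' Construct an EMG trace
#'
#' @param samples numeric vector, arbitrary amplitude units.
#' @param sampling_rate Hz (study hardware: 1500 Hz).
#' @param muscle muscle label.
#' @param side `"left"` or `"right"`.
#' @return object of class `emg_trace`.
#' @export
emg_trace <- function(samples, sampling_rate = 1500,
                      muscle = NA_character_, side = c("left", "right")) {
  side <- match.arg(side)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    stop_vecforce("samples must be finite", "validation_error")
  if (sampling_rate <= 0)
    stop_vecforce("sampling_rate must be > 0", "parameter_error")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 muscle = muscle, side = side),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> %s (%s), %d samples @ %g Hz\n",
              x$muscle, x$side, length(x$samples), x$sampling_rate))
  invisible(x)
}

# Biquad mains notch (RBJ cookbook): centre w0, quality factor Q.
notch_coefs <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter an EMG trace
#'
#' Zero-phase (forward-backward) Butterworth band-pass of prototype order
#' `order` per edge, followed by a zero-phase 50 Hz biquad notch
#' (Q = 30). Zero-phase filtering preserves envelope timing; length is
#' preserved.
#'
#' @param trace an [emg_trace()].
#' @param band passband edges in Hz, default `c(20, 500)`.
#' @param notch mains frequency in Hz (NULL to skip).
#' @param order Butterworth prototype order (default 4).
#' @param notch_q notch quality factor.
#' @return the filtered [emg_trace()].
#' @export
filter_emg <- function(trace, band = c(20, 500), notch = 50, order = 4,
                       notch_q = 30) {
  fs <- trace$sampling_rate
  nyq <- fs / 2
  if (band[2] >= nyq || band[1] <= 0 || band[1] >= band[2])
    stop_vecforce("band edges must satisfy 0 < low < high < Nyquist",
                  "parameter_error")
  bf <- signal::butter(order, band / nyq, type = "pass")
  y <- signal::filtfilt(bf, trace$samples)
  if (!is.null(notch)) {
    if (notch >= nyq) stop_vecforce("notch must be below Nyquist", "parameter_error")
    nc <- notch_coefs(notch, fs, notch_q)
    y <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), y)
  }
  emg_trace(y, fs, trace$muscle, trace$side)
}

#' Moving-RMS envelope
#'
#' Centred sliding root-mean-square with the study's 66.7 ms window
#' (100 samples at 1500 Hz); at the edges the window is truncated to the
#' available samples.
#'
#' @param trace an [emg_trace()] (or numeric vector plus `sampling_rate`).
#' @param window_s window duration in seconds.
#' @param sampling_rate used when `trace` is a bare numeric vector.
#' @return numeric envelope, same length as the input.
#' @export
moving_rms <- function(trace, window_s = 0.0667, sampling_rate = NULL) {
  if (inherits(trace, "emg_trace")) {
    x <- trace$samples; fs <- trace$sampling_rate
  } else {
    x <- as.numeric(trace)
    if (is.null(sampling_rate))
      stop_vecforce("sampling_rate required for bare vectors", "parameter_error")
    fs <- sampling_rate
  }
  w <- round(window_s * fs)
  if (w < 2) stop_vecforce("window must span >= 2 samples", "parameter_error")
  n <- length(x)
  if (w > n) stop_vecforce("window longer than trace", "parameter_error")
  half_l <- floor((w - 1) / 2)
  half_r <- w - 1 - half_l
  cs <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Normalise a trial envelope to %MVC
#'
#' The normalisation denominator is the largest peak across the MVC
#' repetition envelopes (the study records three). The trial is reduced by
#' `stat` -- the envelope mean over the trial by default, or its peak.
#'
#' @param trial_envelope numeric envelope of the trial.
#' @param mvc_envelopes list of numeric envelopes of the MVC repetitions.
#' @param stat `"mean"` or `"peak"` reduction of the trial envelope.
#' @param muscle optional label.
#' @return object of class `activity_value`: list with `muscle`,
#'   `percent_mvc`, `stat`, `mvc_peak`.
#' @export
percent_mvc <- function(trial_envelope, mvc_envelopes,
                        stat = c("mean", "peak"), muscle = NA_character_) {
  stat <- match.arg(stat)
  if (!length(mvc_envelopes))
    stop_vecforce("at least one MVC envelope required", "input_error")
  if (is.numeric(mvc_envelopes)) mvc_envelopes <- list(mvc_envelopes)
  denom <- max(vapply(mvc_envelopes, max, numeric(1)))
  if (denom <= 0)
    stop_vecforce("MVC peak is zero: cannot normalise", "degenerate_error")
  v <- if (stat == "mean") mean(trial_envelope) else max(trial_envelope)
  structure(list(muscle = muscle, percent_mvc = 100 * v / denom,
                 stat = stat, mvc_peak = denom),
            class = "activity_value")
}

#' @export
print.activity_value <- function(x, ...) {
  cat(sprintf("<activity_value> %s: %.2f %%MVC (%s of envelope)\n",
              x$muscle, x$percent_mvc, x$stat))
  invisible(x)
}

#' Spearman correlation of measured vs predicted activity
#'
#' Rank correlation with ties mid-ranked, the comparison used to confront
#' measured %MVC with model-predicted muscle activity.
#'
#' @param measured,predicted paired numeric vectors, n >= 3.
#' @return correlation in \[-1, 1\].
#' @export
spearman_activity <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop_vecforce("series must be paired", "input_error")
  if (length(measured) < 3)
    stop_vecforce("need n >= 3 pairs", "input_error")
  if (sd(measured) == 0 || sd(predicted) == 0)
    stop_vecforce("constant series: Spearman correlation undefined",
                  "undefined_correlation_error")
  cor(measured, predicted, method = "spearman")
}

#' Read multi-channel EMG from CSV
#'
#' One column per channel, header row with muscle labels.
#'
#' @param path CSV path.
#' @param sampling_rate Hz.
#' @return named list of [emg_trace()]s.
#' @export
read_emg_csv <- function(path, sampling_rate = 1500) {
  df <- read.csv(path, check.names = FALSE)
  out <- lapply(names(df), function(nm)
    emg_trace(df[[nm]], sampling_rate, muscle = nm))
  names(out) <- names(df)
  out
}
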