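#' Construct a chin-EMG signal
#'
#' An `emg_signal` is a uniformly sampled EMG trace in microvolts with its
#' sampling rate, channel label and recording-relative start time. It is the
#' input container for the RWA pipeline; the submentalis (chin) derivation is
#' the standard channel for REM-atonia work.
#'
#' @param samples Numeric vector of amplitudes in microvolts (µV).
#' @param rate Sampling frequency in Hz (> 0).
#' @param label Channel label, e.g. `"Chin1-Chin2"`.
#' @param start_time Recording-relative origin in seconds (default 0).
#' @return An object of class `emg_signal`.
#' @examples
#' sig <- emg_signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 256)), rate = 256)
#' duration(sig)
#' @export
emg_signal <- function(samples, rate, label = "EMG", start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("`samples` must contain at least one value")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)")
  }
  structure(
    list(
      samples = samples,
      rate = as.numeric(rate),
      label = as.character(label),
      start_time = as.numeric(start_time)
    ),
    class = "emg_signal"
  )
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf(
    "<emg_signal> %s: %d samples @ %g Hz (%.1f s), start %g s\n",
    x$label, length(x$samples), x$rate, duration(x), x$start_time
  ))
  invisible(x)
}

#' Signal duration in seconds
#' @param sig An [emg_signal()].
#' @return Duration in seconds (`n / rate`).
#' @export
duration <- function(sig) {
  stopifnot(inherits(sig, "emg_signal"))
  length(sig$samples) / sig$rate
}

#' Sample times of a signal
#' @param sig An [emg_signal()].
#' @return Numeric vector of times (seconds from recording start) at which the
#'   samples lie; sample `i` covers the half-open interval
#'   `[t_i, t_i + 1/rate)`.
#' @export
sample_times <- function(sig) {
  stopifnot(inherits(sig, "emg_signal"))
  sig$start_time + (seq_along(sig$samples) - 1L) / sig$rate
}

#' Resample a signal to a new rate
#'
#' Band-limited rational resampling (polyphase FIR, via the signal package).
#' Duration is preserved to within one sample period. Resampling to the
#' signal's own rate returns the signal unchanged.
#'
#' @param sig An [emg_signal()].
#' @param target_rate Target sampling frequency in Hz.
#' @return An [emg_signal()] at `target_rate`.
#' @export
resample_signal <- function(sig, target_rate) {
  stopifnot(inherits(sig, "emg_signal"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stop("`target_rate` must be a single positive number (Hz)")
  }
  if (isTRUE(all.equal(target_rate, sig$rate))) {
    return(sig)
  }
  frac <- .rat(target_rate / sig$rate)
  y <- signal::resample(sig$samples, p = frac$p, q = frac$q, d = 20)
  # signal::resample can come back a sample short/long of n * p / q
  n_target <- round(length(sig$samples) * target_rate / sig$rate)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(y[length(y)], n_target - length(y)))
  emg_signal(y, rate = target_rate, label = sig$label, start_time = sig$start_time)
}

# Small-denominator rational approximation of a rate ratio.
.rat <- function(x, max_den = 4096L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  list(p = as.integer(p1), q = as.integer(q1))
}

#' Band-pass and notch pre-filtering for chin EMG
#'
#' Standard chin-EMG conditioning before envelope extraction: 4th-order
#' Butterworth band-pass (zero-phase, applied forward and backward) plus an
#' optional 2nd-order band-stop around the mains frequency.
#'
#' @param sig An [emg_signal()].
#' @param low,high Band edges in Hz (defaults 10 and 100). `high` is reduced
#'   to 95% of Nyquist when the sampling rate is too low to accommodate it.
#' @param notch Mains frequency to suppress in Hz (default 50); `NULL` or `NA`
#'   disables the notch.
#' @param order Butterworth order of the band-pass prototype (default 4).
#' @return The filtered [emg_signal()].
#' @export
preprocess_emg <- function(sig, low = 10, high = 100, notch = 50, order = 4) {
  stopifnot(inherits(sig, "emg_signal"))
  nyq <- sig$rate / 2
  hi <- min(high, 0.95 * nyq)
  if (low >= hi) stop("band-pass edges do not fit below Nyquist")
  bp <- signal::butter(order / 2, c(low, hi) / nyq, type = "pass")
  x <- .filtfilt_padded(bp, sig$samples)
  if (!is.null(notch) && !is.na(notch) && notch < 0.95 * nyq) {
    bs <- signal::butter(1, c(notch - 2, notch + 2) / nyq, type = "stop")
    x <- .filtfilt_padded(bs, x)
  }
  emg_signal(x, rate = sig$rate, label = sig$label, start_time = sig$start_time)
}

# Zero-phase filtering with reflective edge padding to tame filtfilt edge
# transients on short signals.
.filtfilt_padded <- function(flt, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * 30L) # ~3 filter lengths
  if (pad < 1L) {
    return(as.numeric(signal::filtfilt(flt, x)))
  }
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - (1:pad)])
  y <- as.numeric(signal::filtfilt(flt, xp))
  y[(pad + 1L):(pad + n)]
}
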