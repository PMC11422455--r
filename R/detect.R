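#' Detection configuration for the automatic RWA algorithm
#'
#' Bundles the factors of the motor-activity detector. The defaults are the
#' factor combination with the best reported discrimination between RBD and
#' controls: moving-window baseline, motor activity detection threshold (MADT)
#' at 4 times baseline, minimum event duration 0.3 s, inter-event interval
#' (IEI) 0.5 s, no event exclusions, and scoring on 3-s mini-epochs.
#'
#' @param window_samples Odd width (samples) of the sliding amplitude-curve
#'   window (default 51; about 0.2 s at the canonical 256 Hz).
#' @param madt_factor Threshold as a multiple of the adaptive baseline
#'   (default 4).
#' @param min_event_s Minimum motor-activity-event duration in seconds
#'   (default 0.3), applied after IEI merging.
#' @param iei_s Inter-event interval in seconds (default 0.5); events closer
#'   than this are merged into one.
#' @param mini_epoch_s Mini-epoch length in seconds (default 3).
#' @param occupancy_threshold Fraction of a mini-epoch that events must
#'   strictly exceed for the mini-epoch to count positive (default 0.5).
#' @param baseline_window_s Length of the centered moving window for the
#'   baseline percentile, in seconds (default 30).
#' @param baseline_percentile Percentile of the amplitude curve used as
#'   baseline (default 5).
#' @param baseline_floor_uv Lower clamp on the baseline in µV (default 0.5);
#'   prevents zero thresholds on idealized noise-free signals.
#' @param baseline_cap_ratio Upper clamp on the moving baseline, as a multiple
#'   of the whole-recording `baseline_percentile` of the amplitude curve
#'   (default 2). Guards against baseline inflation when sustained muscle
#'   activity fills the moving window; `Inf` disables the cap.
#' @param baseline_stride_s Grid step (s) at which the moving percentile is
#'   evaluated before linear interpolation (default 0.25); set to `1/rate`
#'   for an exact per-sample baseline.
#' @param exclusions Event-exclusion rule; only `"none"` is defined (the
#'   best-performing factor level), the argument is a hook for artifact-based
#'   exclusion schemes.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(window_samples = 51L,
                             madt_factor = 4,
                             min_event_s = 0.3,
                             iei_s = 0.5,
                             mini_epoch_s = 3,
                             occupancy_threshold = 0.5,
                             baseline_window_s = 30,
                             baseline_percentile = 5,
                             baseline_floor_uv = 0.5,
                             baseline_cap_ratio = 2,
                             baseline_stride_s = 0.25,
                             exclusions = "none") {
  window_samples <- as.integer(window_samples)
  vals <- c(
    window_samples, madt_factor, min_event_s, iei_s, mini_epoch_s,
    occupancy_threshold, baseline_window_s, baseline_percentile,
    baseline_floor_uv, baseline_cap_ratio, baseline_stride_s
  )
  if (any(!is.finite(vals[-10]) | vals[-10] <= 0)) {
    stop("all detection parameters must be positive")
  }
  if (occupancy_threshold >= 1) stop("`occupancy_threshold` must be in (0, 1)")
  if (window_samples %% 2L == 0L) stop("`window_samples` must be odd")
  exclusions <- match.arg(exclusions, "none")
  structure(
    list(
      window_samples = window_samples, madt_factor = madt_factor,
      min_event_s = min_event_s, iei_s = iei_s, mini_epoch_s = mini_epoch_s,
      occupancy_threshold = occupancy_threshold,
      baseline_window_s = baseline_window_s,
      baseline_percentile = baseline_percentile,
      baseline_floor_uv = baseline_floor_uv,
      baseline_cap_ratio = baseline_cap_ratio,
      baseline_stride_s = baseline_stride_s,
      exclusions = exclusions
    ),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Amplitude curve of an EMG signal
#'
#' The amplitude curve (AC) is the peak-to-peak range (max minus min) of the
#' band-pass-filtered EMG within a sliding window centered on each sample
#' (default 51 samples); windows are truncated at the signal edges. The AC is
#' the envelope on which baseline estimation and event detection operate.
#'
#' @param sig A band-pass filtered [emg_signal()] (see [preprocess_emg()]).
#' @param cfg A [detection_config()].
#' @return An `amplitude_curve`: list with `values` (µV, one per sample),
#'   `rate`, `start_time`.
#' @export
compute_amplitude_curve <- function(sig, cfg = detection_config()) {
  stopifnot(inherits(sig, "emg_signal"), inherits(cfg, "detection_config"))
  n <- length(sig$samples)
  if (n < cfg$window_samples) {
    stop(sprintf(
      "signal too short: %d samples < %d-sample amplitude window",
      n, cfg$window_samples
    ))
  }
  structure(
    list(
      values = rolling_range(sig$samples, cfg$window_samples),
      rate = sig$rate,
      start_time = sig$start_time
    ),
    class = "amplitude_curve"
  )
}

#' @export
print.amplitude_curve <- function(x, ...) {
  cat(sprintf(
    "<amplitude_curve> %d samples @ %g Hz, median %.2f uV\n",
    length(x$values), x$rate, stats::median(x$values)
  ))
  invisible(x)
}

#' Adaptive baseline of an amplitude curve
#'
#' The baseline tracks the atonia floor through the night: a low percentile
#' (default the 5th) of the amplitude curve over a centered moving window
#' (default 30 s), clamped from below at `baseline_floor_uv` and from above
#' at `baseline_cap_ratio` times the whole-recording percentile, so that
#' dense sustained muscle activity cannot drag the detection threshold up to
#' its own level.
#'
#' @param ac An `amplitude_curve` from [compute_amplitude_curve()].
#' @param cfg A [detection_config()].
#' @return A `baseline_curve` on the same grid (list with `values`, `rate`,
#'   `start_time`).
#' @export
estimate_baseline <- function(ac, cfg = detection_config()) {
  stopifnot(inherits(ac, "amplitude_curve"), inherits(cfg, "detection_config"))
  n <- length(ac$values)
  if (n == 0L) stop("empty amplitude curve")
  width <- max(1L, as.integer(round(cfg$baseline_window_s * ac$rate)))
  if (width %% 2L == 0L) width <- width + 1L
  p <- cfg$baseline_percentile / 100
  stride <- max(1L, as.integer(round(cfg$baseline_stride_s * ac$rate)))
  at <- unique(c(seq(1L, n, by = stride), n))
  vals_at <- rolling_quantile_at(ac$values, width, p, as.integer(at))
  base <- if (length(at) == n) {
    vals_at
  } else {
    stats::approx(at, vals_at, xout = seq_len(n), rule = 2)$y
  }
  if (is.finite(cfg$baseline_cap_ratio)) {
    global_ref <- stats::quantile(ac$values, p, names = FALSE, type = 7)
    base <- pmin(base, cfg$baseline_cap_ratio * global_ref)
  }
  base <- pmax(base, cfg$baseline_floor_uv)
  structure(
    list(values = base, rate = ac$rate, start_time = ac$start_time),
    class = "baseline_curve"
  )
}

#' Detect motor activity events (MAEs)
#'
#' A sample is supra-threshold when the amplitude curve strictly exceeds
#' `madt_factor` times the baseline. Maximal supra-threshold runs become
#' candidate events; candidates separated by gaps shorter than `iei_s` are
#' merged; merged events shorter than `min_event_s` are dropped. No further
#' exclusions are applied (`exclusions = "none"`).
#'
#' @param ac An `amplitude_curve`.
#' @param base A `baseline_curve` on the same sampling grid.
#' @param cfg A [detection_config()].
#' @return A tibble of events with columns `start`, `end` (seconds, half-open
#'   intervals, sorted, disjoint, each at least `min_event_s` long, gaps at
#'   least `iei_s`).
#' @export
detect_events <- function(ac, base, cfg = detection_config()) {
  stopifnot(inherits(ac, "amplitude_curve"), inherits(base, "baseline_curve"))
  if (length(ac$values) != length(base$values) ||
      abs(ac$rate - base$rate) > 1e-9) {
    stop("amplitude curve and baseline must share one sampling grid")
  }
  above <- ac$values > cfg$madt_factor * base$values
  runs <- .runs_to_intervals(above, ac$rate, ac$start_time)
  merged <- merge_events(runs, iei_s = cfg$iei_s)
  keep <- (merged$end - merged$start) >= cfg$min_event_s
  out <- merged[keep, , drop = FALSE]
  tibble::as_tibble(out)
}

# logical vector -> tibble of half-open [start, end) intervals of TRUE runs
.runs_to_intervals <- function(flag, rate, start_time = 0) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(
    start = start_time + starts[keep] / rate,
    end = start_time + ends[keep] / rate
  )
}

#' Merge events closer than the inter-event interval
#'
#' Consecutive events whose gap is strictly smaller than `iei_s` are fused
#' into a single event; the operation is idempotent.
#'
#' @param events Tibble/data frame with `start`, `end` (sorted, disjoint).
#' @param iei_s Minimum inter-event interval in seconds.
#' @return A tibble with `start`, `end`.
#' @export
merge_events <- function(events, iei_s) {
  events <- tibble::as_tibble(events)[, c("start", "end")]
  n <- nrow(events)
  if (n <= 1L) return(events)
  if (is.unsorted(events$start)) events <- events[order(events$start), ]
  start <- events$start
  end <- events$end
  out_s <- numeric(n); out_e <- numeric(n)
  k <- 1L
  out_s[1] <- start[1]; out_e[1] <- end[1]
  for (i in 2:n) {
    if (start[i] - out_e[k] < iei_s) {
      out_e[k] <- max(out_e[k], end[i])
    } else {
      k <- k + 1L
      out_s[k] <- start[i]
      out_e[k] <- end[i]
    }
  }
  tibble::tibble(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

#' Score 3-s mini-epochs against detected events
#'
#' Each 30-s staging epoch is tiled by `epoch_len / mini_epoch_s` mini-epochs
#' (ten by default) inheriting the epoch's stage. A mini-epoch's occupancy is
#' the total event time overlapping it divided by the mini-epoch length; it is
#' positive when occupancy strictly exceeds the occupancy threshold ("more
#' than 50%" under the defaults).
#'
#' @param events Event tibble from [detect_events()].
#' @param hyp A [hypnogram()].
#' @param cfg A [detection_config()].
#' @return A tibble with `start`, `stage`, `occupancy`, `positive`.
#' @export
score_mini_epochs <- function(events, hyp, cfg = detection_config()) {
  stopifnot(inherits(hyp, "hypnogram"))
  per_epoch <- as.integer(round(hyp$epoch_len / cfg$mini_epoch_s))
  if (per_epoch < 1L) stop("mini-epoch longer than the staging epoch")
  n_mini <- length(hyp$stages) * per_epoch
  start <- (seq_len(n_mini) - 1L) * cfg$mini_epoch_s
  stage <- rep(hyp$stages, each = per_epoch)
  occ <- numeric(n_mini)
  if (!is.null(events) && nrow(events) > 0L) {
    occ <- .interval_overlap(start, start + cfg$mini_epoch_s,
                             events$start, events$end) / cfg$mini_epoch_s
  }
  tibble::tibble(
    start = start,
    stage = stage,
    occupancy = occ,
    positive = occ > cfg$occupancy_threshold
  )
}

# total overlap of each query interval [qs, qe) with the union of the
# (sorted, disjoint) reference intervals [rs, re)
.interval_overlap <- function(qs, qe, rs, re) {
  vapply(seq_along(qs), function(i) {
    sum(pmax(0, pmin(qe[i], re) - pmax(qs[i], rs)))
  }, 1)
}

#' Automatic RWA score
#'
#' The fraction of REM 3-s mini-epochs in which motor activity events occupy
#' more than half of the mini-epoch: 0 means complete muscle atonia during
#' REM, 1 complete absence of atonia.
#'
#' @param minis Mini-epoch tibble from [score_mini_epochs()].
#' @return A single number in \[0, 1\].
#' @export
automatic_rwa <- function(minis) {
  rem <- minis[minis$stage == "REM", , drop = FALSE]
  if (nrow(rem) == 0L) stop("no REM sleep in recording")
  sum(rem$positive) / nrow(rem)
}

#' Per-stage motor-activity metrics
#'
#' For each requested stage: the percentage of its mini-epochs that are
#' positive, the total duration of motor activity events intersecting the
#' stage (seconds), and that duration as a percentage of time spent in the
#' stage. `NREM` is the union of S1, S2 and S3. Stages absent from the
#' hypnogram yield zeros and are flagged.
#'
#' @param events Event tibble from [detect_events()].
#' @param hyp A [hypnogram()].
#' @param cfg A [detection_config()].
#' @param stages Stage codes to summarise (default REM, S1--S3 and NREM).
#' @param minis Optional precomputed mini-epoch tibble (recomputed otherwise).
#' @return A tibble with `stage`, `pct_miniepochs`, `duration_s`,
#'   `pct_duration`, `present`.
#' @export
stage_metrics <- function(events, hyp, cfg = detection_config(),
                          stages = c("REM", "S1", "S2", "S3", "NREM"),
                          minis = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (is.null(minis)) minis <- score_mini_epochs(events, hyp, cfg)
  purrr::map_dfr(stages, function(stg) {
    codes <- if (identical(stg, "NREM")) c("S1", "S2", "S3") else stg
    total_s <- stage_seconds(hyp, stg)
    if (total_s == 0) {
      # absent stage: zeros, flagged by present = FALSE
      return(tibble::tibble(
        stage = stg, pct_miniepochs = 0, duration_s = 0, pct_duration = 0,
        present = FALSE
      ))
    }
    m <- minis[minis$stage %in% codes, , drop = FALSE]
    iv <- stage_intervals(hyp, stg)
    dur <- if (is.null(events) || nrow(events) == 0L) 0 else {
      sum(.interval_overlap(iv$start, iv$end, events$start, events$end))
    }
    tibble::tibble(
      stage = stg,
      pct_miniepochs = 100 * sum(m$positive) / nrow(m),
      duration_s = dur,
      pct_duration = 100 * dur / total_s,
      present = TRUE
    )
  })
}
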