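#' Configuration of the visual-scoring emulation
#'
#' Rule-based emulation of human tonic/phasic/any RWA scoring in the
#' SINBAR tradition: phasic bursts are 0.1--5 s excursions above twice the
#' local background, a 30-s REM epoch is tonic when elevated tone covers more
#' than half of it, and "any" is the union of phasic- and tonic-qualifying
#' activity on 3-s mini-epochs. This emulates the published *rules*, not any
#' individual human scorer.
#'
#' @param phasic_min_s,phasic_max_s Burst duration window in seconds
#'   (defaults 0.1 and 5).
#' @param amp_ratio Amplitude threshold as a multiple of the local background
#'   (default 2).
#' @param tonic_epoch_fraction Fraction of a 30-s epoch that elevated tone
#'   must exceed for a tonic call (default 0.5).
#' @param background_window_s Window (s) for the background level (default
#'   30): the 5th percentile of a rolling-RMS envelope over this window,
#'   clamped like the detector's baseline.
#' @return A list of class `visual_config`.
#' @export
visual_config <- function(phasic_min_s = 0.1, phasic_max_s = 5.0,
                          amp_ratio = 2, tonic_epoch_fraction = 0.5,
                          background_window_s = 30) {
  if (!(phasic_min_s > 0 && phasic_min_s < phasic_max_s)) {
    stop("need 0 < phasic_min_s < phasic_max_s")
  }
  if (amp_ratio <= 1) stop("`amp_ratio` must exceed 1")
  structure(
    list(
      phasic_min_s = phasic_min_s, phasic_max_s = phasic_max_s,
      amp_ratio = amp_ratio, tonic_epoch_fraction = tonic_epoch_fraction,
      background_window_s = background_window_s
    ),
    class = "visual_config"
  )
}

# Shared plumbing: RMS envelope, background level, supra-threshold runs.
#
# The visual emulation compares a rolling-RMS envelope (the "EMG activity"
# level a scorer sees on screen) against amp_ratio times a low-percentile
# background of that envelope. RMS is used instead of the detector's
# peak-to-peak curve because its sampling distribution has no heavy upper
# tail: quiet atonia then never brushes a 2x background threshold, matching
# how a human never scores noise ripple as a burst.
.visual_activity <- function(sig, vcfg, canonical_rate = 256, prefilter = TRUE) {
  if (!is.null(canonical_rate)) sig <- resample_signal(sig, canonical_rate)
  if (prefilter) sig <- preprocess_emg(sig)
  dcfg <- detection_config(baseline_window_s = vcfg$background_window_s)
  env <- .rolling_rms(sig$samples, dcfg$window_samples)
  env_ac <- structure(
    list(values = env, rate = sig$rate, start_time = sig$start_time),
    class = "amplitude_curve"
  )
  background <- estimate_baseline(env_ac, dcfg)
  runs <- .runs_to_intervals(
    env > vcfg$amp_ratio * background$values, sig$rate, sig$start_time
  )
  runs$dur <- runs$end - runs$start
  runs
}

# centered rolling RMS with truncated edge windows, via cumulative sums
.rolling_rms <- function(x, width) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x^2))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

.rem_minis <- function(hyp, mini_s = 3) {
  per_epoch <- as.integer(round(hyp$epoch_len / mini_s))
  n_mini <- length(hyp$stages) * per_epoch
  start <- (seq_len(n_mini) - 1L) * mini_s
  stage <- rep(hyp$stages, each = per_epoch)
  tibble::tibble(start = start, end = start + mini_s, stage = stage)[
    stage == "REM", , drop = FALSE
  ]
}

.overlaps_any <- function(qs, qe, rs, re) {
  if (length(rs) == 0L) return(rep(FALSE, length(qs)))
  vapply(seq_along(qs), function(i) any(re > qs[i] & rs < qe[i]), TRUE)
}

#' Phasic RWA percentage (visual emulation)
#'
#' A REM 3-s mini-epoch is phasic-positive when it overlaps at least one
#' burst of duration `phasic_min_s`--`phasic_max_s` whose amplitude exceeds
#' `amp_ratio` times the local background.
#'
#' @param sig The chin [emg_signal()].
#' @param hyp A [hypnogram()].
#' @param vcfg A [visual_config()].
#' @param ... Passed to the internal activity extraction (`canonical_rate`,
#'   `prefilter`).
#' @return Percentage of REM mini-epochs scored phasic, in \[0, 100\].
#' @export
score_phasic <- function(sig, hyp, vcfg = visual_config(), ...) {
  scores <- score_visual(sig, hyp, vcfg, ...)
  scores$phasic_pct
}

#' Tonic RWA percentage (visual emulation)
#'
#' A REM 30-s epoch is tonic-positive when supra-threshold tone covers more
#' than `tonic_epoch_fraction` of the epoch.
#'
#' @inheritParams score_phasic
#' @return Percentage of REM 30-s epochs scored tonic, in \[0, 100\].
#' @export
score_tonic <- function(sig, hyp, vcfg = visual_config(), ...) {
  scores <- score_visual(sig, hyp, vcfg, ...)
  scores$tonic_pct
}

#' Any RWA percentage (visual emulation)
#'
#' A REM 3-s mini-epoch is any-positive when it overlaps phasic-qualifying or
#' tonic-qualifying (longer than `phasic_max_s`) supra-threshold activity of
#' at least `phasic_min_s`; "any" therefore dominates the phasic score.
#'
#' @inheritParams score_phasic
#' @return Percentage of REM mini-epochs scored any, in \[0, 100\].
#' @export
score_any <- function(sig, hyp, vcfg = visual_config(), ...) {
  scores <- score_visual(sig, hyp, vcfg, ...)
  scores$any_pct
}

#' All three visual RWA parameters at once
#'
#' Computes tonic, phasic and any percentages from one pass over the signal.
#'
#' @inheritParams score_phasic
#' @param canonical_rate,prefilter See [score_recording()].
#' @return A `visual_scores` list: `tonic_pct`, `phasic_pct`, `any_pct`.
#' @export
score_visual <- function(sig, hyp, vcfg = visual_config(),
                         canonical_rate = 256, prefilter = TRUE) {
  stopifnot(inherits(sig, "emg_signal"), inherits(hyp, "hypnogram"))
  if (!any(hyp$stages == "REM")) stop("no REM sleep in recording")
  runs <- .visual_activity(sig, vcfg, canonical_rate, prefilter)

  minis <- .rem_minis(hyp)
  phasic_runs <- runs[runs$dur >= vcfg$phasic_min_s &
                        runs$dur <= vcfg$phasic_max_s, , drop = FALSE]
  any_runs <- runs[runs$dur >= vcfg$phasic_min_s, , drop = FALSE]
  phasic_pos <- .overlaps_any(minis$start, minis$end,
                              phasic_runs$start, phasic_runs$end)
  any_pos <- .overlaps_any(minis$start, minis$end, any_runs$start, any_runs$end)

  rem_iv <- stage_intervals(hyp, "REM")
  epoch_starts <- unlist(purrr::map2(rem_iv$start, rem_iv$end, function(s, e) {
    seq(s, e - hyp$epoch_len, by = hyp$epoch_len)
  }))
  cover <- .interval_overlap(epoch_starts, epoch_starts + hyp$epoch_len,
                             runs$start, runs$end)
  tonic_pos <- cover / hyp$epoch_len > vcfg$tonic_epoch_fraction

  structure(
    list(
      tonic_pct = 100 * mean(tonic_pos),
      phasic_pct = 100 * mean(phasic_pos),
      any_pct = 100 * mean(any_pos),
      n_rem_minis = nrow(minis),
      n_rem_epochs = length(epoch_starts)
    ),
    class = "visual_scores"
  )
}

#' @export
print.visual_scores <- function(x, ...) {
  cat(sprintf(
    "<visual_scores> tonic %.1f%% (of %d REM epochs), phasic %.1f%%, any %.1f%% (of %d REM mini-epochs)\n",
    x$tonic_pct, x$n_rem_epochs, x$phasic_pct, x$any_pct, x$n_rem_minis
  ))
  invisible(x)
}
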