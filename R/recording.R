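#' Bundle signals and a hypnogram into a PSG recording
#'
#' @param signals An [emg_signal()] or list of them (the chin channel is
#'   selected at scoring time by label pattern).
#' @param hypnogram A [hypnogram()].
#' @param meta Optional named list (subject id, recording date, ...).
#' @return An object of class `psg_recording`.
#' @export
psg_recording <- function(signals, hypnogram, meta = list()) {
  if (inherits(signals, "emg_signal")) signals <- list(signals)
  stopifnot(
    length(signals) >= 1L,
    all(vapply(signals, inherits, TRUE, "emg_signal")),
    inherits(hypnogram, "hypnogram")
  )
  span <- max(vapply(signals, function(s) s$start_time + duration(s), 1))
  hyp_span <- length(hypnogram$stages) * hypnogram$epoch_len
  if (hyp_span > span + hypnogram$epoch_len) {
    stop("hypnogram extends more than one epoch beyond the longest signal")
  }
  structure(
    list(signals = signals, hypnogram = hypnogram, meta = meta),
    class = "psg_recording"
  )
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf(
    "<psg_recording> %d signal(s): %s\n",
    length(x$signals),
    paste(vapply(x$signals, function(s) s$label, ""), collapse = ", ")
  ))
  print(x$hypnogram)
  invisible(x)
}

#' Find the chin channel of a recording
#' @param rec A [psg_recording()].
#' @param pattern Case-insensitive pattern against channel labels.
#' @return The matching [emg_signal()].
#' @export
chin_channel <- function(rec, pattern = "chin") {
  labels <- vapply(rec$signals, function(s) s$label, "")
  hit <- grep(pattern, labels, ignore.case = TRUE)
  if (length(hit) == 0L) {
    stop(sprintf(
      "no channel matching '%s'; available: %s",
      pattern, paste(labels, collapse = ", ")
    ))
  }
  if (length(hit) > 1L) {
    stop(sprintf("pattern '%s' matches several channels: %s",
                 pattern, paste(labels[hit], collapse = ", ")))
  }
  rec$signals[[hit]]
}

#' Score a whole recording for REM sleep without atonia
#'
#' Runs the full automatic pipeline on the chin channel: band-pass
#' pre-filtering, amplitude curve, adaptive baseline, motor-activity-event
#' detection, 3-s mini-epoch scoring, the Automatic RWA score and per-stage
#' metrics.
#'
#' @param rec A [psg_recording()].
#' @param cfg A [detection_config()].
#' @param channel Pattern selecting the chin channel (default `"chin"`).
#' @param canonical_rate Rate (Hz) the signal is resampled to before analysis
#'   (default 256, at which the 51-sample window spans about 0.2 s); `NULL`
#'   keeps the native rate.
#' @param prefilter Apply [preprocess_emg()] before the amplitude curve
#'   (default TRUE; set FALSE if the signal is already conditioned).
#' @return An `rwa_result`: list with `auto_rwa`, `per_stage` (tibble),
#'   `events` (tibble), `minis` (tibble), `rem_pct` (REM time as % of total
#'   sleep time), `rem_s`, `n_rem_minis`, `config`.
#' @examples
#' spec <- synth_spec(duration_s = 1800, target_occupancy = 0.3, seed = 7)
#' synth <- generate_signal(spec)
#' res <- score_recording(psg_recording(synth$signal, synth$hypnogram))
#' res$auto_rwa
#' @export
score_recording <- function(rec, cfg = detection_config(), channel = "chin",
                            canonical_rate = 256, prefilter = TRUE) {
  stopifnot(inherits(rec, "psg_recording"))
  sig <- chin_channel(rec, channel)
  if (!is.null(canonical_rate)) sig <- resample_signal(sig, canonical_rate)
  if (prefilter) sig <- preprocess_emg(sig)
  ac <- compute_amplitude_curve(sig, cfg)
  base <- estimate_baseline(ac, cfg)
  events <- detect_events(ac, base, cfg)
  minis <- score_mini_epochs(events, rec$hypnogram, cfg)
  score <- automatic_rwa(minis)
  per_stage <- stage_metrics(events, rec$hypnogram, cfg, minis = minis)
  sleep_s <- sum(stage_seconds(rec$hypnogram, c("REM", "S1", "S2", "S3")))
  rem_s <- stage_seconds(rec$hypnogram, "REM")
  structure(
    list(
      auto_rwa = score,
      per_stage = per_stage,
      events = events,
      minis = minis,
      rem_s = rem_s,
      rem_pct = if (sleep_s > 0) 100 * rem_s / sleep_s else NA_real_,
      n_rem_minis = sum(minis$stage == "REM"),
      config = cfg,
      meta = rec$meta
    ),
    class = "rwa_result"
  )
}

#' @export
print.rwa_result <- function(x, ...) {
  cat(sprintf(
    "<rwa_result> Automatic RWA = %.3f (%d positive of %d REM mini-epochs)\n",
    x$auto_rwa, round(x$auto_rwa * x$n_rem_minis), x$n_rem_minis
  ))
  cat(sprintf("  %d motor activity events; REM = %.1f min (%.1f%% of sleep)\n",
              nrow(x$events), x$rem_s / 60, x$rem_pct))
  print(x$per_stage)
  invisible(x)
}

#' Write a single-subject result to JSON
#'
#' @param res An `rwa_result` (optionally with visual scores attached, see
#'   [score_visual()]).
#' @param path Output JSON file.
#' @param visual Optional `visual_scores` object to merge.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(res, path, visual = NULL) {
  stopifnot(inherits(res, "rwa_result"))
  per_stage <- res$per_stage
  stage_list <- list()
  for (i in seq_len(nrow(per_stage))) {
    stg <- tolower(per_stage$stage[i])
    stage_list[[paste0(stg, "_pct_miniepochs")]] <- per_stage$pct_miniepochs[i]
    stage_list[[paste0(stg, "_duration_s")]] <- per_stage$duration_s[i]
    stage_list[[paste0(stg, "_pct_duration")]] <- per_stage$pct_duration[i]
  }
  out <- c(
    list(
      subject = if (!is.null(res$meta$subject)) res$meta$subject else NA,
      auto_rwa = res$auto_rwa,
      n_rem_minis = res$n_rem_minis,
      rem_pct = res$rem_pct,
      n_events = nrow(res$events)
    ),
    if (!is.null(visual)) {
      list(
        tonic_pct = visual$tonic_pct,
        phasic_pct = visual$phasic_pct,
        any_pct = visual$any_pct
      )
    },
    stage_list
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Flatten results into one cohort-table row
#'
#' Column names follow the cohort CSV contract: `subject`, `group`,
#' `auto_rwa`, `tonic_pct`, `phasic_pct`, `any_pct`, plus per-stage columns
#' `<stage>_pct_miniepochs`, `<stage>_duration_s`, `<stage>_pct_duration`.
#'
#' @param res An `rwa_result`.
#' @param visual Optional `visual_scores`.
#' @param subject,group Identifier and group label for the row.
#' @return A one-row tibble.
#' @export
result_row <- function(res, visual = NULL, subject = NA_character_,
                       group = NA_character_) {
  stopifnot(inherits(res, "rwa_result"))
  wide <- tidyr::pivot_wider(
    res$per_stage[, c("stage", "pct_miniepochs", "duration_s", "pct_duration")],
    names_from = "stage",
    values_from = c("pct_miniepochs", "duration_s", "pct_duration"),
    names_glue = "{tolower(stage)}_{.value}"
  )
  tibble::tibble(
    subject = subject,
    group = group,
    auto_rwa = res$auto_rwa,
    tonic_pct = if (is.null(visual)) NA_real_ else visual$tonic_pct,
    phasic_pct = if (is.null(visual)) NA_real_ else visual$phasic_pct,
    any_pct = if (is.null(visual)) NA_real_ else visual$any_pct
  ) |>
    dplyr::bind_cols(wide)
}
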