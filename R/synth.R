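#' Specification of a synthetic chin-EMG recording
#'
#' Describes a night of synthetic submentalis EMG: a band-limited Gaussian
#' atonia floor, phasic bursts and tonic segments that *multiply* the local
#' envelope (as real motor activity scales the interference pattern), and a
#' block-structured hypnogram. When `target_occupancy` is set, bursts are
#' planted to fully cover exactly `round(target_occupancy * #REM mini-epochs)`
#' REM mini-epochs and no others, giving an exact ground truth for the
#' Automatic RWA score.
#'
#' @param duration_s Recording length in seconds.
#' @param rate Sampling rate in Hz (default 256).
#' @param atonia_rms_uv RMS of the atonia floor in µV (default 2).
#' @param burst_rate_per_min Poisson rate of extra random phasic bursts during
#'   REM (default 0).
#' @param burst_amp_ratio Envelope multiple of bursts relative to the atonia
#'   floor (default 8).
#' @param burst_dur_range_s Duration range of random bursts (default
#'   `c(0.1, 5)`, the phasic range).
#' @param tonic_segments Optional tibble/data frame with `start`, `end`,
#'   `amp_ratio`: sustained envelope elevations.
#' @param target_occupancy Optional fraction in \[0, 1\] of REM mini-epochs to
#'   cover exactly with planted bursts.
#' @param hypnogram_spec Data frame with `stage`, `minutes` defining the
#'   repeating stage-block layout; default
#'   W(10), S1(5), S2(30), S3(20), REM(20) minutes, repeated to fill the
#'   night.
#' @param seed Integer seed; the same spec and seed give bit-identical output.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 7200,
                       rate = 256,
                       atonia_rms_uv = 2,
                       burst_rate_per_min = 0,
                       burst_amp_ratio = 8,
                       burst_dur_range_s = c(0.1, 5),
                       tonic_segments = NULL,
                       target_occupancy = NULL,
                       hypnogram_spec = default_hypnogram_spec(),
                       seed = 1L) {
  if (duration_s <= 0 || rate <= 0 || atonia_rms_uv <= 0) {
    stop("durations, rate and atonia level must be positive")
  }
  if (!is.null(target_occupancy) &&
      (target_occupancy < 0 || target_occupancy > 1)) {
    stop("`target_occupancy` must be in [0, 1]")
  }
  structure(
    list(
      duration_s = duration_s, rate = rate, atonia_rms_uv = atonia_rms_uv,
      burst_rate_per_min = burst_rate_per_min,
      burst_amp_ratio = burst_amp_ratio,
      burst_dur_range_s = burst_dur_range_s,
      tonic_segments = tonic_segments,
      target_occupancy = target_occupancy,
      hypnogram_spec = hypnogram_spec,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' Default stage-block layout of the synthetic hypnogram
#' @return A data frame with `stage` and `minutes`: W(10), S1(5), S2(30),
#'   S3(20), REM(20), repeated to fill the requested duration.
#' @export
default_hypnogram_spec <- function() {
  data.frame(
    stage = c("W", "S1", "S2", "S3", "REM"),
    minutes = c(10, 5, 30, 20, 20)
  )
}

#' Build a hypnogram from a block layout
#' @param hypnogram_spec Data frame with `stage`, `minutes`.
#' @param duration_s Total duration to fill (blocks repeat and the last is
#'   truncated to whole epochs).
#' @param epoch_len Epoch length in seconds (default 30).
#' @return A [hypnogram()].
#' @export
build_hypnogram <- function(hypnogram_spec, duration_s, epoch_len = 30) {
  n_epochs <- as.integer(floor(duration_s / epoch_len))
  if (n_epochs < 1L) stop("duration shorter than one epoch")
  block <- rep(hypnogram_spec$stage,
               times = as.integer(round(hypnogram_spec$minutes * 60 / epoch_len)))
  stages <- rep(block, length.out = n_epochs)
  hypnogram(stages, epoch_len = epoch_len)
}

#' Generate a synthetic chin-EMG recording with ground truth
#'
#' See [synth_spec()] for the signal model. All randomness flows from the
#' spec's single seed (local RNG state; the caller's RNG is untouched).
#'
#' @param spec A [synth_spec()].
#' @return A list with `signal` ([emg_signal()]), `hypnogram`
#'   ([hypnogram()]), and `truth`: a list with `events` (tibble of planted
#'   intervals with `start`, `end`, `class`), `positive_minis` (0-based
#'   indices of REM mini-epochs planted positive within the full mini-epoch
#'   grid), and `target_occupancy`.
#' @export
generate_signal <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  hyp <- build_hypnogram(spec$hypnogram_spec, spec$duration_s)
  n <- as.integer(round(spec$duration_s * spec$rate))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  # atonia floor: band-limited Gaussian noise at the requested RMS
  noise <- stats::rnorm(n)
  nyq <- spec$rate / 2
  bp <- signal::butter(2, c(10, min(100, 0.95 * nyq)) / nyq, type = "pass")
  noise <- .filtfilt_padded(bp, noise)
  noise <- noise * spec$atonia_rms_uv / stats::sd(noise)

  mini_s <- 3
  minis <- .mini_grid(hyp, mini_s)
  rem_idx <- which(minis$stage == "REM")

  events <- tibble::tibble(start = numeric(), end = numeric(),
                           class = character(), ratio = numeric())
  positive_minis <- integer()

  if (!is.null(spec$target_occupancy)) {
    k <- round(spec$target_occupancy * length(rem_idx))
    if (k > length(rem_idx)) {
      stop("infeasible occupancy: more covered mini-epochs than REM mini-epochs")
    }
    if (k > 0) {
      chosen <- .plant_stratified(minis, rem_idx, k, hyp$epoch_len, mini_s)
      positive_minis <- sort(chosen) - 1L
      burst_iv <- .merge_adjacent(minis$start[sort(chosen)], mini_s)
      events <- dplyr::bind_rows(events, tibble::tibble(
        start = burst_iv$start, end = burst_iv$end, class = "phasic",
        ratio = spec$burst_amp_ratio
      ))
    }
  }

  if (spec$burst_rate_per_min > 0) {
    rem_iv <- stage_intervals(hyp, "REM")
    for (i in seq_len(nrow(rem_iv))) {
      span <- rem_iv$end[i] - rem_iv$start[i]
      n_b <- stats::rpois(1, spec$burst_rate_per_min * span / 60)
      if (n_b == 0) next
      d <- stats::runif(n_b, spec$burst_dur_range_s[1], spec$burst_dur_range_s[2])
      s <- stats::runif(n_b, rem_iv$start[i], pmax(rem_iv$start[i], rem_iv$end[i] - d))
      events <- dplyr::bind_rows(events, tibble::tibble(
        start = s, end = pmin(s + d, rem_iv$end[i]), class = "phasic",
        ratio = spec$burst_amp_ratio
      ))
    }
  }

  if (!is.null(spec$tonic_segments) && nrow(spec$tonic_segments) > 0) {
    ts <- tibble::as_tibble(spec$tonic_segments)
    events <- dplyr::bind_rows(events, tibble::tibble(
      start = ts$start, end = ts$end, class = "tonic", ratio = ts$amp_ratio
    ))
  }

  # envelope: bursts/tonic segments multiply the atonia floor
  env <- rep(1, n)
  ramp_s <- 0.02
  for (i in seq_len(nrow(events))) {
    env <- .apply_envelope(env, events$start[i], events$end[i],
                           events$ratio[i], spec$rate, ramp_s)
  }

  sig <- emg_signal(noise * env, rate = spec$rate, label = "Chin1-Chin2")
  events <- events[order(events$start), , drop = FALSE]
  list(
    signal = sig,
    hypnogram = hyp,
    truth = list(
      events = events,
      positive_minis = positive_minis,
      target_occupancy = spec$target_occupancy
    )
  )
}

# full mini-epoch grid (all stages)
.mini_grid <- function(hyp, mini_s) {
  per_epoch <- as.integer(round(hyp$epoch_len / mini_s))
  n_mini <- length(hyp$stages) * per_epoch
  start <- (seq_len(n_mini) - 1L) * mini_s
  tibble::tibble(start = start, stage = rep(hyp$stages, each = per_epoch))
}

# choose k REM mini indices spread across epochs so that every 30-s epoch
# keeps at least one uncovered mini-epoch when the target allows it; keeps the
# moving-window baseline anchored to atonia even at high occupancy
.plant_stratified <- function(minis, rem_idx, k, epoch_len, mini_s) {
  per_epoch <- as.integer(round(epoch_len / mini_s))
  epoch_of <- (rem_idx - 1L) %/% per_epoch
  epochs <- split(rem_idx, epoch_of)
  n_e <- length(epochs)
  base_q <- k %/% n_e
  extra <- k %% n_e
  quota <- rep(base_q, n_e) + c(rep(1L, extra), rep(0L, n_e - extra))
  quota <- quota[sample.int(n_e)] # which epochs carry the remainder
  chosen <- integer(0)
  for (i in seq_len(n_e)) {
    q <- min(quota[i], length(epochs[[i]]))
    if (q > 0) chosen <- c(chosen, sample(epochs[[i]], q))
  }
  # top up if capping ever undershot (epochs shorter than per_epoch)
  if (length(chosen) < k) {
    rest <- setdiff(rem_idx, chosen)
    chosen <- c(chosen, sample(rest, k - length(chosen)))
  }
  chosen
}

# adjacent chosen minis merge into one planted burst interval
.merge_adjacent <- function(starts, mini_s) {
  starts <- sort(starts)
  iv <- tibble::tibble(start = starts, end = starts + mini_s)
  merge_events(iv, iei_s = 1e-9)
}

# multiply env by `ratio` on [t0, t1) with raised-cosine ramps of ramp_s
.apply_envelope <- function(env, t0, t1, ratio, rate, ramp_s) {
  n <- length(env)
  i0 <- max(1L, as.integer(floor(t0 * rate)) + 1L)
  i1 <- min(n, as.integer(ceiling(t1 * rate)))
  if (i1 < i0) return(env)
  seg <- rep(ratio, i1 - i0 + 1L)
  nr <- min(as.integer(round(ramp_s * rate)), (i1 - i0 + 1L) %/% 2L)
  if (nr > 0) {
    up <- 1 + (ratio - 1) * (1 - cos(pi * seq_len(nr) / nr)) / 2
    seg[seq_len(nr)] <- up
    seg[(length(seg) - nr + 1L):length(seg)] <- rev(up)
  }
  env[i0:i1] <- pmax(env[i0:i1], seg)
  env
}

#' Table of cohort group parameters
#'
#' The default parameterisation of [generate_cohort()]: per-group sample
#' sizes, means and SDs of the four RWA parameters, AHI, PLMI and DAT-imaging
#' values for healthy controls (HC), PD without RBD (PDnoRBD), idiopathic RBD
#' (iRBD) and PD with RBD (PD_RBD), as published for the validation cohort.
#' Imaging values are absent for HC (no indication for DAT imaging).
#'
#' @return A tibble with columns `group`, `n`, `variable`, `mean`, `sd`,
#'   `lower`, `upper` (truncation bounds).
#' @export
cohort_table1 <- function() {
  g <- function(group, n, variable, mean, sd, lower, upper) {
    tibble::tibble(group = group, n = n, variable = variable,
                   mean = mean, sd = sd, lower = lower, upper = upper)
  }
  rwa_bounds <- list(
    phasic_pct = c(0, 100), tonic_pct = c(0, 100), any_pct = c(0, 100),
    auto_rwa = c(0, 1), ahi = c(0, Inf), plmi = c(0, Inf),
    age = c(18, Inf),
    caudate_sbr = c(0, Inf), putamen_sbr = c(0, Inf),
    caudate_z = c(-Inf, Inf), putamen_z = c(-Inf, Inf)
  )
  groups <- list(
    HC = list(
      n = 11, age = c(67.27, 11.41),
      phasic_pct = c(3.28, 3.41), tonic_pct = c(1.07, 1.74),
      any_pct = c(4.90, 4.77), auto_rwa = c(0.13, 0.20),
      ahi = c(4.87, 6.80), plmi = c(20.61, 40.86)
    ),
    PDnoRBD = list(
      n = 24, age = c(66.67, 9.47),
      phasic_pct = c(5.77, 3.94), tonic_pct = c(2.73, 2.59),
      any_pct = c(7.78, 4.92), auto_rwa = c(0.11, 0.07),
      ahi = c(12.84, 18.61), plmi = c(5.75, 9.94),
      caudate_sbr = c(2.55, 1.01), putamen_sbr = c(1.53, 0.65),
      caudate_z = c(-1.69, 0.33), putamen_z = c(-1.92, 0.36)
    ),
    iRBD = list(
      n = 45, age = c(68.51, 7.79),
      phasic_pct = c(45.38, 23.03), tonic_pct = c(38.35, 25.40),
      any_pct = c(59.61, 23.48), auto_rwa = c(0.28, 0.18),
      ahi = c(5.72, 7.84), plmi = c(25.22, 37.84),
      caudate_sbr = c(3.52, 1.10), putamen_sbr = c(2.85, 0.95),
      caudate_z = c(-1.24, 0.42), putamen_z = c(-1.29, 0.28)
    ),
    PD_RBD = list(
      n = 46, age = c(72.46, 6.25),
      phasic_pct = c(29.77, 20.22), tonic_pct = c(45.44, 29.97),
      any_pct = c(57.35, 24.81), auto_rwa = c(0.39, 0.21),
      ahi = c(16.41, 18.12), plmi = c(24.24, 27.55),
      caudate_sbr = c(2.24, 0.62), putamen_sbr = c(1.36, 0.51),
      caudate_z = c(-1.69, 0.30), putamen_z = c(-1.85, 0.30)
    )
  )
  purrr::map_dfr(names(groups), function(gn) {
    gl <- groups[[gn]]
    vars <- setdiff(names(gl), "n")
    purrr::map_dfr(vars, function(v) {
      b <- rwa_bounds[[v]]
      g(gn, gl$n, v, gl[[v]][1], gl[[v]][2], b[1], b[2])
    })
  })
}

#' Generate a synthetic subject cohort
#'
#' Draws per-group subject records from truncated-normal marginals (rejection
#' sampling within each variable's valid range), by default parameterised
#' like the published validation cohort (see [cohort_table1()]). Variables
#' are drawn independently unless `rwa_imaging_cor` requests a common
#' Gaussian-copula correlation between `auto_rwa` and the imaging values.
#'
#' @param spec Parameter tibble as returned by [cohort_table1()] (columns
#'   `group`, `n`, `variable`, `mean`, `sd`, `lower`, `upper`).
#' @param n_override Optional named vector of per-group sample sizes replacing
#'   the parameter table's `n` (e.g. `c(HC = 1000)`).
#' @param rwa_imaging_cor Correlation between `auto_rwa` and each imaging
#'   variable (default 0).
#' @param seed Integer seed.
#' @return A tibble of subject records: `subject`, `group`, `sex`, `age`, the
#'   four RWA parameters, `ahi`, `plmi`, imaging columns (NA where a group
#'   has none), and `rbd` (TRUE for iRBD / PD_RBD).
#' @export
generate_cohort <- function(spec = cohort_table1(), n_override = NULL,
                            rwa_imaging_cor = 0, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  imaging_vars <- c("caudate_sbr", "putamen_sbr", "caudate_z", "putamen_z")
  sex_p <- c(HC = 5 / 11, PDnoRBD = 13 / 24, iRBD = 36 / 45, PD_RBD = 29 / 46)
  all_vars <- unique(spec$variable)
  out <- purrr::map_dfr(unique(spec$group), function(gn) {
    gs <- spec[spec$group == gn, , drop = FALSE]
    n <- if (!is.null(n_override) && gn %in% names(n_override)) {
      as.integer(n_override[[gn]])
    } else gs$n[1]
    if (n < 2L) stop("each group needs n >= 2")
    # shared latent normal for the copula between auto_rwa and imaging
    z_common <- stats::rnorm(n)
    draw <- function(v) {
      row <- gs[gs$variable == v, , drop = FALSE]
      if (nrow(row) == 0L) return(rep(NA_real_, n))
      # factor loadings: cor(auto_rwa, imaging) = load_rwa * load_img
      rho <- if (rwa_imaging_cor != 0 && v %in% c("auto_rwa", imaging_vars)) {
        if (v == "auto_rwa") sqrt(abs(rwa_imaging_cor)) else {
          sign(rwa_imaging_cor) * sqrt(abs(rwa_imaging_cor))
        }
      } else 0
      z <- if (rho != 0) {
        rho * z_common + sqrt(1 - rho^2) * stats::rnorm(n)
      } else stats::rnorm(n)
      .trunc_normal_from_z(z, row$mean, row$sd, row$lower, row$upper)
    }
    vals <- purrr::map(all_vars, draw)
    names(vals) <- all_vars
    p_m <- if (gn %in% names(sex_p)) sex_p[[gn]] else 0.5
    tibble::tibble(
      subject = sprintf("%s_%03d", gn, seq_len(n)),
      group = gn,
      sex = ifelse(stats::runif(n) < p_m, "M", "F"),
      !!!vals,
      rbd = gn %in% c("iRBD", "PD_RBD")
    )
  })
  out
}

# map standard-normal draws through a truncated-normal quantile transform
.trunc_normal_from_z <- function(z, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, length(z)))
  a <- stats::pnorm((lower - mean) / sd)
  b <- stats::pnorm((upper - mean) / sd)
  u <- stats::pnorm(z)
  stats::qnorm(a + u * (b - a)) * sd + mean
}
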