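# Shared fixtures and independent brute-force oracles for the test suite.

# REM-dense stage layout for fast closure tests: 30-min cycle, 20 min REM
rem_dense_layout <- function() {
  data.frame(stage = c("W", "S2", "REM"), minutes = c(2, 8, 20))
}

# short recording with planted occupancy, on the REM-dense layout
make_planted <- function(target, seed, duration_s = 1800, ...) {
  generate_signal(synth_spec(
    duration_s = duration_s, target_occupancy = target, seed = seed,
    hypnogram_spec = rem_dense_layout(), ...
  ))
}

# brute-force amplitude curve: explicit window scan
oracle_amplitude_curve <- function(x, width) {
  half <- (width - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    max(w) - min(w)
  }, 1)
}

# brute-force per-sample moving percentile with floor/cap clamps
oracle_baseline <- function(ac_values, rate, cfg) {
  width <- as.integer(round(cfg$baseline_window_s * rate))
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(ac_values)
  p <- cfg$baseline_percentile / 100
  base <- vapply(seq_len(n), function(i) {
    w <- ac_values[max(1L, i - half):min(n, i + half)]
    stats::quantile(w, p, names = FALSE, type = 7)
  }, 1)
  if (is.finite(cfg$baseline_cap_ratio)) {
    base <- pmin(base, cfg$baseline_cap_ratio *
                   stats::quantile(ac_values, p, names = FALSE, type = 7))
  }
  pmax(base, cfg$baseline_floor_uv)
}

# brute-force event detector: sample-by-sample threshold pass, explicit merge
# loop, then duration filter
oracle_detect <- function(ac_values, base_values, rate, cfg) {
  above <- ac_values > cfg$madt_factor * base_values
  # threshold pass
  runs <- list()
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c((i - 1L) / rate, j / rate)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(runs) == 0L) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  # explicit merge loop
  merged <- list(runs[[1L]])
  for (k in seq_along(runs)[-1L]) {
    last <- merged[[length(merged)]]
    if (runs[[k]][1] - last[2] < cfg$iei_s) {
      merged[[length(merged)]] <- c(last[1], runs[[k]][2])
    } else {
      merged[[length(merged) + 1L]] <- runs[[k]]
    }
  }
  # duration filter
  keep <- vapply(merged, function(iv) iv[2] - iv[1] >= cfg$min_event_s, TRUE)
  merged <- merged[keep]
  tibble::tibble(
    start = vapply(merged, `[`, 1, 1L),
    end = vapply(merged, `[`, 1, 2L)
  )
}

# AUC by explicit pair counting (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Fisher 2x2 p by full enumeration of tables with fixed margins
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  x_obs <- tab[1, 1]
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(x_obs, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# synthetic amplitude/baseline pair on a shared grid, as plain objects
fake_ac <- function(values, rate = 256) {
  structure(list(values = values, rate = rate, start_time = 0),
            class = "amplitude_curve")
}

fake_baseline <- function(values, rate = 256) {
  structure(list(values = values, rate = rate, start_time = 0),
            class = "baseline_curve")
}

# piecewise-constant AC: `level` on [from, to) seconds, `background`
# elsewhere; step times must lie on the sampling grid
step_ac <- function(duration_s, rate, background, steps) {
  v <- rep(background, duration_s * rate)
  for (s in steps) {
    i0 <- as.integer(round(s[1] * rate)) + 1L
    i1 <- as.integer(round(s[2] * rate))
    v[i0:i1] <- s[3]
  }
  fake_ac(v, rate)
}
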