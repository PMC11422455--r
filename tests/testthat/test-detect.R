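# amplitude curve, baseline, event detection, mini-epochs, RWA score

test_that("amplitude curve of a constant signal is zero", {
  sig <- emg_signal(rep(3.7, 1000), 256)
  ac <- compute_amplitude_curve(sig)
  expect_true(all(ac$values == 0))
  expect_error(compute_amplitude_curve(emg_signal(1:10, 256)), "too short")
})

test_that("amplitude curve of a fast sine approximates twice the amplitude", {
  a <- 4.2
  t <- seq(0, 4, by = 1 / 256)[-1]
  sig <- emg_signal(a * sin(2 * pi * 25 * t), 256)
  ac <- compute_amplitude_curve(sig)
  interior <- ac$values[100:(length(t) - 100)]
  expect_true(all(abs(interior - 2 * a) / (2 * a) < 0.02))
})

test_that("a single impulse marks exactly the windows containing it", {
  x <- rep(0, 500)
  x[250] <- 5
  sig <- emg_signal(x, 256)
  ac <- compute_amplitude_curve(sig)
  oracle <- oracle_amplitude_curve(x, 51)
  expect_equal(ac$values, oracle)
  expect_equal(sum(ac$values == 5), 51)
})

test_that("amplitude curve equals the brute-force window scan on noise", {
  set.seed(11)
  x <- rnorm(3000)
  ac <- compute_amplitude_curve(emg_signal(x, 256))
  expect_equal(ac$values, oracle_amplitude_curve(x, 51), tolerance = 0)
})

test_that("baseline of constants obeys percentile, floor and cap", {
  cfg <- detection_config(baseline_stride_s = 1 / 256)
  ac2 <- fake_ac(rep(2, 256 * 40))
  expect_true(all(estimate_baseline(ac2, cfg)$values == 2))
  ac0 <- fake_ac(rep(0, 256 * 40))
  expect_true(all(estimate_baseline(ac0, cfg)$values == 0.5))
})

test_that("sparse high contamination leaves the moving percentile near floor level", {
  set.seed(5)
  n <- 256 * 60
  v <- rep(1, n)
  v[sample.int(n, round(0.05 * n))] <- 20
  cfg <- detection_config(baseline_stride_s = 1 / 256)
  base <- estimate_baseline(fake_ac(v), cfg)
  expect_true(all(base$values >= 1))
  expect_lt(max(base$values), 1.5)
})

test_that("baseline equals the brute-force moving percentile at full stride", {
  set.seed(9)
  v <- abs(rnorm(256 * 50, mean = 2))
  cfg <- detection_config(baseline_stride_s = 1 / 256)
  base <- estimate_baseline(fake_ac(v), cfg)
  expect_equal(base$values, oracle_baseline(v, 256, cfg), tolerance = 1e-12)
})

test_that("strided baseline approximates the exact one closely", {
  set.seed(10)
  v <- abs(rnorm(256 * 50, mean = 2))
  exact <- estimate_baseline(fake_ac(v), detection_config(baseline_stride_s = 1 / 256))
  fast <- estimate_baseline(fake_ac(v), detection_config())
  expect_lt(max(abs(exact$values - fast$values)) / stats::median(exact$values), 0.1)
})

test_that("hand-traced threshold, merge and duration rules", {
  rate <- 80 # grid on which 0.1-s step times are exactly representable
  cfg <- detection_config()
  base <- fake_baseline(rep(1, 20 * rate), rate)

  # never above 4x baseline -> no events
  expect_equal(nrow(detect_events(fake_ac(rep(1, 20 * rate), rate), base, cfg)), 0)

  # one clean 0.5-s excursion
  ac <- step_ac(20, rate, 1, list(c(10.0, 10.5, 5)))
  ev <- detect_events(ac, base, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 10.0)
  expect_equal(ev$end, 10.5)

  # two bursts 0.3 s apart merge (gap < IEI 0.5 s)
  ac <- step_ac(20, rate, 1, list(c(10.0, 10.4, 5), c(10.7, 11.1, 5)))
  ev <- detect_events(ac, base, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 10.0)
  expect_equal(ev$end, 11.1)

  # a lone 0.2-s burst dies to the 0.3-s duration filter
  ac <- step_ac(20, rate, 1, list(c(10.0, 10.2, 5)))
  expect_equal(nrow(detect_events(ac, base, cfg)), 0)

  # merge-then-filter: two 0.2-s bursts 0.3 s apart survive as one event
  ac <- step_ac(20, rate, 1, list(c(10.0, 10.2, 5), c(10.5, 10.7, 5)))
  ev <- detect_events(ac, base, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end - ev$start, 0.7)

  expect_error(
    detect_events(fake_ac(rep(1, 100)), fake_baseline(rep(1, 99)), cfg),
    "grid"
  )
})

test_that("detector equals the brute-force oracle on random signals", {
  cfg <- detection_config()
  set.seed(21)
  for (rep_i in 1:25) {
    rate <- 64 # coarse grid exercises many boundary cases
    n <- 60 * rate
    base_v <- rep(1, n)
    ac_v <- rep(1, n)
    n_bursts <- sample(0:12, 1)
    if (n_bursts > 0) {
      for (b in seq_len(n_bursts)) {
        s <- runif(1, 0, 58)
        d <- runif(1, 0.05, 2)
        lvl <- sample(c(3, 5, 10), 1) # some below threshold
        i0 <- floor(s * rate) + 1L
        i1 <- min(n, floor((s + d) * rate))
        ac_v[i0:i1] <- pmax(ac_v[i0:i1], lvl)
      }
    }
    ev <- detect_events(fake_ac(ac_v, rate), fake_baseline(base_v, rate), cfg)
    orc <- oracle_detect(ac_v, base_v, rate, cfg)
    expect_equal(as.data.frame(ev), as.data.frame(orc), tolerance = 0)
  }
})

test_that("event lists satisfy their structural invariants", {
  cfg <- detection_config()
  set.seed(33)
  for (rep_i in 1:10) {
    rate <- 128
    ac_v <- pmax(0.2, rnorm(30 * rate, mean = 1, sd = 1.2))
    ev <- detect_events(fake_ac(ac_v, rate), fake_baseline(rep(0.3, 30 * rate), rate), cfg)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$start) > 0))
      expect_true(all(ev$start[-1] - ev$end[-nrow(ev)] >= cfg$iei_s))
    }
    if (nrow(ev) > 0) {
      expect_true(all(ev$end - ev$start >= cfg$min_event_s))
    }
    # merging an already-merged list is a no-op
    expect_identical(merge_events(ev, cfg$iei_s), ev[, c("start", "end")])
  }
})

test_that("raising the threshold never increases total event time", {
  set.seed(44)
  rate <- 128
  ac_v <- pmax(0.1, rnorm(60 * rate, mean = 1.5, sd = 2))
  base <- fake_baseline(rep(0.4, 60 * rate), rate)
  total_time <- vapply(c(2, 4, 6, 8), function(k) {
    ev <- detect_events(fake_ac(ac_v, rate), base,
                        detection_config(madt_factor = k))
    sum(ev$end - ev$start)
  }, 1)
  expect_true(all(diff(total_time) <= 1e-12))
})

test_that("detection is equivariant to amplitude scaling off the clamps", {
  g <- make_planted(0.2, seed = 77, duration_s = 1800)
  cfg <- detection_config(baseline_floor_uv = 1e-9) # keep floor out of play
  score_of <- function(scale) {
    sig <- emg_signal(g$signal$samples * scale, g$signal$rate)
    ac <- compute_amplitude_curve(sig, cfg)
    base <- estimate_baseline(ac, cfg)
    ev <- detect_events(ac, base, cfg)
    automatic_rwa(score_mini_epochs(ev, g$hypnogram, cfg))
  }
  expect_equal(score_of(1), score_of(7.3), tolerance = 1e-12)
})

test_that("mini-epoch occupancy uses a strict > 50% rule", {
  hyp <- hypnogram(rep("REM", 2))
  cfg <- detection_config()

  full <- tibble::tibble(start = 30.0, end = 33.0)
  m <- score_mini_epochs(full, hyp, cfg)
  expect_equal(m$occupancy[11], 1.0)
  expect_true(m$positive[11])

  half <- tibble::tibble(start = 30.0, end = 31.5)
  m <- score_mini_epochs(half, hyp, cfg)
  expect_equal(m$occupancy[11], 0.5)
  expect_false(m$positive[11]) # exactly 50% is negative

  m0 <- score_mini_epochs(tibble::tibble(start = numeric(), end = numeric()),
                          hyp, cfg)
  expect_true(all(m0$occupancy == 0))
  expect_false(any(m0$positive))
})

test_that("the automatic RWA score is the positive REM mini-epoch fraction", {
  minis <- tibble::tibble(
    start = seq(0, by = 3, length.out = 40),
    stage = "REM",
    occupancy = c(rep(1, 12), rep(0, 28)),
    positive = c(rep(TRUE, 12), rep(FALSE, 28))
  )
  expect_equal(automatic_rwa(minis), 0.3)
  minis$positive <- FALSE
  expect_equal(automatic_rwa(minis), 0)
  minis$positive <- TRUE
  expect_equal(automatic_rwa(minis), 1)
  expect_error(automatic_rwa(minis[minis$stage == "W", ]), "no REM")
})

test_that("stage metrics report durations and percentages per stage", {
  hyp <- hypnogram(c("S2", "S2", "REM", "S1"))
  cfg <- detection_config()
  ev <- tibble::tibble(start = c(10, 40), end = c(20, 45)) # 15 s inside S2
  sm <- stage_metrics(ev, hyp, cfg)
  s2 <- sm[sm$stage == "S2", ]
  expect_equal(s2$duration_s, 15)
  expect_equal(s2$pct_duration, 25) # 15 of 60 s

  zero <- stage_metrics(tibble::tibble(start = numeric(), end = numeric()),
                        hyp, cfg, stages = c("REM", "S1", "S2"))
  expect_true(all(zero$pct_miniepochs == 0 & zero$duration_s == 0 &
                    zero$pct_duration == 0))

  out <- stage_metrics(ev, hyp, cfg, stages = "S3")
  expect_false(out$present)
  expect_equal(out$pct_duration, 0)
})

test_that("NREM metrics add up over S1-S3 for stage-contained events", {
  hyp <- hypnogram(c("S1", "S2", "S3", "REM", "S2"))
  cfg <- detection_config()
  ev <- tibble::tibble(
    start = c(5, 40, 70, 130),
    end = c(8, 44, 75, 133)
  ) # one event per stage, none crossing boundaries
  sm <- stage_metrics(ev, hyp, cfg)
  per <- sm[sm$stage %in% c("S1", "S2", "S3"), ]
  expect_equal(sm$duration_s[sm$stage == "NREM"], sum(per$duration_s))
})
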