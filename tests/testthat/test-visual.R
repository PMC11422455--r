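# rule-based emulation of tonic / phasic / any visual scoring

test_that("atonia-only recordings score zero on all visual parameters", {
  g <- make_planted(0, seed = 2, duration_s = 1800)
  v <- score_visual(g$signal, g$hypnogram)
  expect_equal(v$tonic_pct, 0)
  expect_equal(v$phasic_pct, 0)
  expect_equal(v$any_pct, 0)
})

test_that("one planted burst flags exactly its mini-epochs as phasic", {
  # one 3-s covered mini-epoch out of 400 REM minis
  g <- make_planted(1 / 400, seed = 6, duration_s = 1800)
  stopifnot(nrow(g$truth$events) == 1)
  v <- score_visual(g$signal, g$hypnogram)
  # the planted 3-s burst is within the 0.1-5 s phasic range; the envelope
  # ramps can brush one neighbouring mini-epoch
  expect_gte(v$phasic_pct, 100 * 1 / 400)
  expect_lte(v$phasic_pct, 100 * 3 / 400)
  expect_gte(v$any_pct, v$phasic_pct)
})

test_that("a 6-s sustained elevation is tonic/any-qualifying, not phasic", {
  hyp_layout <- rem_dense_layout()
  ton <- data.frame(start = 600 + 3, end = 600 + 9, amp_ratio = 8)
  g <- generate_signal(synth_spec(
    duration_s = 1800, tonic_segments = ton, seed = 12,
    hypnogram_spec = hyp_layout
  ))
  v <- score_visual(g$signal, g$hypnogram)
  expect_equal(v$phasic_pct, 0)
  expect_gt(v$any_pct, 0)
})

test_that("sustained tone across all REM saturates tonic scoring", {
  rem_iv <- stage_intervals(build_hypnogram(rem_dense_layout(), 1800), "REM")
  ton <- data.frame(start = rem_iv$start, end = rem_iv$end, amp_ratio = 12)
  g <- generate_signal(synth_spec(
    duration_s = 1800, tonic_segments = ton, seed = 3,
    hypnogram_spec = rem_dense_layout()
  ))
  v <- score_visual(g$signal, g$hypnogram)
  expect_equal(v$tonic_pct, 100)
  expect_equal(v$any_pct, 100)
})

test_that("tone covering 40% of each REM epoch is below the tonic rule", {
  hyp <- build_hypnogram(rem_dense_layout(), 1800)
  rem_iv <- stage_intervals(hyp, "REM")
  epoch_starts <- seq(rem_iv$start[1], rem_iv$end[1] - 30, by = 30)
  ton <- data.frame(start = epoch_starts, end = epoch_starts + 12,
                    amp_ratio = 12) # 12 s of 30 s
  g <- generate_signal(synth_spec(
    duration_s = 1800, tonic_segments = ton, seed = 8,
    hypnogram_spec = rem_dense_layout()
  ))
  v <- score_visual(g$signal, g$hypnogram)
  expect_equal(v$tonic_pct, 0)
})

test_that("any dominates phasic and equals it for purely phasic activity", {
  for (seed in c(4, 9)) {
    g <- make_planted(0.15, seed = seed, duration_s = 1800)
    v <- score_visual(g$signal, g$hypnogram)
    expect_gte(v$any_pct, v$phasic_pct)
    expect_true(all(c(v$tonic_pct, v$phasic_pct, v$any_pct) >= 0))
    expect_true(all(c(v$tonic_pct, v$phasic_pct, v$any_pct) <= 100))
  }
})

test_that("visual scores track the automatic score across a synthetic sweep", {
  targets <- rep(c(0.05, 0.2, 0.4, 0.6, 0.8), each = 3)
  auto <- numeric(length(targets))
  any_v <- numeric(length(targets))
  for (i in seq_along(targets)) {
    g <- make_planted(targets[i], seed = 100 + i, duration_s = 900)
    res <- score_recording(psg_recording(g$signal, g$hypnogram),
                           prefilter = FALSE)
    auto[i] <- res$auto_rwa
    any_v[i] <- score_visual(g$signal, g$hypnogram, prefilter = FALSE)$any_pct
  }
  expect_gt(stats::cor(auto, any_v, method = "spearman"), 0)
})

test_that("visual scoring requires REM sleep", {
  g <- generate_signal(synth_spec(
    duration_s = 600, seed = 1,
    hypnogram_spec = data.frame(stage = c("W", "S2"), minutes = c(5, 5))
  ))
  expect_error(score_visual(g$signal, g$hypnogram), "no REM")
})
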