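# synthetic signal generator and cohort generator

test_that("the generator is deterministic and leaves the caller's RNG alone", {
  spec <- synth_spec(duration_s = 900, target_occupancy = 0.2, seed = 42,
                     hypnogram_spec = rem_dense_layout())
  set.seed(999)
  before <- rnorm(3)
  set.seed(999)
  g1 <- generate_signal(spec)
  g2 <- generate_signal(spec)
  expect_identical(g1$signal$samples, g2$signal$samples)
  expect_identical(g1$truth$positive_minis, g2$truth$positive_minis)
  after <- rnorm(3)
  expect_identical(before, after) # RNG state restored around generation
})

test_that("occupancy planting covers exactly the planned mini-epoch count", {
  # 20 min REM on the dense layout -> 400 REM minis; plant half
  g <- make_planted(0.5, seed = 13, duration_s = 1800)
  expect_equal(length(g$truth$positive_minis), 200)
  # planted indices are REM minis and unique
  minis <- score_mini_epochs(g$truth$events, g$hypnogram)
  expect_equal(sum(minis$positive), 200)
  expect_true(all(minis$stage[g$truth$positive_minis + 1L] == "REM"))

  g0 <- make_planted(0, seed = 13, duration_s = 1800)
  expect_equal(nrow(g0$truth$events), 0)
})

test_that("infeasible occupancy is rejected", {
  expect_error(synth_spec(target_occupancy = 1.2), "target_occupancy")
})

test_that("planted events are recovered with high interval overlap", {
  g <- make_planted(0.3, seed = 31, duration_s = 1800)
  res <- score_recording(psg_recording(g$signal, g$hypnogram),
                         prefilter = FALSE)
  truth <- g$truth$events
  iou <- vapply(seq_len(nrow(truth)), function(i) {
    ov <- sum(pmax(0, pmin(truth$end[i], res$events$end) -
                     pmax(truth$start[i], res$events$start)))
    un <- (truth$end[i] - truth$start[i]) +
      sum((res$events$end - res$events$start) *
            (res$events$end > truth$start[i] & res$events$start < truth$end[i])) - ov
    ov / un
  }, 1)
  expect_true(all(iou >= 0.8))
})

test_that("cohort marginals follow the requested means at scale", {
  big <- generate_cohort(
    n_override = c(HC = 4000, PDnoRBD = 4000, iRBD = 4000, PD_RBD = 4000),
    seed = 7
  )
  spec <- cohort_table1()
  # the generator draws truncated normals, so the oracle is the analytic
  # truncated-normal mean, not the raw location parameter
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  for (v in c("any_pct", "auto_rwa", "age")) {
    rows <- spec[spec$variable == v, ]
    for (k in seq_len(nrow(rows))) {
      expected <- trunc_mean(rows$mean[k], rows$sd[k], rows$lower[k],
                             rows$upper[k])
      got <- mean(big[[v]][big$group == rows$group[k]])
      expect_lt(abs(got - expected) / abs(expected), 0.02)
    }
  }
})

test_that("degenerate SD yields constant values and truncation is respected", {
  spec <- cohort_table1()
  spec$sd[spec$variable == "auto_rwa" & spec$group == "HC"] <- 0
  coh <- generate_cohort(spec, seed = 3)
  expect_true(all(coh$auto_rwa[coh$group == "HC"] == 0.13))
  expect_true(all(coh$auto_rwa >= 0 & coh$auto_rwa <= 1))
  expect_true(all(coh$phasic_pct >= 0 & coh$phasic_pct <= 100))
  expect_true(all(is.na(coh$caudate_sbr[coh$group == "HC"])))
  expect_true(all(coh$ahi >= 0))
})

test_that("uncorrelated generation leaves RWA and imaging independent", {
  big <- generate_cohort(n_override = c(iRBD = 10000), seed = 11)
  irbd <- big[big$group == "iRBD", ]
  expect_lt(abs(stats::cor(irbd$auto_rwa, irbd$putamen_z)), 0.05)
})

test_that("requested correlation is induced through the copula", {
  big <- generate_cohort(n_override = c(iRBD = 8000), rwa_imaging_cor = 0.5,
                         seed = 12)
  irbd <- big[big$group == "iRBD", ]
  expect_gt(stats::cor(irbd$auto_rwa, irbd$putamen_z), 0.3)
})

test_that("group sizes default to the published cohort", {
  coh <- generate_cohort(seed = 1)
  expect_equal(as.integer(table(coh$group)[c("HC", "PDnoRBD", "iRBD", "PD_RBD")]),
               c(11L, 24L, 45L, 46L))
  expect_equal(sum(coh$rbd), 91L)
  expect_equal(sum(!coh$rbd), 35L)
})
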