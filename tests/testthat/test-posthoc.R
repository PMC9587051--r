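test_that("the Confidence Index is the normalized top-two margin", {
  expect_equal(confidence_index(c(1, 0, 0, 0)), 1)
  expect_equal(confidence_index(c(0.5, 0.5, 0, 0)), 0)
  expect_equal(confidence_index(c(0.6, 0.2, 0.1, 0.1)), 0.5)
  expect_error(confidence_index(c(0, 0, 0, 0)), "probability")
  # strictly increasing in Pmax - Pmax-1 at fixed Pmax + Pmax-1
  s <- 0.8
  margins <- seq(0, 0.6, by = 0.05)
  cis <- vapply(margins, function(m) {
    confidence_index(c((s + m) / 2, (s - m) / 2, (1 - s) / 2, (1 - s) / 2))
  }, numeric(1))
  expect_true(all(diff(cis) > 0))
  expect_true(all(cis >= 0 & cis <= 1))
})

test_that("the archetypal waveform passes through stage midpoints and is periodic", {
  cyc <- build_archetypal_cycle()
  expect_equal(eval_waveform(cyc, cyc$midpoints_days), c(0.5, 1.5, 2.5, 3.5))
  expect_equal(eval_waveform(cyc, 0), 0)
  t <- runif(50, 0, 20)
  expect_equal(eval_waveform(cyc, t), eval_waveform(cyc, t + 4.8), tolerance = 1e-9)
  # equal fractions put stage boundaries at multiples of 1.2 days
  eq <- build_archetypal_cycle(stage_fractions = rep(0.25, 4))
  expect_equal(unname(eq$boundaries_days), seq(0, 4.8, by = 1.2))
  expect_error(build_archetypal_cycle(stage_fractions = c(0.4, 0.3, 0.2, 0.2)),
               "sum to 1")
  # sinusoid mode: periodic alternative waveform
  sn <- build_archetypal_cycle(waveform = "sinusoid")
  expect_equal(eval_waveform(sn, t), eval_waveform(sn, t + 4.8), tolerance = 1e-9)
})

test_that("phase fitting recovers a noiseless phase on the grid with high correlation", {
  cyc <- build_archetypal_cycle()
  times <- 0:9
  stages <- number_to_stage(eval_waveform(cyc, times + 0.3 * cyc$period_days))
  fit <- fit_cycle_phase(times, stages, cyc)
  expect_equal(fit$best_phase, 0.3)
  expect_gt(fit$pearson_r, 0.9)
  expect_equal(unname(fit$r_by_phase[which.max(fit$r_by_phase)]), fit$pearson_r)
  expect_length(fit$r_by_phase, 10)
})

test_that("degenerate and too-short sequences are rejected", {
  expect_error(fit_cycle_phase(0:9, rep("diestrus", 10)), "degenerate")
  expect_error(fit_cycle_phase(0:3, c("diestrus", "proestrus", "estrus", "metestrus")),
               "more data|more than 4")
  expect_error(fit_cycle_phase(c(0, 1, 1, 2), rep("estrus", 4)), "increasing")
})

test_that("grid best phase matches a dense brute-force maximizer rounded to the grid", {
  cyc <- build_archetypal_cycle()
  times <- 0:9
  stages <- number_to_stage(eval_waveform(cyc, times + 0.25 * cyc$period_days))
  fit <- fit_cycle_phase(times, stages, cyc)
  expect_true(fit$best_phase %in% c(0.2, 0.3))
  nums <- stage_to_number(stages)
  dense <- seq(0, 0.999, by = 0.001)
  r_dense <- vapply(dense, function(phi)
    cor(nums, eval_waveform(cyc, times + phi * cyc$period_days)), numeric(1))
  best_dense <- dense[which.max(r_dense)]
  expect_equal(fit$best_phase, round(best_dense, 1) %% 1)
})

test_that("fitting is invariant to adding whole periods to all times", {
  cyc <- build_archetypal_cycle()
  sp <- sequence_spec(n_days = 12, true_phase = 0.6, seed = 3)
  s <- generate_cycle_sequence(sp, cyc)
  f1 <- fit_cycle_phase(s$collected_at_days, s$stage, cyc)
  f2 <- fit_cycle_phase(s$collected_at_days + 3 * cyc$period_days, s$stage, cyc)
  expect_equal(f1$best_phase, f2$best_phase)
  expect_equal(f1$pearson_r, f2$pearson_r, tolerance = 1e-12)
})

test_that("prediction resolution agrees, flags outliers, or suggests transitions", {
  cyc <- build_archetypal_cycle()
  sp <- sequence_spec(n_days = 10, true_phase = 0.0, seed = 1)
  s <- generate_cycle_sequence(sp, cyc)
  fit <- fit_cycle_phase(s$collected_at_days, s$stage, cyc)
  # agreement: no flags
  t1 <- s$collected_at_days[3]
  cyc_stage <- number_to_stage(eval_waveform(cyc, t1 + fit$best_phase * cyc$period_days))
  probs <- stats::setNames(rep(0.02, 4), canonical_stages())
  probs[cyc_stage] <- 0.94
  r <- resolve_prediction(classification_result(probs), fit, t1, cyc)
  expect_equal(r$stage, cyc_stage)
  expect_false(r$outlier_flag)
  expect_null(r$transition_suggestion)
  # disagreement at high CI: outlier flag, net stage stands
  other <- setdiff(canonical_stages(), cyc_stage)[1]
  probs2 <- stats::setNames(rep(0.05, 4), canonical_stages())
  probs2[other] <- 0.85
  r2 <- resolve_prediction(classification_result(probs2), fit, t1, cyc)
  expect_true(r2$outlier_flag)
  expect_equal(r2$stage, other)
  expect_null(r2$transition_suggestion)
  # disagreement at low CI: transition between the stages nearest the fit
  probs3 <- stats::setNames(c(0.24, 0.24, 0.27, 0.25), canonical_stages())
  net3 <- classification_result(probs3)   # argmax estrus at low confidence
  expect_lt(net3$confidence_index, 0.30)
  # choose a time where the fitted waveform sits at position ~1.95 (proestrus,
  # near the proestrus/estrus boundary) so net and cycle classifications differ
  tgrid <- seq(0, cyc$period_days, by = 0.001)
  pos <- eval_waveform(cyc, tgrid + fit$best_phase * cyc$period_days)
  t3 <- tgrid[which.min(abs(pos - 1.95))]
  r3 <- resolve_prediction(net3, fit, t3, cyc)
  expect_equal(r3$cyclicity_stage, "proestrus")
  expect_equal(r3$transition_suggestion, "proestrus/estrus")
})

test_that("a transition is never suggested at or above the CI threshold", {
  cyc <- build_archetypal_cycle()
  sp <- sequence_spec(n_days = 10, true_phase = 0.5, seed = 11)
  s <- generate_cycle_sequence(sp, cyc)
  fit <- fit_cycle_phase(s$collected_at_days, s$stage, cyc)
  set.seed(21)
  for (i in 1:50) {
    p <- rgamma(4, 1); p <- p / sum(p)
    net <- classification_result(stats::setNames(p, canonical_stages()))
    r <- resolve_prediction(net, fit, runif(1, 0, 10), cyc)
    if (net$confidence_index >= 0.30) expect_null(r$transition_suggestion)
    if (!is.null(r$transition_suggestion)) {
      expect_true(r$transition_suggestion %in% transition_stages())
      expect_false(r$outlier_flag)
    }
  }
})

test_that("pseudopregnancy flags a diestrus run 50% longer than the baseline", {
  # half-day sampling: prior diestrus runs of 2.0 days, current run 3.5 days
  mk <- function(current_samples) {
    stages <- c(rep("diestrus", 4), "proestrus", "estrus", "metestrus",
                rep("diestrus", 4), "proestrus", "estrus", "metestrus",
                rep("diestrus", current_samples))
    times <- seq(0, by = 0.5, length.out = length(stages))
    list(times = times, stages = stages)
  }
  x <- mk(7)   # 3.0 + 0.5 = 3.5 days > 1.5 * 2.0
  r <- detect_pseudopregnancy(x$times, x$stages)
  expect_true(r$flag)
  expect_equal(r$current_run_days, 3.5)
  expect_equal(r$baseline_days, 2.0)
  x2 <- mk(5)  # 2.5 days <= 3.0: no flag
  r2 <- detect_pseudopregnancy(x2$times, x2$stages)
  expect_false(r2$flag)
  # no prior completed diestrus run: insufficient history
  r3 <- detect_pseudopregnancy(0:4, rep("diestrus", 5))
  expect_equal(r3$status, "insufficient_history")
  expect_false(r3$flag)
})

test_that("anestrus flags leukocyte runs strictly longer than two days", {
  expect_true(detect_anestrus_from_counts(1:3, c(0.95, 0.95, 0.95))$flag)
  expect_false(detect_anestrus_from_counts(1:4, c(0.95, 0.5, 0.95, 0.95))$flag)
  expect_false(detect_anestrus_from_counts(numeric(0), numeric(0))$flag)
  # threshold is strict: exactly 0.9 does not count
  expect_false(detect_anestrus_from_counts(1:3, c(0.9, 0.9, 0.9))$flag)
})
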