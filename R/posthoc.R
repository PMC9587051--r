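# Post-hoc machinery downstream of the softmax: the Confidence Index, the
# archetypal estrous cycle and its phase fitting by Pearson-correlation grid
# search, outlier flagging, transition-stage suggestion, and pseudopregnancy /
# anestrus detection.

#' Confidence Index of a softmax output
#'
#' The normalized margin between the two largest per-stage probabilities,
#' `CI = (Pmax - Pmax-1) / (Pmax + Pmax-1)`. A CI of 1 indicates all
#' probability mass in one stage; 0 indicates an exact tie between the top
#' two classifications.
#'
#' @param p Numeric probability vector (at least 2 entries, non-negative, not
#'   all zero).
#' @return CI in `[0, 1]`.
#' @export
confidence_index <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 2 || any(is.na(p)) || any(p < 0)) {
    stopf("confidence_index expects a probability vector of length >= 2")
  }
  if (sum(p) == 0) stopf("all-zero vector is not a probability vector")
  top <- sort(p, decreasing = TRUE)[1:2]
  (top[1] - top[2]) / (top[1] + top[2])
}

#' Build the archetypal estrous cycle
#'
#' Constructs the periodic waveform mapping time in days to stage number.
#' Starting at the metestrus-to-diestrus boundary (stage number 0), each
#' stage occupies its configured fraction of the period; the waveform passes
#' through each stage's temporal midpoint at that stage's number (0.5, 1.5,
#' 2.5, 3.5) and reaches 4 (wrapping to 0) at the end of the period.
#'
#' Two waveform modes are provided, both passing through the five anchor
#' points: `"interpolation"` (default) joins them by periodic piecewise-linear
#' monotone interpolation; `"sinusoid"` least-squares fits
#' `a*sin(2*pi*t/T) + b*cos(2*pi*t/T) + c` to the anchors for comparison.
#'
#' @param stage_fractions Named or positional numeric of 4 positive per-stage
#'   duration fractions (D, P, E, M) summing to 1. The defaults
#'   (0.35, 0.15, 0.30, 0.20) are configurable placeholders, not literature
#'   point estimates.
#' @param period_days Total cycle period in days (default 4.8).
#' @param waveform `"interpolation"` or `"sinusoid"`.
#' @param phase_increment Grid step, in cycle units, used by
#'   [fit_cycle_phase()] (default 0.1).
#' @return An `archetypal_cycle` object.
#' @export
build_archetypal_cycle <- function(stage_fractions = c(diestrus = 0.35,
                                                       proestrus = 0.15,
                                                       estrus = 0.30,
                                                       metestrus = 0.20),
                                   period_days = 4.8,
                                   waveform = c("interpolation", "sinusoid"),
                                   phase_increment = 0.1) {
  waveform <- match.arg(waveform)
  f <- as.numeric(stage_fractions)
  if (length(f) != 4 || any(f <= 0)) stopf("stage_fractions must be 4 positive values")
  if (abs(sum(f) - 1) > 1e-6) stopf("stage_fractions must sum to 1 (tolerance 1e-6)")
  f <- f / sum(f)
  names(f) <- canonical_stages()
  bounds <- c(0, cumsum(f)) * period_days       # stage boundaries in days
  mids <- (bounds[-5] + bounds[-1]) / 2          # temporal midpoints
  anchor_t <- c(0, mids, period_days)
  anchor_v <- c(0, 0.5, 1.5, 2.5, 3.5, 4)
  sin_coef <- NULL
  if (waveform == "sinusoid") {
    X <- cbind(sin(2 * pi * anchor_t / period_days),
               cos(2 * pi * anchor_t / period_days), 1)
    # the two wrap anchors (t = 0 -> 0 and t = T -> 4) average to 2 under a
    # periodic basis; solve in least squares
    sin_coef <- qr.solve(X, anchor_v)
  }
  structure(list(period_days = period_days, stage_fractions = f,
                 stage_numbers = c(diestrus = 0.5, proestrus = 1.5,
                                   estrus = 2.5, metestrus = 3.5),
                 boundaries_days = bounds, midpoints_days = mids,
                 anchor_t = anchor_t, anchor_v = anchor_v,
                 waveform = waveform, sin_coef = sin_coef,
                 phase_increment = phase_increment),
            class = "archetypal_cycle")
}

#' Evaluate the archetypal waveform
#'
#' @param cycle An `archetypal_cycle`.
#' @param t Numeric vector of times in days (any real; the waveform is
#'   periodic with period `cycle$period_days`).
#' @return Stage numbers in `[0, 4)`.
#' @export
eval_waveform <- function(cycle, t) {
  tt <- t %% cycle$period_days
  if (cycle$waveform == "sinusoid") {
    v <- cycle$sin_coef[1] * sin(2 * pi * tt / cycle$period_days) +
      cycle$sin_coef[2] * cos(2 * pi * tt / cycle$period_days) +
      cycle$sin_coef[3]
    return(v %% 4)
  }
  stats::approx(cycle$anchor_t, cycle$anchor_v, xout = tt, method = "linear",
                rule = 2)$y %% 4
}

#' @export
print.archetypal_cycle <- function(x, ...) {
  cat(sprintf("<archetypal_cycle> period %.2f days, %s waveform\n",
              x$period_days, x$waveform))
  cat("stage fractions:",
      paste(names(x$stage_fractions),
            sprintf("%.2f", x$stage_fractions), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

circular_stage_distance <- function(a, b) {
  d <- abs(a - b) %% 4
  pmin(d, 4 - d)
}

#' Fit the cycle phase to a sequence of stage classifications
#'
#' Grid search over phase shifts: for each phase on the grid
#' `{0, phase_increment, ..., 1 - phase_increment}` (cycle units), the Pearson
#' correlation between the numeric encoding of the classified stages and the
#' archetypal waveform evaluated at the shifted sample times is computed; the
#' phase with maximum correlation wins (ties broken toward the smaller
#' phase). Samples whose stage number deviates from the fitted waveform by
#' more than `deviation_threshold` — distance measured on the stage-number
#' circle (modulo 4) — are flagged as outliers.
#'
#' Requires more than four days of samples: `n > 4 * x`, where `x` is the
#' sampling frequency per day (estimated from the median sampling interval
#' when not supplied).
#'
#' @param times Strictly increasing sample times in days.
#' @param stages Character vector of classified stage labels.
#' @param cycle An [build_archetypal_cycle()] result.
#' @param deviation_threshold Outlier threshold on circular stage distance
#'   (default 1.0).
#' @param samples_per_day Optional sampling frequency; estimated from `times`
#'   when `NULL`.
#' @return A `cycle_fit` list: `best_phase`, `pearson_r`, `r_by_phase` (named
#'   by grid phase), `outlier_indices`, `fitted_numbers`, `residuals`.
#' @export
fit_cycle_phase <- function(times, stages, cycle = build_archetypal_cycle(),
                            deviation_threshold = 1.0,
                            samples_per_day = NULL) {
  if (length(times) != length(stages)) stopf("times and stages lengths differ")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  x <- samples_per_day %||%
    (if (length(times) > 1) 1 / stats::median(diff(times)) else 1)
  if (length(times) <= 4 * x) {
    stopf(paste("cycle fitting needs more than 4 days of samples",
                "(n > 4 * samples_per_day); collect more data"))
  }
  nums <- stage_to_number(stages)
  if (stats::sd(nums) == 0) stopf("degenerate sequence: constant stage labels")
  phases <- seq(0, 1 - cycle$phase_increment, by = cycle$phase_increment)
  r_by_phase <- vapply(phases, function(phi) {
    w <- eval_waveform(cycle, times + phi * cycle$period_days)
    if (stats::sd(w) == 0) return(NA_real_)
    cor(nums, w)
  }, numeric(1))
  if (all(is.na(r_by_phase))) stopf("degenerate sequence: constant waveform at all phases")
  names(r_by_phase) <- sprintf("%.1f", phases)
  best <- which.max(r_by_phase)  # which.max takes the first (smallest phase) on ties
  best_phase <- phases[best]
  fitted <- eval_waveform(cycle, times + best_phase * cycle$period_days)
  resid <- circular_stage_distance(nums, fitted)
  structure(list(best_phase = best_phase, pearson_r = unname(r_by_phase[best]),
                 r_by_phase = r_by_phase,
                 outlier_indices = which(resid > deviation_threshold),
                 fitted_numbers = fitted, residuals = resid,
                 times = times, deviation_threshold = deviation_threshold),
            class = "cycle_fit")
}

#' @export
print.cycle_fit <- function(x, ...) {
  cat(sprintf("<cycle_fit> best phase %.1f cycles, Pearson r = %.3f, %d outlier(s)\n",
              x$best_phase, x$pearson_r, length(x$outlier_indices)))
  invisible(x)
}

#' Construct a classification result
#'
#' Bundles the predicted stage, the per-stage probabilities and the
#' Confidence Index computed from them, plus the post-hoc flag slots filled
#' in by [resolve_prediction()].
#'
#' @param probabilities Named per-stage probability vector (summing to 1).
#' @param stage Predicted stage; defaults to the argmax with ties broken in
#'   canonical stage order.
#' @param image_path Optional image identifier carried through to output.
#' @return An `estrous_result`.
#' @export
classification_result <- function(probabilities, stage = NULL,
                                  image_path = NA_character_) {
  p <- as.numeric(probabilities)
  if (abs(sum(p) - 1) > 1e-6) stopf("probabilities must sum to 1")
  nm <- names(probabilities) %||% canonical_stages()[seq_along(p)]
  if (is.null(stage)) stage <- nm[which.max(p)]  # first max = canonical order
  structure(list(image_path = image_path, stage = stage,
                 probabilities = stats::setNames(p, nm),
                 confidence_index = confidence_index(p),
                 cyclicity_stage = NULL, outlier_flag = FALSE,
                 transition_suggestion = NULL, pseudopregnancy_flag = FALSE,
                 fitted_phase = NULL),
            class = "estrous_result")
}

#' @export
print.estrous_result <- function(x, ...) {
  cat(sprintf("<estrous_result> %s (CI %.2f)%s\n", x$stage, x$confidence_index,
              if (!is.null(x$transition_suggestion))
                sprintf(" transition? %s", x$transition_suggestion)
              else if (x$outlier_flag) " [outlier]" else ""))
  invisible(x)
}

#' Reconcile network and cycle-timing classifications
#'
#' Combines a softmax classification with the fitted archetypal cycle at the
#' sample's time. If the network stage and the cyclicity stage agree, the
#' network stage stands with no flags. If they differ and the Confidence
#' Index is at or above `ci_threshold`, the sample is flagged as an outlier
#' and both candidates are reported (the non-interactive default keeps the
#' network stage; an interactive caller may present the choice). If they
#' differ and the CI falls below `ci_threshold`, a transition stage is
#' suggested: the label joining the two canonical stages nearest the fitted
#' waveform position.
#'
#' @param net An `estrous_result` from [classification_result()].
#' @param fit A [fit_cycle_phase()] result covering this sample's time.
#' @param time Sample time in days.
#' @param cycle The [build_archetypal_cycle()] used for fitting.
#' @param ci_threshold CI threshold below which a transition is suggested
#'   (default 0.30).
#' @return The `estrous_result` with `cyclicity_stage`, `outlier_flag`,
#'   `transition_suggestion` and `fitted_phase` populated.
#' @export
resolve_prediction <- function(net, fit, time, cycle = build_archetypal_cycle(),
                               ci_threshold = 0.30) {
  stopifnot(inherits(net, "estrous_result"), inherits(fit, "cycle_fit"))
  position <- eval_waveform(cycle, time + fit$best_phase * cycle$period_days)
  net$fitted_phase <- fit$best_phase
  net$cyclicity_stage <- number_to_stage(position)
  if (identical(net$stage, net$cyclicity_stage)) {
    net$outlier_flag <- FALSE
    net$transition_suggestion <- NULL
    return(net)
  }
  if (net$confidence_index >= ci_threshold) {
    net$outlier_flag <- TRUE  # both candidates reported; net stage stands
    ec_log("outlier flag: net=%s cycle=%s CI=%.2f at day %.2f",
           net$stage, net$cyclicity_stage, net$confidence_index, time)
  } else {
    net$transition_suggestion <- nearest_transition(position)
    ec_log("transition flag: net=%s cycle=%s CI=%.2f -> suggest %s",
           net$stage, net$cyclicity_stage, net$confidence_index,
           net$transition_suggestion)
  }
  net
}

run_durations <- function(times, in_run) {
  # maximal TRUE runs; duration = span + one median sampling interval
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  runs <- rle(in_run)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  data.frame(start = starts[keep], end = ends[keep],
             duration = times[ends[keep]] - times[starts[keep]] + dt)
}

#' Detect pseudopregnancy from prolonged diestrus
#'
#' Tracks consecutive diestrus runs (in days) across a sequentially sampled
#' series and raises a warning flag when the current diestrus run lasts more
#' than `factor` times the mean duration of the diestrus runs of previous
#' complete cycles (default: 50% longer). At least `min_history_cycles`
#' completed prior diestrus runs are required; otherwise the status is
#' `"insufficient_history"`.
#'
#' A run's duration is the time spanned by its samples plus one median
#' sampling interval (so `k` consecutive daily samples count as `k` days).
#'
#' @param times Strictly increasing sample times in days.
#' @param stages Character vector of final stage labels.
#' @param min_history_cycles Minimum number of completed prior diestrus runs.
#' @param factor Flag when current run exceeds `factor` times the baseline
#'   (strictly greater; default 1.5).
#' @return List with `flag`, `status` (`"ok"`, `"flagged"`,
#'   `"insufficient_history"`), `onset_index` (first sample at which the
#'   current run exceeded the threshold, or `NA`), `current_run_days`,
#'   `baseline_days`.
#' @export
detect_pseudopregnancy <- function(times, stages, min_history_cycles = 1,
                                   factor = 1.5) {
  stopifnot(length(times) == length(stages))
  if (length(times) == 0) {
    return(list(flag = FALSE, status = "insufficient_history",
                onset_index = NA_integer_, current_run_days = 0,
                baseline_days = NA_real_))
  }
  stages <- normalize_stage(stages, allow_na = FALSE)
  in_d <- stages == "diestrus"
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  runs <- run_durations(times, in_d)
  n <- length(times)
  current <- if (nrow(runs) > 0 && runs$end[nrow(runs)] == n) runs[nrow(runs), ] else NULL
  prior <- if (is.null(current)) runs else runs[-nrow(runs), , drop = FALSE]
  if (nrow(prior) < min_history_cycles) {
    return(list(flag = FALSE, status = "insufficient_history",
                onset_index = NA_integer_,
                current_run_days = if (is.null(current)) 0 else current$duration,
                baseline_days = NA_real_))
  }
  baseline <- mean(prior$duration)
  threshold <- factor * baseline
  if (is.null(current)) {
    return(list(flag = FALSE, status = "ok", onset_index = NA_integer_,
                current_run_days = 0, baseline_days = baseline))
  }
  # duration of the current run up to each of its samples
  idx <- current$start:current$end
  partial <- times[idx] - times[current$start] + dt
  over <- which(partial > threshold)
  if (length(over) == 0) {
    return(list(flag = FALSE, status = "ok", onset_index = NA_integer_,
                current_run_days = current$duration, baseline_days = baseline))
  }
  onset <- idx[over[1]]
  ec_log("pseudopregnancy flag: diestrus run %.2f d > %.2f x baseline %.2f d (sample %d)",
         current$duration, factor, baseline, onset)
  list(flag = TRUE, status = "flagged", onset_index = onset,
       current_run_days = current$duration, baseline_days = baseline)
}

#' Detect anestrus from leukocyte proportions
#'
#' Flags an anestrous state when the leukocyte fraction exceeds
#' `leuk_threshold` over a consecutive span strictly longer than `min_days`
#' days (default: more than 2 consecutive days above 90% leukocytes). Span
#' duration follows the same convention as [detect_pseudopregnancy()].
#'
#' @param times Strictly increasing sample times in days.
#' @param leukocyte_frac Numeric vector of leukocyte proportions aligned with
#'   `times` (a manifest's `leukocyte_frac` column).
#' @param leuk_threshold Leukocyte proportion threshold (default 0.9,
#'   strictly greater).
#' @param min_days Minimum span in days (default 2, strictly greater).
#' @return List with `flag`, `max_run_days`, `run_start_index` (`NA` when not
#'   flagged).
#' @export
detect_anestrus_from_counts <- function(times, leukocyte_frac,
                                        leuk_threshold = 0.9, min_days = 2) {
  stopifnot(length(times) == length(leukocyte_frac))
  if (length(times) == 0) {
    return(list(flag = FALSE, max_run_days = 0, run_start_index = NA_integer_))
  }
  high <- !is.na(leukocyte_frac) & leukocyte_frac > leuk_threshold
  runs <- run_durations(times, high)
  if (nrow(runs) == 0) {
    return(list(flag = FALSE, max_run_days = 0, run_start_index = NA_integer_))
  }
  k <- which.max(runs$duration)
  flag <- runs$duration[k] > min_days
  if (flag) {
    ec_log("anestrus flag: %.2f consecutive days > %.0f%% leukocytes",
           runs$duration[k], 100 * leuk_threshold)
  }
  list(flag = flag, max_run_days = runs$duration[k],
       run_start_index = if (flag) runs$start[k] else NA_integer_)
}
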