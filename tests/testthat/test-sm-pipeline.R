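test_that("truncated-exponential MLE matches its closed form", {
  f <- fit_dwell_exponential(c(2, 3, 5), t_min = 1, min_n = 3)
  expect_equal(f$koff, 3 / 7)

  # censored dwells contribute survival terms only
  fc <- fit_dwell_exponential(c(2, 3, 5, 10), t_min = 1,
                              censored = c(FALSE, FALSE, FALSE, TRUE),
                              include_censored = TRUE, min_n = 3)
  expect_equal(fc$koff, 3 / (1 + 2 + 4 + 9))
  # excluded by default
  fx <- fit_dwell_exponential(c(2, 3, 5, 10), t_min = 1,
                              censored = c(FALSE, FALSE, FALSE, TRUE),
                              min_n = 3)
  expect_equal(fx$koff, 3 / 7)

  expect_error(fit_dwell_exponential(c(2, 3), min_n = 20), "at least 20")
  expect_error(fit_dwell_exponential(rep(1, 30), t_min = 1), "degenerate")
})

test_that("dwell MLE is unbiased under any truncation point", {
  # memorylessness: the left-truncated MLE stays centred on the rate
  for (t_min in c(0, 0.5, 1)) {
    set.seed(101 + round(10 * t_min))
    est <- replicate(200, {
      d <- rexp(200, 0.1)
      d <- d[d >= t_min]
      fit_dwell_exponential(d, t_min = t_min)$koff
    })
    expect_lt(abs(median(est) / 0.1 - 1), 0.03)
  }
})

test_that("dwell fitting covers the generating single-molecule off-rate", {
  # estimate within its own 95% CI in ~95% of repeats
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    d <- rexp(500, 4.0e-2)
    d <- d[d >= 0.2]
    f <- fit_dwell_exponential(d, t_min = 0.2)
    abs(f$koff - 4.0e-2) <= 1.96 * f$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("dwell analysis is invariant to the acquisition frame interval", {
  # the same process sampled at 0.2 s and 0.5 s exposures gives
  # statistically indistinguishable rates
  est <- vapply(c(0.2, 0.5), function(dt) {
    set.seed(77)
    d <- rexp(2000, 0.138)
    d <- round(d / dt) * dt          # frame quantization
    d <- d[d >= 2 * dt]
    fit_dwell_exponential(d, t_min = 2 * dt)$koff
  }, numeric(1))
  expect_lt(abs(est[1] / est[2] - 1), 0.1)
})

test_that("event detection segments traces by hysteresis thresholding", {
  set.seed(5)
  x <- rnorm(300, sd = 0.1)
  x[51:120] <- x[51:120] + 1          # frames 50..119 (0-based), end 120
  ev <- detect_events(x, frame_interval_s = 0.2, high = 0.5, low = 0.3)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 50L)
  expect_equal(ev$end_frame, 120L)
  expect_equal(ev$duration_s, 70 * 0.2)
  expect_false(ev$censored)

  # pure noise below threshold: nothing detected
  ev0 <- detect_events(rnorm(300, sd = 0.1), 0.2, high = 0.5, low = 0.3)
  expect_equal(nrow(ev0), 0L)

  # an event running off the trace end is censored
  x2 <- rnorm(100, sd = 0.1); x2[81:100] <- x2[81:100] + 1
  ev2 <- detect_events(x2, 0.2, high = 0.5, low = 0.3)
  expect_true(ev2$censored[nrow(ev2)])
  expect_equal(ev2$end_frame[nrow(ev2)], 100L)

  expect_error(detect_events(x, 0.2, high = 0.3, low = 0.5), "inverted")
})

test_that("event detection recovers simulated event lists at SNR 5", {
  # sparse occupancy, as in real surface-tethered experiments: the default
  # noise-derived thresholds assume the trace is mostly unbound
  des <- sm_design(n_traces = 150, trace_frames = 1000, arrival_rate = 0.005,
                   k_neg1 = 0.04, k_b = 0, snr = 5)
  ds <- generate_sm_dataset(des, mode = "traces", seed = 9)
  truth <- ds$truth$events
  recalls <- c(); bnd_err <- c()
  for (pid in unique(truth$particle_id)) {
    tr <- ds$traces[ds$traces$particle_id == pid, ]
    ev <- detect_events(tr$intensity, des$frame_interval_s)
    tru <- truth[truth$particle_id == pid, ]
    for (i in seq_len(nrow(tru))) {
      s_f <- tru$start_s[i] / des$frame_interval_s
      hit <- which(abs(ev$start_frame - s_f) <= 5)
      recalls <- c(recalls, length(hit) > 0)
      if (length(hit)) {
        bnd_err <- c(bnd_err, abs(ev$start_frame[hit[1]] - ceiling(s_f)))
      }
    }
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(median(bnd_err), 1)
})

test_that("rate constants follow from apparent off-rates at two conditions", {
  # equal rates: no transfer
  expect_equal(estimate_rate_constants(0.04, 0.04, 1e-5)$k_theta, 0)

  # the single-molecule worked example: 0.040 -> 0.138 /s across a 10 uM
  # chase implies k_theta = 9.8e3 /M/s and a ratio of 2.45e5 /M
  est <- estimate_rate_constants(4.0e-2, 0.138, 1e-5)
  expect_equal(est$k_theta, 9.8e3, tolerance = 1e-9)
  expect_equal(est$ratio_M, 2.45e5, tolerance = 1e-9)

  expect_warning(est2 <- estimate_rate_constants(0.05, 0.04, 1e-5),
                 "clamped")
  expect_equal(est2$k_theta, 0)
})

test_that("photobleaching is a subtractive competing-risk correction", {
  expect_equal(photobleach_correct(0.04, 0)$koff_corrected, 0.04)
  pc <- photobleach_correct(0.040, 0.004)
  expect_equal(pc$koff_corrected, 0.036)
  expect_equal(pc$bleach_fraction, 0.10)
  expect_error(photobleach_correct(0.03, 0.03), "exceed")

  # competing-risks simulation: apparent rate is the sum, correction
  # recovers the dissociation rate
  set.seed(13)
  d <- pmin(rexp(4000, 0.04), rexp(4000, 0.008))
  app <- fit_dwell_exponential(d[d >= 0.1], t_min = 0.1)$koff
  expect_equal(app, 0.048, tolerance = 0.05)
  expect_equal(photobleach_correct(app, 0.008)$koff_corrected, 0.04,
               tolerance = 0.1)
})

test_that("two-colour transfer classification honours the ternary window", {
  red <- data.frame(particle_id = 1L, start_frame = 0L, end_frame = 100L)
  # arrival 0.1 s after the red departure at 10.0 s: one transfer
  green <- data.frame(particle_id = 1L, start_frame = 101L,
                      end_frame = 150L)
  tr <- detect_transfer_events(red, green, frame_interval_s = 0.1,
                               window_s = 0.15)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$from_channel, "red")
  expect_equal(tr$gap_s, 0.1)

  # a 0.5 s gap is independent rebinding, not transfer
  green2 <- data.frame(particle_id = 1L, start_frame = 105L,
                       end_frame = 150L)
  expect_equal(nrow(detect_transfer_events(red, green2, 0.1, 0.15)), 0L)

  # wrong particle: no colocalization, no transfer
  green3 <- data.frame(particle_id = 2L, start_frame = 101L,
                       end_frame = 150L)
  expect_equal(nrow(detect_transfer_events(red, green3, 0.1, 0.15)), 0L)

  # symmetric under channel swap: same event found, labels exchanged
  tr_sw <- detect_transfer_events(green, red, 0.1, 0.15)
  expect_equal(nrow(tr_sw), 1L)
  expect_equal(tr_sw$gap_s, tr$gap_s)
  expect_equal(tr_sw$from_channel, "green")
})

test_that("simulated two-colour streams give back the transfer fraction", {
  fr <- vapply(1:50, function(s) {
    ds <- generate_sm_dataset(sm_design(n_traces = 150, arrival_rate = 0.05),
                              mode = "two_colour", seed = s)
    tr <- detect_transfer_events(ds$events_red, ds$events_green,
                                 frame_interval_s = 0.2)
    transfer_event_fraction(nrow(tr), ds$truth$n_binding_events)
  }, numeric(1))
  # 8% of departures are generated as transfers; some events are censored
  # (no departure), so the event-level truth sits slightly below 8%
  expect_lt(abs(mean(fr) - 8), 2)
})

test_that("transfer percentages follow from raw counts", {
  expect_equal(round(transfer_event_fraction(36, 453), 1), 7.9)
  expect_equal(round(transfer_event_fraction(34, 781), 1), 4.4)
  expect_equal(transfer_event_fraction(0, 100), 0)
  expect_error(transfer_event_fraction(1, 0), "> 0")
})

test_that("dwell analysis across conditions estimates both rate constants", {
  d0 <- generate_sm_dataset(sm_design(competitor_M = 0), n_events = 800,
                            seed = 2)
  d1 <- generate_sm_dataset(sm_design(competitor_M = 1e-5), n_events = 800,
                            seed = 1002)
  est <- analyze_sm_dwells(rbind(d0$dwells, d1$dwells), t_min = 0.4,
                           k_b = 0.004)
  expect_equal(est$k_neg1, 0.04, tolerance = 0.15)
  expect_equal(est$k_theta, 9800, tolerance = 0.15)
  # estimator consistency: bias shrinks with sample size
  err <- vapply(c(50, 200, 1000), function(n) {
    e <- vapply(1:30, function(s) {
      a <- generate_sm_dataset(sm_design(competitor_M = 0, k_b = 0),
                               n_events = n, seed = s)
      fit_dwell_exponential(a$dwells$duration_s, t_min = 0.4,
                            censored = a$dwells$censored, min_n = 10)$koff
    }, numeric(1))
    abs(mean(e) / 0.04 - 1)
  }, numeric(1))
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1] + 0.05)
})
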