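test_that("half-wave durations follow the band geometry of the input", {
  fs <- 512
  tt <- seq(0, 30, by = 1 / fs)[-1]
  # 2-Hz sinusoid: every half-wave lasts exactly a half period of 0.25 s
  rec2 <- new_recording(matrix(50 * sin(2 * pi * 2 * tt), nrow = 1), fs = fs)
  rec2$wake_mask <- rep(TRUE, ncol(rec2$samples))
  cand <- detect_halfwaves(rec2, threshold_ref = c(ch1 = 0))
  expect_gt(nrow(cand), 50)
  # interior waves are exact half-periods; band-pass edge transients may
  # distort the first and last second of the trace
  interior <- cand$peak_t > 2 & cand$peak_t < 28
  expect_true(all(abs((cand$end_t - cand$start_t)[interior] - 0.25) < 2 / fs))
  # 10-Hz sinusoid: 0.05-s half-waves all rejected by the duration window
  rec10 <- new_recording(matrix(50 * sin(2 * pi * 10 * tt), nrow = 1), fs = fs)
  rec10$wake_mask <- rep(TRUE, ncol(rec10$samples))
  expect_equal(nrow(detect_halfwaves(rec10, threshold_ref = c(ch1 = 0))), 0)
})

test_that("the percentile filter keeps only waves strictly above the cut", {
  fs <- 512
  tt <- seq(0, 50, by = 1 / fs)[-1]
  # equal-amplitude half-waves: nothing is strictly above the 90th percentile
  rec <- new_recording(matrix(50 * sin(2 * pi * 2 * tt), nrow = 1), fs = fs)
  rec$wake_mask <- rep(TRUE, ncol(rec$samples))
  cand <- detect_halfwaves(rec)
  expect_lte(nrow(cand), 0.1 * 2 * 2 * 50)
  # graded amplitudes: close to 10% retained, all from the top
  set.seed(41)
  amp <- 1 + 0.5 * sin(2 * pi * 0.02 * tt)
  rec2 <- new_recording(matrix(50 * amp * sin(2 * pi * 2 * tt), nrow = 1), fs = fs)
  rec2$wake_mask <- rep(TRUE, ncol(rec2$samples))
  cand2 <- detect_halfwaves(rec2)
  expect_gt(nrow(cand2), 0)
  expect_true(all(cand2$amplitude > cand2$threshold))
})

test_that("constant signals produce no candidates", {
  rec <- new_recording(matrix(3, 1, 512 * 10), fs = 512)
  rec$wake_mask <- rep(TRUE, ncol(rec$samples))
  expect_equal(nrow(detect_halfwaves(rec)), 0)
})

test_that("candidates within 1 s of a same-channel IED are discarded", {
  cand <- data.frame(channel = c("a", "a", "a"), start_t = c(5.2, 6.9, 5.2),
                     end_t = c(5.6, 7.3, 5.6), peak_t = c(5.4, 7.1, 5.4),
                     polarity = 1L, amplitude = 10, threshold = 1)
  cand$channel <- c("a", "a", "b")
  ied <- data.frame(kind = "IED", channel = "a", peak_t = 5.0,
                    polarity = 1L, amplitude = 5, burst_id = 1L)
  kept <- exclude_near_ied(cand, ied)
  # 5.4 on channel a removed (0.4 s away); 7.1 kept; 5.4 on channel b kept
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$peak_t == c(7.1, 5.4)))
  expect_identical(kept$channel, c("a", "b"))
  # empty IED set is a no-op
  expect_equal(nrow(exclude_near_ied(cand, empty_events())), 3)
})

test_that("the downstate gate separates downstate from non-downstate waves", {
  cfg <- sim_config(n_channels = 2, duration = 180, seed = 43)
  bg <- make_background(cfg)
  # all times inside simulated wake blocks ([0,30), [60,90) s)
  times <- list(c(20, 65, 85), c(22, 67, 87))
  flags <- list(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, FALSE))
  inj <- inject_events(bg, cfg, ied_times = list(numeric(0), numeric(0)),
                       lows_times = times, lows_downstate = flags)
  rec <- wake_mask(notch_filter(inj$recording))
  cand <- detect_halfwaves(rec)
  lows <- suppressMessages(downstate_gate(cand, rec))
  truth <- inj$truth
  got_ds <- vapply(seq_len(nrow(truth)), function(i)
    any(lows$channel == truth$channel[i] &
          abs(lows$peak_t - truth$peak_t[i]) < 0.25), logical(1))
  # every truth wave with a downstate is kept, no truth wave without one is
  expect_true(all(got_ds[truth$downstate]))
  expect_false(any(got_ds[!truth$downstate]))
  # empty candidate list passes through
  expect_equal(nrow(downstate_gate(cand[0, ], rec)), 0)
})

test_that("LoWS and IED sets are disjoint in time by construction", {
  fx <- fx_small_pipeline()
  for (ch in unique(fx$lows$channel)) {
    lt <- fx$lows$peak_t[fx$lows$channel == ch]
    it <- fx$ied$peak_t[fx$ied$channel == ch]
    if (!length(it) || !length(lt)) next
    expect_gt(min(vapply(lt, function(t) min(abs(t - it)), numeric(1))), 1)
  }
})

test_that("LoWS detection is invariant to global amplitude rescaling", {
  fx <- fx_small_pipeline()
  rec2 <- fx$rec
  rec2$samples <- rec2$samples * 0.1
  l2 <- suppressMessages(detect_lows(rec2, detect_ieds(rec2)))
  expect_equal(l2$peak_t, fx$lows$peak_t)
  expect_equal(l2$channel, fx$lows$channel)
})

test_that("a reference threshold is applied unchanged when supplied", {
  fx <- fx_small_pipeline()
  ref <- setNames(rep(1e9, length(fx$rec$channels)), fx$rec$channels)
  cand <- detect_halfwaves(fx$rec, threshold_ref = ref)
  expect_equal(nrow(cand), 0)  # impossible cut removes everything
})
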