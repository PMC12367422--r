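test_that("degenerate configurations are rejected", {
  expect_error(sim_config(duration = 0), "duration")
  expect_error(sim_config(fs = 256), "fs")
  expect_error(sim_config(ied_rate = -1), "rates")
  expect_error(sim_config(downstate_depth = 1.5), "downstate_depth")
})

test_that("background generation is deterministic given the seed", {
  cfg <- sim_config(n_channels = 2, duration = 30, seed = 7)
  b1 <- make_background(cfg)
  b2 <- make_background(cfg)
  expect_identical(b1$samples, b2$samples)
  b3 <- make_background(sim_config(n_channels = 2, duration = 30, seed = 8))
  expect_false(identical(b1$samples, b3$samples))
})

test_that("background PSD follows the configured 1/f slope", {
  cfg <- sim_config(n_channels = 1, duration = 60, fs = 512,
                    background_slope = 1, alpha_power = 0, seed = 3)
  bg <- make_background(cfg)
  # periodogram oracle: log-log regression of raw periodogram on frequency
  x <- bg$samples[1, ]
  n <- length(x)
  pg <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * 512 / n
  sel <- f >= 1 & f <= 100
  fit <- stats::lm(log(pg[sel]) ~ log(f[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) - (-1)), 0.2)
})

test_that("zero rates leave the signal untouched with an empty truth log", {
  cfg <- sim_config(n_channels = 2, duration = 60, ied_rate = 0,
                    lows_rate = 0, seed = 5)
  bg <- make_background(cfg)
  inj <- inject_events(bg, cfg)
  expect_identical(inj$recording$samples, bg$samples)
  expect_equal(nrow(inj$truth), 0)
})

test_that("an injected IED raises the 20-80 Hz envelope above threshold", {
  cfg <- sim_config(n_channels = 1, duration = 60, ied_amp_factor = 10, seed = 9)
  bg <- make_background(cfg)
  inj <- inject_events(bg, cfg, ied_times = list(30), lows_times = list(numeric(0)))
  env <- wakeslow:::hilbert_envelope(
    wakeslow:::filt_bandpass(inj$recording$samples[1, ], 512, 20, 80))
  m <- mean(wakeslow:::hilbert_envelope(
    wakeslow:::filt_bandpass(bg$samples[1, ], 512, 20, 80)))
  w <- round(30 * 512) + (-40:40)
  expect_gt(max(env[w]) / m, 3.5)
})

test_that("a downstate wave suppresses in-wave high-gamma power", {
  cfg <- sim_config(n_channels = 1, duration = 60, downstate_depth = 0.8, seed = 10)
  bg <- make_background(cfg)
  inj <- inject_events(bg, cfg, ied_times = list(numeric(0)),
                       lows_times = list(20), lows_downstate = list(TRUE))
  x <- inj$recording$samples[1, ]
  hg <- wakeslow:::filt_bandpass(x, 512, 45, 130)^2
  d <- inj$truth$duration[1]
  inside <- round((20 - d / 4) * 512):round((20 + d / 4) * 512)
  flank <- c(round(18 * 512):round(18.5 * 512), round(21.5 * 512):round(22 * 512))
  expect_lt(mean(hg[inside]), mean(hg[flank]))
})

test_that("injection counts follow the configured Poisson rates", {
  cfg <- sim_config(n_channels = 10, duration = 600, seed = 12)
  inj <- inject_events(make_background(cfg), cfg)
  wake_min <- 600 / 60 / 2  # alternating 30-s blocks: half the time is wake
  for (kind in c("IED", "LoWS")) {
    rate <- if (kind == "IED") cfg$ied_rate else cfg$lows_rate
    lambda <- rate * wake_min * 10
    n <- sum(inj$truth$kind == kind)
    expect_lt(abs(n - lambda), 4 * sqrt(lambda))
  }
  # truth log sorted and strictly inside the recording
  expect_true(all(inj$truth$peak_t > 0 & inj$truth$peak_t < 600))
  expect_true(!is.unsorted(inj$truth$peak_t[inj$truth$channel == "ch1"]))
})

test_that("cohort simulation is reproducible and plants the delay interaction", {
  spec <- cohort_spec(n_patients = 12, seed = 4)
  cfg <- sim_config(n_channels = 8, duration = 600, seed = 4)
  c1 <- simulate_cohort(spec, cfg, require_classes = FALSE)
  c2 <- simulate_cohort(spec, cfg, require_classes = FALSE)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$patients, c2$patients)

  # negative planted effect, good outcomes: resected delays shorter on average
  spec_neg <- cohort_spec(n_patients = 20,
                          engel_distribution = c(I = 1, II = 0, III = 0, IV = 0),
                          planted_interaction = 0.4, seed = 6)
  coh <- simulate_cohort(spec_neg, cfg, require_classes = FALSE)
  tab <- cohort_model_table(coh, "delay")
  expect_lt(mean(tab$value[tab$resected]), mean(tab$value[!tab$resected]))
})

test_that("null cohorts carry no resected/nonresected delay asymmetry", {
  coh <- simulate_cohort(cohort_spec(n_patients = 30, planted_interaction = 0,
                                     seed = 13),
                         sim_config(n_channels = 12, duration = 900, seed = 13),
                         require_classes = FALSE)
  tab <- cohort_model_table(coh, "delay")
  ratio <- mean(tab$value[tab$resected]) / mean(tab$value[!tab$resected])
  expect_lt(abs(ratio - 1), 0.15)
})

test_that("simulated events round-trip through the TSV interfaces", {
  coh <- simulate_cohort(cohort_spec(n_patients = 4, seed = 2),
                         sim_config(n_channels = 4, duration = 120, seed = 2),
                         require_classes = FALSE)
  td <- withr::local_tempdir()
  p1 <- file.path(td, "participants.tsv")
  write_participants_tsv(coh$patients, p1)
  back <- read_participants_tsv(p1)
  expect_equal(back$patient, coh$patients$patient)
  expect_equal(back$engel, coh$patients$engel_class)

  ch <- coh$channels[coh$channels$patient == "P01", ]
  p2 <- file.path(td, "channels.tsv")
  write_channels_tsv(ch, p2)
  ch2 <- read_channels_tsv(p2)
  expect_equal(ch2$name, ch$name)
  expect_equal(ch2$resected, ch$resected)

  ev <- coh$events[coh$events$patient == "P01", ]
  p3 <- file.path(td, "events.tsv")
  write_events_tsv(ev, p3)
  ev2 <- read_events_tsv(p3)
  expect_equal(nrow(ev2), nrow(ev))
  expect_equal(ev2$onset, ev$peak_t)
})
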