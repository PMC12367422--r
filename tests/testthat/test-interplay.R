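test_that("event rates are counts per wake minute", {
  ev <- data.frame(channel = rep("c1", 5), kind = "IED", peak_t = 1:5)
  r <- event_rates(ev, wake_min = 5)
  expect_equal(r$rate_ied, 1)
  expect_equal(r$rate_lows, 0)
  # channels absent from the event table get rate zero
  ch <- data.frame(name = c("c1", "c2"), x = 0, y = 0, z = 0,
                   gray = TRUE, soz = c(TRUE, FALSE), resected = FALSE)
  r2 <- event_rates(ev, 5, ch)
  expect_equal(r2$rate_ied, c(1, 0))
  expect_equal(r2$soz, c(TRUE, FALSE))
  expect_message(event_rates(ev, wake_min = 0), "zero wake")
})

test_that("simulated rates fall within the Poisson error bound", {
  cfg <- sim_config(n_channels = 10, duration = 1200, alpha_power = 0, seed = 61)
  spec <- cohort_spec(n_patients = 1, engel_distribution = c(I = 1),
                      planted_interaction = 0, seed = 61)
  coh <- simulate_cohort(spec, cfg, require_classes = FALSE)
  r <- event_rates(coh$events, coh$wake_minutes)
  for (kind in c("rate_ied", "rate_lows")) {
    rate <- if (kind == "rate_ied") cfg$ied_rate else cfg$lows_rate
    est <- mean(r[[kind]])
    lambda <- rate * coh$wake_minutes * 10
    expect_lt(abs(est - rate), 4 * sqrt(lambda) / (coh$wake_minutes * 10))
  }
})

test_that("pairwise delays pair each source with the next same-channel target", {
  ied <- data.frame(channel = "c1", kind = "IED", peak_t = 10)
  lows <- data.frame(channel = "c1", kind = "LoWS", peak_t = c(5, 13))
  d <- pairwise_delays(ied, lows)
  expect_equal(d$raw_delay, 3)
  # no later target: censored
  d2 <- pairwise_delays(ied, lows[1, , drop = FALSE])
  expect_equal(nrow(d2), 0)
  # reverse direction
  d3 <- pairwise_delays(ied, lows, direction = "lows2ied")
  expect_equal(d3$raw_delay, 5)
})

test_that("pairwise delays equal a brute-force minimum-forward-gap oracle", {
  oracle <- function(src, dst) {
    out <- unlist(lapply(src, function(s) {
      fwd <- dst[dst > s]
      if (length(fwd)) min(fwd) - s else NULL
    }))
    if (is.null(out)) numeric(0) else out
  }
  set.seed(62)
  for (i in 1:30) {
    src <- sort(stats::runif(sample(1:15, 1), 0, 100))
    dst <- sort(stats::runif(sample(1:25, 1), 0, 100))
    d <- pairwise_delays(
      data.frame(channel = "c1", peak_t = src),
      data.frame(channel = "c1", peak_t = dst))
    expect_equal(d$raw_delay, oracle(src, dst))
  }
})

test_that("delays crossing segment boundaries are censored", {
  ied <- data.frame(channel = "c1", peak_t = c(10, 40))
  lows <- data.frame(channel = "c1", peak_t = c(35, 45))
  seg <- cbind(c(0, 30), c(20, 60))
  d <- pairwise_delays(ied, lows, segments = seg)
  expect_equal(d$raw_delay, 5)   # only the 40 -> 45 pair stays in one segment
})

test_that("incidence correction follows its definition", {
  rec <- data.frame(channel = "c1", direction = "ied2lows",
                    from_t = 0, to_t = 15, raw_delay = 15)
  rates <- data.frame(channel = "c1", rate_ied = 1, rate_lows = 4)
  # 4 LoWS per minute: expected wait 15 s, so corrected delay is 1
  expect_equal(corrected_delays(rec, rates)$corrected_delay, 1)
  rates0 <- data.frame(channel = "c1", rate_ied = 1, rate_lows = 0)
  expect_message(out <- corrected_delays(rec, rates0), "zero target rate")
  expect_equal(nrow(out), 0)
})

test_that("corrected delays of Poisson trains have median ln 2 and are
           invariant to thinning the target train", {
  set.seed(63)
  meds <- thin_p <- numeric(40)
  for (i in 1:40) {
    ied <- cumsum(stats::rexp(80, 0.7 / 60))
    lows <- cumsum(stats::rexp(600, 3.8 / 60))
    span <- max(ied[80], lows[600]) / 60
    mk <- function(lw) {
      ev <- data.frame(channel = "c1",
                       kind = rep(c("IED", "LoWS"), c(80, length(lw))),
                       peak_t = c(ied, lw))
      d <- pairwise_delays(ev[ev$kind == "IED", ], ev[ev$kind == "LoWS", ])
      corrected_delays(d, event_rates(ev, span))$corrected_delay
    }
    full <- mk(lows)
    half <- mk(lows[stats::runif(600) < 0.5])
    meds[i] <- stats::median(full)
    thin_p[i] <- suppressWarnings(stats::ks.test(full, half)$p.value)
  }
  expect_lt(abs(mean(meds) - log(2)), 0.05)
  expect_gte(mean(thin_p > 0.05), 0.85)
})

test_that("corrected delays are scale-free under joint time rescaling", {
  set.seed(64)
  ied <- sort(stats::runif(30, 0, 600))
  lows <- sort(stats::runif(200, 0, 600))
  mk <- function(f) {
    ev <- data.frame(channel = "c1",
                     kind = rep(c("IED", "LoWS"), c(30, 200)),
                     peak_t = c(ied, lows) * f)
    d <- pairwise_delays(ev[ev$kind == "IED", ], ev[ev$kind == "LoWS", ])
    corrected_delays(d, event_rates(ev, 10 * f))$corrected_delay
  }
  expect_equal(mk(1), mk(3), tolerance = 1e-12)
})

test_that("resection aggregation takes channel medians then group means", {
  recs <- data.frame(channel = rep(c("a", "b", "c"), each = 3),
                     direction = "ied2lows",
                     from_t = 0, to_t = 1,
                     raw_delay = 1,
                     corrected_delay = c(1, 2, 3, 2, 4, 6, 10, 20, 30))
  ch <- data.frame(name = c("a", "b", "c"), x = 0, y = 0, z = 0, gray = TRUE,
                   soz = FALSE, resected = c(TRUE, FALSE, FALSE))
  agg <- aggregate_by_resection(recs, ch)
  expect_equal(agg$resected_mean, 2)            # single channel median
  expect_equal(agg$nonresected_mean, mean(c(4, 20)))
  # identical channels give identical group means
  ch2 <- ch; ch2$resected <- c(TRUE, TRUE, FALSE)
  recs2 <- recs; recs2$corrected_delay <- rep(c(1, 2, 3), 3)
  agg2 <- aggregate_by_resection(recs2, ch2)
  expect_equal(agg2$resected_mean, agg2$nonresected_mean)
  # one empty group excludes the patient
  ch3 <- ch; ch3$resected <- c(TRUE, TRUE, TRUE)
  expect_message(agg3 <- aggregate_by_resection(recs, ch3), "excluded")
  expect_equal(nrow(agg3), 0)
})

test_that("planted 2x shorter resected delays give a ratio near 0.5", {
  set.seed(65)
  rows <- list()
  for (ch in 1:10) {
    res <- ch <= 5
    rows[[ch]] <- data.frame(channel = sprintf("c%02d", ch),
                             direction = "ied2lows", from_t = 0, to_t = 1,
                             raw_delay = 1,
                             corrected_delay = stats::rexp(200, if (res) 2 else 1))
  }
  recs <- do.call(rbind, rows)
  ch <- data.frame(name = sprintf("c%02d", 1:10), x = 0, y = 0, z = 0,
                   gray = TRUE, soz = FALSE, resected = rep(c(TRUE, FALSE), each = 5))
  agg <- aggregate_by_resection(recs, ch)
  expect_lt(abs(agg$resected_mean / agg$nonresected_mean - 0.5), 0.1)
})

test_that("SOZ membership follows the 10-mm rule and preictal windows the
           -10 s cutoff", {
  channels <- data.frame(patient = "P01",
                         name = c("on", "near", "far"),
                         x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 9, 11))
  segments <- data.frame(patient = "P01",
                         segment_id = c("ii", "sz"),
                         kind = c("interictal", "seizure"),
                         start = c(0, 3 * 3600),
                         end = c(600, 3 * 3600 + 130),
                         onset_t = c(NA, 3 * 3600 + 120),
                         onset_channel = c(NA, "on"))
  set.seed(66)
  ev <- do.call(rbind, lapply(c("on", "near", "far"), function(nm) rbind(
    data.frame(patient = "P01", segment_id = "ii", channel = nm, kind = "IED",
               peak_t = stats::runif(10, 0, 600)),
    data.frame(patient = "P01", segment_id = "sz", channel = nm, kind = "LoWS",
               peak_t = stats::runif(22, 3 * 3600, 3 * 3600 + 110)))))
  lt <- suppressMessages(preictal_contrast_table(ev, segments, channels))
  expect_setequal(unique(lt$region), c("SOZ", "extraSOZ"))
  # SOZ = onset channel + the 9-mm neighbour; preictal window is 110 s
  soz_pre <- lt$rate[lt$region == "SOZ" & lt$period == "preictal" & lt$event == "LoWS"]
  # events in [onset-10, onset) must not count: all were placed before
  far_pre <- lt$rate[lt$region == "extraSOZ" & lt$period == "preictal" & lt$event == "LoWS"]
  n_on <- sum(ev$channel %in% c("on", "near") & ev$kind == "LoWS" &
                ev$peak_t < 3 * 3600 + 110)
  expect_equal(soz_pre, n_on / 2 / (110 / 60))
  n_far <- sum(ev$channel == "far" & ev$kind == "LoWS" & ev$peak_t < 3 * 3600 + 110)
  expect_equal(far_pre, n_far / (110 / 60))
})

test_that("interictal segments close to a seizure are dropped", {
  channels <- data.frame(patient = "P01", name = c("a", "b"),
                         x = c(0, 30), y = 0, z = 0)
  segments <- data.frame(patient = "P01",
                         segment_id = c("near_ii", "sz"),
                         kind = c("interictal", "seizure"),
                         start = c(0, 3600),
                         end = c(600, 3600 + 130),
                         onset_t = c(NA, 3600 + 120),
                         onset_channel = c(NA, "a"))
  ev <- data.frame(patient = "P01", segment_id = "near_ii", channel = "a",
                   kind = "IED", peak_t = 10)
  expect_message(lt <- preictal_contrast_table(ev, segments, channels),
                 "2 h")
  expect_false("interictal" %in% lt$period)
})

test_that("the simulated preictal cohort reproduces the planted rate pattern", {
  pc <- simulate_preictal_cohort(n_patients = 12, seed = 67)
  lt <- suppressMessages(preictal_contrast_table(pc$events, pc$segments, pc$channels))
  w <- stats::reshape(lt, idvar = c("patient", "region", "event"),
                      timevar = "period", direction = "wide")
  # LoWS increase before seizures, more outside the SOZ; IEDs stay flat
  dl <- w[w$event == "LoWS", ]
  diff_out <- mean(dl$rate.preictal[dl$region == "extraSOZ"] -
                     dl$rate.interictal[dl$region == "extraSOZ"])
  diff_in <- mean(dl$rate.preictal[dl$region == "SOZ"] -
                    dl$rate.interictal[dl$region == "SOZ"])
  expect_gt(diff_out, diff_in)
  expect_gt(diff_in, 0)
  di <- w[w$event == "IED", ]
  expect_lt(abs(mean(di$rate.preictal - di$rate.interictal)), 0.3)
})
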