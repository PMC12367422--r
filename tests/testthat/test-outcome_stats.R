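test_that("Engel linearisation maps classes and subclasses monotonically", {
  expect_equal(engel_linearize("I"), 1)
  expect_equal(engel_linearize("IV"), 4)
  expect_equal(engel_linearize(c("IA", "IB", "IIC", "IVD")),
               c(1, 1.25, 2.5, 4.75))
  # monotone in class for the default and for any custom map
  labs <- c("I", "II", "III", "IV")
  expect_true(all(diff(engel_linearize(labs)) > 0))
  custom <- c(I = 0, II = 10, III = 20, IV = 40)
  expect_true(all(diff(engel_linearize(labs, map = custom)) > 0))
  expect_error(engel_linearize("I", map = c(I = 2, II = 1, III = 3, IV = 4)),
               "monotone")
  expect_error(engel_linearize("V"), "unknown")
})

test_that("ROUT keeps identical values and flags gross outliers", {
  expect_true(all(rout_outliers(rep(3.2, 20))))
  set.seed(81)
  v <- c(stats::rnorm(20), 50)
  keep <- rout_outliers(v)
  expect_false(keep[21])
  expect_true(all(keep[1:20]))
  # Q -> 0 flags nothing
  expect_true(all(rout_outliers(v, Q = 0)))
  expect_warning(rout_outliers(1:5), "fewer than 8")
})

test_that("the outcome LMM reduces to ordinary regression when the random
           intercept variance vanishes", {
  set.seed(82)
  n <- 40
  tab <- data.frame(patient = rep(sprintf("P%02d", 1:n), each = 2),
                    engel_linear = rep(sample(1:4, n, TRUE), each = 2),
                    resected = rep(c(TRUE, FALSE), n))
  tab$value <- stats::rnorm(2 * n)   # independent errors, no patient effect
  fit <- fit_outcome_lmm(tab, "eq4")
  ols <- stats::lm(value ~ engel_linear * resected,
                   data = transform(tab, resected = as.numeric(resected)))
  t_int <- summary(ols)$coefficients["engel_linear:resected", "t value"]
  expect_equal(fit$F, t_int^2, tolerance = 1e-6)
  expect_equal(fit$df_den, stats::df.residual(ols), tolerance = 1e-6)
})

test_that("a constant resection column is a rank-deficiency error", {
  tab <- data.frame(patient = rep("P01", 4), engel_linear = 1:4,
                    resected = TRUE, value = stats::rnorm(4))
  expect_error(fit_outcome_lmm(tab, "eq4"), "rank-deficient")
})

test_that("eq5 extends eq4 with extra random coefficients and falls back
           cleanly when they are unsupported", {
  coh <- simulate_cohort(cohort_spec(n_patients = 25, seed = 83),
                         sim_config(n_channels = 10, duration = 600, seed = 83),
                         require_classes = FALSE)
  tab <- cohort_model_table(coh, "delay")
  tab$soz <- FALSE
  fit <- fit_outcome_lmm(tab, "eq5")
  expect_true(is.finite(fit$p))
  expect_true(fit$simplified)   # degenerate extra terms trigger the fallback
})

test_that("the paired SOZ rate test behaves under identity, effect and
           sign-flip", {
  set.seed(84)
  # identical pairs: no evidence
  r <- soz_rate_test(rep(1, 8), rep(1, 8))
  expect_equal(r$p.value, 1)
  # doubled SOZ rates at n = 30: significant
  outside <- stats::rexp(30, 1 / 0.75)
  inside <- outside * 2 * stats::runif(30, 0.8, 1.2)
  r2 <- soz_rate_test(inside, outside)
  expect_lt(r2$p.value, 0.05)
  # flipping all differences preserves the p-value
  r3 <- soz_rate_test(outside, inside)
  expect_equal(r3$p.value, r2$p.value)
})

test_that("repeated-measures ANOVAs detect the planted preictal pattern and
           stay quiet on flat tables", {
  pc <- simulate_preictal_cohort(n_patients = 16, seed = 85)
  lt <- suppressMessages(preictal_contrast_table(pc$events, pc$segments,
                                                 pc$channels))
  an <- preictal_anova(lt)
  three <- an$three_way
  p3 <- three$p[three$term == "region:period:event"]
  expect_lt(p3, 0.01)
  p_lows <- an$two_way$LoWS
  expect_lt(p_lows$p[p_lows$term == "region:period"], 0.01)
  # Holm-adjusted post hocs are >= raw and monotone in them
  ph <- an$posthoc
  expect_true(all(ph$p_holm >= ph$p_raw - 1e-12))
  expect_true(all(diff(ph$p_holm[order(ph$p_raw)]) >= -1e-12))
  # the preictal LoWS increase is larger outside the SOZ
  dl <- ph[ph$event == "LoWS", ]
  expect_gt(dl$mean_diff[dl$region == "extraSOZ"],
            dl$mean_diff[dl$region == "SOZ"])

  # near-flat table: no interaction evidence
  set.seed(86)
  flat <- lt
  flat$rate <- 1 + stats::rnorm(nrow(flat), 0, 1e-3)
  an0 <- preictal_anova(flat)
  expect_gt(an0$three_way$p[an0$three_way$term == "region:period:event"], 0.1)
})

test_that("permuting period labels keeps the interaction at its nominal
           level", {
  pc <- simulate_preictal_cohort(n_patients = 10,
                                 preictal_mult = list(ied_in = 1, ied_out = 1,
                                                      lows_in = 1, lows_out = 1),
                                 seed = 87)
  lt <- suppressMessages(preictal_contrast_table(pc$events, pc$segments,
                                                 pc$channels))
  set.seed(88)
  rej <- replicate(60, {
    perm <- lt
    # permute period labels within patient x region x event cells
    for (p in unique(perm$patient)) for (rg in c("SOZ", "extraSOZ"))
      for (ev in c("IED", "LoWS")) {
        i <- which(perm$patient == p & perm$region == rg & perm$event == ev)
        perm$rate[i] <- perm$rate[sample(i)]
      }
    an <- preictal_anova(perm)
    an$two_way$LoWS$p[an$two_way$LoWS$term == "region:period"] < 0.05
  })
  expect_lt(mean(rej), 0.15)
})
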