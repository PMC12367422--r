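#' Linearise Engel outcome classes
#'
#' Monotone map from Engel class (with optional A-D subclasses) to a numeric
#' ordinal score for use as a covariate in the mixed models: by default
#' I -> 1 ... IV -> 4 with subclasses interpolated in quarter steps
#' (IA = 1, IB = 1.25, ..., IID = 2.75, ...). The map is configurable but
#' must remain strictly monotone in class.
#'
#' @param engel_class character vector of class labels (`"I"`, `"IIb"`,
#'   `"IVA"`, ... case-insensitive subclass letters).
#' @param map optional named numeric vector overriding the default table.
#' @return numeric ordinal scores.
#' @export
engel_linearize <- function(engel_class, map = NULL) {
  if (is.null(map)) {
    roman <- c(I = 1, II = 2, III = 3, IV = 4)
    sub <- c(A = 0, B = 0.25, C = 0.5, D = 0.75)
    map <- c(roman, unlist(lapply(names(roman), function(r)
      setNames(roman[[r]] + sub, paste0(r, names(sub))))))
  }
  base_classes <- c("I", "II", "III", "IV")
  if (all(base_classes %in% names(map)) &&
      any(diff(unname(map[base_classes])) <= 0)) {
    stop("map must be strictly monotone in Engel class", call. = FALSE)
  }
  key <- toupper(as.character(engel_class))
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unknown Engel label(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' ROUT-style robust outlier flagging
#'
#' Robust-regression-and-outlier-removal for location data: residuals from a
#' robust centre (the median) are scaled by the robust standard deviation of
#' the residuals (RSDR: the 68.27th percentile of absolute residuals with an
#' n/(n-1) small-sample correction), converted to two-tailed t probabilities,
#' and flagged by a false-discovery-rate sweep at coefficient `Q`, working
#' inward from the largest residual.
#'
#' @param values numeric vector (>= 8 values, otherwise everything is kept
#'   with a warning).
#' @param Q FDR coefficient as a proportion (default 0.01, i.e. 1%).
#' @return logical keep-mask (`TRUE` = keep).
#' @export
rout_outliers <- function(values, Q = 0.01) {
  n <- length(values)
  if (n < 8) {
    warning("fewer than 8 values: no outlier removal performed")
    return(rep(TRUE, n))
  }
  if (Q <= 0) return(rep(TRUE, n))
  resid <- values - stats::median(values)
  rsdr <- stats::quantile(abs(resid), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr == 0) return(rep(TRUE, n))
  tstat <- abs(resid) / rsdr
  pvals <- 2 * stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  ord <- order(pvals)                       # most extreme first
  keep <- rep(TRUE, n)
  # FDR sweep: flag the i most extreme points when p_(i) < Q * i / n
  flagged_upto <- 0L
  for (i in seq_len(n)) {
    if (pvals[ord[i]] < Q * i / n) flagged_upto <- i
  }
  if (flagged_upto > 0) {
    # only flag a contiguous extreme set: all points at least as extreme as
    # the last one passing the criterion
    keep[ord[seq_len(flagged_upto)]] <- FALSE
  }
  keep
}

#' Fit an outcome linear mixed model
#'
#' The prognostic models relate a per-patient, per-resection-group summary
#' (IED rate, LoWS rate, or corrected delay) to the resection status of the
#' tissue, the linearised Engel score, and their interaction, with a random
#' intercept per patient; the Engel-by-resection interaction is the headline
#' term (a regional index associated with outcome must differ between
#' resected and spared tissue as a function of outcome):
#' `value ~ 1 + engel + resected + engel:resected + (1 | patient)`.
#' `model_id = "eq5"` adds random coefficients for SOZ membership, lesional
#' status and therapy type. Fits use REML with Satterthwaite omnibus F
#' tests; non-convergent or singular extended fits fall back stepwise to the
#' random-intercept model and are flagged.
#'
#' @param table data.frame with columns `patient`, `value`, `resected`
#'   (logical/0-1), `engel_linear`, and for `"eq5"` also `soz`, `lesional`,
#'   `therapy`. Use `ilae` scores in `engel_linear` to fit the ILAE variant.
#' @param model_id `"eq2"` (IED rate), `"eq3"` (LoWS rate), `"eq4"`
#'   (corrected delay) — identical formulas on different dependent
#'   variables — or `"eq5"` (corrected delay with extra random coefficients).
#' @return a `ws_fit` for the interaction term, with the full anova table in
#'   `$anova` and the fit in `$fit`.
#' @export
fit_outcome_lmm <- function(table, model_id = c("eq4", "eq2", "eq3", "eq5")) {
  model_id <- match.arg(model_id)
  stopifnot(all(c("patient", "value", "resected", "engel_linear") %in% names(table)))
  table$resected <- as.numeric(table$resected)
  if (stats::var(table$resected) == 0) {
    stop("rank-deficient design: `resected` is constant", call. = FALSE)
  }
  base <- "value ~ 1 + engel_linear + resected + engel_linear:resected + (1 | patient)"
  form <- if (model_id == "eq5") {
    paste(base, "+ (soz | patient) + (lesional | patient) + (therapy | patient)")
  } else base
  fallback <- FALSE
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(stats::as.formula(form), data = table, REML = TRUE))),
    error = function(e) NULL)
  if (model_id == "eq5" && (is.null(fit) || lme4::isSingular(fit))) {
    fallback <- TRUE
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(stats::as.formula(base), data = table, REML = TRUE)))
  }
  if (is.null(fit)) stop("mixed model failed to fit", call. = FALSE)
  an <- suppressWarnings(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  term <- "engel_linear:resected"
  est <- lme4::fixef(fit)[term]
  structure(list(
    term = term,
    estimate = unname(est),
    se = unname(sqrt(diag(as.matrix(stats::vcov(fit))))[term]),
    ci = NULL,
    F = an[term, "F value"],
    df_num = an[term, "NumDF"],
    df_den = an[term, "DenDF"],
    p = an[term, "Pr(>F)"],
    singular = lme4::isSingular(fit),
    simplified = fallback,
    anova = an,
    fit = fit
  ), class = "ws_fit")
}

#' Build the model table for the outcome LMMs from a simulated cohort
#'
#' Runs the delay pipeline (pairwise delays, incidence correction,
#' resection aggregation) or the rate pipeline on a [simulate_cohort()]
#' result and reshapes it into the two-rows-per-patient table
#' [fit_outcome_lmm()] expects.
#'
#' @param cohort result of [simulate_cohort()].
#' @param what `"delay"` (corrected IED-to-LoWS delay), `"delay_rev"`
#'   (LoWS-to-IED), `"rate_ied"` or `"rate_lows"`.
#' @return data.frame: patient, engel_linear, resected, value (plus `soz`,
#'   `lesional`, `therapy` carried from the cohort for the eq5 variant).
#' @export
cohort_model_table <- function(cohort, what = c("delay", "delay_rev",
                                                "rate_ied", "rate_lows")) {
  what <- match.arg(what)
  rows <- list()
  for (p in cohort$patients$patient) {
    ev <- cohort$events[cohort$events$patient == p, ]
    ch <- cohort$channels[cohort$channels$patient == p, ]
    pat <- cohort$patients[cohort$patients$patient == p, ]
    rates <- event_rates(ev, cohort$wake_minutes, ch)
    if (what %in% c("rate_ied", "rate_lows")) {
      rr <- if (what == "rate_ied") rates$rate_ied else rates$rate_lows
      for (flag in c(TRUE, FALSE)) {
        sel <- ch$resected[match(rates$channel, ch$name)] == flag
        if (!any(sel)) next
        rows[[length(rows) + 1]] <- data.frame(
          patient = p, engel_linear = pat$engel_linear, resected = flag,
          value = mean(rr[sel]), lesional = pat$lesional, therapy = pat$therapy)
      }
    } else {
      dirn <- if (what == "delay") "ied2lows" else "lows2ied"
      del <- pairwise_delays(ev[ev$kind == "IED", ], ev[ev$kind == "LoWS", ],
                             direction = dirn)
      del <- corrected_delays(del, rates)
      if (nrow(del)) del$patient <- p
      agg <- suppressMessages(aggregate_by_resection(del, ch))
      if (!nrow(agg)) next
      for (flag in c(TRUE, FALSE)) {
        rows[[length(rows) + 1]] <- data.frame(
          patient = p, engel_linear = pat$engel_linear, resected = flag,
          value = if (flag) agg$resected_mean else agg$nonresected_mean,
          lesional = pat$lesional, therapy = pat$therapy)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon test of rates inside vs outside the SOZ
#'
#' @param inside,outside per-patient mean rates (paired, same order).
#' @return the `htest` result of a two-sided paired Wilcoxon signed-rank
#'   test (exact when fewer than 6 informative pairs).
#' @export
soz_rate_test <- function(inside, outside) {
  stopifnot(length(inside) == length(outside))
  d <- inside - outside
  if (all(d == 0)) {
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          method = "Wilcoxon signed rank test",
                          alternative = "two.sided",
                          data.name = "inside and outside"),
                     class = "htest"))
  }
  exact <- sum(d != 0) < 6
  suppressWarnings(stats::wilcox.test(inside, outside, paired = TRUE,
                                      exact = exact))
}

#' Repeated-measures ANOVAs of preictal vs interictal rates
#'
#' Two-way repeated-measures ANOVAs per event kind (region x period) and a
#' three-way ANOVA with event kind as the third factor, on the long table of
#' [preictal_contrast_table()]. Patients with incomplete cells are dropped
#' with a message. Post hoc paired contrasts of the preictal-minus-interictal
#' difference (per region, per event kind) are Holm-adjusted.
#'
#' @param long_table from [preictal_contrast_table()].
#' @return list: `two_way` (per event kind: data.frame of term, F, df1, df2,
#'   p), `three_way` (same for the 3-factor model), `posthoc` (Holm-adjusted
#'   paired contrasts).
#' @export
preictal_anova <- function(long_table) {
  lt <- long_table
  lt$patient <- factor(lt$patient)
  lt$region <- factor(lt$region); lt$period <- factor(lt$period)
  lt$event <- factor(lt$event)
  # complete-cell filter
  counts <- table(lt$patient)
  full <- names(counts)[counts == 8]
  if (length(full) < length(counts)) {
    message(length(counts) - length(full), " patient(s) dropped: incomplete cells")
  }
  lt <- lt[lt$patient %in% full, ]
  lt$patient <- droplevels(lt$patient)

  tidy_aov <- function(fit) {
    sm <- summary(fit)
    rows <- list()
    for (stratum in sm) {
      tab <- stratum[[1]]
      terms <- trimws(rownames(tab))
      for (i in seq_len(nrow(tab))) {
        if (terms[i] == "Residuals") next
        rows[[length(rows) + 1]] <- data.frame(
          term = terms[i], F = tab[i, "F value"], df1 = tab[i, "Df"],
          df2 = tab["Residuals", "Df"], p = tab[i, "Pr(>F)"])
      }
    }
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  }

  two_way <- lapply(split(lt, lt$event), function(d)
    tidy_aov(stats::aov(rate ~ region * period +
                          Error(patient / (region * period)), data = d)))
  three_way <- tidy_aov(stats::aov(
    rate ~ region * period * event +
      Error(patient / (region * period * event)), data = lt))

  # Holm-adjusted post hocs on preictal-minus-interictal differences
  ph <- list()
  for (ev in levels(lt$event)) for (rg in levels(lt$region)) {
    d <- lt[lt$event == ev & lt$region == rg, ]
    w <- stats::reshape(d[, c("patient", "period", "rate")],
                        idvar = "patient", timevar = "period",
                        direction = "wide")
    diffs <- w$rate.preictal - w$rate.interictal
    tt <- stats::t.test(diffs)
    ph[[length(ph) + 1]] <- data.frame(
      event = ev, region = rg, mean_diff = mean(diffs),
      t = unname(tt$statistic), df = unname(tt$parameter), p_raw = tt$p.value)
  }
  posthoc <- do.call(rbind, ph)
  posthoc$p_holm <- stats::p.adjust(posthoc$p_raw, method = "holm")
  list(two_way = two_way, three_way = three_way, posthoc = posthoc)
}
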