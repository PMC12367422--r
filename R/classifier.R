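#' Patient-level delay ratio metric
#'
#' The classification metric: per patient, the mean (over channels) median
#' corrected IED-to-LoWS delay in resected tissue divided by the same
#' quantity in non-resected tissue. Values below 1 mean the resected region
#' showed shorter-than-elsewhere delays. Patients with a zero non-resected
#' mean are excluded with a message.
#'
#' @param aggregates from [aggregate_by_resection()] (direction
#'   `"ied2lows"`).
#' @return data.frame: patient, metric.
#' @export
patient_ratio_metric <- function(aggregates) {
  bad <- aggregates$nonresected_mean == 0
  if (any(bad)) {
    message("excluding ", sum(bad), " patient(s) with zero non-resected mean")
  }
  a <- aggregates[!bad, , drop = FALSE]
  data.frame(patient = a$patient,
             metric = a$resected_mean / a$nonresected_mean)
}

#' F1 score from precision and sensitivity
#'
#' `F1 = 2 * PPV * Sn / (PPV + Sn)`, the harmonic mean of positive
#' predictive value and sensitivity. Defined as 0 (with a warning) when both
#' are 0.
#'
#' @param ppv positive predictive value in [0,1].
#' @param sn sensitivity in [0,1].
#' @return the F1 score.
#' @export
f1_score <- function(ppv, sn) {
  stopifnot(all(ppv >= 0 & ppv <= 1), all(sn >= 0 & sn <= 1))
  out <- ifelse(ppv + sn == 0, NA_real_, 2 * ppv * sn / (ppv + sn))
  if (anyNA(out)) {
    warning("F1 undefined (PPV = Sn = 0); returning 0")
    out[is.na(out)] <- 0
  }
  out
}

#' ROC evaluation of the delay-ratio metric
#'
#' Rank-based AUC with good outcome as the positive class and a *low* metric
#' as the positive direction (shorter resected-area delays predict success).
#' Tied scores contribute 1/2. The z statistic uses the Hanley-McNeil
#' standard error of the AUC; the p-value is two-sided against AUC = 0.5.
#'
#' @param metrics numeric metric per patient.
#' @param labels logical (or 0/1): `TRUE` = good outcome.
#' @return list: auc, z, p, n_pos, n_neg.
#' @export
roc_evaluate <- function(metrics, labels) {
  labels <- as.logical(labels)
  stopifnot(length(metrics) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present", call. = FALSE)
  score <- -metrics                 # low metric = positive direction
  pos <- score[labels]; neg <- score[!labels]
  n1 <- length(pos); n2 <- length(neg)
  # rank-based concordance (Mann-Whitney), ties counted 1/2
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  z <- if (se > 0) (auc - 0.5) / se else 0
  list(auc = auc, z = z, p = 2 * stats::pnorm(-abs(z)), n_pos = n1, n_neg = n2)
}

# balanced-accuracy-maximising threshold on a training set; ties -> lower
# threshold. Predict good when metric < threshold. Balanced accuracy
# (mean of sensitivity and specificity) keeps the threshold discriminative
# under the cohort's good-outcome prevalence of ~3/4, where raw accuracy is
# maximised by the degenerate call-everything-good rule.
best_threshold <- function(metrics, labels) {
  o <- order(metrics)
  m <- metrics[o]; y <- labels[o]
  cuts <- c(m[1] - 1, (m[-length(m)] + m[-1]) / 2, m[length(m)] + 1)
  bacc <- vapply(cuts, function(cut) {
    sn <- sum(y & m < cut) / sum(y)
    sp <- sum(!y & m >= cut) / sum(!y)
    (sn + sp) / 2
  }, numeric(1))
  cuts[which.max(bacc)]             # which.max takes the first (lowest) tie
}

confusion_metrics <- function(pred_good, truth_good) {
  tp <- sum(pred_good & truth_good)    # good outcome called good
  tn <- sum(!pred_good & !truth_good)
  fp <- sum(pred_good & !truth_good)
  fn <- sum(!pred_good & truth_good)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  or <- ((tp + 0.5) * (tn + 0.5)) / ((fp + 0.5) * (fn + 0.5))
  f1 <- if (!is.na(ppv) && !is.na(sn) && ppv + sn > 0)
    2 * ppv * sn / (ppv + sn) else NA_real_
  c(tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / length(truth_good),
    balanced_accuracy = mean(c(sn, sp), na.rm = TRUE),
    sensitivity = sn, specificity = sp, ppv = ppv, npv = npv,
    odds_ratio = or, f1 = f1)
}

run_repeats <- function(metrics, labels, n_repeats, split_fraction) {
  good_idx <- which(labels); poor_idx <- which(!labels)
  n_tr_g <- max(1L, round(split_fraction * length(good_idx)))
  n_tr_p <- max(1L, round(split_fraction * length(poor_idx)))
  n_tr_g <- min(n_tr_g, length(good_idx) - 1L)
  n_tr_p <- min(n_tr_p, length(poor_idx) - 1L)
  out <- matrix(NA_real_, n_repeats, 13,
                dimnames = list(NULL, c("threshold", "tp", "tn", "fp", "fn",
                                        "accuracy", "balanced_accuracy",
                                        "sensitivity", "specificity",
                                        "ppv", "npv", "odds_ratio", "f1")))
  for (r in seq_len(n_repeats)) {
    tr <- c(sample(good_idx, n_tr_g), sample(poor_idx, n_tr_p))
    va <- setdiff(seq_along(labels), tr)
    thr <- best_threshold(metrics[tr], labels[tr])
    pred <- metrics[va] < thr
    out[r, ] <- c(thr, confusion_metrics(pred, labels[va]))
  }
  out
}

#' Train/validate classification of surgical outcome
#'
#' Repeated stratified splits: in each repeat, `split_fraction` of each class
#' trains a balanced-accuracy-maximising threshold on the metric (ties broken
#' to the lower threshold; balanced accuracy keeps the threshold
#' discriminative despite the ~3:1 good:poor prevalence, under which a raw
#' accuracy objective collapses to the degenerate call-everything-good rule);
#' validation patients with metric below the threshold are predicted good
#' outcome. Performance metrics are summarised as median [IQR] over repeats,
#' together with the threshold mean and SD (a low threshold SD indicates a
#' robust decision boundary). Significance versus chance is assessed by
#' re-running the whole procedure on label permutations: the permutation
#' p-value is the fraction of permutations whose mean validation balanced
#' accuracy reaches the observed one.
#'
#' @param metrics numeric metric per patient ([patient_ratio_metric()]).
#' @param labels logical, `TRUE` = good (Engel I-II) outcome; at least 5
#'   patients per class.
#' @param n_repeats validation repeats (default 1000).
#' @param split_fraction training fraction (default 0.7).
#' @param n_perm label permutations for the chance test (default 1000;
#'   0 skips it).
#' @param seed integer seed.
#' @return a `ws_classification` list: `summary` (median and IQR per
#'   metric), `threshold` (mean, sd), `per_repeat` matrix, `perm_p`,
#'   `perm_accuracy` (null medians), `n_good`, `n_poor`.
#' @export
train_validate <- function(metrics, labels, n_repeats = 1000,
                           split_fraction = 0.7, n_perm = 1000, seed = 1L) {
  labels <- as.logical(labels)
  if (sum(labels) < 5 || sum(!labels) < 5) {
    stop("need at least 5 patients per outcome class", call. = FALSE)
  }
  with_seed(seed, {
    per <- run_repeats(metrics, labels, n_repeats, split_fraction)
    cols <- c("accuracy", "balanced_accuracy", "sensitivity", "specificity",
              "ppv", "npv", "odds_ratio", "f1")
    summ <- t(apply(per[, cols], 2, function(v)
      stats::quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)))
    colnames(summ) <- c("median", "q25", "q75")
    # permutation statistic: *mean* validation balanced accuracy across
    # repeats — smooth enough that exact ties with permuted replicates are
    # rare, keeping the permutation p-value calibrated
    obs_acc <- mean(per[, "balanced_accuracy"], na.rm = TRUE)
    perm_acc <- numeric(0); perm_p <- NA_real_
    if (n_perm > 0) {
      perm_acc <- vapply(seq_len(n_perm), function(i) {
        pl <- sample(labels)
        mean(run_repeats(metrics, pl, n_repeats,
                         split_fraction)[, "balanced_accuracy"],
             na.rm = TRUE)
      }, numeric(1))
      perm_p <- (1 + sum(perm_acc >= obs_acc)) / (n_perm + 1)
    }
    structure(list(
      summary = as.data.frame(summ),
      threshold = c(mean = mean(per[, "threshold"]),
                    sd = stats::sd(per[, "threshold"])),
      per_repeat = per,
      perm_p = perm_p,
      perm_accuracy = perm_acc,
      n_good = sum(labels), n_poor = sum(!labels)
    ), class = "ws_classification")
  })
}

#' @export
print.ws_classification <- function(x, ...) {
  cat("<ws_classification>", x$n_good, "good vs", x$n_poor, "poor patients\n")
  s <- x$summary
  for (m in rownames(s)) {
    cat(sprintf("  %-12s %.2f [%.2f-%.2f]\n", m, s[m, "median"],
                s[m, "q25"], s[m, "q75"]))
  }
  cat(sprintf("  threshold    %.3f (SD %.3f)\n", x$threshold["mean"],
              x$threshold["sd"]))
  if (!is.na(x$perm_p)) cat(sprintf("  permutation p = %.4g\n", x$perm_p))
  invisible(x)
}
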