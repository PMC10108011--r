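#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. The p-value is exact
#' (full enumeration of the U distribution) when the smaller group has at
#' most 8 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param alternative `"two-sided"`, `"one-sided-less"` (group A
#'   stochastically smaller) or `"one-sided-greater"`.
#' @return A `test_result`: method, U statistic (for group A), `p_value`,
#'   `alternative`, group sizes `n`.
#' @export
mann_whitney <- function(group_a, group_b,
                         alternative = c("two-sided", "one-sided-less",
                                         "one-sided-greater")) {
  alternative <- match.arg(alternative)
  if (!length(group_a) || !length(group_b))
    input_error("both groups must be non-empty")
  alt <- switch(alternative, "two-sided" = "two.sided",
                "one-sided-less" = "less", "one-sided-greater" = "greater")
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- min(length(group_a), length(group_b)) <= 8 && !has_ties
  w <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                           alternative = alt, exact = exact,
                                           correct = TRUE))
  structure(list(method = "Mann-Whitney U",
                 statistic = unname(w$statistic),
                 p_value = w$p.value,
                 alternative = alternative,
                 exact = exact,
                 n = c(n_a = length(group_a), n_b = length(group_b))),
            class = "test_result")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed margins,
#' the hypergeometric probabilities not exceeding that of the observed
#' table. The conditional maximum-likelihood odds ratio is reported.
#'
#' @param table 2x2 matrix of non-negative integer counts with at least one
#'   positive margin.
#' @return A `test_result` with the odds ratio as `statistic`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    input_error("table must be 2x2")
  if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
    input_error("table entries must be non-negative integers")
  if (sum(table) == 0) input_error("table has no observations")
  f <- stats::fisher.test(table)
  structure(list(method = "Fisher exact",
                 statistic = unname(f$estimate),
                 p_value = f$p.value,
                 alternative = "two-sided",
                 n = c(n_a = sum(table[1, ]), n_b = sum(table[2, ]))),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %s, p = %.4g (n = %s)\n",
              x$method, x$alternative, format(x$statistic, digits = 4),
              x$p_value, paste(x$n, collapse = " vs ")))
  invisible(x)
}

#' ROC curve and AUC with confidence interval
#'
#' AUC is the probability that a positive-class score exceeds a
#' negative-class score, ties counted 1/2 (the trapezoidal area under the
#' ROC curve). The 95% CI uses the DeLong method by default, or a
#' stratified bootstrap (seeded). An AUC-vs-0.5 p-value is attached via the
#' two-sided Mann-Whitney test between the classes.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) vector; `TRUE` marks the positive class.
#'   Both classes must be present.
#' @param positive_direction `"higher"` if larger scores indicate the
#'   positive class, `"lower"` otherwise.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param n_boot,seed Bootstrap replicates and seed (bootstrap CI only).
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `p_value`, `curve`
#'   (data frame of FPR/TPR including (0,0) and (1,1)), and the
#'   positive-class definition.
#' @export
roc_auc <- function(scores, labels,
                    positive_direction = c("higher", "lower"),
                    ci_method = c("delong", "bootstrap"),
                    n_boot = 2000L, seed = 1L) {
  positive_direction <- match.arg(positive_direction)
  ci_method <- match.arg(ci_method)
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores)) input_error("NA in scores or labels")
  if (!any(labels) || all(labels))
    input_error("both classes must be present")
  direction <- if (positive_direction == "higher") "<" else ">"
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = direction,
                 quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- if (ci_method == "delong") {
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  } else {
    with_seed(seed, suppressWarnings(
      as.numeric(pROC::ci.auc(r, method = "bootstrap",
                              boot.n = n_boot, progress = "none"))))
  }
  ci_low <- max(0, min(ci[1], auc))
  ci_high <- min(1, max(ci[3], auc))
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  rownames(curve) <- NULL
  p <- mann_whitney(scores[labels], scores[!labels], "two-sided")$p_value
  structure(list(auc = auc, ci_low = ci_low, ci_high = ci_high,
                 p_value = p, curve = curve,
                 positive_class = sprintf("%s scores", positive_direction),
                 n = c(n_positive = sum(labels),
                       n_negative = sum(!labels))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), p = %.4g (%d pos vs %d neg)\n",
              x$auc, x$ci_low, x$ci_high, x$p_value,
              x$n["n_positive"], x$n["n_negative"]))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group; with two or more groups and
#' at least one event, the log-rank chi-square is computed with k-1 degrees
#' of freedom. With no events anywhere the statistic is 0 and p = 1 (all
#' curves are flat at 1).
#'
#' @param times Positive follow-up/event times.
#' @param events Logical or 0/1 event indicators (1 = event).
#' @param groups Group labels.
#' @return A `survival_result`: `curves` (data frame: group, time, n_risk,
#'   n_event, survival), `statistic`, `df`, `p_value`.
#' @export
km_logrank <- function(times, events, groups) {
  if (any(times <= 0)) input_error("times must be > 0")
  events <- as.integer(as.logical(events))
  groups <- as.factor(groups)
  df_in <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups,
                           data = df_in)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time))
  else sub("^groups=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       stringsAsFactors = FALSE)
  k <- nlevels(droplevels(groups))
  if (k < 2 || sum(events) == 0) {
    stat <- 0; dfree <- max(k - 1, 0); p <- 1
  } else {
    sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups,
                              data = df_in)
    stat <- sd_$chisq
    dfree <- k - 1
    p <- stats::pchisq(stat, df = dfree, lower.tail = FALSE)
  }
  structure(list(curves = curves, statistic = stat, df = dfree,
                 p_value = p,
                 n = table(droplevels(groups))),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Classify each patient's early c-cfDNA dynamics
#'
#' A patient is called INCREASE when the c-cfDNA level at the follow-up
#' timepoint is strictly greater than at baseline; equal values are
#' NO_INCREASE (ties are resolved away from the negative-prognosis call).
#' Patients missing either timepoint are excluded with a logged reason.
#'
#' @param measurements Long data frame with columns `patient_id`,
#'   `timepoint`, `c_cfdna_copies_ml`.
#' @param baseline,followup Timepoint labels (defaults `"W1D1"`, `"W2D1"`).
#' @return Data frame (`patient_id`, `baseline_value`, `followup_value`,
#'   `call`), with excluded patients and reasons in attribute
#'   `"excluded"`.
#' @export
classify_dynamics <- function(measurements, baseline = "W1D1",
                              followup = "W2D1") {
  need <- c("patient_id", "timepoint", "c_cfdna_copies_ml")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    format_error(sprintf("measurements missing column(s): %s",
                         paste(miss, collapse = ", ")))
  pick <- function(tp) {
    d <- measurements[measurements$timepoint == tp, c("patient_id",
                                                      "c_cfdna_copies_ml")]
    d[!duplicated(d$patient_id), ]
  }
  b <- pick(baseline); f <- pick(followup)
  pids <- unique(measurements$patient_id)
  bv <- b$c_cfdna_copies_ml[match(pids, b$patient_id)]
  fv <- f$c_cfdna_copies_ml[match(pids, f$patient_id)]
  ok <- !is.na(bv) & !is.na(fv)
  excluded <- data.frame(
    patient_id = pids[!ok],
    reason = ifelse(is.na(bv[!ok]) & is.na(fv[!ok]), "missing_both",
                    ifelse(is.na(bv[!ok]), "missing_baseline",
                           "missing_followup")),
    stringsAsFactors = FALSE)
  out <- data.frame(patient_id = pids[ok],
                    baseline_value = bv[ok],
                    followup_value = fv[ok],
                    call = ifelse(fv[ok] > bv[ok], "INCREASE", "NO_INCREASE"),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

# helper: wide per-patient values at one timepoint, joined to outcomes
.values_at <- function(cohort, tp) {
  m <- cohort$measurements[cohort$measurements$timepoint == tp, ]
  v <- m$c_cfdna_copies_ml[match(cohort$outcomes$patient_id, m$patient_id)]
  v
}

.report_row <- function(analysis, method = NA, alternative = NA, n_a = NA,
                        n_b = NA, statistic = NA, p_value = NA,
                        median_a = NA, median_b = NA, auc = NA, ci_low = NA,
                        ci_high = NA, note = NA) {
  data.frame(analysis = analysis, method = method, alternative = alternative,
             n_a = n_a, n_b = n_b, statistic = statistic, p_value = p_value,
             median_a = median_a, median_b = median_b, auc = auc,
             ci_low = ci_low, ci_high = ci_high, note = note,
             stringsAsFactors = FALSE)
}

#' Run the full treatment-response analysis
#'
#' Produces one tabular report over a cohort's c-cfDNA measurements:
#' \describe{
#'   \item{healthy_vs_patient}{baseline c-cfDNA in healthy controls vs
#'     patients (two-sided Mann-Whitney) plus ROC, when healthy values are
#'     supplied;}
#'   \item{baseline_by_trg}{baseline (W1D1) c-cfDNA in good responders
#'     (TRG0-1) vs poor responders (TRG2-3), one-sided Mann-Whitney with
#'     the pre-specified direction "responders lower";}
#'   \item{w2d1_by_pathcr}{W2D1 c-cfDNA in pathCR vs residual disease,
#'     two-sided Mann-Whitney, plus ROC for discriminating pathCR;}
#'   \item{dynamics_vs_relapse}{Fisher's exact test on the 2x2 table of
#'     W1D1-to-W2D1 increase against relapse;}
#'   \item{km_by_dynamics}{Kaplan-Meier/log-rank of time to relapse by
#'     dynamics group.}
#' }
#' Tests with fewer than 2 subjects per arm are skipped with an explicit
#' note, never silently. p-values are unadjusted; the report carries the
#' number of tests performed.
#'
#' @param cohort A `cohort` object (or list with `measurements` and
#'   `outcomes` in the documented schema).
#' @param healthy Optional numeric vector (or data frame with column
#'   `c_cfdna_copies_ml`) of combined scores for healthy controls.
#' @param dynamics_subset Optional character vector of patient ids defining
#'   the subgroup for the dynamics-vs-relapse table (default: all patients
#'   with both timepoints).
#' @return An `analysis_report`: `report` data frame plus `details` (ROC,
#'   survival and dynamics objects).
#' @export
run_response_analysis <- function(cohort, healthy = NULL,
                                  dynamics_subset = NULL) {
  if (!all(c("measurements", "outcomes") %in% names(cohort)))
    input_error("cohort must contain 'measurements' and 'outcomes'")
  outc <- cohort$outcomes
  rows <- list()
  details <- list()
  skip_note <- "skipped: fewer than 2 subjects per arm"

  w1 <- .values_at(cohort, "W1D1")
  w2 <- .values_at(cohort, "W2D1")

  # (a) healthy vs patient at baseline, + ROC
  if (!is.null(healthy)) {
    hv <- if (is.data.frame(healthy)) healthy$c_cfdna_copies_ml else healthy
    pv <- w1[!is.na(w1)]
    if (length(hv) >= 2 && length(pv) >= 2) {
      t <- mann_whitney(hv, pv, "two-sided")
      roc <- roc_auc(c(hv, pv), c(rep(FALSE, length(hv)),
                                  rep(TRUE, length(pv))), "higher")
      details$roc_healthy <- roc
      rows$healthy <- .report_row("healthy_vs_patient", t$method,
                                  t$alternative, length(hv), length(pv),
                                  t$statistic, t$p_value,
                                  stats::median(hv), stats::median(pv),
                                  roc$auc, roc$ci_low, roc$ci_high)
    } else {
      rows$healthy <- .report_row("healthy_vs_patient", note = skip_note)
    }
  }

  # (b) baseline by TRG0-1 vs TRG2-3, one-sided (responders lower)
  good <- outc$trg <= 1
  a <- w1[good & !is.na(w1)]; b <- w1[!good & !is.na(w1)]
  rows$trg <- if (length(a) >= 2 && length(b) >= 2) {
    t <- mann_whitney(a, b, "one-sided-less")
    .report_row("baseline_by_trg", t$method, t$alternative, length(a),
                length(b), t$statistic, t$p_value, stats::median(a),
                stats::median(b))
  } else .report_row("baseline_by_trg", note = skip_note)

  # (c) W2D1 by pathCR, two-sided, + ROC (higher scores -> residual disease)
  a <- w2[outc$path_cr & !is.na(w2)]; b <- w2[!outc$path_cr & !is.na(w2)]
  rows$w2d1 <- if (length(a) >= 2 && length(b) >= 2) {
    t <- mann_whitney(a, b, "two-sided")
    keep <- !is.na(w2)
    roc <- roc_auc(w2[keep], !outc$path_cr[keep], "higher")
    details$roc_w2d1 <- roc
    .report_row("w2d1_by_pathcr", t$method, t$alternative, length(a),
                length(b), t$statistic, t$p_value, stats::median(a),
                stats::median(b), roc$auc, roc$ci_low, roc$ci_high)
  } else .report_row("w2d1_by_pathcr", note = skip_note)

  # (d) dynamics x relapse Fisher table
  dyn <- classify_dynamics(cohort$measurements)
  details$dynamics <- dyn
  dsub <- if (is.null(dynamics_subset)) dyn else
    dyn[dyn$patient_id %in% dynamics_subset, , drop = FALSE]
  dsub$relapse <- outc$relapse[match(dsub$patient_id, outc$patient_id)]
  tab <- matrix(c(sum(dsub$relapse & dsub$call == "INCREASE"),
                  sum(dsub$relapse & dsub$call == "NO_INCREASE"),
                  sum(!dsub$relapse & dsub$call == "INCREASE"),
                  sum(!dsub$relapse & dsub$call == "NO_INCREASE")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("relapse", "no_relapse"),
                                c("increase", "no_increase")))
  details$dynamics_table <- tab
  rows$fisher <- if (sum(dsub$relapse) >= 2 && sum(!dsub$relapse) >= 2) {
    t <- fisher_exact(tab)
    .report_row("dynamics_vs_relapse", t$method, t$alternative,
                sum(dsub$relapse), sum(!dsub$relapse), t$statistic,
                t$p_value)
  } else .report_row("dynamics_vs_relapse", note = skip_note)

  # (e) KM / log-rank by dynamics group
  surv_d <- merge(dsub[, c("patient_id", "call")],
                  outc[, c("patient_id", "relapse", "time_to_event_months")],
                  by = "patient_id")
  rows$km <- if (length(unique(surv_d$call)) >= 2 && nrow(surv_d) >= 4) {
    s <- km_logrank(surv_d$time_to_event_months, surv_d$relapse,
                    surv_d$call)
    details$survival <- s
    .report_row("km_by_dynamics", "log-rank", "two-sided",
                sum(surv_d$call == "INCREASE"),
                sum(surv_d$call == "NO_INCREASE"),
                s$statistic, s$p_value)
  } else .report_row("km_by_dynamics", note = skip_note)

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  n_tests <- sum(!is.na(report$p_value))
  structure(list(report = report, details = details, n_tests = n_tests),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d tests (p-values unadjusted)\n", x$n_tests))
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}
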