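test_that("Mann-Whitney matches hand-enumerated exact p-values", {
  t1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6), "one-sided-less")
  expect_equal(t1$p_value, 0.05)   # 1 of C(6,3) = 20 orderings
  expect_identical(unname(t1$statistic), 0)
  t2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6), "two-sided")
  expect_equal(t2$p_value, 0.10)
  t3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3), "two-sided")
  expect_equal(t3$p_value, 1.0)
  expect_error(mann_whitney(numeric(0), 1:3), class = "ccfdna_input_error")
})

test_that("exact Mann-Whitney agrees with brute-force enumeration", {
  set.seed(17)
  for (n in 1:5) {
    for (m in n:(12 - n)) {
      vals <- sample(seq_len(50), n + m)  # distinct -> exact path
      a <- vals[seq_len(n)]; b <- vals[-seq_len(n)]
      for (alt in c("two-sided", "one-sided-less", "one-sided-greater")) {
        expect_equal(mann_whitney(a, b, alt)$p_value, mw_brute(a, b, alt),
                     info = sprintf("n=%d m=%d alt=%s", n, m, alt))
      }
    }
  }
})

test_that("Fisher's exact test reproduces enumeration on all small tables", {
  # worked example: 7/7 relapsers vs 7/17 non-relapsers with c-cfDNA increase
  t <- fisher_exact(matrix(c(7, 0, 7, 10), nrow = 2, byrow = TRUE))
  expect_equal(round(t$p_value, 3), 0.019)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_value, 1.0)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)),
               class = "ccfdna_input_error")
  expect_error(fisher_exact(matrix(c(0.5, 1, 1, 1), 2)),
               class = "ccfdna_input_error")

  # random sweep against the hypergeometric enumeration oracle
  set.seed(23)
  for (i in 1:200) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, fisher_brute(tab),
                 tolerance = 1e-10,
                 info = paste(tab, collapse = ","))
  }
})

test_that("AUC equals the concordant-pair probability with ties at 1/2", {
  r <- roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(r$auc, 1.0)
  r2 <- roc_auc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r2$auc, 0.875)   # pairs: 1<2, 1<3, 2=2 -> 1/2, 2<3
  r3 <- roc_auc(c(3, 4, 1, 2), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(r3$auc, 0.0)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "ccfdna_input_error")

  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:120, 1)
    scores <- sample(1:40, n, replace = TRUE)  # forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_pairs(scores, labels))
    # CI ordering invariant and curve monotonicity
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
    expect_true(r$ci_low >= 0 && r$ci_high <= 1)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
    expect_equal(r$curve[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ], use.names = FALSE), c(1, 1))
  }
})

test_that("Kaplan-Meier and log-rank behave on canonical configurations", {
  # identical groups: null by construction
  t0 <- km_logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1),
                   rep(c("a", "b"), each = 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1.0)

  # events only in group a vs fully censored group b
  t1 <- km_logrank(c(1, 2, 3, 10, 10, 10), c(1, 1, 1, 0, 0, 0),
                   rep(c("a", "b"), each = 3))
  expect_lt(t1$p_value, 0.05)

  # no censoring: KM equals the empirical survival function
  times <- c(1, 2, 2, 4, 7)
  km <- km_logrank(times, rep(1, 5), rep("g", 5))
  surv_emp <- vapply(sort(unique(times)), function(t) mean(times > t),
                     numeric(1))
  expect_equal(km$curves$survival, surv_emp)

  # single censored subject: curve flat at 1, no test possible
  t2 <- km_logrank(5, 0, "g")
  expect_true(all(t2$curves$survival == 1))
  expect_equal(t2$p_value, 1)

  expect_error(km_logrank(c(0, 1), c(1, 1), c("a", "b")),
               class = "ccfdna_input_error")
})

test_that("dynamics calls use strict increase with ties as NO_INCREASE", {
  meas <- data.frame(
    patient_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    timepoint = rep(c("W1D1", "W2D1"), 4),
    c_cfdna_copies_ml = c(10, 12, 10, 10, 10, 8, 10, NA))
  meas <- meas[!(meas$patient_id == "p4" & meas$timepoint == "W2D1"), ]
  dyn <- classify_dynamics(meas)
  expect_identical(dyn$call, c("INCREASE", "NO_INCREASE", "NO_INCREASE"))
  excl <- attr(dyn, "excluded")
  expect_identical(excl$patient_id, "p4")
  expect_identical(excl$reason, "missing_followup")
})

test_that("the response analysis reproduces a constructed cohort's statistics", {
  # 24 patients built to give the increase-vs-relapse table [[7,0],[7,10]]
  # and perfect W2D1 separation between pathCR and residual disease
  n <- 24
  pid <- sprintf("p%02d", 1:n)
  relapse <- c(rep(TRUE, 7), rep(FALSE, 17))
  increase <- c(rep(TRUE, 7), rep(TRUE, 7), rep(FALSE, 10))
  path_cr <- c(rep(FALSE, 20), rep(TRUE, 4))
  w1 <- seq(20, 43, length.out = n)
  w2 <- ifelse(increase, w1 + 5, w1 - 5)
  w2[path_cr] <- 1:4  # pathCR (non-increase) strictly below every residual w2
  increase <- w2 > w1
  stopifnot(sum(relapse & increase) == 7, sum(relapse & !increase) == 0,
            sum(!relapse & increase) == 7, sum(!relapse & !increase) == 10)
  cohort <- structure(list(
    measurements = data.frame(
      patient_id = rep(pid, 2),
      timepoint = rep(c("W1D1", "W2D1"), each = n),
      c_cfdna_copies_ml = c(w1, w2),
      total_cfdna_ng_ml = 10),
    outcomes = data.frame(
      patient_id = pid, trg = ifelse(path_cr, 0L, 2L), path_cr = path_cr,
      relapse = relapse, time_to_event_months = ifelse(relapse, 12, 30),
      adjuvant = FALSE, kras_detected_baseline = FALSE)),
    class = "cohort")

  res <- run_response_analysis(cohort)
  rep_ <- res$report
  fisher_row <- rep_[rep_$analysis == "dynamics_vs_relapse", ]
  expect_equal(round(fisher_row$p_value, 3), 0.019)
  expect_identical(unname(as.vector(res$details$dynamics_table)),
                   c(7L, 7L, 0L, 10L))
  w2row <- rep_[rep_$analysis == "w2d1_by_pathcr", ]
  expect_identical(w2row$auc, 1.0)   # perfect separation
  expect_true(all(c("baseline_by_trg", "km_by_dynamics") %in% rep_$analysis))
  # every reported test is annotated with method, sidedness and n
  done <- rep_[!is.na(rep_$p_value), ]
  expect_true(all(!is.na(done$method) & !is.na(done$alternative)))

  # too-small arms are skipped with an explicit note
  cohort$outcomes$path_cr <- c(TRUE, rep(FALSE, n - 1))
  res2 <- run_response_analysis(cohort)
  row2 <- res2$report[res2$report$analysis == "w2d1_by_pathcr", ]
  expect_true(is.na(row2$p_value) && grepl("skipped", row2$note))
})

test_that("healthy controls enable the discrimination comparison and ROC", {
  co <- simulate_cohort(cohort_config(seed = 12))
  healthy <- exp(rnorm(29, log(3), 0.8))
  res <- run_response_analysis(co, healthy = healthy)
  row <- res$report[res$report$analysis == "healthy_vs_patient", ]
  expect_false(is.na(row$p_value))
  expect_true(row$auc > 0.5)  # patients carry more colon-derived cfDNA
})
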