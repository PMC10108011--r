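#' Canonical timepoint labels
#'
#' Timepoints are labelled `W{week}D{day}`: week of radiotherapy (1-6) and
#' day within the week (1-7). `W1D1` is baseline; `W2D1` -- the first day of
#' the second treatment week, after a treatment-free weekend -- is the early
#' decision point of the response analysis.
#'
#' @param week,day Integer vectors.
#' @return Character vector of labels.
#' @export
timepoint_label <- function(week, day) {
  if (any(week < 1 | week > 6) || any(day < 1 | day > 7))
    input_error("week must be in 1..6 and day in 1..7")
  sprintf("W%dD%d", as.integer(week), as.integer(day))
}

#' Parse timepoint labels into (week, day)
#' @param label Character vector like `"W2D1"`.
#' @return Data frame with columns `week`, `day`, ordered as given.
#' @export
parse_timepoint <- function(label) {
  m <- regmatches(label, regexec("^W([1-6])D([1-7])$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    input_error(sprintf("malformed timepoint label: %s", label[bad][1]))
  data.frame(week = vapply(m, function(x) as.integer(x[2]), integer(1)),
             day = vapply(m, function(x) as.integer(x[3]), integer(1)))
}

#' Configuration for the longitudinal cohort simulator
#'
#' Emulates a 37-patient neoadjuvant-chemoradiation cohort: a pathologic
#' complete response (pathCR, TRG0) subgroup, residual-disease patients
#' split across TRG1-3, per-timepoint c-cfDNA levels drawn log-normal with
#' group-specific medians, a baseline-to-W2D1 "increase" indicator coupled
#' to later relapse, and right-censored relapse times.
#'
#' Defaults mirror the observed cohort structure: pathCR probability 7/37,
#' TRG1/2/3 split 11/11/8 among 30 residual-disease patients, W2D1 medians
#' 8.6 (pathCR) vs 57.7 (residual) copies/ml, every relapsing patient
#' showing a c-cfDNA increase at W2D1 versus 7/17 of non-relapsing
#' patients, relapse in 8/30 residual and 1/7 pathCR patients, median time
#' to relapse 20 months, and follow-up centred on 25.3 months.
#'
#' @param n_patients Number of patients.
#' @param pathcr_probability Probability of pathCR (TRG0).
#' @param trg_residual_probs Probabilities of TRG 1, 2, 3 given residual
#'   disease (must sum to 1).
#' @param medians_pathcr,medians_residual Named numeric vectors of c-cfDNA
#'   medians (copies/ml) per timepoint label; must share names and contain
#'   `W1D1` and `W2D1`.
#' @param log_sd Log-scale standard deviation of the c-cfDNA distribution.
#' @param relapse_prob_pathcr,relapse_prob_residual Relapse probabilities
#'   per response group.
#' @param p_increase_relapse,p_increase_nonrelapse Probability that c-cfDNA
#'   increases from W1D1 to W2D1 given later relapse / no relapse.
#' @param relapse_time_median_months,relapse_time_log_sd Log-normal
#'   parameters of time to relapse.
#' @param followup_window_months Range of the uniform censoring window for
#'   relapse-free patients (default median 25.3 months).
#' @param total_cfdna_median_ng_ml,total_cfdna_log_sd Log-normal parameters
#'   of total plasma cfDNA concentration.
#' @param adjuvant_probability,kras_detected_probability Bernoulli
#'   probabilities for the adjuvant-chemotherapy and baseline
#'   KRAS-detected flags.
#' @param seed Integer seed; fixed seed gives an identical cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 37L,
                          pathcr_probability = 7 / 37,
                          trg_residual_probs = c(11, 11, 8) / 30,
                          medians_pathcr = c(W1D1 = 25, W2D1 = 8.6,
                                             W3D1 = 15, W4D1 = 25, W5D1 = 35),
                          medians_residual = c(W1D1 = 45, W2D1 = 57.7,
                                               W3D1 = 62, W4D1 = 68, W5D1 = 75),
                          log_sd = 1.0,
                          relapse_prob_pathcr = 1 / 7,
                          relapse_prob_residual = 8 / 30,
                          p_increase_relapse = 1.0,
                          p_increase_nonrelapse = 7 / 17,
                          relapse_time_median_months = 20,
                          relapse_time_log_sd = 0.5,
                          followup_window_months = c(12, 38.6),
                          total_cfdna_median_ng_ml = 10,
                          total_cfdna_log_sd = 0.5,
                          adjuvant_probability = 19 / 37,
                          kras_detected_probability = 6 / 37,
                          seed = 1L) {
  probs <- c(pathcr_probability, trg_residual_probs, relapse_prob_pathcr,
             relapse_prob_residual, p_increase_relapse, p_increase_nonrelapse,
             adjuvant_probability, kras_detected_probability)
  if (any(probs < 0) || any(probs > 1))
    input_error("all probabilities must lie in [0, 1]")
  if (abs(sum(trg_residual_probs) - 1) > 1e-8)
    input_error("trg_residual_probs must sum to 1")
  if (!identical(sort(names(medians_pathcr)), sort(names(medians_residual))))
    input_error("medians_pathcr and medians_residual must share timepoints")
  if (!all(c("W1D1", "W2D1") %in% names(medians_pathcr)))
    input_error("timepoint medians must include W1D1 and W2D1")
  if (any(medians_pathcr <= 0) || any(medians_residual <= 0))
    input_error("medians must be > 0")
  parse_timepoint(names(medians_pathcr))  # validates labels
  structure(as.list(environment()), class = "cohort_config")
}

# Truncated log-normal draw for W2D1 given W1D1 and the increase indicator:
# inverse-CDF sampling from lognormal(median, sd) restricted to the side of
# w1 the indicator demands. At sd = 0 values degenerate to the median and no
# coupling is possible.
.draw_w2d1 <- function(w1, mu2, sd, increase) {
  if (sd == 0) return(exp(rep_len(mu2, length(w1))))
  a <- stats::pnorm((log(w1) - mu2) / sd)
  a <- pmin(pmax(a, 1e-12), 1 - 1e-12)
  u <- stats::runif(length(w1))
  q <- ifelse(increase, a + u * (1 - a), u * a)
  exp(mu2 + sd * stats::qnorm(q))
}

#' Simulate a longitudinal patient cohort
#'
#' @param cfg A [cohort_config()].
#' @return A `cohort` object: list with `measurements` (data frame:
#'   `patient_id`, `timepoint`, `c_cfdna_copies_ml`, `total_cfdna_ng_ml`)
#'   and `outcomes` (data frame: `patient_id`, `trg`, `path_cr`, `relapse`,
#'   `time_to_event_months`, `adjuvant`, `kras_detected_baseline`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    pid <- sprintf("P%03d", seq_len(n))
    path_cr <- stats::runif(n) < cfg$pathcr_probability
    trg <- integer(n)
    n_res <- sum(!path_cr)
    if (n_res)
      trg[!path_cr] <- sample(1:3, n_res, replace = TRUE,
                              prob = cfg$trg_residual_probs)
    relapse <- stats::runif(n) < ifelse(path_cr, cfg$relapse_prob_pathcr,
                                        cfg$relapse_prob_residual)
    increase <- stats::runif(n) < ifelse(relapse, cfg$p_increase_relapse,
                                         cfg$p_increase_nonrelapse)

    tps <- names(cfg$medians_pathcr)
    sd <- cfg$log_sd
    med <- function(tp) ifelse(path_cr, cfg$medians_pathcr[[tp]],
                               cfg$medians_residual[[tp]])
    vals <- matrix(NA_real_, n, length(tps), dimnames = list(NULL, tps))
    vals[, "W1D1"] <- exp(log(med("W1D1")) + sd * stats::rnorm(n))
    vals[, "W2D1"] <- .draw_w2d1(vals[, "W1D1"], log(med("W2D1")), sd, increase)
    for (tp in setdiff(tps, c("W1D1", "W2D1")))
      vals[, tp] <- exp(log(med(tp)) + sd * stats::rnorm(n))

    total <- exp(log(cfg$total_cfdna_median_ng_ml) +
                   cfg$total_cfdna_log_sd *
                     stats::rnorm(n * length(tps)))

    rel_time <- exp(log(cfg$relapse_time_median_months) +
                      cfg$relapse_time_log_sd * stats::rnorm(n))
    cens_time <- stats::runif(n, cfg$followup_window_months[1],
                              cfg$followup_window_months[2])
    time_to_event <- ifelse(relapse, rel_time, cens_time)

    adjuvant <- stats::runif(n) < cfg$adjuvant_probability
    kras <- stats::runif(n) < cfg$kras_detected_probability

    measurements <- data.frame(
      patient_id = rep(pid, times = length(tps)),
      timepoint = rep(tps, each = n),
      c_cfdna_copies_ml = as.vector(vals),
      total_cfdna_ng_ml = total,
      stringsAsFactors = FALSE)
    ord <- order(measurements$patient_id,
                 parse_timepoint(measurements$timepoint)$week,
                 parse_timepoint(measurements$timepoint)$day)
    measurements <- measurements[ord, , drop = FALSE]
    rownames(measurements) <- NULL

    outcomes <- data.frame(
      patient_id = pid, trg = trg, path_cr = path_cr, relapse = relapse,
      time_to_event_months = time_to_event, adjuvant = adjuvant,
      kras_detected_baseline = kras, stringsAsFactors = FALSE)
    structure(list(measurements = measurements, outcomes = outcomes),
              class = "cohort")
  })
}

.meas_cols <- c("patient_id", "timepoint", "c_cfdna_copies_ml",
                "total_cfdna_ng_ml")
.outc_cols <- c("patient_id", "trg", "path_cr", "relapse",
                "time_to_event_months", "adjuvant", "kras_detected_baseline")

#' Write a cohort to CSV files
#'
#' Writes `measurements.csv` (long format) and `outcomes.csv` into `dir`.
#' Reading them back with [read_cohort()] reproduces the cohort.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' @param dir Directory holding `measurements.csv` and `outcomes.csv`, as
#'   written by [write_cohort()].
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "measurements.csv")
  op <- file.path(dir, "outcomes.csv")
  for (p in c(mp, op))
    if (!file.exists(p)) input_error(sprintf("cohort file not found: %s", p))
  meas <- utils::read.csv(mp, stringsAsFactors = FALSE)
  outc <- utils::read.csv(op, stringsAsFactors = FALSE)
  miss_m <- setdiff(.meas_cols, names(meas))
  if (length(miss_m))
    format_error(sprintf("measurements.csv missing column(s): %s",
                         paste(miss_m, collapse = ", ")))
  miss_o <- setdiff(.outc_cols, names(outc))
  if (length(miss_o))
    format_error(sprintf("outcomes.csv missing column(s): %s",
                         paste(miss_o, collapse = ", ")))
  structure(list(measurements = meas, outcomes = outc), class = "cohort")
}

#' Summarise a cohort
#'
#' @param x A `cohort` object or an outcomes data frame.
#' @return List: `n_patients`, `n_pathcr`, `pathcr_rate_percent`,
#'   `n_relapse`, `median_followup_months`, `median_time_to_relapse_months`.
#' @export
cohort_summary <- function(x) {
  outc <- if (inherits(x, "cohort")) x$outcomes else x
  miss <- setdiff(c("patient_id", "path_cr", "relapse",
                    "time_to_event_months"), names(outc))
  if (length(miss))
    format_error(sprintf("outcomes table missing column(s): %s",
                         paste(miss, collapse = ", ")))
  n <- nrow(outc)
  list(n_patients = n,
       n_pathcr = sum(outc$path_cr),
       pathcr_rate_percent = 100 * sum(outc$path_cr) / n,
       n_relapse = sum(outc$relapse),
       median_followup_months = stats::median(outc$time_to_event_months),
       median_time_to_relapse_months =
         if (any(outc$relapse))
           stats::median(outc$time_to_event_months[outc$relapse])
         else NA_real_)
}

#' @export
print.cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf(
    "cohort: %d patients, %d pathCR (%.1f%%), %d relapses, %d measurements\n",
    s$n_patients, s$n_pathcr, s$pathcr_rate_percent, s$n_relapse,
    nrow(x$measurements)))
  invisible(x)
}
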