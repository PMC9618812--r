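# Cohort accounting: responder classification with evaluable-denominator
# logic, printed-style percentages, and a baseline characteristics table.

#' Round-half-up percentage
#'
#' `100 * numerator / denominator` rounded half-up to two decimals — the
#' convention every printed percentage of the reference cohort reproduces
#' (e.g. 65/123 -> 52.85, 40/95 -> 42.11).
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @return Percentage with two decimals.
#' @export
rate <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("rate needs a positive denominator")
  if (any(numerator > denominator)) stop("numerator exceeds denominator")
  round_half_up(100 * numerator / denominator, 2)
}

#' Classify treatment response and account the evaluable denominators
#'
#' A responder achieved CR together with BM uMRD. A non-responder is
#' anyone not in CR (missing BM data cannot rescue a no-CR patient) or in
#' CR with detectable BM MRD. Patients whose CR status is missing, or in
#' CR with missing BM MRD, are unclassifiable. Denominator conventions
#' follow the printed arithmetic of the reference cohort: CR / no-CR
#' percentages are over all patients, MRD percentages over the evaluable
#' patients for that compartment, and responder percentages over the
#' classifiable patients.
#'
#' @param clinical A [clinical_table()].
#' @return List of class `response_summary`: `category` (per-patient
#'   factor responder / non-responder / unclassifiable), `summary`
#'   (outcome, numerator, denominator, percent), and `by_arm`.
#' @export
classify_response <- function(clinical) {
  stopifnot(inherits(clinical, "clinical_table"))
  cr <- as.character(clinical$cr)
  bm <- as.character(clinical$bm_mrd)
  blood <- as.character(clinical$blood_mrd)
  cat <- ifelse(is.na(cr), "unclassifiable",
         ifelse(cr == "no-CR", "non-responder",
         ifelse(is.na(bm), "unclassifiable",
         ifelse(bm == "uMRD", "responder", "non-responder"))))
  category <- factor(cat, levels = c("responder", "non-responder",
                                     "unclassifiable"))
  n <- nrow(clinical)
  n_class <- sum(category != "unclassifiable")
  mk <- function(outcome, num, den) data.frame(
    outcome = outcome, numerator = num, denominator = den,
    percent = if (den > 0) rate(num, den) else NA_real_,
    stringsAsFactors = FALSE)
  summary <- rbind(
    mk("CR", sum(cr == "CR", na.rm = TRUE), n),
    mk("no-CR", sum(cr == "no-CR", na.rm = TRUE), n),
    mk("blood-uMRD", sum(blood == "uMRD", na.rm = TRUE), sum(!is.na(blood))),
    mk("BM-uMRD", sum(bm == "uMRD", na.rm = TRUE), sum(!is.na(bm))),
    mk("responder", sum(category == "responder"), n_class),
    mk("non-responder", sum(category == "non-responder"), n_class))
  by_arm <- NULL
  if ("arm" %in% names(clinical)) {
    by_arm <- do.call(rbind, lapply(levels(clinical$arm), function(a) {
      i <- !is.na(clinical$arm) & clinical$arm == a
      cls <- category[i]
      nc <- sum(cls != "unclassifiable")
      cbind(arm = a, rbind(
        mk("responder", sum(cls == "responder"), nc),
        mk("non-responder", sum(cls == "non-responder"), nc)))
    }))
  }
  structure(list(category = setNames(category, clinical$patient_id),
                 summary = summary, by_arm = by_arm),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat("response accounting (numerator/denominator, percent):\n")
  with(x$summary, cat(sprintf("  %-14s %d/%d (%.2f%%)\n",
                              outcome, numerator, denominator, percent), sep = ""))
  invisible(x)
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7 by
#' default; configurable, since printed IQRs rarely pin down the method).
#'
#' @param values Numeric vector (length >= 1 after NA removal).
#' @param type Quantile algorithm type.
#' @return Named numeric: `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("median_iqr needs at least one value")
  q <- quantile(values, c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Baseline characteristics table
#'
#' Summarises a cohort the way a patients'-characteristics table is
#' printed: categoricals as `n/denominator (percent)` with per-variable
#' evaluable denominators, numerics as `median (IQR)`.
#'
#' @param clinical A [clinical_table()].
#' @param categorical,numeric Columns to summarise; defaults cover the
#'   standard covariates present in the table.
#' @return Data.frame: `variable`, `level`, `n`, `denominator`, `percent`,
#'   `median`, `q1`, `q3`, `formatted`.
#' @export
baseline_table <- function(clinical,
                           categorical = c("sex", "binet", "ecog", "ighv",
                                           "del13q", "del11q", "tri12",
                                           "arm", "cycles"),
                           numeric = c("age", "lymphocytes", "b2m")) {
  stopifnot(inherits(clinical, "clinical_table"))
  rows <- list()
  for (cn in intersect(categorical, names(clinical))) {
    v <- clinical[[cn]]
    den <- sum(!is.na(v))
    if (den == 0) next
    for (lev in sort(unique(as.character(v[!is.na(v)])))) {
      nn <- sum(!is.na(v) & as.character(v) == lev)
      rows[[length(rows) + 1]] <- data.frame(
        variable = cn, level = lev, n = nn, denominator = den,
        percent = rate(nn, den), median = NA_real_, q1 = NA_real_,
        q3 = NA_real_,
        formatted = sprintf("%d/%d (%.2f)", nn, den, rate(nn, den)),
        stringsAsFactors = FALSE)
    }
  }
  for (cn in intersect(numeric, names(clinical))) {
    v <- clinical[[cn]]
    if (all(is.na(v))) next
    q <- median_iqr(v)
    rows[[length(rows) + 1]] <- data.frame(
      variable = cn, level = NA_character_, n = sum(!is.na(v)),
      denominator = sum(!is.na(v)), percent = NA_real_,
      median = q[["median"]], q1 = q[["q1"]], q3 = q[["q3"]],
      formatted = sprintf("%.2f (%.2f-%.2f)", q[["median"]], q[["q1"]],
                          q[["q3"]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Reference clinical table reproducing the published cohort margins
#'
#' A synthetic 123-patient clinical table constructed deterministically so
#' that every printed count of the reference cohort is reproduced: 65 CR
#' and 53 no-CR (5 missing), 69/108 blood uMRD, 40/95 BM uMRD, and 27
#' responders among 107 classifiable patients. Patient-level data were
#' never published; only these margins are faithful. No
#' blood-MRD-detectable patient has BM uMRD.
#'
#' @return A [clinical_table()].
#' @export
reference_clinical_table <- function() {
  n <- 123
  cr <- c(rep("CR", 65), rep("no-CR", 53), rep(NA, 5))
  bm <- rep(NA_character_, n)
  bm[1:27] <- "uMRD"          # CR responders
  bm[28:54] <- "detectable"   # CR, BM positive
  bm[66:78] <- "uMRD"         # no-CR with BM uMRD
  bm[79:106] <- "detectable"
  blood <- rep(NA_character_, n)
  blood[c(1:27, 66:78)] <- "uMRD"   # every BM-uMRD patient is blood-uMRD
  blood[c(28:54, 55:56)] <- "uMRD"  # 29 further blood-uMRD (69 total)
  blood[c(57:65, 79:108)] <- "detectable"
  arm <- c(rep("FCR", 62), rep("Dense-FCR", 61))
  clinical_table(data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    cr = cr, blood_mrd = blood, bm_mrd = bm, arm = arm,
    pfs_time = 42.4, pfs_event = 0, stringsAsFactors = FALSE))
}
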