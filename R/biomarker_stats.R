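# Univariate and multivariate association of miRNAs / clinical covariates
# with binary response outcomes; ROC construction and Youden cutpoints.

## coerce outcome labels to logical (TRUE = positive class)
as_binary <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (is.null(positive))
    stop("factor/character labels need an explicit `positive` class")
  labels == positive
}

#' Shapiro-Wilk-gated two-group comparison
#'
#' Normality is tested per group with the Shapiro-Wilk test at
#' `alpha_normality`; when both groups pass, a two-sample Student t test is
#' used, otherwise the Mann-Whitney test. Groups too small for
#' Shapiro-Wilk (n < 3) fall through to Mann-Whitney directly. For groups
#' above the Shapiro-Wilk size ceiling (5000) a deterministic evenly-spaced
#' subsample of 5000 is tested.
#'
#' @param values Numeric vector.
#' @param labels Binary group labels (logical, 0/1, or factor with
#'   `positive`); `TRUE` is the positive/responder group.
#' @param alpha_normality Gate level (default 0.05).
#' @param positive Positive class for factor labels.
#' @return List: `test_used` (`"t"` or `"mann-whitney"`), `p_value`,
#'   `direction` (sign of positive-group median minus other median),
#'   `degenerate`, `n_pos`, `n_neg`.
#' @export
compare_groups <- function(values, labels, alpha_normality = 0.05,
                           positive = NULL) {
  y <- as_binary(labels, positive)
  keep <- !is.na(values) & !is.na(y)
  values <- values[keep]; y <- y[keep]
  g1 <- values[y]; g0 <- values[!y]
  if (length(g1) == 0 || length(g0) == 0)
    stop("both groups must be non-empty")
  direction <- sign(median(g1) - median(g0))
  if (sd(values) == 0)
    return(list(test_used = "mann-whitney", p_value = 1,
                direction = 0, degenerate = TRUE,
                n_pos = length(g1), n_neg = length(g0)))
  normal_ok <- function(g) {
    n <- length(g)
    if (n < 3 || sd(g) == 0) return(FALSE)
    if (n > 5000) g <- g[round(seq(1, n, length.out = 5000))]
    shapiro.test(g)$p.value > alpha_normality
  }
  if (normal_ok(g1) && normal_ok(g0)) {
    list(test_used = "t",
         p_value = t.test(g1, g0, var.equal = TRUE)$p.value,
         direction = direction, degenerate = FALSE,
         n_pos = length(g1), n_neg = length(g0))
  } else {
    list(test_used = "mann-whitney",
         p_value = suppressWarnings(wilcox.test(g1, g0)$p.value),
         direction = direction, degenerate = FALSE,
         n_pos = length(g1), n_neg = length(g0))
  }
}

## the four response outcome definitions as logical vectors (NA = not
## evaluable for that outcome); denominators differ by design
outcome_labels <- function(clinical) {
  resp <- classify_response(clinical)$category
  list(
    "CR" = ifelse(is.na(clinical$cr), NA, clinical$cr == "CR"),
    "blood-uMRD" = ifelse(is.na(clinical$blood_mrd), NA,
                          clinical$blood_mrd == "uMRD"),
    "BM-uMRD" = ifelse(is.na(clinical$bm_mrd), NA,
                       clinical$bm_mrd == "uMRD"),
    "CR+BM-uMRD" = ifelse(resp == "unclassifiable", NA,
                          resp == "responder"))
}

#' Univariate miRNA scan over the four response outcomes
#'
#' One Shapiro-Wilk-gated comparison per (miRNA, outcome) pair, where the
#' outcomes are CR vs no-CR, blood uMRD vs detectable, BM uMRD vs
#' detectable, and CR-with-BM-uMRD (responder) vs other classifiable
#' patients. Each outcome uses only patients whose label for that outcome
#' is non-missing, so denominators differ across columns.
#'
#' @param expr An [expression_matrix()].
#' @param clinical A [clinical_table()] (matched on `patient_id`).
#' @param mirnas miRNA ids to scan (default: all columns of `expr`).
#' @return Data.frame grid: `mirna`, `outcome`, `n_pos`, `n_neg`,
#'   `test_used`, `p_value`, `direction`, `evaluable`.
#' @export
scan_outcomes <- function(expr, clinical, mirnas = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(clinical, "clinical_table"))
  mirnas <- mirnas %||% colnames(expr)
  common <- intersect(rownames(expr), clinical$patient_id)
  if (length(common) == 0) stop("no shared patient ids")
  cl <- clinical[match(common, clinical$patient_id), ]
  outs <- outcome_labels(cl)
  grid <- expand.grid(mirna = mirnas, outcome = names(outs),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$mirna[i]; o <- grid$outcome[i]
    y <- outs[[o]]
    v <- expr[common, m]
    keep <- !is.na(y) & !is.na(v)
    n_pos <- sum(y[keep]); n_neg <- sum(!y[keep])
    if (n_pos < 2 || n_neg < 2)
      return(data.frame(mirna = m, outcome = o, n_pos = n_pos, n_neg = n_neg,
                        test_used = NA_character_, p_value = NA_real_,
                        direction = NA_real_, evaluable = FALSE,
                        stringsAsFactors = FALSE))
    cg <- compare_groups(v[keep], y[keep])
    data.frame(mirna = m, outcome = o, n_pos = n_pos, n_neg = n_neg,
               test_used = cg$test_used, p_value = cg$p_value,
               direction = cg$direction, evaluable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Chi-square / Fisher association for categorical data
#'
#' Fisher's exact test is used when any expected cell count is 5 or less,
#' otherwise the (uncorrected) chi-square test.
#'
#' @param factor Categorical vector.
#' @param outcome Binary vector (logical or 0/1).
#' @param positive Positive class when `outcome` is a factor.
#' @return List: `p_value`, `test_used`, `degenerate`, `table`.
#' @export
categorical_association <- function(factor, outcome, positive = NULL) {
  y <- as_binary(outcome, positive)
  keep <- !is.na(factor) & !is.na(y)
  f <- droplevels(as.factor(factor[keep]))
  y <- y[keep]
  if (nlevels(f) < 2 || length(unique(y)) < 2)
    return(list(p_value = 1, test_used = NA_character_, degenerate = TRUE,
                table = table(f, y)))
  tab <- table(f, y)
  expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
  if (any(expected <= 5)) {
    list(p_value = fisher.test(tab)$p.value, test_used = "fisher",
         degenerate = FALSE, table = tab)
  } else {
    list(p_value = chisq.test(tab, correct = FALSE)$p.value,
         test_used = "chi2", degenerate = FALSE, table = tab)
  }
}

#' Spearman rank correlation between two numeric variables
#'
#' Tie-aware rank correlation with a two-sided p-value.
#'
#' @param x,y Paired numeric vectors.
#' @return List: `rho`, `p_value`, `n`, `degenerate`.
#' @export
spearman_assoc <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("spearman_assoc needs >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       degenerate = FALSE)
}

## Wald p-value per model term (single-coefficient z, multi-df chi-square)
term_wald_p <- function(fit) {
  asn <- attr(model.matrix(fit), "assign")
  tl <- attr(fit$terms, "term.labels")
  b <- coef(fit)
  V <- vcov(fit)
  vapply(seq_along(tl), function(k) {
    idx <- which(asn == k)
    idx <- idx[!is.na(b[idx])]
    if (length(idx) == 0) return(1)  # aliased term carries no information
    if (length(idx) == 1) {
      z <- b[idx] / sqrt(V[idx, idx])
      2 * pnorm(-abs(z))
    } else {
      w <- drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% b[idx])
      pchisq(w, df = length(idx), lower.tail = FALSE)
    }
  }, numeric(1), USE.NAMES = FALSE) -> p
  setNames(p, tl)
}

#' Backward-selection logistic regression
#'
#' Fits a binomial GLM and iteratively removes the least significant term
#' (largest Wald p-value) until every retained term has `p < alpha_stay`.
#' Odds ratios with Wald 95% confidence intervals are reported per
#' retained coefficient; quasi-separated coefficients are flagged instead
#' of reported as fitted numbers.
#'
#' @param outcome Binary outcome (logical, 0/1, or factor with `positive`).
#' @param covariates Data.frame of candidate covariates (numeric or factor).
#' @param alpha_stay Retention level (default 0.05). `alpha_stay = 1`
#'   returns the full model, `alpha_stay = 0` the empty model.
#' @param positive Positive class for factor outcomes.
#' @return List of class `backward_logistic`: `coefficients` data.frame
#'   (`variable`, `term`, `estimate`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `separation`), `retained`, `dropped` (in drop order),
#'   `n`, and the final `model`.
#' @export
backward_logistic <- function(outcome, covariates, alpha_stay = 0.05,
                              positive = NULL) {
  stopifnot(is.data.frame(covariates), ncol(covariates) >= 1)
  y <- as_binary(outcome, positive)
  dat <- cbind(data.frame(.y = y), covariates)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 10 * ncol(covariates))
    warning(sprintf("only %d complete cases for %d candidates (< 10 per candidate)",
                    n, ncol(covariates)))
  terms_left <- names(covariates)
  dropped <- character(0)
  fit_model <- function(terms) {
    f <- if (length(terms) == 0) ".y ~ 1" else
      paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + "))
    suppressWarnings(glm(as.formula(f), family = binomial(), data = dat))
  }
  fit <- fit_model(terms_left)
  repeat {
    if (length(terms_left) == 0) break
    p <- term_wald_p(fit)
    worst <- which.max(p)
    if (p[worst] < alpha_stay) break
    dropped <- c(dropped, names(p)[worst])
    terms_left <- setdiff(terms_left, names(p)[worst])
    fit <- fit_model(terms_left)
  }
  co <- summary(fit)$coefficients
  keep <- setdiff(rownames(co), "(Intercept)")
  sep_flag <- function(est, se) !is.finite(est) | abs(est) > 10 | se > 50
  if (length(keep) > 0) {
    est <- co[keep, 1]; se <- co[keep, 2]; pv <- co[keep, 4]
    sep <- sep_flag(est, se)
    coefs <- data.frame(
      term = keep,
      estimate = ifelse(sep, NA_real_, est),
      or = ifelse(sep, NA_real_, exp(est)),
      ci_low = ifelse(sep, NA_real_, exp(est - qnorm(0.975) * se)),
      ci_high = ifelse(sep, NA_real_, exp(est + qnorm(0.975) * se)),
      p_value = pv, separation = sep,
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    coefs <- data.frame(term = character(0), estimate = numeric(0),
                        or = numeric(0), ci_low = numeric(0),
                        ci_high = numeric(0), p_value = numeric(0),
                        separation = logical(0))
  }
  structure(list(coefficients = coefs, retained = terms_left,
                 dropped = dropped, n = n, model = fit),
            class = "backward_logistic")
}

#' @export
print.backward_logistic <- function(x, ...) {
  cat(sprintf("backward logistic selection: %d retained of %d candidates (n = %d)\n",
              length(x$retained), length(x$retained) + length(x$dropped), x$n))
  if (nrow(x$coefficients) > 0) print(x$coefficients, digits = 3)
  else cat("  (empty model)\n")
  invisible(x)
}

#' ROC curve with Youden-index cutpoint
#'
#' Thresholds are the midpoints between consecutive sorted unique marker
#' values plus -Inf/+Inf sentinels. Under the default `"high-positive"`
#' orientation a value strictly greater than the threshold is called
#' positive (mirroring the decision tree's routing rule), so sensitivity is
#' non-increasing in the threshold. AUC is the trapezoidal area; the
#' Youden cutpoint maximises J = Se + Sp - 1, ties broken towards the
#' smallest threshold (favouring sensitivity).
#'
#' @param values Numeric marker values.
#' @param labels Binary class labels (`TRUE`/1 = positive).
#' @param orientation `"high-positive"`, `"low-positive"`, or `"auto"`
#'   (direction with AUC >= 0.5).
#' @param positive Positive class for factor labels.
#' @return Object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `j`, `auc`, `youden_threshold`, `youden_j`,
#'   `se_at_youden`, `sp_at_youden`, `orientation`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(values, labels,
                      orientation = c("high-positive", "low-positive", "auto"),
                      positive = NULL) {
  orientation <- match.arg(orientation)
  y <- as_binary(labels, positive)
  keep <- !is.na(values) & !is.na(y)
  values <- values[keep]; y <- y[keep]
  if (!any(y) || all(y)) stop("roc_curve needs both classes present")
  if (orientation == "auto") {
    r <- roc_curve(values, y, "high-positive")
    if (r$auc >= 0.5) return(r)
    return(roc_curve(values, y, "low-positive"))
  }
  flip <- orientation == "low-positive"
  v <- if (flip) -values else values
  n_pos <- sum(y); n_neg <- sum(!y)
  ## per-unique-value class counts, ascending in v (rowsum sorts groups)
  cc <- rowsum(cbind(y + 0, 1 - y), v)
  u <- as.numeric(rownames(cc))
  thr <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  cpos <- unname(cumsum(cc[, 1])); cneg <- unname(cumsum(cc[, 2]))
  if (length(u) > 1) {
    se <- c(1, (n_pos - cpos[-length(u)]) / n_pos, 0)
    sp <- c(0, cneg[-length(u)] / n_neg, 1)
  } else { se <- c(1, 0); sp <- c(0, 1) }
  j <- se + sp - 1
  ## trapezoid over (FPR, TPR) ordered by ascending FPR
  fpr <- rev(1 - sp); tpr <- rev(se)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  if (flip) {  # report thresholds on the original, ascending scale
    thr <- rev(-thr); se <- rev(se); sp <- rev(sp); j <- rev(j)
  }
  best <- which.max(j)  # first maximum = smallest threshold
  out_thr <- thr
  structure(list(thresholds = out_thr, sensitivity = se, specificity = sp,
                 j = j, auc = auc,
                 youden_threshold = out_thr[best], youden_j = j[best],
                 se_at_youden = se[best], sp_at_youden = sp[best],
                 orientation = orientation, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC %.3f over %d+/%d- ; Youden J %.3f at %.4g (Se %.0f%%, Sp %.0f%%)\n",
              x$orientation, x$auc, x$n_pos, x$n_neg, x$youden_j,
              x$youden_threshold, 100 * x$se_at_youden, 100 * x$sp_at_youden))
  invisible(x)
}

#' Youden-optimal cutpoint of a ROC curve
#'
#' @param roc A [roc_curve()].
#' @return List: `threshold`, `se`, `sp`, `j`.
#' @export
youden_cutpoint <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  best <- which.max(roc$j)
  list(threshold = roc$thresholds[best], se = roc$sensitivity[best],
       sp = roc$specificity[best], j = roc$j[best])
}
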