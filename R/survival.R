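# Progression-free-survival analysis of the tree-defined groups:
# Kaplan-Meier estimation, k-group log-rank, Cox regression (Breslow
# ties), landmark filtering, and the published three-tier merge.
# Estimation is delegated to the survival package behind this surface.

#' Kaplan-Meier product-limit estimate
#'
#' Ties between events and censorings are handled events-first. The median
#' is the smallest time with S(t) <= 0.5 and is reported as "not reached"
#' (`median_reached = FALSE`) when the curve never falls that far.
#'
#' @param times Follow-up times in months (>= 0).
#' @param events Event indicators (1/TRUE = progression, 0/FALSE = censored).
#' @return Object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `se` (Greenwood), `median_time`,
#'   `median_reached`, `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("km_estimate needs at least one subject")
  events <- as.integer(as.logical(events))
  stopifnot(length(events) == length(times), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med_idx <- which(fit$surv <= 0.5)
  reached <- length(med_idx) > 0
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, se = fit$std.err * fit$surv,
                 median_time = if (reached) fit$time[med_idx[1]] else NA_real_,
                 median_reached = reached, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median %s\n",
              x$n, sum(x$n_event),
              if (x$median_reached) sprintf("%.1f months", x$median_time)
              else "not reached"))
  invisible(x)
}

#' Survival probability at a fixed time
#'
#' Reads the step value from a Kaplan-Meier curve. The default `"left"`
#' side returns S(t-), the value just before `t`, which is the convention
#' used for follow-up-time readouts such as PFS at the median follow-up.
#'
#' @param km A [km_estimate()] curve.
#' @param t Time in months.
#' @param side `"left"` for S(t-), `"right"` for S(t).
#' @return Survival probability in `[0, 1]`.
#' @export
km_surv_at <- function(km, t, side = c("left", "right")) {
  side <- match.arg(side)
  idx <- if (side == "left") which(km$time < t) else which(km$time <= t)
  if (length(idx) == 0) return(1)
  km$surv[max(idx)]
}

#' k-sample log-rank test
#'
#' Observed-minus-expected event sums with hypergeometric variance,
#' chi-square with k-1 degrees of freedom.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group label per subject (>= 2 non-empty groups).
#' @return List: `chi2`, `df`, `p_value`, `n_per_group`.
#' @export
logrank <- function(times, events, groups) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2) stop("log-rank needs >= 2 groups")
  if (any(table(groups) == 0)) stop("log-rank group with no subjects")
  events <- as.integer(as.logical(events))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
       n_per_group = table(groups))
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' `mode = "univariate"` fits each covariate alone (one hazard ratio per
#' covariate, the layout of a baseline-characteristics table);
#' `"multivariate"` fits them jointly. Wald 95% confidence intervals and
#' p-values are reported. Monotone-likelihood fits (e.g. a level with no
#' events) are flagged non-convergent with no fabricated hazard ratio.
#'
#' @param times,events As in [km_estimate()].
#' @param covariates Data.frame of covariates (numeric or factor).
#' @param mode `"univariate"` or `"multivariate"`.
#' @return Data.frame of class `cox_result`: `variable`, `term`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `converged`, `n`.
#' @export
cox_fit <- function(times, events, covariates,
                    mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(covariates))
  events <- as.integer(as.logical(events))
  one_fit <- function(cols) {
    dat <- cbind(data.frame(.t = times, .e = events),
                 covariates[, cols, drop = FALSE])
    dat <- dat[complete.cases(dat), , drop = FALSE]
    f <- as.formula(paste("survival::Surv(.t, .e) ~",
                          paste(sprintf("`%s`", cols), collapse = " + ")))
    warned <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(f, data = dat, ties = "breslow"),
      warning = function(w) {
        if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
          warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    est <- co[, "coef"]; se <- co[, "se(coef)"]
    bad <- warned | !is.finite(est) | abs(est) > 10 | se > 50
    asn <- attr(model.matrix(fit), "assign")
    tl <- attr(fit$terms, "term.labels")
    data.frame(
      variable = gsub("`", "", tl[asn]),
      term = rownames(co),
      hazard_ratio = ifelse(bad, NA_real_, exp(est)),
      ci_low = ifelse(bad, NA_real_, exp(est - qnorm(0.975) * se)),
      ci_high = ifelse(bad, NA_real_, exp(est + qnorm(0.975) * se)),
      p_value = co[, "Pr(>|z|)"],
      converged = !bad, n = nrow(dat),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- if (mode == "univariate")
    do.call(rbind, lapply(names(covariates), one_fit))
  else one_fit(names(covariates))
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Landmark filtering of survival times
#'
#' Removes subjects whose follow-up ends before the landmark and resets
#' the clock of the survivors, as in a landmark analysis anchored at the
#' MRD assessment time.
#'
#' @param times,events As in [km_estimate()].
#' @param landmark Landmark time in months (>= 0).
#' @return List: `times`, `events`, `kept` (logical index into the input).
#' @export
landmark_filter <- function(times, events, landmark) {
  stopifnot(landmark >= 0)
  keep <- times >= landmark
  if (!any(keep)) warning("landmark beyond all follow-up times; empty set")
  list(times = times[keep] - landmark,
       events = as.integer(as.logical(events))[keep], kept = keep)
}

#' PFS by decision-tree group
#'
#' Joins tree group assignments with the clinical table, optionally merges
#' the six labels into the published three prognostic tiers (high = HHH;
#' intermediate = HHL, HLL, LH; low = HLH, LL), and returns one
#' Kaplan-Meier curve per group plus the across-group log-rank test.
#'
#' @param assignments Output of [assign_groups()].
#' @param clinical A [clinical_table()].
#' @param merge `"none"` or `"paper-three-tier"`.
#' @return List: `curves` (named list of `km_curve`), `logrank` (or `NULL`
#'   for a single group), `groups` (per-patient data.frame).
#' @export
pfs_by_tree_group <- function(assignments, clinical,
                              merge = c("none", "paper-three-tier")) {
  merge <- match.arg(merge)
  stopifnot(inherits(clinical, "clinical_table"))
  idx <- match(assignments$patient_id, clinical$patient_id)
  if (anyNA(idx)) stop("assignment patient(s) absent from clinical table")
  df <- data.frame(patient_id = assignments$patient_id,
                   label = merge_labels(assignments$label, merge),
                   pfs_time = clinical$pfs_time[idx],
                   pfs_event = clinical$pfs_event[idx],
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$label) & !is.na(df$pfs_time) & !is.na(df$pfs_event), ]
  if (nrow(df) == 0) stop("no classifiable patients with follow-up")
  curves <- lapply(split(df, df$label), function(d)
    km_estimate(d$pfs_time, d$pfs_event))
  lr <- if (length(curves) >= 2)
    logrank(df$pfs_time, df$pfs_event, df$label) else NULL
  list(curves = curves, logrank = lr, groups = df)
}
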