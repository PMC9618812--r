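# Discovery-stage TLDA screening statistics: Ct normalisation, geometric-mean
# fold change, per-assay two-group testing, volcano categorisation at a
# fold-change threshold, and the Ct < 30 detection-limit filter.

#' Normalise raw Ct values to delta-Ct
#'
#' `global-mean` subtracts each sample's mean Ct over its detected assays
#' (the standard normalisation for TLDA cards, which assume no single
#' endogenous control); `reference-assay` subtracts a chosen assay's Ct.
#' Relative expression is `2^-deltaCt`.
#'
#' @param ct A [ct_matrix()].
#' @param method `"global-mean"` or `"reference-assay"`.
#' @param reference Assay id, required for `method = "reference-assay"`.
#' @return Numeric delta-Ct matrix (samples x assays). Samples whose
#'   reference assay is undetected get `NA` delta-Ct with a warning.
#' @export
normalize_ct <- function(ct, method = c("global-mean", "reference-assay"),
                         reference = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  method <- match.arg(method)
  if (method == "global-mean") {
    detected <- !ct$undetected
    if (any(rowSums(detected) < 2))
      stop("global-mean normalisation needs >= 2 detected assays per sample")
    norm <- rowSums(ct$ct * detected) / rowSums(detected)
  } else {
    if (is.null(reference) || !reference %in% colnames(ct$ct))
      stop("reference assay not found in Ct matrix")
    norm <- ct$ct[, reference]
    bad <- ct$undetected[, reference]
    if (any(bad)) {
      warning("reference assay undetected in sample(s): ",
              paste(rownames(ct$ct)[bad], collapse = ", "),
              "; their delta-Ct is NA")
      norm[bad] <- NA_real_
    }
  }
  sweep(ct$ct, 1, norm, "-")
}

#' Geometric-mean fold change between two groups
#'
#' Ratio of group geometric means of (positive) relative expression. When
#' the inputs are `2^-deltaCt` this equals `2^(mean dCt_b - mean dCt_a)`.
#'
#' @param expr_a,expr_b Positive expression values for the two groups
#'   (`a` over `b`).
#' @return A positive scalar.
#' @examples
#' fold_change(c(8, 2), c(1, 1)) # 4
#' @export
fold_change <- function(expr_a, expr_b) {
  if (length(expr_a) == 0 || length(expr_b) == 0)
    stop("fold_change needs non-empty groups")
  if (any(expr_a <= 0) || any(expr_b <= 0))
    stop("fold_change needs strictly positive expression values")
  exp(mean(log(expr_a)) - mean(log(expr_b)))
}

#' Two-group differential screen over a Ct matrix
#'
#' Per assay, delta-Ct values are compared between the two screening arms
#' (default: two-sample Student t on delta-Ct, as in the discovery volcano;
#' `"auto"` applies the Shapiro-Wilk gate of [compare_groups()]), the
#' geometric-mean fold change is reported responder-over-other, and each
#' assay is categorised `up` / `down` / `not-significant` against
#' `fc_threshold` and `alpha`. Raw p-values drive the categories (no
#' multiplicity correction at this stage, matching the discovery design);
#' a Benjamini-Hochberg column is provided for reference.
#'
#' @param ct A [ct_matrix()].
#' @param responder Group label treated as the responder (numerator) arm;
#'   default `"responder"` if present, else the first group level.
#' @param alpha Significance level (default 0.05).
#' @param fc_threshold Fold-change threshold (default 2.5).
#' @param test `"t"`, `"mann-whitney"`, or `"auto"`.
#' @param method,reference Passed to [normalize_ct()].
#' @return A `screen_result` data.frame with one row per assay: columns
#'   `assay`, `fold_change`, `log2_fc`, `p_value`, `p_bh`,
#'   `mean_ct_responder`, `mean_ct_other`, `degenerate`, `category`,
#'   and `passes_detection` (`NA` until [detection_filter()] is applied).
#' @export
differential_screen <- function(ct, responder = NULL, alpha = 0.05,
                                fc_threshold = 2.5,
                                test = c("t", "mann-whitney", "auto"),
                                method = "global-mean", reference = NULL) {
  stopifnot(inherits(ct, "ct_matrix"), fc_threshold > 1)
  test <- match.arg(test)
  lev <- levels(ct$groups)
  responder <- responder %||% (if ("responder" %in% lev) "responder" else lev[1])
  if (!responder %in% lev) stop("responder label '", responder, "' not a group")
  other <- setdiff(lev, responder)
  if (sum(ct$groups == responder) < 2 || sum(ct$groups == other) < 2)
    stop("each screening arm needs >= 2 samples")
  dct <- normalize_ct(ct, method = method, reference = reference)
  iR <- ct$groups == responder
  res <- lapply(colnames(dct), function(a) {
    xR <- dct[iR, a]; xO <- dct[!iR, a]
    keep_R <- !is.na(xR); keep_O <- !is.na(xO)
    xR <- xR[keep_R]; xO <- xO[keep_O]
    degenerate <- (sd(c(xR, xO)) == 0) || length(xR) < 2 || length(xO) < 2
    if (degenerate) {
      p <- 1
    } else if (sd(xR) == 0 && sd(xO) == 0) {
      p <- if (mean(xR) == mean(xO)) 1 else {
        suppressWarnings(wilcox.test(xR, xO)$p.value)
      }
    } else {
      p <- switch(test,
        "t" = t.test(xR, xO, var.equal = TRUE)$p.value,
        "mann-whitney" = suppressWarnings(wilcox.test(xR, xO)$p.value),
        "auto" = compare_groups(c(xR, xO),
                                c(rep(TRUE, length(xR)), rep(FALSE, length(xO))))$p_value)
    }
    ## FC on 2^-dCt equals 2^(mean dCt_other - mean dCt_responder)
    log2_fc <- mean(xO) - mean(xR)
    data.frame(assay = a, fold_change = 2^log2_fc, log2_fc = log2_fc,
               p_value = p,
               mean_ct_responder = mean(ct$ct[iR, a]),
               mean_ct_other = mean(ct$ct[!iR, a]),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_bh <- p.adjust(res$p_value, "BH")
  res$category <- "not-significant"
  res$category[res$p_value < alpha & res$fold_change >= fc_threshold] <- "up"
  res$category[res$p_value < alpha & res$fold_change <= 1 / fc_threshold] <- "down"
  res$passes_detection <- NA
  attr(res, "responder") <- responder
  attr(res, "alpha") <- alpha
  attr(res, "fc_threshold") <- fc_threshold
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Detection-limit filter on screen results
#'
#' An assay passes when its mean raw Ct is strictly below `ct_limit` in
#' both arms (one-sided undetectability would otherwise inflate the fold
#' change). Failures are marked, not removed.
#'
#' @param results A `screen_result` from [differential_screen()].
#' @param ct_limit Cycle limit (default 30, strict `<`).
#' @return `results` with `passes_detection` filled in.
#' @export
detection_filter <- function(results, ct_limit = 30) {
  stopifnot(inherits(results, "screen_result"))
  results$passes_detection <- results$mean_ct_responder < ct_limit &
    results$mean_ct_other < ct_limit
  attr(results, "ct_limit") <- ct_limit
  results
}

#' Significant, detection-passing assays
#'
#' Convenience view of a filtered screen: assays categorised up or down
#' that also pass the detection limit.
#'
#' @param results A `screen_result` after [detection_filter()].
#' @return Subset of `results`.
#' @export
significant_detected <- function(results) {
  stopifnot(inherits(results, "screen_result"))
  if (all(is.na(results$passes_detection)))
    stop("apply detection_filter() first")
  results[results$category != "not-significant" & results$passes_detection, ,
          drop = FALSE]
}
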