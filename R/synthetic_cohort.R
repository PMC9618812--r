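# Synthetic cohort and screening-matrix generators with planted ground truth.
# The defaults emulate the reference study conditions: a 123-patient FCR
# cohort, an 11-miRNA validation panel, a six-leaf planted decision tree
# whose split thresholds sit at marginal medians, exponential PFS with
# leaf-dependent hazards, administrative censoring at the 42.4-month
# follow-up, and outcome-specific missingness that reproduces distinct
# evaluable denominators.

#' The 11-miRNA validation panel
#'
#' miRNAs quantified by multiplex RT-qPCR in the validation cohort.
#' @return Character vector of miRNA ids.
#' @export
mirna_panel <- function() {
  c("miR-15b", "miR-125b", "miR-155", "miR-181a", "miR-181c", "miR-193b",
    "miR-324-3p", "miR-412", "miR-532-3p", "miR-642", "miR-652")
}

## published ROC thresholds (relative expression) of the five tree miRNAs;
## the generator centres each tree miRNA's log-normal marginal on its
## threshold so that median splits are recoverable at the published value
published_roc_thresholds <- function() {
  c("miR-15b" = 0.1710, "miR-125b" = 0.0005, "miR-181c" = 0.0019,
    "miR-193b" = 0.0113, "miR-412" = 0.0003)
}

#' Planted six-leaf decision-tree truth
#'
#' The default simulation truth mirrors the published tree topology:
#' miR-125b at the root, miR-15b then miR-181c/miR-412 on the high branch,
#' miR-193b on the low branch. Each split sits at the stated quantile of
#' that miRNA's marginal (default: median). Leaf responder probabilities
#' are 0.72 (HHH) and 0.04 (LL) as reported; the four remaining leaves
#' carry artifact defaults ordered consistently with the published PFS
#' tiers. `pfs_at_followup` is each leaf's progression-free fraction at the
#' 42.4-month follow-up, from which the exponential hazard is derived
#' (the no-relapse HHH group uses 0.99 so its hazard stays positive).
#'
#' @return Nested list of split nodes (`variable`, `q`, `high`, `low`) and
#'   leaves (`leaf`, `prob`, `pfs_at_followup`).
#' @export
planted_tree_default <- function() {
  leaf <- function(lab, prob, pfs) list(leaf = lab, prob = prob,
                                        pfs_at_followup = pfs)
  list(variable = "miR-125b", q = 0.5,
       high = list(variable = "miR-15b", q = 0.5,
                   high = list(variable = "miR-181c", q = 0.5,
                               high = leaf("HHH", 0.72, 0.99),
                               low  = leaf("HHL", 0.50, 0.72)),
                   low  = list(variable = "miR-412", q = 0.5,
                               high = leaf("HLH", 0.10, 0.71),
                               low  = leaf("HLL", 0.35, 0.90))),
       low  = list(variable = "miR-193b", q = 0.5,
                   high = leaf("LH", 0.20, 0.87),
                   low  = leaf("LL", 0.04, 0.52)))
}

truth_tree_leaves <- function(node) {
  if (!is.null(node$leaf)) return(list(node))
  c(truth_tree_leaves(node$high), truth_tree_leaves(node$low))
}

truth_tree_variables <- function(node) {
  if (!is.null(node$leaf)) return(character(0))
  c(node$variable, truth_tree_variables(node$high),
    truth_tree_variables(node$low))
}

#' Specify a synthetic cohort
#'
#' @param n_patients Cohort size (default 123).
#' @param tree Planted truth, as from [planted_tree_default()].
#' @param mirnas Panel of miRNA ids (must contain the tree variables).
#' @param meanlog,sdlog Log-normal location/scale per miRNA (named vectors
#'   recycled from scalars). Defaults centre the five tree miRNAs on their
#'   published ROC thresholds and the rest at 0.01 relative expression,
#'   with sdlog 1.5.
#' @param shifts Optional per-leaf log-scale location shifts for non-tree
#'   miRNAs: a named list `mirna -> named numeric by leaf label`.
#' @param censor_time Administrative censoring time in months (default
#'   42.4, the median follow-up).
#' @param missingness Named probabilities of a missing label for
#'   `cr`, `blood_mrd`, `bm_mrd` (defaults approximate the evaluable
#'   denominators 118/123, 108/123, 95/123).
#' @param p_bm_umrd_nonresp P(BM uMRD | non-responder); such patients are
#'   necessarily no-CR with blood uMRD.
#' @param p_cr_nonresp P(CR | non-responder with detectable BM MRD).
#' @param p_blood_umrd_nonresp P(blood uMRD | non-responder with detectable
#'   BM MRD); blood-detectable with BM-uMRD combinations are never produced.
#' @param seed Integer seed; one RNG stream consumed in documented order
#'   (expression, outcomes, survival, covariates, missingness).
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 123,
                        tree = planted_tree_default(),
                        mirnas = mirna_panel(),
                        meanlog = NULL, sdlog = 1.5,
                        shifts = NULL,
                        censor_time = 42.4,
                        missingness = c(cr = 0.04, blood_mrd = 0.12,
                                        bm_mrd = 0.23),
                        p_bm_umrd_nonresp = 0.16,
                        p_cr_nonresp = 0.40,
                        p_blood_umrd_nonresp = 0.43,
                        seed = 1L) {
  stopifnot(n_patients >= 1, censor_time > 0)
  tv <- truth_tree_variables(tree)
  if (!all(tv %in% mirnas))
    stop("tree variables missing from the miRNA panel: ",
         paste(setdiff(tv, mirnas), collapse = ", "))
  if (is.null(meanlog)) {
    meanlog <- setNames(rep(log(0.01), length(mirnas)), mirnas)
    thr <- published_roc_thresholds()
    meanlog[names(thr)[names(thr) %in% mirnas]] <-
      log(thr[names(thr) %in% mirnas])
  }
  if (length(meanlog) == 1) meanlog <- setNames(rep(meanlog, length(mirnas)), mirnas)
  if (length(sdlog) == 1) sdlog <- setNames(rep(sdlog, length(mirnas)), mirnas)
  stopifnot(all(mirnas %in% names(meanlog)), all(mirnas %in% names(sdlog)),
            all(sdlog > 0))
  leaves <- truth_tree_leaves(tree)
  probs <- vapply(leaves, `[[`, numeric(1), "prob")
  pfs <- vapply(leaves, `[[`, numeric(1), "pfs_at_followup")
  if (any(probs < 0 | probs > 1)) stop("leaf probabilities must be in [0,1]")
  if (any(pfs <= 0 | pfs >= 1)) stop("leaf pfs_at_followup must be in (0,1)")
  stopifnot(all(missingness >= 0 & missingness < 1),
            all(c("cr", "blood_mrd", "bm_mrd") %in% names(missingness)))
  if (!is.null(shifts)) {
    if (any(names(shifts) %in% tv))
      stop("per-leaf shifts may only target non-tree miRNAs")
    stopifnot(all(names(shifts) %in% mirnas))
  }
  structure(list(n_patients = as.integer(n_patients), tree = tree,
                 mirnas = mirnas, meanlog = meanlog[mirnas],
                 sdlog = sdlog[mirnas], shifts = shifts,
                 censor_time = censor_time, missingness = missingness,
                 p_bm_umrd_nonresp = p_bm_umrd_nonresp,
                 p_cr_nonresp = p_cr_nonresp,
                 p_blood_umrd_nonresp = p_blood_umrd_nonresp,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## turn the quantile-specified truth into a decision_tree with numeric
## thresholds (qlnorm of the stated quantile) and per-leaf hazards
instantiate_truth <- function(node, spec) {
  if (!is.null(node$leaf)) {
    hazard <- -log(node$pfs_at_followup) / spec$censor_time
    return(list(type = "leaf", label = node$leaf, probability = node$prob,
                hazard = hazard, n = NA_integer_, responders = NA_integer_))
  }
  thr <- qlnorm(node$q, spec$meanlog[[node$variable]],
                spec$sdlog[[node$variable]])
  list(type = "split", variable = node$variable, threshold = thr,
       quantile = node$q, n = NA_integer_, responders = NA_integer_,
       high = instantiate_truth(node$high, spec),
       low = instantiate_truth(node$low, spec))
}

descend_truth <- function(node, values) {
  while (node$type == "split") {
    node <- if (values[[node$variable]] > node$threshold) node$high else node$low
  }
  node
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Expression is drawn log-normal per miRNA; each patient's true leaf is
#' obtained by running their own expression through the planted tree, the
#' responder outcome is Bernoulli with the leaf probability, and
#' CR / blood-MRD / BM-MRD labels are derived so that responder is exactly
#' CR with BM uMRD and a blood-detectable/BM-undetectable combination never
#' occurs. Event times are exponential with the leaf hazard, censored
#' administratively; missingness is applied independently per outcome.
#'
#' @param spec A [cohort_spec()].
#' @return List with `expression` ([expression_matrix()]), `clinical`
#'   ([clinical_table()]), and `truth` (per-patient leaf and responder
#'   status, the instantiated truth tree, and the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  k <- length(spec$mirnas)
  pid <- sprintf("P%04d", seq_len(n))

  ## 1. expression, miRNA by miRNA in panel order
  X <- matrix(NA_real_, n, k, dimnames = list(pid, spec$mirnas))
  for (m in spec$mirnas)
    X[, m] <- rlnorm(n, spec$meanlog[[m]], spec$sdlog[[m]])

  truth_tree <- instantiate_truth(spec$tree, spec)
  leaf_of <- vapply(seq_len(n), function(i)
    descend_truth(truth_tree, X[i, ])$label, character(1))
  leaf_prob <- vapply(seq_len(n), function(i)
    descend_truth(truth_tree, X[i, ])$probability, numeric(1))
  leaf_hazard <- vapply(seq_len(n), function(i)
    descend_truth(truth_tree, X[i, ])$hazard, numeric(1))

  ## per-leaf shifts on non-tree miRNAs (deterministic given the leaf)
  if (!is.null(spec$shifts)) {
    for (m in names(spec$shifts)) {
      sh <- spec$shifts[[m]]
      idx <- leaf_of %in% names(sh)
      X[idx, m] <- X[idx, m] * exp(sh[leaf_of[idx]])
    }
  }

  ## 2. outcomes
  responder <- rbinom(n, 1, leaf_prob) == 1
  cr <- blood <- bm <- rep(NA_character_, n)
  cr[responder] <- "CR"; blood[responder] <- "uMRD"; bm[responder] <- "uMRD"
  nr <- which(!responder)
  bm_u <- rbinom(length(nr), 1, spec$p_bm_umrd_nonresp) == 1
  ## BM-uMRD non-responders must be no-CR (responder <=> CR & BM uMRD) and,
  ## by the no blood-detectable-with-BM-uMRD rule, blood uMRD
  cr[nr[bm_u]] <- "no-CR"; bm[nr[bm_u]] <- "uMRD"; blood[nr[bm_u]] <- "uMRD"
  det <- nr[!bm_u]
  bm[det] <- "detectable"
  cr[det] <- ifelse(rbinom(length(det), 1, spec$p_cr_nonresp) == 1, "CR", "no-CR")
  blood[det] <- ifelse(rbinom(length(det), 1, spec$p_blood_umrd_nonresp) == 1,
                       "uMRD", "detectable")

  ## 3. survival
  t_event <- rexp(n, leaf_hazard)
  pfs_time <- pmin(t_event, spec$censor_time)
  pfs_event <- as.integer(t_event <= spec$censor_time)

  ## 4. baseline covariates (independent of outcome by design; marginals
  ##    approximate the reference cohort's Table-1-style frequencies)
  age <- round(pmin(pmax(rnorm(n, 58.5, 6), 18), 65), 1)
  sex <- ifelse(runif(n) < 0.268, "F", "M")
  binet <- ifelse(runif(n) < 0.74, "AB", "C")
  ecog <- ifelse(runif(n) < 0.70, 0, 1)
  ighv <- ifelse(runif(n) < 0.63, "unmutated", "mutated")
  del13q <- ifelse(runif(n) < 0.56, "yes", "no")
  del11q <- ifelse(runif(n) < 0.20, "yes", "no")
  tri12 <- ifelse(runif(n) < 0.11, "yes", "no")
  lymphocytes <- round(rlnorm(n, log(71), 0.9), 2)
  b2m <- round(rlnorm(n, log(3.05), 0.35), 2)
  arm <- ifelse(runif(n) < 0.5, "FCR", "Dense-FCR")
  cycles <- sample(c(6L, 5L, 4L, 3L), n, replace = TRUE,
                   prob = c(0.70, 0.15, 0.10, 0.05))

  ## 5. outcome-specific missingness
  cr[runif(n) < spec$missingness[["cr"]]] <- NA
  blood[runif(n) < spec$missingness[["blood_mrd"]]] <- NA
  bm[runif(n) < spec$missingness[["bm_mrd"]]] <- NA

  clinical <- clinical_table(data.frame(
    patient_id = pid, cr = cr, blood_mrd = blood, bm_mrd = bm,
    age = age, sex = sex, binet = binet, ecog = ecog, ighv = ighv,
    del13q = del13q, del11q = del11q, tri12 = tri12,
    lymphocytes = lymphocytes, b2m = b2m, arm = arm, cycles = cycles,
    pfs_time = pfs_time, pfs_event = pfs_event,
    stringsAsFactors = FALSE))

  truth <- structure(list(leaf = setNames(leaf_of, pid),
                          responder = setNames(responder, pid),
                          tree = truth_tree, spec = spec),
                     class = "cohort_truth")
  list(expression = expression_matrix(X), clinical = clinical, truth = truth)
}

#' Planted screening effects from the published 25-miRNA signature
#'
#' Log2 fold changes (responder over non-responder) of the 25 miRNAs that
#' passed the discovery screen, used as the default differential set of
#' [screen_spec()].
#' @return Named numeric vector of log2 fold changes.
#' @export
published_screen_effects <- function() {
  fc <- c("hsa-miR-412" = 0.3, "hsa-miR-155" = 0.3, "hsa-miR-519a" = 2.6,
          "hsa-miR-744" = 2.6, "hsa-miR-339-5p" = 2.8, "hsa-miR-652" = 2.8,
          "hsa-miR-212" = 2.9, "hsa-miR-92a" = 3.0, "hsa-miR-125b" = 3.3,
          "hsa-miR-15b" = 3.4, "hsa-miR-324-3p" = 3.4,
          "hsa-miR-193a-5p" = 3.4, "hsa-miR-423-5p" = 3.5,
          "hsa-miR-139-5p" = 3.5, "hsa-miR-181c" = 3.9, "hsa-miR-193b" = 3.9,
          "hsa-miR-211" = 4.1, "hsa-miR-328" = 4.1, "mmu-miR-134" = 4.2,
          "hsa-miR-494" = 4.3, "hsa-miR-532-3p" = 4.5, "hsa-miR-181a" = 4.8,
          "hsa-miR-642" = 4.9, "hsa-miR-99b" = 5.3, "hsa-miR-202" = 6.5)
  log2(fc)
}

#' Specify a synthetic TLDA screening matrix
#'
#' @param n_per_group Samples per arm (default 8, as in the discovery
#'   screen of responders vs non-responders).
#' @param n_assays Number of assays on the card (default 384).
#' @param de Named numeric vector of planted log2 fold changes (responder
#'   over non-responder); default the published 25-miRNA signature.
#' @param ct_location Optional per-assay baseline Ct means; default drawn
#'   N(26, 2) from the seed stream at generation time.
#' @param ct_sd Within-group Ct standard deviation in cycles (default 0.5).
#' @param undetected_fraction Extra probability that any well reads
#'   undetermined (default 0.02); wells beyond `max_cycles` are always
#'   undetermined.
#' @param max_cycles Cycle ceiling (default 40).
#' @param seed Integer seed.
#' @return A validated `screen_spec` list.
#' @export
screen_spec <- function(n_per_group = 8, n_assays = 384,
                        de = published_screen_effects(),
                        ct_location = NULL, ct_sd = 0.5,
                        undetected_fraction = 0.02, max_cycles = 40,
                        seed = 1L) {
  stopifnot(n_per_group >= 2, n_assays >= 1, ct_sd >= 0,
            undetected_fraction >= 0, undetected_fraction < 1)
  if (length(de) > 0) {
    stopifnot(!is.null(names(de)), all(is.finite(de)))
    if (length(de) > n_assays) stop("more planted effects than assays")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_assays = as.integer(n_assays), de = de,
                 ct_location = ct_location, ct_sd = ct_sd,
                 undetected_fraction = undetected_fraction,
                 max_cycles = max_cycles, seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate a synthetic Ct screening matrix
#'
#' Ct values are normal per assay and group; assays in the planted set are
#' shifted down by their log2 fold change (in cycles) in the responder
#' group, so that higher expression means lower Ct. Wells beyond
#' `max_cycles`, or hit by the extra undetected fraction, are stored at
#' `max_cycles` and flagged.
#'
#' @param spec A [screen_spec()].
#' @return List with `ct` ([ct_matrix()]) and `truth` (planted log2 fold
#'   changes and baseline locations).
#' @export
generate_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  set.seed(spec$seed)
  ng <- spec$n_per_group
  assays <- names(spec$de)
  if (spec$n_assays > length(assays))
    assays <- c(assays, sprintf("assay-%03d", seq_len(spec$n_assays - length(assays))))
  loc <- spec$ct_location %||% rnorm(spec$n_assays, 26, 2)
  loc <- setNames(loc, assays)
  samples <- c(sprintf("R%02d", seq_len(ng)), sprintf("N%02d", seq_len(ng)))
  groups <- rep(c("responder", "non-responder"), each = ng)
  ct <- matrix(NA_real_, 2 * ng, spec$n_assays,
               dimnames = list(samples, assays))
  for (a in assays) {
    shift <- if (a %in% names(spec$de)) spec$de[[a]] else 0
    ct[, a] <- c(rnorm(ng, loc[[a]] - shift, spec$ct_sd),
                 rnorm(ng, loc[[a]], spec$ct_sd))
  }
  und <- ct >= spec$max_cycles
  if (spec$undetected_fraction > 0)
    und <- und | matrix(runif(length(ct)) < spec$undetected_fraction,
                        nrow(ct), ncol(ct))
  ct[und] <- spec$max_cycles
  ct <- pmax(ct, 1e-6)  # guard against non-physical non-positive cycles
  list(ct = ct_matrix(ct, groups, und, spec$max_cycles),
       truth = list(de = spec$de, location = loc))
}
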