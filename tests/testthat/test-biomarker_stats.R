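test_that("roc_curve and youden_cutpoint match the exhaustive-cutpoint oracle", {
  set.seed(2024)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    v <- if (runif(1) < 0.3) sample(1:4, n, replace = TRUE) else rnorm(n)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)  # both classes guaranteed
    r <- roc_curve(v, y, "high-positive")
    o <- roc_oracle(v, y)
    expect_equal(r$auc, o$auc, tolerance = 1e-12)
    expect_equal(r$youden_j, o$j, tolerance = 1e-12)
    expect_equal(r$youden_threshold, o$threshold)
    expect_equal(r$se_at_youden, o$se, tolerance = 1e-12)
    expect_equal(r$sp_at_youden, o$sp, tolerance = 1e-12)
    ## J identity at every threshold
    expect_equal(r$j, r$sensitivity + r$specificity - 1, tolerance = 1e-12)
    ## Se non-increasing as the threshold rises
    expect_true(all(diff(r$sensitivity) <= 1e-12))
  }
})

test_that("roc properties: monotone invariance, label swap, orientation", {
  set.seed(5)
  v <- rlnorm(60)
  ## informative marker: higher expression more likely positive
  y <- runif(60) < plogis(2 * scale(log(v)))
  y[1:2] <- c(TRUE, FALSE)
  r <- roc_curve(v, y)
  ## strictly increasing transform preserves AUC and J
  r2 <- roc_curve(v^3, y)
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  expect_equal(r2$youden_j, r$youden_j, tolerance = 1e-12)
  ## swapping labels maps AUC -> 1 - AUC under fixed orientation
  r3 <- roc_curve(v, !y, "high-positive")
  expect_equal(r3$auc, 1 - r$auc, tolerance = 1e-12)
  ## auto orientation flips an inverted marker
  r4 <- roc_curve(-v, y, "auto")
  expect_equal(r4$orientation, "low-positive")
  expect_equal(r4$auc, r$auc, tolerance = 1e-12)
  expect_equal(r4$youden_j, r$youden_j, tolerance = 1e-12)
  ## perfect separation
  r5 <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r5$youden_j, 1)
  expect_true(r5$youden_threshold > 2 && r5$youden_threshold < 10)
  expect_equal(r5$auc, 1)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("roc agrees with pROC on AUC and the Youden coordinate", {
  skip_if_not_installed("pROC")
  set.seed(77)
  v <- rnorm(80); y <- runif(80) < 0.5; y[1:2] <- c(TRUE, FALSE)
  r <- roc_curve(v, y, "high-positive")
  pr <- pROC::roc(response = y, predictor = v, direction = "<",
                  quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  best <- pROC::coords(pr, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"))
  expect_equal(r$se_at_youden + r$sp_at_youden,
               max(best$sensitivity + best$specificity), tolerance = 1e-10)
})

test_that("compare_groups gates Student t by per-group Shapiro-Wilk", {
  picks <- vapply(1:60, function(s) {
    set.seed(3000 + s)
    compare_groups(c(rnorm(40), rnorm(40, 1)),
                   rep(c(TRUE, FALSE), each = 40))$test_used
  }, character(1))
  expect_gt(mean(picks == "t"), 0.8)
  picks2 <- vapply(1:60, function(s) {
    set.seed(4000 + s)
    compare_groups(c(rexp(40), rexp(40) * 2),
                   rep(c(TRUE, FALSE), each = 40))$test_used
  }, character(1))
  expect_gt(mean(picks2 == "mann-whitney"), 0.5)
  ## identical groups: degenerate, p = 1
  cg <- compare_groups(rep(2, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(cg$p_value, 1)
  expect_true(cg$degenerate)
  ## tiny groups skip the gate entirely
  expect_equal(compare_groups(c(1, 2, 5, 6), c(TRUE, TRUE, FALSE, FALSE))$test_used,
               "mann-whitney")
  expect_error(compare_groups(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("categorical_association picks Fisher below expected count 5", {
  ## [[10,0],[0,10]]: Fisher two-sided p = 2 / C(20,10)
  f <- rep(c("a", "b"), each = 10)
  y <- rep(c(TRUE, FALSE), each = 10)
  res <- categorical_association(f, y)
  expect_equal(res$test_used, "fisher")  # expected counts exactly 5
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  ## [[5,5],[5,5]]: perfect independence
  res2 <- categorical_association(rep(c("a", "b"), each = 10),
                                  rep(c(TRUE, FALSE), 10))
  expect_equal(res2$p_value, 1)
  ## large balanced table uses chi-square
  set.seed(1)
  res3 <- categorical_association(sample(c("a", "b"), 400, TRUE),
                                  runif(400) < 0.5)
  expect_equal(res3$test_used, "chi2")
  ## single-level factor degenerates to p = 1
  expect_true(categorical_association(rep("a", 10),
                                      rep(c(TRUE, FALSE), 5))$degenerate)
})

test_that("spearman_assoc matches an exhaustive permutation oracle at n = 6", {
  set.seed(11)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    obs <- spearman_assoc(x, y)
    rho_all <- apply(perms, 1, function(p) cor(rank(x), rank(y[p])))
    p_perm <- mean(abs(rho_all) >= abs(obs$rho) - 1e-12)
    expect_equal(obs$p_value, p_perm, tolerance = 1e-8)
  }
  expect_equal(spearman_assoc(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10)^3)$rho, -1)
  expect_true(spearman_assoc(1:5, rep(1, 5))$degenerate)
})

test_that("backward_logistic keeps a planted predictor and drops noise", {
  set.seed(210)
  hits <- noise_kept <- 0
  for (s in 1:10) {
    n <- 500
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, c("signal", paste0("noise", 1:5))))
    p <- plogis(-0.5 + 1.2 * x[, "signal"])
    y <- runif(n) < p
    sel <- backward_logistic(y, as.data.frame(x))
    hits <- hits + ("signal" %in% sel$retained)
    noise_kept <- noise_kept + sum(grepl("noise", sel$retained))
  }
  expect_gte(hits, 9)
  expect_lte(noise_kept / (10 * 5), 0.2)
})

test_that("backward_logistic boundary levels return full and empty models", {
  set.seed(3)
  covs <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- runif(60) < 0.5
  expect_setequal(backward_logistic(y, covs, alpha_stay = 1)$retained,
                  c("a", "b", "c"))
  expect_length(backward_logistic(y, covs, alpha_stay = 0)$retained, 0)
})

test_that("backward_logistic odds ratios are consistent at large n", {
  set.seed(99)
  n <- 10000
  x <- rnorm(n)
  y <- runif(n) < plogis(x)  # true coefficient 1, OR = e
  sel <- backward_logistic(y, data.frame(x = x))
  expect_equal(sel$coefficients$or, exp(1), tolerance = 0.1)
  expect_false(sel$coefficients$separation)
  ## perfect separation flagged, not reported as a number
  xs <- x[1:50]
  sep <- suppressWarnings(backward_logistic(xs > 0, data.frame(x = xs),
                                            alpha_stay = 1))
  expect_true(all(sep$coefficients$separation) ||
                nrow(sep$coefficients) == 0)
})

test_that("scan_outcomes books denominators per outcome", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 17))
  grid <- scan_outcomes(co$expression, co$clinical)
  expect_equal(nrow(grid), 11 * 4)
  ## a patient with missing bm_mrd is excluded from BM-uMRD but can count
  ## in the CR column: BM denominators must be <= CR-available patients
  cl <- co$clinical
  n_bm <- sum(!is.na(cl$bm_mrd))
  n_cr <- sum(!is.na(cl$cr))
  g1 <- grid[grid$outcome == "BM-uMRD", ]
  expect_true(all(g1$n_pos + g1$n_neg == n_bm))
  g2 <- grid[grid$outcome == "CR", ]
  expect_true(all(g2$n_pos + g2$n_neg == n_cr))
})

test_that("a planted responder shift is detected and nulls are calibrated", {
  ## shift the high-response leaves up by 2 sdlog so the responder vs
  ## other contrast is about one marginal SD
  shifts <- list("miR-652" = c(HHH = 3, HHL = 3))
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 23,
                                    shifts = shifts))
  grid <- scan_outcomes(co$expression, co$clinical)
  p_shift <- grid$p_value[grid$mirna == "miR-652" &
                            grid$outcome == "CR+BM-uMRD"]
  expect_lt(p_shift, 0.01)
  ## null miRNA significant in roughly alpha of seeds
  pn <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_spec(n_patients = 120, seed = 6000 + s))
    g <- scan_outcomes(co$expression, co$clinical, mirnas = "miR-155")
    g$p_value[g$outcome == "CR"]
  }, numeric(1))
  expect_lt(mean(pn < 0.05, na.rm = TRUE), 0.2)
})
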