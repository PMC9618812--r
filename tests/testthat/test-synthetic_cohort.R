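test_that("identical spec and seed reproduce the cohort exactly", {
  a <- generate_cohort(cohort_spec(n_patients = 80, seed = 42))
  b <- generate_cohort(cohort_spec(n_patients = 80, seed = 42))
  expect_identical(unclass(a$expression), unclass(b$expression))
  expect_identical(as.data.frame(a$clinical), as.data.frame(b$clinical))
  expect_identical(a$truth$leaf, b$truth$leaf)
  c <- generate_cohort(cohort_spec(n_patients = 80, seed = 43))
  expect_false(identical(unclass(a$expression), unclass(c$expression)))
})

test_that("responder label is exactly CR with BM uMRD before missingness", {
  spec <- cohort_spec(n_patients = 600, seed = 9,
                      missingness = c(cr = 0, blood_mrd = 0, bm_mrd = 0))
  co <- generate_cohort(spec)
  responder <- co$truth$responder
  derived <- co$clinical$cr == "CR" & co$clinical$bm_mrd == "uMRD"
  expect_identical(unname(responder), derived)
  ## the forbidden combination never occurs
  expect_false(any(co$clinical$blood_mrd == "detectable" &
                     co$clinical$bm_mrd == "uMRD", na.rm = TRUE))
  ## zero missingness: all denominators equal n
  s <- classify_response(co$clinical)$summary
  expect_true(all(s$denominator == 600))
})

test_that("true leaf is the planted-tree routing of each patient's expression", {
  co <- generate_cohort(cohort_spec(n_patients = 150, seed = 4))
  fix <- co$truth$tree
  tree <- structure(list(root = fix, alpha = NA, min_leaf = NA,
                         max_depth = NA, n = NA, responders = NA),
                    class = "decision_tree")
  relabelled <- vapply(rownames(co$expression), function(p)
    classify(tree, co$expression[p, ])$label, character(1))
  expect_identical(unname(relabelled), unname(co$truth$leaf))
})

test_that("empirical leaf responder fractions converge to planted probabilities", {
  co <- generate_cohort(cohort_spec(n_patients = 5000, seed = 101))
  leaves <- mirtree:::truth_tree_leaves(planted_tree_default())
  probs <- vapply(leaves, `[[`, numeric(1), "prob")
  names(probs) <- vapply(leaves, `[[`, character(1), "leaf")
  for (lab in names(probs)) {
    idx <- co$truth$leaf == lab
    phat <- mean(co$truth$responder[idx])
    se <- sqrt(max(probs[lab] * (1 - probs[lab]), 1e-6) / sum(idx))
    expect_lt(abs(phat - probs[lab]), 3 * se + 1e-12)
  }
})

test_that("degenerate separation: two-level markers rebuild the exact truth", {
  ## noiseless limit: each split miRNA takes one value per side of its
  ## planted threshold, so every Youden cutpoint is exact
  set.seed(60)
  n <- 200
  hi125 <- sample(c(TRUE, FALSE), n, replace = TRUE)
  hi15 <- sample(c(TRUE, FALSE), n, replace = TRUE)
  X <- cbind("miR-125b" = ifelse(hi125, 0.002, 0.0001),
             "miR-15b" = ifelse(hi15, 0.5, 0.05),
             "miR-155" = rlnorm(n))
  rownames(X) <- sprintf("P%03d", 1:n)
  y <- hi125 & hi15
  tr <- build_tree(expression_matrix(X), y)
  expect_equal(tr$root$variable, "miR-125b")
  expect_true(tr$root$threshold > 0.0001 && tr$root$threshold < 0.002)
  expect_equal(tr$root$high$variable, "miR-15b")
  ag <- assign_groups(tr, expression_matrix(X))
  expect_true(all(ag$probability %in% c(0, 1)))
  expect_identical(unname(ag$probability == 1), unname(y))
})

test_that("0/1 leaf probabilities give near-perfect rebuilt classification", {
  ## with continuous expression the empirical root cutpoint can misroute
  ## a handful of boundary patients (threshold estimation, not labels)
  tree <- planted_tree_default()
  set01 <- function(node) {
    if (!is.null(node$leaf)) {
      node$prob <- if (node$leaf %in% c("HHH", "HHL")) 1 else 0
      return(node)
    }
    node$high <- set01(node$high); node$low <- set01(node$low)
    node
  }
  spec <- cohort_spec(n_patients = 800, tree = set01(tree), seed = 12,
                      missingness = c(cr = 0, blood_mrd = 0, bm_mrd = 0))
  co <- generate_cohort(spec)
  built <- build_tree(co$expression, co$truth$responder)
  ag <- assign_groups(built, co$expression)
  agree <- (ag$probability > 0.5) == co$truth$responder
  expect_gte(mean(agree), 0.99)
})

test_that("screen generator plants recoverable fold changes", {
  ## noiseless limit: a single planted log2FC of 2 recovers FC 4 exactly
  sp <- screen_spec(n_per_group = 4, n_assays = 3,
                    de = c("assay-de" = 2), ct_sd = 0,
                    undetected_fraction = 0, seed = 1)
  sc <- generate_screen(sp)
  res <- differential_screen(sc$ct, responder = "responder")
  ## global-mean normalisation spreads the 2-cycle shift over 3 assays:
  ## recovered log2FC is 2 * (1 - 1/3) on the shifted assay
  expect_equal(res$fold_change[res$assay == "assay-de"], 2^(2 * 2 / 3),
               tolerance = 1e-12)
  ## reference-assay normalisation against an unshifted control is exact
  res_ref <- differential_screen(sc$ct, responder = "responder",
                                 method = "reference-assay",
                                 reference = "assay-001")
  expect_equal(res_ref$fold_change[res_ref$assay == "assay-de"], 4,
               tolerance = 1e-12)
})

test_that("planted fold change is recovered within sampling error at n=8", {
  ## Monte-Carlo bias check on the estimated log2 fold change
  errs <- vapply(1:40, function(s) {
    sc <- generate_screen(screen_spec(n_assays = 48, de = c(planted = 2),
                                      ct_sd = 0.5, undetected_fraction = 0,
                                      seed = 500 + s))
    res <- differential_screen(sc$ct, responder = "responder")
    res$log2_fc[res$assay == "planted"] - 2
  }, numeric(1))
  ## se of a single estimate ~ 0.5*sqrt(2/8) = 0.25; mean of 40 ~ 0.04
  expect_lt(abs(mean(errs)), 4 * 0.25 / sqrt(40) + 2 / 48)
})
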