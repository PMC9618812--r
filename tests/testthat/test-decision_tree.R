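test_that("pure cohorts and alpha = 0 collapse the tree as required", {
  co <- generate_cohort(cohort_spec(n_patients = 60, seed = 2))
  ## all responders: a single leaf with probability 1
  t1 <- build_tree(co$expression, rep(TRUE, 60))
  expect_equal(t1$root$type, "leaf")
  expect_equal(t1$root$probability, 1)
  ## alpha = 0: root split only, no child passes the stopping rule
  t2 <- build_tree(co$expression, co$truth$responder, alpha = 0)
  expect_equal(t2$root$type, "split")
  expect_equal(t2$root$variable, "miR-125b")
  expect_equal(t2$root$high$type, "leaf")
  expect_equal(t2$root$low$type, "leaf")
})

test_that("counts are conserved at every split and across the tree", {
  for (s in 1:5) {
    co <- generate_cohort(cohort_spec(n_patients = 300, seed = 700 + s))
    tr <- build_tree(co$expression, co$truth$responder)
    expect_true(validate_tree(tr))
    leaves <- tree_leaves(tr)
    expect_equal(sum(vapply(leaves, `[[`, numeric(1), "n")), tr$n)
    expect_equal(sum(vapply(leaves, `[[`, numeric(1), "responders")),
                 tr$responders)
  }
})

test_that("every leaf truly fails the continuation rule", {
  co <- generate_cohort(cohort_spec(n_patients = 400, seed = 77))
  y <- co$truth$responder
  tr <- build_tree(co$expression, y)
  X <- unclass(co$expression)
  justified <- character(0)
  check_node <- function(node, idx, used, depth) {
    if (node$type == "split") {
      hi <- idx[X[idx, node$variable] > node$threshold]
      check_node(node$high, hi, c(used, node$variable), depth + 1)
      check_node(node$low, setdiff(idx, hi), c(used, node$variable),
                 depth + 1)
      return(invisible(NULL))
    }
    ## a leaf must be pure, too deep, too small, or its most significant
    ## candidate either fails alpha or would starve a child below min_leaf
    reason <- if (depth > tr$max_depth) "depth"
      else if (length(idx) < 2 * tr$min_leaf) "size"
      else if (sum(y[idx]) %in% c(0, length(idx))) "pure"
      else {
        cand <- setdiff(colnames(X), used)
        ps <- vapply(cand, function(m) {
          v <- X[idx, m]
          if (sd(v) == 0) return(Inf)
          compare_groups(v, y[idx])$p_value
        }, numeric(1))
        best <- cand[which.min(ps)]
        if (!is.finite(min(ps)) || min(ps) >= tr$alpha) "alpha"
        else {
          thr <- roc_curve(X[idx, best], y[idx], "auto")$youden_threshold
          n_hi <- sum(X[idx, best] > thr)
          if (min(n_hi, length(idx) - n_hi) < tr$min_leaf) "min_leaf"
          else "UNJUSTIFIED"
        }
      }
    justified <<- c(justified, reason)
  }
  check_node(tr$root, seq_len(nrow(X)), character(0), 1)
  expect_gt(length(justified), 0)
  expect_false(any(justified == "UNJUSTIFIED"))
  expect_true("alpha" %in% justified)  # the significance stop does fire
})

test_that("monotone transform of one miRNA moves its threshold, not the topology", {
  co <- generate_cohort(cohort_spec(n_patients = 500, seed = 31))
  y <- co$truth$responder
  t1 <- build_tree(co$expression, y)
  X <- unclass(co$expression)
  X[, "miR-15b"] <- X[, "miR-15b"]^3   # strictly increasing, stays skewed
  t2 <- build_tree(expression_matrix(X), y)
  shape <- function(node) {
    if (node$type == "leaf")
      return(list(type = "leaf", label = node$label, n = node$n,
                  responders = node$responders))
    list(type = "split", variable = node$variable,
         high = shape(node$high), low = shape(node$low))
  }
  expect_identical(shape(t1$root), shape(t2$root))
})

test_that("same inputs always build the same tree", {
  co <- generate_cohort(cohort_spec(n_patients = 250, seed = 13))
  t1 <- build_tree(co$expression, co$truth$responder)
  t2 <- build_tree(co$expression, co$truth$responder)
  expect_identical(t1, t2)
})

test_that("classification routes strictly-greater high and refuses missing", {
  tr <- published_tree()
  ## exactly at the root threshold routes low
  at_thr <- c("miR-125b" = 0.0005, "miR-193b" = 1)
  expect_equal(classify(tr, at_thr)$label, "LH")
  ## missing path variable -> unclassifiable, no imputation
  res <- classify(tr, c("miR-125b" = 1))
  expect_false(res$classifiable)
  expect_true(is.na(res$label))
})

test_that("published fixture carries the reported thresholds and probabilities", {
  tr <- published_tree()
  expect_true(validate_tree(tr))
  thr <- c("miR-125b" = tr$root$threshold,
           "miR-15b" = tr$root$high$threshold,
           "miR-181c" = tr$root$high$high$threshold,
           "miR-412" = tr$root$high$low$threshold,
           "miR-193b" = tr$root$low$threshold)
  expect_equal(thr, c("miR-125b" = 0.0005, "miR-15b" = 0.1710,
                      "miR-181c" = 0.0019, "miR-412" = 0.0003,
                      "miR-193b" = 0.0113))
  hhh <- classify(tr, c("miR-125b" = 0.001, "miR-15b" = 0.2,
                        "miR-181c" = 0.003))
  expect_equal(hhh$label, "HHH")
  expect_equal(hhh$probability, 0.72)
  ll <- classify(tr, c("miR-125b" = 0.0001, "miR-193b" = 0.001))
  expect_equal(ll$label, "LL")
  expect_equal(ll$probability, 0.04)
  ## unpublished leaves are explicitly marked placeholders
  src <- vapply(tree_leaves(tr), function(l) l$prob_source, character(1))
  expect_setequal(names(table(src)), c("published", "placeholder"))
  expect_equal(sum(src == "published"), 2)
})

test_that("trees round-trip through JSON and export DOT", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 5))
  tr <- build_tree(co$expression, co$truth$responder)
  f <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tr, f)
  ## equal up to JSON floating-point serialisation
  expect_equal(tree_from_json(f), tr, tolerance = 1e-12)
  expect_identical(tree_from_json(as.character(tree_to_json(published_tree()))),
                   published_tree())
  dot <- tree_to_dot(tr)
  expect_match(dot, "digraph")
  expect_match(dot, tr$root$variable, fixed = TRUE)
})

test_that("group assignment partitions classifiable patients", {
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 19))
  tr <- build_tree(co$expression, co$truth$responder)
  ag <- assign_groups(tr, co$expression)
  expect_equal(nrow(ag), 300)
  expect_true(all(ag$classifiable))  # complete expression: all classifiable
  counts <- attr(ag, "counts")
  expect_equal(sum(counts), 300)
  ## group-wise responder fraction equals the leaf probability on the
  ## training cohort (identity of build output)
  for (lab in names(counts)) {
    idx <- ag$label == lab
    expect_equal(unique(ag$probability[idx]),
                 mean(co$truth$responder[idx]))
  }
})

test_that("three-tier merge maps the published groups and rejects strangers", {
  expect_equal(merge_labels(c("HHH", "HHL", "HLH", "HLL", "LH", "LL"),
                            "paper-three-tier"),
               c("high", "intermediate", "low", "intermediate",
                 "intermediate", "low"))
  expect_error(merge_labels("HX", "paper-three-tier"), "HX")
  expect_equal(merge_labels(c("a", "b")), c("a", "b"))
})
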