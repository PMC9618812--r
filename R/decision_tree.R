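# Recursive decision tree over miRNA expression: fixed (or auto) root
# variable, node-local Youden dichotomisation, most-significant-variable
# splitting, significance stopping, H/L path labels, and the published-tree
# fixture.

new_leaf <- function(n, responders, label) {
  list(type = "leaf", n = n, responders = responders,
       probability = if (is.na(n) || n == 0) NA_real_ else responders / n,
       label = label)
}

new_split <- function(variable, threshold, n, responders, p, high, low) {
  list(type = "split", variable = variable, threshold = threshold,
       n = n, responders = responders, split_p = p, high = high, low = low)
}

#' Build a decision tree by recursive Youden dichotomisation
#'
#' The root is split on `root_variable` at its Youden-optimal cutpoint
#' against the responder outcome on the full cohort (the root choice is
#' rationale-driven, not algorithmic; `"auto"` picks the most significant
#' candidate). At every subsequent node, each unused candidate miRNA is
#' compared between responders and others ([compare_groups()]); if the
#' smallest p-value is below `alpha` and both prospective children hold at
#' least `min_leaf` patients, the node splits on that variable at its
#' node-local Youden threshold ("high" = strictly greater). Otherwise the
#' node becomes a leaf carrying its empirical responder probability.
#' Cutpoints use automatic ROC orientation — a marker can predict response
#' when high (most of the panel) or when low (miR-412-like behaviour) —
#' but the split always routes by expression level.
#' Leaf labels accumulate one `H`/`L` letter per level. Ties on p are
#' broken by larger AUC, then lexicographic id; a variable is used at most
#' once along any path.
#'
#' @param expr An [expression_matrix()].
#' @param outcome Responder status per patient of `expr` (logical or 0/1,
#'   no missing values).
#' @param candidates Candidate split variables (default all miRNAs).
#' @param root_variable Root split variable (default `"miR-125b"`), or
#'   `"auto"`.
#' @param alpha Significance level for continuing to split (default 0.05).
#' @param min_leaf Minimum patients per child (default 5).
#' @param max_depth Maximum number of splits along a path (default 4).
#' @return Object of class `decision_tree`.
#' @export
build_tree <- function(expr, outcome, candidates = NULL,
                       root_variable = "miR-125b", alpha = 0.05,
                       min_leaf = 5, max_depth = 4) {
  stopifnot(inherits(expr, "expr_matrix"))
  y <- as_binary(outcome)
  if (anyNA(y) || length(y) != nrow(expr))
    stop("outcome must be one non-missing responder indicator per patient")
  candidates <- candidates %||% colnames(expr)
  stopifnot(all(candidates %in% colnames(expr)))
  X <- unclass(expr)

  node_best <- function(idx, used) {
    cand <- setdiff(candidates, used)
    if (length(cand) == 0) return(NULL)
    stats <- lapply(cand, function(m) {
      v <- X[idx, m]
      if (anyNA(v) || sd(v) == 0) return(list(p = Inf, auc = 0.5))
      cg <- compare_groups(v, y[idx])
      ## orientation auto: a marker may predict response when high (most
      ## miRNAs here) or when low; the cutpoint is a threshold on
      ## expression either way
      r <- roc_curve(v, y[idx], "auto")
      list(p = cg$p_value, auc = r$auc, threshold = r$youden_threshold)
    })
    p <- vapply(stats, `[[`, numeric(1), "p")
    auc <- vapply(stats, `[[`, numeric(1), "auc")
    ord <- order(p, -auc, cand)
    b <- ord[1]
    if (!is.finite(p[b])) return(NULL)
    list(variable = cand[b], p = p[b], threshold = stats[[b]]$threshold)
  }

  grow <- function(idx, used, depth, label) {
    n <- length(idx); resp <- sum(y[idx])
    leaf <- function() new_leaf(n, resp, label)
    if (depth > max_depth || resp == 0 || resp == n || n < 2 * min_leaf)
      return(leaf())
    best <- node_best(idx, used)
    if (is.null(best) || best$p >= alpha) return(leaf())
    hi <- idx[X[idx, best$variable] > best$threshold]
    lo <- setdiff(idx, hi)
    if (length(hi) < min_leaf || length(lo) < min_leaf) return(leaf())
    new_split(best$variable, best$threshold, n, resp, best$p,
              grow(hi, c(used, best$variable), depth + 1, paste0(label, "H")),
              grow(lo, c(used, best$variable), depth + 1, paste0(label, "L")))
  }

  n <- nrow(X); idx <- seq_len(n); resp <- sum(y)
  if (resp == 0 || resp == n) {
    root <- new_leaf(n, resp, "")
  } else {
    if (identical(root_variable, "auto")) {
      best <- node_best(idx, character(0))
      if (is.null(best)) stop("no usable root candidate")
      root_variable <- best$variable
      thr <- best$threshold
      root_p <- best$p
    } else {
      if (!root_variable %in% candidates)
        stop("root_variable must be among the candidates")
      v <- X[, root_variable]
      if (sd(v) == 0) stop("root variable '", root_variable, "' is constant")
      thr <- roc_curve(v, y, "auto")$youden_threshold
      root_p <- compare_groups(v, y)$p_value
    }
    hi <- idx[X[, root_variable] > thr]
    lo <- setdiff(idx, hi)
    if (length(hi) < min_leaf || length(lo) < min_leaf) {
      warning("root split would violate min_leaf; returning a single leaf")
      root <- new_leaf(n, resp, "")
    } else {
      root <- new_split(root_variable, thr, n, resp, root_p,
                        grow(hi, root_variable, 2, "H"),
                        grow(lo, root_variable, 2, "L"))
    }
  }
  structure(list(root = root, alpha = alpha,
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth), n = as.integer(n),
                 responders = as.integer(resp)),
            class = "decision_tree")
}

#' @export
print.decision_tree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s[%s] n=%s responders=%s p(responder)=%s\n", pad,
                  if (nzchar(node$label %||% "")) node$label else "leaf",
                  node$n, node$responders,
                  ifelse(is.na(node$probability), "NA",
                         sprintf("%.2f", node$probability))))
    } else {
      cat(sprintf("%s%s > %.4g ? (n=%s)\n", pad, node$variable,
                  node$threshold, node$n))
      rec(node$high, indent + 1)
      rec(node$low, indent + 1)
    }
  }
  cat("decision tree:\n")
  rec(x$root, 1)
  invisible(x)
}

#' Classify one patient through a decision tree
#'
#' Descends from the root comparing each path variable's value with the
#' node threshold: strictly greater routes high, otherwise low. A missing
#' value for a path variable makes the patient unclassifiable (no
#' imputation).
#'
#' @param tree A `decision_tree`.
#' @param patient_expr Named numeric vector (or 1-row matrix) of
#'   miRNA relative expression.
#' @return List: `label`, `probability`, `classifiable`, and `path`
#'   (data.frame of variable, threshold, side).
#' @export
classify <- function(tree, patient_expr) {
  stopifnot(inherits(tree, "decision_tree"))
  if (is.matrix(patient_expr)) patient_expr <- patient_expr[1, ]
  node <- tree$root
  path <- list()
  while (node$type == "split") {
    v <- if (node$variable %in% names(patient_expr))
      patient_expr[[node$variable]] else NA_real_
    if (is.na(v))
      return(list(label = NA_character_, probability = NA_real_,
                  classifiable = FALSE,
                  path = do.call(rbind, path) %||% data.frame()))
    side <- if (v > node$threshold) "H" else "L"
    path[[length(path) + 1]] <- data.frame(
      variable = node$variable, threshold = node$threshold, side = side,
      stringsAsFactors = FALSE)
    node <- if (side == "H") node$high else node$low
  }
  list(label = node$label, probability = node$probability,
       classifiable = TRUE, path = do.call(rbind, path) %||% data.frame())
}

#' Assign every patient of an expression matrix to a tree group
#'
#' @param tree A `decision_tree`.
#' @param expr An [expression_matrix()].
#' @return Data.frame (`patient_id`, `label`, `probability`,
#'   `classifiable`) with a `counts` attribute (table of labels).
#' @export
assign_groups <- function(tree, expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  rows <- lapply(rownames(expr), function(p) {
    cl <- classify(tree, expr[p, ])
    data.frame(patient_id = p, label = cl$label,
               probability = cl$probability, classifiable = cl$classifiable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- table(out$label[out$classifiable])
  out
}

#' Merge tree labels into the three published prognostic tiers
#'
#' `HHH` is the high-PFS tier; `HHL`, `HLL` and `LH` the intermediate
#' tier; `HLH` and `LL` the low-PFS tier.
#'
#' @param labels Character vector of six-group labels.
#' @param merge `"none"` or `"paper-three-tier"`.
#' @return Character vector of tier labels (or `labels` unchanged).
#' @export
merge_labels <- function(labels, merge = c("none", "paper-three-tier")) {
  merge <- match.arg(merge)
  if (merge == "none") return(labels)
  map <- c(HHH = "high", HHL = "intermediate", HLL = "intermediate",
           LH = "intermediate", HLH = "low", LL = "low")
  known <- is.na(labels) | labels %in% names(map)
  if (!all(known))
    stop("label(s) absent from the three-tier merge map: ",
         paste(unique(labels[!known]), collapse = ", "))
  out <- map[labels]
  out[is.na(labels)] <- NA_character_
  unname(out)
}

#' The published five-miRNA decision tree as a fixture
#'
#' Topology and thresholds of the reported tree: root miR-125b (0.0005),
#' high branch miR-15b (0.1710) then miR-181c (0.0019) / miR-412 (0.0003),
#' low branch miR-193b (0.0113). The HHH (0.72) and LL (0.04) leaf
#' probabilities are the published values; the other four leaves carry the
#' same artifact placeholders as [planted_tree_default()] and are marked
#' `prob_source = "placeholder"`. Cohort counts were not published, so all
#' `n`/`responders` fields are `NA`.
#'
#' @return A `decision_tree`.
#' @export
published_tree <- function() {
  leaf <- function(label, prob, source) {
    l <- new_leaf(NA_integer_, NA_integer_, label)
    l$probability <- prob
    l$prob_source <- source
    l
  }
  na <- NA_integer_
  root <- new_split("miR-125b", 0.0005, na, na, NA_real_,
    new_split("miR-15b", 0.1710, na, na, NA_real_,
      new_split("miR-181c", 0.0019, na, na, NA_real_,
        leaf("HHH", 0.72, "published"),
        leaf("HHL", 0.50, "placeholder")),
      new_split("miR-412", 0.0003, na, na, NA_real_,
        leaf("HLH", 0.10, "placeholder"),
        leaf("HLL", 0.35, "placeholder"))),
    new_split("miR-193b", 0.0113, na, na, NA_real_,
      leaf("LH", 0.20, "placeholder"),
      leaf("LL", 0.04, "published")))
  structure(list(root = root, alpha = 0.05, min_leaf = NA_integer_,
                 max_depth = 3L, n = NA_integer_, responders = NA_integer_),
            class = "decision_tree")
}

#' Extract the leaves of a decision tree
#'
#' @param tree A `decision_tree`.
#' @return List of leaf nodes in left(high)-to-right(low) order.
#' @export
tree_leaves <- function(tree) {
  rec <- function(node) {
    if (node$type == "leaf") return(list(node))
    c(rec(node$high), rec(node$low))
  }
  rec(tree$root)
}

#' Validate decision-tree structural invariants
#'
#' Checks probability ranges, count conservation at every split
#' (`n = n_high + n_low`, responders likewise), no variable reuse along a
#' path, and label uniqueness. Count checks are skipped where counts are
#' unavailable (e.g. the published fixture).
#'
#' @param tree A `decision_tree`.
#' @return `TRUE` (invisibly); errors describe any violation.
#' @export
validate_tree <- function(tree) {
  rec <- function(node, used) {
    if (node$type == "leaf") {
      if (!is.na(node$probability) &&
          (node$probability < 0 || node$probability > 1))
        stop("leaf probability outside [0,1]")
      return(invisible(NULL))
    }
    if (node$variable %in% used)
      stop("variable '", node$variable, "' repeats along a path")
    kids <- list(node$high, node$low)
    if (!is.na(node$n)) {
      if (node$n != sum(vapply(kids, `[[`, numeric(1), "n")))
        stop("count conservation violated at split on ", node$variable)
      if (node$responders != sum(vapply(kids, `[[`, numeric(1), "responders")))
        stop("responder conservation violated at split on ", node$variable)
    }
    rec(node$high, c(used, node$variable))
    rec(node$low, c(used, node$variable))
  }
  rec(tree$root, character(0))
  labs <- vapply(tree_leaves(tree), `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate leaf labels")
  invisible(TRUE)
}

## ---- serialization -------------------------------------------------------

tree_node_to_list <- function(node) {
  if (node$type == "leaf") {
    out <- list(type = "leaf", n = node$n, responders = node$responders,
                probability = node$probability, label = node$label)
    if (!is.null(node$prob_source)) out$prob_source <- node$prob_source
    return(out)
  }
  list(type = "split", variable = node$variable, threshold = node$threshold,
       n = node$n, responders = node$responders, split_p = node$split_p,
       high = tree_node_to_list(node$high), low = tree_node_to_list(node$low))
}

as_int_na <- function(v) if (is.null(v) || is.na(v)) NA_integer_ else as.integer(v)
as_num_na <- function(v) if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)

tree_node_from_list <- function(l) {
  if (l$type == "leaf") {
    node <- new_leaf(as_int_na(l$n), as_int_na(l$responders), l$label)
    node$probability <- as_num_na(l$probability)
    if (!is.null(l$prob_source)) node$prob_source <- l$prob_source
    return(node)
  }
  new_split(l$variable, as_num_na(l$threshold), as_int_na(l$n),
            as_int_na(l$responders), as_num_na(l$split_p),
            tree_node_from_list(l$high), tree_node_from_list(l$low))
}

#' Serialize a decision tree to JSON
#'
#' @param tree A `decision_tree`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "decision_tree"))
  payload <- list(alpha = tree$alpha, min_leaf = tree$min_leaf,
                  max_depth = tree$max_depth, n = tree$n,
                  responders = tree$responders,
                  root = tree_node_to_list(tree$root))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a decision tree from JSON
#'
#' @param x A JSON string or file path produced by [tree_to_json()].
#' @return A `decision_tree`.
#' @export
tree_from_json <- function(x) {
  l <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(list(root = tree_node_from_list(l$root),
                 alpha = as_num_na(l$alpha),
                 min_leaf = as_int_na(l$min_leaf),
                 max_depth = as_int_na(l$max_depth), n = as_int_na(l$n),
                 responders = as_int_na(l$responders)),
            class = "decision_tree")
}

#' Export a decision tree in Graphviz DOT format
#'
#' @param tree A `decision_tree`.
#' @return A character scalar of DOT source.
#' @export
tree_to_dot <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  lines <- c("digraph decision_tree {", "  node [shape=box];")
  counter <- 0L
  rec <- function(node) {
    counter <<- counter + 1L
    id <- sprintf("n%d", counter)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf(
        "  %s [label=\"%s\\np=%s\", style=filled, fillcolor=lightgrey];",
        id, node$label,
        ifelse(is.na(node$probability), "NA", sprintf("%.2f", node$probability))))
      return(id)
    }
    lines <<- c(lines, sprintf("  %s [label=\"%s > %.4g\"];",
                               id, node$variable, node$threshold))
    hid <- rec(node$high); lid <- rec(node$low)
    lines <<- c(lines, sprintf("  %s -> %s [label=\"H\"];", id, hid),
                sprintf("  %s -> %s [label=\"L\"];", id, lid))
    id
  }
  rec(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}

#' Compare a built tree with a planted truth tree
#'
#' A planted split position is recovered when the built tree has a split on
#' the same variable at that position; threshold accuracy is the absolute
#' log-scale error relative to the planted threshold, in units of the
#' generating `sdlog` when supplied. Splits the built tree grows below the
#' planted leaves (the expected behaviour of an alpha-level stopping rule)
#' are not counted against recovery.
#'
#' @param tree A built `decision_tree`.
#' @param truth_tree The instantiated truth tree of a
#'   [generate_cohort()] `truth` record.
#' @param sdlog Named (or scalar) log-scale SDs used to express threshold
#'   errors in SD units; when `NULL` errors are raw log differences.
#' @return List: `topology_recovered` (logical), `splits` data.frame
#'   (`position`, `variable_true`, `variable_built`, `threshold_err_sd`).
#' @export
compare_to_planted <- function(tree, truth_tree, sdlog = NULL) {
  rows <- list()
  rec <- function(tn, bn, pos) {
    if (is.null(tn) || tn$type == "leaf") return(invisible(NULL))
    vb <- if (!is.null(bn) && bn$type == "split") bn$variable else NA_character_
    err <- NA_real_
    if (!is.na(vb) && vb == tn$variable) {
      e <- abs(log(bn$threshold) - log(tn$threshold))
      s <- if (is.null(sdlog)) 1 else
        if (length(sdlog) == 1) sdlog else sdlog[[tn$variable]]
      err <- e / s
    }
    rows[[length(rows) + 1]] <<- data.frame(
      position = pos, variable_true = tn$variable, variable_built = vb,
      threshold_err_sd = err, stringsAsFactors = FALSE)
    rec(tn$high, if (!is.na(vb) && vb == tn$variable) bn$high else NULL,
        paste0(pos, "H"))
    rec(tn$low, if (!is.na(vb) && vb == tn$variable) bn$low else NULL,
        paste0(pos, "L"))
  }
  rec(truth_tree, tree$root, "root")
  splits <- do.call(rbind, rows)
  list(topology_recovered = all(!is.na(splits$variable_built) &
                                  splits$variable_built == splits$variable_true),
       splits = splits)
}
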