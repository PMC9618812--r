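# Typed tables: relative-expression matrix, raw Ct matrix, clinical table.
# All three are plain-text CSV/TSV on disk and validated S3 objects in memory.

## enumerations for categorical clinical fields; anything else is rejected
clinical_levels <- list(
  cr        = c("CR", "no-CR"),
  blood_mrd = c("uMRD", "detectable"),
  bm_mrd    = c("uMRD", "detectable"),
  sex       = c("F", "M"),
  binet     = c("AB", "C"),
  ighv      = c("mutated", "unmutated"),
  del13q    = c("yes", "no"),
  del11q    = c("yes", "no"),
  tri12     = c("yes", "no"),
  arm       = c("FCR", "Dense-FCR")
)
clinical_numeric <- c("age", "ecog", "lymphocytes", "b2m", "cycles",
                      "pfs_time", "pfs_event")
clinical_required <- c("patient_id", "cr", "blood_mrd", "bm_mrd",
                       "pfs_time", "pfs_event")

#' Construct a validated relative-expression matrix
#'
#' Patients are rows, miRNAs are columns, and every non-missing entry is a
#' positive relative expression value on the 2^-deltaCt scale. Missing
#' measurements are `NA`, never zero.
#'
#' @param values Numeric matrix with unique patient ids as `rownames` and
#'   unique miRNA ids as `colnames`.
#' @return The matrix with class `expr_matrix`.
#' @examples
#' m <- matrix(c(1, 2, 0.5, 4), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("miR-15b", "miR-125b")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  pid <- rownames(values)
  mid <- colnames(values)
  if (is.null(pid) || is.null(mid))
    stop("expression matrix needs patient ids (rownames) and miRNA ids (colnames)")
  if (anyDuplicated(pid))
    stop("duplicate patient id: ", pid[duplicated(pid)][1])
  if (anyDuplicated(mid))
    stop("duplicate miRNA id: ", mid[duplicated(mid)][1])
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive expression value (%g) for patient '%s', miRNA '%s'",
                 values[bad[1, 1], bad[1, 2]], pid[bad[1, 1]], mid[bad[1, 2]]))
  class(values) <- c("expr_matrix", "matrix", "array")
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d patients x %d miRNAs (2^-dCt scale)\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 4))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
patients <- function(x) rownames(x)

#' @rdname expression_matrix
#' @export
mirnas <- function(x) colnames(x)

detect_sep <- function(path) {
  l1 <- readLines(path, n = 2L)
  l1 <- l1[!startsWith(l1, "#")][1]
  if (is.na(l1)) stop("empty file: ", path)
  if (lengths(regmatches(l1, gregexpr("\t", l1))) >=
      lengths(regmatches(l1, gregexpr(",", l1)))) "\t" else ","
}

read_delim_raw <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    comment.char = "#", quote = "\"", colClasses = "character")
}

num_col <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0)
    stop(sprintf("non-numeric value '%s' in %s (row %d)", x[bad[1]], what, bad[1]))
  out
}

#' Read a relative-expression table from CSV/TSV
#'
#' The first column holds ids and the header row the other dimension's ids;
#' by default patients are rows. The delimiter is auto-detected (comma vs
#' tab) unless given.
#'
#' @param path File path.
#' @param sep Field delimiter, `NULL` to auto-detect.
#' @param orientation `"patients-as-rows"` (default) or `"mirnas-as-rows"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, sep = NULL,
                            orientation = c("patients-as-rows", "mirnas-as-rows")) {
  orientation <- match.arg(orientation)
  df <- read_delim_raw(path, sep)
  ids <- as.character(df[[1]])
  m <- as.matrix(as.data.frame(lapply(seq_along(df)[-1], function(j)
    num_col(df[[j]], names(df)[j])), check.names = FALSE,
    col.names = names(df)[-1]))
  rownames(m) <- ids
  if (orientation == "mirnas-as-rows") m <- t(m)
  expression_matrix(m)
}

#' Write a relative-expression table
#'
#' Values are written at full double precision so that
#' `read_expression(write_expression(x))` is the identity; missing entries
#' become empty cells.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_expression <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "expr_matrix"))
  body <- apply(unclass(x), 1, fmt_num)
  body <- if (is.matrix(body)) t(body) else matrix(body, nrow = nrow(x))
  out <- cbind(patient_id = rownames(x), body)
  colnames(out) <- c("patient_id", colnames(x))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated clinical annotation table
#'
#' One row per patient: response outcomes (`cr`, `blood_mrd`, `bm_mrd`, each
#' possibly `NA`), baseline covariates, and progression-free survival
#' (`pfs_time` in months, `pfs_event` 1 = progression/relapse, 0 = censored).
#' Missing values stay `NA`; nothing is imputed.
#'
#' @param df A data.frame with at least `patient_id`, `cr`, `blood_mrd`,
#'   `bm_mrd`, `pfs_time`, `pfs_event`.
#' @return `df` with categorical columns as factors on their canonical
#'   levels and class `clinical_table`.
#' @export
clinical_table <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(clinical_required, names(df))
  if (length(miss) > 0)
    stop("missing required clinical column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient id: ", df$patient_id[duplicated(df$patient_id)][1])
  df$patient_id <- as.character(df$patient_id)
  for (cn in intersect(names(clinical_levels), names(df))) {
    v <- as.character(df[[cn]])
    bad <- setdiff(unique(v[!is.na(v)]), clinical_levels[[cn]])
    if (length(bad) > 0)
      stop(sprintf("unknown category '%s' in column '%s' (allowed: %s)",
                   bad[1], cn, paste(clinical_levels[[cn]], collapse = ", ")))
    df[[cn]] <- factor(v, levels = clinical_levels[[cn]])
  }
  for (cn in intersect(clinical_numeric, names(df)))
    df[[cn]] <- as.numeric(df[[cn]])
  if (any(!is.na(df$pfs_time) & df$pfs_time < 0))
    stop("negative pfs_time for patient ",
         df$patient_id[which(df$pfs_time < 0)[1]])
  if (any(!is.na(df$pfs_event) & !df$pfs_event %in% c(0, 1)))
    stop("pfs_event must be 0 (censored) or 1 (event)")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical annotation table from CSV/TSV
#'
#' @param path File path.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(pfs_time = "PFS_months")`.
#' @param sep Field delimiter, `NULL` to auto-detect.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path, schema = NULL, sep = NULL) {
  df <- read_delim_raw(path, sep)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        stop("schema maps '", canon, "' to absent column '", schema[[canon]], "'")
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  ## tolerate word encodings for the event indicator
  if ("pfs_event" %in% names(df)) {
    v <- df$pfs_event
    v[v %in% "event"] <- "1"
    v[v %in% "censored"] <- "0"
    df$pfs_event <- v
  }
  for (cn in intersect(clinical_numeric, names(df)))
    df[[cn]] <- num_col(df[[cn]], cn)
  clinical_table(df)
}

#' Write a clinical annotation table
#'
#' Missing values are written as empty cells; numerics at full precision.
#'
#' @param x A `clinical_table`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_clinical <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "clinical_table"))
  out <- as.data.frame(x)
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- fmt_num(out[[cn]])
    else {
      out[[cn]] <- as.character(out[[cn]])
      out[[cn]][is.na(out[[cn]])] <- ""
    }
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated raw Ct matrix
#'
#' Samples are rows, qPCR assays are columns. Undetermined wells are stored
#' at `max_cycles` with `undetected = TRUE`.
#'
#' @param ct Numeric matrix of threshold cycles in `(0, max_cycles]` with
#'   unique sample / assay ids as dimnames.
#' @param groups Factor (or character) of length `nrow(ct)` naming each
#'   sample's screening arm; exactly two arms.
#' @param undetected Logical matrix like `ct` flagging undetermined wells;
#'   default all `FALSE` except wells at `max_cycles`.
#' @param max_cycles PCR cycle ceiling (default 40).
#' @return An object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, groups, undetected = NULL, max_cycles = 40) {
  if (!is.matrix(ct) || !is.numeric(ct)) stop("ct must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix needs sample ids (rownames) and assay ids (colnames)")
  if (anyDuplicated(rownames(ct)) || anyDuplicated(colnames(ct)))
    stop("duplicate sample or assay id in Ct matrix")
  if (length(groups) != nrow(ct))
    stop("groups must have one label per sample")
  groups <- factor(as.character(groups))
  if (nlevels(groups) != 2)
    stop("Ct screening needs exactly two group labels, got ",
         nlevels(groups))
  if (any(ct <= 0 | ct > max_cycles, na.rm = TRUE))
    stop("Ct values must lie in (0, max_cycles]")
  if (is.null(undetected)) undetected <- !is.na(ct) & ct >= max_cycles
  stopifnot(is.logical(undetected), dim(undetected) == dim(ct))
  structure(list(ct = ct, groups = groups, undetected = undetected,
                 max_cycles = max_cycles),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("Ct matrix: %d samples x %d assays (groups: %s; max %d cycles)\n",
              nrow(x$ct), ncol(x$ct),
              paste(levels(x$groups), table(x$groups), collapse = " vs "),
              x$max_cycles))
  invisible(x)
}

#' Read a raw Ct screening matrix
#'
#' Expected layout: optional `# max_cycles: <n>` comment line, then a header
#' with `sample_id`, `group`, and one column per assay. Undetermined wells
#' are encoded as `ND`.
#'
#' @inheritParams read_clinical
#' @return A [ct_matrix()].
#' @export
read_ct <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  max_cycles <- 40
  if (grepl("^#\\s*max_cycles:", first))
    max_cycles <- as.numeric(sub("^#\\s*max_cycles:\\s*", "", first))
  df <- read_delim_raw(path, sep)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("Ct table needs 'sample_id' and 'group' columns")
  assays <- setdiff(names(df), c("sample_id", "group"))
  und <- ct <- matrix(NA_real_, nrow(df), length(assays),
                      dimnames = list(df$sample_id, assays))
  und <- matrix(FALSE, nrow(df), length(assays),
                dimnames = list(df$sample_id, assays))
  for (a in assays) {
    v <- df[[a]]
    nd <- !is.na(v) & v == "ND"
    v[nd] <- NA
    ct[, a] <- num_col(v, a)
    ct[nd, a] <- max_cycles
    und[, a] <- nd
  }
  ct_matrix(ct, df$group, und, max_cycles)
}

#' Write a raw Ct screening matrix
#'
#' @param x A `ct_matrix`.
#' @inheritParams write_clinical
#' @export
write_ct <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "ct_matrix"))
  cells <- matrix(fmt_num(x$ct), nrow(x$ct), ncol(x$ct))
  cells[x$undetected] <- "ND"
  out <- cbind(sample_id = rownames(x$ct), group = as.character(x$groups), cells)
  colnames(out) <- c("sample_id", "group", colnames(x$ct))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# max_cycles: %s", fmt_num(x$max_cycles)), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
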