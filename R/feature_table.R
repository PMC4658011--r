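#' Radiomic feature tables
#'
#' A `feature_table` is a data frame with one row per lesion, a binary
#' `label` column (1 = triple-negative, the positive class throughout), any
#' number of numeric feature columns, and optional metadata columns
#' (`case_id`, `subtype`, `er`, `pr`, `her2`) used only for task row
#' filters. Each feature column carries a block tag — `clinical`, `density`,
#' `tumor_texture` or `bpe_texture` — used by the modeling scope filters.
#'
#' Block tags are inferred from column names when not given explicitly,
#' following the conventional lesion-table naming: names starting `"tumor "` are
#' tumor enhancement textures, names starting `"parenchyma "` are BPE
#' textures, `"breast density"` is densitometric, and remaining feature
#' columns are clinical.
#'
#' @param df data frame of features plus a label column.
#' @param label_col name of the binary label column.
#' @param blocks optional named character vector mapping feature column
#'   names to blocks; inferred from names when `NULL`.
#' @param drop_constant drop zero-variance feature columns (with a message);
#'   `FALSE` keeps them (useful before [zscore_normalize()], which handles
#'   them itself).
#' @return A `feature_table` (data frame subclass) with attributes `blocks`
#'   and `label_col`.
#' @export
feature_table <- function(df, label_col = "label", blocks = NULL,
                          drop_constant = TRUE) {
  stopifnot(is.data.frame(df))
  if (!label_col %in% names(df))
    stop(sprintf("label column '%s' not found", label_col))
  y <- df[[label_col]]
  if (anyNA(y)) stop("missing labels are not allowed")
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1 (1 = TN)")
  if (length(unique(y)) < 2L)
    stop("both classes must be present")
  df[[label_col]] <- as.integer(y)

  meta_cols <- intersect(c("case_id", "subtype", "er", "pr", "her2"),
                         names(df))
  feat_cols <- setdiff(names(df), c(label_col, meta_cols))
  bad <- feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature columns (encode categoricals first): ",
         paste(bad, collapse = ", "))
  const <- feat_cols[vapply(df[feat_cols],
                            function(x) length(unique(x)) < 2L, logical(1))]
  if (length(const) && drop_constant) {
    message("dropping ", length(const), " constant feature column(s): ",
            paste(const, collapse = ", "))
    df <- df[setdiff(names(df), const)]
    feat_cols <- setdiff(feat_cols, const)
  }
  if (is.null(blocks)) blocks <- infer_blocks(feat_cols)
  blocks <- blocks[feat_cols]
  if (anyNA(blocks)) stop("every feature column needs a block tag")
  structure(df, blocks = blocks, label_col = label_col,
            class = c("feature_table", "data.frame"))
}

infer_blocks <- function(cols) {
  b <- ifelse(startsWith(cols, "tumor "), "tumor_texture",
       ifelse(startsWith(cols, "parenchyma "), "bpe_texture",
       ifelse(cols == "breast density", "density", "clinical")))
  setNames(b, cols)
}

#' @export
print.feature_table <- function(x, ...) {
  b <- attr(x, "blocks")
  cat(sprintf("<feature_table> %d lesions (%d TN), %d features\n",
              nrow(x), sum(x[[attr(x, "label_col")]]), length(b)))
  print(table(block = b))
  invisible(x)
}

#' Feature columns in a modeling scope
#'
#' Maps a scope keyword to feature column names via block tags. `"tumor"`
#' covers the clinical, densitometric and tumor-texture blocks (the
#' tumor-feature models); `"tumor+bpe"` adds the BPE textures; `"bpe"` is
#' the BPE textures alone (the clustering scope). A character vector of
#' block names selects those blocks directly.
#'
#' @param table a [feature_table()].
#' @param scope `"tumor"`, `"tumor+bpe"`, `"bpe"`, or block names.
#' @return Character vector of feature column names.
#' @export
feature_scope <- function(table, scope = "tumor+bpe") {
  blocks <- attr(table, "blocks")
  wanted <- switch(scope[1],
    "tumor"      = c("clinical", "density", "tumor_texture"),
    "tumor+bpe"  = c("clinical", "density", "tumor_texture", "bpe_texture"),
    "bpe"        = "bpe_texture",
    scope)
  cols <- names(blocks)[blocks %in% wanted]
  if (!length(cols)) stop("scope selects no feature columns")
  cols
}

#' Subtype differentiation task row filters
#'
#' Restricts a table to the cases of one differentiation task: the TN cases
#' plus the comparator group. `tn_vs_others` keeps every case;
#' `tn_vs_er` / `tn_vs_pr` keep receptor-positive comparators and
#' `tn_vs_luma` / `tn_vs_lumb` the St. Gallen luminal groups (these need
#' the `er`/`pr`/`subtype` metadata columns).
#'
#' @param table a [feature_table()].
#' @param task one of `"tn_vs_others"`, `"tn_vs_er"`, `"tn_vs_pr"`,
#'   `"tn_vs_luma"`, `"tn_vs_lumb"`.
#' @return The filtered [feature_table()].
#' @export
task_filter <- function(table,
                        task = c("tn_vs_others", "tn_vs_er", "tn_vs_pr",
                                 "tn_vs_luma", "tn_vs_lumb")) {
  task <- match.arg(task)
  if (task == "tn_vs_others") return(table)
  y <- table[[attr(table, "label_col")]]
  keep <- switch(task,
    tn_vs_er   = y == 1 | table$er == 1,
    tn_vs_pr   = y == 1 | table$pr == 1,
    tn_vs_luma = y == 1 | table$subtype == "LumA",
    tn_vs_lumb = y == 1 | table$subtype == "LumB")
  if (is.null(keep)) stop("task metadata columns missing")
  out <- table[keep, , drop = FALSE]
  attributes(out)[c("blocks", "label_col")] <-
    attributes(table)[c("blocks", "label_col")]
  class(out) <- class(table)
  out
}

#' Read and write feature tables as CSV
#'
#' CSV with a header row and a `label` column. Numeric columns are written
#' with 17 significant digits so a write/read round trip reproduces doubles
#' exactly.
#'
#' @param table a [feature_table()] (or plain data frame for writing).
#' @param path CSV file path.
#' @param label_col label column name expected on read.
#' @return `read_feature_csv()` returns a [feature_table()];
#'   `write_feature_csv()` returns `path` invisibly.
#' @export
write_feature_csv <- function(table, path) {
  out <- as.data.frame(table)
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path, label_col = "label") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_col %in% names(df))
    stop(sprintf("CSV has no '%s' column", label_col))
  if ("case_id" %in% names(df) && anyDuplicated(df$case_id))
    stop("duplicate case ids in CSV")
  feature_table(df, label_col = label_col)
}
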