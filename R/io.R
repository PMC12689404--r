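#' Read a delimited expression matrix
#'
#' Reads a rectangular delimited text file whose first column holds feature
#' identifiers and whose header row holds sample identifiers, as exported
#' from array summarization or count quantification.
#'
#' @param path File path.
#' @param scale Value scale of the stored data: `"log_intensity"` or
#'   `"raw_counts"`.
#' @param delim Field delimiter; default guesses from the extension
#'   (`","` for `.csv`, tab otherwise).
#' @param duplicate_policy What to do with duplicated feature IDs:
#'   `"error"` (default) or `"average"` (row-wise mean per sample).
#' @param missing How to handle missing values: `"error"` (default) or
#'   `"median_impute"` (per-feature median across samples).
#' @return Expression tibble (see [expr_tbl()]).
#' @export
read_expression_matrix <- function(path,
                                   scale = c("log_intensity", "raw_counts"),
                                   delim = NULL,
                                   duplicate_policy = c("error", "average"),
                                   missing = c("error", "median_impute")) {
  scale <- match.arg(scale)
  duplicate_policy <- match.arg(duplicate_policy)
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(),
    show_col_types = FALSE, progress = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed expression file (", nrow(probs), " parsing problem(s), first: ",
      probs$expected[1], " vs ", probs$actual[1], " at row ", probs$row[1], ")"
    ))
  }
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort("expression file must have a feature column plus at least one sample column.")
  }
  names(raw)[1] <- "feature_id"
  raw$feature_id <- as.character(raw$feature_id)
  value_cols <- setdiff(names(raw), "feature_id")
  non_num <- value_cols[!vapply(raw[value_cols], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0(
      "non-numeric cells in sample column(s): ", paste(non_num, collapse = ", ")
    ))
  }

  dup <- unique(raw$feature_id[duplicated(raw$feature_id)])
  if (length(dup) > 0) {
    if (duplicate_policy == "error") {
      abort(paste0("duplicated feature IDs: ", paste(head(dup, 5), collapse = ", ")))
    }
    raw <- raw %>%
      group_by(.data$feature_id) %>%
      summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
  }

  m <- as.matrix(raw[value_cols])
  rownames(m) <- raw$feature_id
  if (anyNA(m)) {
    if (missing == "error") {
      abort("expression matrix contains missing values (set missing = 'median_impute' to impute).")
    }
    for (i in which(rowSums(is.na(m)) > 0)) {
      med <- median(m[i, ], na.rm = TRUE)
      if (is.na(med)) abort("a feature row is entirely missing; cannot impute.")
      m[i, is.na(m[i, ])] <- med
    }
  }
  expr_tbl(m, scale = scale)
}

#' Write an expression matrix to delimited text
#'
#' Emits the same format [read_expression_matrix()] accepts, so synthetic
#' data round-trips exactly (up to numeric formatting).
#'
#' @param expr Expression tibble.
#' @param path Output path; `.csv` writes comma-delimited, anything else tab.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  as_expr_matrix(expr) # validates
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(expr, path)
  } else {
    readr::write_tsv(expr, path)
  }
  invisible(path)
}

#' Parse cohort class labels from sample identifiers
#'
#' Public cohort matrices encode disease status in their column headers in
#' two dialects: a case-insensitive `PD`/`Control` prefix (e.g. `PD_01`), or
#' bare sample numbering where samples 001-050 are PD and 051-100 are
#' Control. An explicit lookup table is also supported.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param dialect `"prefix"`, `"numbering"` or `"explicit_table"`.
#' @param table For `dialect = "explicit_table"`, a tibble with `sample_id`
#'   and `class` columns.
#' @return Tibble with columns `sample_id`, `class` (factor, levels
#'   `Control`, `PD`) and `label_source`.
#' @export
#' @examples
#' parse_sample_labels(c("PD_01", "Control_07"), "prefix")
#' parse_sample_labels(c("S003", "S051"), "numbering")
parse_sample_labels <- function(sample_ids,
                                dialect = c("prefix", "numbering", "explicit_table"),
                                table = NULL) {
  dialect <- match.arg(dialect)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) == 0) abort("no sample ids supplied.")

  if (dialect == "prefix") {
    token <- tolower(sub("^([A-Za-z]+).*$", "\\1", sample_ids))
    ok <- token %in% c("pd", "control")
    if (!all(ok)) {
      abort(paste0(
        "sample ids without a PD/Control prefix: ",
        paste(head(sample_ids[!ok], 5), collapse = ", ")
      ))
    }
    cls <- ifelse(token == "pd", "PD", "Control")
    src <- "prefix_parsed"
  } else if (dialect == "numbering") {
    digits <- gsub("\\D", "", sample_ids)
    if (any(digits == "")) {
      abort(paste0(
        "sample ids without a number: ",
        paste(head(sample_ids[digits == ""], 5), collapse = ", ")
      ))
    }
    num <- as.integer(digits)
    bad <- num < 1 | num > 100
    if (any(bad)) {
      abort(paste0(
        "sample numbers outside 1-100: ",
        paste(head(sample_ids[bad], 5), collapse = ", ")
      ))
    }
    cls <- ifelse(num <= 50, "PD", "Control")
    src <- "numbering_inferred"
  } else {
    if (is.null(table) || !all(c("sample_id", "class") %in% names(table))) {
      abort("explicit_table dialect needs `table` with sample_id and class columns.")
    }
    idx <- match(sample_ids, table$sample_id)
    if (anyNA(idx)) {
      abort(paste0(
        "sample ids missing from the label table: ",
        paste(head(sample_ids[is.na(idx)], 5), collapse = ", ")
      ))
    }
    cls <- as.character(table$class[idx])
    if (!all(cls %in% c("Control", "PD"))) {
      abort("explicit labels must be 'Control' or 'PD'.")
    }
    src <- "explicit"
  }

  tibble(
    sample_id = sample_ids,
    class = factor(cls, levels = c("Control", "PD")),
    label_source = src
  )
}
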