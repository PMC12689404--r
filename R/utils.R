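# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL means "use whatever stream is active".
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Per-row variance of a numeric matrix (no matrixStats dependency).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

#' Build an expression table
#'
#' Expression data travel through the package as a tibble whose first column,
#' `feature_id`, holds unique feature identifiers and whose remaining columns
#' are one numeric column per sample. The value scale (`"log_intensity"` for
#' array-like data, `"raw_counts"` for count data) is carried in the
#' `expr_scale` attribute.
#'
#' @param values Numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs).
#' @param scale Value scale, `"log_intensity"` or `"raw_counts"`.
#' @return A tibble with a `feature_id` column plus one column per sample.
#' @export
expr_tbl <- function(values, scale = c("log_intensity", "raw_counts")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  out <- bind_cols(
    tibble(feature_id = rownames(values)),
    as_tibble(values, .name_repair = "minimal")
  )
  attr(out, "expr_scale") <- scale
  out
}

#' @rdname expr_tbl
#' @param expr An expression tibble.
#' @export
expr_scale <- function(expr) {
  sc <- attr(expr, "expr_scale", exact = TRUE)
  if (is.null(sc)) "log_intensity" else sc
}

# Convert an expression tibble back to a numeric matrix with feature rownames,
# validating shape as we go.
as_expr_matrix <- function(expr) {
  if (!is.data.frame(expr) || !"feature_id" %in% names(expr)) {
    abort("`expr` must be a data frame with a `feature_id` column.")
  }
  ids <- as.character(expr$feature_id)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicated feature_id values: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  value_cols <- setdiff(names(expr), "feature_id")
  if (length(value_cols) == 0) abort("`expr` has no sample columns.")
  non_num <- value_cols[!vapply(expr[value_cols], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0("non-numeric sample columns: ", paste(non_num, collapse = ", ")))
  }
  m <- as.matrix(expr[value_cols])
  rownames(m) <- ids
  m
}

# Align a sample annotation tibble to the column order of an expression
# matrix; errors if the two disagree.
align_annotation <- function(m, annotation) {
  if (!"sample_id" %in% names(annotation)) {
    abort("`annotation` must contain a `sample_id` column.")
  }
  missing <- setdiff(colnames(m), annotation$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples missing from annotation: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(annotation$sample_id)) {
    abort("`annotation` has duplicated sample_id rows.")
  }
  annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
}

# Deterministic sub-stream seeds for pipeline stages, kept inside 32-bit
# integer range.
stage_seed <- function(master, stage) {
  stages <- c(
    "mouse_sim", "global_test", "stability", "selection_perm",
    "cohort_sim", "validation", "loocv"
  )
  k <- match(stage, stages)
  if (is.na(k)) abort(paste0("unknown pipeline stage: ", stage))
  as.integer((as.numeric(master) + k * 9973) %% 2147483647)
}
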