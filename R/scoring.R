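# Applying a signature panel to a cohort: preprocessing, z-scoring,
# composite scoring, and permutation-validated ROC analysis.

#' Platform-aware cohort preprocessing
#'
#' Brings a cohort matrix onto the log2 scale expected by z-scoring:
#' log-intensity data pass through unchanged; raw counts are converted to
#' `log2(CPM + 1)` using per-sample library sizes (column totals).
#'
#' @param expr Expression tibble.
#' @param scale Override the stored value scale if needed.
#' @return Expression tibble on the log-intensity scale.
#' @export
cohort_preprocess <- function(expr, scale = NULL) {
  scale <- scale %||% expr_scale(expr)
  if (scale == "log_intensity") return(expr)
  m <- as_expr_matrix(expr)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort(paste0(
      "zero library size in sample(s): ",
      paste(head(colnames(m)[lib <= 0], 5), collapse = ", ")
    ))
  }
  out <- log2(sweep(m, 2, lib, "/") * 1e6 + 1)
  expr_tbl(out, scale = "log_intensity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-score each feature across samples
#'
#' Per feature: subtract the mean and divide by the sample standard
#' deviation (denominator `n - 1`). Constant features become all-zero rows
#' with a warning.
#'
#' @param expr Expression tibble (log scale), >= 2 samples.
#' @return Expression tibble of z-scores.
#' @export
zscore_features <- function(expr) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 2) abort("z-scoring needs at least 2 samples.")
  mu <- rowMeans(m)
  s <- sqrt(row_vars(m))
  zero <- s == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " constant feature(s) z-scored to all zeros."))
    s[zero] <- 1
  }
  z <- (m - mu) / s
  expr_tbl(z, scale = "log_intensity")
}

#' Composite signature score per sample
#'
#' For each sample, the score is the mean of the sign-reversed z-scores of
#' the down-regulated panel members minus the mean z-score of the
#' up-regulated members; a direction with no matched members contributes 0.
#' Panel members are matched on harmonized core name; multiple matching
#' features are averaged.
#'
#' @param zexpr Z-scored expression tibble ([zscore_features()]).
#' @param panel A `signature_panel`.
#' @return Tibble with `sample_id` and `score`; attributes `coverage`
#'   (fraction of panel members matched) and `matched` (the matched core
#'   names).
#' @export
signature_score <- function(zexpr, panel) {
  stopifnot(nrow(panel) > 0)
  m <- as_expr_matrix(zexpr)
  core <- suppressWarnings(normalize_mirna_name(rownames(m)))
  member_z <- function(name) {
    idx <- which(core %in% name)
    if (length(idx) == 0) return(NULL)
    colMeans(m[idx, , drop = FALSE])
  }
  zs <- lapply(panel$core_name, member_z)
  matched <- !vapply(zs, is.null, logical(1))
  if (!any(matched)) abort("no panel member matches any cohort feature.")
  if (!all(matched)) {
    warn(paste0(
      "panel members absent from the cohort: ",
      paste(panel$core_name[!matched], collapse = ", ")
    ))
  }
  z_mat <- do.call(rbind, zs[matched])
  dirs <- panel$direction[matched]
  down <- dirs == "down"
  s_down <- if (any(down)) colMeans(-z_mat[down, , drop = FALSE]) else 0
  s_up <- if (any(!down)) colMeans(z_mat[!down, , drop = FALSE]) else 0
  scores <- s_down - s_up
  out <- tibble(sample_id = colnames(m), score = unname(scores))
  attr(out, "coverage") <- mean(matched)
  attr(out, "matched") <- panel$core_name[matched]
  out
}

# Raw rank-based AUC of `scores` for the positive class, ties counted 1/2
# (Mann-Whitney formulation).
auc_rank <- function(scores, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with orientation handling
#'
#' Computes the rank (Mann-Whitney) AUC treating the positive class as
#' high-scoring, ties counted 1/2. Because signature orientation across
#' platforms is not guaranteed, the headline AUC is
#' `max(AUC, 1 - AUC)` with the orientation recorded.
#'
#' @param scores Numeric scores.
#' @param labels Class labels (two classes).
#' @param positive The positive class (default `"PD"`/`"MPTP"` when present).
#' @return List with `auc` (headline), `auc_raw` (positive-high), and
#'   `orientation` (`"as_scored"` or `"reversed"`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) abort("both classes must be present.")
  if (length(scores) != length(labels)) abort("scores and labels must have equal length.")
  positive <- positive %||% positive_class(labels)
  raw <- auc_rank(scores, labels == positive)
  list(
    auc = max(raw, 1 - raw),
    auc_raw = raw,
    orientation = if (raw >= 0.5) "as_scored" else "reversed"
  )
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples within class and takes percentile bounds of the AUC evaluated
#' in the observed headline orientation.
#'
#' @inheritParams roc_auc
#' @param n_boot Bootstrap resamples (>= 200; default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return List with `ci_low`, `ci_high`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000, conf = 0.95,
                   positive = NULL, seed = NULL) {
  if (n_boot < 200) abort("n_boot must be at least 200.")
  labels <- as.character(labels)
  positive <- positive %||% positive_class(labels)
  obs <- roc_auc(scores, labels, positive)
  flip <- obs$orientation == "reversed"
  idx_pos <- which(labels == positive)
  idx_neg <- which(labels != positive)
  boots <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(b) {
      bi <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
      a <- auc_rank(scores[bi], labels[bi] == positive)
      if (flip) 1 - a else a
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  list(ci_low = qs[1], ci_high = qs[2])
}

#' Youden-optimal operating threshold
#'
#' Scans the observed score cut-points in the headline orientation and
#' returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 1; ties are broken toward higher sensitivity. The rule is "call
#' positive when score >= threshold" in the as-scored orientation and
#' "score <= threshold" when reversed.
#'
#' @inheritParams roc_auc
#' @return List with `threshold` (on the original score scale),
#'   `sensitivity`, `specificity`, `youden_j`, `orientation`.
#' @export
optimal_threshold <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) abort("both classes must be present.")
  positive <- positive %||% positive_class(labels)
  obs <- roc_auc(scores, labels, positive)
  flip <- obs$orientation == "reversed"
  s <- if (flip) -scores else scores
  pos <- labels == positive
  cuts <- sort(unique(s))
  sens <- vapply(cuts, function(c) mean(s[pos] >= c), numeric(1))
  spec <- vapply(cuts, function(c) mean(s[!pos] < c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]
  list(
    threshold = if (flip) -cuts[best] else cuts[best],
    sensitivity = sens[best],
    specificity = spec[best],
    youden_j = j[best],
    orientation = obs$orientation
  )
}

#' Permutation p-value for the AUC
#'
#' Permutes class labels `B` times, recomputing the headline
#' (max-orientation) AUC each time — the same statistic reported for the
#' observed data, so the test stays calibrated. The default p-value uses
#' add-one smoothing `(1 + #\{AUC* >= AUC_obs\}) / (B + 1)`; the literal
#' proportion `#\{AUC* >= AUC_obs\} / B` is available via `smoothing`.
#'
#' @inheritParams roc_auc
#' @param B Number of permutations (>= 100; default 5000).
#' @param smoothing `"add_one"` (default) or `"literal"`.
#' @param seed Optional seed.
#' @return List with `p_value`, `B`, `smoothing`, `null_auc`.
#' @export
auc_permutation_test <- function(scores, labels, B = 5000,
                                 smoothing = c("add_one", "literal"),
                                 positive = NULL, seed = NULL) {
  smoothing <- match.arg(smoothing)
  if (B < 100) abort("B must be at least 100.")
  labels <- as.character(labels)
  positive <- positive %||% positive_class(labels)
  obs <- roc_auc(scores, labels, positive)$auc
  n <- length(scores)
  n1 <- sum(labels == positive)
  r <- rank(scores)
  null_auc <- with_seed_if(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n1)
      a <- (sum(r[idx]) - n1 * (n1 + 1) / 2) / (n1 * (n - n1))
      max(a, 1 - a)
    }, numeric(1))
  })
  exceed <- sum(null_auc >= obs)
  p <- if (smoothing == "add_one") (1 + exceed) / (B + 1) else exceed / B
  list(p_value = p, B = B, smoothing = smoothing, null_auc = null_auc, observed = obs)
}

#' ROC curve coordinates
#'
#' False/true positive rates over all observed cut-points (positive called
#' when score >= cut), for plotting.
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  positive <- positive %||% positive_class(labels)
  pos <- labels == positive
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble(
    threshold = cuts,
    fpr = vapply(cuts, function(c) mean(scores[!pos] >= c), numeric(1)),
    tpr = vapply(cuts, function(c) mean(scores[pos] >= c), numeric(1))
  )
}

#' Score and evaluate a signature panel in one cohort
#'
#' Runs the full per-cohort validation: platform preprocessing, harmonized
#' probe collapse, z-scoring, composite signature scoring, and ROC analysis
#' with bootstrap CI, Youden threshold and permutation p-value.
#'
#' @param expr Cohort expression tibble (any platform scale).
#' @param annotation Sample annotation tibble with `sample_id` and `class`.
#' @param panel A `signature_panel`.
#' @param B Label permutations for the AUC p-value (default 5000).
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param seed Optional seed (drives bootstrap and permutations).
#' @return An object of class `roc_result` with scores, AUC (headline and
#'   raw), orientation, CI, permutation p, threshold, sensitivity,
#'   specificity, class sizes and panel coverage.
#' @export
validate_cohort <- function(expr, annotation, panel, B = 5000, n_boot = 2000,
                            seed = NULL) {
  prep <- cohort_preprocess(expr)
  collapsed <- collapse_probes(prep)
  z <- suppressWarnings(zscore_features(collapsed))
  scores_tbl <- signature_score(z, panel)
  ann <- annotation[match(scores_tbl$sample_id, annotation$sample_id), ]
  if (anyNA(ann$class)) abort("annotation is missing classes for some samples.")
  labels <- as.character(ann$class)
  scores <- scores_tbl$score

  auc <- roc_auc(scores, labels, positive = "PD")
  ci <- auc_ci(scores, labels,
    n_boot = n_boot, positive = "PD",
    seed = if (is.null(seed)) NULL else seed + 1L
  )
  thr <- optimal_threshold(scores, labels, positive = "PD")
  perm <- auc_permutation_test(scores, labels,
    B = B, positive = "PD",
    seed = if (is.null(seed)) NULL else seed + 2L
  )

  structure(
    list(
      scores = bind_cols(scores_tbl, tibble(class = labels)),
      auc = auc$auc, auc_raw = auc$auc_raw, orientation = auc$orientation,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      perm_p = perm$p_value, B = B, null_auc = perm$null_auc,
      threshold = thr$threshold, sensitivity = thr$sensitivity,
      specificity = thr$specificity,
      n_pd = sum(labels == "PD"), n_control = sum(labels == "Control"),
      coverage = attr(scores_tbl, "coverage")
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(
    sprintf(
      "Signature validation: AUC = %.3f (95%% CI %.3f-%.3f, %s), perm p = %.4g\n",
      x$auc, x$ci_low, x$ci_high, x$orientation, x$perm_p
    ),
    sprintf(
      "  threshold = %.3f, sensitivity = %.2f, specificity = %.2f (PD n = %d, Control n = %d)\n",
      x$threshold, x$sensitivity, x$specificity, x$n_pd, x$n_control
    )
  )
  invisible(x)
}
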