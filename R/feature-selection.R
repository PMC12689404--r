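# Day-0 classifier development: univariate filter, LOOCV elastic net,
# stability selection over tiny subsamples, and a permutation null for
# selection frequencies.

# Pooled-variance two-sample t per feature (vectorized).
# X: features x n; pos: logical vector marking the positive class.
# Zero pooled variance yields 0 when the mean difference is also 0 and
# +/-Inf otherwise (a perfectly separating constant difference).
two_class_t <- function(X, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  x1 <- X[, pos, drop = FALSE]
  x0 <- X[, !pos, drop = FALSE]
  d <- rowMeans(x1) - rowMeans(x0)
  sp2 <- ((n1 - 1) * row_vars(x1) + (n0 - 1) * row_vars(x0)) / (n1 + n0 - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- d / denom
  t[denom == 0 & d == 0] <- 0
  t[denom == 0 & d != 0] <- sign(d[denom == 0 & d != 0]) * Inf
  t
}

check_two_classes <- function(class) {
  class <- as.character(class)
  tab <- table(class)
  if (length(tab) != 2) abort("exactly two classes are required.")
  if (any(tab < 2)) abort("each class needs at least 2 samples.")
  class
}

# Positive class: "PD" or "MPTP" when present, else the second sorted level.
positive_class <- function(class) {
  lv <- sort(unique(as.character(class)))
  hit <- intersect(c("PD", "MPTP"), lv)
  if (length(hit) > 0) hit[1] else lv[2]
}

#' Univariate top-k filter by absolute t-statistic
#'
#' Ranks features by the absolute pooled-variance two-sample t-statistic and
#' keeps the top `k`. Ties are broken by feature ID (lexicographic), so the
#' filter is deterministic.
#'
#' @param expr Expression tibble (e.g. day-0 columns only).
#' @param class Class label per sample column (two classes).
#' @param k Number of features to keep.
#' @return Tibble with `feature_id` and `t_statistic`, ranked by `|t|`.
#' @export
univariate_filter <- function(expr, class, k = 20) {
  m <- as_expr_matrix(expr)
  class <- check_two_classes(class)
  if (length(class) != ncol(m)) abort("`class` must have one label per sample column.")
  if (k > nrow(m)) abort("`k` exceeds the number of features.")
  t <- two_class_t(m, class == positive_class(class))
  ord <- order(-abs(t), rownames(m))
  keep <- ord[seq_len(k)]
  tibble(feature_id = rownames(m)[keep], t_statistic = unname(t[keep]))
}

# Elastic-net logistic fit at a fixed fraction of lambda_max; returns the
# feature IDs with nonzero coefficients (may be empty). Works at n = 4.
enet_fixed_lambda <- function(X, y, alpha, lambda_frac) {
  # lambda_max on glmnet's own scale: max absolute gradient of the
  # standardized predictors at the intercept-only model, divided by n*alpha.
  n <- nrow(X)
  xs <- scale(X, center = TRUE, scale = FALSE)
  sds <- sqrt(colSums(xs^2) / n) # glmnet's 1/n variance convention
  ok <- sds > 0
  if (!any(ok)) return(character(0))
  r <- y - mean(y)
  g <- abs(colSums(xs[, ok, drop = FALSE] * r)) / (n * sds[ok])
  lambda_max <- max(g) / max(alpha, 0.001)
  if (!is.finite(lambda_max) || lambda_max <= 0) return(character(0))
  lambda <- lambda_max * exp(seq(0, log(lambda_frac), length.out = 8))
  fit <- tryCatch(
    suppressWarnings(glmnet::glmnet( # n = 4 triggers benign small-class warnings
      X, y,
      family = "binomial", alpha = alpha, lambda = lambda,
      standardize = TRUE
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(character(0))
  beta <- as.matrix(fit$beta)
  nz <- beta[, ncol(beta)] != 0
  colnames(X)[nz]
}

#' Stability selection with elastic-net logistic models
#'
#' Repeatedly subsamples `subsample_per_class` samples per class without
#' replacement, applies the univariate top-`filter_k` filter on the
#' subsample, and fits an elastic-net logistic model at mixing parameter
#' `alpha` and penalty `lambda_frac * lambda_max` (internal cross-validation
#' is impossible at four samples, so the penalty is anchored to the
#' per-subsample `lambda_max`). A feature's selection probability `pi_hat`
#' is the fraction of (non-degenerate) iterations in which its coefficient
#' is nonzero; features with `pi_hat >= threshold` form the selected set.
#'
#' @param expr Expression tibble (day-0 columns).
#' @param class Class label per sample column.
#' @param n_iter Number of subsampling iterations (default 2000).
#' @param subsample_per_class Samples drawn per class (default 2).
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param filter_k Univariate filter size (default 20).
#' @param lambda_frac Penalty as a fraction of the per-subsample
#'   `lambda_max` (default 0.1).
#' @param threshold Selection-probability threshold (default 0.6).
#' @param seed Optional seed.
#' @return An object of class `stability_result`: `pi_hat` (tibble of
#'   per-feature selection probabilities), `selected`, `threshold`,
#'   `n_iterations`, `n_effective` (iterations actually used) and the tuning
#'   parameters.
#' @export
stability_selection <- function(expr, class, n_iter = 2000,
                                subsample_per_class = 2, alpha = 0.5,
                                filter_k = 20, lambda_frac = 0.1,
                                threshold = 0.6, seed = NULL) {
  if (n_iter < 1) abort("n_iter must be at least 1.")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1).")
  m <- as_expr_matrix(expr)
  class <- check_two_classes(class)
  if (length(class) != ncol(m)) abort("`class` must have one label per sample column.")
  pos_lab <- positive_class(class)
  idx_pos <- which(class == pos_lab)
  idx_neg <- which(class != pos_lab)
  if (min(length(idx_pos), length(idx_neg)) < subsample_per_class) {
    abort("each class needs at least `subsample_per_class` samples.")
  }
  k <- min(filter_k, nrow(m))

  counts <- setNames(numeric(nrow(m)), rownames(m))
  n_eff <- 0L
  with_seed_if(seed, {
    for (it in seq_len(n_iter)) {
      sub <- c(sample(idx_pos, subsample_per_class), sample(idx_neg, subsample_per_class))
      Xs <- m[, sub, drop = FALSE]
      if (all(row_vars(Xs) == 0)) next # degenerate subsample, skip
      pos <- rep(c(1, 0), each = subsample_per_class)
      t <- two_class_t(Xs, pos == 1)
      ord <- order(-abs(t), rownames(Xs))[seq_len(k)]
      sel <- enet_fixed_lambda(
        t(Xs[ord, , drop = FALSE]), pos, alpha = alpha, lambda_frac = lambda_frac
      )
      n_eff <- n_eff + 1L
      if (length(sel) > 0) counts[sel] <- counts[sel] + 1
    }
  })
  if (n_eff == 0) abort("all subsamples were degenerate; cannot estimate selection probabilities.")
  pi_hat <- counts / n_eff
  pi_tbl <- tibble(feature_id = names(pi_hat), pi_hat = unname(pi_hat)) %>%
    arrange(desc(.data$pi_hat), .data$feature_id)
  structure(
    list(
      pi_hat = pi_tbl,
      selected = pi_tbl$feature_id[pi_tbl$pi_hat >= threshold],
      threshold = threshold,
      n_iterations = n_iter,
      n_effective = n_eff,
      subsample_per_class = subsample_per_class,
      alpha = alpha, filter_k = filter_k, lambda_frac = lambda_frac,
      seed = seed
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(
    "Stability selection:", x$n_effective, "of", x$n_iterations,
    "iterations used;", length(x$selected), "feature(s) with pi_hat >=",
    x$threshold, "\n"
  )
  if (length(x$selected) > 0) {
    top <- x$pi_hat[x$pi_hat$feature_id %in% x$selected, ]
    print(top, n = min(nrow(top), 10))
  }
  invisible(x)
}

#' Permutation null for stability-selection frequencies
#'
#' Tests whether the observed number of features passing the
#' selection-probability threshold could arise with class labels permuted:
#' per permutation, labels are shuffled and stability selection is re-run at
#' `iter_per_perm` iterations; the null statistic is the count of features
#' with `pi_hat >= threshold` (or, with `statistic = "mean_top_pi"`, the
#' mean of the top `m` selection probabilities, `m` = observed panel size).
#' `p = (1 + #\{stat* >= stat_obs\}) / (B + 1)`.
#'
#' @inheritParams stability_selection
#' @param observed The observed [stability_selection()] result.
#' @param B Number of label permutations (>= 100).
#' @param iter_per_perm Stability iterations per permutation (default 200; a
#'   deliberate reduction that keeps the null tractable).
#' @param statistic `"count_selected"` (default) or `"mean_top_pi"`.
#' @return List with `p_value`, `observed_stat`, `null_stats`, `B`.
#' @export
selection_permutation_test <- function(expr, class, observed, B = 2000,
                                       iter_per_perm = 200,
                                       statistic = c("count_selected", "mean_top_pi"),
                                       seed = NULL) {
  statistic <- match.arg(statistic)
  if (B < 100) abort("B must be at least 100.")
  stopifnot(inherits(observed, "stability_result"))
  class <- check_two_classes(class)
  m_top <- max(length(observed$selected), 1L)
  stat_of <- function(res) {
    if (statistic == "count_selected") {
      length(res$selected)
    } else {
      mean(head(res$pi_hat$pi_hat, m_top))
    }
  }
  obs <- stat_of(observed)
  null_stats <- with_seed_if(seed, {
    vapply(seq_len(B), function(b) {
      perm <- sample(class)
      res <- stability_selection(
        expr, perm,
        n_iter = iter_per_perm,
        subsample_per_class = observed$subsample_per_class,
        alpha = observed$alpha, filter_k = observed$filter_k,
        lambda_frac = observed$lambda_frac, threshold = observed$threshold
      )
      stat_of(res)
    }, numeric(1))
  })
  list(
    p_value = (1 + sum(null_stats >= obs)) / (B + 1),
    observed_stat = obs,
    null_stats = null_stats,
    B = B,
    statistic = statistic
  )
}

# Stratified fold ids for internal CV: shuffle within class, deal round-robin.
stratified_foldid <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' Leave-one-out cross-validation with elastic-net logistic models
#'
#' For each held-out sample: re-apply the top-`filter_k` univariate filter to
#' the remaining samples, fit elastic-net logistic models over `alpha_grid`
#' with the penalty chosen by stratified internal cross-validation
#' (binomial deviance), pick the best alpha, and score the held-out sample.
#' Filtering and fitting never see the held-out sample. When internal CV is
#' infeasible on a training split, the penalty falls back to
#' `lambda_frac * lambda_max` with a warning.
#'
#' @inheritParams stability_selection
#' @param alpha_grid Candidate elastic-net mixing parameters
#'   (default `c(0.1, 0.5, 0.9)`).
#' @param nfolds Internal CV folds (default 3; small samples do not support
#'   more).
#' @return An object of class `cv_report`: `folds` (tibble with one row per
#'   held-out sample: `sample_id`, `class`, `score`, `alpha`, `lambda`) and
#'   `auc` (pooled over all held-out scores, positive class scored high).
#' @export
loocv_elastic_net <- function(expr, class, alpha_grid = c(0.1, 0.5, 0.9),
                              filter_k = 20, nfolds = 3, lambda_frac = 0.1,
                              seed = NULL) {
  m <- as_expr_matrix(expr)
  class <- check_two_classes(class)
  if (length(class) != ncol(m)) abort("`class` must have one label per sample column.")
  if (ncol(m) < 6) abort("LOOCV needs at least 6 samples.")
  pos_lab <- positive_class(class)
  y_all <- as.numeric(class == pos_lab)
  k <- min(filter_k, nrow(m))
  fallback_warned <- FALSE

  rows <- with_seed_if(seed, {
    purrr::map(seq_len(ncol(m)), function(i) {
      Xtr_full <- m[, -i, drop = FALSE]
      ytr <- y_all[-i]
      t <- two_class_t(Xtr_full, ytr == 1)
      ord <- order(-abs(t), rownames(Xtr_full))[seq_len(k)]
      Xtr <- t(Xtr_full[ord, , drop = FALSE])
      xte <- m[ord, i, drop = FALSE]

      best <- NULL
      if (min(table(ytr)) >= nfolds) {
        foldid <- stratified_foldid(ytr, nfolds)
        for (a in alpha_grid) {
          cv <- tryCatch(
            suppressWarnings(glmnet::cv.glmnet(
              Xtr, ytr,
              family = "binomial", alpha = a, foldid = foldid,
              type.measure = "deviance", standardize = TRUE
            )),
            error = function(e) NULL
          )
          if (is.null(cv)) next
          cvm <- min(cv$cvm)
          if (is.null(best) || cvm < best$cvm) {
            best <- list(cvm = cvm, alpha = a, lambda = cv$lambda.min, fit = cv$glmnet.fit)
          }
        }
      }
      if (is.null(best)) {
        if (!fallback_warned) {
          warn("internal CV infeasible on a training split; using the fixed-lambda fallback.")
          fallback_warned <<- TRUE
        }
        a <- alpha_grid[ceiling(length(alpha_grid) / 2)]
        fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = a, standardize = TRUE)
        lam <- max(fit$lambda) * lambda_frac
        best <- list(alpha = a, lambda = lam, fit = fit)
      }
      score <- as.numeric(glmnet::predict.glmnet(
        best$fit, newx = t(xte), s = best$lambda, type = "link"
      ))
      tibble(
        sample_id = colnames(m)[i], class = class[i],
        score = score, alpha = best$alpha, lambda = best$lambda
      )
    })
  })
  folds <- bind_rows(rows)
  auc <- roc_auc(folds$score, folds$class, positive = pos_lab)$auc_raw
  structure(list(folds = folds, auc = auc, positive = pos_lab), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(
    "LOOCV elastic net:", nrow(x$folds), "held-out scores; pooled AUC =",
    format(x$auc, digits = 3), "\n"
  )
  invisible(x)
}

#' Assemble a signature panel from stability selection and DE results
#'
#' Panel members are the stability-selected features; each gets a direction
#' from the sign of its log fold change in the primary time contrast (down
#' if `logFC < 0`) and a harmonized core name for cross-species matching.
#'
#' @param stability A [stability_selection()] result.
#' @param de A `de_result` tibble ([contrast_time_in_group()]).
#' @return A `signature_panel` tibble: `core_name`, `direction`,
#'   `feature_id`, `pi_hat`, `logFC`. Empty (with a warning) when nothing was
#'   selected.
#' @export
build_panel <- function(stability, de) {
  stopifnot(inherits(stability, "stability_result"))
  sel <- stability$selected
  if (length(sel) == 0) {
    warn("no features passed the selection threshold; returning an empty panel.")
    return(new_signature_panel(tibble(
      core_name = character(0), direction = character(0),
      feature_id = character(0), pi_hat = numeric(0), logFC = numeric(0)
    )))
  }
  missing <- setdiff(sel, de$feature_id)
  if (length(missing) > 0) {
    abort(paste0(
      "selected features missing from the DE table: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  de_sel <- de[match(sel, de$feature_id), ]
  out <- tibble(
    core_name = normalize_mirna_name(sel),
    direction = ifelse(de_sel$logFC < 0, "down", "up"),
    feature_id = sel,
    pi_hat = stability$pi_hat$pi_hat[match(sel, stability$pi_hat$feature_id)],
    logFC = de_sel$logFC
  ) %>% arrange(desc(.data$pi_hat), .data$core_name)
  new_signature_panel(out)
}
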