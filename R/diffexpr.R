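#' Fit per-feature cell means for the 2x2 design
#'
#' Fits the saturated cell-means parameterization of the group x time design
#' (equivalent to group + time + interaction): per feature, the mean of each
#' of the four cells, a pooled within-cell residual variance, and the
#' residual degrees of freedom `N - 4`. Sample columns are matched to the
#' annotation by `sample_id`, so results are invariant to column order.
#'
#' @param expr Expression tibble (log scale).
#' @param samples Annotation tibble with `sample_id`, `group`
#'   (Control/MPTP) and `time` (D0/D5); every cell needs >= 2 samples.
#' @return An object of class `cell_means_fit`: feature IDs, the 4-column
#'   matrix of cell means, residual variances `s2`, residual df, per-cell
#'   sample counts and per-feature mean expression.
#' @export
fit_cell_means <- function(expr, samples) {
  m <- as_expr_matrix(expr)
  ann <- align_annotation(m, samples)
  if (!all(c("group", "time") %in% names(ann))) {
    abort("`samples` must contain `group` and `time` columns.")
  }
  cell <- factor(
    paste(ann$group, ann$time, sep = "."),
    levels = c("Control.D0", "Control.D5", "MPTP.D0", "MPTP.D5")
  )
  if (anyNA(cell)) abort("group must be Control/MPTP and time D0/D5.")
  counts <- table(cell)
  if (any(counts < 2)) {
    abort(paste0(
      "every group x time cell needs at least 2 samples; short cells: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  ind <- outer(levels(cell), as.character(cell), "==") * 1
  n_cell <- rowSums(ind)
  means <- t((ind %*% t(m)) / n_cell) # features x 4
  colnames(means) <- levels(cell)
  fitted <- means[, as.integer(cell), drop = FALSE]
  df_res <- ncol(m) - 4L
  s2 <- rowSums((m - fitted)^2) / df_res
  structure(
    list(
      feature_id = rownames(m),
      means = means,
      s2 = unname(s2),
      df_residual = df_res,
      n_per_cell = setNames(as.vector(counts), names(counts)),
      mean_expr = unname(rowMeans(m))
    ),
    class = "cell_means_fit"
  )
}

# Solve trigamma(x) = y for x > 0 by Newton iteration (monotone decreasing
# target, standard for method-of-moments F-distribution fits).
trigamma_inverse <- function(y) {
  if (y <= 0) abort("trigamma_inverse needs a positive argument.")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-feature residual variances toward a common prior by treating
#' them as scaled chi-square draws around an inverse-chi-square prior with
#' `d0` degrees of freedom and scale `s0^2`. Hyperparameters are estimated by
#' the method of moments on `e_g = log s_g^2 - digamma(d/2) + log(d/2)`:
#' `d0` solves `trigamma(d0/2) = var(e) - trigamma(d/2)` and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the observed
#' log-variance spread is at or below its sampling floor
#' (`var(e) <= trigamma(d/2)`), `d0` is infinite and every posterior variance
#' equals `s0^2 = exp(mean(e))`. Posterior variances are
#' `(d0 s0^2 + d s_g^2) / (d0 + d)` and downstream t-statistics gain `d0`
#' degrees of freedom.
#'
#' @param fit A [fit_cell_means()] result.
#' @return `fit` augmented with `prior_df` (`d0`), `prior_var` (`s0^2`) and
#'   `s2_post` (posterior variances).
#' @export
ebayes_moderate <- function(fit) {
  stopifnot(inherits(fit, "cell_means_fit"))
  s2 <- fit$s2
  d <- fit$df_residual
  if (all(s2 == 0)) abort("all residual variances are zero; nothing to moderate.")
  if (length(s2) < 10) abort("need at least 10 features for stable hyperparameter estimation.")
  pos <- s2 > 0
  if (!all(pos)) {
    warn(paste0(sum(!pos), " zero residual variance(s) excluded from hyperparameter estimation."))
  }
  e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
  mean_e <- mean(e)
  rhs <- var(e) - trigamma(d / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    d0 <- Inf
    s02 <- exp(mean_e)
    s2_post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s02 <- exp(mean_e + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  }
  fit$prior_df <- d0
  fit$prior_var <- s02
  fit$s2_post <- s2_post
  fit
}

#' Differential expression for the time effect within one group
#'
#' Extracts the D5 - D0 contrast within `group` from a moderated cell-means
#' fit: the log2 fold change, ordinary and moderated t-statistics, two-sided
#' p-values on `d0 + d` degrees of freedom, and Benjamini-Hochberg adjusted
#' q-values.
#'
#' @param fit A [fit_cell_means()] result passed through [ebayes_moderate()].
#' @param group `"MPTP"` (default) or `"Control"`.
#' @return A tibble of class `de_result` with columns `feature_id`, `logFC`,
#'   `t_ordinary`, `t_moderated`, `p_value`, `q_value`, `mean_expr`;
#'   attributes carry `prior_df`, `prior_var`, `df_total` and the contrast.
#' @export
contrast_time_in_group <- function(fit, group = "MPTP") {
  stopifnot(inherits(fit, "cell_means_fit"))
  if (is.null(fit$s2_post)) abort("run ebayes_moderate() on the fit first.")
  if (!group %in% c("Control", "MPTP")) abort(paste0("unknown group: ", group))
  c5 <- paste0(group, ".D5")
  c0 <- paste0(group, ".D0")
  lfc <- fit$means[, c5] - fit$means[, c0]
  vfac <- 1 / fit$n_per_cell[[c5]] + 1 / fit$n_per_cell[[c0]]
  se_ord <- sqrt(fit$s2 * vfac)
  se_mod <- sqrt(fit$s2_post * vfac)
  t_ord <- lfc / se_ord
  t_mod <- lfc / se_mod
  df_total <- fit$prior_df + fit$df_residual
  p <- 2 * pt(-abs(t_mod), df = df_total)
  out <- tibble(
    feature_id = fit$feature_id,
    logFC = unname(lfc),
    t_ordinary = unname(t_ord),
    t_moderated = unname(t_mod),
    p_value = unname(p),
    q_value = bh_fdr(unname(p)),
    mean_expr = fit$mean_expr
  )
  attr(out, "prior_df") <- fit$prior_df
  attr(out, "prior_var") <- fit$prior_var
  attr(out, "df_total") <- df_total
  attr(out, "contrast") <- paste0(group, ": D5 - D0")
  class(out) <- c("de_result", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin validating wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1] with no NAs.")
  p.adjust(p, method = "BH")
}

#' One-call differential expression for the 2x2 design
#'
#' Convenience wrapper: [fit_cell_means()], [ebayes_moderate()], then
#' [contrast_time_in_group()].
#'
#' @inheritParams fit_cell_means
#' @inheritParams contrast_time_in_group
#' @return A `de_result` tibble (see [contrast_time_in_group()]).
#' @export
run_diffexpr <- function(expr, samples, group = "MPTP") {
  fit <- ebayes_moderate(fit_cell_means(expr, samples))
  contrast_time_in_group(fit, group = group)
}
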