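# broom-style accessors for the package's result objects.

#' @exportS3Method generics::tidy
tidy.stability_result <- function(x, ...) x$pi_hat

#' @exportS3Method generics::glance
glance.stability_result <- function(x, ...) {
  tibble(
    n_selected = length(x$selected),
    threshold = x$threshold,
    n_iterations = x$n_iterations,
    n_effective = x$n_effective,
    alpha = x$alpha,
    filter_k = x$filter_k
  )
}

#' @exportS3Method generics::tidy
tidy.global_perm_test <- function(x, ...) {
  tibble(T_permuted = x$T_permuted)
}

#' @exportS3Method generics::glance
glance.global_perm_test <- function(x, ...) {
  tibble(
    T_observed = x$T_observed, p_value = x$p_value,
    B = x$B, mode = x$mode, statistic = x$statistic
  )
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) as_tibble(x$scores)

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble(
    auc = x$auc, auc_raw = x$auc_raw, orientation = x$orientation,
    ci_low = x$ci_low, ci_high = x$ci_high, perm_p = x$perm_p, B = x$B,
    threshold = x$threshold, sensitivity = x$sensitivity,
    specificity = x$specificity, n_pd = x$n_pd, n_control = x$n_control
  )
}

#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  tibble(auc = x$auc, n_folds = nrow(x$folds), positive = x$positive)
}

#' @exportS3Method generics::tidy
tidy.pca_qc <- function(x, ...) x$coords

#' @exportS3Method generics::glance
glance.pca_qc <- function(x, ...) {
  tibble(
    pc = seq_along(x$var_explained),
    var_explained_pct = x$var_explained
  )
}
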