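# ggplot2 autoplot methods for result objects. Plain plots: volcano,
# selection-probability lollipop, permutation-null histogram, ROC curve,
# PCA scatter.

#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, fdr_cutoff = 0.05, ...) {
  df <- as_tibble(object) %>%
    mutate(significant = .data$q_value < fdr_cutoff)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$logFC, y = -log10(.data$p_value), colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change (D5 - D0)", y = "-log10 p",
      colour = paste0("q < ", fdr_cutoff),
      title = attr(object, "contrast")
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.stability_result <- function(object, top_n = 20, ...) {
  df <- head(object$pi_hat, top_n)
  df$feature_id <- factor(df$feature_id, levels = rev(df$feature_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pi_hat, y = .data$feature_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$pi_hat, yend = .data$feature_id),
      colour = "grey70"
    ) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "selection probability", y = NULL,
      title = paste0("Stability selection (threshold ", object$threshold, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.global_perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(T = object$T_permuted), ggplot2::aes(x = .data$T)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$T_observed, colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(
      x = "permutation statistic", y = "count",
      title = sprintf("Global permutation test (p = %.3g, B = %d)", object$p_value, object$B)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  s <- if (object$orientation == "reversed") -object$scores$score else object$scores$score
  pts <- roc_points(s, object$scores$class, positive = "PD")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf(
        "ROC: AUC = %.3f (95%% CI %.2f-%.2f), perm p = %.3g",
        object$auc, object$ci_low, object$ci_high, object$perm_p
      )
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pca_qc <- function(object, colour = NULL, ...) {
  df <- object$coords
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", object$var_explained[2]),
      title = sprintf("PCA of top %d variable features", object$n_top)
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}
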