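#' Hemolysis proxy: the miR-23a / miR-451 log-ratio
#'
#' Red-cell contamination of serum inflates miR-451 relative to miR-23a, so
#' the per-sample difference of their log2 values serves as a hemolysis
#' proxy. Samples whose statistic exceeds `cutoff` are flagged. Marker rows
#' are located by harmonized core name (`hsa-mir-23a` vs `hsa-mir-451`, with
#' `hsa-mir-451a` accepted for the denominator), averaging multiple matching
#' probes.
#'
#' @param expr Expression tibble on the log2 scale.
#' @param cutoff Flagging threshold for the log2 difference (default 5).
#' @return Tibble with `sample_id`, `log2_ratio`, `flagged`; empty (with a
#'   warning) when either marker is absent.
#' @export
hemolysis_ratio <- function(expr, cutoff = 5) {
  m <- as_expr_matrix(expr)
  core <- suppressWarnings(normalize_mirna_name(rownames(m)))
  i23 <- which(core %in% "hsa-mir-23a")
  i451 <- which(core %in% c("hsa-mir-451", "hsa-mir-451a"))
  if (length(i23) == 0 || length(i451) == 0) {
    warn("hemolysis markers (miR-23a and/or miR-451) not found; no QC flags produced.")
    return(tibble(
      sample_id = character(0), log2_ratio = numeric(0), flagged = logical(0)
    ))
  }
  v23 <- colMeans(m[i23, , drop = FALSE])
  v451 <- colMeans(m[i451, , drop = FALSE])
  stat <- v23 - v451
  tibble(
    sample_id = colnames(m),
    log2_ratio = unname(stat),
    flagged = unname(stat > cutoff)
  )
}

#' PCA of the most variable features, for sample QC
#'
#' Selects the `n_top` features with the largest variance across samples,
#' centres each feature, and decomposes the sample-by-feature matrix.
#' Used to check that replicates group and no sample is an outlier.
#'
#' @param expr Expression tibble (log scale).
#' @param n_top How many top-variance features to use (default 500; must not
#'   exceed the number of features).
#' @return An object of class `pca_qc`: a list with `coords` (tibble of
#'   sample PC coordinates), `var_explained` (percent variance per PC) and
#'   `n_top`.
#' @export
pca_qc <- function(expr, n_top = 500) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 3) abort("PCA QC needs at least 3 samples.")
  if (n_top > nrow(m)) abort("`n_top` exceeds the number of features.")
  v <- row_vars(m)
  keep <- order(v, decreasing = TRUE)[seq_len(n_top)]
  x <- m[keep, , drop = FALSE]
  xc <- x - rowMeans(x)
  pc <- prcomp(t(xc), center = FALSE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  coords <- bind_cols(
    tibble(sample_id = colnames(m)),
    as_tibble(pc$x, .name_repair = "minimal")
  )
  structure(
    list(coords = coords, var_explained = ve, n_top = n_top),
    class = "pca_qc"
  )
}

#' @export
print.pca_qc <- function(x, ...) {
  cat(
    "PCA QC on top", x$n_top, "variable features:",
    paste0(
      "PC", seq_len(min(3, length(x$var_explained))), " = ",
      sprintf("%.1f%%", x$var_explained[seq_len(min(3, length(x$var_explained)))]),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}
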