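# Global permutation test: an omnibus statistic over all features comparing
# time effects between treatment groups, with time labels permuted within
# each group.

# Vectorized sum-of-squared two-sample t statistics.
# X: features x n matrix (one group's samples); A: n x K 0/1 indicator of
# "D5" membership, each column one assignment with a fixed number of ones.
# Returns a length-K vector of sum_g t_g^2 (ordinary pooled-variance t of
# D5 vs D0). Zero pooled variance with zero difference contributes 0.
sum_t2_assignments <- function(X, A) {
  n5 <- sum(A[, 1])
  n0 <- nrow(A) - n5
  X2 <- X^2
  s5 <- X %*% A
  s0 <- rowSums(X) - s5
  q5 <- X2 %*% A
  q0 <- rowSums(X2) - q5
  m5 <- s5 / n5
  m0 <- s0 / n0
  ss5 <- q5 - n5 * m5^2
  ss0 <- q0 - n0 * m0^2
  sp2 <- (ss5 + ss0) / (n5 + n0 - 2)
  denom <- sp2 * (1 / n5 + 1 / n0)
  d <- m5 - m0
  t2 <- d^2 / denom
  t2[denom <= 0 & d == 0] <- 0
  t2[denom <= 0 & d != 0] <- Inf
  colSums(t2)
}

split_groups <- function(expr, samples) {
  m <- as_expr_matrix(expr)
  ann <- align_annotation(m, samples)
  if (!all(c("group", "time") %in% names(ann))) {
    abort("`samples` must contain `group` and `time` columns.")
  }
  out <- list()
  for (g in c("MPTP", "Control")) {
    idx <- which(ann$group == g)
    if (length(idx) == 0) abort(paste0("no samples in group ", g))
    d5 <- ann$time[idx] == "D5"
    if (sum(d5) == 0 || sum(!d5) == 0) {
      abort(paste0("group ", g, " needs samples at both D0 and D5."))
    }
    out[[g]] <- list(X = m[, idx, drop = FALSE], d5 = as.numeric(d5))
  }
  out
}

#' Global sum-of-squared-t statistic
#'
#' Per feature, computes the ordinary two-sample t of D5 vs D0 within each
#' treatment group; the global statistic is either the difference of the
#' per-group sums of squared t-statistics (`"difference"`, default; large
#' when time effects are concentrated in the MPTP group) or the MPTP-only
#' sum (`"mptp_only"`).
#'
#' @param expr Expression tibble (log scale).
#' @param samples Annotation tibble with `sample_id`, `group`, `time`.
#' @param statistic `"difference"` or `"mptp_only"`.
#' @return A single numeric value.
#' @export
global_time_statistic <- function(expr, samples,
                                  statistic = c("difference", "mptp_only")) {
  statistic <- match.arg(statistic)
  gr <- split_groups(expr, samples)
  tm <- sum_t2_assignments(gr$MPTP$X, matrix(gr$MPTP$d5, ncol = 1))
  if (statistic == "mptp_only") return(unname(tm))
  tc <- sum_t2_assignments(gr$Control$X, matrix(gr$Control$d5, ncol = 1))
  unname(tm - tc)
}

#' Permute time labels within each treatment group
#'
#' Reassigns the multiset of D0/D5 labels at random within each group,
#' leaving group membership (and per-group D0/D5 counts) untouched. Uses the
#' current RNG stream.
#'
#' @param samples Annotation tibble with `sample_id`, `group`, `time`.
#' @return The annotation with permuted `time`.
#' @export
permute_time_labels <- function(samples) {
  stopifnot(all(c("group", "time") %in% names(samples)))
  out <- samples
  for (g in unique(samples$group)) {
    idx <- which(samples$group == g)
    out$time[idx] <- samples$time[idx][sample(length(idx))]
  }
  out
}

#' Global permutation test of group-specific time effects
#'
#' Compares the observed [global_time_statistic()] to its distribution under
#' random reassignment of time labels within each treatment group. In
#' `"sampled"` mode, `B` permutations are drawn with replacement and the
#' one-sided p-value uses add-one smoothing,
#' `p = (1 + #\{T* >= T_obs\}) / (B + 1)`. In `"exhaustive"` mode all
#' distinct within-group assignments are enumerated (the observed assignment
#' included) and `p = #\{T* >= T_obs\} / N`.
#'
#' @inheritParams global_time_statistic
#' @param B Number of sampled permutations (>= 100; ignored in exhaustive
#'   mode).
#' @param mode `"sampled"` or `"exhaustive"`.
#' @param statistic Passed to [global_time_statistic()].
#' @param seed Optional seed for the sampled mode.
#' @return An object of class `global_perm_test`: `T_observed`,
#'   `T_permuted`, `p_value`, `B`, `mode`, `statistic`, `n_distinct`.
#' @export
global_permutation_test <- function(expr, samples, B = 5000,
                                    mode = c("sampled", "exhaustive"),
                                    statistic = c("difference", "mptp_only"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  gr <- split_groups(expr, samples)
  t_obs <- global_time_statistic(expr, samples, statistic = statistic)

  n_distinct <- prod(vapply(
    gr, function(g) choose(length(g$d5), sum(g$d5)), numeric(1)
  ))

  if (mode == "sampled") {
    if (B < 100) abort("sampled mode needs B >= 100.")
    if (B > n_distinct) {
      warn(paste0(
        "B = ", B, " exceeds the ", n_distinct,
        " distinct assignments; consider mode = 'exhaustive'."
      ))
    }
    t_perm <- with_seed_if(seed, {
      per_group <- lapply(gr, function(g) {
        n <- length(g$d5)
        A <- matrix(0, n, B)
        for (b in seq_len(B)) A[sample(n, sum(g$d5)), b] <- 1
        sum_t2_assignments(g$X, A)
      })
      if (statistic == "difference") {
        per_group$MPTP - per_group$Control
      } else {
        per_group$MPTP
      }
    })
    p <- (1 + sum(t_perm >= t_obs)) / (B + 1)
  } else {
    per_group <- lapply(gr, function(g) {
      n <- length(g$d5)
      combos <- combn(n, sum(g$d5))
      A <- matrix(0, n, ncol(combos))
      A[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = nrow(combos)))] <- 1
      sum_t2_assignments(g$X, A)
    })
    if (statistic == "difference") {
      t_perm <- as.vector(outer(per_group$MPTP, per_group$Control, "-"))
    } else {
      t_perm <- rep(per_group$MPTP, times = length(per_group$Control))
    }
    p <- sum(t_perm >= t_obs) / length(t_perm)
    B <- length(t_perm)
  }

  structure(
    list(
      T_observed = t_obs, T_permuted = t_perm, p_value = p,
      B = B, mode = mode, statistic = statistic, n_distinct = n_distinct
    ),
    class = "global_perm_test"
  )
}

#' @export
print.global_perm_test <- function(x, ...) {
  cat(
    "Global permutation test (", x$statistic, ", ", x$mode, " mode)\n",
    "  T_observed = ", format(x$T_observed, digits = 5),
    ", one-sided p = ", format(x$p_value, digits = 4),
    " (B = ", x$B, ")\n",
    sep = ""
  )
  invisible(x)
}
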