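test_that("count preprocessing is log2-CPM with +1 offset; log data pass through", {
  m <- withr::with_seed(1, matrix(rpois(5 * 4, 100), 5, 4))
  rownames(m) <- paste0("f", 1:5)
  colnames(m) <- paste0("s", 1:4)
  counts <- expr_tbl(m, scale = "raw_counts")
  out <- cohort_preprocess(counts)
  oracle <- log2(sweep(m, 2, colSums(m), "/") * 1e6 + 1)
  expect_equal(as.matrix(out[-1]), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(out, "expr_scale"), "log_intensity")

  logd <- random_expr(5, 4, seed = 2)
  expect_identical(cohort_preprocess(logd), logd)

  # equal counts per sample collapse to identical log-CPM columns
  eq <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  rownames(eq) <- paste0("f", 1:3)
  colnames(eq) <- paste0("s", 1:4)
  out_eq <- as.matrix(cohort_preprocess(expr_tbl(eq, scale = "raw_counts"))[-1])
  expect_true(all(out_eq == out_eq[, 1]))

  zero <- expr_tbl(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
    scale = "raw_counts"
  )
  expect_error(cohort_preprocess(zero), "library size")
})

test_that("z-scoring normalizes rows, flags constants, and is idempotent", {
  expr <- random_expr(10, 8, seed = 3)
  z <- zscore_features(expr)
  zm <- as.matrix(z[-1])
  expect_equal(unname(rowMeans(zm)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(zm, 1, sd)), rep(1, 10), tolerance = 1e-12)
  z2 <- zscore_features(z)
  expect_equal(as.matrix(z2[-1]), zm, tolerance = 1e-10)

  const <- expr_tbl(matrix(5, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4))))
  expect_warning(zc <- zscore_features(const), "constant")
  expect_true(all(as.matrix(zc[-1]) == 0))
  one <- expr_tbl(matrix(1, 2, 1, dimnames = list(c("a", "b"), "s1")))
  expect_error(zscore_features(one), "2 samples")
})

test_that("signature score follows the down-minus-up z-score formula", {
  z <- rbind(
    "hsa-mir-1" = c(-1, -1, 2),
    "hsa-mir-2" = c(-1, 0.5, 1),
    "hsa-mir-3" = c(0.25, -0.5, 1)
  )
  colnames(z) <- paste0("s", 1:3)
  all_down <- new_panel_for_test(c("hsa-mir-1", "hsa-mir-2"), c("down", "down"))
  s <- signature_score(expr_tbl(z), all_down)
  expect_equal(s$score, c(1, 0.25, -1.5)) # mean of -z over the two members

  mixed <- new_panel_for_test(c("hsa-mir-1", "hsa-mir-3"), c("down", "up"))
  s2 <- signature_score(expr_tbl(z), mixed)
  expect_equal(s2$score, -z["hsa-mir-1", ] - z["hsa-mir-3", ], ignore_attr = TRUE)
})

test_that("missing panel members reduce coverage; zero matches error", {
  z <- random_expr(4, 5, seed = 4, prefix = "hsa-mir-z")
  panel <- new_panel_for_test(
    c(z$feature_id[1], "hsa-mir-absent"), c("down", "down")
  )
  expect_warning(s <- signature_score(z, panel), "absent")
  expect_equal(attr(s, "coverage"), 0.5)
  none <- new_panel_for_test("hsa-mir-nope", "down")
  expect_error(suppressWarnings(signature_score(z, none)), "no panel member")
})

test_that("panel members measured by several probes are averaged before scoring", {
  z <- rbind(
    "hsa-miR-9-5p" = c(1, -1),
    "hsa-miR-9-3p" = c(3, -3),
    "hsa-miR-10-5p" = c(0, 0)
  )
  colnames(z) <- c("s1", "s2")
  panel <- new_panel_for_test("hsa-mir-9", "down")
  s <- signature_score(expr_tbl(z), panel)
  expect_equal(s$score, c(-2, 2)) # -(mean of the two arms)
})

test_that("rank AUC matches trivial cases and the all-pairs oracle", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c("PD", "PD", "Control", "Control"))$auc_raw, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), c("PD", "PD", "Control", "Control"))$auc_raw, 0.5)
  withr::with_seed(5, {
    for (i in 1:100) {
      n1 <- sample(2:10, 1)
      n0 <- sample(2:10, 1)
      scores <- sample(seq(-2, 2, by = 0.5), n1 + n0, replace = TRUE) # forces ties
      labels <- c(rep("PD", n1), rep("Control", n0))
      got <- roc_auc(scores, labels, positive = "PD")$auc_raw
      expect_equal(got, auc_pairs_oracle(scores, labels == "PD"), tolerance = 1e-12)
    }
  })
})

test_that("AUC of negated scores is the complement (tie-half convention)", {
  withr::with_seed(6, {
    for (i in 1:50) {
      scores <- sample(seq(-3, 3, 0.5), 12, replace = TRUE)
      labels <- sample(c("PD", "Control"), 12, replace = TRUE, prob = c(0.5, 0.5))
      if (length(unique(labels)) < 2) next
      a <- roc_auc(scores, labels)$auc_raw
      b <- roc_auc(-scores, labels)$auc_raw
      expect_equal(a + b, 1, tolerance = 1e-12)
    }
  })
})

test_that("rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    scores <- rnorm(40)
    labels <- rep(c("PD", "Control"), each = 20)
  })
  got <- roc_auc(scores, labels, positive = "PD")$auc_raw
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("Control", "PD"), direction = "<", quiet = TRUE
  )))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("bootstrap CI brackets the point estimate and caps at 1 under separation", {
  scores <- c(rnorm(30, 3), rnorm(30, -3))
  labels <- rep(c("PD", "Control"), each = 30)
  ci <- auc_ci(scores, labels, n_boot = 300, seed = 1)
  expect_equal(ci$ci_high, 1)
  expect_true(ci$ci_low <= 1 && ci$ci_low >= 0)
  a <- roc_auc(scores, labels)$auc
  expect_true(ci$ci_low <= a && a <= ci$ci_high)
})

test_that("null-score CI covers 0.5 at roughly the nominal rate", {
  cover <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      scores <- rnorm(40)
      labels <- rep(c("PD", "Control"), each = 20)
    })
    # CI in the raw (PD-positive) orientation for coverage of the truth 0.5
    idx_pos <- which(labels == "PD")
    idx_neg <- which(labels != "PD")
    boots <- withr::with_seed(s, vapply(1:200, function(b) {
      bi <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
      mirsig:::auc_rank(scores[bi], labels[bi] == "PD")
    }, numeric(1)))
    q <- quantile(boots, c(0.025, 0.975))
    q[1] <= 0.5 && 0.5 <= q[2]
  }, logical(1))
  expect_gt(mean(cover), 0.85)
})

test_that("Youden threshold maximizes J (exhaustive check) and handles degeneracy", {
  withr::with_seed(8, {
    for (i in 1:100) {
      scores <- sample(seq(-2, 2, 0.25), 14, replace = TRUE)
      labels <- sample(c("PD", "Control"), 14, replace = TRUE)
      if (length(unique(labels)) < 2) next
      out <- optimal_threshold(scores, labels, positive = "PD")
      s_or <- if (out$orientation == "reversed") -scores else scores
      expect_equal(out$youden_j, youden_oracle(s_or, labels == "PD"), tolerance = 1e-12)
    }
  })
  # perfect separation: sens = spec = 1
  sep <- optimal_threshold(c(5, 6, -5, -6), c("PD", "PD", "Control", "Control"))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  # all scores identical: the single trivial cut calls everything positive
  same <- optimal_threshold(rep(2, 6), rep(c("PD", "Control"), 3))
  expect_equal(same$sensitivity, 1)
  expect_equal(same$specificity, 0)
})

test_that("AUC permutation p hits the add-one floor under perfect separation", {
  scores <- c(rnorm(20, 10), rnorm(20, -10))
  labels <- rep(c("PD", "Control"), each = 20)
  out <- auc_permutation_test(scores, labels, B = 500, seed = 2)
  expect_equal(out$p_value, 1 / 501)
  lit <- auc_permutation_test(scores, labels, B = 500, smoothing = "literal", seed = 2)
  expect_equal(lit$p_value, 0)
  expect_gte(out$p_value, lit$p_value) # add-one is never smaller
})

test_that("max-orientation permutation p is calibrated under the null", {
  ps <- vapply(1:200, function(s) {
    withr::with_seed(3000 + s, {
      scores <- rnorm(30)
      labels <- rep(c("PD", "Control"), each = 15)
    })
    auc_permutation_test(scores, labels, B = 200, seed = s)$p_value
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.08) # valid despite the max() statistic
  expect_gt(mean(ps < 0.5), 0.3) # and not wildly conservative
})

test_that("signature scores are invariant to constant feature shifts before z-scoring", {
  expr <- random_expr(6, 10, seed = 9, prefix = "hsa-mir-s")
  panel <- new_panel_for_test(expr$feature_id[1:3], rep("down", 3))
  s1 <- signature_score(zscore_features(expr), panel)
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$feature_id
  m[2, ] <- m[2, ] + 7
  s2 <- signature_score(zscore_features(expr_tbl(m)), panel)
  expect_equal(s1$score, s2$score, tolerance = 1e-10)
})

test_that("a cohort with depressed panel z-scores in PD scores PD higher", {
  panel <- signature_panel_reference()
  sim <- simulate_human_cohort(
    cohort_sim_spec(30, 30, "array_continuous", "prefix", rng_seed = 10), panel
  )
  v <- validate_cohort(sim$expr, sim$samples, panel, B = 200, n_boot = 200, seed = 11)
  mean_pd <- mean(v$scores$score[v$scores$class == "PD"])
  mean_ctl <- mean(v$scores$score[v$scores$class == "Control"])
  expect_gt(mean_pd, mean_ctl) # down-regulation flips sign into the score
  expect_identical(v$orientation, "as_scored")
  expect_gte(v$auc, v$auc_raw)
  expect_true(v$ci_low <= v$auc && v$auc <= v$ci_high)
})
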