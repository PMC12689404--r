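test_that("univariate filter ranks a strongly separating feature first", {
  m <- withr::with_seed(1, matrix(rnorm(30 * 8), 30, 8))
  m[7, 1:4] <- m[7, 1:4] + 5 # 5-SD shift in the positive class
  rownames(m) <- sprintf("f%02d", 1:30)
  colnames(m) <- paste0("s", 1:8)
  cls <- rep(c("PD", "Control"), each = 4)
  out <- univariate_filter(expr_tbl(m), cls, k = 5)
  expect_identical(out$feature_id[1], "f07")
})

test_that("filter with k = n_features returns everything; label swap leaves |t| invariant", {
  expr <- random_expr(12, 8, seed = 2)
  cls <- rep(c("PD", "Control"), each = 4)
  out <- univariate_filter(expr, cls, k = 12)
  expect_setequal(out$feature_id, expr$feature_id)
  swapped <- ifelse(cls == "PD", "Control", "PD")
  out2 <- univariate_filter(expr, swapped, k = 12)
  expect_identical(out$feature_id, out2$feature_id)
  expect_equal(abs(out$t_statistic), abs(out2$t_statistic), tolerance = 1e-12)
})

test_that("zero-variance features get t = 0 (never NaN) and constant shifts give infinite t", {
  m <- rbind(f1 = rep(1, 6), f2 = c(2, 2, 2, 5, 5, 5), f3 = rnorm(6))
  colnames(m) <- paste0("s", 1:6)
  cls <- rep(c("PD", "Control"), each = 3)
  out <- univariate_filter(expr_tbl(m), cls, k = 3)
  t_by_id <- setNames(out$t_statistic, out$feature_id)
  expect_identical(unname(t_by_id["f1"]), 0)
  expect_identical(unname(abs(t_by_id["f2"])), Inf)
  expect_false(anyNA(out$t_statistic))
})

test_that("stability selection is reproducible and rejects bad inputs", {
  sim <- mouse_fixture(n_features = 30, seed = 3)
  a <- stability_selection(sim$expr_d0, sim$class_d0, n_iter = 60, seed = 4)
  b <- stability_selection(sim$expr_d0, sim$class_d0, n_iter = 60, seed = 4)
  expect_identical(a$pi_hat, b$pi_hat)
  expect_true(all(a$pi_hat$pi_hat >= 0 & a$pi_hat$pi_hat <= 1))
  expect_error(stability_selection(sim$expr_d0, sim$class_d0, n_iter = 0), "at least 1")
  expect_error(
    stability_selection(sim$expr_d0, sim$class_d0, n_iter = 10, threshold = 1.2),
    "0, 1"
  )
})

test_that("planted day-0 features dominate background selection probabilities", {
  panel <- panel_mouse_names()
  ratios <- vapply(1:8, function(s) {
    sim <- mouse_fixture(n_features = 46, seed = 500 + s)
    st <- stability_selection(sim$expr_d0, sim$class_d0, n_iter = 250, seed = s)
    pi <- setNames(st$pi_hat$pi_hat, st$pi_hat$feature_id)
    mean(pi[panel]) - mean(pi[setdiff(names(pi), panel)])
  }, numeric(1))
  expect_true(all(ratios > 0.3))
})

test_that("all six planted features are selected at small background (fixed seed)", {
  sim <- mouse_fixture(n_features = 26, seed = 1001)
  st <- stability_selection(sim$expr_d0, sim$class_d0, n_iter = 500, seed = 11)
  expect_true(all(panel_mouse_names() %in% st$selected))
})

test_that("pure-noise day-0 data keep average selection probabilities low", {
  # With lambda fixed at 0.1 * lambda_max the fit is deliberately liberal, so
  # baseline selection sits near the filter pass rate (~0.3 here), well below
  # both the planted-feature level (~0.95) and the 0.6 selection threshold.
  # Individual chance-correlated features can still spike at n = 4 + 4, so
  # the average, not the maximum, is the stable null property.
  mean_pi <- vapply(1:10, function(s) {
    sim <- simulate_mouse_null(mouse_sim_spec(n_features = 46, rng_seed = 2000 + s))
    d0 <- sim$samples$sample_id[sim$samples$time == "D0"]
    e0 <- sim$expr[, c("feature_id", d0)]
    cls <- as.character(sim$samples$group[match(d0, sim$samples$sample_id)])
    st <- stability_selection(e0, cls, n_iter = 150, seed = s)
    mean(st$pi_hat$pi_hat)
  }, numeric(1))
  expect_lt(mean(mean_pi), 0.45)
})

test_that("sampled selection probabilities match exhaustive enumeration of the 36 subsamples", {
  sim <- mouse_fixture(n_features = 20, seed = 77)
  m <- as.matrix(sim$expr_d0[-1])
  rownames(m) <- sim$expr_d0$feature_id
  pos_idx <- which(sim$class_d0 == "MPTP")
  neg_idx <- which(sim$class_d0 == "Control")

  # exhaustive: every 2-of-4 x 2-of-4 subsample exactly once
  counts <- setNames(numeric(nrow(m)), rownames(m))
  combos <- combn(4, 2, simplify = FALSE)
  for (a in combos) {
    for (b in combos) {
      sub <- c(pos_idx[a], neg_idx[b])
      Xs <- m[, sub]
      pos <- rep(c(1, 0), each = 2)
      t <- mirsig:::two_class_t(Xs, pos == 1)
      ord <- order(-abs(t), rownames(Xs))[1:20]
      sel <- mirsig:::enet_fixed_lambda(t(Xs[ord, ]), pos, alpha = 0.5, lambda_frac = 0.1)
      counts[sel] <- counts[sel] + 1
    }
  }
  pi_exact <- counts / 36

  st <- stability_selection(sim$expr_d0, sim$class_d0, n_iter = 2000, seed = 5)
  pi_hat <- setNames(st$pi_hat$pi_hat, st$pi_hat$feature_id)[names(pi_exact)]
  mc_se <- sqrt(pmax(pi_exact * (1 - pi_exact), 0.25 / 36) / 2000) * 6
  expect_true(all(abs(pi_hat - pi_exact) < pmax(4 * mc_se, 0.06)))
})

test_that("LOOCV separates strongly shifted day-0 classes and not permuted ones", {
  sim <- mouse_fixture(n_features = 40, seed = 55, d0_group_shift = 3)
  cv <- loocv_elastic_net(sim$expr_d0, sim$class_d0, seed = 6)
  expect_equal(nrow(cv$folds), 8)
  expect_gte(cv$auc, 0.9)

  null_auc <- vapply(1:10, function(s) {
    perm <- withr::with_seed(s, sample(sim$class_d0))
    suppressWarnings(loocv_elastic_net(sim$expr_d0, perm, seed = s)$auc)
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.2)
})

test_that("LOOCV never lets the held-out sample influence filtering or fitting", {
  # leakage oracle: a feature whose only signal lives in the held-out sample
  # must not change that sample's fold. A filter computed on all n samples
  # would rank it first; a correctly blinded filter sees a constant feature.
  m <- withr::with_seed(66, matrix(rnorm(29 * 8), 29, 8))
  rownames(m) <- sprintf("f%02d", 1:29)
  colnames(m) <- paste0("s", 1:8)
  cls <- rep(c("MPTP", "Control"), each = 4)
  leak <- rbind(leaky = rep(0, 8))
  a <- expr_tbl(rbind(m, leak))
  leak["leaky", 3] <- 100 # extreme value in (PD-class) sample 3 only
  b <- expr_tbl(rbind(m, leak))
  cv_a <- loocv_elastic_net(a, cls, filter_k = 10, seed = 7)
  cv_b <- loocv_elastic_net(b, cls, filter_k = 10, seed = 7)
  expect_identical(cv_a$folds$score[3], cv_b$folds$score[3])
  expect_identical(cv_a$folds$alpha[3], cv_b$folds$alpha[3])
})

test_that("selection permutation p is maximal when nothing is selected", {
  sim <- simulate_mouse_null(mouse_sim_spec(n_features = 25, rng_seed = 3001))
  d0 <- sim$samples$sample_id[sim$samples$time == "D0"]
  e0 <- sim$expr[, c("feature_id", d0)]
  cls <- as.character(sim$samples$group[match(d0, sim$samples$sample_id)])
  st <- stability_selection(e0, cls, n_iter = 100, threshold = 0.95, seed = 2)
  if (length(st$selected) == 0) {
    out <- selection_permutation_test(e0, cls, st, B = 100, iter_per_perm = 20, seed = 3)
    expect_equal(out$p_value, 1)
  } else {
    succeed("threshold 0.95 selected features on this draw; covered elsewhere")
  }
})

test_that("selection permutation shifts p toward small values under planted signal", {
  # Permuting labels leaves the liberal baseline selection in place, so the
  # count statistic has a heavy null; planted signal still pushes p low but
  # not to the floor. Assert the distributional shift over a few seeds.
  ps <- vapply(1:4, function(s) {
    sim <- mouse_fixture(n_features = 26, seed = 1000 + s)
    st <- stability_selection(sim$expr_d0, sim$class_d0, n_iter = 300, seed = s)
    out <- selection_permutation_test(
      sim$expr_d0, sim$class_d0, st,
      B = 100, iter_per_perm = 40, seed = s + 50
    )
    expect_equal(out$B, 100)
    out$p_value
  }, numeric(1))
  expect_lt(mean(ps), 0.3)
  expect_lt(min(ps), 0.1)
})

test_that("build_panel assigns directions from the DE contrast and harmonizes names", {
  sim <- mouse_fixture(n_features = 26, seed = 1001)
  de <- suppressWarnings(run_diffexpr(sim$expr, sim$samples))
  st <- stability_selection(sim$expr_d0, sim$class_d0, n_iter = 500, seed = 11)
  panel <- suppressWarnings(build_panel(st, de))
  expect_s3_class(panel, "signature_panel")
  six <- panel[panel$feature_id %in% panel_mouse_names(), ]
  expect_equal(nrow(six), 6)
  expect_true(all(six$direction == "down"))
  expect_identical(
    sort(six$core_name),
    sort(normalize_mirna_name(panel_mouse_names()))
  )
  # selected feature absent from the DE table is an error
  expect_error(build_panel(st, de[de$feature_id != st$selected[1], ]), "missing")
})

test_that("an empty selection yields an empty panel with a warning", {
  sim <- mouse_fixture(n_features = 20, seed = 4)
  de <- run_diffexpr(sim$expr, sim$samples)
  st <- stability_selection(sim$expr_d0, sim$class_d0, n_iter = 50, seed = 5)
  st$selected <- character(0)
  expect_warning(panel <- build_panel(st, de), "empty")
  expect_equal(nrow(panel), 0)
})

test_that("mixed planted directions are labelled by their logFC signs", {
  spec <- mouse_sim_spec(
    n_features = 20,
    planted_down = c("mmu-miR-92b-3p", "mmu-miR-133a-3p"),
    planted_up = c("mmu-miR-7047-5p"),
    planted_panel = c("mmu-miR-92b-3p", "mmu-miR-133a-3p"),
    rng_seed = 12
  )
  sim <- simulate_mouse_experiment(spec)
  de <- run_diffexpr(sim$expr, sim$samples)
  st <- structure(
    list(
      pi_hat = tibble::tibble(
        feature_id = c("mmu-miR-92b-3p", "mmu-miR-7047-5p"), pi_hat = c(0.9, 0.8)
      ),
      selected = c("mmu-miR-92b-3p", "mmu-miR-7047-5p"),
      threshold = 0.6
    ),
    class = "stability_result"
  )
  panel <- build_panel(st, de)
  expect_identical(panel$direction[panel$feature_id == "mmu-miR-92b-3p"], "down")
  expect_identical(panel$direction[panel$feature_id == "mmu-miR-7047-5p"], "up")
})
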