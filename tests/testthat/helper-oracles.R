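# Brute-force oracles and tiny fixtures shared across tests. Every oracle is
# written independently of the implementation it checks.

# Benjamini-Hochberg step-up, computed literally from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# AUC by explicit all-pairs counting, ties 1/2.
auc_pairs_oracle <- function(scores, pos) {
  s1 <- scores[pos]
  s0 <- scores[!pos]
  total <- 0
  for (a in s1) for (b in s0) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(s1) * length(s0))
}

# Youden J maximized by exhaustive scan (positive called when score >= cut).
youden_oracle <- function(scores, pos) {
  cuts <- sort(unique(scores))
  best <- -Inf
  for (c in cuts) {
    sens <- mean(scores[pos] >= c)
    spec <- mean(scores[!pos] < c)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Random expression tibble fixture.
random_expr <- function(n_feat, n_samp, seed = 1, prefix = "f") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp)
    rownames(m) <- sprintf("%s%03d", prefix, seq_len(n_feat))
    colnames(m) <- sprintf("s%02d", seq_len(n_samp))
    expr_tbl(m)
  })
}

# A small mouse experiment and its day-0 slice.
mouse_fixture <- function(n_features = 46, seed = 42, ...) {
  sim <- simulate_mouse_experiment(
    mouse_sim_spec(n_features = n_features, rng_seed = seed, ...)
  )
  d0 <- sim$samples$sample_id[sim$samples$time == "D0"]
  expr_d0 <- sim$expr[, c("feature_id", d0)]
  attr(expr_d0, "expr_scale") <- "log_intensity"
  sim$class_d0 <- as.character(sim$samples$group[match(d0, sim$samples$sample_id)])
  sim$expr_d0 <- expr_d0
  sim
}

panel_mouse_names <- function() mirna_ortholog_reference()$mouse_name

new_panel_for_test <- function(core, dir) {
  mirsig:::new_signature_panel(tibble::tibble(core_name = core, direction = dir))
}
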