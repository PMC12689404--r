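# Orchestration: discovery (mouse) -> panel -> validation (human cohorts),
# with deterministic per-stage seed substreams and optional artifact output.

#' Pipeline configuration
#'
#' Bundles every tunable of the discovery/validation workflow with the
#' published defaults: 5,000 global-test permutations, 2,000 stability
#' iterations and 2,000 selection-null permutations, 5,000 AUC permutations,
#' top-20 univariate filter, alpha grid \{0.1, 0.5, 0.9\}, selection
#' threshold 0.6, FDR cutoff 0.05 and master seed 20250912. Each stochastic
#' stage derives its own sub-stream seed from the master seed, so a config
#' reproduces its outputs exactly.
#'
#' @param mouse A [mouse_sim_spec()] or a path to a delimited mouse
#'   expression matrix (with `mouse_annotation` giving labels).
#' @param mouse_annotation Annotation tibble when `mouse` is a file path.
#' @param cohorts Named list of [cohort_sim_spec()] objects, or lists
#'   `list(path =, dialect =, scale =)` describing files to read.
#' @param B_global,B_selection,B_auc Permutation counts for the global test,
#'   the selection-frequency null, and the AUC test.
#' @param n_stability_iter Stability-selection iterations.
#' @param iter_per_perm Stability iterations inside each selection-null
#'   permutation.
#' @param filter_k Univariate filter size.
#' @param alpha_grid LOOCV elastic-net mixing grid.
#' @param stability_alpha Fixed mixing parameter inside stability selection.
#' @param lambda_frac Penalty fraction of `lambda_max` in stability fits.
#' @param pi_threshold Selection-probability threshold.
#' @param fdr_cutoff Significance cutoff on BH-adjusted q-values.
#' @param run_loocv,run_selection_perm Toggle the LOOCV report and the
#'   selection-frequency permutation null (both part of the full workflow,
#'   but expensive).
#' @param seed Master seed (default 20250912).
#' @param output_dir Optional directory for TSV/JSON artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mouse = mouse_sim_spec(),
                            mouse_annotation = NULL,
                            cohorts = default_cohort_specs(),
                            B_global = 5000,
                            B_selection = 2000,
                            B_auc = 5000,
                            n_stability_iter = 2000,
                            iter_per_perm = 200,
                            filter_k = 20,
                            alpha_grid = c(0.1, 0.5, 0.9),
                            stability_alpha = 0.5,
                            lambda_frac = 0.1,
                            pi_threshold = 0.6,
                            fdr_cutoff = 0.05,
                            run_loocv = TRUE,
                            run_selection_perm = FALSE,
                            seed = 20250912,
                            output_dir = NULL) {
  structure(
    list(
      mouse = mouse, mouse_annotation = mouse_annotation, cohorts = cohorts,
      B_global = B_global, B_selection = B_selection, B_auc = B_auc,
      n_stability_iter = n_stability_iter, iter_per_perm = iter_per_perm,
      filter_k = filter_k, alpha_grid = alpha_grid,
      stability_alpha = stability_alpha, lambda_frac = lambda_frac,
      pi_threshold = pi_threshold, fdr_cutoff = fdr_cutoff,
      run_loocv = run_loocv, run_selection_perm = run_selection_perm,
      seed = seed, output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Default synthetic validation cohorts
#'
#' Three cohorts mirroring the emulated study's shapes: a PBMC-style
#' continuous array cohort (19 PD / 13 Control, prefix labels), an exosome
#' count cohort (46 PD / 30 Control, prefix labels) and an exosome count
#' cohort (50/50, numbering labels).
#'
#' @param panel_effect_sd_units Planted standardized PD shift (default 0.8).
#' @param seed Base seed; each cohort offsets it.
#' @return Named list of [cohort_sim_spec()] objects.
#' @export
default_cohort_specs <- function(panel_effect_sd_units = 0.8, seed = 20250912) {
  list(
    pbmc = cohort_sim_spec(
      n_pd = 19, n_control = 13, platform = "array_continuous",
      label_dialect = "prefix", panel_effect_sd_units = panel_effect_sd_units,
      rng_seed = seed + 101
    ),
    exosome_2022 = cohort_sim_spec(
      n_pd = 46, n_control = 30, platform = "exosome_counts",
      label_dialect = "prefix", panel_effect_sd_units = panel_effect_sd_units,
      rng_seed = seed + 102
    ),
    exosome_2020 = cohort_sim_spec(
      n_pd = 50, n_control = 50, platform = "exosome_counts",
      label_dialect = "numbering", panel_effect_sd_units = panel_effect_sd_units,
      rng_seed = seed + 103
    )
  )
}

resolve_mouse_input <- function(config) {
  if (inherits(config$mouse, "mouse_sim_spec")) {
    simulate_mouse_experiment(config$mouse)
  } else if (is.character(config$mouse)) {
    if (is.null(config$mouse_annotation)) {
      abort("reading mouse data from file requires `mouse_annotation`.")
    }
    list(
      expr = read_expression_matrix(config$mouse, scale = "log_intensity"),
      samples = config$mouse_annotation
    )
  } else {
    abort("`mouse` must be a mouse_sim_spec or a file path.")
  }
}

#' Run the discovery arm (mouse experiment to signature panel)
#'
#' Differential expression of the within-MPTP time contrast, the global
#' permutation test, optional LOOCV performance estimate, stability
#' selection on the day-0 samples, the optional selection-frequency
#' permutation null, and panel assembly. Artifacts (TSV tables and a JSON
#' manifest recording every parameter and sub-seed) are written when the
#' config has an `output_dir`.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `discovery_result`: `de`, `global_test`,
#'   `loocv`, `stability`, `selection_perm`, `panel`, `qc` (PCA), and
#'   `manifest`.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- resolve_mouse_input(config)
  expr <- data$expr
  samples <- data$samples

  qc <- pca_qc(expr, n_top = min(500, nrow(expr)))
  suppressWarnings(hemo <- hemolysis_ratio(expr))

  de <- run_diffexpr(expr, samples, group = "MPTP")
  n_sig <- sum(de$q_value < config$fdr_cutoff)

  gt <- global_permutation_test(
    expr, samples,
    B = config$B_global, mode = "sampled",
    seed = stage_seed(config$seed, "global_test")
  )

  d0 <- samples$sample_id[samples$time == "D0"]
  expr_d0 <- expr[, c("feature_id", d0)]
  attr(expr_d0, "expr_scale") <- expr_scale(expr)
  class_d0 <- as.character(samples$group[match(d0, samples$sample_id)])

  cv <- NULL
  if (isTRUE(config$run_loocv)) {
    cv <- loocv_elastic_net(
      expr_d0, class_d0,
      alpha_grid = config$alpha_grid, filter_k = config$filter_k,
      lambda_frac = config$lambda_frac,
      seed = stage_seed(config$seed, "loocv")
    )
  }

  stab <- stability_selection(
    expr_d0, class_d0,
    n_iter = config$n_stability_iter, subsample_per_class = 2,
    alpha = config$stability_alpha, filter_k = config$filter_k,
    lambda_frac = config$lambda_frac, threshold = config$pi_threshold,
    seed = stage_seed(config$seed, "stability")
  )

  sel_perm <- NULL
  if (isTRUE(config$run_selection_perm)) {
    sel_perm <- selection_permutation_test(
      expr_d0, class_d0, stab,
      B = config$B_selection, iter_per_perm = config$iter_per_perm,
      seed = stage_seed(config$seed, "selection_perm")
    )
  }

  panel <- suppressWarnings(build_panel(stab, de))

  manifest <- list(
    seed = config$seed,
    stage_seeds = list(
      global_test = stage_seed(config$seed, "global_test"),
      loocv = stage_seed(config$seed, "loocv"),
      stability = stage_seed(config$seed, "stability"),
      selection_perm = stage_seed(config$seed, "selection_perm")
    ),
    parameters = config[c(
      "B_global", "B_selection", "B_auc", "n_stability_iter", "iter_per_perm",
      "filter_k", "alpha_grid", "stability_alpha", "lambda_frac",
      "pi_threshold", "fdr_cutoff"
    )],
    n_features = nrow(expr), n_samples = ncol(expr) - 1L,
    n_significant = n_sig,
    package_version = as.character(utils::packageVersion("mirsig"))
  )

  out <- structure(
    list(
      de = de, global_test = gt, loocv = cv, stability = stab,
      selection_perm = sel_perm, panel = panel, qc = qc, hemolysis = hemo,
      manifest = manifest
    ),
    class = "discovery_result"
  )
  if (!is.null(config$output_dir)) write_discovery(out, config$output_dir)
  out
}

write_discovery <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x$de, file.path(dir, "de_results.tsv"))
  readr::write_tsv(x$stability$pi_hat, file.path(dir, "stability_pi_hat.tsv"))
  readr::write_tsv(as_tibble(x$panel), file.path(dir, "panel.tsv"))
  jsonlite::write_json(
    list(
      T_observed = x$global_test$T_observed, p = x$global_test$p_value,
      B = x$global_test$B, mode = x$global_test$mode
    ),
    file.path(dir, "global_test.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    x$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

resolve_cohort_input <- function(spec, panel) {
  if (inherits(spec, "cohort_sim_spec")) {
    sim <- simulate_human_cohort(spec, panel)
    # Re-parse the generated headers through the declared dialect so the
    # label-parsing path is exercised end to end.
    ann <- parse_sample_labels(sim$samples$sample_id, dialect = spec$label_dialect)
    list(expr = sim$expr, annotation = ann)
  } else if (is.list(spec) && !is.null(spec$path)) {
    expr <- read_expression_matrix(spec$path, scale = spec$scale %||% "log_intensity")
    ids <- setdiff(names(expr), "feature_id")
    ann <- parse_sample_labels(ids,
      dialect = spec$dialect %||% "prefix",
      table = spec$table
    )
    list(expr = expr, annotation = ann)
  } else {
    abort("each cohort must be a cohort_sim_spec or list(path=, dialect=, scale=).")
  }
}

#' Run the validation arm over the configured cohorts
#'
#' For every cohort: resolve input (simulate or read), parse labels in the
#' cohort's dialect, then [validate_cohort()] with the configured `B_auc`.
#' Cohorts with zero panel coverage are skipped with an error record rather
#' than failing the run.
#'
#' @param config A [pipeline_config()].
#' @param panel A `signature_panel` (e.g. from [run_discovery()] or
#'   [signature_panel_reference()]).
#' @return An object of class `validation_result`: `summary` (one tibble row
#'   per cohort) and `cohorts` (named list of `roc_result` objects or error
#'   records).
#' @export
run_validation <- function(config, panel) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(panel) || nrow(panel) == 0) {
    abort("cannot validate an empty signature panel.")
  }
  base_seed <- stage_seed(config$seed, "validation")
  results <- imap(config$cohorts, function(spec, name) {
    input <- resolve_cohort_input(spec, panel)
    tryCatch(
      validate_cohort(
        input$expr, input$annotation, panel,
        B = config$B_auc, n_boot = 2000,
        seed = base_seed + match(name, names(config$cohorts)) * 17L
      ),
      error = function(e) structure(list(message = conditionMessage(e)), class = "cohort_error")
    )
  })
  summary <- bind_rows(imap(results, function(r, name) {
    if (inherits(r, "cohort_error")) {
      tibble(
        cohort = name, n = NA_integer_, n_pd = NA_integer_,
        n_control = NA_integer_, auc = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, perm_p = NA_real_, threshold = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_,
        coverage = NA_real_, error = r$message
      )
    } else {
      tibble(
        cohort = name, n = r$n_pd + r$n_control, n_pd = r$n_pd,
        n_control = r$n_control, auc = r$auc, ci_low = r$ci_low,
        ci_high = r$ci_high, perm_p = r$perm_p, threshold = r$threshold,
        sensitivity = r$sensitivity, specificity = r$specificity,
        coverage = r$coverage, error = NA_character_
      )
    }
  }))
  out <- structure(list(summary = summary, cohorts = results), class = "validation_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(summary, file.path(config$output_dir, "validation_summary.tsv"))
  }
  out
}

#' Run discovery and validation end to end
#'
#' [run_discovery()], then [run_validation()] with the discovered panel
#' (falling back to `fallback_panel` with a warning when discovery selects
#' nothing), plus a plain-markdown report when the config has an
#' `output_dir`.
#'
#' @param config A [pipeline_config()].
#' @param fallback_panel Panel to validate when discovery returns an empty
#'   one (default `NULL`: validation is skipped in that case).
#' @return List of class `pipeline_result` with `discovery` and
#'   `validation` (possibly `NULL`).
#' @export
run_all <- function(config, fallback_panel = NULL) {
  disc <- run_discovery(config)
  panel <- disc$panel
  validation <- NULL
  if (nrow(panel) == 0 && !is.null(fallback_panel)) {
    warn("discovery selected no features; validating the fallback panel instead.")
    panel <- fallback_panel
  }
  if (nrow(panel) > 0) {
    validation <- run_validation(config, panel)
  } else {
    warn("no panel to validate; skipping the validation arm.")
  }
  out <- structure(
    list(discovery = disc, validation = validation, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_report(out, config$output_dir)
  out
}

write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  disc <- x$discovery
  lines <- c(
    "# miRNA signature pipeline report",
    "",
    "## Parameters and seeds",
    paste0("- master seed: ", x$config$seed),
    paste0(
      "- stage seeds: ",
      paste(names(disc$manifest$stage_seeds), unlist(disc$manifest$stage_seeds),
        sep = " = ", collapse = ", "
      )
    ),
    paste0(
      "- B (global/selection/AUC): ", x$config$B_global, "/",
      x$config$B_selection, "/", x$config$B_auc,
      "; stability iterations: ", x$config$n_stability_iter,
      "; filter k: ", x$config$filter_k,
      "; pi threshold: ", x$config$pi_threshold,
      "; FDR cutoff: ", x$config$fdr_cutoff
    ),
    "",
    "## Discovery",
    paste0(
      "- significant features (q < ", x$config$fdr_cutoff, "): ",
      disc$manifest$n_significant,
      " (down: ", sum(disc$de$q_value < x$config$fdr_cutoff & disc$de$logFC < 0),
      ", up: ", sum(disc$de$q_value < x$config$fdr_cutoff & disc$de$logFC > 0), ")"
    ),
    paste0(
      "- global permutation test: T = ",
      format(disc$global_test$T_observed, digits = 5),
      ", one-sided p = ", format(disc$global_test$p_value, digits = 4),
      " (B = ", disc$global_test$B, ")"
    ),
    if (!is.null(disc$loocv)) {
      paste0("- LOOCV pooled AUC: ", format(disc$loocv$auc, digits = 3))
    },
    if (!is.null(disc$selection_perm)) {
      paste0(
        "- selection-frequency permutation p: ",
        format(disc$selection_perm$p_value, digits = 4)
      )
    },
    paste0("- panel size: ", nrow(disc$panel)),
    ""
  )
  if (!is.null(x$validation)) {
    lines <- c(
      lines, "## Validation",
      readr::format_tsv(x$validation$summary)
    )
  }
  writeLines(unlist(lines), file.path(dir, "report.md"))
  invisible(dir)
}
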