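#' Specification for a synthetic mouse serum miRNA experiment
#'
#' Describes a 2x2 (group x timepoint) serum miRNA array experiment:
#' `n_features` probes measured on `4 * n_per_cell` samples (Control/MPTP at
#' day 0 and day 5). Per-feature baselines are uniform on
#' `baseline_mean_range` (log2 intensity) with i.i.d. Gaussian noise.
#' Three planted effect sets drive the downstream analyses:
#'
#' * `planted_down` / `planted_up`: features whose day-5 values in the MPTP
#'   group are shifted by `logfc_down` / `logfc_up` (the time effect the
#'   differential-expression contrast estimates);
#' * `planted_panel` (a subset of `planted_down`): features additionally
#'   shifted *down* by `d0_group_shift` in all MPTP samples (day 0 and day
#'   5), making them day-0 discriminative — the signal stability selection
#'   is meant to recover. Applying the shift at both timepoints leaves the
#'   within-group time contrast untouched.
#'
#' Defaults mirror the emulated study: 3,163 probes, 4 replicates per cell,
#' 15 down-regulated features at logFC -2.0 (the first six being the
#' signature miRNAs, which also form the default panel), 2 up-regulated
#' features at logFC +1.4, and a day-0 group shift of magnitude 1.5.
#'
#' @param n_features Number of probes (default 3163).
#' @param n_per_cell Replicates per group x timepoint cell (default 4).
#' @param baseline_mean_range Range of per-feature baseline means, log2
#'   (default `c(4, 12)`).
#' @param noise_sd Residual SD in log2 units (default 0.5).
#' @param planted_down,planted_up,planted_panel Character vectors of feature
#'   IDs; `NULL` uses the defaults described above. `planted_panel` must be a
#'   subset of `planted_down`.
#' @param logfc_down,logfc_up Planted day-5 effects (defaults -2.0, +1.4).
#' @param d0_group_shift Magnitude of the day-0 MPTP-vs-Control shift applied
#'   (negatively) to panel features (default 1.5).
#' @param rng_seed Seed for generation (default 20250912).
#' @return An object of class `mouse_sim_spec`.
#' @export
mouse_sim_spec <- function(n_features = 3163,
                           n_per_cell = 4,
                           baseline_mean_range = c(4, 12),
                           noise_sd = 0.5,
                           planted_down = NULL,
                           planted_up = NULL,
                           planted_panel = NULL,
                           logfc_down = -2.0,
                           logfc_up = 1.4,
                           d0_group_shift = 1.5,
                           rng_seed = 20250912) {
  if (n_per_cell < 2) abort("n_per_cell must be at least 2.")
  if (noise_sd < 0) abort("noise_sd must be non-negative.")
  panel6 <- mirna_ortholog_reference()$mouse_name
  if (is.null(planted_down)) {
    planted_down <- c(panel6, sprintf("mmu-miR-sim%04d-3p", 1:9))
  }
  if (is.null(planted_up)) {
    planted_up <- c("mmu-miR-7047-5p", "mmu-miR-6937-5p")
  }
  if (is.null(planted_panel)) {
    planted_panel <- intersect(panel6, planted_down)
  }
  if (length(intersect(planted_down, planted_up)) > 0) {
    abort("planted_down and planted_up must be disjoint.")
  }
  if (!all(planted_panel %in% planted_down)) {
    abort("planted_panel must be a subset of planted_down.")
  }
  n_planted <- length(planted_down) + length(planted_up)
  if (n_features < n_planted) {
    abort("n_features is smaller than the number of planted features.")
  }
  feature_ids <- c(
    planted_down, planted_up,
    sprintf("mmu-miR-sim%04d-5p", seq_len(n_features - n_planted) + 100)
  )
  if (anyDuplicated(feature_ids)) abort("feature IDs must be unique.")
  structure(
    list(
      n_features = n_features, n_per_cell = n_per_cell,
      baseline_mean_range = baseline_mean_range, noise_sd = noise_sd,
      feature_ids = feature_ids,
      planted_down = planted_down, planted_up = planted_up,
      planted_panel = planted_panel,
      logfc_down = logfc_down, logfc_up = logfc_up,
      d0_group_shift = d0_group_shift, rng_seed = rng_seed
    ),
    class = "mouse_sim_spec"
  )
}

#' Simulate the 2x2 mouse serum experiment
#'
#' @param spec A [mouse_sim_spec()].
#' @return A list with `expr` (log-intensity expression tibble, features x
#'   samples) and `samples` (tibble with `sample_id`, `group`, `time`).
#' @export
#' @examples
#' sim <- simulate_mouse_experiment(mouse_sim_spec(n_features = 50))
#' dim(sim$expr)
simulate_mouse_experiment <- function(spec) {
  stopifnot(inherits(spec, "mouse_sim_spec"))
  n <- spec$n_per_cell
  groups <- rep(c("Control", "MPTP"), each = 2 * n)
  times <- rep(rep(c("D0", "D5"), each = n), times = 2)
  sample_id <- paste(groups, times, rep(seq_len(n), times = 4), sep = "_")
  ids <- spec$feature_ids

  m <- with_seed_if(spec$rng_seed, {
    mu <- runif(spec$n_features, spec$baseline_mean_range[1], spec$baseline_mean_range[2])
    mu + matrix(
      rnorm(spec$n_features * length(sample_id), 0, spec$noise_sd),
      spec$n_features, length(sample_id)
    )
  })
  rownames(m) <- ids
  colnames(m) <- sample_id

  mptp_d5 <- groups == "MPTP" & times == "D5"
  mptp <- groups == "MPTP"
  m[match(spec$planted_down, ids), mptp_d5] <-
    m[match(spec$planted_down, ids), mptp_d5] + spec$logfc_down
  m[match(spec$planted_up, ids), mptp_d5] <-
    m[match(spec$planted_up, ids), mptp_d5] + spec$logfc_up
  if (length(spec$planted_panel) > 0) {
    m[match(spec$planted_panel, ids), mptp] <-
      m[match(spec$planted_panel, ids), mptp] - spec$d0_group_shift
  }

  list(
    expr = expr_tbl(m, scale = "log_intensity"),
    samples = tibble(
      sample_id = sample_id,
      group = factor(groups, levels = c("Control", "MPTP")),
      time = factor(times, levels = c("D0", "D5"))
    )
  )
}

#' Simulate a null mouse experiment (no planted effects)
#'
#' Identical to [simulate_mouse_experiment()] with every planted effect set
#' empty; used to calibrate type-I error of the downstream tests.
#'
#' @param spec A [mouse_sim_spec()]; its planted sets are ignored.
#' @return As [simulate_mouse_experiment()].
#' @export
simulate_mouse_null <- function(spec) {
  stopifnot(inherits(spec, "mouse_sim_spec"))
  spec$planted_down <- character(0)
  spec$planted_up <- character(0)
  spec$planted_panel <- character(0)
  simulate_mouse_experiment(spec)
}

#' Specification for a synthetic human validation cohort
#'
#' Describes a case/control cohort on one of two platforms: array-like
#' continuous log2 intensities (`"array_continuous"`) or exosome small-RNA
#' sequencing counts (`"exosome_counts"`, negative binomial with per-sample
#' library sizes). Panel members are shifted in PD samples by
#' `panel_effect_sd_units` standard deviations on the log2 scale (down
#' members negatively, up members positively); background features are
#' exchangeable noise. Column headers follow one of the two label dialects
#' [parse_sample_labels()] understands.
#'
#' @param n_pd,n_control Class sizes (each >= 2).
#' @param platform `"array_continuous"` or `"exosome_counts"`.
#' @param label_dialect `"prefix"` (`PD_01`, `Control_01`, ...) or
#'   `"numbering"` (`S001`...; PD numbered from 1, controls from 51 — class
#'   sizes must be <= 50 each).
#' @param panel_effect_sd_units Standardized PD shift on panel members
#'   (default 0.8).
#' @param n_background_features Background features (default 500).
#' @param nb_dispersion Negative-binomial dispersion for the count platform
#'   (default 0.3).
#' @param library_size_range Range of per-sample total counts (count
#'   platform; default `c(2e5, 1e6)`).
#' @param rng_seed Seed (default 20250912).
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_pd,
                            n_control,
                            platform = c("array_continuous", "exosome_counts"),
                            label_dialect = c("prefix", "numbering"),
                            panel_effect_sd_units = 0.8,
                            n_background_features = 500,
                            nb_dispersion = 0.3,
                            library_size_range = c(2e5, 1e6),
                            rng_seed = 20250912) {
  platform <- match.arg(platform)
  label_dialect <- match.arg(label_dialect)
  if (n_pd < 2 || n_control < 2) abort("each class needs at least 2 samples.")
  if (!is.finite(panel_effect_sd_units)) abort("panel_effect_sd_units must be finite.")
  if (nb_dispersion <= 0) abort("nb_dispersion must be positive.")
  if (label_dialect == "numbering" && (n_pd > 50 || n_control > 50)) {
    abort("numbering dialect supports at most 50 samples per class (PD 001-050, Control 051-100).")
  }
  structure(
    list(
      n_pd = n_pd, n_control = n_control, platform = platform,
      label_dialect = label_dialect,
      panel_effect_sd_units = panel_effect_sd_units,
      n_background_features = n_background_features,
      nb_dispersion = nb_dispersion,
      library_size_range = library_size_range,
      rng_seed = rng_seed
    ),
    class = "cohort_sim_spec"
  )
}

#' Simulate a human validation cohort for a signature panel
#'
#' @param spec A [cohort_sim_spec()].
#' @param panel A signature panel (e.g. [signature_panel_reference()] or the
#'   output of [build_panel()]); its core names become cohort features.
#' @return A list with `expr` (expression tibble; log intensities or raw
#'   counts per `spec$platform`) and `samples` (annotation tibble with
#'   `sample_id`, `class`, `label_source`).
#' @export
simulate_human_cohort <- function(spec, panel) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (is.null(panel) || nrow(panel) == 0) abort("`panel` must be non-empty.")
  n_pd <- spec$n_pd
  n_ctl <- spec$n_control

  if (spec$label_dialect == "prefix") {
    sample_id <- c(sprintf("PD_%02d", seq_len(n_pd)), sprintf("Control_%02d", seq_len(n_ctl)))
  } else {
    sample_id <- sprintf("S%03d", c(seq_len(n_pd), 50 + seq_len(n_ctl)))
  }
  cls <- c(rep("PD", n_pd), rep("Control", n_ctl))

  feature_ids <- c(
    panel$core_name,
    sprintf("hsa-mir-sim%04d", seq_len(spec$n_background_features))
  )
  n_feat <- length(feature_ids)
  n_samp <- length(sample_id)
  is_pd <- cls == "PD"
  effect <- numeric(n_feat)
  effect[seq_len(nrow(panel))] <-
    ifelse(panel$direction == "down", -1, 1) * spec$panel_effect_sd_units

  out <- with_seed_if(spec$rng_seed, {
    base <- runif(n_feat, 4, 12)
    latent <- base + matrix(rnorm(n_feat * n_samp), n_feat, n_samp)
    latent[, is_pd] <- latent[, is_pd] + effect
    if (spec$platform == "array_continuous") {
      latent
    } else {
      lib <- runif(n_samp, spec$library_size_range[1], spec$library_size_range[2])
      p <- 2^latent
      p <- sweep(p, 2, colSums(p), "/")
      mu <- sweep(p, 2, lib, "*")
      matrix(
        rnbinom(n_feat * n_samp, mu = mu, size = 1 / spec$nb_dispersion),
        n_feat, n_samp
      )
    }
  })
  rownames(out) <- feature_ids
  colnames(out) <- sample_id

  list(
    expr = expr_tbl(
      out,
      scale = if (spec$platform == "array_continuous") "log_intensity" else "raw_counts"
    ),
    samples = tibble(
      sample_id = sample_id,
      class = factor(cls, levels = c("Control", "PD")),
      label_source = "explicit"
    )
  )
}
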