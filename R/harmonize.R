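#' Normalize miRNA identifiers to a cross-species core name
#'
#' Mature miRNA names differ across platforms and species in case, species
#' prefix and arm suffix. This maps every identifier to a canonical "core"
#' form so mouse-derived panels can be matched against human data: names are
#' lower-cased, the mouse prefix (`mmu-`) is replaced by the human one
#' (`hsa-`), a missing species prefix is assumed human, and a trailing
#' `-3p`/`-5p` arm suffix is stripped. Identifiers from other species
#' (e.g. viral `ebv-` entries carried on arrays) cannot be harmonized and are
#' returned as `NA` with a warning, to be excluded upstream.
#'
#' The mapping is idempotent: applying it to its own output is a no-op.
#'
#' @param name Character vector of miRNA identifiers.
#' @return Character vector of core names (`"hsa-mir-92b"` style); `NA` for
#'   excluded (non-human/non-mouse) identifiers.
#' @export
#' @examples
#' normalize_mirna_name(c("mmu-miR-92b-3p", "hsa-miR-326", "miR-133a-3p"))
normalize_mirna_name <- function(name) {
  if (length(name) == 0) return(character(0))
  if (!is.character(name)) name <- as.character(name)
  if (any(is.na(name) | trimws(name) == "")) {
    abort("miRNA names must be non-empty strings.")
  }
  x <- tolower(trimws(name))

  has_species <- grepl("^[a-z]{2,6}-(mir|let)(-|$)", x)
  bare <- grepl("^(mir|let)(-|$)", x)
  x[bare] <- paste0("hsa-", x[bare])
  x[has_species] <- sub("^mmu-", "hsa-", x[has_species])

  species <- sub("^([a-z]{2,6})-(mir|let).*$", "\\1", x)
  foreign <- (has_species | bare) & species != "hsa"
  unparseable <- !(has_species | bare)
  excluded <- foreign | unparseable
  if (any(excluded)) {
    warn(paste0(
      "excluded ", sum(excluded), " identifier(s) that are not human/mouse miRNA names: ",
      paste(head(unique(name[excluded]), 5), collapse = ", "),
      if (length(unique(name[excluded])) > 5) ", ..." else ""
    ))
  }

  x <- sub("-(3p|5p)$", "", x)
  x[excluded] <- NA_character_
  x
}

#' Collapse probe-level rows to core miRNA names
#'
#' When several probes map to the same core miRNA name, their expression
#' values are averaged (arithmetic mean on the stored scale, per sample).
#'
#' @param expr Expression tibble (see [expr_tbl()]).
#' @param probe_map Optional tibble with columns `probe_id` and `core_name`
#'   mapping features to core names. When `NULL`, core names are derived with
#'   [normalize_mirna_name()].
#' @param unmapped What to do with features that have no core mapping:
#'   `"drop"` (default) or `"error"`.
#' @return Expression tibble with one row per core name, same scale.
#' @export
collapse_probes <- function(expr, probe_map = NULL, unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  m <- as_expr_matrix(expr)
  if (is.null(probe_map)) {
    core <- suppressWarnings(normalize_mirna_name(rownames(m)))
  } else {
    if (!all(c("probe_id", "core_name") %in% names(probe_map)) || nrow(probe_map) == 0) {
      abort("`probe_map` must be a non-empty table with probe_id and core_name columns.")
    }
    core <- probe_map$core_name[match(rownames(m), probe_map$probe_id)]
  }
  bad <- is.na(core)
  if (any(bad)) {
    if (unmapped == "error") {
      abort(paste0(
        "features without a core mapping: ",
        paste(head(rownames(m)[bad], 5), collapse = ", ")
      ))
    }
    m <- m[!bad, , drop = FALSE]
    core <- core[!bad]
  }
  if (nrow(m) == 0) abort("no features left after applying the core-name mapping.")
  groups <- factor(core, levels = unique(core))
  # group means per sample via an indicator matrix (fast and exact)
  ind <- outer(levels(groups), as.character(groups), "==") * 1
  out <- (ind %*% m) / rowSums(ind)
  rownames(out) <- levels(groups)
  expr_tbl(out, scale = expr_scale(expr))
}

#' Extract the seed region of a mature miRNA sequence
#'
#' The seed is nucleotides 2-8 (1-based, inclusive) of the mature sequence:
#' seven nucleotides, the primary determinant of target recognition and the
#' natural unit for cross-species comparability.
#'
#' @param sequence Character vector of RNA sequences (alphabet A/C/G/U,
#'   length >= 8; case-insensitive).
#' @return Character vector of 7-nt seeds (upper case).
#' @export
#' @examples
#' extract_seed("UAUUGCACUCGUCCCGGCCUCC") # "AUUGCAC"
extract_seed <- function(sequence) {
  if (length(sequence) == 0) return(character(0))
  s <- toupper(as.character(sequence))
  if (any(is.na(s))) abort("sequences must not be NA.")
  if (any(nchar(s) < 8)) {
    abort(paste0(
      "sequences shorter than 8 nt: ",
      paste(head(sequence[nchar(s) < 8], 5), collapse = ", ")
    ))
  }
  bad <- grepl("[^ACGU]", s)
  if (any(bad)) {
    abort(paste0(
      "sequences with characters outside A/C/G/U: ",
      paste(head(sequence[bad], 5), collapse = ", ")
    ))
  }
  substr(s, 2, 8)
}

#' Compare mouse/human ortholog sequences
#'
#' Fills in seed regions, seed-match and full-identity flags for a table of
#' mouse/human mature sequence pairs, recomputing everything from the
#' sequences themselves.
#'
#' @param records Tibble with at least `mouse_seq` and `human_seq` columns.
#' @return The input tibble with (re)computed columns `seed_mouse`,
#'   `seed_human`, `seed_match` and `full_identity`, and an attribute
#'   `summary` holding `n_full_identity`, `n_seed_match`, `n_total`.
#' @export
#' @examples
#' cmp <- compare_orthologs(mirna_ortholog_reference())
#' attr(cmp, "summary")
compare_orthologs <- function(records) {
  if (!all(c("mouse_seq", "human_seq") %in% names(records))) {
    abort("`records` must contain mouse_seq and human_seq columns.")
  }
  out <- records %>%
    mutate(
      seed_mouse = extract_seed(.data$mouse_seq),
      seed_human = extract_seed(.data$human_seq),
      seed_match = .data$seed_mouse == .data$seed_human,
      full_identity = .data$mouse_seq == .data$human_seq
    )
  attr(out, "summary") <- list(
    n_full_identity = sum(out$full_identity),
    n_seed_match = sum(out$seed_match),
    n_total = nrow(out)
  )
  out
}
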