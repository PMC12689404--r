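#' Reference sequence table for the six-miRNA signature
#'
#' Returns the published cross-species comparison of the six signature
#' miRNAs: mouse and human mature names, mature sequences, the printed seed
#' regions (nucleotides 2-8) and seed-match calls. Five of the six mature
#' sequences are identical between species; miR-326 is represented by
#' different arms (mouse 5p, human without arm suffix) and is the sole seed
#' mismatch.
#'
#' The printed seed columns are carried verbatim so that seed extraction and
#' ortholog comparison can be checked against them; [compare_orthologs()]
#' recomputes seeds and identity flags from the sequences alone.
#'
#' @return A tibble with one row per signature miRNA and columns
#'   `mouse_name`, `human_name`, `mouse_seq`, `human_seq`, `seed_mouse`,
#'   `seed_human`, `seed_match`, `note`.
#' @export
#' @examples
#' mirna_ortholog_reference()
mirna_ortholog_reference <- function() {
  tibble(
    mouse_name = c(
      "mmu-miR-92b-3p", "mmu-miR-133a-3p", "mmu-miR-326-5p",
      "mmu-miR-125b-5p", "mmu-miR-148a-3p", "mmu-miR-30b-5p"
    ),
    human_name = c(
      "hsa-miR-92b-3p", "hsa-miR-133a-3p", "hsa-miR-326",
      "hsa-miR-125b-5p", "hsa-miR-148a-3p", "hsa-miR-30b-5p"
    ),
    mouse_seq = c(
      "UAUUGCACUCGUCCCGGCCUCC",
      "UUUGGUCCCCUUCAACCAGCUG",
      "GGGGGCAGGGCCUUUGUGAAGGCG",
      "UCCCUGAGACCCUAACUUGUGA",
      "UCAGUGCACUACAGAACUUUGU",
      "UGUAAACAUCCUACACUCAGCU"
    ),
    human_seq = c(
      "UAUUGCACUCGUCCCGGCCUCC",
      "UUUGGUCCCCUUCAACCAGCUG",
      "CCUCUGGGCCCUUCCUCCAG",
      "UCCCUGAGACCCUAACUUGUGA",
      "UCAGUGCACUACAGAACUUUGU",
      "UGUAAACAUCCUACACUCAGCU"
    ),
    seed_mouse = c("AUUGCAC", "UUGGUCC", "GGGGCAG", "CCCUGAG", "CAGUGCA", "GUAAACA"),
    seed_human = c("AUUGCAC", "UUGGUCC", "CUCUGGG", "CCCUGAG", "CAGUGCA", "GUAAACA"),
    seed_match = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    note = c(
      "Identical", "Identical", "Not identical",
      "Identical", "Identical", "Identical"
    )
  )
}

#' The six-miRNA signature as a scoring panel
#'
#' Builds a [signature panel][build_panel] from the published six-miRNA
#' signature: all members are down-regulated (lower expression in disease),
#' with core names harmonized across species.
#'
#' @return A `signature_panel` tibble with columns `core_name`, `direction`,
#'   `mouse_name`, `human_name`.
#' @export
#' @examples
#' signature_panel_reference()
signature_panel_reference <- function() {
  ref <- mirna_ortholog_reference()
  out <- tibble(
    core_name = normalize_mirna_name(ref$mouse_name),
    direction = "down",
    mouse_name = ref$mouse_name,
    human_name = ref$human_name
  )
  new_signature_panel(out)
}

new_signature_panel <- function(x) {
  stopifnot(all(c("core_name", "direction") %in% names(x)))
  if (anyDuplicated(x$core_name)) abort("panel core names must be unique.")
  if (!all(x$direction %in% c("up", "down"))) {
    abort("panel direction must be 'up' or 'down'.")
  }
  class(x) <- c("signature_panel", class(x))
  x
}

#' Write the ortholog reference table to a tab-delimited file
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ortholog_reference <- function(path) {
  readr::write_tsv(mirna_ortholog_reference(), path)
  invisible(path)
}
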