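#' Read a ligand-receptor pair table
#'
#' CSV with columns `pair_id`, `ligand`, `receptor`, `pathway`. Multi-subunit
#' ligands/receptors are "+"-joined on disk (e.g. `ITGA4+ITGB1`) and stored
#' as list-columns of uppercase symbol vectors.
#'
#' @param csv_path Path to the CSV.
#' @return A tibble of class `lr_database` with list-columns
#'   `ligand_subunits` and `receptor_subunits`.
#' @export
load_lr_database <- function(csv_path) {
  df <- readr::read_csv(csv_path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("pair_id", "ligand", "receptor", "pathway")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste("ligand-receptor table missing columns:", paste(missing, collapse = ", ")),
          class = "trtniche_format_error")
  }
  lr_database(df$pair_id, df$ligand, df$receptor, df$pathway)
}

#' Construct a ligand-receptor database from "+"-joined subunit strings
#'
#' @param pair_id Unique pair identifiers.
#' @param ligand,receptor "+"-joined subunit gene symbols.
#' @param pathway Pathway label per pair.
#' @return An `lr_database` tibble.
#' @export
lr_database <- function(pair_id, ligand, receptor, pathway) {
  split_subunits <- function(x, what) {
    parts <- strsplit(as.character(x), "+", fixed = TRUE)
    parts <- lapply(parts, function(p) toupper(trimws(p)))
    empty <- vapply(parts, function(p) length(p) == 0L || any(!nzchar(p)) || anyNA(p), TRUE)
    if (any(empty)) {
      abort(sprintf("empty %s subunit in pair '%s'", what, pair_id[which(empty)[1]]),
            class = "trtniche_format_error")
    }
    parts
  }
  if (anyDuplicated(pair_id)) {
    abort("duplicate pair_id", class = "trtniche_validation_error")
  }
  out <- tibble::tibble(
    pair_id = as.character(pair_id),
    ligand_subunits = split_subunits(ligand, "ligand"),
    receptor_subunits = split_subunits(receptor, "receptor"),
    pathway = as.character(pathway)
  )
  class(out) <- c("lr_database", class(out))
  out
}

#' Write a ligand-receptor database to CSV
#'
#' @param lrdb An `lr_database`.
#' @param csv_path Output path.
#' @return Invisibly, the input.
#' @export
write_lr_database <- function(lrdb, csv_path) {
  df <- tibble::tibble(
    pair_id = lrdb$pair_id,
    ligand = vapply(lrdb$ligand_subunits, paste, "", collapse = "+"),
    receptor = vapply(lrdb$receptor_subunits, paste, "", collapse = "+"),
    pathway = lrdb$pathway
  )
  readr::write_csv(df, csv_path)
  invisible(lrdb)
}

#' Default ligand-receptor database
#'
#' The pairs relevant to the macrophage to tumor-reactive T cell axis:
#' osteopontin (SPP1) and fibronectin (FN1) ligands meeting CD44 and the
#' ITGA4_ITGB1 / ITGA4_ITGB7 integrin complexes, plus TGF-beta and IL-6
#' pairs as additional pathways.
#'
#' @return An `lr_database` tibble.
#' @export
default_lr_database <- function() {
  lr_database(
    pair_id = c("SPP1_CD44", "SPP1_ITGA4_ITGB1",
                "FN1_CD44", "FN1_ITGA4_ITGB1", "FN1_ITGA4_ITGB7",
                "TGFB1_TGFBR1_TGFBR2", "IL6_IL6R"),
    ligand = c("SPP1", "SPP1", "FN1", "FN1", "FN1", "TGFB1", "IL6"),
    receptor = c("CD44", "ITGA4+ITGB1", "CD44", "ITGA4+ITGB1", "ITGA4+ITGB7",
                 "TGFBR1+TGFBR2", "IL6R"),
    pathway = c("SPP1", "SPP1", "FN1", "FN1", "FN1", "TGFb", "IL6")
  )
}
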