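#' Gene set collection
#'
#' A named list of gene-symbol vectors with per-set descriptions. Symbols are
#' uppercased and deduplicated within a set; empty sets and duplicate names
#' are rejected.
#'
#' @param sets Named list of character vectors.
#' @param description Optional named character vector of descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("all gene sets must be named", class = "trtniche_validation_error")
  }
  if (anyDuplicated(names(sets))) {
    abort("duplicate gene set names", class = "trtniche_validation_error")
  }
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0L)) {
    abort("empty gene set", class = "trtniche_validation_error")
  }
  if (is.null(description)) {
    description <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 description = description[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then gene symbols.
#' Symbols are case-folded to uppercase and deduplicated per set.
#'
#' @param gmt_path Path to a GMT file.
#' @return A `gene_set_collection`.
#' @export
load_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]),
          class = "trtniche_format_error")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  desc <- setNames(vapply(fields, `[[`, "", 2L), names(sets))
  gene_set_collection(sets, desc)
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set_collection`.
#' @param gmt_path Output path.
#' @return Invisibly, the input.
#' @export
write_gene_sets <- function(sets, gmt_path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, sets$description[[nm]], sets$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, gmt_path)
  invisible(sets)
}
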