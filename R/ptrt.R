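#' Classify potentially tumor-reactive T (pTRT) cells
#'
#' A CD8 T cell is called pTRT when its z-normalized enrichment score
#' reaches `cutoff_z` in at least `min_sets` signatures — the stringent
#' multi-signature rule. Only CD8 T cells carry calls; `NA` (undefined)
#' sets are ignored both in the count and in the `min_sets` default.
#'
#' @param scores A z-normalized `score_matrix` over the pTRT signatures.
#' @param annotation Cell annotation tibble (needs `cell_id`, `coarse_type`).
#' @param cutoff_z Z-score cutoff (default 2).
#' @param min_sets Minimum number of signatures passed; default
#'   `ceiling(0.1 * n_sets)`.
#' @return Tibble of class `ptrt_calls`: `cell_id`, `is_ptrt`,
#'   `n_sets_passed`, `cutoff_z`, `min_sets`.
#' @export
classify_ptrt <- function(scores, annotation, cutoff_z = 2, min_sets = NULL) {
  stopifnot(inherits(scores, "score_matrix"))
  if (is.null(scores$z)) abort("scores must be z-normalized first")
  defined <- colSums(is.na(scores$z)) < nrow(scores$z)
  n_sets <- sum(defined)
  if (is.null(min_sets)) min_sets <- ceiling(0.1 * n_sets)
  cd8 <- annotation$cell_id[annotation$coarse_type == "CD8T"]
  cd8 <- intersect(scores$cell_ids, cd8)
  if (length(cd8) == 0L) {
    warn("no CD8 T cells among scored cells; returning empty call table")
    out <- tibble::tibble(cell_id = character(), is_ptrt = logical(),
                          n_sets_passed = integer(),
                          cutoff_z = numeric(), min_sets = integer())
    return(structure(out, class = c("ptrt_calls", class(out))))
  }
  z <- scores$z[match(cd8, scores$cell_ids), defined, drop = FALSE]
  n_pass <- rowSums(z >= cutoff_z, na.rm = TRUE)
  out <- tibble::tibble(cell_id = cd8, is_ptrt = n_pass >= min_sets,
                        n_sets_passed = as.integer(n_pass),
                        cutoff_z = cutoff_z, min_sets = as.integer(min_sets))
  structure(out, class = c("ptrt_calls", class(out)))
}

#' Per-patient, per-tissue pTRT frequency
#'
#' Frequency of pTRT calls among CD8 T cells for every (patient, tissue)
#' cell; tissues without scored CD8 T cells get an `NA` frequency row. The
#' cohort-level summary (mean of per-patient fractions per tissue) is
#' available via [summarize_ptrt_frequency()].
#'
#' @param calls A `ptrt_calls` tibble.
#' @param annotation Cell annotation tibble.
#' @return Tibble of class `ptrt_frequency`: `patient`, `tissue`, `n_cd8`,
#'   `n_ptrt`, `frequency`.
#' @export
tissue_ptrt_frequency <- function(calls, annotation) {
  joined <- dplyr::inner_join(tibble::as_tibble(calls), annotation, by = "cell_id")
  out <- joined |>
    dplyr::group_by(.data$patient, .data$tissue) |>
    dplyr::summarise(n_cd8 = dplyr::n(), n_ptrt = sum(.data$is_ptrt),
                     .groups = "drop") |>
    tidyr::complete(patient = unique(annotation$patient),
                    tissue = unique(annotation$tissue),
                    fill = list(n_cd8 = 0L, n_ptrt = 0L)) |>
    dplyr::mutate(frequency = ifelse(.data$n_cd8 > 0,
                                     .data$n_ptrt / .data$n_cd8, NA_real_))
  structure(out, class = c("ptrt_frequency", class(out)))
}

#' Cohort-level pTRT frequency per tissue
#'
#' @param freq A `ptrt_frequency` tibble.
#' @return Tibble with `tissue`, `mean_frequency` (mean of defined
#'   per-patient fractions), `n_patients`.
#' @export
summarize_ptrt_frequency <- function(freq) {
  freq |>
    dplyr::filter(!is.na(.data$frequency)) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(mean_frequency = mean(.data$frequency),
                     n_patients = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_frequency))
}

#' Cluster composition of pTRT cells per tissue
#'
#' Within each tissue, the fraction of pTRT cells falling in each CD8 T cell
#' cluster; fractions sum to 1 wherever any pTRT cell is present.
#'
#' @param calls A `ptrt_calls` tibble.
#' @param annotation Cell annotation tibble with `cluster` labels.
#' @return Tibble of class `ptrt_composition`: `tissue`, `cluster`,
#'   `n_ptrt`, `fraction_of_ptrt`.
#' @export
cluster_composition <- function(calls, annotation) {
  joined <- dplyr::inner_join(tibble::as_tibble(calls), annotation, by = "cell_id")
  out <- joined |>
    dplyr::filter(.data$is_ptrt) |>
    dplyr::count(.data$tissue, .data$cluster, name = "n_ptrt") |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(fraction_of_ptrt = .data$n_ptrt / sum(.data$n_ptrt)) |>
    dplyr::ungroup()
  structure(out, class = c("ptrt_composition", class(out)))
}
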