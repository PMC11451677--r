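#' Per-patient pseudobulk mean of one gene
#'
#' Mean lognorm expression over a patient's cells of one tissue, optionally
#' restricted to one coarse cell type (e.g. SPP1 by macrophages). The mean
#' of lognorm values (not a count sum) keeps library-size differences
#' between patients from masquerading as biology. Patients without any
#' filtered cell are omitted with a warning.
#'
#' @param expr An `expr_matrix` (lognorm layer).
#' @param annotation Cell annotation tibble.
#' @param tissue Tissue compartment.
#' @param gene Gene symbol.
#' @param cell_filter Optional coarse type(s) to restrict to.
#' @return Tibble `patient`, `tissue`, `gene`, `cell_filter`, `mean_expr`,
#'   `n_cells`.
#' @export
pseudobulk_mean <- function(expr, annotation, tissue, gene, cell_filter = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  gene <- toupper(gene)
  if (!gene %in% expr$gene_ids) abort(sprintf("gene '%s' not measured", gene))
  ann <- annotation[annotation$tissue == tissue &
                      annotation$cell_id %in% expr$cell_ids, ]
  if (!is.null(cell_filter)) ann <- ann[ann$coarse_type %in% cell_filter, ]
  dropped <- setdiff(unique(annotation$patient), unique(ann$patient))
  if (length(dropped)) {
    warn(sprintf("%d patient(s) without cells after filtering: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  vals <- expr$values[ann$cell_id, gene]
  ann |>
    dplyr::mutate(value = vals) |>
    dplyr::group_by(.data$patient) |>
    dplyr::summarise(mean_expr = mean(.data$value), n_cells = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(tissue = tissue, gene = gene,
                  cell_filter = paste(cell_filter %||% "all", collapse = "+")) |>
    dplyr::relocate("patient", "tissue", "cell_filter", "gene")
}

#' Cross-compartment correlation between per-patient measures
#'
#' Ordinary least squares plus Pearson correlation over the patients shared
#' by the two tables (simple linear regression, the figure-legend model for
#' the cytokine-to-FN1/SPP1 panels).
#'
#' @param xs,ys Tibbles with `patient` and `mean_expr` columns (from
#'   [pseudobulk_mean()]), or named numeric vectors keyed by patient.
#' @param x_label,y_label Axis labels stored on the result.
#' @return An object of class `xcorr` wrapping the `lm` fit; use `tidy()`
#'   for coefficients and `glance()` for r / slope / p-value.
#' @export
cross_compartment_correlation <- function(xs, ys, x_label = "x", y_label = "y") {
  as_named <- function(v) {
    if (is.data.frame(v)) setNames(v$mean_expr, v$patient) else v
  }
  xv <- as_named(xs); yv <- as_named(ys)
  shared <- intersect(names(xv), names(yv))
  if (length(shared) < 3) abort("fewer than 3 shared patients")
  df <- tibble::tibble(patient = shared, x = unname(xv[shared]),
                       y = unname(yv[shared]))
  fit <- lm(y ~ x, data = df)
  structure(list(data = df, fit = fit,
                 r = cor(df$x, df$y), n = nrow(df),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = summary(fit)$coefficients[2, 2],
                 p_value = summary(fit)$coefficients[2, 4],
                 x_label = x_label, y_label = y_label),
            class = "xcorr")
}

#' @export
print.xcorr <- function(x, ...) {
  cat(sprintf("<xcorr> %s ~ %s: r = %.3f, slope = %.3f (SE %.3f), p = %.3g, n = %d\n",
              x$y_label, x$x_label, x$r, x$slope, x$slope_se, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.xcorr <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
                 statistic = co[, 3], p.value = co[, 4])
}

#' @export
glance.xcorr <- function(x, ...) {
  tibble::tibble(x_label = x$x_label, y_label = x$y_label, n = x$n,
                 r = x$r, r.squared = x$r^2, slope = x$slope,
                 intercept = x$intercept, slope_se = x$slope_se,
                 p.value = x$p_value)
}

#' Paired per-patient expression comparison between two tissues
#'
#' Paired t-test on per-patient pseudobulk means of one gene in two
#' compartments (e.g. fibronectin in MT versus PT); patients missing either
#' compartment are excluded from the pair set.
#'
#' @param expr An `expr_matrix` (lognorm layer).
#' @param annotation Cell annotation tibble.
#' @param gene Gene symbol.
#' @param tissue_a,tissue_b Compartments to compare (A minus B).
#' @param cell_filter Optional coarse type restriction.
#' @return An object of class `paired_compare`: per-patient means plus the
#'   paired t statistic and p-value; `tidy()`/`glance()` supported.
#' @export
paired_expression_compare <- function(expr, annotation, gene, tissue_a,
                                      tissue_b, cell_filter = NULL) {
  a <- suppressWarnings(pseudobulk_mean(expr, annotation, tissue_a, gene, cell_filter))
  b <- suppressWarnings(pseudobulk_mean(expr, annotation, tissue_b, gene, cell_filter))
  wide <- dplyr::inner_join(
    dplyr::select(a, "patient", a_mean = "mean_expr"),
    dplyr::select(b, "patient", b_mean = "mean_expr"), by = "patient")
  if (nrow(wide) < 3) abort("fewer than 3 patients with both tissues")
  ht <- safe_paired_t(wide$a_mean, wide$b_mean)
  structure(list(per_patient = wide, gene = toupper(gene),
                 tissue_a = tissue_a, tissue_b = tissue_b,
                 mean_a = mean(wide$a_mean), mean_b = mean(wide$b_mean),
                 statistic = ht$statistic, p_value = ht$p_value,
                 n_pairs = nrow(wide)),
            class = "paired_compare")
}

#' @export
print.paired_compare <- function(x, ...) {
  cat(sprintf("<paired_compare> %s %s %.3f vs %s %.3f (t = %.3g, p = %.3g, n = %d)\n",
              x$gene, x$tissue_a, x$mean_a, x$tissue_b, x$mean_b,
              x$statistic, x$p_value, x$n_pairs))
  invisible(x)
}

#' @export
tidy.paired_compare <- function(x, ...) x$per_patient

#' @export
glance.paired_compare <- function(x, ...) {
  tibble::tibble(gene = x$gene, tissue_a = x$tissue_a, tissue_b = x$tissue_b,
                 mean_a = x$mean_a, mean_b = x$mean_b,
                 statistic = x$statistic, p_value = x$p_value,
                 n_pairs = x$n_pairs)
}
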