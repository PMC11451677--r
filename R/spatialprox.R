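#' Threshold phenotyping of segmented imaging cells
#'
#' Each phenotype is a conjunction of marker-at-least-cutoff terms from a
#' declarative definition list; intensities exactly at the cutoff count as
#' positive. Any referenced marker missing from the table is an error
#' naming it.
#'
#' @param cells A `spatial_cells` table.
#' @param definitions Named list of named cutoff vectors, e.g.
#'   `list(macrophage = c(CD68 = 4))`; see
#'   [default_phenotype_definitions()].
#' @return A tibble of class `phenotype_table`: `cell_id`, `sample_id` and
#'   one logical column per phenotype.
#' @export
threshold_phenotypes <- function(cells, definitions = default_phenotype_definitions()) {
  markers <- unique(unlist(lapply(definitions, names)))
  missing <- setdiff(markers, names(cells))
  if (length(missing)) {
    abort(paste("missing marker(s):", paste(missing, collapse = ", ")),
          class = "trtniche_format_error")
  }
  out <- tibble::tibble(cell_id = cells$cell_id, sample_id = cells$sample_id)
  for (ph in names(definitions)) {
    cuts <- definitions[[ph]]
    hit <- rep(TRUE, nrow(cells))
    for (m in names(cuts)) hit <- hit & cells[[m]] >= cuts[[m]]
    out[[ph]] <- hit
  }
  structure(out, class = c("phenotype_table", class(out)))
}

#' Even-odd point-in-polygon test
#'
#' Ray casting with the boundary counted as inside (vertices and edge
#' points are inside by convention).
#'
#' @param x,y Point coordinates.
#' @param vertices Two-column vertex matrix.
#' @return Logical.
#' @export
point_in_polygon <- function(x, y, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # boundary check: point on segment (j, i)
    dx <- vx[i] - vx[j]; dy <- vy[i] - vy[j]
    cross <- dx * (y - vy[j]) - dy * (x - vx[j])
    if (abs(cross) < 1e-9 &&
        x >= min(vx[i], vx[j]) - 1e-9 && x <= max(vx[i], vx[j]) + 1e-9 &&
        y >= min(vy[i], vy[j]) - 1e-9 && y <= max(vy[i], vy[j]) + 1e-9) {
      return(TRUE)
    }
    if ((vy[i] > y) != (vy[j] > y)) {
      xint <- vx[j] + (y - vy[j]) / (vy[i] - vy[j]) * dx
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Assign cells to annotated regions
#'
#' Even-odd point-in-polygon with boundary-inside convention; overlapping
#' polygons are resolved in favor of the first listed. Cells outside every
#' polygon belong to the alpha-SMA negative background.
#'
#' @param cells A `spatial_cells` table.
#' @param regions A `region_set` of the same sample.
#' @return A tibble of class `region_assignment`: `cell_id`, `region_id`
#'   (`NA` for background), `region_class`.
#' @export
assign_regions <- function(cells, regions) {
  if (!all(regions$sample_id == cells$sample_id[1])) {
    abort("cells and regions must share a sample_id",
          class = "trtniche_validation_error")
  }
  region_id <- rep(NA_character_, nrow(cells))
  region_class <- rep("ASMA_NEG", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    for (r in seq_len(nrow(regions))) {
      if (point_in_polygon(cells$x[i], cells$y[i], regions$vertices[[r]])) {
        region_id[i] <- regions$region_id[r]
        region_class[i] <- regions$class[r]
        break
      }
    }
  }
  out <- tibble::tibble(cell_id = cells$cell_id, region_id = region_id,
                        region_class = region_class)
  structure(out, class = c("region_assignment", class(out)))
}

#' Shoelace polygon area
#'
#' @param vertices Two-column vertex matrix (um).
#' @return Area in square micrometers.
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Phenotype density per region class
#'
#' Cells per square millimeter in the alpha-SMA+ polygons versus the
#' negative background (field area minus positive area). A zero-area class
#' yields an `NA` density.
#'
#' @param assign A `region_assignment`.
#' @param pheno A `phenotype_table`.
#' @param regions The `region_set` (its `field` attribute supplies the
#'   total field area).
#' @param phenotypes Phenotype columns to report (default: all).
#' @return Tibble `sample_id`, `region_class`, `phenotype`, `n_cells`,
#'   `area_mm2`, `density_per_mm2`.
#' @export
region_density <- function(assign, pheno, regions, phenotypes = NULL) {
  field <- attr(regions, "field")
  if (is.null(field)) abort("region set carries no field extent")
  pos_area <- sum(vapply(regions$vertices[regions$class == "ASMA_POS"],
                         polygon_area, 0))
  neg_area <- prod(field) - pos_area +
    sum(vapply(regions$vertices[regions$class == "ASMA_NEG"], polygon_area, 0))
  areas <- c(ASMA_POS = pos_area, ASMA_NEG = neg_area) / 1e6 # um^2 -> mm^2
  if (is.null(phenotypes)) {
    phenotypes <- setdiff(names(pheno), c("cell_id", "sample_id"))
  }
  df <- dplyr::inner_join(tibble::as_tibble(assign), tibble::as_tibble(pheno),
                          by = "cell_id")
  purrr::map_dfr(phenotypes, function(ph) {
    counts <- table(factor(df$region_class[df[[ph]]],
                           levels = c("ASMA_POS", "ASMA_NEG")))
    tibble::tibble(sample_id = pheno$sample_id[1],
                   region_class = names(areas),
                   phenotype = ph,
                   n_cells = as.integer(counts[names(areas)]),
                   area_mm2 = unname(areas),
                   density_per_mm2 = ifelse(areas > 0,
                                            as.integer(counts[names(areas)]) / areas,
                                            NA_real_))
  })
}

#' Nearest-neighbor distances between two point sets
#'
#' Exact Euclidean distance from each query point to its nearest target,
#' computed by blocked vectorized distance evaluation (verified against a
#' double-loop oracle in the test suite). An empty target set yields `NA`
#' distances.
#'
#' @param query,target Two-column coordinate matrices (um).
#' @param return_index Also return the index of the nearest target.
#' @return Numeric vector of distances, or a list `(distance, index)`.
#' @export
nn_distance <- function(query, target, return_index = FALSE) {
  query <- as.matrix(query); target <- as.matrix(target)
  if (nrow(target) == 0L) {
    d <- rep(NA_real_, nrow(query))
    return(if (return_index) list(distance = d, index = rep(NA_integer_, nrow(query))) else d)
  }
  d <- rep(Inf, nrow(query)); idx <- rep(NA_integer_, nrow(query))
  block <- 512L
  for (start in seq(1L, nrow(query), by = block)) {
    rows <- start:min(start + block - 1L, nrow(query))
    dx <- outer(query[rows, 1], target[, 1], "-")
    dy <- outer(query[rows, 2], target[, 2], "-")
    dd <- dx * dx + dy * dy
    j <- max.col(-dd, ties.method = "first")
    d[rows] <- sqrt(dd[cbind(seq_along(rows), j)])
    idx[rows] <- j
  }
  if (return_index) list(distance = d, index = idx) else d
}

#' Fraction of query cells within a radius of their nearest target
#'
#' @param nn_distances Nearest-neighbor distances (um).
#' @param rho Radius in micrometers (default 100, the proximity rule).
#' @return Fraction in `[0, 1]`; `NA` for empty input.
#' @export
fraction_within_radius <- function(nn_distances, rho = 100) {
  if (rho <= 0) abort("rho must be positive")
  if (length(nn_distances) == 0L) return(NA_real_)
  mean(nn_distances <= rho, na.rm = TRUE)
}

#' Region-stratified proximity summary for phenotype pairs
#'
#' For each (sample, region class, query phenotype, target phenotype):
#' nearest-neighbor distance summaries and the fraction of query cells
#' within `rho`. The query phenotype's cells are stratified by region
#' class; the target cells are NOT region-filtered, so a cell near a region
#' border keeps its true nearest neighbor (avoids boundary truncation
#' bias).
#'
#' @param cells A `spatial_cells` table.
#' @param pheno Its `phenotype_table`.
#' @param assign Its `region_assignment`.
#' @param pairs Data frame with columns `query`, `target` naming phenotype
#'   columns.
#' @param rho Proximity radius in um (default 100).
#' @return A tibble of class `proximity_stats`.
#' @export
proximity_summary <- function(cells, pheno, assign, pairs, rho = 100) {
  xy <- as.matrix(cells[, c("x", "y")])
  df <- dplyr::inner_join(tibble::as_tibble(pheno), tibble::as_tibble(assign),
                          by = "cell_id")
  out <- purrr::pmap_dfr(pairs, function(query, target) {
    tgt_xy <- xy[df[[target]], , drop = FALSE]
    purrr::map_dfr(c("ASMA_POS", "ASMA_NEG"), function(rc) {
      q_rows <- which(df[[query]] & df$region_class == rc)
      if (length(q_rows) == 0L || nrow(tgt_xy) == 0L) {
        return(tibble::tibble(sample_id = cells$sample_id[1], region_class = rc,
                              query = query, target = target, n_query = length(q_rows),
                              mean_nn = NA_real_, median_nn = NA_real_,
                              frac_within = NA_real_))
      }
      d <- nn_distance(xy[q_rows, , drop = FALSE], tgt_xy)
      # a cell is its own nearest neighbor when query == target; drop zeros
      if (query == target) {
        d <- nn_distance_self(xy[q_rows, , drop = FALSE], tgt_xy)
      }
      tibble::tibble(sample_id = cells$sample_id[1], region_class = rc,
                     query = query, target = target, n_query = length(q_rows),
                     mean_nn = mean(d), median_nn = median(d),
                     frac_within = fraction_within_radius(d, rho))
    })
  })
  structure(out, class = c("proximity_stats", class(out)))
}

# NN distance excluding an exact self-match (used when query == target)
nn_distance_self <- function(query, target) {
  vapply(seq_len(nrow(query)), function(i) {
    dd <- sqrt((target[, 1] - query[i, 1])^2 + (target[, 2] - query[i, 2])^2)
    dd <- dd[dd > 0]
    if (length(dd)) min(dd) else NA_real_
  }, 0)
}

#' Paired alpha-SMA+/- comparison across samples
#'
#' Classical two-sided paired t-test on a per-sample summary (mean NN
#' distance by default, or any numeric column of the proximity/density
#' tables), alpha-SMA+ versus alpha-SMA- within each sample.
#'
#' @param stats A `proximity_stats` (or [region_density()]) tibble covering
#'   several samples.
#' @param query,target Phenotype pair to extract (ignored for density
#'   tables if absent).
#' @param metric Summary column (default `"mean_nn"`).
#' @return An object of class `paired_region_test`: list with `per_sample`
#'   tibble and the test results; `tidy()`/`glance()` supported.
#' @export
paired_region_stats <- function(stats, query = NULL, target = NULL,
                                metric = "mean_nn") {
  df <- tibble::as_tibble(stats)
  if (!is.null(query) && "query" %in% names(df)) df <- df[df$query == query, ]
  if (!is.null(target) && "target" %in% names(df)) df <- df[df$target == target, ]
  if (!is.null(query) && "phenotype" %in% names(df)) df <- df[df$phenotype == query, ]
  wide <- df |>
    dplyr::select("sample_id", "region_class", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "region_class", values_from = dplyr::all_of(metric))
  complete <- wide[!is.na(wide$ASMA_POS) & !is.na(wide$ASMA_NEG), ]
  if (nrow(complete) < 3) abort("fewer than 3 samples with both region classes")
  ht <- safe_paired_t(complete$ASMA_POS, complete$ASMA_NEG)
  structure(list(
    per_sample = complete,
    metric = metric, query = query, target = target,
    mean_pos = mean(complete$ASMA_POS), mean_neg = mean(complete$ASMA_NEG),
    statistic = ht$statistic, p_value = ht$p_value,
    n_pairs = nrow(complete)
  ), class = "paired_region_test")
}

#' @export
print.paired_region_test <- function(x, ...) {
  cat(sprintf("<paired_region_test> %s %s->%s: POS %.3g vs NEG %.3g (t = %.3g, p = %.3g, n = %d)\n",
              x$metric, x$query %||% "", x$target %||% "", x$mean_pos,
              x$mean_neg, x$statistic, x$p_value, x$n_pairs))
  invisible(x)
}

#' @export
tidy.paired_region_test <- function(x, ...) x$per_sample

#' @export
glance.paired_region_test <- function(x, ...) {
  tibble::tibble(metric = x$metric, query = x$query %||% NA_character_,
                 target = x$target %||% NA_character_, mean_pos = x$mean_pos,
                 mean_neg = x$mean_neg, statistic = x$statistic,
                 p_value = x$p_value, n_pairs = x$n_pairs)
}
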