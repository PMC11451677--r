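#' Generate one synthetic multiplexed-imaging sample
#'
#' One square field (default 2000 x 2000 um) carrying 2-4 axis-aligned
#' alpha-SMA+ rectangles (the remainder is alpha-SMA negative background, so
#' region areas are analytically known). CD8 T cells, NK cells and Tregs are
#' homogeneous Poisson over the field; macrophages are likewise uniform, but
#' every macrophage falling inside an alpha-SMA+ rectangle is displaced
#' toward its nearest CD8 T cell by the `spatial_attraction` factor (0 keeps
#' the null; NK/Treg are never displaced and serve as negative controls).
#' Marker intensities are drawn well-separated so threshold phenotyping at
#' the default cutoffs recovers the planted types exactly.
#'
#' @param config A `cohort_config`.
#' @param sample_id Sample identifier.
#' @param seed_offset Integer added to `config$seed` so multi-sample cohorts
#'   are reproducible sample by sample.
#' @return A list with `cells` (`spatial_cells`), `regions` (`region_set`)
#'   and `truth` (tibble of planted cell types and the planted displacement).
#' @export
make_spatial_sample <- function(config, sample_id = "S01", seed_offset = 0L) {
  stopifnot(inherits(config, "cohort_config"))
  fs <- config$field_size
  with_seed(config$seed + 404L + as.integer(seed_offset), {
    # rectangles placed uniformly INCLUDING border overlap (then clipped):
    # positive and negative cells then share one positional distribution,
    # so edge effects cancel between region classes under the null.
    # Overlapping rectangles are rejected to keep class areas analytic.
    n_rect <- sample(2:4, 1)
    boxes <- matrix(numeric(0), 0, 4) # x0, x1, y0, y1
    for (i in seq_len(n_rect)) {
      for (try in 1:50) {
        w <- runif(1, 300, 600); h <- runif(1, 300, 600)
        x0 <- max(runif(1, -w / 2, fs - w / 2), 0)
        y0 <- max(runif(1, -h / 2, fs - h / 2), 0)
        x1 <- min(x0 + w, fs); y1 <- min(y0 + h, fs)
        clash <- nrow(boxes) > 0 &&
          any(x0 < boxes[, 2] & x1 > boxes[, 1] &
                y0 < boxes[, 4] & y1 > boxes[, 3])
        if (!clash) { boxes <- rbind(boxes, c(x0, x1, y0, y1)); break }
      }
    }
    polys <- lapply(seq_len(nrow(boxes)), function(i) {
      b <- boxes[i, ]
      cbind(x = c(b[1], b[2], b[2], b[1]), y = c(b[3], b[3], b[4], b[4]))
    })
    names(polys) <- sprintf("%s_R%d", sample_id, seq_along(polys))
    n_rect <- length(polys)
    regions <- region_set(polys, rep("ASMA_POS", n_rect), sample_id,
                          field = c(fs, fs))

    place <- function(n_mean) {
      n <- rpois(1, n_mean)
      cbind(x = runif(n, 0, fs), y = runif(n, 0, fs))
    }
    cd8 <- place(350); mac <- place(350); nk <- place(150); treg <- place(150)

    # displace alpha-SMA+ macrophages toward their nearest CD8 T cell
    if (config$spatial_attraction > 0 && nrow(mac) > 0 && nrow(cd8) > 0) {
      in_pos <- vapply(seq_len(nrow(mac)), function(i) {
        any(vapply(polys, function(p) point_in_polygon(mac[i, 1], mac[i, 2], p), TRUE))
      }, TRUE)
      if (any(in_pos)) {
        nn <- nn_distance(mac[in_pos, , drop = FALSE], cd8, return_index = TRUE)
        target <- cd8[nn$index, , drop = FALSE]
        mac[in_pos, ] <- mac[in_pos, , drop = FALSE] +
          config$spatial_attraction * (target - mac[in_pos, , drop = FALSE])
      }
    }

    types <- c(rep("CD8T", nrow(cd8)), rep("macrophage", nrow(mac)),
               rep("NK", nrow(nk)), rep("Treg", nrow(treg)))
    xy <- rbind(cd8, mac, nk, treg)
    n_all <- nrow(xy)
    hi <- function(on) ifelse(on, rnorm(n_all, 8, 1), abs(rnorm(n_all, 0.5, 0.3)))
    cells <- tibble::tibble(
      cell_id = sprintf("%s_c%05d", sample_id, seq_len(n_all)),
      x = xy[, 1], y = xy[, 2],
      CD8 = hi(types == "CD8T"),
      CD68 = hi(types == "macrophage"),
      CD56 = hi(types == "NK"),
      FOXP3 = hi(types == "Treg"),
      # functional markers carried by random CD8 subsets
      KI67 = hi(types == "CD8T" & runif(n_all) < 0.3),
      CD45RA = hi(types == "CD8T" & runif(n_all) < 0.4),
      CD45RO = hi(types == "CD8T" & runif(n_all) < 0.4),
      CD39 = hi(types == "CD8T" & runif(n_all) < 0.25)
    )
    cells <- dplyr::mutate(cells, dplyr::across(dplyr::where(is.numeric) &
                                                  !dplyr::any_of(c("x", "y")),
                                                ~ pmax(.x, 0)))
    truth <- tibble::tibble(cell_id = cells$cell_id, true_type = types,
                            region_effect = config$spatial_attraction)
    list(cells = spatial_cells(cells, sample_id), regions = regions,
         truth = truth)
  })
}

#' Generate a cohort of spatial samples
#'
#' @param config A `cohort_config`; `n_spatial_samples` controls the size.
#' @return A list of [make_spatial_sample()] results, one per sample.
#' @export
make_spatial_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(seq_len(config$n_spatial_samples), function(i) {
    make_spatial_sample(config, sprintf("S%02d", i), seed_offset = i)
  })
}

#' Default phenotype definitions matching the synthetic imaging panel
#'
#' Each phenotype is a conjunction of marker-at-least-cutoff terms. Subset
#' phenotypes (e.g. `CD39pos_CD8T`) include their parent's terms so the
#' subset-implies-parent invariant holds by construction.
#'
#' @param cutoff Intensity cutoff applied to every marker (default 4).
#' @return Named list of named cutoff vectors.
#' @export
default_phenotype_definitions <- function(cutoff = 4) {
  list(
    macrophage = c(CD68 = cutoff),
    CD8T = c(CD8 = cutoff),
    NK = c(CD56 = cutoff),
    Treg = c(FOXP3 = cutoff),
    KI67pos_CD8T = c(CD8 = cutoff, KI67 = cutoff),
    CD45RApos_CD8T = c(CD8 = cutoff, CD45RA = cutoff),
    CD45ROpos_CD8T = c(CD8 = cutoff, CD45RO = cutoff),
    CD39pos_CD8T = c(CD8 = cutoff, CD39 = cutoff)
  )
}
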