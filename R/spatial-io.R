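#' Construct a segmented-cell table for one imaging sample
#'
#' Coordinates are micrometers in the image plane (origin top-left, y
#' increasing downward). All marker intensity columns must be nonnegative
#' and coordinates finite.
#'
#' @param cells Data frame with columns `cell_id`, `x`, `y` and one numeric
#'   column per marker.
#' @param sample_id Sample identifier shared with the companion region set.
#' @return A tibble of class `spatial_cells` with attribute `markers`.
#' @export
spatial_cells <- function(cells, sample_id) {
  cells <- tibble::as_tibble(cells)
  need <- c("cell_id", "x", "y")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    abort(paste("cell table missing columns:", paste(missing, collapse = ", ")),
          class = "trtniche_format_error")
  }
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y))) {
    abort("non-finite cell coordinate", class = "trtniche_validation_error")
  }
  markers <- setdiff(names(cells), c(need, "sample_id"))
  for (m in markers) {
    if (!is.numeric(cells[[m]]) || any(!is.finite(cells[[m]])) || any(cells[[m]] < 0)) {
      abort(sprintf("marker '%s' must be finite and nonnegative", m),
            class = "trtniche_validation_error")
    }
  }
  cells$sample_id <- as.character(sample_id)
  cells <- dplyr::relocate(cells, "cell_id", "sample_id", "x", "y")
  attr(cells, "markers") <- markers
  class(cells) <- c("spatial_cells", class(cells))
  cells
}

#' Construct a region set of annotated polygons
#'
#' Each polygon is an alpha-SMA positive or negative annotation given as a
#' two-column vertex matrix in micrometers. Polygons must be simple (at
#' least 3 vertices, non-self-intersecting in the rectangle/convex cases
#' checked here).
#'
#' @param polygons Named list of 2-column vertex matrices.
#' @param class Character vector, `"ASMA_POS"` or `"ASMA_NEG"`, one per polygon.
#' @param sample_id Sample identifier.
#' @param field Numeric `c(width, height)` of the imaged field in
#'   micrometers, used for background-area computations.
#' @return A tibble of class `region_set` with list-column `vertices`.
#' @export
region_set <- function(polygons, class, sample_id, field = NULL) {
  if (is.null(names(polygons)) || anyDuplicated(names(polygons))) {
    abort("polygons must have unique region_id names", class = "trtniche_validation_error")
  }
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 3L) {
      abort("polygon with fewer than 3 vertices", class = "trtniche_validation_error")
    }
    if (!all(is.finite(p))) {
      abort("non-finite polygon vertex", class = "trtniche_validation_error")
    }
    colnames(p) <- c("x", "y")
    p
  })
  if (!all(class %in% c("ASMA_POS", "ASMA_NEG"))) {
    abort("region class must be ASMA_POS or ASMA_NEG", class = "trtniche_validation_error")
  }
  out <- tibble::tibble(
    region_id = names(polygons),
    class = as.character(class),
    sample_id = as.character(sample_id),
    vertices = unname(polygons)
  )
  attr(out, "field") <- field
  structure(out, class = c("region_set", class(out)))
}

#' Load a spatial sample: segmented cells plus region annotations
#'
#' Reads a cell CSV (`cell_id, x, y, sample_id, <marker columns>`) and a
#' GeoJSON FeatureCollection of polygons whose `properties` carry
#' `region_id`, `class` and `sample_id`; an optional top-level `bbox`
#' `[0, 0, width, height]` records the field extent.
#'
#' @param cells_csv Path to the cell table CSV.
#' @param regions_json Path to the GeoJSON region file.
#' @return A list with elements `cells` (`spatial_cells`) and `regions`
#'   (`region_set`) sharing one `sample_id`.
#' @export
load_spatial_sample <- function(cells_csv, regions_json) {
  df <- readr::read_csv(cells_csv, show_col_types = FALSE)
  if (!"sample_id" %in% names(df)) {
    abort("cell CSV must carry a sample_id column", class = "trtniche_format_error")
  }
  sid <- unique(df$sample_id)
  if (length(sid) != 1L) abort("cell CSV must contain exactly one sample")
  cells <- spatial_cells(dplyr::select(df, -"sample_id"), sid)

  gj <- jsonlite::read_json(regions_json)
  if (is.null(gj$features)) abort("regions file is not a FeatureCollection",
                                  class = "trtniche_format_error")
  polys <- list(); cls <- character(0); sids <- character(0)
  for (f in gj$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    # GeoJSON rings are closed; drop the repeated final vertex
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    polys[[f$properties$region_id]] <- m
    cls <- c(cls, f$properties$class)
    sids <- c(sids, f$properties$sample_id %||% sid)
  }
  if (!all(sids == sid)) abort("region sample_id does not match cell table",
                               class = "trtniche_validation_error")
  field <- if (!is.null(gj$bbox)) c(gj$bbox[[3]], gj$bbox[[4]]) else NULL
  regions <- region_set(polys, cls, sid, field = field)
  list(cells = cells, regions = regions)
}

#' Write a spatial sample to CSV + GeoJSON
#'
#' @param cells A `spatial_cells` table.
#' @param regions A `region_set`.
#' @param cells_csv,regions_json Output paths.
#' @return Invisibly, `NULL`.
#' @export
write_spatial_sample <- function(cells, regions, cells_csv, regions_json) {
  readr::write_csv(cells, cells_csv)
  features <- purrr::pmap(
    list(regions$region_id, regions$class, regions$sample_id, regions$vertices),
    function(id, cls, sid, v) {
      ring <- lapply(seq_len(nrow(v)), function(i) list(v[i, 1], v[i, 2]))
      ring <- c(ring, ring[1]) # close the ring
      list(type = "Feature",
           geometry = list(type = "Polygon", coordinates = list(ring)),
           properties = list(region_id = id, class = cls, sample_id = sid))
    })
  gj <- list(type = "FeatureCollection", features = features)
  field <- attr(regions, "field")
  if (!is.null(field)) gj$bbox <- list(0, 0, field[1], field[2])
  jsonlite::write_json(gj, regions_json, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
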