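#' Build a symmetrized kNN cell graph in PC space
#'
#' Principal components of the lognorm matrix (centered, unscaled) feed a
#' k-nearest-neighbor search with deterministic lexicographic tie-breaking;
#' the directed kNN relation is symmetrized by union (an edge exists if
#' either endpoint lists the other), which keeps the root component large.
#' Edge weights are binary.
#'
#' @param expr An `expr_matrix` (lognorm layer).
#' @param k Neighbors per cell (default 15).
#' @param n_pcs Principal components retained (default 20).
#' @param seed Integer seed (PCA sign conventions and downstream use).
#' @return An object of class `cell_graph`: list with `graph` (igraph),
#'   `adjacency` (sparse symmetric 0/1), `cell_ids`, `pcs`.
#' @export
build_cell_graph <- function(expr, k = 15, n_pcs = 20, seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  n <- length(expr$cell_ids)
  if (k >= n) abort("k must be smaller than the number of cells")
  n_pcs <- min(n_pcs, n - 1, length(expr$gene_ids))
  pcs <- with_seed(seed, {
    p <- prcomp(expr$values, center = TRUE, scale. = FALSE, rank. = n_pcs)
    p$x
  })
  d <- as.matrix(dist(pcs))
  diag(d) <- Inf
  # deterministic neighbor choice: distance, then cell-id order
  ord_ids <- order(expr$cell_ids)
  adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(n, n))
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    nb <- ord_ids[order(d[i, ord_ids], method = "radix")][seq_len(k)]
    ii <- c(ii, rep(i, k)); jj <- c(jj, nb)
  }
  adj <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(n, n), use.last.ij = FALSE)
  adj@x[] <- 1 # union symmetrization, binary weights
  dimnames(adj) <- list(expr$cell_ids, expr$cell_ids)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  if (max(comp$csize) < 0.95 * n) {
    warn("largest graph component spans < 95% of cells")
  }
  structure(list(graph = g, adjacency = adj, cell_ids = expr$cell_ids,
                 pcs = pcs), class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, %d edges\n", length(x$cell_ids),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Diffusion-distance pseudotime over a cell graph
#'
#' Embeds the row-normalized graph in a 10-component diffusion map and
#' assigns each cell the diffusion distance to the root, min-max scaled to
#' `[0, 1]`. The root is either an explicit cell id or the cell maximizing
#' a per-cell score (by default the Kupffer-cell program score computed
#' from `expr`, placing the root at the resident-macrophage end). Branch
#' ids come from a simple spine splitter: components left after removing
#' the shortest root-to-terminus path, merged back onto their nearest spine
#' position (single-branch data yields one branch).
#'
#' @param graph A `cell_graph`.
#' @param expr The `expr_matrix` the graph was built from (lognorm).
#' @param root `"max-kc"` (default), or a cell id, or a named numeric
#'   per-cell score whose argmax is used.
#' @param kc_genes Kupffer-cell marker set for the default root rule.
#' @param n_comp Diffusion components (default 10).
#' @return A tibble of class `pseudotime_result`: `cell_id`, `pseudotime`,
#'   `branch_id`; attributes `root_cell_id`.
#' @export
compute_pseudotime <- function(graph, expr, root = "max-kc",
                               kc_genes = c("VSIG4", "CSF1R", "CD163",
                                            "CD206", "IL18"),
                               n_comp = 10) {
  stopifnot(inherits(graph, "cell_graph"))
  n <- length(graph$cell_ids)
  if (is.numeric(root)) {
    root_cell <- names(root)[which.max(root)]
  } else if (identical(root, "max-kc")) {
    sc <- score_gene_program(expr, "KC",
                             gene_set_collection(list(KC = kc_genes)))
    root_cell <- sc$cell_id[which.max(sc$score)]
  } else {
    root_cell <- root
  }
  if (!root_cell %in% graph$cell_ids) abort("root cell not in graph")
  comp <- igraph::components(graph$graph)
  root_comp <- comp$membership[match(root_cell, graph$cell_ids)]
  in_comp <- comp$membership == root_comp
  if (sum(in_comp) < 0.5 * n) {
    abort("root component covers < 50% of cells; graph too fragmented")
  }

  a <- graph$adjacency[in_comp, in_comp, drop = FALSE]
  deg <- Matrix::rowSums(a)
  dhalf <- 1 / sqrt(deg)
  m <- Matrix::Diagonal(x = dhalf) %*% a %*% Matrix::Diagonal(x = dhalf)
  es <- eigen(as.matrix(Matrix::symmpart(m)), symmetric = TRUE)
  n_comp <- min(n_comp, sum(in_comp) - 1)
  keep <- seq_len(n_comp) + 1 # drop the trivial stationary component
  # diffusion coordinates with the accumulated-transition scaling
  # lambda/(1 - lambda): slow mixing modes dominate, noise modes vanish
  lam <- es$values[keep]
  psi <- sweep(es$vectors[, keep, drop = FALSE] * dhalf, 2,
               lam / (1 - lam), "*")
  ridx <- match(root_cell, graph$cell_ids[in_comp])
  dd <- sqrt(rowSums(sweep(psi, 2, psi[ridx, ], "-")^2))
  t_scaled <- (dd - min(dd)) / (max(dd) - min(dd))

  t_all <- rep(NA_real_, n)
  t_all[in_comp] <- t_scaled
  branch <- assign_branches(graph, in_comp, root_cell, t_all)
  out <- tibble::tibble(cell_id = graph$cell_ids, pseudotime = t_all,
                        branch_id = branch)
  attr(out, "root_cell_id") <- root_cell
  structure(out, class = c("pseudotime_result", class(out)))
}

# spine splitter: remove the shortest root->terminus path, label remaining
# components, and attach spine cells to the branch of their nearest neighbor
assign_branches <- function(graph, in_comp, root_cell, t_all) {
  ids <- graph$cell_ids
  branch <- rep(NA_integer_, length(ids))
  sub_ids <- ids[in_comp]
  terminus <- sub_ids[which.max(t_all[in_comp])]
  sp <- igraph::shortest_paths(graph$graph, from = root_cell, to = terminus,
                               output = "vpath")$vpath[[1]]
  spine <- ids[as.integer(sp)]
  off <- setdiff(sub_ids, spine)
  if (length(off) == 0L) {
    branch[in_comp] <- 1L
    return(branch)
  }
  g_off <- igraph::induced_subgraph(graph$graph, off)
  comp_off <- igraph::components(g_off)
  # components ordered by size; everything in/attached to the largest is branch 1
  size_rank <- rank(-comp_off$csize, ties.method = "first")
  branch[match(off, ids)] <- size_rank[comp_off$membership]
  # spine cells join the branch of their nearest off-spine graph neighbor
  for (s in spine) {
    nb <- ids[as.integer(igraph::neighbors(graph$graph, s))]
    nb_branch <- branch[match(setdiff(nb, spine), ids)]
    nb_branch <- nb_branch[!is.na(nb_branch)]
    branch[match(s, ids)] <- if (length(nb_branch)) min(nb_branch) else 1L
  }
  branch
}

#' Moran's I graph autocorrelation of a per-cell value
#'
#' `I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with binary symmetric weights. A constant `x` returns 0 by convention.
#'
#' @param graph A `cell_graph` (or a symmetric 0/1 adjacency matrix).
#' @param x Finite numeric vector, one value per graph node.
#' @return Moran's I.
#' @export
morans_i <- function(graph, x) {
  a <- if (inherits(graph, "cell_graph")) graph$adjacency else graph
  if (length(x) != nrow(a)) abort("x must have one value per node")
  if (!all(is.finite(x))) abort("x must be finite")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(0)
  w_total <- sum(a)
  num <- as.numeric(xc %*% (a %*% xc))
  (length(x) / w_total) * num / denom
}

#' Rank genes by Moran's I along the cell graph
#'
#' Scores every gene's smoothness over the graph and attaches a permutation
#' p-value (values shuffled over nodes). Ranking is by decreasing I with a
#' lexicographic gene-id tiebreak.
#'
#' @param graph A `cell_graph`.
#' @param expr An `expr_matrix` (lognorm) over the same cells.
#' @param n_perm Permutations per gene (default 199).
#' @param seed Integer seed.
#' @return A tibble of class `moran_table`: `gene`, `moran_i`, `p_value`,
#'   `rank`.
#' @export
rank_trajectory_genes <- function(graph, expr, n_perm = 199, seed = 1) {
  stopifnot(inherits(graph, "cell_graph"), inherits(expr, "expr_matrix"))
  a <- graph$adjacency
  v <- expr$values[graph$cell_ids, , drop = FALSE]
  n <- nrow(v)
  w_total <- sum(a)
  pref <- n / w_total
  obs <- numeric(ncol(v)); pval <- numeric(ncol(v))
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      x <- v[, j]
      xc <- x - mean(x)
      denom <- sum(xc^2)
      if (denom == 0) { obs[j] <- 0; pval[j] <- 1; next }
      obs[j] <- pref * as.numeric(xc %*% (a %*% xc)) / denom
      perm <- matrix(xc[vapply(seq_len(n_perm), function(b) sample.int(n),
                               integer(n))], n, n_perm)
      i_perm <- pref * colSums(perm * as.matrix(a %*% perm)) / denom
      pval[j] <- (1 + sum(i_perm >= obs[j])) / (1 + n_perm)
    }
  })
  out <- tibble::tibble(gene = colnames(v), moran_i = obs, p_value = pval)
  out <- out[order(-out$moran_i, out$gene), ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("moran_table", class(out)))
}

#' Subcluster a pseudotime branch into KC / IC / SPP1 states
#'
#' Seeded k-means (10 restarts) on marker-panel z-scores concatenated with
#' pseudotime. Clusters are labeled KC by maximal Kupffer-cell score, SPP1
#' by maximal SPP1 expression and IC by maximal IC score; if those argmax
#' labels collide, the fallback is pseudotime order (earliest = KC,
#' latest = SPP1).
#'
#' @param ptime A `pseudotime_result`.
#' @param expr The matching `expr_matrix` (lognorm).
#' @param branch_id Branch to subcluster (`NULL` = all cells with finite
#'   pseudotime).
#' @param n_clusters Number of clusters (default 3).
#' @param markers Marker panel for the feature space (default: KC markers,
#'   IC markers and SPP1).
#' @param seed Integer seed for k-means.
#' @return A tibble of class `branch_clusters`: `cell_id`, `pseudotime`,
#'   `cluster`, `state`; attribute `state_summary`.
#' @export
subcluster_branch <- function(ptime, expr, branch_id = NULL, n_clusters = 3,
                              markers = NULL, seed = 1) {
  stopifnot(inherits(ptime, "pseudotime_result"))
  kc_set <- c("VSIG4", "CSF1R", "CD163", "CD206", "IL18")
  ic_set <- c("SPP1", "TGFBR1", "IL6R", "CSF1R", "VSIG4", "CD163")
  if (is.null(markers)) markers <- unique(c(kc_set, ic_set))
  markers <- intersect(markers, expr$gene_ids)
  cells <- ptime$cell_id[!is.na(ptime$pseudotime)]
  if (!is.null(branch_id)) {
    cells <- intersect(cells, ptime$cell_id[ptime$branch_id %in% branch_id])
  }
  if (length(cells) < 3 * n_clusters) {
    abort("branch too small for the requested number of clusters")
  }
  t_cells <- ptime$pseudotime[match(cells, ptime$cell_id)]
  feat <- scale(expr$values[cells, markers, drop = FALSE])
  feat[, apply(feat, 2, function(c) any(!is.finite(c)))] <- 0
  feat <- cbind(feat, pseudotime = as.numeric(scale(t_cells)))
  km <- with_seed(seed, kmeans(feat, centers = n_clusters, nstart = 10))
  cl <- km$cluster
  if (any(table(cl) < 3)) warn("degenerate subcluster with < 3 cells")

  sub <- subset_expression(expr, cells = cells)
  kc_score <- score_gene_program(sub, "KC", gene_set_collection(list(KC = kc_set)))$score
  ic_score <- score_gene_program(sub, "IC", gene_set_collection(list(IC = ic_set)))$score
  spp1 <- if ("SPP1" %in% expr$gene_ids) sub$values[, "SPP1"] else rep(0, length(cells))
  by_cl <- function(x) vapply(seq_len(n_clusters), function(k) mean(x[cl == k]), 0)
  cand <- c(KC = which.max(by_cl(kc_score)), IC = which.max(by_cl(ic_score)),
            SPP1 = which.max(by_cl(spp1)))
  med_t <- by_cl(t_cells)
  if (n_clusters == 3 && anyDuplicated(cand)) {
    # conflict: fall back to pseudotime order, earliest = KC, latest = SPP1
    ord <- order(med_t)
    cand <- c(KC = ord[1], IC = ord[2], SPP1 = ord[3])
  }
  state <- rep(NA_character_, length(cells))
  if (n_clusters == 3) {
    for (nm in names(cand)) state[cl == cand[[nm]]] <- nm
  } else {
    state <- as.character(cl)
  }
  out <- tibble::tibble(cell_id = cells, pseudotime = t_cells,
                        cluster = cl, state = state)
  attr(out, "state_summary") <- out |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(n = dplyr::n(), median_pseudotime = median(.data$pseudotime),
                     .groups = "drop")
  structure(out, class = c("branch_clusters", class(out)))
}

#' IC-marker co-expression frequency, liver versus colon
#'
#' A macrophage or monocyte co-expresses the IC program when its lognorm
#' value is strictly positive for ALL six markers (SPP1, TGFBR1, IL6R,
#' CSF1R, VSIG4, CD163). Frequencies are per patient within each tissue
#' group and compared by a paired t-test across patients present in both
#' groups (others are kept in the table, dropped from the test).
#'
#' @param expr An `expr_matrix`.
#' @param annotation Cell annotation tibble.
#' @param ic_genes The marker sextet (default as above).
#' @param tissues Named list mapping group labels to tissue codes (default
#'   liver = MT+MN, colon = PT+PN).
#' @return An object of class `ic_frequency`: list with `frequencies`
#'   tibble (`patient`, `group`, `n_macmono`, `n_ic`, `frequency`) and
#'   `test` (paired t-test tibble). `tidy()` returns the table, `glance()`
#'   the test.
#' @export
ic_coexpression_frequency <- function(expr, annotation,
                                      ic_genes = c("SPP1", "TGFBR1", "IL6R",
                                                   "CSF1R", "VSIG4", "CD163"),
                                      tissues = list(liver = c("MT", "MN"),
                                                     colon = c("PT", "PN"))) {
  stopifnot(inherits(expr, "expr_matrix"))
  ic_genes <- toupper(ic_genes)
  missing <- setdiff(ic_genes, expr$gene_ids)
  if (length(missing)) abort(paste("IC genes absent:", paste(missing, collapse = ", ")))
  ann <- annotation[annotation$coarse_type %in% c("macrophage", "monocyte") &
                      annotation$cell_id %in% expr$cell_ids, ]
  co <- rowSums(expr$values[ann$cell_id, ic_genes, drop = FALSE] > 0) == length(ic_genes)
  ann$coexpr <- co
  ann$group <- NA_character_
  for (g in names(tissues)) ann$group[ann$tissue %in% tissues[[g]]] <- g
  freq <- ann |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$patient, .data$group) |>
    dplyr::summarise(n_macmono = dplyr::n(), n_ic = sum(.data$coexpr),
                     .groups = "drop") |>
    dplyr::mutate(frequency = .data$n_ic / .data$n_macmono)
  wide <- tidyr::pivot_wider(freq, id_cols = "patient", names_from = "group",
                             values_from = "frequency")
  grp <- names(tissues)[1:2]
  test <- NULL
  paired <- if (all(grp %in% names(wide))) {
    wide[!is.na(wide[[grp[1]]]) & !is.na(wide[[grp[2]]]), ]
  } else {
    wide[0, ]
  }
  if (nrow(paired) >= 3) {
    ht <- safe_paired_t(paired[[grp[1]]], paired[[grp[2]]])
    test <- tibble::tibble(comparison = paste(grp, collapse = " vs "),
                           n_pairs = nrow(paired),
                           mean_diff = mean(paired[[grp[1]]] - paired[[grp[2]]]),
                           statistic = ht$statistic,
                           p_value = ht$p_value)
  }
  structure(list(frequencies = freq, test = test), class = "ic_frequency")
}

#' @export
print.ic_frequency <- function(x, ...) {
  cat("<ic_frequency>\n")
  print(x$frequencies, n = 6)
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}

#' @export
tidy.ic_frequency <- function(x, ...) x$frequencies

#' @export
glance.ic_frequency <- function(x, ...) {
  x$test %||% tibble::tibble(comparison = NA_character_, n_pairs = 0L,
                             mean_diff = NA_real_, statistic = NA_real_,
                             p_value = NA_real_)
}
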