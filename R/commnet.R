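#' Per-group trimean expression summary
#'
#' Summarizes each group's expression by Tukey's trimean with
#' linear-interpolation quantiles. Because the summary is a per-group
#' statistic rather than a sum, interaction strengths are normalized for
#' cell-type frequency: group size cancels out. Groups below `min_cells`
#' are excluded with a warning.
#'
#' @param expr An `expr_matrix` (lognorm layer).
#' @param annotation Cell annotation tibble.
#' @param grouping Name of the annotation column defining groups.
#' @param genes Optional gene subset to summarize (default: all genes).
#' @param min_cells Minimum group size (default 10).
#' @return An object of class `group_expression`: list with `summary`
#'   (groups x genes matrix), `sizes`, `grouping`, `excluded`.
#' @export
group_trimean <- function(expr, annotation, grouping, genes = NULL,
                          min_cells = 10) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$layer_tag != "lognorm") abort("group_trimean expects a lognorm layer")
  if (!grouping %in% names(annotation)) {
    abort(sprintf("grouping column '%s' not in annotation", grouping))
  }
  ann <- annotation[annotation$cell_id %in% expr$cell_ids, ]
  labels <- setNames(as.character(ann[[grouping]]), ann$cell_id)
  if (is.null(genes)) genes <- expr$gene_ids else genes <- intersect(toupper(genes), expr$gene_ids)
  v <- expr$values[names(labels), genes, drop = FALSE]
  sizes <- table(labels)
  excluded <- names(sizes)[sizes < min_cells]
  if (length(excluded)) {
    warn(sprintf("excluding %d group(s) below min_cells = %d: %s",
                 length(excluded), min_cells, paste(excluded, collapse = ", ")))
  }
  keep <- setdiff(names(sizes), excluded)
  summ <- trimean_by_group(v, labels, keep)
  structure(list(summary = summ, sizes = c(sizes[keep]), grouping = grouping,
                 excluded = excluded), class = "group_expression")
}

# groups x genes trimean matrix for given group labels
trimean_by_group <- function(v, labels, groups) {
  out <- matrix(NA_real_, length(groups), ncol(v),
                dimnames = list(groups, colnames(v)))
  for (g in groups) {
    idx <- which(labels == g)
    sub <- v[idx, , drop = FALSE]
    q <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
               names = FALSE, type = 7)
    out[g, ] <- (q[1, ] + 2 * q[2, ] + q[3, ]) / 4
  }
  out
}

#' Law-of-mass-action interaction strength
#'
#' Hill-form strength `P = L*R / (Kh + L*R)` where `L` and `R` are the
#' geometric means of the ligand / receptor subunit summaries in the sender
#' and receiver group (a zero subunit nullifies the obligate complex). A
#' subunit absent from the measured genes yields strength 0 with a warning.
#'
#' @param ge A `group_expression`.
#' @param pair One row of an `lr_database` (or a list with
#'   `ligand_subunits` and `receptor_subunits`).
#' @param sender,receiver Group names.
#' @param kh Hill constant (default 0.5, on the lognorm summary scale).
#' @return Strength in `[0, 1)`.
#' @export
interaction_strength <- function(ge, pair, sender, receiver, kh = 0.5) {
  stopifnot(inherits(ge, "group_expression"))
  if (kh <= 0) abort("kh must be positive")
  lig <- unlist(pair$ligand_subunits)
  rec <- unlist(pair$receptor_subunits)
  measured <- colnames(ge$summary)
  if (!all(lig %in% measured) || !all(rec %in% measured)) {
    warn(sprintf("subunit gene(s) absent from matrix for pair %s; strength 0",
                 pair$pair_id %||% ""))
    return(0)
  }
  l <- geomean(ge$summary[sender, lig])
  r <- geomean(ge$summary[receiver, rec])
  (l * r) / (kh + l * r)
}

# strengths for every (sender, receiver, pair): internal vectorized core
comm_strengths <- function(summ, lrdb, kh) {
  groups <- rownames(summ)
  gm <- function(subunits) {
    vapply(subunits, function(s) {
      if (!all(s %in% colnames(summ))) return(rep(NA_real_, length(groups)))
      apply(summ[, s, drop = FALSE], 1, geomean)
    }, numeric(length(groups)))
  }
  lmat <- gm(lrdb$ligand_subunits) # groups x pairs
  rmat <- gm(lrdb$receptor_subunits)
  edges <- tidyr::expand_grid(sender = groups, receiver = groups,
                              k = seq_len(nrow(lrdb)))
  l <- lmat[cbind(match(edges$sender, groups), edges$k)]
  r <- rmat[cbind(match(edges$receiver, groups), edges$k)]
  lr <- l * r
  p <- ifelse(is.na(lr), 0, lr / (kh + lr))
  tibble::tibble(sender = edges$sender, receiver = edges$receiver,
                 pair_id = lrdb$pair_id[edges$k],
                 pathway = lrdb$pathway[edges$k], strength = p)
}

#' Communication graph with permutation p-values
#'
#' Computes the observed interaction strength for every (sender, receiver,
#' ligand-receptor pair) and its significance under random permutation of
#' group labels among cells: `p = (1 + #{perm: P_perm >= P_obs}) /
#' (1 + n_perm)`. Missing subunit genes yield strength-0 edges whose
#' p-value is 1 by the tie-counting convention.
#'
#' @param expr An `expr_matrix` (lognorm layer).
#' @param annotation Cell annotation tibble.
#' @param lrdb An `lr_database`.
#' @param grouping Annotation column defining the communicating groups.
#' @param n_perm Number of permutations (default 100, minimum 20).
#' @param seed Integer seed for the permutations.
#' @param kh Hill constant (default 0.5).
#' @param min_cells Minimum group size (default 10).
#' @param condition_tag Optional label stored on the graph (e.g. "MT").
#' @return A tibble of class `comm_graph` with columns `sender`, `receiver`,
#'   `pair_id`, `pathway`, `strength`, `p_value`; attribute `condition_tag`.
#' @export
permutation_pvalues <- function(expr, annotation, lrdb, grouping,
                                n_perm = 100, seed = 1, kh = 0.5,
                                min_cells = 10, condition_tag = NULL) {
  if (n_perm < 20) abort("n_perm must be at least 20")
  lr_genes <- unique(unlist(c(lrdb$ligand_subunits, lrdb$receptor_subunits)))
  ge <- group_trimean(expr, annotation, grouping,
                      genes = intersect(lr_genes, expr$gene_ids),
                      min_cells = min_cells)
  obs <- comm_strengths(ge$summary, lrdb, kh)

  ann <- annotation[annotation$cell_id %in% expr$cell_ids, ]
  labels <- setNames(as.character(ann[[grouping]]), ann$cell_id)
  labels <- labels[labels %in% rownames(ge$summary)]
  v <- expr$values[names(labels), colnames(ge$summary), drop = FALSE]

  exceed <- numeric(nrow(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- setNames(sample(labels), names(labels))
      summ_b <- trimean_by_group(v, perm, rownames(ge$summary))
      p_b <- comm_strengths(summ_b, lrdb, kh)$strength
      exceed <- exceed + (p_b >= obs$strength)
    }
  })
  obs$p_value <- (1 + exceed) / (1 + n_perm)
  attr(obs, "condition_tag") <- condition_tag
  attr(obs, "excluded_groups") <- ge$excluded
  structure(obs, class = c("comm_graph", class(obs)))
}

#' Differential communication network between two conditions
#'
#' Per (sender, receiver): the difference in significant-edge counts and in
#' summed significant strengths, condition A minus condition B, with the
#' dominant direction. Groups present in only one condition are compared
#' against zero and flagged.
#'
#' @param graph_a,graph_b `comm_graph` objects sharing a grouping vocabulary.
#' @param alpha_sig Significance level for including edges (default 0.05).
#' @return An object of class `diff_comm`: list with `summary` (per
#'   sender-receiver tibble), `edges` (per-pair tibble), `cond_a`, `cond_b`.
#' @export
differential_network <- function(graph_a, graph_b, alpha_sig = 0.05) {
  cond_a <- attr(graph_a, "condition_tag") %||% "condA"
  cond_b <- attr(graph_b, "condition_tag") %||% "condB"
  a <- tibble::as_tibble(graph_a)
  b <- tibble::as_tibble(graph_b)
  edges <- dplyr::full_join(a, b, by = c("sender", "receiver", "pair_id", "pathway"),
                            suffix = c("_a", "_b"))
  flagged <- is.na(edges$strength_a) | is.na(edges$strength_b)
  if (any(flagged)) {
    warn(sprintf("%d edge(s) present in one condition only; other side counted as 0",
                 sum(flagged)))
  }
  edges <- edges |>
    dplyr::mutate(
      flag = flagged,
      sig_a = !is.na(.data$p_value_a) & .data$p_value_a < alpha_sig,
      sig_b = !is.na(.data$p_value_b) & .data$p_value_b < alpha_sig,
      s_a = ifelse(.data$sig_a, .data$strength_a, 0),
      s_b = ifelse(.data$sig_b, .data$strength_b, 0),
      delta_strength = .data$s_a - .data$s_b
    )
  summary <- edges |>
    dplyr::group_by(.data$sender, .data$receiver) |>
    dplyr::summarise(delta_count = sum(.data$sig_a) - sum(.data$sig_b),
                     delta_strength = sum(.data$delta_strength),
                     flag = any(.data$flag), .groups = "drop") |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$delta_strength > 0 ~ cond_a,
      .data$delta_strength < 0 ~ cond_b,
      TRUE ~ NA_character_))
  structure(list(summary = summary,
                 edges = dplyr::select(edges, "sender", "receiver", "pair_id",
                                       "pathway", "strength_a", "p_value_a",
                                       "sig_a", "strength_b", "p_value_b",
                                       "sig_b", "delta_strength", "flag"),
                 cond_a = cond_a, cond_b = cond_b, alpha_sig = alpha_sig),
            class = "diff_comm")
}

#' @export
print.diff_comm <- function(x, ...) {
  cat(sprintf("<diff_comm> %s vs %s, %d sender-receiver pairs\n",
              x$cond_a, x$cond_b, nrow(x$summary)))
  print(x$summary, n = 10)
  invisible(x)
}

#' @export
tidy.diff_comm <- function(x, ...) x$edges

#' @export
glance.diff_comm <- function(x, ...) {
  tibble::tibble(cond_a = x$cond_a, cond_b = x$cond_b,
                 n_edges = nrow(x$edges),
                 n_sig_a = sum(x$edges$sig_a), n_sig_b = sum(x$edges$sig_b))
}

#' Pathway-level contribution to a differential network
#'
#' Aggregates significant-edge strength differences by pathway over a
#' sender/receiver class of interest (macrophage to pTRT by default usage),
#' ranked by the condition-A excess.
#'
#' @param diff A `diff_comm`.
#' @param sender,receiver Optional filters on the edge table.
#' @return Tibble `pathway`, `sender`, `receiver`, `delta_strength`,
#'   sorted decreasing.
#' @export
pathway_contribution <- function(diff, sender = NULL, receiver = NULL) {
  stopifnot(inherits(diff, "diff_comm"))
  e <- diff$edges
  if (!is.null(sender)) e <- e[e$sender %in% sender, ]
  if (!is.null(receiver)) e <- e[e$receiver %in% receiver, ]
  e |>
    dplyr::group_by(.data$pathway, .data$sender, .data$receiver) |>
    dplyr::summarise(delta_strength = sum(.data$delta_strength),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$delta_strength))
}
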