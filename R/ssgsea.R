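#' Per-cell single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each cell, genes are ranked by decreasing expression (ties get
#' average ranks for the hit weights and a deterministic lexicographic
#' gene-id tiebreak for positions). With `N` genes, a set `S` and weight
#' `w_i = (N - r_i + 1)^alpha` for hits, the enrichment score is the full
#' running-sum integral `ES = sum_i [P_hit(i) - P_miss(i)]` where `P_hit`
#' accumulates normalized hit weights and `P_miss` the fraction of misses
#' seen so far. The score is rank-based: any strictly monotone transform of
#' a cell's expression leaves it unchanged.
#'
#' Cells with zero library size are excluded from scoring (their count is
#' reported); set genes absent from the matrix are dropped with a warning;
#' a set with no measured genes yields `NA` scores; a set covering the whole
#' gene universe is an error (no misses to integrate against).
#'
#' @param expr An `expr_matrix` with a lognorm layer.
#' @param sets A `gene_set_collection`.
#' @param alpha Hit-weight exponent (default 0.25, standard single-sample
#'   GSEA weighting; 0 gives the unweighted statistic with closed forms).
#' @return An object of class `score_matrix`: list with `raw`
#'   (cells x sets), `z` (`NULL` until [normalize_scores()]), `cell_ids`,
#'   `set_names`.
#' @export
ssgsea_cell_scores <- function(expr, sets, alpha = 0.25) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sets, "gene_set_collection"))
  if (expr$layer_tag != "lognorm") abort("ssgsea_cell_scores expects a lognorm layer")
  if (alpha < 0) abort("alpha must be nonnegative")
  v <- expr$values
  keep <- rowSums(v) > 0
  if (!all(keep)) {
    inform(sprintf("excluding %d cells with zero library size from scoring",
                   sum(!keep)))
    v <- v[keep, , drop = FALSE]
  }
  if (nrow(v) == 0L) abort("no cells left to score")
  n_genes <- ncol(v)
  gene_ids <- colnames(v)

  present <- lapply(sets$sets, intersect, x = gene_ids)
  n_drop <- lengths(sets$sets) - lengths(present)
  if (any(n_drop > 0)) {
    warn(sprintf("%d set(s) had genes absent from the matrix (%d genes dropped)",
                 sum(n_drop > 0), sum(n_drop)))
  }
  full <- lengths(present) == n_genes
  if (any(full)) {
    abort(sprintf("set '%s' covers every measured gene; ES is undefined",
                  names(present)[full][1]))
  }
  empty <- lengths(present) == 0L

  # membership matrix: genes x sets (empty sets stay all-zero, scored NA)
  mem <- matrix(0, n_genes, length(present),
                dimnames = list(gene_ids, names(present)))
  for (j in seq_along(present)) mem[present[[j]], j] <- 1

  # per-cell reversed positions and tie-averaged weights
  lex <- order(gene_ids) # precomputed lexicographic tiebreak
  rev_pos <- matrix(0, nrow(v), n_genes)
  wt <- matrix(0, nrow(v), n_genes)
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    ord <- lex[order(-x[lex], method = "radix")] # stable: ties stay lexicographic
    rp <- numeric(n_genes)
    rp[ord] <- n_genes:1
    rev_pos[i, ] <- rp
    r_avg <- rank(-x, ties.method = "average")
    wt[i, ] <- (n_genes - r_avg + 1)^alpha
  }

  m <- colSums(mem)
  a <- (wt * rev_pos) %*% mem          # sum over hits of w * (N - pos + 1)
  w_hit <- wt %*% mem                  # sum over hits of w
  b <- rev_pos %*% mem                 # sum over hits of (N - pos + 1)
  total <- n_genes * (n_genes + 1) / 2
  es <- a / w_hit - sweep(-b + total, 2, n_genes - m, "/")
  es[, empty] <- NA_real_

  structure(list(raw = es, z = NULL, cell_ids = rownames(v),
                 set_names = names(present), alpha = alpha),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d cells x %d sets%s\n", length(x$cell_ids),
              length(x$set_names), if (is.null(x$z)) "" else " (z-normalized)"))
  invisible(x)
}

#' Z-normalize enrichment scores per set
#'
#' Centers and scales each set's scores across all scored cells (population
#' standard deviation), making the stringent classification cutoff
#' scale-free. Zero-variance sets are set to 0 with a warning; undefined
#' (`NA`) sets stay `NA`.
#'
#' @param scores A `score_matrix` with a raw layer.
#' @return The `score_matrix` with its `z` layer filled.
#' @export
normalize_scores <- function(scores) {
  stopifnot(inherits(scores, "score_matrix"))
  raw <- scores$raw
  mu <- colMeans(raw)
  n <- nrow(raw)
  sd_pop <- sqrt(colMeans(sweep(raw, 2, mu, "-")^2))
  flat <- !is.na(sd_pop) & sd_pop == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance set(s); z set to 0", sum(flat)))
    sd_pop[flat] <- 1
  }
  z <- sweep(sweep(raw, 2, mu, "-"), 2, sd_pop, "/")
  scores$z <- z
  scores
}

#' Tidy a score matrix into long format
#'
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `cell_id`, `set`, `raw` and (if normalized) `z`.
#' @export
tidy.score_matrix <- function(x, ...) {
  out <- tibble::tibble(
    cell_id = rep(x$cell_ids, times = length(x$set_names)),
    set = rep(x$set_names, each = length(x$cell_ids)),
    raw = as.vector(x$raw)
  )
  if (!is.null(x$z)) out$z <- as.vector(x$z)
  out
}

#' Random control gene sets
#'
#' Uniform sampling without replacement from the measured gene universe,
#' the negative control for the multi-signature classification (500-gene
#' sets in the emulated design).
#'
#' @param expr An `expr_matrix`.
#' @param n_genes Genes per control set (must not exceed the universe).
#' @param n_sets Number of control sets.
#' @param seed Integer seed; fixed seed gives identical sets.
#' @return A `gene_set_collection` with sets `random_ctrl_001` ...
#' @export
random_control_sets <- function(expr, n_genes = 500, n_sets = 1, seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  universe <- expr$gene_ids
  if (n_genes > length(universe)) {
    abort(sprintf("n_genes (%d) exceeds the measured gene universe (%d)",
                  n_genes, length(universe)))
  }
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(universe, n_genes))
    names(sets) <- sprintf("random_ctrl_%03d", seq_len(n_sets))
    gene_set_collection(sets, setNames(rep("random control", n_sets), names(sets)))
  })
}

#' Score one named gene program per cell
#'
#' Single-set convenience wrapper over [ssgsea_cell_scores()] returning the
#' z-normalized score, used for the Kupffer-cell, collagen-regulation and IC
#' composite scores.
#'
#' @param expr An `expr_matrix` (lognorm layer).
#' @param set_name Name of the set inside `sets`.
#' @param sets A `gene_set_collection`.
#' @param alpha Hit-weight exponent (default 0.25).
#' @return Tibble with columns `cell_id` and `score`.
#' @export
score_gene_program <- function(expr, set_name, sets, alpha = 0.25) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!set_name %in% names(sets$sets)) {
    abort(sprintf("unknown gene set '%s'", set_name))
  }
  one <- gene_set_collection(sets$sets[set_name], sets$description[set_name])
  sm <- normalize_scores(ssgsea_cell_scores(expr, one, alpha = alpha))
  tibble::tibble(cell_id = sm$cell_ids, score = sm$z[, 1])
}
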