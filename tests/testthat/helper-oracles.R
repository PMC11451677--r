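# Independent oracle implementations used to cross-check the fast paths.

# literal running-sum ssGSEA: walks the ranked gene list position by
# position, accumulating P_hit and P_miss
ssgsea_oracle <- function(x, gene_ids, set, alpha) {
  n <- length(x)
  ord <- order(-x, gene_ids)
  r_avg <- rank(-x, ties.method = "average")
  w <- (n - r_avg + 1)^alpha
  hits <- gene_ids %in% set
  m <- sum(hits)
  w_total <- sum(w[hits])
  es <- 0; ph <- 0; pm <- 0
  for (i in seq_len(n)) {
    g <- ord[i]
    if (hits[g]) ph <- ph + w[g] / w_total else pm <- pm + 1 / (n - m)
    es <- es + (ph - pm)
  }
  es
}

# double-loop Moran's I on a 0/1 symmetric adjacency matrix
moran_oracle <- function(adj, x) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0; w_total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + adj[i, j] * xc[i] * xc[j]
      w_total <- w_total + adj[i, j]
    }
  }
  denom <- sum(xc^2)
  if (denom == 0) return(0)
  (n / w_total) * num / denom
}

# double-loop nearest-neighbor distances
nn_oracle <- function(query, target) {
  vapply(seq_len(nrow(query)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(target))) {
      d <- sqrt(sum((query[i, ] - target[j, ])^2))
      if (d < best) best <- d
    }
    best
  }, 0)
}

# small helper: wrap a plain matrix as a lognorm expr_matrix
as_lognorm <- function(mat, cells = NULL, genes = NULL) {
  cells <- cells %||% sprintf("c%02d", seq_len(nrow(mat)))
  genes <- genes %||% sprintf("G%02d", seq_len(ncol(mat)))
  expression_matrix(mat, cells, genes, "lognorm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
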