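test_that("Moran's I matches the path-graph worked value and conventions", {
  adj <- matrix(0, 4, 4)
  adj[cbind(1:3, 2:4)] <- 1; adj <- adj + t(adj)
  expect_equal(morans_i(adj, c(1, 2, 3, 4)), 1 / 3)
  expect_identical(morans_i(adj, rep(2, 4)), 0) # constant convention
})

test_that("Moran's I equals the double-loop oracle on random graphs", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- 30
      adj <- matrix(rbinom(n * n, 1, 0.15), n, n)
      adj[lower.tri(adj, diag = TRUE)] <- 0
      adj <- adj + t(adj)
      if (sum(adj) == 0) next
      x <- rnorm(n)
      expect_equal(morans_i(adj, x), moran_oracle(adj, x), tolerance = 1e-12)
    }
  })
})

test_that("permutation null of Moran's I centers on -1/(n-1)", {
  withr::with_seed(33, {
    n <- 30
    adj <- matrix(rbinom(n * n, 1, 0.2), n, n)
    adj[lower.tri(adj, diag = TRUE)] <- 0
    adj <- adj + t(adj)
    sims <- vapply(1:400, function(i) morans_i(adj, rnorm(n)), 0)
    se <- sd(sims) / sqrt(length(sims))
    expect_lt(abs(mean(sims) - (-1 / (n - 1))), 3 * se)
  })
})

test_that("kNN graph construction is deterministic and respects structure", {
  # identical cells: tied distances broken deterministically, symmetric result
  e <- as_lognorm(matrix(1, 3, 4))
  g1 <- build_cell_graph(e, k = 1)
  g2 <- build_cell_graph(e, k = 1)
  expect_identical(as.matrix(g1$adjacency), as.matrix(g2$adjacency))
  expect_true(Matrix::isSymmetric(g1$adjacency))
  expect_error(build_cell_graph(e, k = 3), "smaller")

  # duplicated rows get identical adjacency patterns to their twins
  withr::with_seed(2, {
    base <- matrix(abs(rnorm(20 * 6)), 20, 6)
    e2 <- as_lognorm(rbind(base, base[1, , drop = FALSE]),
                     cells = c(sprintf("c%02d", 1:20), "c21"))
    g <- build_cell_graph(e2, k = 3)
    expect_true(g$adjacency["c01", "c21"] > 0) # duplicates are neighbors
  })

  # two well-separated blobs keep edges within blobs
  withr::with_seed(4, {
    blob <- rbind(matrix(rnorm(25 * 5), 25, 5),
                  matrix(rnorm(25 * 5, mean = 50), 25, 5))
    g <- suppressWarnings(build_cell_graph(as_lognorm(abs(blob)), k = 5))
    a <- as.matrix(g$adjacency)
    cross <- sum(a[1:25, 26:50])
    expect_lt(cross / sum(a), 0.01)
  })
})

test_that("pseudotime recovers the planted continuum and its reversal", {
  cfg <- cohort_config(seed = 3)
  cont <- make_macrophage_continuum(cfg)
  e <- normalize_expression(cont$expr)
  g <- build_cell_graph(e, seed = 1)
  pt <- compute_pseudotime(g, e)
  expect_equal(pt$pseudotime[pt$cell_id == attr(pt, "root_cell_id")], 0)
  m <- dplyr::inner_join(pt, cont$truth$latent_time, by = "cell_id")
  expect_gte(cor(m$pseudotime, m$latent_time, method = "spearman"), 0.9)

  # rooting at the max-SPP1 cell reverses the ordering
  spp1 <- setNames(e$values[, "SPP1"], e$cell_ids)
  pt_rev <- compute_pseudotime(g, e, root = spp1)
  m2 <- dplyr::inner_join(pt_rev, cont$truth$latent_time, by = "cell_id")
  expect_lte(cor(m2$pseudotime, m2$latent_time, method = "spearman"), -0.9)

  # invariance to global scaling of the expression matrix
  e_scaled <- expression_matrix(e$values * 3, e$cell_ids, e$gene_ids, "lognorm")
  g_s <- build_cell_graph(e_scaled, seed = 1)
  pt_s <- compute_pseudotime(g_s, e_scaled)
  expect_equal(pt_s$pseudotime, pt$pseudotime, tolerance = 1e-8)
})

test_that("gene ranking places trajectory-tracking genes on top", {
  cfg <- cohort_config(seed = 3, traj_n_cells = 150, traj_n_genes = 150)
  cont <- make_macrophage_continuum(cfg)
  e <- normalize_expression(cont$expr)
  g <- build_cell_graph(e, seed = 1)
  pt <- compute_pseudotime(g, e)
  # a synthetic gene equal to pseudotime itself must rank first
  e2 <- expression_matrix(cbind(e$values, AATIME = pt$pseudotime + 1),
                          e$cell_ids, c(e$gene_ids, "AATIME"), "lognorm")
  # truly i.i.d. genes (no library-size coupling) are mostly non-significant
  withr::with_seed(99, {
    noise <- matrix(abs(rnorm(nrow(e2$values) * 10)), ncol = 10,
                    dimnames = list(NULL, sprintf("ZNOISE%02d", 1:10)))
    e2 <- expression_matrix(cbind(e2$values, noise), e2$cell_ids,
                            c(e2$gene_ids, colnames(noise)), "lognorm")
  })
  mt <- rank_trajectory_genes(g, e2, n_perm = 49, seed = 5)
  expect_identical(mt$gene[1], "AATIME")
  expect_identical(mt$rank, seq_len(nrow(mt)))
  noise_p <- mt$p_value[grepl("^ZNOISE", mt$gene)]
  expect_gt(mean(noise_p > 0.05), 0.8)
})

test_that("branch subclustering isolates an intermediate IC state", {
  cfg <- cohort_config(seed = 3)
  cont <- make_macrophage_continuum(cfg)
  e <- normalize_expression(cont$expr)
  g <- build_cell_graph(e, seed = 1)
  pt <- compute_pseudotime(g, e)
  bc <- suppressWarnings(subcluster_branch(pt, e, seed = 1))
  med <- attr(bc, "state_summary")
  med_t <- setNames(med$median_pseudotime, med$state)
  expect_true(med_t["KC"] < med_t["IC"] && med_t["IC"] < med_t["SPP1"])
  for (gene in c("TGFBR1", "IL6R")) {
    by_state <- tapply(e$values[bc$cell_id, gene], bc$state, mean)
    expect_identical(names(which.max(by_state)), "IC")
  }
  one <- suppressWarnings(subcluster_branch(pt, e, n_clusters = 1, seed = 1))
  expect_identical(length(unique(one$cluster)), 1L)
})

test_that("IC co-expression is a strict conjunction and ignores other cell types", {
  genes <- c("SPP1", "TGFBR1", "IL6R", "CSF1R", "VSIG4", "CD163")
  vals <- rbind(rep(1, 6), c(1, 1, 1, 1, 1, 0), rep(2, 6))
  e <- expression_matrix(vals, c("m1", "m2", "x1"), genes, "lognorm")
  ann <- tibble::tibble(cell_id = c("m1", "m2", "x1"), patient = "P01",
                        tissue = c("MT", "MT", "MT"), cluster = "Mac",
                        coarse_type = c("macrophage", "macrophage", "CD8T"))
  icf <- ic_coexpression_frequency(e, ann)
  # m1 counts, m2 misses CD163 only, the CD8 cell is ignored entirely
  expect_equal(icf$frequencies$n_ic, 1L)
  expect_equal(icf$frequencies$n_macmono, 2L)
  # adding non-macrophage cells does not change the frequency
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(
    cell_id = "x1", patient = "P01", tissue = "MT", cluster = "T",
    coarse_type = "other"))
  expect_equal(ic_coexpression_frequency(e, ann)$frequencies$n_ic,
               ic_coexpression_frequency(e, ann2[-3, ])$frequencies$n_ic)
})

test_that("planted liver IC excess is detected by the paired test", {
  cfg <- cohort_config(seed = 11, n_patients = 8, cells_per_tissue = 150,
                       n_genes = 120, tissues = c("MT", "MN", "PT", "PN"))
  co <- make_cohort(cfg)
  icf <- ic_coexpression_frequency(co$expr, co$annotation)
  expect_lt(icf$test$p_value, 0.05)
  expect_gt(icf$test$mean_diff, 0)
})
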