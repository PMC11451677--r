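test_that("single top/bottom gene at alpha = 0 hits the closed forms ES = +/- N/2", {
  x <- c(4, 3, 2, 1)
  e <- as_lognorm(rbind(x), genes = c("G1", "G2", "G3", "G4"))
  top <- ssgsea_cell_scores(e, gene_set_collection(list(S = "G1")), alpha = 0)
  expect_equal(unname(top$raw[1, 1]), 2)
  bottom <- ssgsea_cell_scores(e, gene_set_collection(list(S = "G4")), alpha = 0)
  expect_equal(unname(bottom$raw[1, 1]), -2)
})

test_that("fast ssGSEA equals the literal running-sum oracle on random instances", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n_genes <- 50; n_cells <- 5
      genes <- sprintf("G%02d", seq_len(n_genes))
      mat <- matrix(round(rexp(n_cells * n_genes), 2), n_cells, n_genes)
      mat[sample(length(mat), length(mat) / 3)] <- 0 # heavy ties at zero
      e <- as_lognorm(mat, genes = genes)
      alpha <- sample(c(0, 0.25, 1), 1)
      sets <- lapply(1:5, function(i) sample(genes, sample(2:49, 1)))
      names(sets) <- sprintf("S%d", 1:5)
      sm <- ssgsea_cell_scores(e, gene_set_collection(sets), alpha = alpha)
      for (ci in seq_len(n_cells)) {
        for (si in seq_along(sets)) {
          expect_equal(unname(sm$raw[ci, si]),
                       ssgsea_oracle(mat[ci, ], genes, sets[[si]], alpha),
                       tolerance = 1e-9)
        }
      }
    }
  })
})

test_that("ES is rank-based: monotone transforms leave scores unchanged", {
  withr::with_seed(7, {
    mat <- matrix(rexp(10 * 30), 10, 30)
    e1 <- as_lognorm(mat)
    e2 <- as_lognorm(log1p(mat) * 3)
    sets <- gene_set_collection(list(S = sprintf("G%02d", 1:7)))
    expect_equal(ssgsea_cell_scores(e1, sets)$raw,
                 ssgsea_cell_scores(e2, sets)$raw, tolerance = 1e-12)
  })
})

test_that("ssGSEA handles absent genes, empty sets and degenerate inputs", {
  e <- as_lognorm(rbind(c(3, 2, 1), c(1, 2, 3)), genes = c("A", "B", "C"))
  expect_warning(sm <- ssgsea_cell_scores(e, gene_set_collection(list(S = c("A", "ZZZ")))),
                 "absent")
  expect_true(all(is.finite(sm$raw)))
  sm2 <- suppressWarnings(
    ssgsea_cell_scores(e, gene_set_collection(list(S = c("Q1", "Q2")))))
  expect_true(all(is.na(sm2$raw))) # undefined-flag when no set gene measured
  expect_error(ssgsea_cell_scores(e, gene_set_collection(list(S = c("A", "B", "C")))),
               "every measured gene")
  # zero-library cells are excluded from scoring
  e3 <- as_lognorm(rbind(c(1, 2, 0), c(0, 0, 0)), genes = c("A", "B", "C"))
  expect_message(sm3 <- ssgsea_cell_scores(e3, gene_set_collection(list(S = "A"))),
                 "zero library")
  expect_identical(length(sm3$cell_ids), 1L)
})

test_that("z-normalization is population-scaled per set", {
  sm <- ssgsea_cell_scores(as_lognorm(matrix(rexp(40), 4, 10)),
                           gene_set_collection(list(S = c("G01", "G02"))))
  # constant column -> zeros with a warning
  sm$raw[, 1] <- 5
  expect_warning(z <- normalize_scores(sm), "zero-variance")
  expect_true(all(z$z[, 1] == 0))
  # (-1, 1) is already standardized under the population convention
  sm2 <- sm; sm2$raw <- matrix(c(-1, 1), 2, 1,
                               dimnames = list(NULL, "S"))
  sm2$cell_ids <- c("a", "b"); sm2$set_names <- "S"
  z2 <- normalize_scores(sm2)
  expect_equal(unname(z2$z[, 1]), c(-1, 1))
  expect_lt(abs(mean(z2$z[, 1])), 1e-9)
})

test_that("pTRT classification applies the multi-signature cutoff rule", {
  z <- matrix(0, 3, 10, dimnames = list(NULL, sprintf("s%d", 1:10)))
  z[2, 1] <- 3 # passes exactly min_sets = 1 set
  sm <- structure(list(raw = z, z = z, cell_ids = c("a", "b", "c"),
                       set_names = colnames(z)), class = "score_matrix")
  ann <- tibble::tibble(cell_id = c("a", "b", "c"),
                        coarse_type = c("CD8T", "CD8T", "macrophage"))
  calls <- classify_ptrt(sm, ann, cutoff_z = 2, min_sets = 1)
  expect_identical(calls$cell_id, c("a", "b")) # only CD8 T cells carry calls
  expect_identical(calls$is_ptrt, c(FALSE, TRUE))
  # all-zero z matrix: zero pTRT
  calls0 <- classify_ptrt(sm, ann, cutoff_z = 2, min_sets = NULL)
  expect_identical(sum(calls0$is_ptrt[calls0$cell_id == "a"]), 0L)
  expect_warning(classify_ptrt(sm, dplyr::mutate(ann, coarse_type = "NK")),
                 "no CD8")
})

test_that("frequency and composition tables follow their contracts", {
  calls <- structure(tibble::tibble(
    cell_id = sprintf("c%d", 1:10),
    is_ptrt = c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5)), # 3 Tex + 1 TRM
    n_sets_passed = 0L, cutoff_z = 2, min_sets = 10L),
    class = c("ptrt_calls", "tbl_df", "tbl", "data.frame"))
  ann <- tibble::tibble(cell_id = sprintf("c%d", 1:10), patient = "P01",
                        tissue = "MT", cluster = rep(c("Tex", "TRM"), c(4, 6)),
                        coarse_type = "CD8T")
  freq <- tissue_ptrt_frequency(calls, ann)
  expect_equal(freq$frequency[freq$tissue == "MT"], 0.4)
  comp <- cluster_composition(calls, ann)
  expect_equal(sum(comp$fraction_of_ptrt), 1, tolerance = 1e-9)
  expect_equal(comp$fraction_of_ptrt[comp$cluster == "Tex"], 0.75)
  # tissue with zero CD8 cells gets an NA frequency row
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(
    cell_id = "x1", patient = "P01", tissue = "PN", cluster = "Mac",
    coarse_type = "macrophage"))
  freq2 <- tissue_ptrt_frequency(calls, ann2)
  expect_true(is.na(freq2$frequency[freq2$tissue == "PN"]))
})

test_that("random control sets are seeded and bounded by the universe", {
  e <- as_lognorm(matrix(rexp(60), 3, 20))
  a <- random_control_sets(e, 10, 2, seed = 9)
  b <- random_control_sets(e, 10, 2, seed = 9)
  expect_identical(a$sets, b$sets)
  expect_error(random_control_sets(e, 21, 1), "exceeds")
  full <- random_control_sets(e, 20, 1)
  expect_setequal(full$sets[[1]], e$gene_ids)
})

test_that("score_gene_program equals the matching ssGSEA column", {
  withr::with_seed(11, {
    e <- as_lognorm(matrix(rexp(200), 10, 20))
    sets <- gene_set_collection(list(A = sprintf("G%02d", 1:4),
                                     B = sprintf("G%02d", 5:9)))
    full <- normalize_scores(ssgsea_cell_scores(e, sets))
    one <- score_gene_program(e, "B", sets)
    expect_equal(one$score, unname(full$z[, "B"]))
    expect_error(score_gene_program(e, "missing", sets), "unknown")
  })
})

test_that("permuting tissue labels destroys the planted frequency ordering", {
  cfg <- cohort_config(seed = 9, n_patients = 4, cells_per_tissue = 150,
                       n_genes = 150)
  co <- make_cohort(cfg)
  ann <- co$annotation
  calls <- structure(
    dplyr::inner_join(co$truth$ptrt_labels,
                      ann[ann$coarse_type == "CD8T", "cell_id"], by = "cell_id") |>
      dplyr::mutate(n_sets_passed = 0L, cutoff_z = 2, min_sets = 1L),
    class = c("ptrt_calls", "tbl_df", "tbl", "data.frame"))
  planted_rank <- setNames(1:6, c("MT", "LN", "PT", "MN", "PN", "PBMC"))
  taus <- withr::with_seed(123, vapply(1:30, function(i) {
    perm_ann <- ann
    perm_ann$tissue <- sample(perm_ann$tissue)
    summ <- summarize_ptrt_frequency(tissue_ptrt_frequency(calls, perm_ann))
    cor(planted_rank[summ$tissue], seq_len(nrow(summ)), method = "kendall")
  }, 0))
  # centered on zero: permutation removes the ordering signal
  expect_lt(abs(mean(taus)), 2.5 * sd(taus) / sqrt(length(taus)) + 0.05)
  # the unpermuted labels sit far above that null (rare-tissue counts can
  # swap adjacent ranks at this cohort size, so exact tau = 1 is not asked)
  real <- summarize_ptrt_frequency(tissue_ptrt_frequency(calls, ann))
  expect_gte(cor(planted_rank[real$tissue], seq_len(nrow(real)),
                 method = "kendall"), 0.7)
})
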