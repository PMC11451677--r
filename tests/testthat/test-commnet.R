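test_that("trimean matches the quantile worked examples", {
  expect_equal(trimean(c(1, 2, 3, 4)), 2.5) # Q1 = 1.75, Q2 = 2.5, Q3 = 3.25
  expect_equal(trimean(rep(7, 5)), 7)
  expect_equal(trimean(c(0, 0, 0, 0, 10)), 0) # sparse expression suppressed
})

test_that("group summaries normalize for cell-type frequency", {
  withr::with_seed(3, {
    vals <- matrix(rexp(60 * 4), 60, 4)
    e <- as_lognorm(vals)
    ann <- tibble::tibble(cell_id = e$cell_ids,
                          group = rep(c("A", "B"), c(20, 40)))
    ge <- group_trimean(e, ann, "group")
    # duplicating every cell of one group leaves the trimean essentially
    # unchanged (size cancels; only quantile interpolation moves)
    e2 <- as_lognorm(rbind(vals, vals[1:20, ]),
                     cells = c(e$cell_ids, sprintf("dup%02d", 1:20)))
    ann2 <- dplyr::bind_rows(ann, dplyr::mutate(ann[1:20, ],
                                                cell_id = sprintf("dup%02d", 1:20)))
    ge2 <- group_trimean(e2, ann2, "group")
    expect_lt(max(abs(ge$summary["A", ] - ge2$summary["A", ])), 0.05)
    expect_equal(ge$summary["B", ], ge2$summary["B", ], tolerance = 1e-12)
    # small groups are excluded with a warning
    ann3 <- ann; ann3$group[1:5] <- "tiny"
    expect_warning(ge3 <- group_trimean(e, ann3, "group"), "min_cells")
    expect_false("tiny" %in% rownames(ge3$summary))
  })
})

test_that("mass-action strength follows the Hill form", {
  summ <- rbind(A = c(SPP1 = 1, CD44 = 0.5, X = 0),
                B = c(SPP1 = 2, CD44 = 1, X = 3))
  ge <- structure(list(summary = summ, sizes = c(A = 10, B = 10),
                       grouping = "g", excluded = character(0)),
                  class = "group_expression")
  pair <- list(pair_id = "SPP1_CD44", ligand_subunits = list("SPP1"),
               receptor_subunits = list("CD44"))
  # L*R = Kh gives the Hill midpoint 0.5 (L = 1 in A, R = 0.5 in A)
  expect_equal(interaction_strength(ge, pair, "A", "A", kh = 0.5), 0.5)
  # L = 0 nullifies
  pair0 <- list(pair_id = "X", ligand_subunits = list("X"),
                receptor_subunits = list("CD44"))
  expect_equal(interaction_strength(ge, pair0, "A", "B"), 0)
  # direct arithmetic: L = R = 1 with Kh = 0.5 -> 2/3
  expect_equal(interaction_strength(ge, pair, "A", "B", kh = 0.5), 2 / 3)
  # absent subunit -> strength 0 with warning
  pair_na <- list(pair_id = "Q", ligand_subunits = list("NOPE"),
                  receptor_subunits = list("CD44"))
  expect_warning(s <- interaction_strength(ge, pair_na, "A", "B"), "absent")
  expect_equal(s, 0)
})

test_that("strength is monotone in ligand and receptor and saturates at 1", {
  p <- function(l, r, kh = 0.5) (l * r) / (kh + l * r)
  ls <- seq(0, 5, 0.5)
  expect_true(all(diff(p(ls, 1)) >= 0))
  expect_true(all(diff(p(1, ls)) >= 0))
  expect_lt(1 - p(1e6, 1e6), 1e-10)
})

test_that("permutation p-values respect the +1 estimator bounds", {
  withr::with_seed(5, {
    vals <- matrix(rexp(80 * 3), 80, 3)
    e <- as_lognorm(vals, genes = c("SPP1", "CD44", "FN1"))
    ann <- tibble::tibble(cell_id = e$cell_ids,
                          group = rep(c("A", "B"), 40))
    lr <- lr_database("SPP1_CD44", "SPP1", "CD44", "SPP1")
    g <- permutation_pvalues(e, ann, lr, "group", n_perm = 20, seed = 1)
    expect_true(all(g$p_value >= 1 / 21 & g$p_value <= 1))
    # an edge whose strength is 0 (missing gene) gets p = 1 by tie counting
    lr2 <- lr_database("Q_R", "MISSING", "CD44", "Q")
    g2 <- suppressWarnings(permutation_pvalues(e, ann, lr2, "group",
                                               n_perm = 20, seed = 1))
    expect_true(all(g2$strength == 0))
    expect_true(all(g2$p_value == 1))
    expect_error(permutation_pvalues(e, ann, lr, "group", n_perm = 5), "at least 20")
  })
})

test_that("differential network handles identical graphs and one-sided edges", {
  g <- structure(tibble::tibble(
    sender = "A", receiver = "B", pair_id = "p1", pathway = "SPP1",
    strength = 0.4, p_value = 0.01), class = c("comm_graph", "tbl_df", "tbl", "data.frame"))
  attr(g, "condition_tag") <- "MT"
  gb <- g; attr(gb, "condition_tag") <- "PT"
  d0 <- differential_network(g, gb)
  expect_equal(d0$summary$delta_count, 0L)
  expect_equal(d0$summary$delta_strength, 0)
  expect_true(is.na(d0$summary$direction))

  # significant only in condition A with P = 0.4
  gb2 <- dplyr::mutate(gb, p_value = 0.8)
  attr(gb2, "condition_tag") <- "PT"
  class(gb2) <- class(g)
  d1 <- differential_network(g, gb2)
  expect_equal(d1$summary$delta_count, 1L)
  expect_equal(d1$summary$delta_strength, 0.4)
  expect_identical(d1$summary$direction, "MT")

  # group present in one condition only: other side counted as zero, flagged
  gb3 <- dplyr::mutate(gb, sender = "C")
  class(gb3) <- class(g); attr(gb3, "condition_tag") <- "PT"
  expect_warning(d2 <- differential_network(g, gb3), "one condition")
  expect_true(all(d2$summary$flag))
})

test_that("pathway contributions aggregate edge differences", {
  edges <- tibble::tibble(
    sender = "macrophage", receiver = "pTRT",
    pair_id = c("a", "b", "c"), pathway = c("FN1", "FN1", "SPP1"),
    strength_a = 1, p_value_a = 0.01, sig_a = TRUE,
    strength_b = 1, p_value_b = 0.01, sig_b = TRUE,
    delta_strength = c(0.2, 0.3, 0.1), flag = FALSE)
  diff <- structure(list(summary = NULL, edges = edges, cond_a = "MT",
                         cond_b = "PT", alpha_sig = 0.05), class = "diff_comm")
  pc <- pathway_contribution(diff)
  expect_equal(pc$delta_strength[pc$pathway == "FN1"], 0.5)
  expect_equal(pc$delta_strength[pc$pathway == "SPP1"], 0.1)
})

test_that("planted SPP1 pathway dominates the macrophage-to-pTRT differential", {
  # at this reduced cohort size the strict first-place ranking is noisy
  # (the full-size ranking is checked by the acceptance suite); here the
  # stable properties are the flagged SPP1_CD44 edge and a top-2 pathway
  res <- vapply(1:5, function(s) {
    cfg <- cohort_config(seed = s, n_patients = 6, cells_per_tissue = 200,
                         tissues = c("MT", "PT"), n_genes = 150)
    co <- make_cohort(cfg)
    ann <- co$annotation
    truth <- co$truth$ptrt_labels
    grp <- ann$coarse_type
    grp[ann$cell_id %in% truth$cell_id[truth$is_ptrt]] <- "pTRT"
    grp[grp == "CD8T"] <- "CD8_nonreactive"
    ann$group <- grp
    graph_of <- function(tis, sd) {
      sub_ann <- ann[ann$tissue == tis, ]
      sub <- normalize_expression(subset_expression(co$expr, cells = sub_ann$cell_id))
      suppressWarnings(permutation_pvalues(sub, sub_ann, default_lr_database(),
                                           "group", n_perm = 50, seed = sd,
                                           condition_tag = tis))
    }
    diff <- suppressWarnings(differential_network(graph_of("MT", s), graph_of("PT", s + 100)))
    pc <- pathway_contribution(diff, sender = "macrophage", receiver = "pTRT")
    e <- diff$edges[diff$edges$sender == "macrophage" &
                      diff$edges$receiver == "pTRT" &
                      diff$edges$pair_id == "SPP1_CD44", ]
    c(edge = e$delta_strength > 0 && e$sig_a,
      top2 = which(pc$pathway == "SPP1") <= 2)
  }, c(edge = TRUE, top2 = TRUE))
  expect_gte(sum(res["edge", ]), 4)
  expect_gte(sum(res["top2", ]), 4)
})
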