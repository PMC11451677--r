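test_that("threshold phenotyping uses the at-least convention and subset logic", {
  cells <- spatial_cells(tibble::tibble(
    cell_id = c("a", "b", "c"), x = 1:3, y = 1:3,
    CD8 = c(4, 0, 5), CD68 = c(0, 0, 0), CD56 = 0, FOXP3 = 0,
    KI67 = c(0, 0, 6), CD45RA = 0, CD45RO = 0, CD39 = 0), "S")
  ph <- threshold_phenotypes(cells, default_phenotype_definitions(cutoff = 4))
  expect_identical(ph$CD8T, c(TRUE, FALSE, TRUE)) # boundary counts as positive
  expect_identical(ph$macrophage, rep(FALSE, 3)) # all-zero intensities
  # subset phenotype implies parent
  expect_true(all(!ph$KI67pos_CD8T | ph$CD8T))
  expect_error(threshold_phenotypes(cells, list(x = c(NOPE = 1))), "NOPE")
})

test_that("point-in-polygon follows the even-odd, boundary-inside convention", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_true(point_in_polygon(0.5, 0.5, square))
  expect_false(point_in_polygon(1.5, 0.5, square))
  expect_true(point_in_polygon(0, 0, square))   # vertex
  expect_true(point_in_polygon(0.5, 0, square)) # edge midpoint
})

test_that("region assignment resolves overlaps by order and defaults to background", {
  cells <- spatial_cells(tibble::tibble(
    cell_id = c("a", "b", "c"), x = c(0.75, 1.5, 0.25), y = c(0.75, 0.5, 0.25)), "S")
  regions <- region_set(
    list(R1 = cbind(c(0, 0.5, 0.5, 0), c(0, 0, 0.5, 0.5)),
         R2 = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
    c("ASMA_NEG", "ASMA_POS"), "S", field = c(2, 2))
  asg <- assign_regions(cells, regions)
  expect_identical(asg$region_id, c("R2", NA, "R1")) # first listed wins for c
  expect_identical(asg$region_class, c("ASMA_POS", "ASMA_NEG", "ASMA_NEG"))
})

test_that("density arithmetic is exact on known-area rectangles", {
  cells <- spatial_cells(tibble::tibble(
    cell_id = sprintf("m%d", 1:5), x = seq(10, 90, 20), y = 50,
    CD68 = 9), "S")
  regions <- region_set(list(R1 = cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))),
                        "ASMA_POS", "S", field = c(1000, 1000))
  ph <- threshold_phenotypes(cells, list(macrophage = c(CD68 = 4)))
  asg <- assign_regions(cells, regions)
  dens <- region_density(asg, ph, regions)
  # 5 macrophages in a 100x100 um polygon = 500 per mm^2
  expect_equal(unname(dens$density_per_mm2[dens$region_class == "ASMA_POS"]), 500)
  expect_equal(unname(dens$density_per_mm2[dens$region_class == "ASMA_NEG"]), 0)
  # density conservation: sum(density * area) = total count
  expect_equal(sum(dens$density_per_mm2 * dens$area_mm2), 5)
})

test_that("nearest-neighbor distances are exact", {
  expect_equal(nn_distance(cbind(0, 0), cbind(3, 4)), 5) # 3-4-5 triangle
  expect_equal(nn_distance(cbind(1, 1), rbind(c(5, 5), c(1, 1))), 0)
  expect_true(is.na(nn_distance(cbind(0, 0), matrix(0, 0, 2))))
  withr::with_seed(13, {
    q <- matrix(runif(400) * 100, 200, 2)
    t_ <- matrix(runif(400) * 100, 200, 2)
    expect_equal(nn_distance(q, t_), nn_oracle(q, t_), tolerance = 1e-9)
  })
})

test_that("distance statistics are translation and rotation invariant", {
  withr::with_seed(14, {
    q <- matrix(runif(60), 30, 2); t_ <- matrix(runif(60), 30, 2)
    d0 <- nn_distance(q, t_)
    shift <- c(13, -7)
    expect_equal(nn_distance(sweep(q, 2, shift, "+"), sweep(t_, 2, shift, "+")),
                 d0, tolerance = 1e-9)
    th <- 0.7; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(nn_distance(q %*% rot, t_ %*% rot), d0, tolerance = 1e-9)
  })
})

test_that("fraction within radius follows the 100 um rule", {
  expect_equal(fraction_within_radius(c(50, 150), rho = 100), 0.5)
  expect_equal(fraction_within_radius(c(200, 300), rho = 100), 0)
  expect_equal(fraction_within_radius(c(200, 300), rho = Inf), 1)
  expect_true(is.na(fraction_within_radius(numeric(0))))
  expect_error(fraction_within_radius(1, rho = 0), "positive")
})

test_that("paired region comparison honors its degenerate conventions", {
  base <- tibble::tibble(
    sample_id = rep(sprintf("S%d", 1:4), each = 2),
    region_class = rep(c("ASMA_POS", "ASMA_NEG"), 4),
    query = "macrophage", target = "CD8T",
    mean_nn = rep(c(30, 30), 4))
  t0 <- paired_region_stats(base, "macrophage", "CD8T")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # constant shift with zero noise: p -> 0 with matching sign
  shifted <- dplyr::mutate(base, mean_nn = ifelse(region_class == "ASMA_POS",
                                                  20, 30))
  t1 <- paired_region_stats(shifted, "macrophage", "CD8T")
  expect_equal(t1$p_value, 0)
  expect_lt(t1$statistic, 0)
  expect_error(paired_region_stats(base[1:4, ], "macrophage", "CD8T"),
               "fewer than 3")
})
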