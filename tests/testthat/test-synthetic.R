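test_that("the elevation generator is deterministic and honors basin counts", {
  a <- generate_dem(20, 25, 3, noise_sd = 0.05, seed = 7)
  b <- generate_dem(20, 25, 3, noise_sd = 0.05, seed = 7)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$truth$basin_labels, b$truth$basin_labels)
  c2 <- generate_dem(20, 25, 3, noise_sd = 0.05, seed = 8)
  expect_false(identical(a$dem$values, c2$dem$values))
  expect_error(generate_dem(5, 5, 50, seed = 1), "infeasible")
  expect_error(generate_dem(10, 10, 0, seed = 1), ">= 1")
})

test_that("a single noiseless bowl delineates to exactly one unit", {
  sim <- generate_dem(15, 15, 1, seed = 2)
  du <- delineate_units(sim$dem)
  expect_equal(nrow(du$units), 1L)
  expect_equal(du$units$n_cells, 225L)
})

test_that("noiseless multi-basin surfaces delineate to the ground truth away from ridges", {
  for (seed in c(3, 13, 23)) {
    sim <- generate_dem(24, 24, 4, seed = seed)
    du <- delineate_units(sim$dem)
    away <- sim$truth$ridge_distance > 1
    got <- du$basin[away]
    want <- sim$truth$basin_labels[away]
    # perfect agreement up to label names: each truth basin maps to exactly
    # one delineated basin (adjusted Rand 1 on this subset)
    tab <- table(got, want)
    expect_equal(nrow(tab), 4L)
    expect_equal(sum(apply(tab, 2, max)), sum(tab))
    expect_equal(sum(apply(tab, 1, max)), sum(tab))
  }
})

test_that("unit geometry tessellation partitions the rectangle exactly", {
  one <- generate_unit_geometries(1, mean_area_m2 = 10000, seed = 5)
  expect_equal(nrow(one$units), 1L)
  g1 <- one$grid
  expect_equal(one$units$area_m2, g1$nrow * g1$ncol * g1$cellsize^2)

  u <- generate_unit_geometries(12, mean_area_m2 = 20000, seed = 6)
  expect_equal(nrow(u$units), 12L)
  g <- u$grid
  expect_equal(sum(u$units$area_m2), g$nrow * g$ncol * g$cellsize^2)
  expect_false(anyNA(u$labels))
  # adjacency symmetric and equal to a brute-force shared-edge scan
  adj <- u$adjacency
  brute <- lapply(stats::setNames(nm = as.character(u$units$id)),
                  function(...) integer(0))
  for (i in seq_len(g$nrow)) for (j in seq_len(g$ncol)) {
    for (d in list(c(0, 1), c(1, 0))) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni > g$nrow || nj > g$ncol) next
      a <- u$labels[i, j]; b <- u$labels[ni, nj]
      if (a != b) {
        brute[[as.character(a)]] <- union(brute[[as.character(a)]], b)
        brute[[as.character(b)]] <- union(brute[[as.character(b)]], a)
      }
    }
  }
  for (id in names(adj)) {
    expect_setequal(adj[[id]], brute[[id]])
    for (v in adj[[id]]) expect_true(as.integer(id) %in% adj[[as.character(v)]])
  }
})

test_that("the copula generator reproduces target correlations", {
  idn <- diag(10)
  g0 <- generate_indicator_table(2000, target_correlation = idn, seed = 42)
  emp0 <- cor(as.matrix(g0$table[, -1]))
  expect_lt(max(abs(emp0[upper.tri(emp0)])), 0.06)

  tgt <- default_target_correlation()
  g1 <- generate_indicator_table(2000, seed = 42)
  emp1 <- cor(as.matrix(g1$table[, -1]))
  expect_lt(max(abs(emp1 - tgt)), 0.06)
  expect_lt(abs(emp1["TIDER", "RESID"] - tgt["TIDER", "RESID"]), 0.03)
  expect_gt(tgt["TIDER", "RESID"], 0.9)   # the strongest published pair

  # determinism
  g2 <- generate_indicator_table(2000, seed = 42)
  expect_identical(g1$table, g2$table)

  bad <- idn; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(generate_indicator_table(100, target_correlation = bad),
               "positive semidefinite")
})

test_that("raw values live on the published ranges and orientation is monotone", {
  g <- generate_indicator_table(500, seed = 3)
  spec <- wvi_indicators()
  for (k in seq_len(10)) {
    lb <- spec$label[k]
    expect_gte(min(g$raw[[lb]]), spec$range_min[k])
    expect_lte(max(g$raw[[lb]]), spec$range_max[k])
    rho <- cor(g$raw[[lb]], g$table[[lb]], method = "spearman")
    expect_equal(rho, if (spec$direction[k] == "inverted") -1 else 1)
  }
})

test_that("monotone marginals leave percentile ranks unchanged", {
  g <- generate_indicator_table(200, seed = 9)
  for (lb in c("TIDER", "UVVR", "SHORE")) {
    # oriented table values are strictly increasing in the copula uniform,
    # so the percentile categories must coincide with those of the latent
    from_table <- percentile_rank(g$table[[lb]])$category
    from_latent <- percentile_rank(g$truth$uniforms[, lb])$category
    expect_identical(from_table, from_latent)
  }
})

test_that("spatial gradients tilt the selected indicators along the axis", {
  u <- generate_unit_geometries(60, seed = 21)
  g <- generate_indicator_table(u, gradient_axis = "NS",
                                gradient_strength = 3, seed = 22)
  y <- u$units$centroid_y
  expect_gt(cor(g$table$TIDER, y), 0.4)
  expect_gt(cor(g$table$RESID, y), 0.4)
  g0 <- generate_indicator_table(u, gradient_strength = 0, seed = 22)
  expect_lt(abs(cor(g0$table$TIDER, y)), 0.4)
})

test_that("clustered tables carry exact sizes, labels and recoverable structure", {
  gc <- generate_clustered_table(sizes = c(51L, 18L, 31L), seed = 4)
  expect_equal(dim(gc$table), c(100L, 10L))
  expect_equal(as.integer(table(gc$labels)), c(51L, 18L, 31L))
  expect_identical(gc$table,
                   generate_clustered_table(sizes = c(51L, 18L, 31L),
                                            seed = 4)$table)
  # a single component gives vanishing departures
  one <- generate_clustered_table(sizes = 80L, means = matrix(0, 1, 4),
                                  covariances = list(diag(4)), seed = 5)
  dep <- cluster_departures(znormalize(one$table), rep(1L, 80))
  expect_true(all(abs(dep$means) < 1e-12))
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(generate_clustered_table(sizes = c(10L, 10L),
                                        means = matrix(0, 2, 2),
                                        covariances = list(bad, bad),
                                        seed = 1),
               "positive definite")
})

test_that("the default target correlation is a valid PSD correlation matrix", {
  tgt <- default_target_correlation()
  expect_true(isSymmetric(tgt))
  expect_equal(unname(diag(tgt)), rep(1, 10))
  expect_gte(min(eigen(tgt, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_true(all(abs(tgt) <= 1 + 1e-12))
  # signed structure: strong TIDER-RESID, negative SEDIM pairs, ELEVA-UVVR
  expect_gt(tgt["TIDER", "RESID"], 0.9)
  expect_lt(tgt["SEDIM", "TIDER"], -0.4)
  expect_lt(tgt["SEDIM", "RESID"], -0.4)
  expect_gt(tgt["ELEVA", "UVVR"], 0.4)
})
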