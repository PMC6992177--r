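grid44 <- list(xll = 0, yll = 0, cellsize = 10, nrow = 4, ncol = 4)

two_unit_set <- function() {
  lab <- matrix(NA_integer_, 4, 4)
  lab[1, 1] <- 1L; lab[2, 1] <- 1L        # unit 1: two cells
  lab[1, 3] <- 2L; lab[2, 3] <- 2L        # unit 2: two cells
  marsh_units(lab, grid44)
}

test_that("zonal means reduce to the constant and to two-cell averages", {
  u <- two_unit_set()
  const <- wvi_raster(matrix(7, 4, 4), cellsize = 10)
  expect_equal(unname(zonal_mean(const, u)), c(7, 7))
  v <- matrix(NA_real_, 4, 4)
  v[1, 1] <- 1; v[2, 1] <- 3; v[1, 3] <- 10; v[2, 3] <- 20
  expect_equal(unname(zonal_mean(wvi_raster(v, cellsize = 10), u)), c(2, 15))
})

test_that("zonal means equal a cell-by-cell masked-sum oracle and its bounds", {
  set.seed(17)
  sim <- generate_dem(12, 12, 4, cellsize = 10, seed = 4)
  u <- delineate_units(sim$dem)
  layer <- wvi_raster(matrix(rnorm(144), 12, 12), cellsize = 10)
  got <- zonal_mean(layer, u)
  for (id in u$units$id) {
    cells <- which(as.vector(u$labels) == id)
    vals <- as.vector(layer$values)[cells]
    expect_equal(got[[as.character(id)]], sum(vals) / length(vals))
    expect_gte(got[[as.character(id)]], min(vals))
    expect_lte(got[[as.character(id)]], max(vals))
  }
})

test_that("misaligned layers are rejected", {
  u <- two_unit_set()
  expect_error(zonal_mean(wvi_raster(matrix(0, 5, 4), cellsize = 10), u),
               "aligned")
  expect_error(zonal_mean(wvi_raster(matrix(0, 4, 4), cellsize = 5), u),
               "aligned")
})

test_that("shoreline rates snap to the nearest unit boundary within tolerance", {
  u <- two_unit_set()
  # both points nearest unit 1's boundary (cells centered x=5, y=25/35)
  rates <- data.frame(x = c(4, 6), y = c(30, 34), rate = c(-0.4, -0.8))
  got <- shoreline_mean(rates, u)
  expect_equal(unname(got), c(-0.6, NA))
  # nothing within tolerance
  far <- data.frame(x = 500, y = 500, rate = 1)
  expect_true(all(is.na(shoreline_mean(far, u))))
  expect_true(all(is.na(shoreline_mean(rates[0, ], u))))
})

test_that("shoreline assignment matches a brute-force nearest-geometry oracle", {
  set.seed(23)
  sim <- generate_dem(10, 10, 3, cellsize = 10, seed = 9)
  u <- delineate_units(sim$dem)
  pts <- data.frame(x = runif(25, -10, 110), y = runif(25, -10, 110),
                    rate = rnorm(25))
  tol <- 20
  got <- shoreline_mean(pts, u, tolerance = tol)
  # oracle: distance of each point to every unit's open-water boundary cells
  ids <- u$units$id
  assign <- rep(NA_integer_, nrow(pts))
  for (p in seq_len(nrow(pts))) {
    d <- sapply(ids, function(id) {
      cells <- marshwvi:::unit_boundary_cells(u, id)
      if (!length(cells)) return(Inf)
      min(sapply(cells, function(cell) {
        i <- (cell - 1) %% 10 + 1; j <- (cell - 1) %/% 10 + 1
        x0 <- (j - 1) * 10; y1 <- (10 - i + 1) * 10
        dx <- max(x0 - pts$x[p], 0, pts$x[p] - (x0 + 10))
        dy <- max((y1 - 10) - pts$y[p], 0, pts$y[p] - y1)
        sqrt(dx^2 + dy^2)
      }))
    })
    if (min(d) <= tol) assign[p] <- ids[which.min(d)]
  }
  orc <- sapply(as.character(ids), function(id)
    mean(pts$rate[!is.na(assign) & assign == as.integer(id)]))
  orc[is.nan(orc)] <- NA
  expect_equal(got, orc)
})

test_that("UVVR covers the zero, unity and severe-bin cases", {
  lab <- matrix(NA_integer_, 4, 4)
  lab[, 1] <- 1L; lab[, 2] <- 2L; lab[, 4] <- 3L
  u <- marsh_units(lab, grid44)
  lc <- matrix(NA_real_, 4, 4)
  lc[, 1] <- 1                      # unit 1 fully vegetated -> 0
  lc[, 2] <- c(1, 2, 1, 2)          # unit 2 equal split -> 1
  lc[, 4] <- 2                      # unit 3 no vegetated -> undefined
  got <- compute_uvvr(wvi_raster(lc, cellsize = 10), u)
  expect_equal(unname(got[1:2]), c(0, 1))
  expect_true(is.na(got[[3]]))
  expect_equal(attr(got, "undefined"), "3")
  # ratio arithmetic at the published severe-bin edge: 810 / 200 = 4.05
  expect_equal(810 / 200, 4.05)
  expect_error(compute_uvvr(wvi_raster(matrix(9, 4, 4), cellsize = 10), u),
               "unknown land-cover class")
})

test_that("orientation negates inverted indicators and preserves direct ones", {
  expect_equal(orient(c(0.2, 0.6), "ELEVA"), c(-0.2, -0.6))
  # the 0.2 m unit outranks the 0.6 m unit in vulnerability
  expect_gt(orient(0.2, "ELEVA"), orient(0.6, "ELEVA"))
  # erosion (-0.8 m/y) maps to higher vulnerability than accretion (+2.0)
  expect_gt(orient(-0.8, "SHORE"), orient(2.0, "SHORE"))
  expect_identical(orient(c(1, 5, NA), "SALIN"), c(1, 5, NA))
  expect_identical(orient(c(3, NA), "inverted"), c(-3, NA))
  expect_error(orient(1, "NOPE"), "unknown indicator")
})

test_that("assembled tables are complete, oriented and rank-consistent", {
  set.seed(3)
  n <- 40
  raw <- lapply(stats::setNames(nm = wvi_indicators()$label),
                function(lb) runif(n))
  tab <- assemble_indicators(seq_len(n), raw)
  expect_equal(dim(tab), c(n, 11L))
  spec <- wvi_indicators()
  for (lb in spec$label) {
    rho <- stats::cor(raw[[lb]], tab[[lb]], method = "spearman")
    expect_equal(rho, if (spec$direction[spec$label == lb] == "inverted") -1 else 1)
  }
  # missing layers become all-NA columns, never zeros
  tab2 <- assemble_indicators(1:5, list(UVVR = runif(5)))
  expect_true(all(is.na(tab2$ELEVA)))
  expect_error(assemble_indicators(1:5, list(XXX = 1:5)), "unknown indicator")
})
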