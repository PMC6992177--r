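# toy layouts on a 10 m grid; areas in m2

test_that("the seed threshold is mean + k sd with degenerate handling", {
  expect_equal(wvi_threshold(c(0.2, 0.4, 0.6)), mean(c(0.2, 0.4, 0.6)) +
                 sd(c(0.2, 0.4, 0.6)))
  # all equal: threshold = c, strict inequality leaves no seeds
  expect_equal(wvi_threshold(rep(0.3, 5)), 0.3)
  set.seed(91)
  v <- rep(c(0, 1), 500)
  expect_equal(wvi_threshold(v), 0.5 + sd(v))
  expect_gt(wvi_threshold(v), 1)           # so no unit can exceed it
  expect_error(wvi_threshold(c(0.5, NA)), "at least 2")
})

test_that("raising the threshold multiplier never adds seed units", {
  set.seed(92)
  wvi <- runif(50)
  n_seeds <- sapply(seq(0, 2, by = 0.25), function(m)
    sum(wvi > wvi_threshold(wvi, m)))
  expect_true(all(diff(n_seeds) <= 0))
})

make_strip_units <- function(widths, nrows = 10, cellsize = 10) {
  lab <- matrix(NA_integer_, nrows, sum(widths))
  j0 <- 0L
  for (u in seq_along(widths)) {
    lab[, j0 + seq_len(widths[u])] <- u
    j0 <- j0 + widths[u]
  }
  marsh_units(lab, list(xll = 0, yll = 0, cellsize = cellsize,
                        nrow = nrows, ncol = sum(widths)))
}

test_that("no seeds means no zones", {
  u <- make_strip_units(c(5, 5, 5))
  hs <- identify_hotspots(u, c(0.2, 0.3, 0.25), threshold = 0.9,
                          buffer_m = 100, min_area_m2 = 100)
  expect_length(hs$zones, 0)
  expect_length(hs$seed_ids, 0)
})

test_that("one seed pulls in centroid-near neighbours, matching a distance oracle", {
  # four 25-cell units (2500 m2 each) in a 10x10 grid; unit 1 seeds
  lab <- matrix(NA_integer_, 10, 10)
  lab[1:5, 1:5] <- 1L; lab[1:5, 6:10] <- 2L
  lab[6:10, 1:5] <- 3L; lab[6:10, 6:10] <- 4L
  u <- marsh_units(lab, list(xll = 0, yll = 0, cellsize = 10,
                             nrow = 10, ncol = 10))
  wvi <- c(0.9, 0.2, 0.2, 0.2)
  hs <- identify_hotspots(u, wvi, threshold = 0.8, buffer_m = 60,
                          min_n = 2, min_area_m2 = 9000)
  expect_length(hs$zones, 1)
  z <- hs$zones[[1]]
  expect_equal(z$seed_unit_ids, 1L)
  expect_equal(z$total_area_m2, 10000)
  # oracle: centroid of each unit within 60 m of seed geometry (cells of 1)
  seed_cells <- which(as.vector(u$labels) == 1L)
  orc <- u$units$id[sapply(seq_len(4), function(r)
    marshwvi:::point_to_cells_distance(u$units$centroid_x[r],
                                       u$units$centroid_y[r],
                                       seed_cells, u$grid) <= 60)]
  expect_equal(z$member_unit_ids, sort(orc))
  expect_equal(z$n_units, 4)
})

test_that("zones failing the area or count criteria are dropped", {
  u <- make_strip_units(c(5, 5))          # two 5000 m2 units
  wvi <- c(0.9, 0.1)
  # area criterion fails: members total 10000 m2 < 1 km2
  hs <- identify_hotspots(u, wvi, threshold = 0.8, buffer_m = 100,
                          min_n = 2, min_area_m2 = 1e6)
  expect_length(hs$zones, 0)
  # count criterion fails when the buffer reaches nobody else
  far <- make_strip_units(c(5))
  hs2 <- identify_hotspots(far, 0.9, threshold = 0.8, buffer_m = 10,
                           min_n = 2, min_area_m2 = 100)
  expect_length(hs2$zones, 0)
  # both satisfied
  hs3 <- identify_hotspots(u, wvi, threshold = 0.8, buffer_m = 100,
                           min_n = 2, min_area_m2 = 10000)
  expect_length(hs3$zones, 1)
  # every reported zone satisfies all three criteria
  for (z in hs3$zones) {
    expect_gte(z$n_units, 2)
    expect_gte(z$total_area_m2, 10000)
    expect_gte(length(z$seed_unit_ids), 1)
  }
})

test_that("overlapping seed buffers dissolve and membership stays disjoint", {
  u <- make_strip_units(rep(2, 8))        # eight 2000 m2 strips
  wvi <- c(0.9, 0.1, 0.9, 0.1, 0.1, 0.1, 0.1, 0.9)
  hs <- identify_hotspots(u, wvi, threshold = 0.8, buffer_m = 30,
                          min_n = 2, min_area_m2 = 2000)
  members <- unlist(lapply(hs$zones, `[[`, "member_unit_ids"))
  expect_equal(anyDuplicated(members), 0L)
  # zones numbered by descending area
  areas <- sapply(hs$zones, `[[`, "total_area_m2")
  expect_true(all(diff(areas) <= 0))
  expect_equal(sapply(hs$zones, `[[`, "zone_id"), seq_along(hs$zones))
})

test_that("zone profiles flag departures beyond one standard deviation", {
  set.seed(93)
  z <- znormalize(matrix(rnorm(300), 30, 10))
  colnames(z) <- wvi_indicators()$label
  ids <- 1:30
  # whole-domain zone: all means 0
  all_prof <- zone_profile(ids, z, ids)
  expect_true(all(abs(all_prof$means) < 1e-12))
  expect_length(all_prof$significant, 0)
  # constructed +2 sigma offset on one indicator
  z2 <- z
  z2[1:5, "UVVR"] <- 2
  prof <- zone_profile(1:5, z2, ids)
  expect_equal(unname(prof$means[["UVVR"]]), 2)
  expect_true("UVVR" %in% prof$significant)
  # +0.5 sigma everywhere stays unflagged
  z3 <- matrix(0.5, 30, 10, dimnames = list(NULL, colnames(z)))
  expect_length(zone_profile(1:5, z3, ids)$significant, 0)
})

test_that("transects order units by entry distance and reverse with the line", {
  u <- make_strip_units(c(3, 3, 3))       # strips at x [0,30], [30,60], [60,90]
  line <- rbind(c(-5, 50), c(95, 50))
  tr <- extract_transect(u, line)
  expect_equal(tr$unit_id, c(1L, 2L, 3L))
  expect_true(all(diff(tr$distance_m) > 0))
  expect_equal(tr$distance_m, c(5, 35, 65))
  rev_tr <- extract_transect(u, line[2:1, ])
  expect_equal(rev_tr$unit_id, c(3L, 2L, 1L))
  # a line missing everything yields an empty profile, not an error
  miss <- extract_transect(u, rbind(c(-5, 500), c(95, 500)))
  expect_equal(nrow(miss), 0L)
  # attached values follow the traversal order
  vals <- data.frame(unit_id = 1:3, WVI = c(0.1, 0.5, 0.9))
  expect_equal(extract_transect(u, line, vals)$WVI, c(0.1, 0.5, 0.9))
})

test_that("transect entry points match a brute-force segment parameterization", {
  set.seed(94)
  sim <- generate_dem(12, 12, 4, cellsize = 10, seed = 12)
  u <- delineate_units(sim$dem)
  line <- rbind(c(-3, 7), c(123, 111))
  tr <- extract_transect(u, line)
  # oracle: walk the segment in tiny steps, record first hit per unit
  p <- line[1, ]; q <- line[2, ]
  len <- sqrt(sum((q - p)^2))
  tt <- seq(0, 1, length.out = 60000)
  first <- list()
  for (t in tt) {
    pt <- p + t * (q - p)
    j <- floor(pt[1] / 10) + 1; i <- 12 - floor(pt[2] / 10)
    if (i < 1 || i > 12 || j < 1 || j > 12) next
    id <- u$labels[i, j]
    if (!is.na(id) && is.null(first[[as.character(id)]]))
      first[[as.character(id)]] <- t * len
  }
  orc <- sort(unlist(first))
  expect_equal(as.character(tr$unit_id), names(orc))
  expect_equal(tr$distance_m, unname(orc), tolerance = 0.01)
})
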