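test_that("eight evenly spread values split two per category", {
  pr <- percentile_rank(1:8)
  expect_equal(as.character(pr$category),
               rep(c("low", "moderate", "high", "severe"), each = 2))
  expect_equal(pr$rank_value, rep(c(0, 1/3, 2/3, 1), each = 2))
})

test_that("remainders go to the earliest categories and match the sort/cut oracle", {
  set.seed(4)
  v <- sample(runif(10))
  pr <- percentile_rank(v)
  expect_equal(as.integer(table(pr$category)), c(3L, 3L, 2L, 2L))
  expect_equal(as.integer(pr$category), oracle_quartile_bins(v))
  # occupancy within 1 and oracle agreement across sizes and ties
  for (trial in 1:25) {
    n <- sample(4:40, 1)
    v <- sample(0:5, n, replace = TRUE) + 0   # heavy ties
    pr <- percentile_rank(v)
    counts <- table(pr$category)
    expect_lte(max(counts) - min(counts), 1)
    expect_equal(as.integer(pr$category), oracle_quartile_bins(v))
  }
  expect_error(percentile_rank(c(1, 2, 3)), "only 3 non-missing")
})

test_that("estimated quantile cuts converge on uniform data", {
  set.seed(8)
  pr <- percentile_rank(runif(10000))
  expect_true(all(abs(pr$cuts - c(0.25, 0.5, 0.75)) < 0.02))
})

test_that("ranking is invariant under strictly increasing transforms", {
  set.seed(12)
  v <- rnorm(37)
  base <- percentile_rank(v)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) 5 * x - 2, function(x) atan(x))) {
    tr <- percentile_rank(f(v))
    expect_identical(tr$category, base$category)
    expect_identical(tr$rank_value, base$rank_value)
  }
})

test_that("threshold bins partition the observed raw range, inverted included", {
  set.seed(21)
  tab <- make_indicator_table(50)
  rk <- rank_indicators(tab)
  spec <- wvi_indicators()
  for (lb in spec$label) {
    th <- rk$thresholds[[lb]]
    inverted <- spec$direction[spec$label == lb] == "inverted"
    raw <- if (inverted) -tab[[lb]] else tab[[lb]]   # table is oriented
    # bins are contiguous and span exactly the observed raw range
    if (inverted) {
      expect_equal(th$raw_lower[1], max(raw))
      expect_equal(th$raw_upper[4], min(raw))
      expect_true(all(th$raw_lower >= th$raw_upper))  # decreasing bins
    } else {
      expect_equal(th$raw_lower[1], min(raw))
      expect_equal(th$raw_upper[4], max(raw))
      expect_true(all(th$raw_lower <= th$raw_upper))
    }
    expect_equal(th$raw_lower[-1], th$raw_upper[-4])
  }
})

test_that("WVI attains its closed-form values and the chronic/episodic identity", {
  labs <- wvi_indicators()$label
  rk4 <- rank_indicators(make_indicator_table(20, seed = 2))
  rec <- vulnerability_records(rk4)
  expect_true(all(rec$WVI >= 0 & rec$WVI <= 1))
  expect_equal(rec$WVI, (rec$WVIC + rec$WVIE) / 2)
  expect_equal(rec$n_used, rep(10, 20))

  # all ten indicators severe -> WVI = 1 (unit 20 of an ordered table)
  ordered <- data.frame(unit_id = 1:20)
  for (lb in labs) ordered[[lb]] <- 1:20
  ro <- rank_indicators(ordered)
  expect_equal(compute_wvi(ro, "all")[[20]], 1)
  expect_equal(compute_wvi(ro, "all")[[1]], 0)

  # explicit arithmetic-mean check on a constructed rank pattern
  rv <- c(0, 1/3, 2/3, 1, 0, 1/3, 2/3, 1, 0, 1)
  expect_equal(mean(rv), 0.5)
  fake <- structure(list(unit_id = 1L,
                         rank_values = as.data.frame(as.list(
                           stats::setNames(rv, labs))),
                         categories = NULL, n_bins = 4L),
                    class = "wvi_ranked")
  expect_equal(compute_wvi(fake, "all")[[1]], 0.5)
})

test_that("missing indicators shrink N rather than zeroing the index", {
  tab <- make_indicator_table(12, seed = 5)
  tab$SHORE <- NA_real_
  tab$UVVR[1:3] <- NA
  rk <- rank_indicators(tab)
  wvi <- compute_wvi(rk, "all")
  n_used <- attr(wvi, "n_used")
  expect_equal(unname(n_used[1]), 8)
  expect_equal(unname(n_used[12]), 9)
  expect_true(all(wvi >= 0 & wvi <= 1, na.rm = TRUE))
  # hand-check one unit: mean over available rank values only
  rv <- as.numeric(rk$rank_values[1, ])
  expect_equal(wvi[[1]], mean(rv, na.rm = TRUE))
})

test_that("raising one indicator's category never lowers the index", {
  set.seed(9)
  for (trial in 1:10) {
    tab <- make_indicator_table(16, seed = trial)
    rk <- rank_indicators(tab)
    base <- compute_wvi(rk, "all")
    lb <- sample(wvi_indicators()$label, 1)
    u <- sample(16, 1)
    rk2 <- rk
    rk2$rank_values[[lb]][u] <- min(rk$rank_values[[lb]][u] + 1/3, 1)
    expect_gte(compute_wvi(rk2, "all")[[u]], base[[u]])
  }
})

test_that("rank dispersion matches closed forms and a two-pass oracle", {
  labs <- wvi_indicators()$label
  const <- structure(list(unit_id = 1L,
                          rank_values = as.data.frame(as.list(
                            stats::setNames(rep(2/3, 10), labs)))),
                     class = "wvi_ranked")
  expect_equal(rank_dispersion(const), 0)
  half <- structure(list(unit_id = 1L,
                         rank_values = as.data.frame(as.list(
                           stats::setNames(rep(c(0, 1), each = 5), labs)))),
                    class = "wvi_ranked")
  expect_equal(rank_dispersion(half), 0.5)
  rk <- rank_indicators(make_indicator_table(15, seed = 8))
  disp <- rank_dispersion(rk)
  expect_true(all(disp >= 0 & disp <= 0.5))
  for (u in 1:15) {
    x <- as.numeric(rk$rank_values[u, ])
    expect_equal(disp[u], sqrt(sum((x - sum(x) / 10)^2) / 10))
  }
})
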