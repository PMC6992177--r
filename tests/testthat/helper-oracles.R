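# Independent brute-force oracles, coded against the documented rules only
# (never calling into the implementation paths they check).

# D8 neighbor table in the documented tie-break order E, SE, S, SW, W, NW, N, NE
ORC_DI <- c(0, 1, 1, 1, 0, -1, -1, -1)
ORC_DJ <- c(1, 1, 0, -1, -1, -1, 0, 1)
ORC_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# per-cell scan of all 8 neighbors maximizing drop/distance; first listed
# neighbor wins ties; 0 = pit (no strictly lower neighbor)
oracle_flow_directions <- function(z, cellsize = 1) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(z[i, j])) next
    best <- -Inf; pick <- 0L
    for (k in 1:8) {
      ni <- i + ORC_DI[k]; nj <- j + ORC_DJ[k]
      if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
      if (is.na(z[ni, nj]) || z[ni, nj] >= z[i, j]) next
      g <- (z[i, j] - z[ni, nj]) / (ORC_DIST[k] * cellsize)
      if (g > best) { best <- g; pick <- k }
    }
    out[i, j] <- pick
  }
  out
}

# exhaustive steepest-descent path tracing: every cell walked independently
# to its terminal pit; returns the pit's linear (column-major) index per cell
oracle_basins <- function(z, cellsize = 1) {
  dirs <- oracle_flow_directions(z, cellsize)
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(z[i, j])) next
    ci <- i; cj <- j
    repeat {
      k <- dirs[ci, cj]
      if (k == 0L) break
      ci2 <- ci + ORC_DI[k]; cj2 <- cj + ORC_DJ[k]
      ci <- ci2; cj <- cj2
    }
    out[i, j] <- as.integer(ci + (cj - 1) * nr)
  }
  out
}

# greedy smallest-first merge on abstract unit tables: areas (named), adjacency
# (named list), centroids (named 2-col matrix); returns final named areas
oracle_greedy_merge <- function(areas, adjacency, centroids, min_area) {
  repeat {
    small <- names(areas)[areas < min_area]
    if (length(small) == 0L) break
    u <- small[order(areas[small], as.integer(small))][1L]
    nb <- as.character(adjacency[[u]])
    nb <- nb[nb %in% names(areas)]
    if (length(nb) == 0L) break
    d <- sqrt((centroids[nb, 1] - centroids[u, 1])^2 +
              (centroids[nb, 2] - centroids[u, 2])^2)
    tgt <- nb[order(d, as.integer(nb))][1L]
    # weighted centroid update, area sum, adjacency union
    w <- areas[c(u, tgt)] / sum(areas[c(u, tgt)])
    centroids[tgt, ] <- w[1] * centroids[u, ] + w[2] * centroids[tgt, ]
    areas[tgt] <- areas[tgt] + areas[u]
    merged_nb <- setdiff(union(adjacency[[u]], adjacency[[tgt]]),
                         as.integer(c(u, tgt)))
    adjacency[[tgt]] <- merged_nb
    for (v in names(adjacency)) {
      a <- adjacency[[v]]
      if (as.integer(u) %in% a)
        adjacency[[v]] <- sort(unique(c(setdiff(a, as.integer(u)),
                                        as.integer(tgt))))
    }
    areas <- areas[names(areas) != u]
    adjacency[[u]] <- NULL
    centroids <- centroids[rownames(centroids) != u, , drop = FALSE]
  }
  areas
}

# sort-and-cut quartile oracle: ascending stable sort, first r of the 4 bins
# take the extra members
oracle_quartile_bins <- function(v) {
  n <- length(v)
  sizes <- rep(n %/% 4, 4) + (1:4 <= n %% 4)
  rep(1:4, times = sizes)[order(order(v, seq_along(v)))]
}

# direct textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# simple synthetic ranked table for index tests
make_indicator_table <- function(n, seed = 1) {
  set.seed(seed)
  labs <- wvi_indicators()$label
  tab <- data.frame(unit_id = seq_len(n))
  for (lb in labs) tab[[lb]] <- stats::runif(n)
  tab
}
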