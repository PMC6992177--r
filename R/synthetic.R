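## Seeded synthetic-data generators: multi-basin elevation surfaces,
## tessellated unit geometries, Gaussian-copula indicator tables with a
## target correlation structure, and mixture-structured unit populations.
## Every generator is deterministic under a fixed seed and returns ground
## truth alongside the data.

#' Generate a multi-basin synthetic elevation surface
#'
#' Builds a smooth surface of inverted Gaussian bowls at seeded centers
#' (ridgelines arise where neighboring bowls meet), plus a tiny
#' deterministic slope toward the nearest center (so the far field drains
#' and has no exactly-flat cells) and optional additive Gaussian noise.
#' Ground truth is the nearest-center attraction basin of the noiseless
#' surface.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_basins number of drainage basins (`>= 1`); centers are placed
#'   by seeded rejection sampling with a minimum separation, and an error
#'   is raised when the grid cannot host that many basins.
#' @param relief_m total relief of the surface in meters (default 2).
#' @param noise_sd standard deviation of additive elevation noise in meters
#'   (default 0).
#' @param cellsize cell size in meters (default 1).
#' @param seed integer seed.
#' @return List with `dem` (a [wvi_raster()]) and `truth`: list with
#'   `basin_labels` (integer matrix of nearest-center ids), `centers`
#'   (n_basins x 2 of row/col positions), `ridge_distance` (matrix of each
#'   cell's margin between its nearest and second-nearest center, in
#'   cells -- small values flag ridge-adjacent cells), and the generator
#'   parameters.
#' @export
generate_dem <- function(n_rows, n_cols, n_basins, relief_m = 2,
                         noise_sd = 0, cellsize = 1, seed = 1L) {
  if (n_basins < 1L) stop("`n_basins` must be >= 1")
  if (n_basins > n_rows * n_cols / 9)
    stop("infeasible basin count: ", n_basins, " basins need more than a ",
         n_rows, "x", n_cols, " grid (at least 9 cells per basin)")
  set.seed(seed)
  min_sep <- 0.45 * sqrt(n_rows * n_cols / n_basins)
  centers <- matrix(NA_real_, n_basins, 2L)
  placed <- 0L
  for (tries in seq_len(2000L)) {
    cand <- c(stats::runif(1, 0.5, n_rows + 0.5),
              stats::runif(1, 0.5, n_cols + 0.5))
    if (placed == 0L ||
        min(sqrt((centers[seq_len(placed), 1L] - cand[1L])^2 +
                 (centers[seq_len(placed), 2L] - cand[2L])^2)) >= min_sep) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n_basins) break
    }
  }
  if (placed < n_basins)
    stop("infeasible basin count: could not place ", n_basins,
         " centers on a ", n_rows, "x", n_cols, " grid")

  ii <- matrix(rep(seq_len(n_rows), n_cols), n_rows, n_cols)
  jj <- matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols)
  d2 <- array(0, c(n_rows, n_cols, n_basins))
  for (k in seq_len(n_basins))
    d2[, , k] <- (ii - centers[k, 1L])^2 + (jj - centers[k, 2L])^2
  sigma <- 0.35 * sqrt(n_rows * n_cols / n_basins)
  bowls <- exp(-d2 / (2 * sigma^2))
  nearest <- apply(d2, c(1L, 2L), which.min)
  if (n_basins > 1L) {
    d_sorted <- apply(d2, c(1L, 2L),
                      function(v) sqrt(sort(v)[1:2]))
    d1 <- matrix(d_sorted[1L, , ], n_rows, n_cols)
    ridge_distance <- (matrix(d_sorted[2L, , ], n_rows, n_cols) - d1) / 2
  } else {
    d1 <- sqrt(d2[, , 1L])
    ridge_distance <- matrix(Inf, n_rows, n_cols)
  }

  z <- relief_m * (1 - apply(bowls, c(1L, 2L), max)) +
    1e-3 * relief_m * d1 / sqrt(n_rows^2 + n_cols^2)
  if (noise_sd > 0)
    z <- z + matrix(stats::rnorm(n_rows * n_cols, 0, noise_sd),
                    n_rows, n_cols)

  list(
    dem = wvi_raster(z, cellsize = cellsize),
    truth = list(basin_labels = nearest, centers = centers,
                 ridge_distance = ridge_distance,
                 params = list(n_basins = n_basins, relief_m = relief_m,
                               noise_sd = noise_sd, sigma = sigma,
                               seed = seed))
  )
}

#' Generate a tessellated set of unit geometries
#'
#' Partitions a rectangle into `n_units` polygons by a seeded Voronoi-style
#' tessellation on a fine grid: sites are placed by rejection sampling with
#' a minimum separation and each cell takes the label of its nearest site,
#' with a fix-up pass reassigning any rook-disconnected slivers so every
#' unit is contiguous. Areas sum exactly to the rectangle's area.
#'
#' @param n_units number of units (`>= 1`).
#' @param mean_area_m2 target mean unit area (default 20000 m2).
#' @param seed integer seed.
#' @return A [marsh_units()] object with `n_units` units, provenance
#'   `"original"`; the generating sites are kept in attribute `sites`.
#' @export
generate_unit_geometries <- function(n_units, mean_area_m2 = 20000, seed = 1L) {
  if (n_units < 1L) stop("`n_units` must be >= 1")
  set.seed(seed)
  total <- n_units * mean_area_m2
  width <- sqrt(total * 4 / 3)
  height <- total / width
  cs <- sqrt(mean_area_m2) / 20
  nc <- max(2L, round(width / cs))
  nr <- max(2L, round(height / cs))

  sites <- matrix(NA_real_, n_units, 2L)
  min_sep <- 0.5 * sqrt(width * height / n_units)
  placed <- 0L
  for (tries in seq_len(5000L)) {
    cand <- c(stats::runif(1, 0, nc * cs), stats::runif(1, 0, nr * cs))
    if (placed == 0L ||
        min(sqrt((sites[seq_len(placed), 1L] - cand[1L])^2 +
                 (sites[seq_len(placed), 2L] - cand[2L])^2)) >= min_sep) {
      placed <- placed + 1L
      sites[placed, ] <- cand
      if (placed == n_units) break
    }
  }
  if (placed < n_units) stop("could not place ", n_units, " separated sites")

  grid <- list(xll = 0, yll = 0, cellsize = cs, nrow = nr, ncol = nc)
  xy <- cell_centers(structure(list(grid = grid), class = "marsh_units"))
  d2 <- sapply(seq_len(n_units), function(k)
    (xy[, 1L] - sites[k, 1L])^2 + (xy[, 2L] - sites[k, 2L])^2)
  if (n_units == 1L) d2 <- matrix(d2, ncol = 1L)
  labels <- matrix(max.col(-d2, ties.method = "first"), nr, nc)

  ## reattach rook-disconnected slivers of discretized Voronoi cells
  for (pass in seq_len(10L)) {
    changed <- FALSE
    for (u in seq_len(n_units)) {
      comp <- rook_components(labels == u)
      ncomp <- max(comp, na.rm = TRUE)
      if (ncomp <= 1L) next
      sizes <- tabulate(comp[!is.na(comp)], ncomp)
      main <- which.max(sizes)
      for (c0 in setdiff(seq_len(ncomp), main)) {
        cells <- which(!is.na(comp) & comp == c0)
        for (cell in cells) {
          i <- ((cell - 1L) %% nr) + 1L
          j <- ((cell - 1L) %/% nr) + 1L
          nb <- c()
          for (k in c(1L, 3L, 5L, 7L)) {
            ni <- i + D8_DI[k]; nj <- j + D8_DJ[k]
            if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
                labels[ni, nj] != u)
              nb <- c(nb, labels[ni, nj])
          }
          if (length(nb)) {
            labels[cell] <- nb[1L]
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }

  drainage <- list()
  for (u in seq_len(n_units)) {
    cells <- which(as.vector(labels) == u)
    d <- (xy[cells, 1L] - sites[u, 1L])^2 + (xy[cells, 2L] - sites[u, 2L])^2
    dcell <- cells[which.min(d)]
    drainage[[as.character(u)]] <- c(((dcell - 1L) %% nr) + 1L,
                                     ((dcell - 1L) %/% nr) + 1L)
  }
  out <- marsh_units(labels, grid, drainage = drainage)
  attr(out, "sites") <- sites
  out
}

#' Default target correlation structure of the indicators
#'
#' A 10 x 10 correlation matrix encoding the reported signed dependence
#' structure among the indicators -- a strong positive tidal-range /
#' residence-time pair, negative sediment-supply correlations with both,
#' a positive elevation-UVVR pair, near-zero shoreline-change
#' correlations -- projected to the nearest positive-semidefinite
#' correlation matrix (eigenvalue clipping followed by rescaling to a unit
#' diagonal).
#'
#' @return Symmetric PSD 10 x 10 matrix with unit diagonal, dimnames from
#'   [wvi_indicators()].
#' @export
default_target_correlation <- function() {
  labs <- indicator_labels()
  R <- diag(10)
  dimnames(R) <- list(labs, labs)
  set_r <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_r("SCORR", "CONDC", -0.21)
  set_r("ELEVA", "CONDC", -0.01); set_r("ELEVA", "SCORR", 0.13)
  set_r("EXSAL", "CONDC", 0.15); set_r("EXSAL", "SCORR", -0.13)
  set_r("EXSAL", "ELEVA", 0.25)
  set_r("RESID", "CONDC", -0.10); set_r("RESID", "SCORR", 0.41)
  set_r("RESID", "ELEVA", 0.43); set_r("RESID", "EXSAL", -0.21)
  set_r("SALIN", "CONDC", -0.23); set_r("SALIN", "SCORR", 0.29)
  set_r("SALIN", "ELEVA", -0.09); set_r("SALIN", "EXSAL", 0.15)
  set_r("SALIN", "RESID", 0.12)
  set_r("SEDIM", "CONDC", 0.28); set_r("SEDIM", "SCORR", -0.31)
  set_r("SEDIM", "ELEVA", -0.25); set_r("SEDIM", "EXSAL", 0.28)
  set_r("SEDIM", "RESID", -0.53); set_r("SEDIM", "SALIN", -0.08)
  set_r("SHORE", "CONDC", 0.10); set_r("SHORE", "SCORR", -0.04)
  set_r("SHORE", "ELEVA", 0.05); set_r("SHORE", "EXSAL", -0.10)
  set_r("SHORE", "RESID", 0.13); set_r("SHORE", "SALIN", -0.07)
  set_r("SHORE", "SEDIM", -0.18)
  set_r("TIDER", "CONDC", -0.14); set_r("TIDER", "SCORR", 0.45)
  set_r("TIDER", "ELEVA", 0.50); set_r("TIDER", "EXSAL", -0.18)
  set_r("TIDER", "RESID", 0.93); set_r("TIDER", "SALIN", 0.11)
  set_r("TIDER", "SEDIM", -0.57); set_r("TIDER", "SHORE", 0.13)
  set_r("UVVR", "CONDC", 0.00); set_r("UVVR", "SCORR", -0.11)
  set_r("UVVR", "ELEVA", 0.51); set_r("UVVR", "EXSAL", 0.21)
  set_r("UVVR", "RESID", 0.14); set_r("UVVR", "SALIN", -0.05)
  set_r("UVVR", "SEDIM", -0.08); set_r("UVVR", "SHORE", 0.15)
  set_r("UVVR", "TIDER", 0.20)
  nearest_psd_correlation(R)
}

#' Nearest positive-semidefinite correlation matrix
#'
#' Clips negative eigenvalues at a small floor and rescales to a unit
#' diagonal. Used to repair hand-specified target correlation matrices.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param floor eigenvalue floor (default 1e-8).
#' @return A symmetric PSD matrix with unit diagonal.
#' @export
nearest_psd_correlation <- function(R, floor = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values >= 0)) return(R)
  vals <- pmax(e$values, floor)
  M <- e$vectors %*% diag(vals) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(M)))
  out <- D %*% M %*% D
  dimnames(out) <- dimnames(R)
  (out + t(out)) / 2
}

#' Generate a per-unit indicator table by Gaussian copula
#'
#' Draws latent multivariate-normal vectors with the target correlation and
#' maps each margin monotonically onto the indicator's published raw range
#' through a damped probit (`pnorm(z / 2)`), giving bounded, bell-shaped
#' marginals whose Pearson correlations track the latent target closely
#' (inverted indicators take the reversed margin so the raw values sit on
#' their natural scale). Because the marginal transforms are strictly
#' monotone, rank-based downstream statistics are unaffected by the
#' marginal choice.
#' An optional monotone along-estuary gradient can be added to selected
#' indicators via the unit centroid coordinate, emulating the longitudinal
#' structure of real estuarine indicator fields.
#'
#' @param units a [marsh_units()] object, or an integer number of units.
#' @param target_correlation PSD correlation matrix on the oriented scale
#'   (default [default_target_correlation()]).
#' @param gradient_axis `"none"`, `"NS"` (uses centroid y) or `"EW"`
#'   (centroid x); requires a `marsh_units` object for the coordinates.
#' @param gradient_strength latent-scale amplitude of the gradient (0
#'   disables it).
#' @param gradient_indicators labels receiving the gradient.
#' @param seed integer seed.
#' @return List with `table` (oriented indicator data.frame from
#'   [assemble_indicators()]), `raw` (raw-scale data.frame), and `truth`
#'   (target correlation, copula uniforms, parameters).
#' @export
generate_indicator_table <- function(units,
                                     target_correlation = default_target_correlation(),
                                     gradient_axis = c("none", "NS", "EW"),
                                     gradient_strength = 0,
                                     gradient_indicators = c("TIDER", "RESID", "ELEVA"),
                                     seed = 1L) {
  gradient_axis <- match.arg(gradient_axis)
  labs <- indicator_labels()
  if (!all(dim(target_correlation) == c(10L, 10L)))
    stop("`target_correlation` must be 10 x 10")
  if (is.null(dimnames(target_correlation)))
    dimnames(target_correlation) <- list(labs, labs)
  ev <- eigen((target_correlation + t(target_correlation)) / 2,
              symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("`target_correlation` is not positive semidefinite; ",
         "repair it with nearest_psd_correlation()")

  if (inherits(units, "marsh_units")) {
    ids <- units$units$id
    coord <- switch(gradient_axis,
                    NS = units$units$centroid_y,
                    EW = units$units$centroid_x,
                    none = NULL)
  } else {
    ids <- seq_len(as.integer(units))
    coord <- NULL
    if (gradient_axis != "none" && gradient_strength != 0)
      stop("a marsh_units object is needed for a spatial gradient")
  }
  n <- length(ids)

  set.seed(seed)
  ## empirical = TRUE pins the latent SAMPLE correlation to the target, so
  ## the generated table's correlation structure deviates from the target
  ## only through the (small) marginal-transform bias, not sampling noise
  Z <- MASS::mvrnorm(n, mu = rep(0, 10L),
                     Sigma = nearest_psd_correlation(target_correlation),
                     empirical = n > 10L)
  colnames(Z) <- labs
  if (!is.null(coord) && gradient_strength != 0) {
    s <- (coord - min(coord)) / max(max(coord) - min(coord), 1e-12) - 0.5
    for (lb in intersect(gradient_indicators, labs))
      Z[, lb] <- Z[, lb] + gradient_strength * s
  }
  U <- stats::pnorm(Z / 2)

  spec <- wvi_indicators()
  raw <- data.frame(unit_id = ids)
  for (lb in labs) {
    k <- which(spec$label == lb)
    u <- if (spec$direction[k] == "inverted") 1 - U[, lb] else U[, lb]
    raw[[lb]] <- spec$range_min[k] + u * (spec$range_max[k] - spec$range_min[k])
  }
  table <- assemble_indicators(ids, as.list(raw[labs]))
  list(table = table, raw = raw,
       truth = list(target_correlation = target_correlation, uniforms = U,
                    params = list(seed = seed, gradient_axis = gradient_axis,
                                  gradient_strength = gradient_strength)))
}

#' Generate a mixture-structured unit population
#'
#' Draws per-component multivariate-Gaussian indicator vectors with known
#' labels, for cluster-recovery experiments. The default configuration
#' mirrors a three-regime estuary: a majority cluster (about half the
#' units) and two minority clusters of roughly 18% and 31%.
#'
#' @param sizes integer vector of component sizes (default `c(51, 18, 31)`,
#'   the three-cluster share pattern).
#' @param means K x d matrix of component means; default: three components
#'   offset on the tidal-range/residence-time, condition/UVVR and
#'   sediment axes.
#' @param covariances list of K d x d SPD matrices (default identity).
#' @param seed integer seed.
#' @return List with `table` (numeric matrix, rows in component blocks),
#'   `labels` (integer ground-truth component per row), and the parameters.
#' @export
generate_clustered_table <- function(sizes = c(51L, 18L, 31L),
                                     means = NULL, covariances = NULL,
                                     seed = 1L) {
  K <- length(sizes)
  if (is.null(means)) {
    labs <- indicator_labels()
    means <- matrix(0, K, 10L, dimnames = list(NULL, labs))
    if (K >= 1L) means[1L, c("RESID", "TIDER")] <- 1.0
    if (K >= 1L) means[1L, "SEDIM"] <- -1.0
    if (K >= 2L) means[2L, c("CONDC", "UVVR")] <- 1.0
    if (K >= 2L) means[2L, c("SHORE", "ELEVA")] <- -1.0
    if (K >= 3L) means[3L, "SEDIM"] <- 1.0
    if (K >= 3L) means[3L, c("SCORR", "RESID", "TIDER")] <- -1.0
  }
  means <- as.matrix(means)
  if (nrow(means) != K) stop("`means` must have one row per component")
  d <- ncol(means)
  if (is.null(covariances)) covariances <- replicate(K, diag(d), simplify = FALSE)
  if (length(covariances) != K) stop("need one covariance per component")
  for (S in covariances) {
    if (!isTRUE(all.equal(S, t(S))) ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("covariances must be symmetric positive definite")
  }
  set.seed(seed)
  blocks <- lapply(seq_len(K), function(k) {
    matrix(MASS::mvrnorm(sizes[k], mu = means[k, ], Sigma = covariances[[k]]),
           nrow = sizes[k])
  })
  table <- do.call(rbind, blocks)
  colnames(table) <- colnames(means)
  list(table = table,
       labels = rep(seq_len(K), times = sizes),
       params = list(sizes = sizes, means = means,
                     covariances = covariances, seed = seed))
}
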