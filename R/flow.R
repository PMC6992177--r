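## D8 steepest-descent flow routing with deterministic tie-breaks.
## Neighbor order (also the tie-break order) is E, SE, S, SW, W, NW, N, NE.

D8_DI   <- c( 0L, 1L, 1L,  1L,  0L, -1L, -1L, -1L)
D8_DJ   <- c( 1L, 1L, 0L, -1L, -1L, -1L,  0L,  1L)
D8_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
D8_PIT  <- 0L

#' Compute a D8 flow field from an elevation raster
#'
#' Assigns every data cell its steepest-descent neighbor among the eight
#' adjacent cells (drop divided by center-to-center distance; diagonal
#' distance is `cellsize * sqrt(2)`), then accumulates the count of upstream
#' cells by topological summation over the resulting drainage graph.
#'
#' Rules, applied in order:
#' \itemize{
#'   \item A cell with at least one strictly lower data neighbor drains to
#'     the neighbor maximizing drop/distance; ties are broken by the fixed
#'     neighbor order E, SE, S, SW, W, NW, N, NE.
#'   \item A cell with no strictly lower neighbor that can reach one through
#'     a connected run of equal-elevation cells drains across the flat by
#'     breadth-first gradient toward the nearest draining cell of the flat.
#'   \item Any remaining cell (a closed minimum, including each cell of a
#'     closed flat and boundary cells whose descent would leave the grid) is
#'     a pit/sink (`direction == 0`).
#' }
#' Nodata cells are impermeable: flow neither enters nor crosses them, and
#' descent may not leave the raster edge, so low boundary cells become edge
#' sinks.
#'
#' @param dem a [wvi_raster()] elevation grid (meters, planar CRS in meters).
#' @return An object of class `wvi_flow`: list with integer matrix
#'   `direction` (1..8 = E, SE, S, SW, W, NW, N, NE; 0 = pit/sink; `NA` =
#'   nodata) and numeric matrix `accumulation` (upstream cell count including
#'   the cell itself, so every data cell has accumulation >= 1).
#' @examples
#' dem <- wvi_raster(matrix(rep(4:1, each = 4), 4, 4))  # tilted east
#' f <- compute_flow_field(dem)
#' f$accumulation[1, ]  # 1 2 3 4
#' @export
compute_flow_field <- function(dem) {
  validate_dem(dem)
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  data_cell <- !is.na(z)

  direction <- matrix(NA_integer_, nr, nc)

  ## steepest strictly-descending neighbor, vectorized over the 8 shifts;
  ## iterating in D8 order with a strict ">" update makes the first-listed
  ## neighbor win ties
  best_grad <- matrix(-Inf, nr, nc)
  for (k in seq_len(8L)) {
    zn <- shift_matrix(z, D8_DI[k], D8_DJ[k])
    grad <- (z - zn) / (D8_DIST[k] * dem$cellsize)
    ok <- data_cell & !is.na(zn) & zn < z & grad > best_grad
    best_grad[ok] <- grad[ok]
    direction[ok] <- k
  }

  ## flats: cells with no strictly lower neighbor, resolvable by BFS across
  ## equal-elevation neighbors toward the nearest cell that already drains
  undrained <- data_cell & is.na(direction)
  if (any(undrained)) {
    direction <- resolve_flats(z, direction, undrained, nr, nc)
  }
  ## whatever is left is a closed minimum: a pit
  direction[data_cell & is.na(direction)] <- D8_PIT

  acc <- accumulate_flow(direction, nr, nc, data_cell)
  structure(list(direction = direction, accumulation = acc),
            class = "wvi_flow")
}

#' @export
print.wvi_flow <- function(x, ...) {
  d <- x$direction
  cat(sprintf("<wvi_flow> %d x %d; %d data cells, %d sinks, max accumulation %g\n",
              nrow(d), ncol(d), sum(!is.na(d)), sum(d == D8_PIT, na.rm = TRUE),
              max(x$accumulation, na.rm = TRUE)))
  invisible(x)
}

## shift a matrix so element [i,j] holds the value at [i+di, j+dj] (NA off-grid)
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr); rj <- seq_len(nc)
  si <- ri + di; sj <- rj + dj
  keep_i <- si >= 1L & si <= nr
  keep_j <- sj >= 1L & sj <= nc
  out[ri[keep_i], rj[keep_j]] <- m[si[keep_i], sj[keep_j]]
  out
}

## multi-source BFS over equal-elevation flats: sources are undrained cells
## with an equal-elevation neighbor that drains; each reached cell points at
## the neighbor it was discovered from
resolve_flats <- function(z, direction, undrained, nr, nc) {
  idx <- which(undrained)
  queue <- integer(0)
  for (cell in idx) {
    i <- ((cell - 1L) %% nr) + 1L
    j <- ((cell - 1L) %/% nr) + 1L
    for (k in seq_len(8L)) {
      ni <- i + D8_DI[k]; nj <- j + D8_DJ[k]
      if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
      if (is.na(z[ni, nj]) || z[ni, nj] != z[i, j]) next
      dk <- direction[ni, nj]
      if (!is.na(dk) && dk != D8_PIT) {     # neighbor already drains
        direction[i, j] <- k
        queue <- c(queue, cell)
        break
      }
    }
  }
  head <- 1L
  while (head <= length(queue)) {
    cell <- queue[head]; head <- head + 1L
    i <- ((cell - 1L) %% nr) + 1L
    j <- ((cell - 1L) %/% nr) + 1L
    for (k in seq_len(8L)) {
      ni <- i + D8_DI[k]; nj <- j + D8_DJ[k]
      if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
      ncell <- ni + (nj - 1L) * nr
      if (is.na(z[ni, nj]) || z[ni, nj] != z[i, j]) next
      if (!is.na(direction[ni, nj])) next
      ## reverse direction: neighbor must point back at `cell`
      direction[ni, nj] <- match(TRUE, D8_DI == -D8_DI[k] & D8_DJ == -D8_DJ[k])
      queue <- c(queue, ncell)
    }
  }
  direction
}

## linear index (column-major) of the cell each cell drains to; 0 for pits/NA
flow_targets <- function(direction, nr, nc) {
  tgt <- integer(nr * nc)
  idx <- which(!is.na(direction) & direction != D8_PIT)
  if (length(idx)) {
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    k <- direction[idx]
    tgt[idx] <- (i + D8_DI[k]) + (j + D8_DJ[k] - 1L) * nr
  }
  tgt
}

## Kahn topological pass: accumulation = 1 + sum over upstream neighbors
accumulate_flow <- function(direction, nr, nc, data_cell) {
  tgt <- flow_targets(direction, nr, nc)
  acc <- ifelse(data_cell, 1, NA_real_)
  indeg <- integer(nr * nc)
  tab <- tabulate(tgt[tgt > 0L], nbins = nr * nc)
  indeg <- tab
  queue <- which(data_cell & indeg == 0L)
  head <- 1L
  queue <- as.integer(queue)
  while (head <= length(queue)) {
    cell <- queue[head]; head <- head + 1L
    t <- tgt[cell]
    if (t > 0L) {
      acc[t] <- acc[t] + acc[cell]
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
  }
  matrix(acc, nr, nc)
}
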