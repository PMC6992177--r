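## MarshUnitSet: a label grid plus per-unit attribute table and adjacency.

#' Build a marsh unit set from a unit label grid
#'
#' Internal-facing constructor used by [delineate_units()],
#' [merge_small_units()] and the synthetic generators. Areas, centroids and
#' rook (shared cell-edge) adjacency are derived from the label matrix;
#' polygons are implicit in the labels and can be exported with
#' [units_to_geojson()].
#'
#' @param labels integer matrix of unit ids (`NA` = nodata), same layout as
#'   the source raster (row 1 = north).
#' @param grid list with `xll`, `yll`, `cellsize`, `nrow`, `ncol`.
#' @param drainage optional named list mapping unit id to `c(row, col)` of
#'   its drainage cell.
#' @param provenance optional named character vector per unit id
#'   (`"original"`, `"merged"` or `"aggregated"`).
#' @return An object of class `marsh_units`: list with `labels`, `units`
#'   (data.frame: id, n_cells, area_m2, centroid_x, centroid_y, drainage_row,
#'   drainage_col, drainage_x, drainage_y, provenance), `adjacency` (named
#'   list of integer vectors) and `grid`.
#' @export
marsh_units <- function(labels, grid, drainage = NULL, provenance = NULL) {
  stopifnot(is.matrix(labels))
  ids <- sort(unique(labels[!is.na(labels)]))
  cs <- grid$cellsize
  nr <- grid$nrow; nc <- grid$ncol
  cellarea <- cs * cs

  n_cells <- centroid_x <- centroid_y <- numeric(length(ids))
  xy <- cell_centers(structure(list(grid = grid), class = "marsh_units"))
  lab_vec <- as.vector(labels)
  for (u in seq_along(ids)) {
    sel <- which(lab_vec == ids[u])
    n_cells[u] <- length(sel)
    centroid_x[u] <- mean(xy[sel, 1L])
    centroid_y[u] <- mean(xy[sel, 2L])
  }

  dr <- matrix(NA_integer_, length(ids), 2L)
  if (!is.null(drainage)) {
    for (u in seq_along(ids)) {
      d <- drainage[[as.character(ids[u])]]
      if (!is.null(d)) dr[u, ] <- d
    }
  }
  prov <- rep("original", length(ids))
  if (!is.null(provenance)) {
    m <- provenance[as.character(ids)]
    prov[!is.na(m)] <- m[!is.na(m)]
  }

  units <- data.frame(
    id = ids,
    n_cells = as.integer(n_cells),
    area_m2 = n_cells * cellarea,
    centroid_x = centroid_x,
    centroid_y = centroid_y,
    drainage_row = dr[, 1L],
    drainage_col = dr[, 2L],
    drainage_x = ifelse(is.na(dr[, 2L]), NA_real_,
                        grid$xll + (dr[, 2L] - 0.5) * cs),
    drainage_y = ifelse(is.na(dr[, 1L]), NA_real_,
                        grid$yll + (nr - dr[, 1L] + 0.5) * cs),
    provenance = prov,
    stringsAsFactors = FALSE
  )

  structure(
    list(labels = labels, units = units,
         adjacency = label_adjacency(labels), grid = grid),
    class = "marsh_units"
  )
}

#' @export
print.marsh_units <- function(x, ...) {
  cat(sprintf("<marsh_units> %d units over %d cells (%g m cells)\n",
              nrow(x$units), sum(!is.na(x$labels)), x$grid$cellsize))
  cat(sprintf("  area: total %g m2, range [%g, %g] m2\n",
              sum(x$units$area_m2), min(x$units$area_m2),
              max(x$units$area_m2)))
  pv <- table(x$units$provenance)
  cat("  provenance:", paste(names(pv), pv, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.marsh_units <- function(x) c(x$grid$nrow, x$grid$ncol)

## symmetric rook adjacency between labels (shared cell edge)
label_adjacency <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-nr, ]), as.vector(labels[-1L, ])),   # vertical
    cbind(as.vector(labels[, -nc]), as.vector(labels[, -1L]))    # horizontal
  )
  pairs <- pairs[!is.na(pairs[, 1L]) & !is.na(pairs[, 2L]) &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  ids <- sort(unique(labels[!is.na(labels)]))
  adj <- stats::setNames(vector("list", length(ids)), as.character(ids))
  for (u in as.character(ids)) adj[[u]] <- integer(0)
  if (nrow(pairs)) {
    pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
    uq <- unique(pairs)
    for (u in as.character(ids)) {
      adj[[u]] <- sort(uq[uq[, 1L] == as.integer(u), 2L])
    }
  }
  adj
}

## rook-connected components within a logical mask; returns integer matrix
## (NA outside mask) numbered in first-cell scan order
rook_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(NA_integer_, nr, nc)
  nxt <- 0L
  for (start in which(mask & is.na(comp))) {
    if (!is.na(comp[start])) next
    nxt <- nxt + 1L
    queue <- start; head <- 1L
    comp[start] <- nxt
    while (head <= length(queue)) {
      cell <- queue[head]; head <- head + 1L
      i <- ((cell - 1L) %% nr) + 1L
      j <- ((cell - 1L) %/% nr) + 1L
      for (k in c(1L, 3L, 5L, 7L)) {            # E, S, W, N
        ni <- i + D8_DI[k]; nj <- j + D8_DJ[k]
        if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
        if (!mask[ni, nj]) next
        ncell <- ni + (nj - 1L) * nr
        if (is.na(comp[ncell])) {
          comp[ncell] <- nxt
          queue <- c(queue, ncell)
        }
      }
    }
  }
  comp
}

## minimum distance from point (px,py) to the closed cell squares of the
## given linear cell indices (0 when inside a cell)
point_to_cells_distance <- function(px, py, cells, grid) {
  nr <- grid$nrow; cs <- grid$cellsize
  i <- ((cells - 1L) %% nr) + 1L
  j <- ((cells - 1L) %/% nr) + 1L
  x0 <- grid$xll + (j - 1L) * cs; x1 <- x0 + cs
  y1 <- grid$yll + (nr - i + 1L) * cs; y0 <- y1 - cs
  dx <- pmax(x0 - px, 0, px - x1)
  dy <- pmax(y0 - py, 0, py - y1)
  min(sqrt(dx * dx + dy * dy))
}

## cells of each unit lying on the open-water boundary: rook-adjacent to a
## nodata cell or to the raster edge
unit_boundary_cells <- function(units_obj, unit_id) {
  lab <- units_obj$labels
  nr <- nrow(lab); nc <- ncol(lab)
  cells <- which(as.vector(lab) == unit_id)
  keep <- logical(length(cells))
  for (q in seq_along(cells)) {
    cell <- cells[q]
    i <- ((cell - 1L) %% nr) + 1L
    j <- ((cell - 1L) %/% nr) + 1L
    for (k in c(1L, 3L, 5L, 7L)) {
      ni <- i + D8_DI[k]; nj <- j + D8_DJ[k]
      if (ni < 1L || ni > nr || nj < 1L || nj > nc || is.na(lab[ni, nj])) {
        keep[q] <- TRUE; break
      }
    }
  }
  cells[keep]
}
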