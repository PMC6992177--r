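#' Delineate conceptual marsh units from a flow field
#'
#' Labels every data cell by the sink (pit or edge sink) its steepest-descent
#' path terminates at, then polygonizes each sink's cell set into marsh
#' units. Ridge lines between drainage basins are the implicit unit
#' boundaries; each unit's drainage point is its terminal sink cell. Because
#' unit contiguity is rook (shared cell edge) while D8 paths may step
#' diagonally, a basin that is connected only through cell corners is split
#' into separate units; the part not containing the sink takes its lowest
#' cell as drainage point.
#'
#' @param dem a [wvi_raster()] elevation grid.
#' @param flow the [compute_flow_field()] result for `dem`; computed if
#'   missing.
#' @return A [marsh_units()] object. The attribute `basin` on the returned
#'   object's `labels` element is not set; use [basin_labels()] for the raw
#'   cell-to-sink map.
#' @examples
#' dem <- wvi_raster(outer(4:1, 4:1, function(a, b) a + b) + 0)  # SE corner sink
#' du <- delineate_units(dem)
#' nrow(du$units)  # 1
#' @export
delineate_units <- function(dem, flow = compute_flow_field(dem)) {
  validate_dem(dem)
  if (!inherits(flow, "wvi_flow")) stop("`flow` must come from compute_flow_field()")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  basin <- basin_labels(flow)
  data_cell <- !is.na(z)
  if (!any(data_cell)) stop("empty domain: raster is entirely nodata")

  ## split each basin into rook-connected units
  labels <- matrix(NA_integer_, nr, nc)
  drainage <- list()
  nxt <- 0L
  sinks <- sort(unique(basin[!is.na(basin)]))
  for (s in sinks) {
    comp <- rook_components(!is.na(basin) & basin == s)
    for (cid in sort(unique(comp[!is.na(comp)]))) {
      nxt <- nxt + 1L
      cells <- which(!is.na(comp) & comp == cid)
      labels[cells] <- nxt
      if (s %in% cells) {
        dcell <- s
      } else {
        dcell <- cells[which.min(z[cells])]     # flow exits at lowest cell
      }
      drainage[[as.character(nxt)]] <-
        c(((dcell - 1L) %% nr) + 1L, ((dcell - 1L) %/% nr) + 1L)
    }
  }

  grid <- list(xll = dem$xll, yll = dem$yll, cellsize = dem$cellsize,
               nrow = nr, ncol = nc)
  out <- marsh_units(labels, grid, drainage = drainage)
  out$basin <- basin
  out
}

#' Cell-to-sink basin map of a flow field
#'
#' Follows every cell's drainage pointer to its terminal sink by pointer
#' doubling. The returned matrix holds, for every data cell, the linear
#' (column-major) index of the sink cell it drains to.
#'
#' @param flow a `wvi_flow` object.
#' @return Integer matrix, `NA` on nodata cells.
#' @export
basin_labels <- function(flow) {
  d <- flow$direction
  nr <- nrow(d); nc <- ncol(d)
  tgt <- flow_targets(d, nr, nc)
  term <- seq_len(nr * nc)
  live <- which(!is.na(as.vector(d)))
  nxt <- ifelse(tgt == 0L, seq_len(nr * nc), tgt)  # sinks point at themselves
  repeat {
    step2 <- nxt[nxt]
    if (all(step2 == nxt)) break
    nxt <- step2
  }
  term <- rep(NA_integer_, nr * nc)
  term[live] <- nxt[live]
  matrix(term, nr, nc)
}

#' Merge marsh units below a minimum surface area
#'
#' Iteratively enforces the minimum-area rule used to clean up peripheral
#' slivers after delineation: while any unit is smaller than `min_area`, the
#' smallest such unit is merged into its nearest adjacent unit (the
#' shared-boundary neighbor with the closest centroid). When a rook-connected
#' cluster of sub-threshold units has no adjacent unit at or above the
#' threshold, the whole cluster is dissolved into a single new unit with
#' provenance `"aggregated"`. Areas, centroids and adjacency are recomputed
#' after every merge; ties (equal areas, equal centroid distances) resolve to
#' the lowest unit id. Isolated units with no neighbors at all are left in
#' place: nothing exists to merge them into.
#'
#' @param units a [marsh_units()] object.
#' @param min_area minimum unit surface area in square meters; default
#'   5000 m2.
#' @return A [marsh_units()] object in which every unit with at least one
#'   neighbor has `area_m2 >= min_area`. Total area and the cell partition
#'   are conserved.
#' @export
merge_small_units <- function(units, min_area = 5000) {
  if (!inherits(units, "marsh_units")) stop("`units` must be a marsh_units object")
  if (!is.numeric(min_area) || length(min_area) != 1L || !is.finite(min_area) ||
      min_area <= 0)
    stop("`min_area` must be a single positive number (m2)")

  labels <- units$labels
  grid <- units$grid
  drainage <- units_drainage_list(units)
  provenance <- stats::setNames(units$units$provenance,
                                as.character(units$units$id))
  cur <- units
  frozen <- integer(0)   # isolated sub-threshold units that cannot be merged

  repeat {
    tab <- cur$units
    small <- tab[tab$area_m2 < min_area & !(tab$id %in% frozen), , drop = FALSE]
    if (nrow(small) == 0L) break
    u <- small$id[order(small$area_m2, small$id)][1L]
    nb <- cur$adjacency[[as.character(u)]]

    if (length(nb) == 0L) {
      frozen <- c(frozen, u)
      next
    }

    big_nb <- nb[tab$area_m2[match(nb, tab$id)] >= min_area]
    if (length(big_nb) == 0L &&
        all(tab$area_m2[match(nb, tab$id)] < min_area)) {
      ## sub-threshold cluster: is any unit of the connected small-cluster
      ## adjacent to a large unit? if not, dissolve the cluster
      cluster <- small_cluster(cur, u, min_area)
      touches_large <- any(vapply(cluster, function(v) {
        any(tab$area_m2[match(cur$adjacency[[as.character(v)]], tab$id)] >=
              min_area)
      }, logical(1)))
      if (!touches_large) {
        new_id <- max(tab$id) + 1L
        labels[labels %in% cluster] <- new_id
        drainage[[as.character(new_id)]] <-
          drainage[[as.character(min(cluster))]]
        provenance[as.character(new_id)] <- "aggregated"
        drainage[as.character(cluster)] <- NULL
        provenance <- provenance[!(names(provenance) %in% as.character(cluster))]
        cur <- marsh_units(labels, grid, drainage, provenance)
        next
      }
      ## else fall through: merge u into its nearest adjacent unit as usual
    }

    cx <- tab$centroid_x[tab$id == u]; cy <- tab$centroid_y[tab$id == u]
    nbi <- match(nb, tab$id)
    d2 <- (tab$centroid_x[nbi] - cx)^2 + (tab$centroid_y[nbi] - cy)^2
    target <- nb[order(d2, nb)][1L]

    labels[labels == u] <- target
    provenance[as.character(target)] <- "merged"
    drainage[as.character(u)] <- NULL
    provenance <- provenance[names(provenance) != as.character(u)]
    cur <- marsh_units(labels, grid, drainage, provenance)
  }
  cur
}

units_drainage_list <- function(units) {
  out <- list()
  for (r in seq_len(nrow(units$units))) {
    if (!is.na(units$units$drainage_row[r]))
      out[[as.character(units$units$id[r])]] <-
        c(units$units$drainage_row[r], units$units$drainage_col[r])
  }
  out
}

## connected component of sub-threshold units containing `u` in the unit
## adjacency graph restricted to sub-threshold units
small_cluster <- function(units, u, min_area) {
  tab <- units$units
  is_small <- stats::setNames(tab$area_m2 < min_area, as.character(tab$id))
  seen <- u
  queue <- u
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- units$adjacency[[as.character(v)]]
    nb <- nb[is_small[as.character(nb)] & !(nb %in% seen)]
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  sort(seen)
}
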