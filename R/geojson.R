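## GeoJSON export of marsh units: unit polygons are traced from the label
## grid (exterior rings counterclockwise, holes clockwise, per RFC 7946).

#' Export marsh units as GeoJSON
#'
#' Traces each unit's cell-edge boundary into polygon rings and writes a
#' GeoJSON FeatureCollection with fields `id`, `area_m2`, `drainage_x`,
#' `drainage_y` and `provenance`. Optional per-unit attributes (e.g. WVI)
#' can be joined in through `extra`.
#'
#' @param units a [marsh_units()] object.
#' @param path output file; when `NULL` the GeoJSON string is returned.
#' @param extra optional data.frame with an `id` column to join additional
#'   properties per unit.
#' @return `path` invisibly (or the JSON string when `path` is `NULL`).
#' @export
units_to_geojson <- function(units, path = NULL, extra = NULL) {
  if (!inherits(units, "marsh_units")) stop("`units` must be a marsh_units object")
  tab <- units$units
  if (!is.null(extra)) {
    if (!"id" %in% names(extra)) stop("`extra` needs an `id` column")
    tab <- merge(tab, extra, by = "id", all.x = TRUE, sort = TRUE)
  }
  feats <- lapply(seq_len(nrow(tab)), function(r) {
    id <- tab$id[r]
    rings <- trace_unit_rings(units, id)
    props <- as.list(tab[r, setdiff(names(tab),
                                    c("n_cells", "drainage_row", "drainage_col",
                                      "centroid_x", "centroid_y")),
                         drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  js <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

## boundary rings of one unit; first ring is the CCW exterior, the rest are
## CW holes. Each ring is a closed list of [x, y] vertex pairs.
trace_unit_rings <- function(units, unit_id) {
  lab <- units$labels
  g <- units$grid
  nr <- g$nrow; nc <- g$ncol; cs <- g$cellsize
  cells <- which(as.vector(lab) == unit_id)
  inside <- matrix(FALSE, nr, nc); inside[cells] <- TRUE

  ## directed boundary edges with the unit interior on the left; integer
  ## corner coordinates (col index 0..nc along x, "rows from bottom" along y)
  from <- to <- matrix(0L, 0L, 2L)
  add <- function(fx, fy, tx, ty) {
    from <<- rbind(from, c(fx, fy)); to <<- rbind(to, c(tx, ty))
  }
  for (cell in cells) {
    i <- ((cell - 1L) %% nr) + 1L
    j <- ((cell - 1L) %/% nr) + 1L
    x0 <- j - 1L; x1 <- j; y1 <- nr - i + 1L; y0 <- y1 - 1L
    if (i == nr || !inside[i + 1L, j]) add(x0, y0, x1, y0)   # south edge, W->E
    if (j == nc || !inside[i, j + 1L]) add(x1, y0, x1, y1)   # east edge, S->N
    if (i == 1L || !inside[i - 1L, j]) add(x1, y1, x0, y1)   # north edge, E->W
    if (j == 1L || !inside[i, j - 1L]) add(x0, y1, x0, y0)   # west edge, N->S
  }

  key <- function(p) paste(p[, 1L], p[, 2L])
  used <- rep(FALSE, nrow(from))
  start_of <- split(seq_len(nrow(from)), key(from))
  rings <- list()
  for (e0 in seq_len(nrow(from))) {
    if (used[e0]) next
    ring <- list(from[e0, ])
    cur <- e0
    repeat {
      used[cur] <- TRUE
      ring[[length(ring) + 1L]] <- to[cur, ]
      if (all(to[cur, ] == from[e0, ])) break
      cand <- start_of[[paste(to[cur, 1L], to[cur, 2L])]]
      cand <- cand[!used[cand]]
      cur <- cand[1L]           # deterministic pick at pinch corners
    }
    rings[[length(rings) + 1L]] <- ring
  }

  coords <- lapply(rings, function(ring) {
    m <- do.call(rbind, ring)
    cbind(g$xll + m[, 1L] * cs, g$yll + m[, 2L] * cs)
  })
  ## signed area: CCW (positive) = exterior first
  sgn <- vapply(coords, ring_signed_area, numeric(1))
  coords[order(-sgn)]
}

ring_signed_area <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  n <- nrow(m)
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}
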