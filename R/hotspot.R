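## Hotspot zoning: seed units above a WVI threshold, 1 km buffers dissolved
## into zones, membership by centroid-in-buffer, minimum unit-count and
## minimum-area filters. Plus transect profiles across marsh units.

#' WVI hotspot seed threshold
#'
#' The seeding threshold for hotspot analysis: the mean WVI plus
#' `multiplier` sample standard deviations. Units strictly above the
#' threshold seed hotspot zones.
#'
#' @param wvi numeric per-unit index values (`NA` allowed).
#' @param multiplier number of standard deviations above the mean
#'   (default 1).
#' @return The threshold value.
#' @export
wvi_threshold <- function(wvi, multiplier = 1) {
  v <- wvi[!is.na(wvi)]
  if (length(v) < 2L) stop("need at least 2 units with defined WVI")
  mean(v) + multiplier * stats::sd(v)
}

#' Identify vulnerability hotspot zones
#'
#' Implements the buffer/count/area zoning rule: (1) seed units are those
#' with `wvi` strictly above `threshold`; (2) a buffer of `buffer_m` is
#' drawn around each seed unit's geometry and overlapping buffers dissolve
#' into candidate zones; (3) a unit belongs to a zone when its centroid
#' falls inside the zone's buffer polygon (equivalently, within `buffer_m`
#' of some member seed's geometry); a unit reachable from several zones is
#' assigned to the zone of the nearest seed; (4) only zones with at least
#' `min_n` member units AND total member area of at least `min_area_m2`
#' are kept. Surviving zones are numbered by descending total area.
#'
#' @param units a [marsh_units()] object (planar CRS in meters).
#' @param wvi per-unit WVI, aligned with `units$units$id`.
#' @param threshold seed threshold; default [wvi_threshold()] of `wvi`.
#' @param buffer_m buffer radius in meters (default 1000).
#' @param min_n minimum member count per zone (default 2, i.e. n > 1).
#' @param min_area_m2 minimum total member area (default 2e6 m2 = 2 km2).
#' @return An object of class `wvi_hotspots`: list with `zones` (list of
#'   lists: zone_id, seed_unit_ids, member_unit_ids, n_units,
#'   total_area_m2), `threshold`, `seed_ids`, and `membership` (data.frame
#'   unit_id/zone_id for members).
#' @export
identify_hotspots <- function(units, wvi, threshold = NULL, buffer_m = 1000,
                              min_n = 2L, min_area_m2 = 2e6) {
  if (!inherits(units, "marsh_units")) stop("`units` must be a marsh_units object")
  tab <- units$units
  if (length(wvi) != nrow(tab)) stop("`wvi` must have one value per unit")
  if (is.null(threshold)) threshold <- wvi_threshold(wvi)

  seed_ids <- tab$id[!is.na(wvi) & wvi > threshold]
  empty <- structure(list(zones = list(), threshold = threshold,
                          seed_ids = seed_ids,
                          membership = data.frame(unit_id = integer(0),
                                                  zone_id = integer(0))),
                     class = "wvi_hotspots")
  if (length(seed_ids) == 0L) return(empty)

  ## seed geometries (boundary cells suffice for minimum distances)
  seed_cells <- lapply(seed_ids, function(u)
    which(as.vector(units$labels) == u))
  names(seed_cells) <- as.character(seed_ids)

  ## dissolve overlapping buffers: seeds whose geometries lie within
  ## 2 * buffer_m of each other share a zone
  ns <- length(seed_ids)
  grp <- seq_len(ns)
  if (ns > 1L) {
    for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
      if (unit_geometry_distance(units, seed_ids[a], seed_ids[b]) <
          2 * buffer_m) {
        ga <- grp[a]; gb <- grp[b]
        grp[grp == max(ga, gb)] <- min(ga, gb)
      }
    }
  }

  ## membership: centroid within buffer_m of a seed geometry; ties to the
  ## nearest seed
  member_zone <- rep(NA_integer_, nrow(tab))
  member_dist <- rep(Inf, nrow(tab))
  for (s in seq_len(ns)) {
    d <- vapply(seq_len(nrow(tab)), function(r)
      point_to_cells_distance(tab$centroid_x[r], tab$centroid_y[r],
                              seed_cells[[s]], units$grid), numeric(1))
    closer <- d <= buffer_m & d < member_dist
    member_zone[closer] <- grp[s]
    member_dist[closer] <- d[closer]
  }

  zones <- list()
  for (g in sort(unique(grp))) {
    members <- tab$id[!is.na(member_zone) & member_zone == g]
    area <- sum(tab$area_m2[tab$id %in% members])
    if (length(members) >= min_n && area >= min_area_m2) {
      zones[[length(zones) + 1L]] <- list(
        seed_unit_ids = sort(seed_ids[grp == g]),
        member_unit_ids = sort(members),
        n_units = length(members),
        total_area_m2 = area
      )
    }
  }
  if (length(zones) == 0L) return(empty)

  ord <- order(-vapply(zones, `[[`, numeric(1), "total_area_m2"))
  zones <- zones[ord]
  for (z in seq_along(zones)) zones[[z]]$zone_id <- z
  membership <- do.call(rbind, lapply(zones, function(z)
    data.frame(unit_id = z$member_unit_ids, zone_id = z$zone_id)))
  structure(list(zones = zones, threshold = threshold, seed_ids = seed_ids,
                 membership = membership),
            class = "wvi_hotspots")
}

#' @export
print.wvi_hotspots <- function(x, ...) {
  cat(sprintf("<wvi_hotspots> %d zones (threshold %.4g, %d seed units)\n",
              length(x$zones), x$threshold, length(x$seed_ids)))
  for (z in x$zones)
    cat(sprintf("  zone %d: %d units, %.3g m2\n",
                z$zone_id, z$n_units, z$total_area_m2))
  invisible(x)
}

## minimum distance between two units' cell geometries (exact for unions of
## axis-aligned cell squares; attained at boundary cells)
unit_geometry_distance <- function(units, id_a, id_b) {
  g <- units$grid; nr <- g$nrow; cs <- g$cellsize
  ca <- unit_boundary_cells_any(units, id_a)
  cb <- unit_boundary_cells_any(units, id_b)
  rect <- function(cells) {
    i <- ((cells - 1L) %% nr) + 1L
    j <- ((cells - 1L) %/% nr) + 1L
    x0 <- g$xll + (j - 1L) * cs
    y1 <- g$yll + (nr - i + 1L) * cs
    cbind(x0 = x0, x1 = x0 + cs, y0 = y1 - cs, y1 = y1)
  }
  ra <- rect(ca); rb <- rect(cb)
  best <- Inf
  for (q in seq_len(nrow(ra))) {
    dx <- pmax(rb[, "x0"] - ra[q, "x1"], 0, ra[q, "x0"] - rb[, "x1"])
    dy <- pmax(rb[, "y0"] - ra[q, "y1"], 0, ra[q, "y0"] - rb[, "y1"])
    best <- min(best, min(sqrt(dx * dx + dy * dy)))
  }
  best
}

## cells of a unit adjacent to anything that is not the unit (other units,
## nodata, or the raster edge)
unit_boundary_cells_any <- function(units, unit_id) {
  lab <- units$labels
  nr <- nrow(lab); nc <- ncol(lab)
  cells <- which(as.vector(lab) == unit_id)
  keep <- logical(length(cells))
  for (q in seq_along(cells)) {
    cell <- cells[q]
    i <- ((cell - 1L) %% nr) + 1L
    j <- ((cell - 1L) %/% nr) + 1L
    for (k in c(1L, 3L, 5L, 7L)) {
      ni <- i + D8_DI[k]; nj <- j + D8_DJ[k]
      if (ni < 1L || ni > nr || nj < 1L || nj > nc ||
          is.na(lab[ni, nj]) || lab[ni, nj] != unit_id) {
        keep[q] <- TRUE; break
      }
    }
  }
  cells[keep]
}

#' Indicator departure profile of a hotspot zone
#'
#' Mean z-score of each indicator over the zone's member units, with a
#' significance flag where the magnitude exceeds one standard deviation
#' from the global mean (`|mean z| > 1`).
#'
#' @param member_ids unit ids of the zone's members.
#' @param z z-scored indicator matrix with rownames (or row order) matching
#'   `unit_ids`.
#' @param unit_ids unit ids aligned with the rows of `z`.
#' @return List with `means` (named numeric per indicator) and
#'   `significant` (labels with `|mean| > 1`).
#' @export
zone_profile <- function(member_ids, z, unit_ids) {
  rows <- match(member_ids, unit_ids)
  if (anyNA(rows)) stop("member id(s) not found among unit_ids")
  m <- colMeans(as.matrix(z)[rows, , drop = FALSE])
  list(means = m, significant = names(m)[abs(m) > 1])
}

#' Extract a transect profile across marsh units
#'
#' Orders the units a polyline crosses by the distance along the line at
#' which the line first enters each unit, and attaches per-unit values
#' (e.g. WVI and ranked indicators). A line touching no unit yields an
#' empty profile.
#'
#' @param units a [marsh_units()] object.
#' @param line two-column matrix of polyline vertices (planar meters), in
#'   traversal order.
#' @param values optional data.frame with an `id` or `unit_id` column of
#'   per-unit attributes to attach.
#' @return data.frame with `unit_id` and `distance_m` (distance along the
#'   line at first entry, strictly increasing), plus any attached columns.
#' @export
extract_transect <- function(units, line, values = NULL) {
  if (!inherits(units, "marsh_units")) stop("`units` must be a marsh_units object")
  line <- as.matrix(line)
  if (ncol(line) != 2L || nrow(line) < 2L)
    stop("`line` must be a matrix of at least two x/y vertices")
  g <- units$grid; nr <- g$nrow; cs <- g$cellsize
  lab <- as.vector(units$labels)

  seg_len <- sqrt(rowSums((line[-1L, , drop = FALSE] -
                           line[-nrow(line), , drop = FALSE])^2))
  cum0 <- c(0, cumsum(seg_len))

  entry <- stats::setNames(rep(Inf, nrow(units$units)),
                           as.character(units$units$id))
  for (u in units$units$id) {
    cells <- which(lab == u)
    i <- ((cells - 1L) %% nr) + 1L
    j <- ((cells - 1L) %/% nr) + 1L
    x0 <- g$xll + (j - 1L) * cs; x1 <- x0 + cs
    y1 <- g$yll + (nr - i + 1L) * cs; y0 <- y1 - cs
    for (s in seq_len(nrow(line) - 1L)) {
      if (!is.finite(seg_len[s]) || seg_len[s] == 0) next
      t0 <- segment_rects_entry(line[s, ], line[s + 1L, ], x0, x1, y0, y1)
      if (is.finite(t0))
        entry[as.character(u)] <- min(entry[as.character(u)],
                                      cum0[s] + t0 * seg_len[s])
    }
  }
  hit <- names(entry)[is.finite(entry)]
  out <- data.frame(unit_id = as.integer(hit),
                    distance_m = as.numeric(entry[hit]))
  out <- out[order(out$distance_m, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(values)) {
    key <- if ("unit_id" %in% names(values)) "unit_id" else "id"
    idx <- match(out$unit_id, values[[key]])
    out <- cbind(out, values[idx, setdiff(names(values), key), drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

## smallest parameter t in [0,1] at which segment p->q intersects any of the
## axis-aligned rectangles (vectors x0,x1,y0,y1); Inf when none (slab test)
segment_rects_entry <- function(p, q, x0, x1, y0, y1) {
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  if (dx == 0) {
    okx <- p[1] >= x0 & p[1] <= x1
    tx_lo <- ifelse(okx, 0, Inf); tx_hi <- ifelse(okx, 1, -Inf)
  } else {
    ta <- (x0 - p[1]) / dx; tb <- (x1 - p[1]) / dx
    tx_lo <- pmin(ta, tb); tx_hi <- pmax(ta, tb)
  }
  if (dy == 0) {
    oky <- p[2] >= y0 & p[2] <= y1
    ty_lo <- ifelse(oky, 0, Inf); ty_hi <- ifelse(oky, 1, -Inf)
  } else {
    ta <- (y0 - p[2]) / dy; tb <- (y1 - p[2]) / dy
    ty_lo <- pmin(ta, tb); ty_hi <- pmax(ta, tb)
  }
  lo <- pmax(tx_lo, ty_lo, 0)
  hi <- pmin(tx_hi, ty_hi, 1)
  ok <- lo <= hi
  if (!any(ok)) return(Inf)
  min(lo[ok])
}
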