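## The ten vulnerability indicators: labels, units, orientation and
## chronic/episodic class, plus the published min-max ranges used by the
## synthetic generator's marginal transforms.

#' Vulnerability indicator specification
#'
#' The ten physical/biophysical indicator layers the index is built from.
#' `direction == "inverted"` marks indicators whose LOWER raw values mean
#' HIGHER vulnerability (lower elevation, lower tidal range, lower sediment
#' supply, more negative shoreline change); these are negated by [orient()]
#' before ranking so that larger oriented values always mean more vulnerable.
#' Chronic indicators describe annual-to-decadal drivers; episodic indicators
#' describe storm-event drivers.
#'
#' @return A data.frame with columns `label`, `indicator`, `units`,
#'   `direction` (`"direct"`/`"inverted"`), `class` (`"chronic"`/
#'   `"episodic"`), `range_min`, `range_max` (published raw-value ranges).
#' @examples
#' wvi_indicators()$label
#' @export
wvi_indicators <- function() {
  data.frame(
    label = c("CONDC", "SCORR", "ELEVA", "EXSAL", "RESID",
              "SALIN", "SEDIM", "SHORE", "TIDER", "UVVR"),
    indicator = c("Marsh condition change", "Contaminant exposure potential",
                  "Lower elevation", "Longer salinity exposure",
                  "Higher residence time", "Higher salinity change",
                  "Lower sediment supply", "Shoreline change",
                  "Lower tidal range", "More unvegetated (UVVR)"),
    units = c("-", "-", "m", "g kg-1 d", "d", "g kg-1", "kg m-3",
              "m y-1", "m", "-"),
    direction = c("direct", "direct", "inverted", "direct", "direct",
                  "direct", "inverted", "inverted", "inverted", "direct"),
    class = c("episodic", "episodic", "chronic", "episodic", "chronic",
              "episodic", "episodic", "chronic", "chronic", "chronic"),
    range_min = c(0.50, 0, 0, 0.25, 0.03, 0.29, 0, -9.29, 0, 0),
    range_max = c(4, 39.62, 3.45, 114.95, 50.63, 32.69, 0.77, 9.48,
                  1.13, 4.05),
    stringsAsFactors = FALSE
  )
}

indicator_labels <- function() wvi_indicators()$label

#' @rdname wvi_indicators
#' @param class `"chronic"` or `"episodic"`.
#' @export
indicator_class_labels <- function(class = c("chronic", "episodic")) {
  class <- match.arg(class)
  spec <- wvi_indicators()
  spec$label[spec$class == class]
}

#' Zonal mean of a raster layer over marsh units
#'
#' Arithmetic mean of the layer's cell values over every cell whose center
#' falls inside the unit (cell membership is by the shared label grid, so
#' the layer must be aligned to the unit grid: same dimensions, origin and
#' cell size). Layer nodata cells are ignored; a unit entirely over nodata
#' gets `NA`.
#'
#' @param layer a [wvi_raster()] aligned with `units`.
#' @param units a [marsh_units()] object.
#' @return Named numeric vector, one value per unit id.
#' @export
zonal_mean <- function(layer, units) {
  if (!inherits(layer, "wvi_raster")) stop("`layer` must be a wvi_raster")
  if (!inherits(units, "marsh_units")) stop("`units` must be a marsh_units object")
  g <- units$grid
  if (nrow(layer$values) != g$nrow || ncol(layer$values) != g$ncol ||
      layer$cellsize != g$cellsize ||
      layer$xll != g$xll || layer$yll != g$yll)
    stop("layer grid is not aligned with the unit grid (CRS/geometry mismatch)")
  lab <- as.vector(units$labels)
  val <- as.vector(layer$values)
  keep <- !is.na(lab) & !is.na(val)
  means <- tapply(val[keep], lab[keep], mean)
  out <- stats::setNames(rep(NA_real_, nrow(units$units)),
                         as.character(units$units$id))
  out[names(means)] <- means
  out
}

#' Average shoreline-change rates along each unit's shoreline
#'
#' Each rate observation (a transect intercept or point, in m/yr) is snapped
#' to the unit whose open-water boundary (cells adjacent to nodata or to the
#' raster edge) is nearest, provided that distance is within `tolerance`.
#' Units with no snapped observations -- including landlocked units, which
#' have no shoreline -- get `NA`.
#'
#' @param rates data.frame with columns `x`, `y`, `rate` (planar meters,
#'   m/yr).
#' @param units a [marsh_units()] object.
#' @param tolerance snap distance in meters; default two cell sizes.
#' @return Named numeric vector of mean rates per unit id.
#' @export
shoreline_mean <- function(rates, units, tolerance = 2 * units$grid$cellsize) {
  if (!inherits(units, "marsh_units")) stop("`units` must be a marsh_units object")
  out <- stats::setNames(rep(NA_real_, nrow(units$units)),
                         as.character(units$units$id))
  if (is.null(rates) || nrow(rates) == 0L) return(out)
  if (!all(c("x", "y", "rate") %in% names(rates)))
    stop("`rates` needs columns x, y, rate")
  ids <- units$units$id
  bnd <- lapply(ids, function(u) unit_boundary_cells(units, u))
  names(bnd) <- as.character(ids)
  assigned <- rep(NA_integer_, nrow(rates))
  for (p in seq_len(nrow(rates))) {
    d <- vapply(as.character(ids), function(u) {
      if (length(bnd[[u]]) == 0L) return(Inf)
      point_to_cells_distance(rates$x[p], rates$y[p], bnd[[u]], units$grid)
    }, numeric(1))
    best <- which.min(d)
    if (d[best] <= tolerance) assigned[p] <- ids[best]
  }
  ok <- !is.na(assigned)
  if (any(ok)) {
    m <- tapply(rates$rate[ok], assigned[ok], mean)
    out[names(m)] <- m
  }
  out
}

#' Unvegetated-to-vegetated area ratio per unit
#'
#' UVVR is the ratio of a unit's unvegetated area to its vegetated area, an
#' integrative stability metric for microtidal marshes. Computed from a
#' classified land-cover grid aligned with the unit grid.
#'
#' @param landcover a [wvi_raster()] of integer class codes aligned with
#'   `units`.
#' @param units a [marsh_units()] object.
#' @param classes named vector mapping the codes: must name `vegetated` and
#'   `unvegetated`; any additional named codes (e.g. `other`) are ignored in
#'   the ratio. Codes present in the grid but absent from `classes` are an
#'   error.
#' @return Named numeric vector of ratios per unit id; a unit with zero
#'   vegetated area gets `NA` (undefined ratio), with the affected ids in
#'   attribute `undefined`.
#' @export
compute_uvvr <- function(landcover, units,
                         classes = c(vegetated = 1, unvegetated = 2, other = 0)) {
  if (!all(c("vegetated", "unvegetated") %in% names(classes)))
    stop("`classes` must name `vegetated` and `unvegetated` codes")
  g <- units$grid
  if (nrow(landcover$values) != g$nrow || ncol(landcover$values) != g$ncol)
    stop("land-cover grid is not aligned with the unit grid")
  lab <- as.vector(units$labels)
  lc <- as.vector(landcover$values)
  keep <- !is.na(lab) & !is.na(lc)
  unknown <- setdiff(unique(lc[keep]), unname(classes))
  if (length(unknown))
    stop("unknown land-cover class code(s): ", paste(unknown, collapse = ", "))
  ids <- as.character(units$units$id)
  veg <- tapply(lc[keep] == classes[["vegetated"]], lab[keep], sum)
  unv <- tapply(lc[keep] == classes[["unvegetated"]], lab[keep], sum)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  v <- stats::setNames(rep(0, length(ids)), ids); v[names(veg)] <- veg
  u <- stats::setNames(rep(0, length(ids)), ids); u[names(unv)] <- unv
  defined <- v > 0
  out[defined] <- u[defined] / v[defined]
  attr(out, "undefined") <- ids[!defined]
  out
}

#' Orient raw indicator values so larger means more vulnerable
#'
#' Direct indicators pass through unchanged; inverted indicators (lower raw
#' value implies higher vulnerability) are negated, so ordering by
#' vulnerability is ascending in the output. Missing values propagate.
#'
#' @param values numeric vector of raw per-unit values.
#' @param label indicator label (one of [wvi_indicators()]'s labels), or
#'   directly `"direct"`/`"inverted"`.
#' @return Oriented numeric vector.
#' @export
orient <- function(values, label) {
  dir <- if (label %in% c("direct", "inverted")) label else {
    spec <- wvi_indicators()
    if (!label %in% spec$label) stop("unknown indicator label: ", label)
    spec$direction[spec$label == label]
  }
  if (dir == "inverted") -values else values
}

#' Assemble an indicator table from raw per-unit layers
#'
#' Applies [orient()] to each raw layer and binds the ten columns into the
#' units x indicators table consumed by [rank_indicators()]. Missing cells
#' stay `NA` (they are carried, never imputed; ranking uses non-missing
#' values only).
#'
#' @param unit_ids integer vector of unit ids (row order of the table).
#' @param raw named list of raw numeric vectors (names from
#'   [wvi_indicators()]'s labels, each of length `length(unit_ids)`).
#'   Indicators not supplied are filled with `NA`.
#' @return A data.frame with column `unit_id` followed by the ten oriented
#'   indicator columns.
#' @export
assemble_indicators <- function(unit_ids, raw) {
  labs <- indicator_labels()
  bad <- setdiff(names(raw), labs)
  if (length(bad)) stop("unknown indicator label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(unit_id = unit_ids)
  for (lb in labs) {
    v <- raw[[lb]]
    if (is.null(v)) v <- rep(NA_real_, length(unit_ids))
    if (length(v) != length(unit_ids))
      stop("layer ", lb, " has length ", length(v), ", expected ",
           length(unit_ids))
    out[[lb]] <- orient(unname(v), lb)
  }
  out
}
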