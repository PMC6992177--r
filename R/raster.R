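#' Elevation / layer raster on a regular planar grid
#'
#' Lightweight container for a single-band raster: a numeric matrix whose
#' first row is the northernmost row, together with the planar coordinates of
#' the lower-left corner and a square cell size in meters. Missing cells are
#' `NA`. All delineation and zonal operations in the package consume this
#' class; [read_ascii_grid()] / [write_ascii_grid()] exchange it with the
#' ESRI ASCII grid format, a plain-text raster interchange format understood
#' by standard GIS software.
#'
#' @param values numeric matrix of cell values; row 1 is the top (north) row.
#'   `NA` marks nodata cells.
#' @param xll,yll planar coordinates (meters) of the lower-left corner of the
#'   grid extent.
#' @param cellsize cell edge length in meters (square cells); must be > 0.
#' @return An object of class `wvi_raster`: a list with elements `values`,
#'   `xll`, `yll`, `cellsize`.
#' @examples
#' r <- wvi_raster(matrix(1:12, 3, 4), cellsize = 5)
#' cell_centers(r)[1, ]
#' @export
wvi_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0)
    stop("`cellsize` must be a single positive number (meters)")
  if (any(is.nan(values)))
    stop("raster contains NaN among data values; use NA for nodata")
  if (any(is.infinite(values)))
    stop("raster contains non-finite data values")
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize)),
    class = "wvi_raster"
  )
}

#' @export
print.wvi_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<wvi_raster> %d x %d cells, cellsize %g m\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xll, x$xll + ncol(v) * x$cellsize,
              x$yll, x$yll + nrow(v) * x$cellsize))
  cat(sprintf("  data cells: %d of %d; range [%g, %g]\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.wvi_raster <- function(x) dim(x$values)

#' Planar coordinates of every cell center
#'
#' @param r a [wvi_raster()] or a `marsh_units` object.
#' @return A two-column matrix (`x`, `y`) with one row per cell in
#'   column-major matrix order.
#' @export
cell_centers <- function(r) {
  g <- if (inherits(r, "marsh_units")) r$grid else
    list(xll = r$xll, yll = r$yll, cellsize = r$cellsize,
         nrow = nrow(r$values), ncol = ncol(r$values))
  nr <- g$nrow %||% nrow(r$values)
  nc <- g$ncol %||% ncol(r$values)
  i <- rep(seq_len(nr), times = nc)
  j <- rep(seq_len(nc), each = nr)
  cbind(x = g$xll + (j - 0.5) * g$cellsize,
        y = g$yll + (nr - i + 0.5) * g$cellsize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_dem <- function(dem) {
  if (!inherits(dem, "wvi_raster")) stop("`dem` must be a wvi_raster")
  if (!any(!is.na(dem$values)))
    stop("empty domain: raster is entirely nodata")
  invisible(dem)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange. `NODATA_value` is honored on read
#' and written as -9999. Cell values are written with full double precision
#' so a write/read round trip is lossless.
#'
#' @param path file path of the `.asc` grid.
#' @param r a [wvi_raster()].
#' @return `read_ascii_grid()` returns a [wvi_raster()]; `write_ascii_grid()`
#'   returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (is.null(nc) || is.null(nr)) stop("not an ESRI ASCII grid: ", path)
  body <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nr * nc) stop("grid body size mismatch in ", path)
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  wvi_raster(vals, xll = xll, yll = yll, cellsize = hdr$cellsize %||% 1)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(r, path) {
  if (!inherits(r, "wvi_raster")) stop("`r` must be a wvi_raster")
  v <- r$values
  v[is.na(v)] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    "NODATA_value -9999"
  )
  rows <- apply(v, 1L, function(x) paste(format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
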