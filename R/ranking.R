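## Percentile (equal-frequency) classification into the four vulnerability
## categories and aggregation into the wetland vulnerability index.

WVI_CATEGORIES <- c("low", "moderate", "high", "severe")

#' Equal-frequency percentile classification of one indicator
#'
#' Sorts the non-missing oriented values ascending (most vulnerable last)
#' and cuts at the quartiles of ordinal position so that category counts are
#' as equal as possible: with `n = 4q + r`, the first `r` categories get
#' `q + 1` members and the rest `q`. The sort is made stable by breaking
#' value ties on `ids`, so tied values may straddle a category edge by
#' ordinal position -- this preserves exact equal occupancy, which is the
#' point of the classification. Categories are encoded numerically as
#' 0, 1/3, 2/3, 1 (low .. severe).
#'
#' @param values oriented numeric values (larger = more vulnerable); `NA`
#'   allowed.
#' @param ids tie-break ordering key, default positional.
#' @param n_bins number of categories (default 4: low, moderate, high,
#'   severe).
#' @return List with `category` (factor, `NA` for missing input),
#'   `rank_value` (numeric in `[0, 1]`), and `cuts`: the `n_bins - 1`
#'   oriented-scale boundaries (midpoints between the values adjacent to
#'   each ordinal cut).
#' @examples
#' percentile_rank(1:8)$category
#' @export
percentile_rank <- function(values, ids = seq_along(values), n_bins = 4L) {
  ok <- which(!is.na(values))
  n <- length(ok)
  if (n < n_bins)
    stop("cannot rank: only ", n, " non-missing values for ", n_bins, " bins")
  ord <- ok[order(values[ok], ids[ok])]
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  bin <- rep(seq_len(n_bins), times = sizes)

  cat_labels <- if (n_bins == 4L) WVI_CATEGORIES else paste0("bin", seq_len(n_bins))
  category <- factor(rep(NA_character_, length(values)), levels = cat_labels)
  category[ord] <- cat_labels[bin]
  rank_value <- rep(NA_real_, length(values))
  rank_value[ord] <- (bin - 1) / (n_bins - 1)

  ends <- cumsum(sizes)
  sorted <- values[ord]
  cuts <- (sorted[ends[-n_bins]] + sorted[ends[-n_bins] + 1L]) / 2
  list(category = category, rank_value = rank_value, cuts = cuts)
}

#' Rank all indicators of a table into vulnerability categories
#'
#' Applies [percentile_rank()] column-wise to an oriented indicator table
#' and reports, per indicator, the category thresholds converted back to
#' the raw (unoriented) scale as contiguous bins covering the observed
#' range -- for inverted indicators the raw-scale bins decrease with
#' vulnerability, matching how such thresholds are conventionally tabulated.
#'
#' @param indicators data.frame from [assemble_indicators()] (column
#'   `unit_id` + oriented indicator columns).
#' @param n_bins number of categories, default 4.
#' @return An object of class `wvi_ranked`: list with `unit_id`,
#'   `categories` (data.frame of factors), `rank_values` (data.frame in
#'   `[0, 1]`), `thresholds` (named list of data.frames: category,
#'   raw_lower, raw_upper), `n_bins`.
#' @export
rank_indicators <- function(indicators, n_bins = 4L) {
  if (!"unit_id" %in% names(indicators))
    stop("`indicators` needs a unit_id column")
  labs <- setdiff(names(indicators), "unit_id")
  spec <- wvi_indicators()
  categories <- rank_values <- list()
  thresholds <- list()
  for (lb in labs) {
    v <- indicators[[lb]]
    if (sum(!is.na(v)) < n_bins) {
      categories[[lb]] <- factor(rep(NA_character_, length(v)),
                                 levels = WVI_CATEGORIES)
      rank_values[[lb]] <- rep(NA_real_, length(v))
      thresholds[[lb]] <- NULL
      next
    }
    pr <- percentile_rank(v, ids = indicators$unit_id, n_bins = n_bins)
    categories[[lb]] <- pr$category
    rank_values[[lb]] <- pr$rank_value
    inverted <- lb %in% spec$label && spec$direction[spec$label == lb] == "inverted"
    thresholds[[lb]] <- threshold_bins(v, pr$cuts, inverted, n_bins)
  }
  structure(
    list(unit_id = indicators$unit_id,
         categories = as.data.frame(categories, optional = TRUE),
         rank_values = as.data.frame(rank_values, optional = TRUE),
         thresholds = thresholds,
         n_bins = n_bins),
    class = "wvi_ranked"
  )
}

## oriented-scale cuts -> raw-scale contiguous bins (low .. severe). The
## oriented scale of an inverted indicator is the negated raw scale, so the
## raw bins run downward with increasing vulnerability.
threshold_bins <- function(oriented, cuts, inverted, n_bins) {
  lo <- min(oriented, na.rm = TRUE)
  hi <- max(oriented, na.rm = TRUE)
  edges <- c(lo, cuts, hi)
  lower <- edges[seq_len(n_bins)]
  upper <- edges[seq_len(n_bins) + 1L]
  if (inverted) {
    lower <- -lower
    upper <- -upper
  }
  cat_labels <- if (n_bins == 4L) WVI_CATEGORIES else paste0("bin", seq_len(n_bins))
  data.frame(category = cat_labels, raw_lower = lower, raw_upper = upper,
             stringsAsFactors = FALSE)
}

#' @export
print.wvi_ranked <- function(x, ...) {
  cat(sprintf("<wvi_ranked> %d units x %d indicators, %d categories\n",
              length(x$unit_id), ncol(x$rank_values), x$n_bins))
  invisible(x)
}

#' Wetland vulnerability index per unit
#'
#' The WVI of a unit is the arithmetic mean of its ranked indicator values
#' (each in \{0, 1/3, 2/3, 1\}) over the indicators in `subset`; the divisor
#' is the number of indicators actually available for that unit, so units
#' with missing layers keep a defined index. A unit with no usable
#' indicators gets `NA`.
#'
#' @param ranked a `wvi_ranked` object from [rank_indicators()].
#' @param subset `"all"`, `"chronic"` (WVIC) or `"episodic"` (WVIE).
#' @return Numeric vector in `[0, 1]`, one value per unit, with attribute
#'   `n_used` (indicators contributing per unit).
#' @export
compute_wvi <- function(ranked, subset = c("all", "chronic", "episodic")) {
  subset <- match.arg(subset)
  rv <- ranked$rank_values
  if (subset != "all") {
    keep <- intersect(names(rv), indicator_class_labels(subset))
    rv <- rv[, keep, drop = FALSE]
  }
  m <- as.matrix(rv)
  n_used <- rowSums(!is.na(m))
  out <- ifelse(n_used > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  attr(out, "n_used") <- n_used
  out
}

#' Per-unit dispersion of ranked indicator values
#'
#' Population standard deviation of a unit's ranked values (0, 1/3, 2/3, 1
#' encoding) over its non-missing indicators. Low dispersion means the
#' indicator layers agree on the unit's vulnerability; the maximum, 0.5, is
#' attained when half the indicators are low and half severe.
#'
#' @param ranked a `wvi_ranked` object.
#' @return Numeric vector in `[0, 0.5]` per unit.
#' @export
rank_dispersion <- function(ranked) {
  m <- as.matrix(ranked$rank_values)
  apply(m, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
  })
}

#' Full vulnerability record table
#'
#' Combines [compute_wvi()] over the three subsets with [rank_dispersion()]
#' into the per-unit summary table: WVI, its chronic-only (WVIC) and
#' episodic-only (WVIE) variants, rank dispersion and the number of
#' indicators used. Whenever all ten indicators are present,
#' `WVI == (WVIC + WVIE) / 2`.
#'
#' @param ranked a `wvi_ranked` object.
#' @return data.frame: unit_id, WVI, WVIC, WVIE, dispersion, n_used.
#' @export
vulnerability_records <- function(ranked) {
  wvi <- compute_wvi(ranked, "all")
  data.frame(
    unit_id = ranked$unit_id,
    WVI = as.numeric(wvi),
    WVIC = as.numeric(compute_wvi(ranked, "chronic")),
    WVIE = as.numeric(compute_wvi(ranked, "episodic")),
    dispersion = rank_dispersion(ranked),
    n_used = attr(wvi, "n_used")
  )
}
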